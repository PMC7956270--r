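# Rigid molecular templates, Angstrom. Water: O-H 0.96, H-O-H 104.5 deg.
# Methanol: O-H 0.96, C-O 1.43, C-O-H 108.5 deg, C-H 1.09 tetrahedral.
water_template <- function() {
  th <- 104.5 * pi / 180
  list(xyz = rbind(c(0, 0, 0),
                   c(0.96, 0, 0),
                   c(0.96 * cos(th), 0.96 * sin(th), 0)),
       role = c("water_O", "water_H", "water_H"))
}

methanol_template <- function() {
  th <- 108.5 * pi / 180
  tc <- acos(-1 / 3)  # tetrahedral angle
  cpos <- c(1.43, 0, 0)
  hdir <- function(phi) c(cos(pi - tc),
                          sin(pi - tc) * cos(phi),
                          sin(pi - tc) * sin(phi))
  list(xyz = rbind(c(0, 0, 0),
                   0.96 * c(cos(th), sin(th), 0),
                   cpos,
                   cpos + 1.09 * hdir(pi / 2),
                   cpos + 1.09 * hdir(pi / 2 + 2 * pi / 3),
                   cpos + 1.09 * hdir(pi / 2 + 4 * pi / 3)),
       role = c("hydroxyl_O", "hydroxyl_H", "methyl_C",
                "methyl_H", "methyl_H", "methyl_H"))
}

mixture_counts <- function(n_molecules, x_methanol) {
  n_me <- round(n_molecules * x_methanol)
  c(water = n_molecules - n_me, methanol = n_me)
}

#' Box edge length from atom count and atomic number density
#' @param n_atoms total atoms.
#' @param number_density atoms per cubic Angstrom.
#' @return cubic box edge in Angstrom.
#' @export
box_from_density <- function(n_atoms, number_density) {
  (n_atoms / number_density)^(1 / 3)
}

assemble_molecules <- function(centers, rots, types) {
  tw <- water_template(); tm <- methanol_template()
  parts <- lapply(seq_along(types), function(i) {
    t <- if (types[i] == "water") tw else tm
    xyz <- t$xyz %*% t(rots[[i]])
    xyz <- sweep(xyz, 2, centers[i, ], "+")
    data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               species = ROLE_SPECIES[t$role], mol_id = i, role = t$role,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Ideal-gas configuration of rigid molecules
#'
#' Places rigid water/methanol molecules at independent uniform positions
#' with uniform random orientations: centres are completely uncorrelated, so
#' all intermolecular pair correlations are flat (g = 1) and the weighted
#' total structure factor of the intermolecular part vanishes. Used as the
#' null fixture for the distribution-function and scattering chain.
#'
#' @param n_molecules number of molecules.
#' @param number_density atomic number density (atoms per cubic Angstrom);
#'   with `n_molecules` this fixes the cubic box edge.
#' @param x_methanol methanol mole fraction (default 0: pure water).
#' @param seed integer; fully determines the output.
#' @return a `liq_configuration`.
#' @export
generate_ideal_gas <- function(n_molecules, number_density, x_methanol = 0,
                               seed = 1) {
  stopifnot(n_molecules >= 1, number_density > 0)
  cnt <- mixture_counts(n_molecules, x_methanol)
  n_at <- cnt["water"] * 3 + cnt["methanol"] * 6
  L <- box_from_density(n_at, number_density)
  if (L < 8) warning("box edge ", round(L, 2),
                     " Angstrom is below twice a molecular diameter")
  set.seed(seed)
  types <- c(rep("water", cnt["water"]), rep("methanol", cnt["methanol"]))
  centers <- matrix(stats::runif(3 * n_molecules, 0, L), ncol = 3)
  rots <- random_rotations(n_molecules)
  configuration(rep(L, 3), assemble_molecules(centers, rots, types))
}

#' Hard-core random packing of a water-methanol mixture
#'
#' Random sequential insertion of rigid molecules with a minimum
#' intermolecular O-O distance (default 2.4 Angstrom), followed by a short
#' Metropolis hard-core relaxation (random single-molecule translations,
#' rejected on overlap). Emulates the excluded-volume statistics of a dense
#' molecular liquid well enough to exercise histogramming and hydrogen-bond
#' detection on disordered input; it does not reproduce realistic liquid
#' structure.
#'
#' With `orient = "hbond"` (the default) each inserted molecule tries
#' several random orientations and keeps the one forming the most hydrogen
#' bonds (geometric criterion) to the molecules already placed, emulating
#' the orientational correlations of a hydrogen-bonded liquid: water, with
#' two donor hydrogens, then knits a denser network than methanol, and the
#' molecule-level graph contains cycles, which the ring statistics need.
#' `orient = "random"` keeps orientations uncorrelated (a pure hard-core
#' fluid).
#'
#' @inheritParams generate_ideal_gas
#' @param min_OO hard-core intermolecular O-O distance, Angstrom.
#' @param max_attempts insertion attempts per molecule before giving up.
#' @param mc_sweeps Metropolis relaxation sweeps over all molecules.
#' @param mc_step maximum displacement per Metropolis move, Angstrom.
#' @param orient "hbond" or "random", see above.
#' @param n_orientations trial orientations per molecule for
#'   `orient = "hbond"`.
#' @return a `liq_configuration`.
#' @export
generate_mixture_packing <- function(n_molecules, number_density,
                                     x_methanol = 0, seed = 1, min_OO = 2.4,
                                     max_attempts = 500, mc_sweeps = 2,
                                     mc_step = 0.4,
                                     orient = c("hbond", "random"),
                                     n_orientations = 16) {
  orient <- match.arg(orient)
  stopifnot(n_molecules >= 1, number_density > 0, x_methanol >= 0,
            x_methanol <= 1)
  cnt <- mixture_counts(n_molecules, x_methanol)
  n_at <- cnt["water"] * 3 + cnt["methanol"] * 6
  L <- box_from_density(n_at, number_density)
  box <- rep(L, 3)
  set.seed(seed)
  types <- sample(c(rep("water", cnt["water"]), rep("methanol", cnt["methanol"])))
  centers <- matrix(NA_real_, n_molecules, 3)
  # oxygens are at the molecular origin of both templates, so the hard core
  # is enforced on the centres directly
  for (i in seq_len(n_molecules)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- stats::runif(3, 0, L)
      if (i == 1 ||
          all(pbc_distances(matrix(p, 1), centers[seq_len(i - 1), , drop = FALSE],
                            box) >= min_OO)) {
        centers[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("insertion failed after ", max_attempts,
           " attempts; lower n_molecules or the density")
  }
  if (mc_sweeps > 0) {
    for (s in seq_len(mc_sweeps)) {
      for (i in seq_len(n_molecules)) {
        p <- (centers[i, ] + stats::runif(3, -mc_step, mc_step)) %% L
        d <- pbc_distances(matrix(p, 1), centers[-i, , drop = FALSE], box)
        if (all(d >= min_OO)) centers[i, ] <- p
      }
    }
  }
  if (orient == "random") {
    rots <- random_rotations(n_molecules)
    return(configuration(box, assemble_molecules(centers, rots, types)))
  }
  # hydrogen-bond-seeking orientations: greedily keep, per molecule, the
  # trial rotation that bonds most strongly to the already-placed neighbours
  tw <- water_template(); tm <- methanol_template()
  crit <- hbond_criteria()
  placed_xyz <- vector("list", n_molecules)
  placed_role <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    t <- if (types[i] == "water") tw else tm
    trial <- random_rotations(n_orientations)
    nb <- which(pbc_distances(centers[seq_len(max(0, i - 1)), , drop = FALSE],
                              matrix(centers[i, ], 1), box) <
                  crit$r_OO_max + 1.2)
    best <- 1L; best_score <- -1L
    for (k in seq_len(n_orientations)) {
      xyz <- sweep(t$xyz %*% t(trial[[k]]), 2, centers[i, ], "+")
      score <- if (length(nb))
        hbond_score(xyz, t$role, placed_xyz[nb], placed_role[nb], box, crit)
      else 0L
      if (score > best_score) { best_score <- score; best <- k }
      if (!length(nb)) break
    }
    placed_xyz[[i]] <- sweep(t$xyz %*% t(trial[[best]]), 2, centers[i, ], "+")
    placed_role[[i]] <- t$role
  }
  atoms <- do.call(rbind, lapply(seq_len(n_molecules), function(i)
    data.frame(x = placed_xyz[[i]][, 1], y = placed_xyz[[i]][, 2],
               z = placed_xyz[[i]][, 3],
               species = ROLE_SPECIES[placed_role[[i]]], mol_id = i,
               role = placed_role[[i]], stringsAsFactors = FALSE)))
  configuration(box, atoms)
}

# number of geometric hydrogen bonds (either direction) between a candidate
# molecule (xyz/roles) and a set of placed molecules
hbond_score <- function(xyz, roles, nb_xyz, nb_roles, box, crit) {
  don <- c("water_H", "hydroxyl_H")
  accO <- c("water_O", "hydroxyl_O")
  o_self <- xyz[which(roles %in% accO)[1], , drop = FALSE]
  h_self <- xyz[roles %in% don, , drop = FALSE]
  score <- 0L
  for (j in seq_along(nb_xyz)) {
    oxj <- nb_xyz[[j]][which(nb_roles[[j]] %in% accO)[1], , drop = FALSE]
    hxj <- nb_xyz[[j]][nb_roles[[j]] %in% don, , drop = FALSE]
    r_OO <- pbc_distances(o_self, oxj, box)[1, 1]
    if (r_OO >= crit$r_OO_max) next
    # self donates to neighbour
    if (nrow(h_self)) {
      rho <- pbc_distances(h_self, oxj, box)[, 1]
      ang <- bond_angle(h_self, o_self[rep(1, nrow(h_self)), , drop = FALSE],
                        oxj[rep(1, nrow(h_self)), , drop = FALSE],
                        box, crit$angle_vertex)
      score <- score + sum(rho < crit$r_OH_max & angle_passes(ang, crit))
    }
    # neighbour donates to self
    if (nrow(hxj)) {
      rho <- pbc_distances(hxj, o_self, box)[, 1]
      ang <- bond_angle(hxj, oxj[rep(1, nrow(hxj)), , drop = FALSE],
                        o_self[rep(1, nrow(hxj)), , drop = FALSE],
                        box, crit$angle_vertex)
      score <- score + sum(rho < crit$r_OH_max & angle_passes(ang, crit))
    }
  }
  score
}

#' Periodic diamond-lattice hydrogen-bond network fixture
#'
#' Oxygen sites on a diamond-cubic lattice under periodic boundary
#' conditions form a 4-coordinated network whose primitive rings are all
#' six-membered (for cells large enough that no cycle wraps the box within
#' the ring-size cap; `n_cells >= 3` guarantees this up to size 10, see the
#' methods vignette). Hydrogens are placed at bond midpoints along an ice-rule
#' (Eulerian) orientation of the lattice edges, so each oxygen donates
#' exactly two hydrogens, every molecule is a topologically valid water, and
#' every lattice edge satisfies the geometric hydrogen-bond criterion by
#' construction (collinear, O...O equal to the bond length).
#'
#' @param n_cells conventional cubic cells per box edge (default 3).
#' @param lattice_constant conventional cell edge, Angstrom; the default
#'   makes the nearest-neighbour O-O distance exactly 2.8 Angstrom.
#' @return list with `config` (a `liq_configuration`), `adjacency`
#'   (two-column matrix of bonded molecule-id pairs, the ground truth) and
#'   `lattice_constant`.
#' @export
generate_diamond_network <- function(n_cells = 3,
                                     lattice_constant = 2.8 * 4 / sqrt(3)) {
  stopifnot(n_cells >= 1)
  a <- lattice_constant
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  basis <- rbind(c(0, 0, 0), c(.25, .25, .25))
  cells <- as.matrix(expand.grid(0:(n_cells - 1), 0:(n_cells - 1),
                                 0:(n_cells - 1)))
  frac <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    do.call(rbind, lapply(seq_len(4), function(j)
      sweep(basis, 2, fcc[j, ] + cells[i, ], "+")))))
  pos <- frac * a
  box <- rep(n_cells * a, 3)
  n <- nrow(pos)
  bond <- a * sqrt(3) / 4
  D <- pbc_distances(pos, pos, box)
  adj <- which(abs(D - bond) < 1e-6 & upper.tri(D), arr.ind = TRUE)
  colnames(adj) <- c("i", "j")
  # ice-rule orientation: Eulerian circuit of the 4-regular graph gives
  # every vertex out-degree 2
  dir_edges <- eulerian_orientation(adj, n)
  atoms <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      species = "O", mol_id = seq_len(n), role = "water_O",
                      stringsAsFactors = FALSE)
  hx <- lapply(seq_len(nrow(dir_edges)), function(k) {
    u <- dir_edges[k, 1]; v <- dir_edges[k, 2]
    d <- vapply(1:3, function(ax) min_image(pos[v, ax] - pos[u, ax], box[ax]),
                numeric(1))
    h <- (pos[u, ] + d / 2) %% box
    data.frame(x = h[1], y = h[2], z = h[3], species = "H", mol_id = u,
               role = "water_H", stringsAsFactors = FALSE)
  })
  atoms <- rbind(atoms, do.call(rbind, hx))
  atoms <- atoms[order(atoms$mol_id), ]
  cfg <- configuration(box, atoms)
  list(config = cfg, adjacency = unname(as.matrix(adj)),
       lattice_constant = a)
}

# Hierholzer's algorithm: orient every edge along one Eulerian circuit.
# All vertices have even degree (4) and the graph is connected, so the
# circuit exists; each vertex then has out-degree = degree / 2 = 2.
eulerian_orientation <- function(edges, n) {
  m <- nrow(edges)
  inc <- vector("list", n)
  for (k in seq_len(m)) {
    inc[[edges[k, 1]]] <- c(inc[[edges[k, 1]]], k)
    inc[[edges[k, 2]]] <- c(inc[[edges[k, 2]]], k)
  }
  used <- logical(m)
  ptr <- rep(1L, n)
  circuit <- integer(0)          # vertex sequence
  stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]
    advanced <- FALSE
    while (ptr[v] <= length(inc[[v]])) {
      k <- inc[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      if (!used[k]) {
        used[k] <- TRUE
        w <- if (edges[k, 1] == v) edges[k, 2] else edges[k, 1]
        stack <- c(stack, w)
        advanced <- TRUE
        break
      }
    }
    if (!advanced) {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  if (length(circuit) != m + 1)
    stop("graph is not connected; no Eulerian circuit")
  cbind(circuit[-length(circuit)], circuit[-1])
}

#' Planted-ring random graph with known primitive-ring census
#'
#' Builds a graph containing vertex-disjoint planted cycles of the requested
#' sizes; all remaining vertices are attached by tree edges (uniformly random
#' parents), which cannot create new cycles. The exact primitive-ring census
#' is therefore known by construction and returned alongside the graph.
#'
#' @param n_nodes total vertices.
#' @param ring_sizes integer vector of planted cycle sizes, each in 3..10.
#' @param seed integer seed.
#' @return list with `graph` (igraph, undirected simple), `census` (named
#'   count per size) and `rings` (list of ground-truth vertex cycles).
#' @export
generate_planted_ring_graph <- function(n_nodes, ring_sizes = integer(0),
                                        seed = 1) {
  ring_sizes <- as.integer(ring_sizes)
  if (length(ring_sizes) && (any(ring_sizes < 3) || any(ring_sizes > 10)))
    stop("planted ring sizes must lie in [3, 10]")
  if (sum(ring_sizes) > n_nodes)
    stop("requested ring sizes exceed the node budget")
  set.seed(seed)
  perm <- sample.int(n_nodes)   # random labelling of all structure
  edges <- matrix(integer(0), 0, 2)
  rings <- list()
  nxt <- 1L
  for (s in ring_sizes) {
    vs <- perm[nxt:(nxt + s - 1L)]
    nxt <- nxt + s
    edges <- rbind(edges, cbind(vs, c(vs[-1], vs[1])))
    rings[[length(rings) + 1L]] <- vs
  }
  if (nxt <= n_nodes) {
    for (i in nxt:n_nodes) {
      if (i == 1L) next  # isolated root when nothing planted
      parent <- perm[sample.int(i - 1L, 1L)]
      edges <- rbind(edges, c(parent, perm[i]))
    }
  }
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  census <- table(factor(vapply(rings, length, integer(1)), levels = 3:10))
  list(graph = igraph::simplify(g),
       census = stats::setNames(as.integer(census), names(census)),
       rings = rings)
}
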