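#' Geometric hydrogen-bond criteria
#'
#' A donor O-H and acceptor O are classified as hydrogen bonded when all
#' three conditions hold: O...O distance below `r_OO_max`, H...O(acceptor)
#' distance below `r_OH_max`, and the O-H...O arrangement is near-linear.
#' Defaults are the standard geometric criterion for water/alcohol systems:
#' r_OO < 3.6 Angstrom, r_OH < 2.5 Angstrom, angle > 150 degrees.
#'
#' The linearity condition can be expressed at either vertex:
#' `angle_vertex = "hydrogen"` (default, the prevailing convention for an
#' "O-H..O angle") requires the angle at H between the covalent H->O(donor)
#' and H->O(acceptor) directions to exceed `angle_min`; `"donor"` requires
#' the angle at the donor oxygen between O->H and O->O(acceptor) to fall
#' below 180 - `angle_min` degrees, the equivalent near-linearity bound
#' phrased at the other vertex.
#'
#' @param r_OO_max,r_OH_max distance cutoffs, Angstrom.
#' @param angle_min linearity threshold, degrees, in (0, 180].
#' @param angle_vertex "hydrogen" or "donor".
#' @return a `liq_hbond_criteria` list.
#' @export
hbond_criteria <- function(r_OO_max = 3.6, r_OH_max = 2.5, angle_min = 150,
                           angle_vertex = c("hydrogen", "donor")) {
  angle_vertex <- match.arg(angle_vertex)
  stopifnot(r_OO_max > 0, r_OH_max > 0, angle_min > 0, angle_min <= 180)
  structure(list(r_OO_max = r_OO_max, r_OH_max = r_OH_max,
                 angle_min = angle_min, angle_vertex = angle_vertex),
            class = "liq_hbond_criteria")
}

#' Detect hydrogen bonds in a configuration
#'
#' Applies the geometric criterion of [hbond_criteria()] to every
#' (donor O-H, acceptor O) pair under minimum-image periodic boundary
#' conditions. Donor hydrogens are water and hydroxyl hydrogens only
#' (methyl hydrogens never donate); every oxygen is a potential acceptor;
#' intramolecular pairs are never candidates. Candidate acceptor oxygens are
#' found with a cell-list neighbour search (linear scaling in system size);
#' `method = "brute"` instead checks all donor-acceptor pairs directly and
#' exists as an independent cross-check.
#'
#' By default a donor hydrogen is assigned at most one bond (the acceptor
#' with the shortest H...O distance wins if the criterion admits several);
#' set `allow_bifurcated = TRUE` to keep all matches.
#'
#' @param cfg a `liq_configuration`.
#' @param criteria a `liq_hbond_criteria`.
#' @param method "cell" (default) or "brute".
#' @param allow_bifurcated keep multiple acceptors per donor H.
#' @return a `liq_hbond_graph`: list with `n_molecules`, `mol_type`,
#'   `edges` (data.frame: donor_mol, acceptor_mol, donor_H, r_HO, r_OO,
#'   angle), and `criteria`.
#' @export
detect_hbonds <- function(cfg, criteria = hbond_criteria(),
                          method = c("cell", "brute"),
                          allow_bifurcated = FALSE) {
  method <- match.arg(method)
  validate_configuration(cfg)
  at <- cfg$atoms
  box <- cfg$box
  don_H <- which(at$role %in% c("water_H", "hydroxyl_H"))
  acc_O <- which(at$role %in% c("water_O", "hydroxyl_O"))
  nmol <- n_molecules(cfg)
  empty <- data.frame(donor_mol = integer(0), acceptor_mol = integer(0),
                      donor_H = integer(0), r_HO = numeric(0),
                      r_OO = numeric(0), angle = numeric(0))
  if (!length(don_H) || !length(acc_O))
    return(new_hbond_graph(nmol, cfg$mol_type, empty, criteria))
  # covalent O of each donor H = the (unique) O in the same molecule
  o_by_mol <- stats::setNames(acc_O, at$mol_id[acc_O])
  don_O <- o_by_mol[as.character(at$mol_id[don_H])]
  cand <- if (method == "cell") {
    cell_candidates(atom_xyz(cfg, don_H), atom_xyz(cfg, acc_O), box,
                    criteria$r_OH_max)
  } else {
    d <- pbc_distances(atom_xyz(cfg, don_H), atom_xyz(cfg, acc_O), box)
    which(d < criteria$r_OH_max, arr.ind = TRUE)
  }
  if (!nrow(cand))
    return(new_hbond_graph(nmol, cfg$mol_type, empty, criteria))
  hi <- don_H[cand[, 1]]          # donor H atom index
  ai <- acc_O[cand[, 2]]          # acceptor O atom index
  oi <- don_O[cand[, 1]]          # covalent donor O atom index
  keep <- at$mol_id[hi] != at$mol_id[ai]
  hi <- hi[keep]; ai <- ai[keep]; oi <- oi[keep]
  if (!length(hi))
    return(new_hbond_graph(nmol, cfg$mol_type, empty, criteria))
  xh <- atom_xyz(cfg)[hi, , drop = FALSE]
  xa <- atom_xyz(cfg)[ai, , drop = FALSE]
  xo <- atom_xyz(cfg)[oi, , drop = FALSE]
  r_HO <- pbc_distances(xh, xa, box, paired = TRUE)
  r_OO <- pbc_distances(xo, xa, box, paired = TRUE)
  ang <- bond_angle(xh, xo, xa, box, criteria$angle_vertex)
  ok <- r_HO < criteria$r_OH_max & r_OO < criteria$r_OO_max &
    angle_passes(ang, criteria)
  edges <- data.frame(donor_mol = at$mol_id[hi][ok],
                      acceptor_mol = at$mol_id[ai][ok],
                      donor_H = hi[ok], r_HO = r_HO[ok], r_OO = r_OO[ok],
                      angle = ang[ok])
  if (!allow_bifurcated && nrow(edges) > 1) {
    edges <- edges[order(edges$donor_H, edges$r_HO), , drop = FALSE]
    edges <- edges[!duplicated(edges$donor_H), , drop = FALSE]
  }
  edges <- edges[order(edges$donor_mol, edges$acceptor_mol, edges$donor_H), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  new_hbond_graph(nmol, cfg$mol_type, edges, criteria)
}

new_hbond_graph <- function(nmol, mol_type, edges, criteria) {
  structure(list(n_molecules = nmol, mol_type = mol_type, edges = edges,
                 criteria = criteria), class = "liq_hbond_graph")
}

angle_passes <- function(ang, criteria) {
  if (criteria$angle_vertex == "hydrogen") ang > criteria$angle_min
  else ang < 180 - criteria$angle_min
}

# Angle in degrees at the chosen vertex. "hydrogen": angle O_d-H...O_a at H;
# "donor": angle H-O_d-O_a at the donor oxygen. All vectors minimum-image.
bond_angle <- function(xh, xo, xa, box, vertex) {
  mi <- function(m) {
    for (k in 1:3) m[, k] <- min_image(m[, k], box[k])
    m
  }
  if (vertex == "hydrogen") {
    v1 <- mi(xo - xh); v2 <- mi(xa - xh)
  } else {
    v1 <- mi(xh - xo); v2 <- mi(xa - xo)
  }
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Cell-list neighbour candidates: returns (row in A, row in B) index pairs
# with minimum-image distance below cutoff. Cells are at least `cutoff`
# wide, so only the 27 neighbouring cells need scanning.
cell_candidates <- function(A, B, box, cutoff) {
  ncell <- pmax(1L, floor(box / cutoff))
  width <- box / ncell
  cell_id <- function(X) {
    ix <- floor((X[, 1] %% box[1]) / width[1]) %% ncell[1]
    iy <- floor((X[, 2] %% box[2]) / width[2]) %% ncell[2]
    iz <- floor((X[, 3] %% box[3]) / width[3]) %% ncell[3]
    as.integer(ix + ncell[1] * (iy + ncell[2] * iz))
  }
  cb <- cell_id(B)
  b_by_cell <- split(seq_len(nrow(B)), cb)
  ca <- cell_id(A)
  ax <- floor((A[, 1] %% box[1]) / width[1]) %% ncell[1]
  ay <- floor((A[, 2] %% box[2]) / width[2]) %% ncell[2]
  az <- floor((A[, 3] %% box[3]) / width[3]) %% ncell[3]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_a <- integer(0); out_b <- integer(0)
  for (g in unique(ca)) {
    arows <- which(ca == g)
    ix <- ax[arows[1]]; iy <- ay[arows[1]]; iz <- az[arows[1]]
    neigh <- unique(as.integer(
      ((ix + offs[, 1]) %% ncell[1]) +
        ncell[1] * (((iy + offs[, 2]) %% ncell[2]) +
                      ncell[2] * ((iz + offs[, 3]) %% ncell[3]))))
    brows <- unlist(b_by_cell[as.character(neigh)], use.names = FALSE)
    if (is.null(brows) || !length(brows)) next
    d <- pbc_distances(A[arows, , drop = FALSE], B[brows, , drop = FALSE],
                       box)
    hit <- which(d < cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      out_a <- c(out_a, arows[hit[, 1]])
      out_b <- c(out_b, brows[hit[, 2]])
    }
  }
  cbind(out_a, out_b)
}

#' Molecule-level simple graph of a hydrogen-bond network
#'
#' Collapses the bond list to an undirected simple graph on molecules:
#' parallel donor/acceptor bonds between the same molecule pair merge into
#' one topological edge, the form ring analysis operates on.
#'
#' @param hb a `liq_hbond_graph`.
#' @return an igraph undirected simple graph with `n_molecules` vertices.
#' @export
hbond_molecule_graph <- function(hb) {
  g <- igraph::make_empty_graph(n = hb$n_molecules, directed = FALSE)
  if (nrow(hb$edges))
    g <- igraph::add_edges(g, t(cbind(hb$edges$donor_mol,
                                      hb$edges$acceptor_mol)))
  igraph::simplify(g)
}

#' Donor/acceptor statistics of a hydrogen-bond graph
#'
#' @param hb a `liq_hbond_graph`.
#' @return list with `by_type` (data.frame: mol_type, mean_donated,
#'   mean_accepted, mean_total), `degree_distribution` (table of total
#'   bonds per molecule) and `mean_bonds_per_molecule`.
#' @export
hbond_statistics <- function(hb) {
  don <- tabulate(hb$edges$donor_mol, nbins = hb$n_molecules)
  acc <- tabulate(hb$edges$acceptor_mol, nbins = hb$n_molecules)
  total <- don + acc
  type <- hb$mol_type[as.character(seq_len(hb$n_molecules))]
  if (length(type) == 0) type <- character(0)
  by_type <- do.call(rbind, lapply(unique(type), function(tt) {
    i <- which(type == tt)
    data.frame(mol_type = tt, n = length(i),
               mean_donated = mean(don[i]), mean_accepted = mean(acc[i]),
               mean_total = mean(total[i]))
  }))
  list(by_type = by_type,
       degree_distribution = table(total),
       mean_bonds_per_molecule =
         if (hb$n_molecules) 2 * nrow(hb$edges) / hb$n_molecules else 0)
}

#' Export a hydrogen-bond edge list as CSV
#' @param hb a `liq_hbond_graph`.
#' @param path output file.
#' @param frame frame id recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_hbond_csv <- function(hb, path, frame = 1L) {
  e <- hb$edges
  out <- data.frame(frame = rep(frame, nrow(e)),
                    donor_mol = e$donor_mol, acceptor_mol = e$acceptor_mol,
                    donor_type = hb$mol_type[as.character(e$donor_mol)],
                    acceptor_type = hb$mol_type[as.character(e$acceptor_mol)],
                    r_HO = e$r_HO, r_OO = e$r_OO, angle = e$angle)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
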