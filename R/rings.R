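as_ring_graph <- function(g) {
  if (inherits(g, "liq_hbond_graph")) return(hbond_molecule_graph(g))
  if (igraph::is_igraph(g)) return(igraph::simplify(igraph::as_undirected(g)))
  if (is.matrix(g) && ncol(g) == 2) {
    gg <- igraph::make_empty_graph(n = max(g), directed = FALSE)
    return(igraph::simplify(igraph::add_edges(gg, t(g))))
  }
  stop("expected an igraph, a two-column edge matrix, or a liq_hbond_graph")
}

canonical_ring <- function(v) {
  n <- length(v)
  k <- which.min(v)
  v <- v[c(k:n, seq_len(k - 1))]            # rotate: smallest id first
  if (n > 2 && v[n] < v[2]) v <- c(v[1], rev(v[-1]))  # direction tie-break
  v
}

ring_key <- function(v) paste(v, collapse = ",")

# TRUE iff for every vertex pair of the cycle the along-ring distance equals
# the graph shortest-path distance (the no-shortcut, "primitive" property).
is_primitive_cycle <- function(v, D) {
  n <- length(v)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ringd <- min(j - i, n - (j - i))
    if (D[v[i], v[j]] != ringd) return(FALSE)
  }
  TRUE
}

#' Enumerate primitive (shortest-path) rings of a graph
#'
#' A cycle is primitive when no pair of its vertices is connected by a path
#' shorter than the along-ring distance (no shortcut). Enumeration follows
#' the shortest-path construction used for network ring statistics: every
#' primitive ring of even size 2k consists of two vertex-disjoint geodesics
#' between a vertex and its ring antipode (distance k); every odd ring of
#' size 2k+1 consists of two geodesics from a vertex to the endpoints of its
#' antipodal edge. Candidates built this way are then verified against the
#' full shortest-path matrix and deduplicated under a canonical ordering
#' (smallest vertex first, lexicographically smaller direction).
#'
#' @param graph an igraph, a two-column edge matrix, or a
#'   `liq_hbond_graph` (collapsed to its molecule-level simple graph).
#' @param max_size largest ring size reported (default 10).
#' @return list of integer vertex cycles in canonical form, sorted.
#' @export
find_primitive_rings <- function(graph, max_size = 10) {
  if (max_size < 3) stop("max_size must be at least 3")
  g <- as_ring_graph(graph)
  n <- igraph::vcount(g)
  if (n == 0 || igraph::ecount(g) == 0) return(list())
  D <- igraph::distances(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  found <- new.env(parent = emptyenv())
  add_candidate <- function(v) {
    if (anyDuplicated(v)) return()
    if (!is_primitive_cycle(v, D)) return()
    cv <- canonical_ring(v)
    assign(ring_key(cv), cv, envir = found)
  }
  kmax <- max_size %/% 2
  for (s in seq_len(n)) {
    # all geodesics from s to every vertex within half the ring-size cap;
    # only arcs whose internal vertices exceed s can belong to a ring whose
    # smallest vertex is s
    targets <- which(D[s, ] >= 1 & D[s, ] <= kmax & seq_len(n) > s)
    if (!length(targets)) next
    aps <- igraph::all_shortest_paths(g, from = s, to = targets)$vpaths
    aps <- lapply(aps, as.integer)
    aps <- Filter(function(p)
      length(p) < 3 || all(p[2:(length(p) - 1)] > s), aps)
    byend <- split(aps, vapply(aps, function(p) p[length(p)], integer(1)))
    # even rings 2k: two internally disjoint geodesics from s to its ring
    # antipode t, d(s, t) = k >= 2
    for (t in targets) {
      k <- D[s, t]
      if (k < 2 || 2 * k > max_size) next
      ps <- byend[[as.character(t)]]
      if (is.null(ps) || length(ps) < 2) next
      for (a in seq_len(length(ps) - 1)) for (b in (a + 1):length(ps)) {
        p1 <- ps[[a]]; p2 <- ps[[b]]
        if (length(intersect(p1[-c(1, k + 1)], p2[-c(1, k + 1)])) == 0)
          add_candidate(c(p1, rev(p2[-c(1, k + 1)])))
      }
    }
    # odd rings 2k+1: geodesics from s to both endpoints of its antipodal
    # edge (u, v), d(s, u) = d(s, v) = k
    cand_e <- which(D[s, el[, 1]] == D[s, el[, 2]] &
                      D[s, el[, 1]] >= 1 &
                      2 * D[s, el[, 1]] + 1 <= max_size &
                      el[, 1] > s & el[, 2] > s)
    for (e in cand_e) {
      u <- el[e, 1]; v <- el[e, 2]
      pu <- byend[[as.character(u)]]; pv <- byend[[as.character(v)]]
      if (is.null(pu) || is.null(pv)) next
      for (p1 in pu) for (p2 in pv) {
        if (length(intersect(p1[-1], p2[-1])) == 0)
          add_candidate(c(p1, rev(p2[-1])))
      }
    }
  }
  rings <- as.list(found)
  if (length(rings)) rings <- rings[order(names(rings))]
  names(rings) <- NULL
  rings
}

#' Exhaustive primitive-ring enumeration (test oracle)
#'
#' Depth-first enumeration of every simple cycle up to `max_size` (rooted at
#' the cycle's smallest vertex, each direction once), followed by shortcut
#' filtering against the all-pairs shortest-path matrix. Exponential in ring
#' size; refuses graphs above `max_nodes`. Kept deliberately independent of
#' [find_primitive_rings()] so the two can validate each other.
#'
#' @param graph as in [find_primitive_rings()].
#' @param max_size largest ring size.
#' @param max_nodes refuse larger graphs (default 300).
#' @return list of canonical rings, sorted; identical format to
#'   [find_primitive_rings()].
#' @export
brute_force_rings <- function(graph, max_size = 10, max_nodes = 300) {
  if (max_size < 3) stop("max_size must be at least 3")
  g <- as_ring_graph(graph)
  n <- igraph::vcount(g)
  if (n > max_nodes)
    stop("graph has ", n, " nodes, above the brute-force budget of ",
         max_nodes)
  if (n == 0 || igraph::ecount(g) == 0) return(list())
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  D <- igraph::distances(g)
  cycles <- list()
  # DFS from each root r over vertices > r; a neighbour equal to r closes a
  # simple cycle. Direction dedup: require path[2] < path[end].
  for (r in seq_len(n)) {
    stack <- list(r)
    while (length(stack)) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      tip <- path[length(path)]
      for (w in adj[[tip]]) {
        if (w == r && length(path) >= 3 && path[2] < tip) {
          if (is_primitive_cycle(path, D))
            cycles[[length(cycles) + 1L]] <- canonical_ring(path)
        } else if (w > r && !(w %in% path) && length(path) < max_size) {
          stack[[length(stack) + 1L]] <- c(path, w)
        }
      }
    }
  }
  if (!length(cycles)) return(list())
  keys <- vapply(cycles, ring_key, character(1))
  cycles <- cycles[!duplicated(keys)]
  cycles[order(vapply(cycles, ring_key, character(1)))]
}

#' Ring census of a census list
#' @param rings list of rings (integer vectors).
#' @param max_size sizes reported, 3..max_size.
#' @return named integer vector of counts by size.
#' @export
ring_size_counts <- function(rings, max_size = 10) {
  sz <- vapply(rings, length, integer(1))
  tab <- table(factor(sz, levels = 3:max_size))
  stats::setNames(as.integer(tab), names(tab))
}

#' Frame-averaged primitive-ring census and participation ratios
#'
#' Runs [find_primitive_rings()] on each frame's molecule-level graph and
#' averages. Two per-size normalisations are reported: `participation`, the
#' fraction of molecules belonging to at least one primitive ring of that
#' size (the default reading of "ratio of molecules participating in
#' rings"), and `count_per_molecule`, the mean number of rings of that size
#' divided by the molecule count.
#'
#' @param graphs a `liq_hbond_graph`, igraph, or a list of them (one per
#'   frame).
#' @param max_size largest ring size (default 10).
#' @param n_molecules vertex count; inferred from `liq_hbond_graph` or
#'   igraph inputs when omitted.
#' @return a `liq_ring_census`: list with `table` (data.frame: size,
#'   mean_count, min_count, max_count, participation, count_per_molecule),
#'   `per_frame` (list of count vectors), `n_molecules`,
#'   `frames_averaged`, `rings_per_frame`.
#' @export
ring_census <- function(graphs, max_size = 10, n_molecules = NULL) {
  if (!is.list(graphs) || inherits(graphs, "liq_hbond_graph") ||
      igraph::is_igraph(graphs))
    graphs <- list(graphs)
  nf <- length(graphs)
  sizes <- 3:max_size
  counts <- matrix(0, nf, length(sizes),
                   dimnames = list(NULL, as.character(sizes)))
  part <- matrix(0, nf, length(sizes))
  rings_per_frame <- vector("list", nf)
  for (f in seq_len(nf)) {
    gf <- graphs[[f]]
    nv <- if (inherits(gf, "liq_hbond_graph")) gf$n_molecules
    else if (igraph::is_igraph(gf)) igraph::vcount(gf)
    else n_molecules
    if (is.null(nv)) stop("n_molecules must be given for edge-matrix input")
    if (is.null(n_molecules)) n_molecules <- nv
    rings <- find_primitive_rings(gf, max_size)
    rings_per_frame[[f]] <- rings
    counts[f, ] <- ring_size_counts(rings, max_size)
    sz <- vapply(rings, length, integer(1))
    for (k in seq_along(sizes)) {
      mem <- unique(unlist(rings[sz == sizes[k]]))
      part[f, k] <- length(mem) / nv
    }
  }
  tab <- data.frame(size = sizes,
                    mean_count = colMeans(counts),
                    min_count = apply(counts, 2, min),
                    max_count = apply(counts, 2, max),
                    participation = colMeans(part),
                    count_per_molecule = colMeans(counts) / n_molecules)
  rownames(tab) <- NULL
  structure(list(table = tab, per_frame = counts,
                 n_molecules = n_molecules, frames_averaged = nf,
                 rings_per_frame = rings_per_frame),
            class = "liq_ring_census")
}

#' @export
print.liq_ring_census <- function(x, ...) {
  cat(sprintf("<liq_ring_census> %d frame(s), %d molecules\n",
              x$frames_averaged, x$n_molecules))
  print(x$table, row.names = FALSE)
  invisible(x)
}
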