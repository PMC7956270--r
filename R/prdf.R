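# Species selectors: a selection is a role name, a chemical element, or one
# of the five concentration classes used for neutron weighting.
SELECTOR_ROLES <- list(
  O = c("water_O", "hydroxyl_O"),
  H = c("water_H", "hydroxyl_H", "methyl_H"),
  C = "methyl_C",
  H_water = "water_H", H_hydroxyl = "hydroxyl_H", H_methyl = "methyl_H",
  O_water = "water_O", O_hydroxyl = "hydroxyl_O")

resolve_selection <- function(cfg, sel) {
  roles <- if (sel %in% ALL_ROLES) sel
  else if (sel %in% names(SELECTOR_ROLES)) SELECTOR_ROLES[[sel]]
  else stop("unknown species selection: ", sel)
  which(cfg$atoms$role %in% roles)
}

#' Partial radial distribution function under periodic boundary conditions
#'
#' Histograms minimum-image distances between two atom selections over all
#' frames of a trajectory and normalises to the ideal-gas expectation:
#' \deqn{g_{ij}(r_k) = \langle n_{ij}(r_k)\rangle / (N_i \, 4\pi r_k^2 \Delta r \, \rho_j)}
#' with \eqn{\rho_j = (N_j - m)/V}, where m is the mean number of partner
#' atoms per centre removed from candidacy: the identical atom for a self
#' pair (giving the usual \eqn{(N_j-1)/V}), plus same-molecule partners when
#' intramolecular pairs are excluded. This keeps g = 1 exact for
#' uncorrelated molecules. Distances use the minimum-image
#' convention in an orthorhombic box; `r_max` must not exceed half the
#' shortest box edge.
#'
#' Selections may be atom roles (`"water_O"`, `"hydroxyl_H"`, ...), elements
#' (`"O"`, `"H"`, `"C"`), or the neutron-weighting classes (`"H_water"`,
#' `"H_hydroxyl"`, `"H_methyl"`, `"O_water"`, `"O_hydroxyl"`).
#'
#' @param traj a `liq_trajectory` or single `liq_configuration`.
#' @param pair character(2): the two selections.
#' @param bin_width histogram bin width, Angstrom (default 0.02).
#' @param r_max histogram range; default 0.49 x the shortest box edge.
#' @param exclude_intramolecular drop pairs within the same molecule
#'   (default TRUE; switch off when the distribution feeds total-scattering
#'   structure factors, which contain the molecular form factor).
#' @param range `"half_box"` (default): histogram up to `r_max` (at most
#'   L/2) with spherical-shell normalisation. `"full_cell"` (cubic boxes
#'   only): histogram every minimum-image pair distance, out to
#'   \eqn{\sqrt{3}L/2}, normalising each bin by the exact sphere-cube shell
#'   volume. The full-cell form counts every pair exactly once, so the
#'   pair-count sum rule holds frame by frame and the Fourier transform is
#'   free of the low-Q number-fluctuation noise of truncated histograms
#'   (see the methods vignette); it is the default input of
#'   [total_structure_factor()].
#' @return a `liq_prdf`: list with `pair`, `r` (bin centres), `g`,
#'   `counts` (raw summed pair counts, ordered pairs), `bin_width`,
#'   `rho_partner`, `n_frames`, `n_center`, `volume`, `shell_volumes`,
#'   `range`, `intramolecular_excluded`.
#' @export
compute_prdf <- function(traj, pair, bin_width = 0.02, r_max = NULL,
                         exclude_intramolecular = TRUE,
                         range = c("half_box", "full_cell")) {
  range <- match.arg(range)
  traj <- as_trajectory(traj)
  stopifnot(length(pair) == 2, bin_width > 0)
  box <- traj$frames[[1]]$box
  if (range == "full_cell") {
    if (max(abs(box - box[1])) > 1e-9 * box[1])
      stop("range = \"full_cell\" requires a cubic box")
    r_max <- sqrt(3) / 2 * box[1]
  }
  if (is.null(r_max)) r_max <- 0.49 * min(box)
  if (range == "half_box" && r_max > 0.5 * min(box) + 1e-9)
    stop("r_max must not exceed half the shortest box edge")
  if (bin_width > r_max) stop("bin_width exceeds r_max")
  nbin <- ceiling(r_max / bin_width)
  breaks <- seq(0, by = bin_width, length.out = nbin + 1)
  counts <- numeric(nbin)
  n_i <- n_j <- n_excl <- NULL
  for (cfg in traj$frames) {
    si <- resolve_selection(cfg, pair[1])
    sj <- resolve_selection(cfg, pair[2])
    if (!length(si) || !length(sj))
      stop("empty selection for pair ", paste(pair, collapse = "-"))
    n_i <- length(si); n_j <- length(sj)
    # ordered pairs removed from candidacy (self pairs, and same-molecule
    # pairs under intramolecular exclusion); the partner density is reduced
    # accordingly so that uncorrelated molecules give g = 1 exactly
    n_excl <- if (exclude_intramolecular) {
      mi <- table(cfg$atoms$mol_id[si])
      mj <- table(cfg$atoms$mol_id[sj])
      common <- intersect(names(mi), names(mj))
      sum(as.numeric(mi[common]) * as.numeric(mj[common]))
    } else {
      length(intersect(si, sj))
    }
    counts <- counts + pair_histogram(cfg, si, sj, breaks,
                                      exclude_intramolecular)
  }
  nf <- length(traj$frames)
  V <- prod(box)
  rho_j <- (n_j - n_excl / n_i) / V
  r <- breaks[-1] - bin_width / 2
  shell <- if (range == "full_cell") {
    diff(cube_sphere_volume(breaks, box[1]))
  } else {
    4 * pi * r^2 * bin_width
  }
  g <- counts / (nf * n_i * shell * rho_j)
  structure(list(pair = pair, r = r, g = g, counts = counts,
                 bin_width = bin_width, r_max = nbin * bin_width,
                 rho_partner = rho_j, n_frames = nf, n_center = n_i,
                 n_partner = n_j, volume = V, box = box,
                 shell_volumes = shell, range = range,
                 intramolecular_excluded = exclude_intramolecular),
            class = "liq_prdf")
}

# Chunked ordered-pair minimum-image histogram. Self pairs (identical atom
# index) always excluded; intramolecular pairs optionally.
pair_histogram <- function(cfg, si, sj, breaks, exclude_intra,
                           chunk = 512L) {
  box <- cfg$box
  xi <- atom_xyz(cfg, si); xj <- atom_xyz(cfg, sj)
  mi <- cfg$atoms$mol_id[si]; mj <- cfg$atoms$mol_id[sj]
  nbin <- length(breaks) - 1
  r_max <- breaks[nbin + 1]
  counts <- numeric(nbin)
  for (a in seq(1, length(si), by = chunk)) {
    b <- min(a + chunk - 1, length(si))
    d <- pbc_distances(xi[a:b, , drop = FALSE], xj, box)
    drop <- outer(si[a:b], sj, "==")
    if (exclude_intra) drop <- drop | outer(mi[a:b], mj, "==")
    d <- d[!drop]
    d <- d[d < r_max]
    if (length(d)) {
      idx <- pmin(nbin, floor(d / (r_max / nbin)) + 1L)
      counts <- counts + tabulate(idx, nbins = nbin)
    }
  }
  counts
}

#' @export
print.liq_prdf <- function(x, ...) {
  cat(sprintf("<liq_prdf> %s-%s, %d bins of %.3g A up to %.3g A, %d frame(s)%s\n",
              x$pair[1], x$pair[2], length(x$r), x$bin_width, x$r_max,
              x$n_frames,
              if (x$intramolecular_excluded) ", intramolecular excluded" else ""))
  invisible(x)
}

#' Running coordination number from a partial RDF
#'
#' \eqn{n(r_c) = 4\pi\rho_j \int_0^{r_c} g(r) r^2 \, dr}, evaluated by the
#' trapezoid rule on the histogram grid (with the exact zero at r = 0
#' prepended).
#'
#' @param prdf a `liq_prdf`.
#' @param r_cut integration limit, Angstrom (must not exceed the grid).
#' @return mean number of partner atoms within `r_cut` of a centre atom.
#' @export
coordination_number <- function(prdf, r_cut) {
  if (r_cut > prdf$r_max + 1e-9) stop("r_cut exceeds the histogram range")
  if (r_cut <= 0) return(0)
  keep <- prdf$r <= r_cut
  r <- c(0, prdf$r[keep])
  y <- c(0, prdf$g[keep] * prdf$r[keep]^2)
  4 * pi * prdf$rho_partner *
    sum(diff(r) * (y[-length(y)] + y[-1]) / 2)
}

#' Write a partial RDF as CSV
#'
#' Header comment lines record the pair, bin width, partner density, frame
#' count and intramolecular-exclusion flag.
#'
#' @param prdf a `liq_prdf`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_prdf_csv <- function(prdf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pair: %s-%s", prdf$pair[1], prdf$pair[2]),
    sprintf("# bin_width_A: %.12g", prdf$bin_width),
    sprintf("# rho_partner_A3: %.12g", prdf$rho_partner),
    sprintf("# frames: %d", prdf$n_frames),
    sprintf("# intramolecular_excluded: %s", prdf$intramolecular_excluded)),
    con)
  utils::write.csv(data.frame(r = prdf$r, g = prdf$g), con, row.names = FALSE)
  invisible(path)
}
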