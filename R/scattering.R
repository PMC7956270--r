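#' Load the shipped coherent neutron scattering lengths
#'
#' Sears-tabulation coherent scattering lengths in femtometres for H, D, C
#' and O, shipped as an editable CSV asset.
#'
#' @return named numeric vector of b_coh in fm.
#' @export
load_scattering_lengths <- function() {
  path <- system.file("extdata", "scattering_lengths.csv",
                      package = "liqstruct")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(tab$b_coh_fm, tab$isotope)
}

# element of each weighting class
CLASS_ELEMENT <- c(O = "O", H_water = "H", H_hydroxyl = "H",
                   H_methyl = "H", C = "C")

#' Neutron weighting scheme for a mixture
#'
#' Builds per-species concentrations and coherent scattering lengths for the
#' five atomic classes of a water-methanol mixture (O aggregated, the three
#' hydrogen classes kept separate so they can be deuterated independently).
#' Configurations are isotope-blind; isotope identity enters only here,
#' through `isotope_map`. The default maps every hydrogen class to deuterium,
#' matching a fully deuterated sample (D2O + CD3OD).
#'
#' @param comp a `liq_composition` or methanol mole fraction.
#' @param isotope_map named character vector assigning an isotope ("H" or
#'   "D") to each hydrogen class; entries missing default to "D".
#' @param b_table named scattering-length vector (fm); default the shipped
#'   Sears values.
#' @return a `liq_weights`: list with `species`, `c` (concentrations,
#'   sum 1), `b` (fm), and `w` (the Faber-Ziman weight matrix
#'   \eqn{c_i c_j b_i b_j / (\sum_k c_k b_k)^2}, which sums to 1 over all
#'   ordered pairs).
#' @export
scattering_weights <- function(comp,
                               isotope_map = c(H_water = "D",
                                               H_hydroxyl = "D",
                                               H_methyl = "D"),
                               b_table = load_scattering_lengths()) {
  conc <- atomic_concentrations(comp)
  species <- names(conc)
  iso <- CLASS_ELEMENT[species]
  hsel <- iso == "H"
  iso[hsel] <- ifelse(is.na(isotope_map[species[hsel]]), "D",
                      isotope_map[species[hsel]])
  b <- unname(b_table[iso])
  if (any(is.na(b))) stop("missing scattering length for isotope(s): ",
                          paste(iso[is.na(b)], collapse = ", "))
  mb <- sum(conc * b)
  if (abs(mb) < 1e-12)
    stop("mean scattering length is zero; weights undefined")
  w <- outer(conc * b, conc * b) / mb^2
  dimnames(w) <- list(species, species)
  structure(list(species = species, c = conc,
                 b = stats::setNames(b, species), w = w,
                 mean_b = mb),
            class = "liq_weights")
}

#' Fourier transform a partial RDF to a partial structure factor
#'
#' Faber-Ziman partial structure factor
#' \deqn{S_{ij}(Q) = 1 + 4\pi\rho_0 \int_0^{r_{max}} r^2 [g_{ij}(r) - 1]\,
#'   M(r)\, \frac{\sin Qr}{Qr}\, dr}
#' evaluated by trapezoid quadrature on the histogram grid. `M(r)` is 1
#' (`window = "none"`) or the Lorch damping function
#' \eqn{\sin(\pi r/r_{max})/(\pi r/r_{max})}, which suppresses truncation
#' ripples at the cost of broadening. Q = 0 uses the analytic
#' \eqn{\sin(Qr)/(Qr) \to 1} limit.
#'
#' @param prdf a `liq_prdf` (or any list with `r`, `g` fields).
#' @param rho0 total atomic number density, atoms per cubic Angstrom.
#' @param Q_grid momentum-transfer grid, inverse Angstrom (default
#'   0.1 to 20 by 0.05, the working display range).
#' @param window "none" or "lorch".
#' @return a `liq_sq`: list with `Q`, `S`, `pair`, `window`, `rho0`.
#' @export
partial_sq <- function(prdf, rho0, Q_grid = default_q_grid(),
                       window = c("none", "lorch")) {
  window <- match.arg(window)
  stopifnot(rho0 > 0)
  r <- prdf$r
  h <- prdf$g - 1
  r_max <- max(r)
  M <- if (window == "lorch") {
    u <- pi * r / r_max
    ifelse(u == 0, 1, sin(u) / u)
  } else rep(1, length(r))
  # 4 pi r^2 dr volume element: trapezoid on the uniform grid; full-cell
  # histograms instead carry exact sphere-cube shell volumes, for which the
  # histogram-sum (midpoint) form is the identity-preserving quadrature
  if (identical(prdf$range, "full_cell")) {
    vol <- prdf$shell_volumes
    integrand <- h * M * vol / (4 * pi)
    wts <- rep(1, length(r))
  } else {
    integrand <- r^2 * h * M
    wts <- rep(prdf$bin_width, length(r))
    wts[c(1, length(r))] <- prdf$bin_width / 2
  }
  S <- vapply(Q_grid, function(Q) {
    sinc <- if (Q == 0) rep(1, length(r)) else sin(Q * r) / (Q * r)
    1 + 4 * pi * rho0 * sum(integrand * sinc * wts)
  }, numeric(1))
  structure(list(Q = Q_grid, S = S, pair = prdf$pair, window = window,
                 rho0 = rho0), class = "liq_sq")
}

#' Default momentum-transfer grid
#' @return numeric vector, 0.1 to 20 inverse Angstrom in steps of 0.05.
#' @export
default_q_grid <- function() seq(0.1, 20, by = 0.05)

#' Inverse transform a partial structure factor back to r-space
#'
#' \deqn{g(r) = 1 + \frac{1}{2\pi^2\rho_0 }\int Q^2 [S(Q) - 1]
#'   \frac{\sin Qr}{Qr}\, dQ} by trapezoid quadrature; mainly used to verify
#' forward-transform fidelity on smooth distributions.
#'
#' @param sq a `liq_sq`.
#' @param r_grid target r grid, Angstrom.
#' @param rho0 atomic number density; defaults to the one stored in `sq`.
#' @return data.frame with columns `r`, `g`.
#' @export
inverse_partial_sq <- function(sq, r_grid, rho0 = sq$rho0) {
  Q <- sq$Q
  h <- sq$S - 1
  wts <- c(diff(Q) / 2, 0) + c(0, diff(Q) / 2)
  g <- vapply(r_grid, function(r) {
    sinc <- if (r == 0) rep(1, length(Q)) else sin(Q * r) / (Q * r)
    1 + sum(Q^2 * h * sinc * wts) / (2 * pi^2 * rho0)
  }, numeric(1))
  data.frame(r = r_grid, g = g)
}

#' Neutron-weighted total scattering structure factor
#'
#' Combines partial structure factors into the total
#' \deqn{F(Q) = \sum_{i \le j} (2 - \delta_{ij})\, c_i c_j b_i b_j\,
#'   [S_{ij}(Q) - 1] \, / \, (\textstyle\sum_k c_k b_k)^2}
#' under the default Faber-Ziman mean-scattering-length-squared
#' normalization; `"unnormalized"` drops the denominator (fm^2 units). The
#' normalization tag is recorded in the result since conventions differ
#' between data-reduction packages.
#'
#' @param partials named list of `liq_sq` objects; names are "A|B" pair keys
#'   over the weight species, one entry per unordered pair (see
#'   [pair_key()]).
#' @param weights a `liq_weights`.
#' @param normalization "faber_ziman_mean_b_squared" or "unnormalized".
#' @return a `liq_fq`: list with `Q`, `F`, `normalization`, `weights`,
#'   `window`.
#' @export
total_fq <- function(partials, weights,
                     normalization = c("faber_ziman_mean_b_squared",
                                       "unnormalized")) {
  normalization <- match.arg(normalization)
  sp <- weights$species
  need <- unlist(lapply(seq_along(sp), function(i)
    vapply(i:length(sp), function(j) pair_key(sp[i], sp[j]), character(1))))
  missing <- setdiff(need, names(partials))
  if (length(missing))
    stop("missing partial structure factor(s): ",
         paste(missing, collapse = ", "))
  Q <- partials[[need[1]]]$Q
  FQ <- numeric(length(Q))
  for (i in seq_along(sp)) for (j in i:length(sp)) {
    key <- pair_key(sp[i], sp[j])
    sij <- partials[[key]]
    if (!isTRUE(all.equal(sij$Q, Q)))
      stop("inconsistent Q grids across partials")
    mult <- if (i == j) 1 else 2
    num <- mult * weights$c[i] * weights$c[j] * weights$b[i] * weights$b[j]
    den <- if (normalization == "faber_ziman_mean_b_squared")
      weights$mean_b^2 else 1
    FQ <- FQ + num / den * (sij$S - 1)
  }
  structure(list(Q = Q, F = FQ, normalization = normalization,
                 weights = weights,
                 window = partials[[need[1]]]$window),
            class = "liq_fq")
}

#' Canonical unordered pair key
#' @param a,b species names.
#' @return "A|B" with the two names sorted.
#' @export
pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Full scattering chain for a trajectory
#'
#' Convenience wrapper: computes every distinct species-class partial RDF,
#' Fourier transforms each, and combines them with neutron weights into the
#' total F(Q). Intramolecular pairs are included by default because the
#' total scattering pattern contains the molecular form factor; exclude them
#' to isolate the intermolecular signal.
#'
#' @param traj trajectory or configuration.
#' @param comp a `liq_composition` or methanol mole fraction; must match the
#'   trajectory's actual composition.
#' @param rho0 atomic number density; default from box and atom count.
#' @param bin_width,Q_grid,window passed through.
#' @param exclude_intramolecular default FALSE (see above).
#' @param range histogram range convention, see [compute_prdf()]; the
#'   default `"full_cell"` keeps the transform free of low-Q truncation
#'   noise.
#' @param isotope_map passed to [scattering_weights()].
#' @return list with `fq` (`liq_fq`), `partials` (named `liq_sq` list),
#'   `prdfs` (named `liq_prdf` list), `weights`.
#' @export
total_structure_factor <- function(traj, comp, rho0 = NULL,
                                   bin_width = 0.02,
                                   Q_grid = default_q_grid(),
                                   window = "none",
                                   exclude_intramolecular = FALSE,
                                   range = "full_cell",
                                   isotope_map = c(H_water = "D",
                                                   H_hydroxyl = "D",
                                                   H_methyl = "D")) {
  traj <- as_trajectory(traj)
  cfg <- traj$frames[[1]]
  if (is.null(rho0)) rho0 <- n_atoms(cfg) / prod(cfg$box)
  weights <- scattering_weights(comp, isotope_map = isotope_map)
  sp <- weights$species
  conc_obs <- table(factor(class_of_role(cfg$atoms$role), levels = sp))
  conc_obs <- as.numeric(conc_obs) / n_atoms(cfg)
  if (max(abs(conc_obs - as.numeric(weights$c))) > 0.02)
    stop("composition mismatch: trajectory species fractions differ from ",
         "the supplied composition")
  prdfs <- list(); partials <- list()
  for (i in seq_along(sp)) for (j in i:length(sp)) {
    key <- pair_key(sp[i], sp[j])
    pr <- compute_prdf(traj, c(sp[i], sp[j]), bin_width = bin_width,
                       exclude_intramolecular = exclude_intramolecular,
                       range = range)
    prdfs[[key]] <- pr
    partials[[key]] <- partial_sq(pr, rho0, Q_grid = Q_grid, window = window)
  }
  fq <- total_fq(partials, weights)
  list(fq = fq, partials = partials, prdfs = prdfs, weights = weights)
}

class_of_role <- function(role) {
  map <- c(water_O = "O", hydroxyl_O = "O", water_H = "H_water",
           hydroxyl_H = "H_hydroxyl", methyl_H = "H_methyl",
           methyl_C = "C")
  unname(map[role])
}

#' Position and height of the first maximum of F(Q)
#'
#' Locates the discrete maximum inside `Q_range` and refines it by parabolic
#' interpolation through the three surrounding grid points, the standard
#' sub-grid peak estimator for diffraction patterns. If the maximum sits on
#' the range boundary no interior peak exists and the result is flagged.
#'
#' @param fq a `liq_fq`, or a list with `Q` and `F`.
#' @param Q_range numeric(2) search window, inverse Angstrom.
#' @return list with `position`, `height`, `boundary` (flag).
#' @export
first_peak_metrics <- function(fq, Q_range) {
  sel <- which(fq$Q >= Q_range[1] & fq$Q <= Q_range[2])
  if (length(sel) < 3) stop("Q_range covers fewer than 3 grid points")
  Fv <- fq$F[sel]; Qv <- fq$Q[sel]
  k <- which.max(Fv)
  if (k == 1 || k == length(sel))
    return(list(position = Qv[k], height = Fv[k], boundary = TRUE))
  y <- Fv[(k - 1):(k + 1)]; x <- Qv[(k - 1):(k + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom == 0)
    return(list(position = Qv[k], height = Fv[k], boundary = FALSE))
  dx <- 0.5 * (y[1] - y[3]) / denom * (x[2] - x[1])
  pos <- x[2] + dx
  ht <- y[2] - 0.25 * (y[1] - y[3]) * dx / (x[2] - x[1])
  list(position = pos, height = ht, boundary = FALSE)
}
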