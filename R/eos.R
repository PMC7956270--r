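#' Per-molecule volume from atomic number density
#'
#' The shipped density table stores atomic number densities (atoms per cubic
#' Angstrom); the Tait analysis works on per-molecule volumes,
#' \eqn{V_{mol} = \bar{n}_{atoms} / \rho_0} with
#' \eqn{\bar{n}_{atoms} = 3(1-x) + 6x} atoms per molecule at methanol mole
#' fraction x.
#'
#' @param density atomic number density, inverse cubic Angstrom.
#' @param comp a `liq_composition` or methanol mole fraction.
#' @return per-molecule volume, cubic Angstrom.
#' @export
density_to_volume <- function(density, comp) {
  stopifnot(all(density > 0))
  x <- if (inherits(comp, "liq_composition")) comp$x_methanol else comp
  atoms_per_molecule(x) / density
}

#' Modified Tait equation of state
#'
#' \deqn{1 - V(p)/V_0 = C \ln\frac{B + p}{B + p_0}}
#' with reference pressure p0 and reference volume V0 = V(p0).
#'
#' @param p pressure, GPa.
#' @param V0 reference volume.
#' @param C dimensionless Tait coefficient.
#' @param B Tait pressure parameter, GPa.
#' @param p0 reference pressure, GPa.
#' @return predicted volume at `p`.
#' @export
tait_volume <- function(p, V0, C, B, p0) {
  stopifnot(all(B + p > 0), B + p0 > 0)
  V0 * (1 - C * log((B + p) / (B + p0)))
}

#' Fit the modified Tait equation to volume-pressure data
#'
#' Least squares in relative volume: minimises
#' \eqn{\sum_i [\,(1 - V_i/V_0) - C \ln((B + p_i)/(B + p_0))\,]^2}
#' over (C, B), with V0 fixed to the measured volume at the reference
#' pressure p0 (which must be among the data points). For fixed B the
#' optimal C is linear-least-squares in closed form, so the fit profiles the
#' one-dimensional objective over a deterministic logarithmic B grid and
#' then refines the best bracket with Brent's method; no random starts, so
#' the fit is exactly reproducible.
#'
#' @param p pressures, GPa (>= 3 points).
#' @param V volumes (any consistent unit; the objective is scale-free).
#' @param p0 reference pressure, GPa; default the smallest `p`.
#' @param B_range search range for B, GPa.
#' @return a `liq_tait_fit`: list with `C`, `B`, `V0`, `p0`, `fitted`,
#'   `residuals` (relative, (V_fit - V)/V0), `max_abs_residual`, `sse`,
#'   `p`, `V`.
#' @export
fit_tait <- function(p, V, p0 = min(p), B_range = c(1e-3, 100)) {
  stopifnot(length(p) == length(V), length(p) >= 3, all(V > 0))
  i0 <- which(abs(p - p0) < 1e-12)
  if (!length(i0)) stop("p0 must be one of the supplied pressures")
  V0 <- V[i0[1]]
  y <- 1 - V / V0
  if (max(abs(y)) < 1e-12)
    stop("degenerate input: volume does not vary with pressure")
  sse_of <- function(B) {
    l <- log((B + p) / (B + p0))
    C <- sum(y * l) / sum(l^2)
    sum((y - C * l)^2)
  }
  Bgrid <- exp(seq(log(B_range[1]), log(B_range[2]), length.out = 200))
  sse <- vapply(Bgrid, sse_of, numeric(1))
  k <- which.min(sse)
  lo <- Bgrid[max(1, k - 1)]; hi <- Bgrid[min(length(Bgrid), k + 1)]
  opt <- stats::optimize(sse_of, lower = lo, upper = hi,
                         tol = .Machine$double.eps^0.5)
  B <- opt$minimum
  l <- log((B + p) / (B + p0))
  C <- sum(y * l) / sum(l^2)
  fitted <- tait_volume(p, V0, C, B, p0)
  res <- (fitted - V) / V0
  structure(list(C = C, B = B, V0 = V0, p0 = p0, fitted = fitted,
                 residuals = res, max_abs_residual = max(abs(res)),
                 sse = opt$objective, p = p, V = V),
            class = "liq_tait_fit")
}

#' @export
print.liq_tait_fit <- function(x, ...) {
  cat(sprintf("<liq_tait_fit> C = %.6g, B = %.6g GPa, V0 = %.6g at p0 = %g GPa\n",
              x$C, x$B, x$V0, x$p0))
  cat(sprintf("  max |relative residual| = %.3g over %d points\n",
              x$max_abs_residual, length(x$p)))
  invisible(x)
}

#' Tait consistency check of the shipped density table
#'
#' Converts the tabulated atomic number densities of one composition to
#' per-molecule volumes and fits the modified Tait equation, reporting the
#' fit and its residuals. This is the density-consistency analysis run over
#' the full composition grid by `analysis/01_densities_tait.R`.
#'
#' @param x_methanol mole fraction present in the shipped table.
#' @param table density table; default the shipped asset.
#' @return a `liq_tait_fit`.
#' @export
tait_check_density_table <- function(x_methanol,
                                     table = load_density_table()) {
  rows <- table[abs(table$x_methanol - x_methanol) < 1e-9, ]
  if (nrow(rows) < 3) stop("no tabulated densities for x = ", x_methanol)
  rows <- rows[order(rows$pressure_GPa), ]
  V <- density_to_volume(rows$number_density, x_methanol)
  fit_tait(rows$pressure_GPa, V, p0 = min(rows$pressure_GPa))
}
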