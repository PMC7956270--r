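# Exact volume of the intersection of a sphere of radius r with a cube of
# side L, both centred at the origin. Piecewise: full sphere up to L/2;
# minus six spherical caps up to L/sqrt(2); beyond that the caps overlap
# pairwise and the remaining area fraction is obtained by inclusion-
# exclusion with the two-cap intersection evaluated by quadrature (corner
# triple overlaps first appear only at r = sqrt(3)L/2, the largest distance
# in the cell). Used to normalise pair histograms over the full periodic
# cell, where spherical shells are clipped by the box.

# area fraction of the unit-sphere region {u_x > c, u_y > c}
two_cap_fraction <- function(c) {
  if (c >= sqrt(0.5)) return(0)
  up <- sqrt(1 - c^2)
  val <- stats::integrate(function(t) acos(pmin(1, c / sqrt(1 - t^2))),
                          lower = c, upper = up,
                          rel.tol = 1e-10, abs.tol = 1e-13,
                          stop.on.error = FALSE)$value
  2 * val / (4 * pi)
}

# fraction of the sphere of radius r (centred in a cube of side L) lying
# inside the cube
sphere_in_cube_fraction <- function(r, L) {
  c <- L / (2 * r)
  if (c >= 1) return(1)
  if (c <= 1 / sqrt(3)) return(0)
  p <- 1 - 6 * (1 - c) / 2
  if (c < sqrt(0.5)) p <- p + 12 * two_cap_fraction(c)
  p
}

#' Sphere-cube intersection volume
#'
#' Volume of a sphere of radius `r` intersected with a concentric cube of
#' side `L`. Closed form for `r <= L/sqrt(2)`; accurate quadrature of the
#' inside-area beyond. Equals the cube volume for `r >= sqrt(3)L/2`.
#'
#' @param r radii (vectorised).
#' @param L cube side.
#' @return intersection volumes.
#' @export
cube_sphere_volume <- function(r, L) {
  vapply(r, function(ri) {
    if (ri <= 0) return(0)
    if (ri >= sqrt(3) * L / 2) return(L^3)
    if (ri <= L / 2) return(4 / 3 * pi * ri^3)
    if (ri <= L / sqrt(2)) {
      h <- ri - L / 2
      return(4 / 3 * pi * ri^3 - 6 * pi * h^2 * (3 * ri - h) / 3)
    }
    v0 <- cube_sphere_volume(L / sqrt(2), L)
    v0 + stats::integrate(function(t)
      vapply(t, function(ti) 4 * pi * ti^2 * sphere_in_cube_fraction(ti, L),
             numeric(1)),
      lower = L / sqrt(2), upper = ri,
      rel.tol = 1e-9, abs.tol = 1e-12, stop.on.error = FALSE)$value
  }, numeric(1))
}
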