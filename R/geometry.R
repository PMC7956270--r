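#' Minimum-image displacement components
#'
#' Wraps per-axis differences into `(-L/2, L/2]` for an orthorhombic box.
#'
#' @param d numeric vector/matrix of coordinate differences along one axis.
#' @param L box length along that axis.
#' @return wrapped differences.
#' @keywords internal
min_image <- function(d, L) d - L * round(d / L)

#' Minimum-image distances between two coordinate sets
#'
#' Computes the full matrix (or a paired vector) of minimum-image distances
#' under orthorhombic periodic boundary conditions. Vectorised; memory is
#' O(n_a * n_b) for the matrix form.
#'
#' @param a,b numeric matrices with columns x, y, z.
#' @param box numeric(3) box lengths.
#' @param paired if TRUE, `a` and `b` must have equal rows and distances are
#'   computed row-by-row.
#' @return distance matrix (rows of `a` by rows of `b`) or vector.
#' @export
pbc_distances <- function(a, b, box, paired = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (paired) {
    d2 <- 0
    for (k in 1:3) d2 <- d2 + min_image(a[, k] - b[, k], box[k])^2
    return(sqrt(d2))
  }
  d2 <- 0
  for (k in 1:3) {
    dk <- min_image(outer(a[, k], b[, k], "-"), box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

atom_xyz <- function(cfg, sel = NULL) {
  m <- as.matrix(cfg$atoms[, c("x", "y", "z")])
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

#' Uniform random rotation matrices
#'
#' Draws rotations uniformly over SO(3) via random unit quaternions.
#'
#' @param n number of rotations.
#' @return list of 3x3 rotation matrices.
#' @keywords internal
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) {
    w <- q[i, 1]; x <- q[i, 2]; y <- q[i, 3]; z <- q[i, 4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
  })
}
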