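# Shared fixtures and independent oracles, all built in code.

# single-species point set in a cubic box (no molecular typing; PRDF-only)
mono_config <- function(xyz, L) {
  xyz <- as.matrix(xyz)
  configuration(L, data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              species = "O", mol_id = seq_len(nrow(xyz)),
                              role = "water_O"), validate = FALSE)
}

simple_cubic_config <- function(n = 5, a = 3.0) {
  g <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1))) * a
  mono_config(g, n * a)
}

# water dimer: donor at the origin with its O-H along +x; acceptor water at
# `accpos` (its own hydrogens point away, along +x and +y from its O)
water_dimer <- function(accpos, L = 40) {
  at <- data.frame(
    x = c(0, 0.96, -0.24, accpos[1], accpos[1] + 0.96, accpos[1] - 0.24),
    y = c(0, 0, 0.93, accpos[2], accpos[2], accpos[2] + 0.93),
    z = c(0, 0, 0, accpos[3], accpos[3], accpos[3]),
    species = c("O", "H", "H", "O", "H", "H"),
    mol_id = c(1, 1, 1, 2, 2, 2),
    role = rep(c("water_O", "water_H", "water_H"), 2))
  configuration(L, at)
}

# acceptor placed so that the O_d-H...O_a angle at H is `angle_deg` while
# H...O_a = d_HO
bent_dimer <- function(angle_deg, d_HO = 1.84, L = 40) {
  phi <- (180 - angle_deg) * pi / 180
  water_dimer(c(0.96 + d_HO * cos(phi), d_HO * sin(phi), 0), L)
}

# independent O(N^2) histogram oracle with explicit 27-image search
brute_prdf_counts <- function(cfg, sel_i, sel_j, breaks, exclude_intra) {
  xi <- atom_xyz(cfg, sel_i); xj <- atom_xyz(cfg, sel_j)
  box <- cfg$box
  mi <- cfg$atoms$mol_id[sel_i]; mj <- cfg$atoms$mol_id[sel_j]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbin <- length(breaks) - 1
  counts <- numeric(nbin)
  r_max <- breaks[nbin + 1]
  for (a in seq_along(sel_i)) for (b in seq_along(sel_j)) {
    if (sel_i[a] == sel_j[b]) next
    if (exclude_intra && mi[a] == mj[b]) next
    images <- t(offs %*% diag(box)) + xj[b, ]   # 3 x 27, recycled by column
    d <- min(sqrt(colSums((xi[a, ] - images)^2)))
    if (d < r_max) {
      k <- min(nbin, floor(d / (r_max / nbin)) + 1L)
      counts[k] <- counts[k] + 1
    }
  }
  counts
}

# closed-form Fourier transform of g(r) = 1 + A exp(-(r-r0)^2 / (2 s^2))
gaussian_sq_closed_form <- function(Q, rho, A, r0, s) {
  1 + (4 * pi * rho * A / Q) * sqrt(2 * pi) * s * exp(-s^2 * Q^2 / 2) *
    (r0 * sin(Q * r0) + s^2 * Q * cos(Q * r0))
}

# synthetic liq_prdf from an analytic g(r) on a uniform grid
analytic_prdf <- function(gfun, r_max = 15, dr = 0.01) {
  r <- seq(dr / 2, r_max, by = dr)
  structure(list(pair = c("O", "O"), r = r, g = gfun(r), bin_width = dr,
                 r_max = r_max, range = "half_box"),
            class = "liq_prdf")
}

sorted_edge_matrix <- function(hb) {
  e <- cbind(pmin(hb$edges$donor_mol, hb$edges$acceptor_mol),
             pmax(hb$edges$donor_mol, hb$edges$acceptor_mol))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

ring_keys <- function(rings) vapply(rings, paste, character(1), collapse = ",")
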