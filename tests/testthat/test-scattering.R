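test_that("a flat g transforms to S identically one", {
  pr <- analytic_prdf(function(r) rep(1, length(r)))
  sq <- partial_sq(pr, rho0 = 0.1)
  expect_equal(sq$S, rep(1, length(sq$Q)), tolerance = 1e-14)
  # Q = 0 uses the analytic sinc limit without warnings
  sq0 <- partial_sq(pr, rho0 = 0.1, Q_grid = c(0, 1))
  expect_equal(sq0$S, c(1, 1), tolerance = 1e-14)
})

test_that("a Gaussian peak matches its closed-form transform to 1e-3", {
  A <- 0.5; r0 <- 5; s <- 0.4; rho <- 0.03
  pr <- analytic_prdf(function(r) 1 + A * exp(-(r - r0)^2 / (2 * s^2)))
  sq <- partial_sq(pr, rho0 = rho)
  expect_lt(max(abs(sq$S - gaussian_sq_closed_form(sq$Q, rho, A, r0, s))),
            1e-3)
})

test_that("the Lorch window damps truncation ringing at high Q", {
  # g truncated mid-feature: a step that ends abruptly at r_max
  pr <- analytic_prdf(function(r) 1 + 0.5 * (r > 12), r_max = 15)
  Q <- seq(0.1, 20, by = 0.05)
  bare <- partial_sq(pr, rho0 = 0.05, Q_grid = Q, window = "none")
  lorch <- partial_sq(pr, rho0 = 0.05, Q_grid = Q, window = "lorch")
  hi <- Q > 10
  expect_lt(max(abs(lorch$S[hi] - 1)), max(abs(bare$S[hi] - 1)))
  expect_lt(mean(abs(lorch$S[hi] - 1)), mean(abs(bare$S[hi] - 1)))
})

test_that("faber-ziman weights are normalised for every composition", {
  for (x in seq(0, 1, by = 0.1)) {
    w <- scattering_weights(x)
    expect_equal(sum(w$w), 1, tolerance = 1e-12)
    expect_equal(sum(w$c), 1, tolerance = 1e-12)
  }
})

test_that("equal scattering lengths collapse the total to S - 1", {
  flat_b <- c(H = 5, D = 5, C = 5, O = 5)
  w <- scattering_weights(0.3, b_table = flat_b)
  sp <- w$species
  S <- sin(seq(0.1, 20, by = 0.05)) * 0.2 + 1
  partials <- list()
  for (i in seq_along(sp)) for (j in i:length(sp))
    partials[[pair_key(sp[i], sp[j])]] <-
      structure(list(Q = seq(0.1, 20, by = 0.05), S = S, window = "none"),
                class = "liq_sq")
  fq <- total_fq(partials, w)
  expect_equal(fq$F, S - 1, tolerance = 1e-14)
})

test_that("a single species gives F = S - 1 regardless of b", {
  w <- structure(list(species = "O", c = c(O = 1),
                      b = c(O = 5.803), mean_b = 5.803,
                      w = matrix(1, 1, 1, dimnames = list("O", "O"))),
                 class = "liq_weights")
  Q <- seq(0.5, 10, by = 0.5)
  S <- 1 + exp(-Q / 3)
  fq <- total_fq(list(`O|O` = structure(list(Q = Q, S = S, window = "none"),
                                        class = "liq_sq")), w)
  expect_equal(fq$F, S - 1, tolerance = 1e-14)
})

test_that("missing partials and mismatched compositions are rejected", {
  w <- scattering_weights(0)
  expect_error(total_fq(list(), w), "missing partial")
  cfg <- generate_ideal_gas(20, 0.1, x_methanol = 0.5, seed = 1)
  expect_error(total_structure_factor(cfg, 0), "composition mismatch")
})

test_that("deuteration changes the total but never the partials", {
  frames <- generate_ideal_gas(60, 0.1074, seed = 12)
  resD <- total_structure_factor(frames, 0, bin_width = 0.1)
  resH <- total_structure_factor(frames, 0, bin_width = 0.1,
                                 isotope_map = c(H_water = "H"))
  for (key in names(resD$partials))
    expect_identical(resD$partials[[key]]$S, resH$partials[[key]]$S)
  expect_gt(max(abs(resD$fq$F - resH$fq$F)), 0)
})

test_that("the intermolecular chain stays near zero for an ideal gas", {
  frames <- lapply(1:6, function(k) generate_ideal_gas(300, 0.1074,
                                                       seed = 40 + k))
  res <- total_structure_factor(trajectory(frames), 0, bin_width = 0.05,
                                exclude_intramolecular = TRUE)
  Q <- res$fq$Q
  # away from the lowest box modes the weighted total is flat; the lowest
  # few modes carry irreducible finite-sample number fluctuations
  expect_lt(max(abs(res$fq$F[Q >= 2])), 0.05)
  expect_lt(mean(abs(res$fq$F[Q >= 2])), 0.01)
})

test_that("the inverse transform recovers a smooth g within 2 percent RMS", {
  A <- 0.4; r0 <- 4; s <- 0.5; rho <- 0.04
  pr <- analytic_prdf(function(r) 1 + A * exp(-(r - r0)^2 / (2 * s^2)),
                      r_max = 14)
  sq <- partial_sq(pr, rho0 = rho, Q_grid = seq(0.02, 40, by = 0.02))
  rg <- seq(1.5, 12, by = 0.05)
  inv <- inverse_partial_sq(sq, rg)
  gex <- 1 + A * exp(-(rg - r0)^2 / (2 * s^2))
  expect_lt(sqrt(mean((inv$g - gex)^2)), 0.02)
})

test_that("first-peak metrics locate and track a constructed maximum", {
  Q <- seq(0.5, 4, by = 0.05)
  bump <- function(q0) exp(-(Q - q0)^2 / (2 * 0.3^2))
  p1 <- first_peak_metrics(list(Q = Q, F = bump(1.7)), c(1, 2.5))
  expect_false(p1$boundary)
  expect_equal(p1$position, 1.7, tolerance = 0.025)
  p2 <- first_peak_metrics(list(Q = Q, F = bump(1.8)), c(1, 2.5))
  expect_equal(p2$position - p1$position, 0.1, tolerance = 0.025)
  mono <- first_peak_metrics(list(Q = Q, F = Q), c(1, 2.5))
  expect_true(mono$boundary)
})

test_that("first-peak positions are extractable across the composition grid", {
  pos <- vapply(c(0, 0.3, 0.7, 1), function(x) {
    cfg <- generate_mixture_packing(120, lookup_density(x, 0.15), x,
                                    seed = 21)
    res <- total_structure_factor(cfg, x, bin_width = 0.05,
                                  exclude_intramolecular = TRUE)
    pk <- first_peak_metrics(res$fq, c(1, 3.5))
    expect_false(pk$boundary)
    pk$position
  }, numeric(1))
  expect_true(all(pos > 1 & pos < 3.5))
  # intermolecular first peak moves to lower Q with rising alcohol content
  expect_true(all(diff(pos) < 0))
})
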