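test_that("two atoms at a known separation fill exactly one bin", {
  cfg <- mono_config(rbind(c(1, 1, 1), c(4, 1, 1)), 30)
  pr <- compute_prdf(cfg, c("water_O", "water_O"), bin_width = 0.1)
  expect_equal(sum(pr$counts > 0), 1)
  expect_equal(pr$counts[pr$counts > 0], 2)       # ordered pairs
  expect_equal(pr$r[which(pr$counts > 0)], 3.05)  # bin centre holding r = 3
})

test_that("histogram counts equal the O(N^2) explicit-image oracle", {
  for (range in c("half_box", "full_cell")) {
    for (excl in c(TRUE, FALSE)) {
      cfg <- generate_ideal_gas(40, 0.08, x_methanol = 0.25,
                                seed = 17 + excl)
      pr <- compute_prdf(cfg, c("O", "H"), bin_width = 0.25,
                         exclude_intramolecular = excl, range = range)
      breaks <- seq(0, by = 0.25, length.out = length(pr$r) + 1)
      oracle <- brute_prdf_counts(cfg, resolve_selection(cfg, "O"),
                                  resolve_selection(cfg, "H"),
                                  breaks, excl)
      expect_identical(pr$counts, oracle)
    }
  }
})

test_that("pair symmetry is exact: the i-j and j-i histograms coincide", {
  cfg <- generate_ideal_gas(30, 0.09, x_methanol = 0.5, seed = 23)
  a <- compute_prdf(cfg, c("O", "H_methyl"), bin_width = 0.1)
  b <- compute_prdf(cfg, c("H_methyl", "O"), bin_width = 0.1)
  expect_identical(a$counts, b$counts)
  # normalisations differ (N_i vs N_j) but g is identical
  expect_equal(a$g, b$g, tolerance = 1e-12)
})

test_that("simple-cubic crystal: first shell sits at a with coordination 6", {
  cfg <- simple_cubic_config(5, 3.0)
  pr <- compute_prdf(cfg, c("water_O", "water_O"), bin_width = 0.02)
  first <- which(pr$counts > 0)[1]
  expect_true(abs(pr$r[first] - 3.0) <= 0.02)
  expect_equal(coordination_number(pr, 3.5), 6, tolerance = 0.05)
  # second shell: 12 neighbours at a*sqrt(2)
  expect_equal(coordination_number(pr, 4.6), 18, tolerance = 0.1)
  expect_equal(coordination_number(pr, 0), 0)
})

test_that("ideal-gas coordination follows the uniform-density integral", {
  cfg <- generate_ideal_gas(400, 0.1074, seed = 31)
  pr <- compute_prdf(cfg, c("O", "O"), bin_width = 0.05)
  r_cut <- 8
  expect_equal(coordination_number(pr, r_cut),
               4 / 3 * pi * r_cut^3 * pr$rho_partner, tolerance = 0.05)
})

test_that("frame averaging is linear in per-frame histograms", {
  f1 <- generate_ideal_gas(30, 0.1, seed = 1)
  f2 <- generate_ideal_gas(30, 0.1, seed = 2)
  both <- compute_prdf(trajectory(list(f1, f2)), c("O", "O"),
                       bin_width = 0.2)
  one <- compute_prdf(f1, c("O", "O"), bin_width = 0.2)
  two <- compute_prdf(f2, c("O", "O"), bin_width = 0.2)
  expect_equal(both$g, (one$g + two$g) / 2, tolerance = 1e-12)
})

test_that("full-cell histograms satisfy the pair-count sum rule exactly", {
  cfg <- generate_ideal_gas(25, 0.09, x_methanol = 0.4, seed = 3)
  classes <- names(atomic_concentrations(0.4))
  total <- 0
  for (cl in classes) {
    pr <- compute_prdf(cfg, c("O", cl), bin_width = 0.2,
                       exclude_intramolecular = FALSE, range = "full_cell")
    total <- total + sum(pr$counts) / pr$n_center
  }
  # every other atom seen exactly once from each centre oxygen
  expect_equal(total, n_atoms(cfg) - 1, tolerance = 1e-12)
  # and the density-weighted integral of g over the cell matches it
  pr <- compute_prdf(cfg, c("O", "H_water"), bin_width = 0.2,
                     exclude_intramolecular = FALSE, range = "full_cell")
  expect_equal(pr$rho_partner * sum(pr$g * pr$shell_volumes),
               sum(pr$counts) / pr$n_center, tolerance = 1e-9)
})

test_that("ideal-gas g stays within Poisson bands beyond molecular range", {
  frames <- lapply(1:6, function(k) generate_ideal_gas(300, 0.1074,
                                                       seed = 600 + k))
  pr <- compute_prdf(trajectory(frames), c("O", "O"), bin_width = 0.1)
  sel <- pr$r >= 5
  expected <- pr$n_frames * pr$n_center * pr$rho_partner *
    4 * pi * pr$r[sel]^2 * pr$bin_width
  dev <- abs(pr$g[sel] - 1) * sqrt(expected)
  # individual 3-sigma exceedances occur at the Poisson rate (~0.3%); with
  # ~50 bins at most one is statistically admissible
  expect_lte(sum(dev > 3), 1)
  expect_lt(max(dev), 5)
})

test_that("invalid histogram requests error cleanly", {
  cfg <- generate_ideal_gas(10, 0.05, seed = 1)
  expect_error(compute_prdf(cfg, c("O", "C")), "empty selection")
  expect_error(compute_prdf(cfg, c("O", "O"), bin_width = 30), "exceeds")
  expect_error(compute_prdf(cfg, c("O", "O"), r_max = 100),
               "half the shortest box edge")
  pr <- compute_prdf(cfg, c("O", "O"), bin_width = 0.1)
  expect_error(coordination_number(pr, 100), "exceeds")
})

test_that("prdf csv round trips through the pipeline reader", {
  cfg <- generate_ideal_gas(20, 0.1, seed = 6)
  pr <- compute_prdf(cfg, c("O", "O"), bin_width = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_prdf_csv(pr, f)
  back <- read_prdf_csv(f)
  expect_equal(back$g, pr$g, tolerance = 1e-12)
  expect_identical(back$pair, pr$pair)
  expect_equal(back$rho_partner, pr$rho_partner, tolerance = 1e-9)
})
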