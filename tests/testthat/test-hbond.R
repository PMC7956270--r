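test_that("the dimer battery classifies exactly per the geometric criterion", {
  # collinear O-H...O with O...O = 2.8 A: all three conditions hold
  hb <- detect_hbonds(water_dimer(c(2.8, 0, 0)))
  expect_equal(nrow(hb$edges), 1)
  expect_equal(hb$edges$donor_mol, 1)
  expect_equal(hb$edges$acceptor_mol, 2)
  expect_equal(hb$edges$r_OO, 2.8, tolerance = 1e-9)
  expect_equal(hb$edges$angle, 180, tolerance = 1e-6)
  # same geometry bent to 140 degrees at H: angle criterion fails
  expect_equal(nrow(detect_hbonds(bent_dimer(140))$edges), 0)
  # still bonded just above the threshold
  expect_equal(nrow(detect_hbonds(bent_dimer(155))$edges), 1)
  # O...O = 4.0 A: distance criterion fails even though collinear
  expect_equal(nrow(detect_hbonds(water_dimer(c(4.0, 0, 0)))$edges), 0)
})

test_that("methyl hydrogens never donate", {
  # methanol with acceptor water placed collinearly beyond a methyl H
  tm <- methanol_template()$xyz
  hpos <- tm[4, ]
  dirv <- (hpos - tm[3, ]) / sqrt(sum((hpos - tm[3, ])^2))
  opos <- hpos + 1.8 * dirv
  at <- data.frame(
    x = c(tm[, 1], opos[1], opos[1] + 0.96, opos[1] - 0.24),
    y = c(tm[, 2], opos[2], opos[2], opos[2] + 0.93),
    z = c(tm[, 3], opos[3], opos[3], opos[3]),
    species = c("O", "H", "C", "H", "H", "H", "O", "H", "H"),
    mol_id = c(rep(1, 6), rep(2, 3)),
    role = c("hydroxyl_O", "hydroxyl_H", "methyl_C", "methyl_H",
             "methyl_H", "methyl_H", "water_O", "water_H", "water_H"))
  cfg <- configuration(40, at)
  hb <- detect_hbonds(cfg)
  expect_false(any(hb$edges$donor_mol == 1 &
                     cfg$atoms$role[hb$edges$donor_H] == "methyl_H"))
})

test_that("cell-list detection equals the brute-force all-pairs oracle", {
  for (s in 1:4) {
    x <- c(0, 0.2, 0.5, 0.8)[s]
    cfg <- generate_mixture_packing(150, lookup_density(x, 0.4), x,
                                    seed = 50 + s)
    a <- detect_hbonds(cfg, method = "cell")
    b <- detect_hbonds(cfg, method = "brute")
    expect_identical(a$edges, b$edges)
    expect_gt(nrow(a$edges), 0)
  }
})

test_that("detection on the diamond network recovers the exact adjacency", {
  dn <- generate_diamond_network(2)
  hb <- detect_hbonds(dn$config)
  det <- sorted_edge_matrix(hb)
  gt <- t(apply(dn$adjacency, 1, sort))
  gt <- gt[order(gt[, 1], gt[, 2]), , drop = FALSE]
  expect_equal(det, gt, ignore_attr = TRUE)
  st <- hbond_statistics(hb)
  expect_true(all(st$by_type$mean_donated == 2))
  expect_true(all(st$by_type$mean_accepted == 2))
  expect_equal(names(st$degree_distribution), "4")
})

test_that("criteria monotonicity: tightening never adds, loosening never removes", {
  cfg <- generate_mixture_packing(120, lookup_density(0.2, 0.15), 0.2,
                                  seed = 77)
  base <- detect_hbonds(cfg, allow_bifurcated = TRUE)
  key <- function(hb) paste(hb$edges$donor_H, hb$edges$acceptor_mol)
  tighter <- list(hbond_criteria(r_OO_max = 3.2),
                  hbond_criteria(r_OH_max = 2.2),
                  hbond_criteria(angle_min = 160))
  looser <- list(hbond_criteria(r_OO_max = 4.0),
                 hbond_criteria(r_OH_max = 2.8),
                 hbond_criteria(angle_min = 140))
  for (cr in tighter)
    expect_true(all(key(detect_hbonds(cfg, cr, allow_bifurcated = TRUE))
                    %in% key(base)))
  for (cr in looser)
    expect_true(all(key(base) %in%
                      key(detect_hbonds(cfg, cr,
                                        allow_bifurcated = TRUE))))
})

test_that("the edge set is invariant under rigid translation modulo the box", {
  cfg <- generate_mixture_packing(100, lookup_density(0.3, 0.15), 0.3,
                                  seed = 13)
  shifted <- cfg
  shifted$atoms$x <- (shifted$atoms$x + 7.3) %% cfg$box[1]
  shifted$atoms$y <- (shifted$atoms$y - 4.1) %% cfg$box[2]
  shifted$atoms$z <- (shifted$atoms$z + 11.9) %% cfg$box[3]
  a <- detect_hbonds(cfg)
  b <- detect_hbonds(shifted)
  expect_identical(a$edges[, c("donor_mol", "acceptor_mol", "donor_H")],
                   b$edges[, c("donor_mol", "acceptor_mol", "donor_H")])
  expect_equal(a$edges$angle, b$edges$angle, tolerance = 1e-9)
})

test_that("both angle-vertex conventions accept a linear bond", {
  for (v in c("hydrogen", "donor")) {
    hb <- detect_hbonds(water_dimer(c(2.8, 0, 0)),
                        hbond_criteria(angle_vertex = v))
    expect_equal(nrow(hb$edges), 1)
  }
  # strongly bent geometry fails under both conventions
  for (v in c("hydrogen", "donor"))
    expect_equal(nrow(detect_hbonds(bent_dimer(120),
                                    hbond_criteria(angle_vertex = v))$edges),
                 0)
})

test_that("hbond statistics count dimers and empty graphs correctly", {
  hb0 <- detect_hbonds(water_dimer(c(10, 0, 0)))
  st0 <- hbond_statistics(hb0)
  expect_equal(st0$mean_bonds_per_molecule, 0)
  expect_true(all(st0$by_type$mean_total == 0))
  hb1 <- detect_hbonds(water_dimer(c(2.8, 0, 0)))
  expect_equal(hbond_statistics(hb1)$mean_bonds_per_molecule, 1)  # 2 / 2
})

test_that("bifurcated donors are suppressed unless requested", {
  # one donor H flanked by two acceptors at equal small angles
  th <- 10 * pi / 180
  d <- 1.9
  at <- data.frame(
    x = c(0, 0.96, -0.24,
          0.96 + d * cos(th), 0.96 + d * cos(th) + 0.96,
          0.96 + d * cos(th) - 0.24,
          0.96 + d * cos(th), 0.96 + d * cos(th) + 0.96,
          0.96 + d * cos(th) - 0.24),
    y = c(0, 0, 0.93,
          d * sin(th), d * sin(th), d * sin(th) + 0.93,
          -d * sin(th), -d * sin(th), -d * sin(th) + 0.93),
    z = rep(0, 9) + c(0, 0, 0, 0, 0, 0, 0.0, 0, 0),
    species = rep(c("O", "H", "H"), 3),
    mol_id = rep(1:3, each = 3),
    role = rep(c("water_O", "water_H", "water_H"), 3))
  at$z[7:9] <- at$z[7:9] + 0.01  # break exact overlap of the two acceptors
  cfg <- configuration(40, at)
  single <- detect_hbonds(cfg)
  multi <- detect_hbonds(cfg, allow_bifurcated = TRUE)
  don1 <- which(cfg$atoms$mol_id == 1 & cfg$atoms$role == "water_H")[1]
  expect_equal(sum(single$edges$donor_H == don1), 1)
  expect_equal(sum(multi$edges$donor_H == don1), 2)
})
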