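make_graph_from_edges <- function(edges, n = max(edges)) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::add_edges(g, t(edges))
}

test_that("canonical small graphs are enumerated correctly by both routes", {
  hexagon <- make_graph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 4),
                                         c(4, 5), c(5, 6), c(6, 1)))
  for (fn in list(find_primitive_rings, brute_force_rings)) {
    r <- fn(hexagon, 10)
    expect_length(r, 1)
    expect_identical(r[[1]], 1:6)
  }
  # K4: four triangles; every 4-cycle has a chord shortcut
  k4 <- igraph::make_full_graph(4)
  for (fn in list(find_primitive_rings, brute_force_rings)) {
    expect_equal(ring_size_counts(fn(k4, 10)),
                 c(`3` = 4L, `4` = 0L, `5` = 0L, `6` = 0L, `7` = 0L,
                   `8` = 0L, `9` = 0L, `10` = 0L))
  }
  # two triangles sharing an edge: the enclosing 4-cycle is short-cut
  bowtie <- make_graph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1),
                                        c(2, 4), c(4, 3)))
  for (fn in list(find_primitive_rings, brute_force_rings))
    expect_equal(unname(ring_size_counts(fn(bowtie, 10))[c("3", "4")]),
                 c(2L, 0L))
  # forest
  tree <- make_graph_from_edges(rbind(c(1, 2), c(2, 3), c(2, 4)))
  expect_length(find_primitive_rings(tree, 10), 0)
  expect_length(brute_force_rings(tree, 10), 0)
})

test_that("enumeration arguments are validated", {
  g <- igraph::make_full_graph(4)
  expect_error(find_primitive_rings(g, 2), "at least 3")
  expect_error(brute_force_rings(g, 2), "at least 3")
  big <- igraph::make_lattice(c(20, 20))
  expect_error(brute_force_rings(big, 6, max_nodes = 100), "budget")
})

test_that("fast and brute-force enumerations agree on random planted graphs", {
  set.seed(99)
  for (s in 1:40) {
    sizes <- sample(3:10, sample.int(3, 1), replace = TRUE)
    n <- sum(sizes) + sample.int(20, 1)
    pg <- generate_planted_ring_graph(n, sizes, seed = 1000 + s)
    fast <- find_primitive_rings(pg$graph, 10)
    brute <- brute_force_rings(pg$graph, 10)
    expect_identical(ring_keys(fast), ring_keys(brute))
    expect_equal(ring_size_counts(fast), pg$census)
  }
})

test_that("the census is invariant under vertex relabelling", {
  pg <- generate_planted_ring_graph(25, c(5, 8), seed = 3)
  set.seed(7)
  perm <- sample(25)
  gp <- igraph::permute(pg$graph, perm)
  expect_equal(ring_size_counts(find_primitive_rings(gp, 10)),
               ring_size_counts(find_primitive_rings(pg$graph, 10)))
})

test_that("removing a ring edge destroys exactly that ring", {
  hexagon <- make_graph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 4),
                                         c(4, 5), c(5, 6), c(6, 1)))
  cut <- igraph::delete_edges(hexagon, igraph::get_edge_ids(hexagon,
                                                            c(1, 2)))
  expect_length(find_primitive_rings(cut, 10), 0)
})

test_that("periodic diamond: both enumerations agree; 3 cells give pure 6-rings", {
  dn2 <- generate_diamond_network(2)
  hb2 <- detect_hbonds(dn2$config)
  fast <- find_primitive_rings(hb2, 10)
  brute <- brute_force_rings(hb2, 10)
  expect_identical(ring_keys(fast), ring_keys(brute))
  dn3 <- generate_diamond_network(3)
  census <- ring_census(detect_hbonds(dn3$config), max_size = 10)
  tab <- census$table
  expect_equal(tab$mean_count[tab$size == 6], 2 * 216)  # 2 rings per site
  expect_equal(sum(tab$mean_count[tab$size != 6]), 0)
  expect_equal(tab$participation[tab$size == 6], 1)
})

test_that("participation ratios follow the definition on known fixtures", {
  hexagon <- make_graph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 4),
                                         c(4, 5), c(5, 6), c(6, 1)), n = 60)
  cen <- ring_census(hexagon, max_size = 10)
  expect_equal(cen$table$participation[cen$table$size == 6], 0.1)  # 6/60
  expect_equal(cen$table$count_per_molecule[cen$table$size == 6], 1 / 60)
  # frame averaging: ring present in one of two frames
  empty <- igraph::make_empty_graph(60, directed = FALSE)
  cen2 <- ring_census(list(hexagon, empty), max_size = 10)
  expect_equal(cen2$table$participation[cen2$table$size == 6], 0.05)
  expect_equal(cen2$table$mean_count[cen2$table$size == 6], 0.5)
  expect_equal(cen2$frames_averaged, 2)
  # ring-free input: all-zero census
  cen0 <- ring_census(empty, max_size = 10)
  expect_true(all(cen0$table$mean_count == 0))
  expect_true(all(cen0$table$participation == 0))
})

test_that("denser water content yields more rings on packed mixtures", {
  nr <- function(x, s) {
    cfg <- generate_mixture_packing(250, lookup_density(x, 0.15), x,
                                    seed = s)
    length(find_primitive_rings(detect_hbonds(cfg), 10))
  }
  water_rich <- sum(vapply(1:3, function(s) nr(0.1, s), numeric(1)))
  meoh_rich <- sum(vapply(1:3, function(s) nr(0.7, s), numeric(1)))
  expect_gt(water_rich, meoh_rich)
})
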