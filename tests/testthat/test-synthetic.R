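test_that("generators are deterministic given the seed", {
  sc <- aggregation_scenario(n_peptides = 9L, n_frames = 20L, seed = 77L)
  t1 <- generate_aggregation_trajectory(sc)
  t2 <- generate_aggregation_trajectory(sc)
  expect_identical(lapply(t1$frames, `[[`, "coords"),
                   lapply(t2$frames, `[[`, "coords"))
  pot <- axial_potential_gaussian(1.5, 5, 0.8)
  b1 <- generate_boltzmann_particles(pot, 500, seed = 3L)
  b2 <- generate_boltzmann_particles(pot, 500, seed = 3L)
  expect_identical(b1$frames[[1]]$coords, b2$frames[[1]]$coords)
  b3 <- generate_boltzmann_particles(pot, 500, seed = 4L)
  expect_false(identical(b1$frames[[1]]$coords, b3$frames[[1]]$coords))
})

test_that("generator RNG use does not disturb the global RNG stream", {
  set.seed(100)
  before <- stats::runif(1)
  set.seed(100)
  invisible(generate_aggregation_trajectory(
    aggregation_scenario(n_peptides = 4L, n_frames = 3L, seed = 9L)))
  expect_identical(stats::runif(1), before)
})

test_that("without attraction and small steps no chains ever merge", {
  sc <- aggregation_scenario(attraction = 0, diffusion_step = 0.02,
                             n_frames = 100L, seed = 6L)
  cs <- cluster_count_series(generate_aggregation_trajectory(sc))
  expect_true(all(cs$n_clusters == 25L))
})

test_that("with attraction the cluster count is non-increasing and drops", {
  sc <- aggregation_scenario(attraction = 1.0, n_frames = 150L, seed = 13L)
  cs <- cluster_count_series(generate_aggregation_trajectory(sc))
  expect_true(all(diff(cs$n_clusters) <= 0))
  expect_lt(cs$n_clusters[nrow(cs)], 25L)
})

test_that("infeasible packing is rejected", {
  expect_error(generate_aggregation_trajectory(
    aggregation_scenario(n_peptides = 49L, box = c(10, 10, 11))),
    "infeasible initial packing")
})

test_that("flat-potential Boltzmann samples are uniform in z", {
  pot <- axial_potential_constant(0, z_range = c(1, 9))
  traj <- generate_boltzmann_particles(pot, 1e5, seed = 17L)
  z <- traj$frames[[1]]$coords[, 3]
  ks <- suppressWarnings(stats::ks.test(z, "punif", 1, 9))
  expect_gt(ks$p.value, 0.01)
})

test_that("a Gaussian barrier produces its antimode at the barrier centre", {
  pot <- axial_potential_gaussian(3, center = 5, width = 0.5,
                                  z_range = c(2, 8))
  traj <- generate_boltzmann_particles(pot, 5e4, seed = 18L)
  z <- traj$frames[[1]]$coords[, 3]
  h <- hist(z, breaks = seq(2, 8, by = 0.25), plot = FALSE)
  expect_lt(abs(h$mids[which.min(h$counts)] - 5), 0.5)
})

test_that("empirical bin probabilities match the integrated target density", {
  pot <- axial_potential_gaussian(2, center = 5.5, width = 0.7,
                                  z_range = c(1, 10))
  n <- 1e5
  traj <- generate_boltzmann_particles(pot, n, temperature = 310, seed = 19L)
  z <- traj$frames[[1]]$coords[, 3]
  edges <- seq(1, 10, length.out = 31)
  counts <- hist(z, breaks = edges, plot = FALSE)$counts
  # numerically integrate exp(-U/RT) over each bin
  p_exact <- vapply(seq_len(30), function(k)
    stats::integrate(function(zz)
      exp(-eval_potential(pot, zz) / (R_KCAL * 310)),
      edges[k], edges[k + 1])$value, numeric(1))
  p_exact <- p_exact / sum(p_exact)
  se <- sqrt(p_exact * (1 - p_exact) / n)
  expect_true(all(abs(counts / n - p_exact) <= 4 * se + 1e-12))
})

test_that("the pore scene encloses the requested lumen and stays vertical", {
  pore <- generate_pore_scene(7, lumen_radius = 0.55)
  pr <- pore_radius(pore$frames[[1]], pore$topology, 1:7,
                    grid_spacing = 0.02)
  expect_equal(pr$status, "ok")
  expect_equal(pr$radius_nm, 0.55, tolerance = 0.05)
  expect_error(generate_pore_scene(2), "n_peptides")
  expect_error(generate_pore_scene(7, lumen_radius = -1), "lumen_radius")
})

test_that("the fiber scene is collinear, parallel and unenclosed", {
  fib <- generate_fiber_scene(6, spacing = 0.9)
  coms <- chain_coms(fib$frames[[1]], fib$topology)
  expect_true(all(abs(diff(coms[, 2])) < 1e-12))
  expect_equal(diff(coms[, 1]), rep(0.9, 5), ignore_attr = TRUE)
  expect_equal(order_parameter(fib$frames[[1]], fib$topology, 1:6), 1,
               tolerance = 1e-6)
  pr <- pore_radius(fib$frames[[1]], fib$topology, 1:6)
  expect_equal(pr$radius_nm, 0)
  expect_match(pr$status, "no")
})

test_that("axial potentials evaluate their functional forms", {
  pc <- axial_potential_constant(1.2, c(0, 5))
  expect_equal(eval_potential(pc, c(0, 2.5, 5)), rep(1.2, 3))
  pg <- axial_potential_gaussian(2, 3, 0.5, c(0, 6), baseline = 0.3)
  expect_equal(eval_potential(pg, 3), 2.3)
  expect_equal(eval_potential(pg, 300), 0.3, tolerance = 1e-12)
  pt <- axial_potential_table(c(0, 1, 2), c(0, 1, 0))
  expect_equal(eval_potential(pt, 0.5), 0.5)
  expect_error(axial_potential_table(c(0, 1), c(0, Inf)))
})
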