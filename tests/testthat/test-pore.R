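test_that("axial density is flat for a homogeneous system", {
  pot <- axial_potential_constant(0, z_range = c(0, 10))
  traj <- generate_boltzmann_particles(pot, 1e5, lateral_radius = 1.5,
                                       seed = 61L)
  dp <- axial_density(traj, "water", 3, 7, n_bins = 10, cylinder_radius = 1.5,
                      bulk_cross_section = "cylinder")
  expect_true(all(abs(dp$profile$rho_over_bulk - 1) < 0.1))
})

test_that("an empty channel yields zero density and an error on inversion", {
  top <- make_chain_topology(1L, n_water = 50L)
  set.seed(62)
  coords <- rbind(c(5, 5, 0.5),
                  cbind(stats::runif(50, 0, 10), stats::runif(50, 0, 10),
                        stats::runif(50, 0, 1)))  # all water below z = 1
  traj <- trajectory(top, list(traj_frame(0, c(10, 10, 10), coords)))
  dp <- axial_density(traj, "water", 3, 7, n_bins = 5, cylinder_radius = 3)
  expect_true(all(dp$profile$rho == 0))
  expect_error(density_pmf(dp), "empty")
  expect_error(axial_density(traj, "ion", 3, 7), "no particles")
})

test_that("density-based PMF reproduces closed forms", {
  top <- make_chain_topology(1L, n_water = 10L)
  dp <- structure(list(
    profile = data.frame(z_nm = c(1, 2), rho = c(2, 1),
                         rho_over_bulk = c(1, 0.5)),
    rho_bulk = 2, species = "water", z_lo = 0.5, z_hi = 2.5,
    cylinder_radius = 1, center_xy = c(5, 5), bulk_margin = 1,
    bulk_cross_section = "box", n_frames = 1L),
    class = "mp_density_profile")
  pmf <- density_pmf(dp, 310)
  expect_equal(pmf$profile$dG_kcal_mol[1], 0)
  expect_equal(pmf$profile$dG_kcal_mol[2], R_KCAL * 310 * log(2),
               tolerance = 1e-6)
  expect_equal(pmf$barrier, R_KCAL * 310 * log(2), tolerance = 1e-6)
})

test_that("PMF recovery: Boltzmann ensemble returns the generating barrier", {
  pot <- axial_potential_gaussian(2.5, center = 4.4, width = 0.6,
                                  z_range = c(0, 11))
  traj <- generate_boltzmann_particles(pot, 1e5, temperature = 310,
                                       lateral_radius = 1.0, seed = 1L)
  dp <- axial_density(traj, "water", 2.32, 6.55, n_bins = 17,
                      cylinder_radius = 1.0, bulk_cross_section = "cylinder")
  pmf <- density_pmf(dp, 310)
  expect_equal(pmf$barrier, 2.5, tolerance = 0.15)
  # per-bin: dG should track U(z) - min U within a few standard errors
  ref <- eval_potential(pot, dp$profile$z_nm)
  defined <- !is.na(pmf$profile$dG_kcal_mol)
  expect_lt(stats::median(abs(pmf$profile$dG_kcal_mol[defined] -
                              ref[defined])), 0.1)
})

test_that("permeation counting resolves hand-built crossings", {
  # one particle moving monotonically through the slab: one +z event
  z1 <- seq(1, 8, length.out = 15)
  traj <- make_scripted_water_trajectory(matrix(z1, 1), box = c(10, 10, 10))
  ev <- count_permeation_events(traj, "water", 2.32, 6.55,
                                cylinder_radius = 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "+z")
  expect_lt(ev$entry_time_ns, ev$exit_time_ns)
  # aborted crossing: enters from below, retreats below z_lo
  z2 <- c(1, 2, 4, 3, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  traj2 <- make_scripted_water_trajectory(matrix(z2, 1), box = c(10, 10, 10))
  expect_equal(nrow(count_permeation_events(traj2, "water", 2.32, 6.55, 1)),
               0L)
  # crossing the periodic boundary is not a slab traversal
  z3 <- c(1, 0.5, 9.8, 9, 8, 8, 8, 8, 8, 8, 8, 8, 8, 8, 8)
  traj3 <- make_scripted_water_trajectory(matrix(z3, 1), box = c(10, 10, 10))
  expect_equal(nrow(count_permeation_events(traj3, "water", 2.32, 6.55, 1)),
               0L)
  # leaving the cylinder mid-traversal invalidates the event
  z4 <- seq(1, 8, length.out = 15)
  in_cyl <- matrix(TRUE, 1, 15); in_cyl[1, 8] <- FALSE
  traj4 <- make_scripted_water_trajectory(matrix(z4, 1), in_cyl,
                                          box = c(10, 10, 10))
  expect_equal(nrow(count_permeation_events(traj4, "water", 2.32, 6.55, 1)),
               0L)
})

test_that("permeation counts are invariant to frame-wise rewrapping", {
  set.seed(63)
  nt <- 60L
  z <- matrix(NA_real_, 5, nt)
  for (p in 1:5) z[p, ] <- cumsum(c(stats::runif(1, 0, 10),
                                    stats::rnorm(nt - 1, 0.15, 0.4)))
  traj_wrapped <- make_scripted_water_trajectory(z %% 10, box = c(10, 10, 10))
  traj_raw <- make_scripted_water_trajectory(z, box = c(10, 10, 10))
  e1 <- count_permeation_events(traj_wrapped, "water", 2.32, 6.55, 2)
  e2 <- count_permeation_events(traj_raw, "water", 2.32, 6.55, 2)
  expect_equal(nrow(e1), nrow(e2))
  expect_equal(e1$direction, e2$direction)
})

test_that("pore radius scales with the constructed lumen and converges", {
  pore <- generate_pore_scene(9, lumen_radius = 0.6)
  pr <- pore_radius(pore$frames[[1]], pore$topology, 1:9, 0.02)
  expect_equal(pr$radius_nm, 0.6, tolerance = 0.05)
  # doubling the lumen doubles the estimate
  pore2 <- generate_pore_scene(9, lumen_radius = 1.2)
  pr2 <- pore_radius(pore2$frames[[1]], pore2$topology, 1:9, 0.02)
  expect_equal(pr2$radius_nm / pr$radius_nm, 2, tolerance = 0.1)
  # halving the grid spacing changes the estimate by < 2%
  pr_half <- pore_radius(pore$frames[[1]], pore$topology, 1:9, 0.01)
  expect_lt(abs(pr_half$radius_nm - pr$radius_nm) / pr$radius_nm, 0.02)
  expect_error(pore_radius(pore$frames[[1]], pore$topology, 1:2), ">= 3")
})

test_that("direct-contact counting uses a strict minimum-image cutoff", {
  top <- make_chain_topology(3L, beads = 2L, n_water = 3L)
  pep <- rbind(c(5, 5, 5), c(5, 5, 5.3),
               c(6, 5, 5), c(6, 5, 5.3),
               c(7, 5, 5), c(7, 5, 5.3))
  wat <- rbind(c(5, 5, 5.6),    # 0.3 nm above a bead: contact
               c(5, 5.4, 5.3),  # exactly 0.4 nm: not a contact (strict <)
               c(0.2, 5, 5))    # near image of x=7 bead? 4.8 nm away: no
  fr <- traj_frame(0, c(10, 10, 10), rbind(pep, wat))
  cc <- channel_contacts(fr, top, 1:3, "water", 0.4)
  expect_identical(cc$in_contact, c(TRUE, FALSE, FALSE))
  expect_equal(cc$n_contact, 1L)
  expect_error(channel_contacts(fr, top, integer(0), "water"), "empty cluster")
})

test_that("contact flags equal the brute-force all-pairs oracle", {
  set.seed(64)
  box <- c(8, 8, 8)
  top <- make_chain_topology(2L, beads = 14L, n_water = 1000L)
  pep <- matrix(stats::runif(28 * 3, 3, 5), ncol = 3)
  wat <- cbind(stats::runif(1000, 0, 8), stats::runif(1000, 0, 8),
               stats::runif(1000, 0, 8))
  fr <- traj_frame(0, box, rbind(pep, wat))
  cc <- channel_contacts(fr, top, 1:2, "water", 0.4)
  want <- vapply(seq_len(1000), function(i) {
    any(vapply(seq_len(28), function(j)
      brute_min_image_distance(wat[i, ], pep[j, ], box) < 0.4, logical(1)))
  }, logical(1))
  expect_identical(cc$in_contact, want)
})
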