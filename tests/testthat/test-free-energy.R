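test_that("histogram2d handles delta, split and uniform inputs", {
  h <- histogram2d(rep(2.5, 40), rep(1.1, 40), bins = c(10, 10))
  expect_equal(sum(h$P), 1, tolerance = 1e-12)
  expect_equal(sum(h$P > 0), 1L)
  expect_equal(max(h$P), 1)

  h2 <- histogram2d(rep(c(0, 1), each = 500), rep(0.5, 1000), bins = c(2, 2))
  expect_equal(sort(h2$P[h2$P > 0]), c(0.5, 0.5))

  set.seed(51)
  n <- 1e4
  h3 <- histogram2d(stats::runif(n), stats::runif(n), bins = c(5, 5),
                    xlim = c(0, 1), ylim = c(0, 1))
  se <- sqrt((1 / 25) * (1 - 1 / 25) / n)
  expect_true(all(abs(h3$P - 1 / 25) < 5 * se))
  expect_error(histogram2d(numeric(0), numeric(0)))
})

test_that("Boltzmann inversion satisfies the closed-form pair relation", {
  # uniform -> flat surface at 0
  P <- matrix(1 / 12, 3, 4)
  ls <- boltzmann_invert(P, 310)
  expect_true(all(abs(ls$W) < 1e-12))
  # probability ratio e^-1 at 310 K -> dG = R*T
  P2 <- matrix(0, 2, 1)
  P2[1, 1] <- 1 / (1 + exp(-1)); P2[2, 1] <- exp(-1) / (1 + exp(-1))
  ls2 <- boltzmann_invert(P2, 310)
  expect_equal(ls2$W[2, 1] - ls2$W[1, 1], R_KCAL * 310, tolerance = 1e-6)
  expect_error(boltzmann_invert(matrix(0, 2, 2)), "all-empty")
})

test_that("re-exponentiating W recovers P on occupied bins", {
  set.seed(52)
  counts <- matrix(rpois(100, 40), 10, 10)
  ls <- boltzmann_invert(counts / sum(counts), 310)
  P_back <- exp(-ls$W / ls$RT)
  P_back[!ls$occupied] <- 0
  P_back <- P_back / sum(P_back)
  expect_equal(P_back[ls$occupied], ls$P[ls$occupied], tolerance = 1e-12)
  expect_equal(min(ls$W, na.rm = TRUE), 0)
})

test_that("basin finding returns construction minima and collapses plateaus", {
  # flat landscape: every bin tied -> a single basin
  ls_flat <- boltzmann_invert(matrix(1 / 25, 5, 5), 310)
  expect_equal(nrow(find_basins(ls_flat)), 1L)
  # two-Gaussian-well surface: exactly 2 basins at the construction centres
  surf <- fel_reference_surface()
  xy <- sample_landscape(surf, 2e5, seed = 53)
  ls <- boltzmann_invert(histogram2d(xy$x, xy$y, c(40, 40)), 310)
  b <- find_basins(ls, min_separation = 3, max_w = 2)
  expect_equal(nrow(b), 2L)
  expect_equal(b$x, surf$centers[, 1], tolerance = 0.1)
  expect_equal(b$y, surf$centers[, 2], tolerance = 0.1)
  # single well
  g <- outer(seq(-2, 2, length.out = 21), seq(-2, 2, length.out = 21),
             function(x, y) exp(-(x^2 + y^2)))
  ls1 <- boltzmann_invert(g / sum(g), 310)
  expect_equal(nrow(find_basins(ls1)), 1L)
  expect_equal(find_basins(ls1)$ix, 11L)
})

test_that("barrier heights come from the minimax saddle path", {
  # monotonic valley: forward barrier = dW, backward = 0
  W <- matrix(NA_real_, 1, 5)
  W[1, ] <- c(0, 0.5, 1.0, 1.5, 2.0)
  ls <- list(W = W, occupied = !is.na(W))
  class(ls) <- "mp_landscape"
  br <- barrier_height(ls, c(1, 1), c(1, 5))
  expect_equal(br$forward, 2.0)
  expect_equal(br$backward, 0)
  # identical basins: zero barrier
  br0 <- barrier_height(ls, c(1, 3), c(1, 3))
  expect_equal(br0$forward, 0)
  # ridge with a known saddle
  W2 <- rbind(c(0.0, 3.0, 0.5),
              c(2.0, 1.2, 2.5),
              c(0.4, 3.0, 0.1))
  ls2 <- list(W = W2, occupied = matrix(TRUE, 3, 3))
  class(ls2) <- "mp_landscape"
  br2 <- barrier_height(ls2, c(1, 1), c(3, 3))
  expect_equal(br2$saddle, dfs_minimax(W2, c(1, 1), c(3, 3)))
  # disconnected basins: infinite barrier with diagnostic
  W3 <- matrix(c(0, NA, 1), 1, 3)
  ls3 <- list(W = W3, occupied = !is.na(W3))
  class(ls3) <- "mp_landscape"
  br3 <- barrier_height(ls3, c(1, 1), c(1, 3))
  expect_false(br3$connected)
  expect_true(is.infinite(br3$forward))
})

test_that("minimax saddle is symmetric and consistent with basin depths", {
  set.seed(54)
  for (k in 1:20) {
    W <- matrix(stats::runif(16, 0, 5), 4, 4)
    ls <- list(W = W, occupied = matrix(TRUE, 4, 4))
    class(ls) <- "mp_landscape"
    a <- c(sample(4, 1), sample(4, 1))
    b <- c(sample(4, 1), sample(4, 1))
    f <- barrier_height(ls, a, b)
    r <- barrier_height(ls, b, a)
    expect_equal(f$saddle, r$saddle, tolerance = 1e-12)
    expect_equal(f$forward - f$backward, W[b[1], b[2]] - W[a[1], a[2]],
                 tolerance = 1e-12)
    expect_gte(f$forward, -1e-12)
    expect_gte(f$backward, -1e-12)
  }
})

test_that("threshold-connectivity oracle agrees with DFS path enumeration", {
  set.seed(55)
  for (k in 1:10) {
    W <- matrix(stats::runif(9, 0, 3), 3, 3)
    a <- c(1, 1); b <- c(3, 3)
    expect_equal(threshold_minimax(W, a, b), dfs_minimax(W, a, b))
  }
})

test_that("sampled two-basin landscape recovers the prescribed surface", {
  surf <- fel_reference_surface(depth_difference = 1.0, barrier = 2.5)
  xy <- sample_landscape(surf, 2e5, temperature = 310, seed = 56)
  ls <- boltzmann_invert(histogram2d(xy$x, xy$y, c(50, 50)), 310)
  # expected bin probabilities by numerical integration of exp(-W0/RT)
  # over each bin (5x5 subgrid), so the only discrepancy left is noise
  RT <- R_KCAL * 310
  wx <- diff(ls$x_edges)[1]; wy <- diff(ls$y_edges)[1]
  sub <- (1:5 - 3) / 5
  occ <- which(ls$counts >= 100, arr.ind = TRUE)
  p_true <- apply(occ, 1, function(ij) {
    xs <- ls$x_centers[ij[1]] + sub * wx
    ys <- ls$y_centers[ij[2]] + sub * wy
    mean(exp(-outer(xs, ys, surf$fun) / RT))
  })
  w_true <- -RT * log(p_true)
  w_got <- ls$W[occ]
  dev <- (w_got - min(w_got)) - (w_true - min(w_true))
  # per-bin 5-standard-error bound on the inverted counts
  se <- RT / sqrt(ls$counts[occ])
  expect_true(all(abs(dev) <= 5 * se + 0.02))
})
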