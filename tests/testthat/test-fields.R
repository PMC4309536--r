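empty_rasters <- function(n) {
  list(I_CT = matrix(0L, n, n), I_Cm = matrix(0L, n, n),
       node_i = integer(0), node_j = integer(0))
}

test_that("a uniform field with no sources follows the exact decay law", {
  fs <- tiny_field(n = 21, L = 2)
  K0 <- 3.7
  fs$K <- matrix(K0, 21, 21)
  dt <- 0.5
  for (k in 1:10) fs <- step_fields(fs, empty_rasters(21), NULL, dt = dt)
  expect_lt(max(abs(fs$K - K0 * exp(-fs$params$mu_K * 5))), 1e-10)
  expect_equal(fs$clamp_events, 0L)
})

test_that("zero-flux stepping conserves mass when reactions are off", {
  fs <- tiny_field(n = 31, L = 3, mu_C = 0)
  set.seed(4)
  fs$C <- matrix(runif(31 * 31), 31, 31)
  total0 <- sum(fs$C)
  for (k in 1:20) {
    fs <- step_fields(fs, empty_rasters(31), NULL, dt = 0.5)
    expect_equal(sum(fs$C), total0, tolerance = 1e-10)
  }
})

test_that("matrix density relaxes logistically to carrying capacity", {
  fs <- tiny_field(n = 11, L = 1)
  fs$rho <- matrix(0.3 * fs$params$rho_star, 11, 11)
  prev <- fs$rho[1, 1]
  for (k in 1:30) {
    fs <- step_fields(fs, empty_rasters(11), NULL, dt = 0.1)
    expect_gte(fs$rho[1, 1], prev)  # monotone without proteinase
    prev <- fs$rho[1, 1]
  }
  expect_equal(prev, fs$params$rho_star, tolerance = 1e-6)
  # strong proteinase degrades the matrix instead
  fs$P <- matrix(1e-4, 11, 11)
  before <- fs$rho[1, 1]
  fs <- step_fields(fs, empty_rasters(11), NULL, dt = 0.1)
  expect_lt(fs$rho[1, 1], before)
})

test_that("proteinase is produced only on invasive-cell sites", {
  fs <- tiny_field(n = 21, L = 2)
  cells <- new_cells(c(1000, 1500), c(1000, 1500))  # positions in um
  cells$phase <- c("Tm", "Tp")
  rast <- rasterize_cells(cells, fs)
  expect_equal(sum(rast$I_CT), 2L)
  expect_equal(sum(rast$I_Cm), 1L)
  # apoptotic cells are excluded from both rasters
  cells$status[1] <- "apoptotic"
  rast2 <- rasterize_cells(cells, fs)
  expect_equal(sum(rast2$I_CT), 1L)
  expect_equal(sum(rast2$I_Cm), 0L)
  # no cells at all
  rast0 <- rasterize_cells(cells[0, ], fs)
  expect_equal(sum(rast0$I_CT) + sum(rast0$I_Cm), 0L)
})

test_that("sampling is exact on linear fields and rejects outside points", {
  fs <- tiny_field(n = 21, L = 2)
  cgrid <- outer(fs$xs, rep(1, 21)) * 3.5  # C = 3.5 x
  fs$C <- cgrid
  pts_x <- c(0.3, 1.1, 1.9); pts_y <- c(0.2, 1.0, 1.7)
  expect_equal(sample_field(fs, "C", pts_x, pts_y), 3.5 * pts_x,
               tolerance = 1e-12)
  g <- sample_gradient(fs, "C", c(0.5, 1.3), c(0.5, 1.1))
  expect_equal(g[, 1], c(3.5, 3.5), tolerance = 1e-10)
  expect_equal(g[, 2], c(0, 0), tolerance = 1e-12)
  # uniform field: zero gradient everywhere
  fs$G <- matrix(2, 21, 21)
  gu <- sample_gradient(fs, "G", c(0.1, 1.9), c(0.1, 1.9))
  expect_equal(max(abs(gu)), 0)
  expect_error(sample_field(fs, "C", 2.5, 0.5), "outside")
})

test_that("a steady point injection decays radially toward the source", {
  # fast-decaying tracer so the zero-flux boundary (5 mm away) is far
  # relative to the decay length (0.63 mm) and the infinite-domain
  # modified-Bessel profile applies
  fs <- field_state(L = 10, n = 101, params = field_params(mu_C = 4.2e-4))
  src <- source_footprint(fs, matrix(c(5, 5), 1, 2), sigma = 0.1)
  p <- fs$params
  Cst <- steady_field(fs, p$D_C, p$mu_C, p$l_in_C * src)
  fs$C <- Cst
  # values decrease with radius; gradient points toward the source
  radii <- c(0.7, 1.2, 1.8, 2.6)
  vals <- sample_field(fs, "C", 5 + radii, rep(5, 4))
  expect_true(all(diff(vals) < 0))
  g <- sample_gradient(fs, "C", 5 + radii, rep(5, 4))
  expect_true(all(g[, 1] < 0))
  # modified-Bessel reference: ratios of mid-range values match the
  # analytic K0 profile of a 2-D point source away from boundaries
  kappa <- sqrt(p$mu_C / p$D_C)
  want <- besselK(kappa * radii, 0)
  expect_equal(vals[2] / vals[3], want[2] / want[3], tolerance = 0.05)
  expect_equal(vals[3] / vals[4], want[3] / want[4], tolerance = 0.05)
})

test_that("the discrete steady field is a fixed point of the stepper", {
  fs <- field_state(L = 10, n = 51)
  src_sites <- matrix(c(3, 3, 7, 6), 2, 2, byrow = TRUE)
  W <- source_footprint(fs, src_sites, sigma = 0.1)
  p <- fs$params
  dt <- 0.5
  fs$G <- discrete_steady_field(fs, p$D_G, p$mu_G, p$r_G * W, dt)
  vessels <- list(I_B = (W > 0.999) * 1L, W_B = W)
  before <- fs$G
  fs2 <- step_fields(fs, empty_rasters(51), vessels, dt = dt)
  expect_equal(max(abs(fs2$G - before)) / max(before), 0, tolerance = 1e-10)
})

test_that("glucose-to-signal mapping is anchored, capped and monotone", {
  expect_equal(glucose_to_signal(2.4, G_ref = 2.4), 1.0)
  expect_equal(glucose_to_signal(0, G_ref = 2.4), 0.0)
  expect_equal(glucose_to_signal(0.45 * 2.4, G_ref = 2.4), 0.45)
  expect_equal(glucose_to_signal(10, G_ref = 2.4), 1.2)  # capped
  x <- seq(0, 5, by = 0.1)
  expect_true(all(diff(glucose_to_signal(x, 2.4)) >= 0))
})

test_that("negative excursions are clamped and counted", {
  fs <- tiny_field(n = 11, L = 1)
  fs$G <- matrix(1e-9, 11, 11)
  cells <- new_cells(500, 500)
  rast <- rasterize_cells(cells, fs)
  counts <- matrix(0, 11, 11)
  counts[rast$node_i[1], rast$node_j[1]] <- 1e7  # absurd density
  fs2 <- step_fields(fs, rast, NULL, dt = 0.5, n_cells_per_node = counts)
  expect_gt(fs2$clamp_events, 0)
  expect_true(all(fs2$G >= 0))
})
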