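test_that("neighbour search matches the distance definition", {
  one <- new_cells(0, 0)
  expect_equal(nrow(neighbor_pairs(one, 25)), 0L)

  # boundary inclusive at exactly d_n
  two <- new_cells(c(0, 25), c(0, 0))
  expect_equal(nrow(neighbor_pairs(two, 25)), 1L)
  expect_equal(neighbor_pairs(two, 25)$dist, 25)

  # collinear triple at spacing d_n / 2: outer pair included iff within d_n
  tri <- new_cells(c(0, 12.5, 25), c(0, 0, 0))
  expect_equal(nrow(neighbor_pairs(tri, 25)), 3L)
  tri2 <- new_cells(c(0, 13, 26), c(0, 0, 0))
  expect_equal(nrow(neighbor_pairs(tri2, 25)), 2L)
})

test_that("binned neighbour search agrees with brute force", {
  set.seed(7)
  big <- new_cells(runif(600, 0, 900), runif(600, 0, 900))
  got <- dplyr::arrange(neighbor_pairs(big, 25), i, j)
  # brute force oracle
  d <- as.matrix(dist(cbind(big$x, big$y)))
  idx <- which(upper.tri(d) & d <= 25 & d > 0, arr.ind = TRUE)
  want <- tibble::tibble(i = as.integer(unname(idx[, 1])),
                         j = as.integer(unname(idx[, 2]))) |>
    dplyr::arrange(i, j)
  expect_equal(got$i, want$i)
  expect_equal(got$j, want$j)
})

test_that("physical-constraint rule blocks motion into occupied sectors", {
  expect_false(is_constrained(c(0, 0), NULL, c(1, 0)))
  # neighbour dead ahead blocks
  expect_true(is_constrained(c(0, 0), cbind(15, 0), c(1, 0)))
  # perpendicular neighbour does not (45 degree half-angle)
  expect_false(is_constrained(c(0, 0), cbind(0, 15), c(1, 0)))
  # zero intended direction: no intended motion
  expect_false(is_constrained(c(0, 0), cbind(15, 0), c(0, 0)))
  # an interior cell of a hexagonal cluster is blocked in every direction
  cl <- hex_cluster()
  nb <- cbind(cl$x[-1], cl$y[-1])
  for (ang in seq(0, 2 * pi, length.out = 25)) {
    expect_true(is_constrained(c(cl$x[1], cl$y[1]), nb,
                               c(cos(ang), sin(ang))))
  }
})

test_that("traction obeys the gating, constraint and magnitude rules", {
  p1 <- mechanics_params(psi1 = 1, psi2 = 0, psi3 = 0)
  free <- new_cells(500, 500)  # migratory defaults: A = 3.96 > th_A
  no_pairs <- neighbor_pairs(free, p1$d_n)

  set.seed(1)
  tr <- traction_forces(free, no_pairs, NULL, NULL, p1, sig)
  mag <- sqrt(tr$tx^2 + tr$ty^2)
  expect_gte(mag, 0.8 * p1$F0)
  expect_lte(mag, 1.2 * p1$F0)
  # co-linear with the random direction
  expect_equal(tr$tx / mag, free$dr_x, tolerance = 1e-12)

  # proliferative signal (A below threshold) turns traction off entirely
  prolif <- new_cells(500, 500, M = 3.0, A = 0.6, R = 4.1)
  tr2 <- traction_forces(prolif, no_pairs, NULL, NULL, p1, sig)
  expect_equal(c(tr2$tx, tr2$ty), c(0, 0))

  # pure chemotaxis weight with no chemoattractant gradient: no traction
  p3 <- mechanics_params(psi1 = 0, psi2 = 0, psi3 = 1)
  tr3 <- traction_forces(free, no_pairs, NULL, matrix(0, 1, 2), p3, sig)
  expect_equal(c(tr3$tx, tr3$ty), c(0, 0))

  # fully surrounded interior cell: zero traction
  cl <- hex_cluster()
  prs <- neighbor_pairs(cl, mech$d_n)
  tr4 <- traction_forces(cl, prs, NULL, NULL, p1, sig)
  expect_equal(tr4$tx[1], 0)
  expect_equal(tr4$ty[1], 0)
  expect_true(tr4$constrained[1])
})

test_that("traction magnitude never exceeds 1.2 F0 over random states", {
  set.seed(11)
  p <- mechanics_params(psi1 = 0.3, psi2 = 0.3, psi3 = 0.4)
  for (k in 1:20) {
    cells <- new_cells(runif(10, 0, 2000), runif(10, 0, 2000))
    ang <- runif(10, 0, 2 * pi)
    cells$dr_x <- cos(ang); cells$dr_y <- sin(ang)
    gG <- matrix(rnorm(20, sd = 2), 10, 2)
    gC <- matrix(rnorm(20, sd = 2), 10, 2)
    tr <- traction_forces(cells, neighbor_pairs(cells, p$d_n), gG, gC, p, sig)
    expect_true(all(sqrt(tr$tx^2 + tr$ty^2) <= 1.2 * p$F0 + 1e-9))
  }
})

test_that("growth gate follows the proliferative conjunction and quiescence", {
  prolif <- data.frame(M = 3.0, A = 0.6, R = 4.1)
  migr <- data.frame(M = 0.3, A = 4.0, R = 1.4)
  expect_equal(growth_gate(prolif, 0L, sig), 1L)
  expect_equal(growth_gate(prolif, 1L, sig), 0L)  # quiescence overrides
  expect_equal(growth_gate(migr, 0L, sig), 0L)
})

test_that("growth rate is gated, tapered and calibrated to volume doubling", {
  expect_equal(growth_rate(mech$sigma_plus, 1, mech), 0)
  expect_equal(growth_rate(0, 0, mech), 0)
  g_max <- growth_rate(0, 1, mech)
  expect_gt(g_max, 0)
  # unstressed gated growth doubles the volume in exactly one cycle
  cell <- new_cells(0, 0)
  V0 <- cell_volume(cell, mech)
  cell$ug <- g_max * mech$T_cyc
  expect_equal(cell_volume(cell, mech) / V0, 2, tolerance = 1e-10)
  # taper is continuous and within [0, g_max]
  sig_grid <- seq(mech$sigma_minus, mech$sigma_plus, length.out = 200)
  g <- growth_rate(sig_grid, 1, mech)
  expect_true(all(g >= 0 & g <= g_max + 1e-12))
})

test_that("passive rheology relaxes to rest and conserves volume", {
  cell <- new_cells(0, 0)
  cell$u0_a <- 1.5; cell$u0_b <- -0.7
  # project initial state onto the constraint for a valid start
  l <- mech$b0 + c(1.5, -0.7, 0)
  l <- l * (mech$b0^3 / prod(l))^(1 / 3)
  cell$u0_a <- l[1] - mech$b0; cell$u0_b <- l[2] - mech$b0
  cell$u0_c <- l[3] - mech$b0
  prod0 <- prod(mech$b0 + c(cell$u0_a, cell$u0_b, cell$u0_c))

  dt <- 0.002
  set.seed(3)
  for (k in 1:400) {
    f <- if (k < 200) rnorm(3, sd = 50) else c(0, 0, 0)
    cell <- update_axes(cell, f, dt, gate = 0L, sigma = 0, params = mech)
    prod_k <- prod(mech$b0 + c(cell$u0_a, cell$u0_b, cell$u0_c))
    expect_equal(prod_k, prod0, tolerance = 1e-6)
  }
  # with forcing off, deformation decays toward the resting shape
  expect_lt(abs(cell$u0_a), 0.02)
  expect_lt(abs(cell$u0_b), 0.02)

  expect_error(update_axes(cell, c(0, 0, 0), dt = 10, params = mech),
               "relaxation")
})

test_that("velocity solve reproduces the single-cell closed form", {
  p <- mechanics_params()
  cell <- new_cells(500, 500)
  no_pairs <- neighbor_pairs(cell, p$d_n)
  Tf <- c(40, 20)
  v <- solve_velocities(cell, list(fx = Tf[1], fy = Tf[2]), no_pairs, p)
  r <- p$b0
  A_tot <- 4 * pi * r^2
  drag <- p$chi_drag * (p$f_substrate * A_tot * p$mu_s_i +
                          (1 - p$f_substrate) * A_tot * p$mu_f_i)
  pref <- A_tot / (6 * pi * r)
  expect_equal(as.numeric(v), pref * Tf / drag, tolerance = 1e-10)
  # co-linear with the traction
  expect_equal(v[1] / v[2], Tf[1] / Tf[2], tolerance = 1e-10)

  # zero forces, many cells: all velocities zero
  cl <- hex_cluster()
  prs <- neighbor_pairs(cl, p$d_n)
  v0 <- solve_velocities(cl, list(fx = rep(0, 7), fy = rep(0, 7)), prs, p)
  expect_equal(max(abs(v0)), 0)

  # mirror symmetry: equal and opposite tractions give opposite velocities
  two <- new_cells(c(480, 520), c(500, 500))
  prs2 <- neighbor_pairs(two, p$d_n)
  v2 <- solve_velocities(two, list(fx = c(-50, 50), fy = c(0, 0)), prs2, p)
  expect_equal(v2[1, ], -v2[2, ], tolerance = 1e-12)
})

test_that("pairwise reactive forces cancel over the population", {
  set.seed(5)
  cells <- new_cells(runif(40, 0, 120), runif(40, 0, 120))
  pairs <- neighbor_pairs(cells, mech$d_n)
  rf <- glioswitch:::reactive_forces(cells, pairs, mech)
  expect_lt(abs(sum(rf$fx)), 1e-9)
  expect_lt(abs(sum(rf$fy)), 1e-9)
})

test_that("division conserves volume and is reproducible under a seed", {
  p <- mechanics_params()
  parent <- new_cells(500, 500)
  parent$ug <- p$b0 * (2^(1 / 3) - 1)  # doubled volume
  V_parent <- cell_volume(parent, p)
  set.seed(9)
  d <- divide_cell(parent, new_id = 99L, params = p)
  expect_equal(nrow(d), 2L)
  V0 <- 4 / 3 * pi * p$b0^3
  expect_equal(sum(cell_volume(d, p)) / V_parent, 1, tolerance = 0.01)
  expect_equal(sort(d$id), c(1L, 99L))
  expect_equal(d$cycle_clock, c(0, 0))
  # daughters sit one resting semi-axis either side of the parent
  expect_equal(sqrt(diff(d$x)^2 + diff(d$y)^2), 2 * p$b0, tolerance = 1e-9)
  set.seed(9)
  d2 <- divide_cell(parent, new_id = 99L, params = p)
  expect_identical(d, d2)
})

test_that("daughter overlap with a bystander is relaxed by the dynamics", {
  p <- mechanics_params()
  cells <- new_cells(c(500, 515), c(500, 500))  # overlapping pair
  sep0 <- 15
  for (k in 1:5) {
    prs <- neighbor_pairs(cells, p$d_n)
    rf <- glioswitch:::reactive_forces(cells, prs, p)
    v <- solve_velocities(cells, rf, prs, p)
    disp <- sqrt(v[, 1]^2 + v[, 2]^2) * 0.5
    sc <- ifelse(disp > p$v_cap, p$v_cap / disp, 1)
    cells$x <- cells$x + v[, 1] * sc * 0.5
    cells$y <- cells$y + v[, 2] * sc * 0.5
    sep <- abs(diff(cells$x))
    expect_gt(sep, sep0 - 1e-12)  # separation non-decreasing
    sep0 <- sep
  }
  expect_gt(sep0, 18)
})

test_that("cycle clock advances only while gated", {
  cells <- new_cells(c(0, 0), c(0, 0))
  c1 <- advance_cycle(cells, dt = 5, gate = c(0L, 1L), params = mech)
  expect_equal(c1$cycle_clock, c(0, 5))
  # full gated traversal covers all phases in order
  cell <- new_cells(0, 0)
  phases <- character(0)
  for (k in seq_len(2 * mech$T_cyc)) {
    cell <- advance_cycle(cell, dt = 0.5, gate = 1L, params = mech)
    phases <- c(phases, cell$cycle_phase)
  }
  expect_equal(unique(phases), c("G1", "S", "G2", "M"))
  # 50% duty cycle doubles the wall-clock duration of the cycle
  cell2 <- new_cells(0, 0)
  t_wall <- 0
  while (cell2$cycle_clock < mech$T_cyc) {
    gate <- as.integer(t_wall %% 1 < 0.5)
    cell2 <- advance_cycle(cell2, dt = 0.5, gate = gate, params = mech)
    t_wall <- t_wall + 0.5
  }
  expect_equal(t_wall, 2 * mech$T_cyc, tolerance = 0.5 / mech$T_cyc)
})

test_that("drug kill is threshold- and phase-specific and leaves markers", {
  cells <- new_cells(c(0, 10, 20), c(0, 0, 0))
  cells$cycle_phase <- c("G1", "S", "S")
  # no drug anywhere: no deaths
  k0 <- apply_drug_kill(cells, c(0, 0, 0), th_D = 0.5)
  expect_true(all(k0$status == "alive"))
  # S-G2-M drug at high dose spares G1
  k1 <- apply_drug_kill(cells, c(10, 10, 0.1), th_D = 0.5)
  expect_equal(k1$status, c("alive", "apoptotic", "alive"))
  # G1-targeting flips the pattern
  k2 <- apply_drug_kill(cells, c(10, 10, 10), th_D = 0.5, targeting = "G1")
  expect_equal(k2$status, c("apoptotic", "alive", "alive"))
  # apoptotic cells generate no reactive forces
  k1$x <- c(0, 5, 200)  # overlap pair 1-2 with one dead
  rf <- glioswitch:::reactive_forces(k1, neighbor_pairs(k1, 25), mech)
  expect_equal(max(abs(c(rf$fx, rf$fy))), 0)
})
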