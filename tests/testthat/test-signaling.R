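test_that("right-hand sides match the closed-form rates", {
  # at the origin both Hill terms sit at their maxima
  r0 <- core_rhs(tibble::tibble(M = 0, A = 0, R = 0, G_signal = 0), sig)
  expect_equal(r0$dM, 4.0)
  expect_equal(r0$dA, (0.2 + 4.0) / 0.02)
  expect_equal(r0$dR, (1.2 + 4.0) / 0.02)

  # near the printed proliferative fixed point the equation residuals are
  # small (the fast A and R rates carry the 1/eps factor, so the residual of
  # the underlying balance is eps times the returned rate)
  r1 <- core_rhs(tibble::tibble(M = 3.0, A = 0.6, R = 4.1, G_signal = 0.45),
                 sig)
  expect_lt(abs(r1$dM), 0.2)
  expect_lt(abs(r1$dA) * sig$eps1, 0.2)
  expect_lt(abs(r1$dR) * sig$eps2, 0.2)

  # removing the inhibition (alpha = 0) reduces dM to the linear form
  p0 <- signaling_params(alpha = 0)
  st <- tibble::tibble(M = 1.3, A = 7.2, R = 0.4, G_signal = 0.7)
  expect_equal(core_rhs(st, p0)$dM, 1 * 0.7 + 4 - 1.3)

  expect_error(core_rhs(tibble::tibble(M = NaN, A = 0, R = 0, G_signal = 0)),
               "non-finite")
})

test_that("equilibrium counts and branches follow the bistability structure", {
  e1 <- find_equilibria(0.1, sig)
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$stability, "stable")
  expect_equal(e1$branch, "migratory")
  expect_equal(classify_phase(e1, sig), "Tm")

  e3 <- find_equilibria(0.45, sig)
  expect_equal(nrow(e3), 3L)
  expect_equal(sum(e3$stability == "stable"), 2L)
  expect_equal(sum(e3$stability == "unstable"), 1L)
  expect_equal(e3$branch, c("migratory", "middle", "proliferative"))

  e_hi <- find_equilibria(0.8, sig)
  expect_equal(nrow(e_hi), 1L)
  expect_equal(e_hi$branch, "proliferative")

  # decoupled cascade (alpha = 0) has the unique fixed point M = G + lambda1
  e0 <- find_equilibria(0.45, signaling_params(alpha = 0))
  expect_equal(nrow(e0), 1L)
  expect_equal(e0$M, 4.45, tolerance = 1e-8)
})

test_that("solver equilibria agree with the brute-force scalar oracle", {
  for (G in c(0, 0.1, 0.3, 0.45, 0.55, 0.7, 1.0)) {
    got <- sort(find_equilibria(G, sig)$M)
    want <- sort(oracle_equilibria_M(G))
    expect_equal(length(got), length(want), info = paste("G =", G))
    expect_equal(got, want, tolerance = 1e-6, info = paste("G =", G))
  }
})

test_that("equilibrium count is 1 or 3, and 3 exactly inside the knees", {
  bd <- scan_bifurcation(seq(0, 1, length.out = 200), sig)
  counts <- dplyr::count(bd$equilibria, G)
  expect_true(all(counts$n %in% c(1L, 3L)))
  inside <- counts$G > bd$knee_low & counts$G < bd$knee_high
  expect_true(all(counts$n[inside] == 3L))
  expect_true(all(counts$n[!inside] == 1L))
})

test_that("knees land on the exact saddle-node folds", {
  # independent fold location: solve F = 0 together with dF/dM = 0
  A_of <- function(M) 0.2 + 4 / (1 + M^2)
  dF <- function(M) {
    dA <- -8 * M / (1 + M^2)^2
    -12.8 * A_of(M) * dA / (1 + 1.6 * A_of(M)^2)^2 - 1
  }
  Mc_hi <- uniroot(dF, c(0.5, 2), tol = 1e-12)$root
  Mc_lo <- uniroot(dF, c(2, 3.5), tol = 1e-12)$root
  G_hi <- Mc_hi - 4 / (1 + 1.6 * A_of(Mc_hi)^2)
  G_lo <- Mc_lo - 4 / (1 + 1.6 * A_of(Mc_lo)^2)

  bd <- scan_bifurcation(seq(0, 1, length.out = 101), sig)
  expect_equal(bd$knee_high, G_hi, tolerance = 1e-3)
  expect_equal(bd$knee_low, G_lo, tolerance = 1e-3)

  # monotone decoupled system: no window
  bd0 <- scan_bifurcation(seq(0, 1, length.out = 51),
                          signaling_params(alpha = 1e-9))
  expect_true(is.na(bd0$knee_low))

  g <- glance(bd)
  expect_true(g$bistable)
  expect_s3_class(tidy(bd), "tbl_df")
})

test_that("trajectories converge to the attractor selected by history", {
  # unique attractor at low glucose, from several starts
  for (y0 in list(c(M = 0, A = 0, R = 0), c(M = 5, A = 5, R = 5),
                  c(M = 2, A = 0.1, R = 4))) {
    tr <- integrate_core(y0, sig, G = 0.1, t_end = 60, dt = 0.2)
    expect_equal(unlist(tail(tr, 1)[, c("M", "A", "R")]),
                 c(M = 0.2534, A = 3.9586, R = 1.4399), tolerance = 1e-3)
  }
  # bistable at G = 0.45: nearby starts split between branches
  lo <- integrate_core(c(M = 2.1, A = 4.0, R = 5.0), sig, G = 0.45,
                       t_end = 60, dt = 0.2)
  hi <- integrate_core(c(M = 2.2, A = 0.1, R = 0.1), sig, G = 0.45,
                       t_end = 60, dt = 0.2)
  expect_lt(tail(lo$M, 1), 1)    # migratory branch
  expect_gt(tail(hi$M, 1), 2.5)  # proliferative branch
  # equilibrium initial condition stays put
  eq <- find_equilibria(0, sig)
  tr <- integrate_core(c(M = eq$M, A = eq$A, R = eq$R), sig, G = 0,
                       t_end = 10, dt = 0.1)
  expect_equal(tail(tr$M, 1), eq$M, tolerance = 1e-6)
})

test_that("positivity is preserved from nonnegative starts", {
  set.seed(42)
  for (k in 1:5) {
    y0 <- runif(3, 0, 6)
    tr <- integrate_core(c(M = y0[1], A = y0[2], R = y0[3]), sig,
                         G = runif(1, 0, 1), t_end = 20, dt = 0.05)
    expect_true(all(tr$M >= 0 & tr$A >= 0 & tr$R >= 0))
  }
})

test_that("stability labels match perturbed long-time integration", {
  e3 <- find_equilibria(0.45, sig)
  for (k in seq_len(nrow(e3))) {
    y0 <- c(M = e3$M[k] + 1e-3, A = e3$A[k], R = e3$R[k])
    tr <- integrate_core(y0, sig, G = 0.45, t_end = 40, dt = 0.2)
    final_dist <- abs(tail(tr$M, 1) - e3$M[k])
    if (e3$stability[k] == "stable") {
      expect_lt(final_dist, 1e-4)
    } else {
      expect_gt(final_dist, 0.1)
    }
  }
})

test_that("phase classification uses strict inequalities with neutral ties", {
  expect_equal(classify_phase(data.frame(M = 3.0, A = 0.6, R = 4.1), sig), "Tp")
  expect_equal(classify_phase(data.frame(M = 0.3, A = 4.0, R = 1.4), sig), "Tm")
  expect_equal(classify_phase(data.frame(M = 2.5, A = 2.5, R = 2.5), sig),
               "neither")
  # boundary equalities are neither
  expect_equal(classify_phase(data.frame(M = 2.0, A = 4.0, R = 1.4), sig),
               "neither")
  expect_equal(classify_phase(data.frame(M = 3.0, A = 2.0, R = 4.0), sig),
               "neither")
})

test_that("vectorised integrator agrees with the stiff reference solver", {
  y0 <- c(M = 1.5, A = 1.0, R = 2.0)
  ref <- integrate_core(y0, sig, G = 0.45, t_end = 5)
  fast <- glioswitch:::signal_advance(y0[1], y0[2], y0[3], 0.45, sig,
                                      dt_total = 5, dt_sub = 0.01)
  expect_equal(tail(ref$M, 1), unname(fast$M), tolerance = 1e-4)
  expect_equal(tail(ref$A, 1), unname(fast$A), tolerance = 1e-4)
  expect_equal(tail(ref$R, 1), unname(fast$R), tolerance = 1e-4)
})
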