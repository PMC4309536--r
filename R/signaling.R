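#' Parameters of the miR-451-AMPK-mTOR core switch
#'
#' Constructs the dimensionless parameter set of the intracellular
#' miR-451-AMPK-mTOR control system. `M` (miR-451) is driven by the glucose
#' signal and inhibited by the AMPK complex `A`, `A` is inhibited by `M`, and
#' mTOR `R` is inhibited by `A`; each node also self-enhances through a
#' Hill-type term. Defaults are the published reference values for glioma
#' cells.
#'
#' @param lambda_g Glucose signalling rate onto miR-451.
#' @param lambda1,lambda3,lambda5 Autocatalytic production rates of miR-451,
#'   AMPK complex and mTOR.
#' @param lambda2,lambda4,lambda6 Hill-type inhibition saturation constants.
#' @param alpha Inhibition strength of miR-451 by the AMPK complex.
#' @param beta Inhibition strength of the AMPK complex by miR-451.
#' @param gamma Inhibition strength of mTOR by the AMPK complex.
#' @param S1,S2 Constitutive signalling sources of AMPK complex and mTOR.
#' @param eps1,eps2 Time-scale ratios of the fast AMPK and mTOR relaxation
#'   relative to miR-451 (both much smaller than 1).
#' @param th_M,th_A,th_R Phase thresholds defining the migratory region
#'   (`M < th_M`, `A > th_A`, `R < th_R`) and the proliferative region
#'   (`M > th_M`, `A < th_A`, `R > th_R`).
#' @param tau_hours Wall-clock hours corresponding to one dimensionless time
#'   unit of the switch (used by the simulation layer).
#'
#' @return An object of class `signaling_params` (a validated named list).
#' @export
#' @examples
#' p <- signaling_params()
#' find_equilibria(0.45, p)
signaling_params <- function(lambda_g = 1.0,
                             lambda1 = 4.0, lambda2 = 1.0,
                             lambda3 = 4.0, lambda4 = 1.0,
                             lambda5 = 4.0, lambda6 = 1.0,
                             alpha = 1.6, beta = 1.0, gamma = 1.0,
                             S1 = 0.2, S2 = 1.2,
                             eps1 = 0.02, eps2 = 0.02,
                             th_M = 2.0, th_A = 2.0, th_R = 3.0,
                             tau_hours = 1.0) {
  p <- list(lambda_g = lambda_g,
            lambda1 = lambda1, lambda2 = lambda2,
            lambda3 = lambda3, lambda4 = lambda4,
            lambda5 = lambda5, lambda6 = lambda6,
            alpha = alpha, beta = beta, gamma = gamma,
            S1 = S1, S2 = S2, eps1 = eps1, eps2 = eps2,
            th_M = th_M, th_A = th_A, th_R = th_R,
            tau_hours = tau_hours)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("signaling_params: all parameters must be finite scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  if (any(unlist(p[setdiff(names(p), "alpha")]) <= 0) || alpha < 0) {
    stop("signaling_params: parameters must be strictly positive (alpha >= 0).",
         call. = FALSE)
  }
  structure(p, class = "signaling_params")
}

#' @export
print.signaling_params <- function(x, ...) {
  cat("<signaling_params> miR-451-AMPK-mTOR switch\n")
  print(tibble::as_tibble(unclass(x)))
  invisible(x)
}

as_signaling_params <- function(params) {
  if (inherits(params, "signaling_params")) return(params)
  do.call(signaling_params, as.list(params))
}

# Steady-state cascade: at equilibrium A and R are explicit in M.
.steady_A <- function(M, p) p$S1 + p$lambda3 * p$lambda4^2 / (p$lambda4^2 + p$beta * M^2)
.steady_R <- function(A, p) p$S2 + p$lambda5 * p$lambda6^2 / (p$lambda6^2 + p$gamma * A^2)

# Scalar reduced map whose roots are the M-components of equilibria.
.reduced_map <- function(M, G, p) {
  A <- .steady_A(M, p)
  p$lambda_g * G + p$lambda1 * p$lambda2^2 / (p$lambda2^2 + p$alpha * A^2) - M
}

#' Right-hand side of the core switch ODEs
#'
#' Evaluates the dimensionless rates
#' \deqn{dM/d\tau = \lambda_g G + \lambda_1 \lambda_2^2/(\lambda_2^2+\alpha A^2) - M}
#' \deqn{dA/d\tau = [S_1 + \lambda_3 \lambda_4^2/(\lambda_4^2+\beta M^2) - A]/\epsilon_1}
#' \deqn{dR/d\tau = [S_2 + \lambda_5 \lambda_6^2/(\lambda_6^2+\gamma A^2) - R]/\epsilon_2}
#'
#' @param state A data frame (or tibble) with columns `M`, `A`, `R` and
#'   `G_signal` (dimensionless glucose input); rows are evaluated in parallel.
#' @param params A [signaling_params()] object.
#' @return A tibble with columns `dM`, `dA`, `dR`.
#' @export
core_rhs <- function(state, params = signaling_params()) {
  p <- as_signaling_params(params)
  state <- tibble::as_tibble(state)
  need <- c("M", "A", "R", "G_signal")
  if (!all(need %in% names(state))) {
    stop("core_rhs: `state` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vals <- unlist(state[need], use.names = FALSE)
  if (!all(is.finite(vals))) stop("core_rhs: non-finite state values.", call. = FALSE)
  M <- state$M; A <- state$A; R <- state$R; G <- state$G_signal
  tibble::tibble(
    dM = p$lambda_g * G + p$lambda1 * p$lambda2^2 / (p$lambda2^2 + p$alpha * A^2) - M,
    dA = (p$S1 + p$lambda3 * p$lambda4^2 / (p$lambda4^2 + p$beta * M^2) - A) / p$eps1,
    dR = (p$S2 + p$lambda5 * p$lambda6^2 / (p$lambda6^2 + p$gamma * A^2) - R) / p$eps2
  )
}

# Analytic Jacobian of the full 3-variable system (eps retained: it affects
# stability, not root locations).
.core_jacobian <- function(M, A, R, p) {
  dM_dA <- -2 * p$lambda1 * p$lambda2^2 * p$alpha * A / (p$lambda2^2 + p$alpha * A^2)^2
  dA_dM <- -2 * p$lambda3 * p$lambda4^2 * p$beta * M / (p$lambda4^2 + p$beta * M^2)^2
  dR_dA <- -2 * p$lambda5 * p$lambda6^2 * p$gamma * A / (p$lambda6^2 + p$gamma * A^2)^2
  matrix(c(-1,             dM_dA,          0,
           dA_dM / p$eps1, -1 / p$eps1,    0,
           0,              dR_dA / p$eps2, -1 / p$eps2),
         nrow = 3, byrow = TRUE)
}

#' Integrate the core switch over time
#'
#' Solves the stiff three-variable system with a prescribed (possibly
#' time-varying) glucose signal, using a stiff solver so that the fast
#' AMPK/mTOR relaxation (time scale `eps1`, `eps2`) is resolved.
#'
#' @param state0 Named numeric vector or one-row data frame with `M`, `A`, `R`.
#' @param params A [signaling_params()] object.
#' @param G Either a single glucose value held constant or a function of
#'   dimensionless time returning the glucose signal.
#' @param t_end End time (dimensionless units).
#' @param dt Output sampling interval (default `eps1 / 5`).
#' @param method `deSolve` method (default `"lsoda"`).
#' @return A tibble with columns `time`, `M`, `A`, `R`, `G_signal`.
#' @export
integrate_core <- function(state0, params = signaling_params(), G = 0.1,
                           t_end = 50, dt = NULL, method = "lsoda") {
  p <- as_signaling_params(params)
  if (is.data.frame(state0)) state0 <- unlist(state0[1, c("M", "A", "R")])
  y0 <- as.numeric(state0[c("M", "A", "R")])
  if (length(y0) != 3 || !all(is.finite(y0)) || any(y0 < 0)) {
    stop("integrate_core: `state0` must be finite nonnegative M, A, R.",
         call. = FALSE)
  }
  Gfun <- if (is.function(G)) G else function(t) G
  if (is.null(dt)) dt <- p$eps1 / 5
  rhs <- function(t, y, parms) {
    d <- core_rhs(tibble::tibble(M = y[1], A = y[2], R = y[3],
                                 G_signal = Gfun(t)), p)
    list(c(d$dM, d$dA, d$dR))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) {
    stop("integrate_core: stiff solver failed to converge.", call. = FALSE)
  }
  out <- tibble::tibble(time = sol[, 1], M = sol[, 2], A = sol[, 3], R = sol[, 4])
  # the dynamics preserve nonnegativity; clip solver round-off only
  out$M <- pmax(out$M, 0); out$A <- pmax(out$A, 0); out$R <- pmax(out$R, 0)
  out$G_signal <- vapply(out$time, Gfun, numeric(1))
  out
}

#' Equilibria of the core switch at a fixed glucose signal
#'
#' Exploits the cascade structure of the steady state (`A` and `R` are
#' explicit functions of `M`), reducing root finding to a scalar equation in
#' `M` solved by dense sign-change bracketing plus bisection. Stability comes
#' from the eigenvalues of the full 3x3 Jacobian.
#'
#' @param G Dimensionless glucose signal (scalar, `>= 0`).
#' @param params A [signaling_params()] object.
#' @param M_max Upper end of the scanned `M` interval.
#' @param n_scan Number of scan points for sign-change bracketing.
#' @return A tibble with columns `G`, `M`, `A`, `R`, `stability`
#'   (`"stable"`/`"unstable"`), `branch`
#'   (`"migratory"`/`"middle"`/`"proliferative"`) and `max_re` (largest real
#'   part of the Jacobian eigenvalues).
#' @export
find_equilibria <- function(G, params = signaling_params(),
                            M_max = NULL, n_scan = 2000L) {
  p <- as_signaling_params(params)
  stopifnot(is.numeric(G), length(G) == 1L, is.finite(G), G >= 0)
  if (is.null(M_max)) M_max <- p$lambda_g * G + p$lambda1 + 2
  Ms <- seq(0, M_max, length.out = n_scan)
  f <- .reduced_map(Ms, G, p)
  idx <- which(f[-1] * f[-length(f)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(.reduced_map, c(Ms[i], Ms[i + 1]), G = G, p = p,
                   tol = 1e-12)$root
  }, numeric(1))
  roots <- c(roots, Ms[f == 0])  # exact grid hits, if any
  roots <- sort(unique(roots))
  if (length(roots) == 0) {
    stop("find_equilibria: no steady state found (scan range too small?).",
         call. = FALSE)
  }
  A <- .steady_A(roots, p)
  R <- .steady_R(A, p)
  max_re <- vapply(seq_along(roots), function(i) {
    max(Re(eigen(.core_jacobian(roots[i], A[i], R[i], p),
                 only.values = TRUE)$values))
  }, numeric(1))
  stability <- ifelse(max_re < 0, "stable", "unstable")
  branch <- if (length(roots) == 3) {
    c("migratory", "middle", "proliferative")
  } else {
    ifelse(stability == "unstable", "middle",
           ifelse(roots < p$th_M, "migratory", "proliferative"))
  }
  tibble::tibble(G = G, M = roots, A = A, R = R,
                 stability = stability, branch = branch, max_re = max_re)
}

#' Scan the bifurcation structure of the switch over a glucose range
#'
#' Tabulates all equilibria over `G_grid` and refines, by bisection on the
#' equilibrium count, the two saddle-node "knees" that bound the bistability
#' window: `knee_low`, the smallest glucose at which the proliferative branch
#' exists, and `knee_high`, the largest glucose at which the migratory branch
#' survives.
#'
#' @param G_grid Increasing glucose values to scan (should span at least
#'   `[0, 1]` for the default parameters).
#' @param params A [signaling_params()] object.
#' @param tol Bisection tolerance for the knee locations.
#' @return An object of class `bifurcation_diagram`: a list with `equilibria`
#'   (tibble of all equilibria), `knee_low`, `knee_high` (`NA` if no
#'   bistability), and `params`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
scan_bifurcation <- function(G_grid = seq(0, 1, length.out = 201),
                             params = signaling_params(), tol = 1e-4) {
  p <- as_signaling_params(params)
  stopifnot(length(G_grid) >= 2, !is.unsorted(G_grid))
  eq <- purrr::map_dfr(G_grid, find_equilibria, params = p)
  counts <- dplyr::count(eq, .data$G)
  has3 <- counts$n[match(G_grid, counts$G)] == 3L
  n_eq_at <- function(G) nrow(find_equilibria(G, p))
  bisect <- function(lo, hi, want3_at_hi) {
    # invariant: count differs between lo and hi
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if ((n_eq_at(mid) == 3L) == want3_at_hi) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  if (!any(has3)) {
    knee_low <- NA_real_; knee_high <- NA_real_
  } else {
    i3 <- range(which(has3))
    knee_low <- if (i3[1] == 1L) G_grid[1] else
      bisect(G_grid[i3[1] - 1L], G_grid[i3[1]], want3_at_hi = TRUE)
    knee_high <- if (i3[2] == length(G_grid)) G_grid[length(G_grid)] else {
      # here the 3-root region is at the *low* end of the bracket
      lo <- G_grid[i3[2]]; hi <- G_grid[i3[2] + 1L]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (n_eq_at(mid) == 3L) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
  }
  structure(list(equilibria = eq, knee_low = knee_low, knee_high = knee_high,
                 params = p),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram> miR-451-AMPK-mTOR switch\n")
  if (is.na(x$knee_low)) {
    cat("  no bistability window on the scanned range\n")
  } else {
    cat(sprintf("  bistability window: G in (%.4f, %.4f)\n",
                x$knee_low, x$knee_high))
  }
  cat(sprintf("  %d equilibria tabulated over %d glucose values\n",
              nrow(x$equilibria), dplyr::n_distinct(x$equilibria$G)))
  invisible(x)
}

#' @rdname scan_bifurcation
#' @param x A `bifurcation_diagram`.
#' @param ... Unused.
#' @method tidy bifurcation_diagram
#' @export
tidy.bifurcation_diagram <- function(x, ...) x$equilibria

#' @rdname scan_bifurcation
#' @method glance bifurcation_diagram
#' @export
glance.bifurcation_diagram <- function(x, ...) {
  tibble::tibble(knee_low = x$knee_low, knee_high = x$knee_high,
                 bistable = !is.na(x$knee_low),
                 n_G = dplyr::n_distinct(x$equilibria$G),
                 n_equilibria = nrow(x$equilibria))
}

#' @rdname scan_bifurcation
#' @param object A `bifurcation_diagram`.
#' @method autoplot bifurcation_diagram
#' @export
autoplot.bifurcation_diagram <- function(object, ...) {
  eq <- tidyr::pivot_longer(object$equilibria, cols = c("M", "A", "R"),
                            names_to = "variable", values_to = "steady_state")
  gg <- ggplot2::ggplot(eq, ggplot2::aes(x = .data$G, y = .data$steady_state,
                                         colour = .data$variable,
                                         linetype = .data$stability)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "glucose signal G", y = "steady state",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$knee_low)) {
    gg <- gg + ggplot2::geom_vline(xintercept = c(object$knee_low,
                                                  object$knee_high),
                                   linetype = "dotted", colour = "grey40")
  }
  gg
}

#' Classify a signalling state as migratory, proliferative or neither
#'
#' The migratory phase `Tm` requires `M < th_M`, `A > th_A`, `R < th_R`; the
#' proliferative phase `Tp` requires `M > th_M`, `A < th_A`, `R > th_R`.
#' Threshold equalities classify as `"neither"` (the region definitions use
#' strict inequalities).
#'
#' @param state Data frame with columns `M`, `A`, `R` (vectorised over rows).
#' @param params A [signaling_params()] object.
#' @return Character vector in `c("Tm", "Tp", "neither")`.
#' @export
classify_phase <- function(state, params = signaling_params()) {
  p <- as_signaling_params(params)
  M <- state$M; A <- state$A; R <- state$R
  out <- rep("neither", length(M))
  out[M < p$th_M & A > p$th_A & R < p$th_R] <- "Tm"
  out[M > p$th_M & A < p$th_A & R > p$th_R] <- "Tp"
  out
}

# Vectorised fixed-step RK4 advance of (M, A, R) for many cells at once with
# per-cell constant glucose over the step. Used by the simulation loop, where
# a deSolve call per cell per step would dominate runtime.
signal_advance <- function(M, A, R, G, params, dt_total, dt_sub = NULL) {
  p <- as_signaling_params(params)
  if (is.null(dt_sub)) dt_sub <- 2 * p$eps1  # inside the RK4 stability region
  n_sub <- max(1L, ceiling(dt_total / dt_sub))
  h <- dt_total / n_sub
  f <- function(M, A, R) {
    list(dM = p$lambda_g * G + p$lambda1 * p$lambda2^2 / (p$lambda2^2 + p$alpha * A^2) - M,
         dA = (p$S1 + p$lambda3 * p$lambda4^2 / (p$lambda4^2 + p$beta * M^2) - A) / p$eps1,
         dR = (p$S2 + p$lambda5 * p$lambda6^2 / (p$lambda6^2 + p$gamma * A^2) - R) / p$eps2)
  }
  for (s in seq_len(n_sub)) {
    k1 <- f(M, A, R)
    k2 <- f(M + h / 2 * k1$dM, A + h / 2 * k1$dA, R + h / 2 * k1$dR)
    k3 <- f(M + h / 2 * k2$dM, A + h / 2 * k2$dA, R + h / 2 * k2$dR)
    k4 <- f(M + h * k3$dM, A + h * k3$dA, R + h * k3$dR)
    M <- pmax(M + h / 6 * (k1$dM + 2 * k2$dM + 2 * k3$dM + k4$dM), 0)
    A <- pmax(A + h / 6 * (k1$dA + 2 * k2$dA + 2 * k3$dA + k4$dA), 0)
    R <- pmax(R + h / 6 * (k1$dR + 2 * k2$dR + 2 * k3$dR + k4$dR), 0)
  }
  list(M = M, A = A, R = R)
}

#' Quasi-static hysteresis sweep of the switch
#'
#' Sweeps the glucose signal forward and backward across a grid, integrating
#' to equilibrium at each value starting from the previous state. Inside the
#' bistability window the two sweeps settle on different branches; outside it
#' they coincide.
#'
#' @param G_grid Increasing glucose values.
#' @param params A [signaling_params()] object.
#' @param t_relax Integration time per glucose value (dimensionless).
#' @return Tibble with columns `G`, `direction` (`"forward"`/`"backward"`),
#'   `M`, `A`, `R`.
#' @export
hysteresis_sweep <- function(G_grid = seq(0, 1, by = 0.02),
                             params = signaling_params(), t_relax = 60) {
  p <- as_signaling_params(params)
  sweep_one <- function(grid, direction) {
    eq0 <- find_equilibria(grid[1], p)
    st <- dplyr::filter(eq0, .data$stability == "stable")
    st <- st[if (direction == "forward") which.min(st$M) else which.max(st$M), ]
    M <- st$M; A <- st$A; R <- st$R
    purrr::map_dfr(grid, function(G) {
      res <- signal_advance(M, A, R, G, p, dt_total = t_relax, dt_sub = 0.04)
      M <<- res$M; A <<- res$A; R <<- res$R
      tibble::tibble(G = G, direction = direction, M = M, A = A, R = R)
    })
  }
  dplyr::bind_rows(sweep_one(G_grid, "forward"),
                   sweep_one(rev(G_grid), "backward"))
}
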