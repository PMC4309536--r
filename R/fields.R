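#' Parameters of the reaction-diffusion fields
#'
#' Six concentration fields live on a regular grid over the square tissue
#' domain: oxygen `K`, glucose `G`, chemoattractant `C`, extracellular matrix
#' `rho`, matrix-degrading proteinase `P` and chemotherapy drug `D`. Defaults
#' are the published values, converted to the internal mm/h unit system.
#'
#' @param D_K,D_G,D_C,D_P,D_D Diffusion coefficients (cm^2/s, as published).
#' @param r_K,r_G Vessel supply rates (g/(cm^3 s)).
#' @param l_in_C Base chemoattractant injection rate (g/(cm^3 s)); scenario
#'   sweeps use dimensionless multiples of this rate.
#' @param l_c_K,l_c_G Tumour consumption rates (pg/cell/min).
#' @param mu_K Oxygen removal rate (1/s).
#' @param mu_G Glucose removal rate (1/min).
#' @param mu_C,mu_P Chemoattractant and proteinase decay rates (1/s).
#' @param mu_D Drug decay rate (1/h).
#' @param l1 Matrix degradation rate by proteinase (cm^3/(g s)).
#' @param l2 Matrix remodelling rate (1/s).
#' @param l3 Proteinase production rate by invasive cells (g/(cm^3 s)).
#' @param rho_star Matrix carrying capacity (normalised matrix units; the
#'   published table leaves its absolute value open, default 1).
#' @param l_b_D Drug infusion multiplier relative to the reference rate at
#'   which the kill threshold is defined (0 = no intravenous drug).
#' @param slab_um Effective tissue slab thickness (um) converting per-cell
#'   consumption/production into volumetric rates.
#' @param G_cap Upper cap of the dimensionless glucose signal.
#'
#' @return An object of class `field_params` with rates converted to 1/h and
#'   mm^2/h alongside the published raw values.
#' @export
field_params <- function(D_K = 2.0e-5, D_G = 6.7e-7, D_C = 1.66e-6,
                         D_P = 8.0e-9, D_D = 6.9e-6,
                         r_K = 6.35e-4, r_G = 1.4e-3,
                         l_in_C = 2.68e-9,
                         l_c_K = 0.8, l_c_G = 0.8,
                         mu_K = 2.0e-5, mu_G = 0.0034,
                         mu_C = 8.02e-6, mu_P = 5.0e-5, mu_D = 1.849,
                         l1 = 3.0e4, l2 = 5.6e-3, l3 = 1.0e-9,
                         rho_star = 1.0, l_b_D = 0,
                         slab_um = 20, G_cap = 1.2) {
  cm2s_to_mm2h <- function(x) x * 100 * 3600
  per_s_to_per_h <- function(x) x * 3600
  structure(list(
    # diffusion, mm^2/h
    D_K = cm2s_to_mm2h(D_K), D_G = cm2s_to_mm2h(D_G),
    D_C = cm2s_to_mm2h(D_C), D_P = cm2s_to_mm2h(D_P),
    D_D = cm2s_to_mm2h(D_D),
    # supply / injection, g/(cm^3 h)
    r_K = per_s_to_per_h(r_K), r_G = per_s_to_per_h(r_G),
    l_in_C = per_s_to_per_h(l_in_C),
    # consumption pg/cell/min -> g/cell/h
    l_c_K = l_c_K * 1e-12 * 60, l_c_G = l_c_G * 1e-12 * 60,
    # decay, 1/h
    mu_K = per_s_to_per_h(mu_K), mu_G = mu_G * 60,
    mu_C = per_s_to_per_h(mu_C), mu_P = per_s_to_per_h(mu_P), mu_D = mu_D,
    l1 = per_s_to_per_h(l1), l2 = per_s_to_per_h(l2),
    l3 = per_s_to_per_h(l3),
    rho_star = rho_star, l_b_D = l_b_D,
    slab_um = slab_um, G_cap = G_cap,
    raw = list(D_K = D_K, D_G = D_G, D_C = D_C, D_P = D_P, D_D = D_D,
               r_K = r_K, r_G = r_G, l_in_C = l_in_C,
               l_c_K = l_c_K, l_c_G = l_c_G,
               mu_K = mu_K, mu_G = mu_G, mu_C = mu_C, mu_P = mu_P,
               mu_D = mu_D, l1 = l1, l2 = l2, l3 = l3)
  ), class = "field_params")
}

as_field_params <- function(params) {
  if (inherits(params, "field_params")) return(params)
  do.call(field_params, as.list(params))
}

#' Create a field state on a regular grid
#'
#' @param L Domain side length (mm).
#' @param n Number of grid nodes per side.
#' @param params A [field_params()] object.
#' @param rho0 Initial matrix density (fraction of `rho_star`).
#' @return An object of class `field_state`: grid metadata, the six field
#'   matrices, diffusion-scaling map and clamp counters.
#' @export
field_state <- function(L = 10, n = 101, params = field_params(),
                        rho0 = 0.5) {
  p <- as_field_params(params)
  zero <- matrix(0, n, n)
  structure(list(
    L = L, n = n, h = L / (n - 1),
    xs = seq(0, L, length.out = n), ys = seq(0, L, length.out = n),
    K = zero, G = zero, C = zero,
    rho = zero + rho0 * p$rho_star, P = zero, D = zero,
    diff_scale = matrix(1, n, n),   # spatial diffusion multiplier map
    clamp_events = 0L,
    params = p
  ), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> %dx%d grid over [0, %g]^2 mm (h = %g mm)\n",
              x$n, x$n, x$L, x$h))
  for (f in c("K", "G", "C", "rho", "P", "D")) {
    cat(sprintf("  %-3s range [%.3g, %.3g]\n", f, min(x[[f]]), max(x[[f]])))
  }
  invisible(x)
}

# Divergence-form 5-point Laplacian with spatially varying coefficient
# (face values by harmonic mean) and zero-flux boundaries. Returns a sparse
# matrix L such that dU/dt = L U conserves sum(U) exactly.
diffusion_operator <- function(n, h, Dmap) {
  idx <- function(i, j) (j - 1L) * n + i
  harm <- function(a, b) 2 * a * b / (a + b)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  # horizontal faces (i, j)-(i+1, j) and vertical faces (i, j)-(i, j+1)
  ig <- rep(seq_len(n - 1), n); jg <- rep(seq_len(n), each = n - 1)
  a <- idx(ig, jg); b <- idx(ig + 1L, jg)
  w <- harm(Dmap[cbind(ig, jg)], Dmap[cbind(ig + 1L, jg)]) / h^2
  ii <- c(ii, a, b, a, b); jj <- c(jj, b, a, a, b); xx <- c(xx, w, w, -w, -w)
  ig <- rep(seq_len(n), n - 1); jg <- rep(seq_len(n - 1), each = n)
  a <- idx(ig, jg); b <- idx(ig, jg + 1L)
  w <- harm(Dmap[cbind(ig, jg)], Dmap[cbind(ig, jg + 1L)]) / h^2
  ii <- c(ii, a, b, a, b); jj <- c(jj, b, a, a, b); xx <- c(xx, w, w, -w, -w)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n * n, n * n))
}

# Pre-factorised backward-Euler solvers (I - dt D L) for each diffusing
# field. Factorisation is done once per (grid, dt) and reused every step.
field_solvers <- function(state, dt) {
  p <- state$params
  n <- state$n
  Lop <- diffusion_operator(n, state$h, state$diff_scale)
  I <- Matrix::Diagonal(n * n)
  mk <- function(D) Matrix::Cholesky(
    Matrix::forceSymmetric(I - dt * D * Lop), LDL = FALSE, perm = TRUE)
  list(dt = dt,
       K = mk(p$D_K), G = mk(p$D_G), C = mk(p$D_C),
       P = mk(p$D_P), D = mk(p$D_D),
       Lop = Lop)
}

be_solve <- function(chol_fac, U) {
  matrix(as.numeric(Matrix::solve(chol_fac, as.numeric(U))),
         nrow = nrow(U))
}

#' Smooth source footprint around point sites
#'
#' Vessels and injection sites act through a Gaussian bump of fixed physical
#' width rather than a single grid node, so that source terms (and hence the
#' fields) converge under grid refinement.
#'
#' @param state A [field_state()].
#' @param sites Matrix of site coordinates (mm).
#' @param sigma Bump width (mm).
#' @return Matrix of weights with peak 1 at each site.
#' @export
source_footprint <- function(state, sites, sigma = 0.1) {
  W <- matrix(0, state$n, state$n)
  for (k in seq_len(nrow(sites))) {
    dx <- state$xs - sites[k, 1]
    dy <- state$ys - sites[k, 2]
    Wk <- exp(-outer(dx^2, dy^2, "+") / (2 * sigma^2))
    Wk[Wk < 1e-4] <- 0
    W <- pmax(W, Wk)
  }
  W
}

#' Steady state of the discrete field-update scheme
#'
#' The per-step update for a supplied, diffusing, decaying field is
#' `U <- exp(-mu dt) (BE(U) + dt S)` with `BE` the backward-Euler diffusion
#' solve. Its fixed point satisfies a single sparse linear system, which this
#' solves directly. It is the level the stepped field actually relaxes to
#' (and converges to the continuum steady state as `dt -> 0`); scenario
#' reference levels (glucose signal anchor, drug kill threshold) use it so
#' that they are exactly consistent with the dynamics.
#'
#' @param state A [field_state()].
#' @param D_mm2h Diffusion coefficient (mm^2/h).
#' @param mu Decay rate (1/h).
#' @param source Source matrix (per-node rate).
#' @param dt Step (h) of the scheme.
#' @return Matrix of steady concentrations.
#' @export
discrete_steady_field <- function(state, D_mm2h, mu, source, dt) {
  n <- state$n
  Lop <- diffusion_operator(n, state$h, state$diff_scale)
  e <- exp(-mu * dt)
  A <- Matrix::forceSymmetric((1 - e) * Matrix::Diagonal(n * n) -
                                dt * D_mm2h * Lop)
  W <- matrix(as.numeric(Matrix::solve(A, e * dt * as.numeric(source))), n, n)
  e * (W + dt * source)
}

#' Rasterise cells to tumour and invasive-cell indicators
#'
#' Node value 1 where a living cell's footprint covers the node; the
#' invasive-cell raster additionally filters on the migratory phase `Tm`.
#' Apoptotic cells are excluded from both.
#'
#' @param cells Cell tibble (positions in um).
#' @param state A [field_state()].
#' @return List with integer matrices `I_CT` (all living tumour cells) and
#'   `I_Cm` (migratory cells), plus per-cell node indices `node_i`, `node_j`.
#' @export
rasterize_cells <- function(cells, state) {
  n <- state$n
  I_CT <- matrix(0L, n, n); I_Cm <- matrix(0L, n, n)
  if (nrow(cells) == 0) {
    return(list(I_CT = I_CT, I_Cm = I_Cm,
                node_i = integer(0), node_j = integer(0)))
  }
  # positions in um -> mm -> nearest node
  xi <- pmin(pmax(round(cells$x / 1000 / state$h) + 1L, 1L), n)
  yj <- pmin(pmax(round(cells$y / 1000 / state$h) + 1L, 1L), n)
  alive <- cells$status == "alive"
  I_CT[cbind(xi[alive], yj[alive])] <- 1L
  mig <- alive & cells$phase == "Tm"
  I_Cm[cbind(xi[mig], yj[mig])] <- 1L
  list(I_CT = I_CT, I_Cm = I_Cm, node_i = xi, node_j = yj)
}

# Exact per-step logistic/degradation update for the matrix field with the
# proteinase frozen over the step: drho/dt = rho (a - b rho).
logistic_step <- function(rho, a, b, dt) {
  ea <- exp(a * dt)
  num <- a * rho * ea
  den <- a + b * rho * (ea - 1)
  out <- ifelse(abs(a) > 1e-14, num / pmax(den, 1e-300),
                rho / (1 + b * rho * dt))
  pmax(out, 0)
}

#' Advance all fields by one operator-split step
#'
#' One step is: implicit (backward-Euler) diffusion in divergence form with
#' zero-flux boundaries for each diffusing field, then pointwise reactions --
#' vessel supply, tumour consumption, exponential decay, chemoattractant
#' injection, exact logistic matrix remodelling with proteinase degradation,
#' proteinase production on invasive-cell sites, and drug infusion.
#' Concentrations are clamped at zero and clamping events counted.
#'
#' @param state A [field_state()].
#' @param rasters Output of [rasterize_cells()].
#' @param vessels Vessel map from [make_vessels()] (or `NULL` for none).
#' @param solvers Pre-factorised solvers from `field_solvers()`; rebuilt on
#'   the fly when `NULL`.
#' @param dt Time step (h).
#' @param t Current time (h), used for injection windows.
#' @param injection Optional injection schedule: list with `sites` (matrix of
#'   mm coordinates), `windows` (two-column matrix of start/end hours) and
#'   `rate` (multiple of the base injection rate).
#' @param n_cells_per_node Optional matrix of living-cell counts per node
#'   (defaults to the 0/1 tumour indicator).
#' @return The updated `field_state`.
#' @export
step_fields <- function(state, rasters, vessels = NULL, solvers = NULL,
                        dt = 0.5, t = 0, injection = NULL,
                        n_cells_per_node = NULL) {
  p <- state$params
  n <- state$n
  if (is.null(solvers) || solvers$dt != dt) solvers <- field_solvers(state, dt)
  W_B <- if (is.null(vessels)) matrix(0, n, n) else
    (if (!is.null(vessels$W_B)) vessels$W_B else vessels$I_B)
  any_vessels <- any(W_B > 0)
  I_CT <- rasters$I_CT
  counts <- if (is.null(n_cells_per_node)) I_CT else n_cells_per_node
  node_vol_cm3 <- (state$h / 10)^2 * (p$slab_um / 1e4)  # h mm -> cm
  clamp <- function(U) {
    neg <- U < 0
    if (any(neg)) {
      state$clamp_events <<- state$clamp_events + sum(neg)
      U[neg] <- 0
    }
    U
  }
  # oxygen and glucose: diffusion -> supply/consumption -> exact decay
  react_KG <- function(U, fac, r_sup, l_con, mu) {
    U <- be_solve(fac, U)
    U <- U + dt * (r_sup * W_B - l_con * counts / node_vol_cm3)
    U <- clamp(U)
    U * exp(-mu * dt)
  }
  state$K <- react_KG(state$K, solvers$K, p$r_K, p$l_c_K, p$mu_K)
  state$G <- react_KG(state$G, solvers$G, p$r_G, p$l_c_G, p$mu_G)
  # chemoattractant: diffusion -> scheduled injection -> decay
  inj_active <- !is.null(injection) && nrow(injection$windows) > 0 &&
    any(t >= injection$windows[, 1] & t < injection$windows[, 2])
  if (inj_active || any(state$C > 0)) {
    state$C <- be_solve(solvers$C, state$C)
    if (inj_active) {
      if (!is.null(injection$src)) {
        state$C <- state$C + dt * injection$src
      } else {
        si <- pmin(pmax(round(injection$sites[, 1] / state$h) + 1L, 1L), n)
        sj <- pmin(pmax(round(injection$sites[, 2] / state$h) + 1L, 1L), n)
        state$C[cbind(si, sj)] <- state$C[cbind(si, sj)] +
          dt * injection$rate * p$l_in_C
      }
    }
    state$C <- clamp(state$C) * exp(-p$mu_C * dt)
  }
  # matrix: exact logistic with degradation (no diffusion)
  a <- p$l2 - p$l1 * state$P
  b <- p$l2 / p$rho_star
  state$rho <- logistic_step(state$rho, a, b, dt)
  # proteinase: diffusion -> production on invasive sites -> decay
  any_P_src <- any(rasters$I_Cm > 0)
  if (any_P_src || any(state$P > 0)) {
    state$P <- be_solve(solvers$P, state$P)
    state$P <- clamp(state$P + dt * p$l3 * rasters$I_Cm) * exp(-p$mu_P * dt)
  }
  # drug: diffusion -> infusion at vessels -> decay
  if ((p$l_b_D > 0 && any_vessels) || any(state$D > 0)) {
    state$D <- be_solve(solvers$D, state$D)
    state$D <- clamp(state$D + dt * p$l_b_D * W_B) * exp(-p$mu_D * dt)
  }
  state
}

#' Sample a field by bilinear interpolation
#'
#' @param state A [field_state()].
#' @param field One of `"K"`, `"G"`, `"C"`, `"rho"`, `"P"`, `"D"`.
#' @param x,y Positions (mm), vectorised.
#' @return Interpolated values.
#' @export
sample_field <- function(state, field, x, y) {
  U <- state[[field]]
  h <- state$h; n <- state$n
  if (any(x < -1e-9 | x > state$L + 1e-9 | y < -1e-9 | y > state$L + 1e-9)) {
    stop("sample_field: position outside the domain.", call. = FALSE)
  }
  fx <- pmin(pmax(x / h, 0), n - 1); fy <- pmin(pmax(y / h, 0), n - 1)
  i0 <- pmin(floor(fx) + 1, n - 1); j0 <- pmin(floor(fy) + 1, n - 1)
  tx <- fx - (i0 - 1); ty <- fy - (j0 - 1)
  U[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    U[cbind(i0 + 1, j0)] * tx * (1 - ty) +
    U[cbind(i0, j0 + 1)] * (1 - tx) * ty +
    U[cbind(i0 + 1, j0 + 1)] * tx * ty
}

#' Sample a field gradient (per mm) at arbitrary positions
#'
#' Central differences at interior nodes (one-sided at boundaries),
#' bilinearly interpolated to the requested positions.
#'
#' @inheritParams sample_field
#' @return Two-column matrix of gradients (field units per mm).
#' @export
sample_gradient <- function(state, field, x, y) {
  U <- state[[field]]
  h <- state$h; n <- state$n
  gx <- U; gy <- U
  gx[2:(n - 1), ] <- (U[3:n, ] - U[1:(n - 2), ]) / (2 * h)
  gx[1, ] <- (U[2, ] - U[1, ]) / h
  gx[n, ] <- (U[n, ] - U[n - 1, ]) / h
  gy[, 2:(n - 1)] <- (U[, 3:n] - U[, 1:(n - 2)]) / (2 * h)
  gy[, 1] <- (U[, 2] - U[, 1]) / h
  gy[, n] <- (U[, n] - U[, n - 1]) / h
  tmp <- state
  tmp$gx_ <- gx; tmp$gy_ <- gy
  cbind(sample_field(tmp, "gx_", x, y), sample_field(tmp, "gy_", x, y))
}

#' Map physical glucose to the dimensionless switch input
#'
#' `G_signal = min(G / G_ref, G_cap)` where `G_ref` is the steady near-vessel
#' glucose under default supply (computed once per scenario); monotone and
#' continuous, anchored so the signal is 1 at a vessel.
#'
#' @param G_physical Glucose concentrations (any nonnegative units).
#' @param G_ref Reference near-vessel steady concentration (same units).
#' @param G_cap Signal cap.
#' @return Dimensionless glucose signal in `[0, G_cap]`.
#' @export
glucose_to_signal <- function(G_physical, G_ref, G_cap = 1.2) {
  stopifnot(G_ref > 0)
  pmin(pmax(G_physical, 0) / G_ref, G_cap)
}

#' Steady no-tumour field (direct solve)
#'
#' Solves `0 = div(D grad U) + r I_B - mu U` directly; used to pre-equilibrate
#' oxygen and glucose before a scenario and to define reference near-vessel
#' levels.
#'
#' @param state A [field_state()].
#' @param D_mm2h Diffusion coefficient (mm^2/h).
#' @param mu Decay rate (1/h).
#' @param source Source matrix (g/(cm^3 h) per node).
#' @return Matrix of steady concentrations.
#' @export
steady_field <- function(state, D_mm2h, mu, source) {
  n <- state$n
  Lop <- diffusion_operator(n, state$h, state$diff_scale)
  A <- Matrix::forceSymmetric(mu * Matrix::Diagonal(n * n) - D_mm2h * Lop)
  matrix(as.numeric(Matrix::solve(A, as.numeric(source))), n, n)
}
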