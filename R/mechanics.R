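#' Parameters of the cell-based mechanical component
#'
#' Off-lattice agents are spheroids tracked by semi-axis changes; contacts are
#' treated isotropically through an effective radius. Internal units are
#' micrometres, hours and nanonewtons; the published adhesion coefficients
#' (dyn s/cm) are converted on construction.
#'
#' @param mu_cell,mu_s,mu_f Cell-cell, cell-substrate and fluid friction
#'   coefficients (dyn s/cm, as published).
#' @param c_plus Raw growth-rate scale of the published growth law
#'   (mm/(min nN)); retained for fidelity experiments, the default growth rate
#'   is instead calibrated to volume doubling over one cell cycle.
#' @param sigma_plus,sigma_minus Growth-arrest force bounds (nN): growth stops
#'   outside `(sigma_minus, sigma_plus)`.
#' @param k_a,k2 Spring constants of the Maxwell element and the parallel
#'   nonlinear spring (dyn/cm).
#' @param mu_a Dashpot viscosity of the Maxwell element (dyn min/cm).
#' @param F0 Maximal traction magnitude (nN).
#' @param phi_r_range Interval for the uniform random traction factor.
#' @param psi1,psi2,psi3 Direction weights for random motility, glucose
#'   gradient and chemoattractant gradient; must sum to 1.
#' @param K_G,K_C Gradient saturation scalers (dimensionless).
#' @param p_bar Internal pressure force (nN); the published value is never
#'   printed, default 0.
#' @param b0 Resting semi-axis (um).
#' @param d_n Neighbour-search radius (um).
#' @param cone_half_angle Half-angle (radians) of the blocking cone for the
#'   physical-constraint rule; default 45 degrees (a 90-degree sector centred
#'   on the intended direction).
#' @param u_ref Strain scale (um) of the cubic-stiffening nonlinear spring
#'   `f2(u) = k2 u (1 + (u/u_ref)^2)`.
#' @param T_cyc Cell-cycle length (h); the default matches typical
#'   glioblastoma doubling times.
#' @param cycle_fractions Fractions of `T_cyc` spent in G1, S, G2, M.
#' @param chi_drag Dimensionless drag multiplier closing the units of the
#'   velocity solve so that a free cell at traction `F0` moves at a speed
#'   consistent with measured glioma speeds.
#' @param f_substrate Fraction of the undeformed surface area in contact with
#'   the substrate.
#' @param tau_persist Persistence time (h) of the random-walk direction.
#' @param v_cap Per-step displacement cap (um) guarding the explicit position
#'   update against contact-force overshoot.
#'
#' @return An object of class `mechanics_params`.
#' @export
mechanics_params <- function(mu_cell = 27.0, mu_s = 27.0, mu_f = 2.7,
                             c_plus = 1.016089e-7,
                             sigma_plus = 800, sigma_minus = -4,
                             k_a = 163.8, k2 = 147.5, mu_a = 123,
                             F0 = 64,
                             phi_r_range = c(0.8, 1.2),
                             psi1 = 0.2, psi2 = 0.8, psi3 = 0,
                             K_G = 1.0, K_C = 1.0,
                             p_bar = 0,
                             b0 = 10, d_n = 25,
                             cone_half_angle = pi / 4,
                             u_ref = 3,
                             T_cyc = 24,
                             cycle_fractions = c(G1 = 0.5, S = 0.3,
                                                 G2 = 0.15, M = 0.05),
                             chi_drag = 1.0,
                             f_substrate = 1 / 3,
                             tau_persist = 1.0,
                             v_cap = 25) {
  psi <- c(psi1, psi2, psi3)
  if (abs(sum(psi) - 1) > 1e-8 || any(psi < 0) || any(psi > 1)) {
    stop("mechanics_params: psi1 + psi2 + psi3 must equal 1, each in [0, 1].",
         call. = FALSE)
  }
  if (!(sigma_minus < 0 && 0 < sigma_plus)) {
    stop("mechanics_params: need sigma_minus < 0 < sigma_plus.", call. = FALSE)
  }
  if (abs(sum(cycle_fractions) - 1) > 1e-8) {
    stop("mechanics_params: cycle_fractions must sum to 1.", call. = FALSE)
  }
  # dyn s/cm -> nN h/um : 1 dyn = 1e4 nN, 1 s = 1/3600 h, 1 cm = 1e4 um
  to_nN_h_um <- function(x) x / 3600
  structure(list(
    mu_cell = mu_cell, mu_s = mu_s, mu_f = mu_f,
    mu_cell_i = to_nN_h_um(mu_cell), mu_s_i = to_nN_h_um(mu_s),
    mu_f_i = to_nN_h_um(mu_f),
    c_plus = c_plus, sigma_plus = sigma_plus, sigma_minus = sigma_minus,
    # dyn/cm -> nN/um: 1e4 nN / 1e4 um = 1; dyn min/cm -> nN h/um: /60
    k_a = k_a, k2 = k2, mu_a = mu_a / 60,
    F0 = F0, phi_r_range = phi_r_range,
    psi1 = psi1, psi2 = psi2, psi3 = psi3,
    K_G = K_G, K_C = K_C, p_bar = p_bar,
    b0 = b0, d_n = d_n, cone_half_angle = cone_half_angle,
    u_ref = u_ref, T_cyc = T_cyc, cycle_fractions = cycle_fractions,
    chi_drag = chi_drag, f_substrate = f_substrate,
    tau_persist = tau_persist, v_cap = v_cap
  ), class = "mechanics_params")
}

as_mechanics_params <- function(params) {
  if (inherits(params, "mechanics_params")) return(params)
  do.call(mechanics_params, as.list(params))
}

#' Construct a population of cell agents
#'
#' @param x,y Positions (um).
#' @param M,A,R Initial intracellular levels (defaults: the low-glucose
#'   migratory steady state).
#' @param params A [mechanics_params()] object.
#' @param sig_params A [signaling_params()] object used for phase labels.
#' @return A tibble with one row per cell: position, velocity, passive
#'   (`u0_*`) and growth (`ug`) semi-axis changes, signalling state, phase,
#'   cell-cycle bookkeeping, status and random-walk direction.
#' @export
new_cells <- function(x, y, M = 0.2534, A = 3.9586, R = 1.4399,
                      params = mechanics_params(),
                      sig_params = signaling_params()) {
  n <- length(x)
  stopifnot(length(y) == n)
  cells <- tibble::tibble(
    id = seq_len(n),
    x = as.numeric(x), y = as.numeric(y),
    vx = 0, vy = 0,
    u0_a = 0, u0_b = 0, u0_c = 0,
    ug = 0,
    M = rep_len(M, n), A = rep_len(A, n), R = rep_len(R, n),
    G_signal = 0,
    phase = NA_character_,
    cycle_clock = 0, cycle_phase = "G1", G0_flag = 0L,
    status = "alive",
    dr_x = 1, dr_y = 0, dr_age = Inf,
    sigma = 0
  )
  cells$phase <- classify_phase(cells, sig_params)
  cells
}

# Semi-axis lengths and derived geometry. Growth is isotropic (ug on each
# axis); contact is isotropic through the volume-equivalent radius.
cell_axes <- function(cells, p) {
  list(a = p$b0 + cells$u0_a + cells$ug,
       b = p$b0 + cells$u0_b + cells$ug,
       c = p$b0 + cells$u0_c + cells$ug)
}

#' Cell volumes (um^3)
#' @param cells Cell tibble from [new_cells()].
#' @param params A [mechanics_params()] object.
#' @export
cell_volume <- function(cells, params = mechanics_params()) {
  p <- as_mechanics_params(params)
  ax <- cell_axes(cells, p)
  4 / 3 * pi * ax$a * ax$b * ax$c
}

# Volume-equivalent radius used for isotropic contact.
cell_radius <- function(cells, p) {
  ax <- cell_axes(cells, p)
  (ax$a * ax$b * ax$c)^(1 / 3)
}

#' Neighbour search: contact graph of a population
#'
#' Returns all unordered pairs of living cells whose centre distance is at
#' most `d_n` (boundary inclusive) and positive. Uses spatial binning so the
#' cost stays near-linear in the population size.
#'
#' @param cells Cell tibble.
#' @param d_n Neighbour radius (um).
#' @return Tibble with columns `i`, `j` (row indices into `cells`, `i < j`)
#'   and `dist` (um).
#' @export
neighbor_pairs <- function(cells, d_n = mechanics_params()$d_n) {
  n <- nrow(cells)
  empty <- tibble::tibble(i = integer(), j = integer(), dist = numeric())
  if (n < 2) return(empty)
  x <- cells$x; y <- cells$y
  if (n <= 300) {
    i <- rep.int(seq_len(n - 1), (n - 1):1)
    j <- sequence((n - 1):1, from = 2:n)
    d2 <- (x[i] - x[j])^2 + (y[i] - y[j])^2
    keep <- d2 <= d_n^2 & d2 > 0
    return(tibble::tibble(i = i[keep], j = j[keep], dist = sqrt(d2[keep])))
  }
  # cell-list binning at the search radius; bins keyed by a single integer,
  # candidate pairs expanded arithmetically (no per-cell loop)
  bx <- floor((x - min(x)) / d_n)
  by <- floor((y - min(y)) / d_n)
  span <- max(by) + 3
  key <- bx * span + by
  ord <- order(key)
  ks <- key[ord]
  r <- rle(ks)
  uk <- r$values
  len <- r$lengths
  start <- cumsum(c(1L, len[-length(len)]))
  cand_i <- integer(0); cand_j <- integer(0)
  # half-neighbourhood offsets cover each unordered bin pair exactly once
  for (off in c(0L, span, 1L, span + 1L, span - 1L)) {
    m <- match(uk + off, uk)
    sel <- which(!is.na(m))
    if (!length(sel)) next
    if (off == 0L) sel <- sel[len[sel] > 1L]
    if (!length(sel)) next
    na <- len[sel]; nb <- len[m[sel]]
    tot <- na * nb
    grp <- rep.int(seq_along(sel), tot)
    pos <- sequence(tot) - 1L
    pa <- pos %/% nb[grp]
    pb <- pos %% nb[grp]
    a <- ord[start[sel][grp] + pa]
    b <- ord[start[m[sel]][grp] + pb]
    if (off == 0L) {
      keep <- a < b
      a <- a[keep]; b <- b[keep]
    }
    cand_i <- c(cand_i, a); cand_j <- c(cand_j, b)
  }
  if (!length(cand_i)) return(empty)
  d2 <- (x[cand_i] - x[cand_j])^2 + (y[cand_i] - y[cand_j])^2
  keep <- d2 <= d_n^2 & d2 > 0
  tibble::tibble(i = pmin(cand_i[keep], cand_j[keep]),
                 j = pmax(cand_i[keep], cand_j[keep]),
                 dist = sqrt(d2[keep]))
}

#' Physical-constraint test for the traction direction
#'
#' A cell is constrained when some neighbour's centre lies within the blocking
#' cone around its intended direction of motion: another cell is in the way.
#'
#' @param pos Length-2 position of the focal cell (um).
#' @param neighbor_pos Two-column matrix of neighbour centres (already
#'   restricted to the search radius `d_n`).
#' @param T_hat Length-2 unit vector of intended motion.
#' @param cone_half_angle Cone half-angle (radians).
#' @return `TRUE` if blocked. A zero `T_hat` returns `FALSE` (no intended
#'   motion).
#' @export
is_constrained <- function(pos, neighbor_pos, T_hat,
                           cone_half_angle = pi / 4) {
  if (is.null(neighbor_pos) || NROW(neighbor_pos) == 0) return(FALSE)
  nrm <- sqrt(sum(T_hat^2))
  if (nrm == 0) return(FALSE)
  T_hat <- T_hat / nrm
  dx <- neighbor_pos[, 1] - pos[1]
  dy <- neighbor_pos[, 2] - pos[2]
  dn <- sqrt(dx^2 + dy^2)
  ok <- dn > 0
  if (!any(ok)) return(FALSE)
  cosang <- (dx[ok] * T_hat[1] + dy[ok] * T_hat[2]) / dn[ok]
  any(cosang >= cos(cone_half_angle) - 1e-12)
}

#' Growth gate from the intracellular switch
#'
#' Growth is permitted only under the full proliferative signal
#' (`M > th_M`, `A < th_A`, `R > th_R`) outside quiescence (`G0_flag == 0`).
#'
#' @param state Data frame with columns `M`, `A`, `R` (vectorised).
#' @param G0_flag Quiescence flag, 0 or 1 (recycled).
#' @param params A [signaling_params()] object (thresholds).
#' @return Integer vector of 0/1 gates.
#' @export
growth_gate <- function(state, G0_flag = 0L, params = signaling_params()) {
  p <- as_signaling_params(params)
  as.integer(state$M > p$th_M & state$A < p$th_A & state$R > p$th_R &
               rep_len(G0_flag, nrow(state)) == 0L)
}

#' Force-dependent axis growth rate
#'
#' Growth is gated on/off by the intracellular signal and shut down outside
#' the force window `(sigma_minus, sigma_plus)`; within it the rate follows a
#' continuous piecewise-linear taper, maximal near zero force. The plateau
#' rate is calibrated so that an unstressed gated cell exactly doubles its
#' volume over one cell cycle.
#'
#' @param sigma Axial force (nN, vectorised); compression positive.
#' @param gate 0/1 growth gate (recycled).
#' @param params A [mechanics_params()] object.
#' @return Axis growth rate (um/h).
#' @export
growth_rate <- function(sigma, gate, params = mechanics_params()) {
  p <- as_mechanics_params(params)
  g_max <- p$b0 * (2^(1 / 3) - 1) / p$T_cyc
  taper <- rep(0, length(sigma))
  inside <- sigma > p$sigma_minus & sigma < p$sigma_plus
  up <- inside & sigma > 0.9 * p$sigma_plus
  lo <- inside & sigma < 0.9 * p$sigma_minus
  taper[inside] <- 1
  taper[up] <- (p$sigma_plus - sigma[up]) / (0.1 * p$sigma_plus)
  taper[lo] <- (sigma[lo] - p$sigma_minus) / (-0.1 * p$sigma_minus)
  g_max * taper * rep_len(gate, length(sigma))
}

# Nonlinear parallel spring: odd, monotone, linearises to k2 at small strain.
f2_spring <- function(u, p) p$k2 * u * (1 + (u / p$u_ref)^2)

#' Update semi-axis deformations of a single cell
#'
#' Advances the passive Maxwell-plus-spring rheology under applied axial
#' forces and accumulates isotropic growth. The passive deformation is
#' projected back onto the incompressibility constraint (the product of the
#' three passive axis lengths is conserved) after every step.
#'
#' @param cell One-row cell tibble.
#' @param f_axes Length-3 vector of axial forces (nN) on the a, b, c axes.
#' @param dt Time step (h); must be below the rheological relaxation scale
#'   `mu_a / k_a`.
#' @param gate 0/1 growth gate.
#' @param sigma Scalar force (nN) entering the growth taper.
#' @param params A [mechanics_params()] object.
#' @return The cell with updated `u0_a`, `u0_b`, `u0_c`, `ug`.
#' @export
update_axes <- function(cell, f_axes = c(0, 0, 0), dt = 0.1, gate = 0L,
                        sigma = 0, params = mechanics_params()) {
  p <- as_mechanics_params(params)
  if (dt > p$mu_a / p$k_a) {
    stop("update_axes: dt exceeds the rheological relaxation scale mu_a/k_a.",
         call. = FALSE)
  }
  u0 <- c(cell$u0_a, cell$u0_b, cell$u0_c)
  # Eq for the passive element: du0/dt = (k/mu [f + p_bar - f2(u0)]) /
  # (f2'(u0) + k), with df/dt = 0 across a step.
  f2p <- p$k2 * (1 + 3 * (u0 / p$u_ref)^2)
  du <- (p$k_a / p$mu_a * (f_axes + p$p_bar - f2_spring(u0, p))) / (f2p + p$k_a)
  u0 <- u0 + dt * du
  # incompressibility projection of the passive element
  l <- p$b0 + u0
  if (any(l <= 0)) {
    stop("update_axes: non-physical negative axis length.", call. = FALSE)
  }
  l <- l * (p$b0^3 / prod(l))^(1 / 3)
  u0 <- l - p$b0
  cell$u0_a <- u0[1]; cell$u0_b <- u0[2]; cell$u0_c <- u0[3]
  cell$ug <- cell$ug + dt * growth_rate(sigma, gate, p)
  cell
}

#' Traction forces for a cell population
#'
#' Migratory cells (AMPK above threshold) that are not physically constrained
#' exert a traction of magnitude `F0 * phi_r` along the unit combination of a
#' persistent random direction and the saturated glucose and chemoattractant
#' gradients. The force is identically zero for cells with `A <= th_A`
#' (proliferative signal), blocked cells, or a vanishing direction
#' combination.
#'
#' @param cells Cell tibble (the `dr_x`, `dr_y` columns supply the random
#'   direction).
#' @param pairs Contact graph from [neighbor_pairs()].
#' @param grad_G,grad_C Two-column matrices of dimensionless glucose and
#'   chemoattractant gradients at the cell centres.
#' @param params A [mechanics_params()] object.
#' @param sig_params A [signaling_params()] object (for `th_A`).
#' @param ecm_factor Optional per-cell multiplier in `[0, 1]` (dense matrix
#'   blocking, off by default in the simulation).
#' @return Tibble with columns `tx`, `ty` (nN) and `constrained` (logical).
#' @export
traction_forces <- function(cells, pairs, grad_G, grad_C,
                            params = mechanics_params(),
                            sig_params = signaling_params(),
                            ecm_factor = 1) {
  p <- as_mechanics_params(params)
  sp <- as_signaling_params(sig_params)
  n <- nrow(cells)
  gG <- if (is.null(grad_G)) matrix(0, n, 2) else grad_G
  gC <- if (is.null(grad_C)) matrix(0, n, 2) else grad_C
  satur <- function(g, K) {
    m2 <- g[, 1]^2 + g[, 2]^2
    g / (K + m2)
  }
  sG <- satur(gG, p$K_G)
  sC <- satur(gC, p$K_C)
  dirx <- p$psi1 * cells$dr_x + p$psi2 * sG[, 1] + p$psi3 * sC[, 1]
  diry <- p$psi1 * cells$dr_y + p$psi2 * sG[, 2] + p$psi3 * sC[, 2]
  phi_r <- stats::runif(n, p$phi_r_range[1], p$phi_r_range[2])
  eligible <- cells$status == "alive" & cells$A > sp$th_A
  # physical constraint against the intended direction (only cells that can
  # exert traction need their neighbour lists)
  constrained <- rep(FALSE, n)
  if (nrow(pairs) > 0 && any(eligible)) {
    el <- which(eligible)
    rel <- pairs$i %in% el | pairs$j %in% el
    pi_ <- pairs$i[rel]; pj <- pairs$j[rel]
    focal <- c(pi_, pj); other <- c(pj, pi_)
    keep <- focal %in% el
    focal <- focal[keep]; other <- other[keep]
    if (length(focal)) {
      nbrs <- split(other, focal)
      for (nm in names(nbrs)) {
        i <- as.integer(nm)
        nb <- nbrs[[nm]]
        constrained[i] <- is_constrained(
          c(cells$x[i], cells$y[i]),
          cbind(cells$x[nb], cells$y[nb]),
          c(dirx[i], diry[i]), p$cone_half_angle)
      }
    }
  }
  on <- eligible & !constrained
  tx <- ifelse(on, p$F0 * phi_r * dirx * ecm_factor, 0)
  ty <- ifelse(on, p$F0 * phi_r * diry * ecm_factor, 0)
  tibble::tibble(tx = tx, ty = ty, constrained = constrained)
}

# Contact geometry for the velocity solve: sphere-sphere overlap chord areas
# plus fixed substrate fraction; remainder faces the interstitial fluid.
contact_areas <- function(cells, pairs, p) {
  r <- cell_radius(cells, p)
  A_tot <- 4 * pi * r^2
  A_ij <- numeric(nrow(pairs))
  if (nrow(pairs) > 0) {
    ri <- r[pairs$i]; rj <- r[pairs$j]; d <- pairs$dist
    touching <- d < ri + rj
    # chord radius of the sphere-sphere intersection circle
    a2 <- (4 * d^2 * ri^2 - (d^2 - rj^2 + ri^2)^2) / (4 * d^2)
    A_ij[touching] <- pi * pmax(a2[touching], 0)
    A_ij <- pmin(A_ij, 0.45 * pmin(A_tot[pairs$i], A_tot[pairs$j]))
  }
  A_is <- p$f_substrate * A_tot
  sum_Aij <- numeric(nrow(cells))
  if (nrow(pairs) > 0) {
    sm <- rowsum(c(A_ij, A_ij), c(pairs$i, pairs$j))
    sum_Aij[as.integer(rownames(sm))] <- sm[, 1]
  }
  A_if <- pmax(A_tot - A_is - sum_Aij, 0.05 * A_tot)
  list(A_tot = A_tot, A_ij = A_ij, A_is = A_is, A_if = A_if,
       r_ib = p$b0 + cells$u0_b + cells$ug)
}

# Pairwise reactive (overlap) forces from the nonlinear spring law; equal and
# opposite by construction. Returns per-cell force components plus the
# largest pairwise compressive magnitude (used by the growth taper).
reactive_forces <- function(cells, pairs, p) {
  n <- nrow(cells)
  fx <- numeric(n); fy <- numeric(n); sigma <- numeric(n)
  if (nrow(pairs) == 0) return(list(fx = fx, fy = fy, sigma = sigma))
  r <- cell_radius(cells, p)
  overlap <- r[pairs$i] + r[pairs$j] - pairs$dist
  act <- overlap > 0
  if (!any(act)) return(list(fx = fx, fy = fy, sigma = sigma))
  pi_ <- pairs$i[act]; pj <- pairs$j[act]
  ux <- (cells$x[pi_] - cells$x[pj]) / pairs$dist[act]
  uy <- (cells$y[pi_] - cells$y[pj]) / pairs$dist[act]
  fmag <- f2_spring(overlap[act], p)
  # dead cells are inert: no force generation through them
  alive_i <- cells$status[pi_] == "alive"
  alive_j <- cells$status[pj] == "alive"
  fmag <- fmag * as.numeric(alive_i & alive_j)
  grp <- c(pi_, pj)
  sm <- rowsum(cbind(c(fmag * ux, -fmag * ux), c(fmag * uy, -fmag * uy)), grp)
  rows <- as.integer(rownames(sm))
  fx[rows] <- sm[, 1]; fy[rows] <- sm[, 2]
  mx <- tapply(c(fmag, fmag), grp, max)
  sigma[as.integer(names(mx))] <- as.numeric(mx)
  list(fx = fx, fy = fy, sigma = sigma)
}

#' Overdamped velocity solve for the population
#'
#' Solves the force balance in which substrate/fluid drag and cell-cell
#' friction balance the surface forces (traction plus pairwise reactive
#' forces), i.e. a symmetric positive-definite linear system per velocity
#' component.
#'
#' @param cells Cell tibble.
#' @param forces Tibble/list with per-cell `fx`, `fy` (nN): traction plus
#'   pairwise contributions.
#' @param pairs Contact graph from [neighbor_pairs()].
#' @param params A [mechanics_params()] object.
#' @return Two-column matrix of velocities (um/h).
#' @export
solve_velocities <- function(cells, forces, pairs,
                             params = mechanics_params()) {
  p <- as_mechanics_params(params)
  n <- nrow(cells)
  geo <- contact_areas(cells, pairs, p)
  pref <- geo$A_tot / (6 * pi * geo$r_ib)       # um
  drag <- p$chi_drag * (geo$A_if * p$mu_f_i + geo$A_is * p$mu_s_i)
  if (any(drag <= 0)) {
    stop("solve_velocities: singular drag (isolated cell with zero contact).",
         call. = FALSE)
  }
  rhs_x <- pref * forces$fx
  rhs_y <- pref * forces$fy
  if (nrow(pairs) == 0) {
    return(cbind(rhs_x / drag, rhs_y / drag))
  }
  w <- p$chi_drag * p$mu_cell_i * geo$A_ij
  w_sum <- numeric(n)
  sm <- rowsum(c(w, w), c(pairs$i, pairs$j))
  w_sum[as.integer(rownames(sm))] <- sm[, 1]
  Amat <- Matrix::sparseMatrix(
    i = c(seq_len(n), pairs$i, pairs$j),
    j = c(seq_len(n), pairs$j, pairs$i),
    x = c(drag + w_sum, -w, -w),
    dims = c(n, n))
  sol <- Matrix::solve(Amat, cbind(rhs_x, rhs_y))
  as.matrix(sol)
}

#' Divide a cell into two daughters
#'
#' Both daughters start at resting volume, offset by one resting semi-axis on
#' either side of the parent centre along a random division axis; they inherit
#' the parent's signalling state and restart their cycle clocks.
#'
#' @param cell One-row cell tibble (volume should be about twice resting).
#' @param new_id Id for the second daughter.
#' @param params A [mechanics_params()] object.
#' @return Two-row tibble of daughters.
#' @export
divide_cell <- function(cell, new_id, params = mechanics_params()) {
  p <- as_mechanics_params(params)
  theta <- stats::runif(1, 0, 2 * pi)
  off <- c(cos(theta), sin(theta)) * p$b0
  d1 <- cell; d2 <- cell
  d1$x <- cell$x + off[1]; d1$y <- cell$y + off[2]
  d2$x <- cell$x - off[1]; d2$y <- cell$y - off[2]
  d2$id <- new_id
  for (d in c("u0_a", "u0_b", "u0_c", "ug")) {
    d1[[d]] <- 0; d2[[d]] <- 0
  }
  d1$cycle_clock <- 0; d2$cycle_clock <- 0
  d1$cycle_phase <- "G1"; d2$cycle_phase <- "G1"
  dplyr::bind_rows(d1, d2)
}

#' Advance the cell-cycle clocks
#'
#' The clock advances only while the growth gate is on (growth arrest
#' lengthens the effective cycle); the phase follows the configured G1/S/G2/M
#' fractions of the cycle length.
#'
#' @param cells Cell tibble.
#' @param dt Time step (h).
#' @param gate Integer 0/1 vector (recycled).
#' @param params A [mechanics_params()] object.
#' @return Updated cell tibble.
#' @export
advance_cycle <- function(cells, dt, gate, params = mechanics_params()) {
  p <- as_mechanics_params(params)
  cells$cycle_clock <- cells$cycle_clock +
    dt * rep_len(gate, nrow(cells)) * (cells$status == "alive")
  frac <- pmin(cells$cycle_clock / p$T_cyc, 1)
  cf <- cumsum(p$cycle_fractions)
  cells$cycle_phase <- dplyr::case_when(
    frac < cf[1] ~ "G1",
    frac < cf[2] ~ "S",
    frac < cf[3] ~ "G2",
    TRUE ~ "M"
  )
  cells
}

#' Apply phase-specific drug kill
#'
#' A living cell becomes apoptotic when the local drug concentration reaches
#' the kill threshold and its cycle phase is in the drug's target set.
#' Apoptotic cells persist as inert markers.
#'
#' @param cells Cell tibble.
#' @param drug_local Drug concentration sampled at each cell centre.
#' @param th_D Kill threshold.
#' @param targeting `"S-G2-M"` (default) or `"G1"`.
#' @return Updated cell tibble.
#' @export
apply_drug_kill <- function(cells, drug_local, th_D,
                            targeting = c("S-G2-M", "G1")) {
  targeting <- match.arg(targeting)
  target_set <- if (targeting == "S-G2-M") c("S", "G2", "M") else "G1"
  kill <- cells$status == "alive" & drug_local >= th_D &
    cells$cycle_phase %in% target_set
  cells$status[kill] <- "apoptotic"
  cells
}
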