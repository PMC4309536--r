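#' Scenario configuration for the hybrid simulation
#'
#' Bundles all module parameter blocks with the scenario descriptors:
#' domain, vessel count, post-resection cell layout, intervention schedule
#' and seeds. The defaults describe the reference post-surgery setting: a
#' 10 mm square of brain tissue, a central resection cavity emptied at
#' `t = 0`, residual invasive cells scattered in the surrounding annulus and
#' vessels placed with near-uniform density.
#'
#' @param L Domain side (mm).
#' @param n_grid Grid nodes per side.
#' @param dt_cell Cell/intracellular step (h).
#' @param field_substeps Field substeps per field update (implicit stepping,
#'   so 1 suffices at the default `dt_cell`).
#' @param field_every Cell steps between field updates; the fields advance
#'   implicitly with step `dt_cell * field_every` (their relaxation times are
#'   hours, so 1 h updates lose nothing).
#' @param t_end End time (h).
#' @param seed Master seed; all stochastic elements derive from it.
#' @param N_b Number of vessel sites.
#' @param vessel_min_sep Minimum vessel separation (mm).
#' @param N_init Residual invasive cells after surgery.
#' @param cavity_radius Resection cavity radius (mm).
#' @param annulus Radial interval (mm from the domain centre) in which the
#'   residual cells are scattered.
#' @param psi Direction-weight triple `(psi1, psi2, psi3)` for random
#'   motility, glucose gradient and chemoattractant gradient.
#' @param injection `NULL`, or list with `sites` (matrix, mm), `windows`
#'   (two-column matrix of start/end hours) and `rate` (multiple of the base
#'   injection rate).
#' @param drug `NULL`, or list with `start` (h), `rate` (multiple of the
#'   reference infusion rate), `targeting` (`"S-G2-M"` or `"G1"`).
#' @param diff_left Diffusion multiplier applied to the left half of the
#'   domain (tissue-stiffness scenarios; 1 = homogeneous).
#' @param ecm_block If `TRUE`, traction is scaled by
#'   `max(0, 1 - rho / (0.85 rho_star))`.
#' @param max_cells Crowding cap: divisions are suppressed (and logged) once
#'   the population reaches this size.
#' @param record_traj Record per-step cell trajectories.
#' @param record_every Interval (h) between metric/trajectory records.
#' @param signaling,mechanics,fields Parameter blocks; psi overrides the
#'   mechanics block.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(L = 10, n_grid = 101, dt_cell = 0.5,
                       field_substeps = 1, field_every = 2, t_end = 240,
                       seed = 1,
                       N_b = 47, vessel_min_sep = 0.8,
                       N_init = 50, cavity_radius = 0.7,
                       annulus = c(2.4, 4.5),
                       psi = c(0.2, 0.8, 0),
                       injection = NULL, drug = NULL,
                       diff_left = 1, ecm_block = FALSE,
                       max_cells = 1000,
                       record_traj = TRUE, record_every = 1,
                       signaling = signaling_params(),
                       mechanics = NULL,
                       fields = field_params()) {
  if (is.null(mechanics)) {
    mechanics <- mechanics_params(psi1 = psi[1], psi2 = psi[2], psi3 = psi[3])
  }
  cfg <- list(L = L, n_grid = n_grid, dt_cell = dt_cell,
              field_substeps = field_substeps, field_every = field_every,
              t_end = t_end, seed = seed,
              N_b = N_b, vessel_min_sep = vessel_min_sep,
              N_init = N_init, cavity_radius = cavity_radius,
              annulus = annulus, psi = psi,
              injection = injection, drug = drug,
              diff_left = diff_left, ecm_block = ecm_block,
              max_cells = max_cells,
              record_traj = record_traj, record_every = record_every,
              signaling = as_signaling_params(signaling),
              mechanics = as_mechanics_params(mechanics),
              fields = as_field_params(fields))
  class(cfg) <- "sim_config"
  cfg
}

#' Configuration hash embedded in every output
#' @param config A [sim_config()].
#' @return Character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "seed")])
}

#' Place vessel sites with near-uniform density
#'
#' Seeded uniform rejection sampling with a minimum-separation rule; sites
#' inside the resection cavity are excluded and positions are snapped to grid
#' nodes.
#'
#' @param N_b Number of vessels.
#' @param state A [field_state()] (for grid geometry).
#' @param min_sep Minimum separation (mm).
#' @param cavity Optional list with `center` (mm) and `radius` (mm).
#' @return List with `sites` (matrix of mm coordinates) and raster `I_B`.
#' @export
make_vessels <- function(N_b, state, min_sep = 0.8, cavity = NULL) {
  L <- state$L
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < N_b && tries < 20000) {
    tries <- tries + 1
    cand <- stats::runif(2, 0.02 * L, 0.98 * L)
    if (!is.null(cavity) &&
        sqrt(sum((cand - cavity$center)^2)) < cavity$radius) next
    if (nrow(pts) > 0 &&
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) < min_sep) next
    pts <- rbind(pts, cand)
  }
  if (nrow(pts) < N_b) {
    stop("make_vessels: could not place ", N_b,
         " vessels at separation ", min_sep, call. = FALSE)
  }
  # snap to grid nodes
  i <- round(pts[, 1] / state$h) + 1L
  j <- round(pts[, 2] / state$h) + 1L
  sites <- cbind((i - 1L) * state$h, (j - 1L) * state$h)
  I_B <- matrix(0L, state$n, state$n)
  I_B[cbind(i, j)] <- 1L
  # smooth fixed-width footprint so supply converges under grid refinement
  W_B <- source_footprint(state, sites, sigma = 0.1)
  list(sites = sites, I_B = I_B, W_B = W_B, N_b = N_b)
}

#' Initialise a simulation state
#'
#' Empties the resection cavity, scatters the residual invasive cells in the
#' surrounding annulus (migratory-branch signalling state), places vessels,
#' pre-equilibrates oxygen and glucose to their no-tumour steady state, and
#' computes the scenario reference levels: near-vessel glucose `G_ref`
#' (anchor of the glucose signal), the chemoattractant normalisation and the
#' drug kill threshold.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_state`.
#' @export
initialize_sim <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  fs <- field_state(L = cfg$L, n = cfg$n_grid, params = cfg$fields)
  if (cfg$diff_left != 1) {
    left <- fs$xs < cfg$L / 2
    fs$diff_scale[left, ] <- cfg$diff_left
  }
  center <- c(cfg$L / 2, cfg$L / 2)
  cavity <- list(center = center, radius = cfg$cavity_radius)
  vessels <- make_vessels(cfg$N_b, fs, cfg$vessel_min_sep, cavity)
  p <- fs$params
  dtf <- cfg$dt_cell * cfg$field_every / cfg$field_substeps
  # no-tumour steady oxygen and glucose (steady state of the discrete
  # scheme, so the signal anchor is exactly consistent with the dynamics)
  fs$K <- discrete_steady_field(fs, p$D_K, p$mu_K, p$r_K * vessels$W_B, dtf)
  fs$G <- discrete_steady_field(fs, p$D_G, p$mu_G, p$r_G * vessels$W_B, dtf)
  # the glucose-signal anchor is a units conversion: it is defined on
  # homogeneous reference tissue so that tissue-stiffness scenarios do not
  # rescale the switch input of unaffected regions
  if (cfg$diff_left == 1) {
    G_ref <- max(fs$G[vessels$I_B == 1L])
  } else {
    hom <- fs; hom$diff_scale <- matrix(1, fs$n, fs$n)
    G_hom <- discrete_steady_field(hom, p$D_G, p$mu_G, p$r_G * vessels$W_B,
                                   dtf)
    G_ref <- max(G_hom[vessels$I_B == 1L])
  }
  # chemoattractant normalisation: the steady level, at the strongest
  # injection rate considered, on the mid-annulus ring where the residual
  # cells start -- so the dimensionless gradient driving chemotaxis is of
  # order one at the cells that must respond
  C_scale <- 1
  if (!is.null(cfg$injection)) {
    W_inj <- source_footprint(fs, cfg$injection$sites, sigma = 0.1)
    cfg$injection$src <- cfg$injection$rate * p$l_in_C * W_inj
    # like G_ref, the normalisation is defined on homogeneous reference
    # tissue so heterogeneity scenarios do not rescale the chemotactic gain
    hom <- fs; hom$diff_scale <- matrix(1, fs$n, fs$n)
    C_ref_field <- discrete_steady_field(hom, p$D_C, p$mu_C,
                                         567 * p$l_in_C * W_inj, dtf)
    tmp <- fs; tmp$C <- C_ref_field
    r_ref <- mean(cfg$annulus)
    ang <- seq(0, 2 * pi, length.out = 33)[-33]
    ring <- cbind(center[1] + r_ref * cos(ang), center[2] + r_ref * sin(ang))
    ring <- ring[ring[, 1] > 0 & ring[, 1] < cfg$L &
                   ring[, 2] > 0 & ring[, 2] < cfg$L, , drop = FALSE]
    C_scale <- mean(sample_field(tmp, "C", ring[, 1], ring[, 2]))
  }
  # drug kill threshold: half the near-vessel steady level at the reference
  # infusion rate (multiplier 1); only needed when a drug is scheduled
  th_D <- Inf
  if (!is.null(cfg$drug)) {
    D_ref <- discrete_steady_field(fs, p$D_D, p$mu_D, 1.0 * vessels$W_B, dtf)
    th_D <- 0.5 * max(D_ref[vessels$I_B == 1L])
  }
  # residual invasive cells in the annulus
  n_try <- 0; xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < cfg$N_init && n_try < 100000) {
    n_try <- n_try + 1
    r <- sqrt(stats::runif(1, cfg$annulus[1]^2, cfg$annulus[2]^2))
    th <- stats::runif(1, 0, 2 * pi)
    cx <- center[1] + r * cos(th); cy <- center[2] + r * sin(th)
    if (cx < 0.02 * cfg$L || cx > 0.98 * cfg$L ||
        cy < 0.02 * cfg$L || cy > 0.98 * cfg$L) next
    if (length(xs) > 0 &&
        min((xs - cx)^2 + (ys - cy)^2) < (3 * cfg$mechanics$b0 / 1000)^2) next
    xs <- c(xs, cx); ys <- c(ys, cy)
  }
  if (length(xs) < cfg$N_init) {
    stop("initialize_sim: infeasible cell placement (too many cells).",
         call. = FALSE)
  }
  cells <- new_cells(xs * 1000, ys * 1000, params = cfg$mechanics,
                     sig_params = cfg$signaling)
  if (cfg$N_init > 0) {
    ang <- stats::runif(nrow(cells), 0, 2 * pi)
    cells$dr_x <- cos(ang); cells$dr_y <- sin(ang); cells$dr_age <- 0
  }
  st <- list(
    t = 0, cells = cells, fields = fs, vessels = vessels,
    cavity = cavity, config = cfg,
    G_ref = G_ref, C_scale = C_scale, th_D = th_D,
    next_id = nrow(cells) + 1L,
    step_count = 0L,
    n_divisions = 0L, n_deaths = 0L,
    events = list(),
    traj = list(), metrics = list(),
    solvers = NULL,
    rng = .Random.seed
  )
  class(st) <- "sim_state"
  st
}

#' @export
print.sim_state <- function(x, ...) {
  alive <- sum(x$cells$status == "alive")
  cat(sprintf("<sim_state> t = %g h, %d cells alive (%d dead), %d vessels\n",
              x$t, alive, sum(x$cells$status != "alive"), x$vessels$N_b))
  invisible(x)
}

# record a metrics/trajectory row
.record <- function(st) {
  cfg <- st$config
  counts <- population_counts(st$cells, st$vessels,
                              r_bv = 0.02 * cfg$L * 1000)
  st$metrics[[length(st$metrics) + 1L]] <-
    dplyr::bind_cols(tibble::tibble(t = st$t), counts)
  if (cfg$record_traj) {
    st$traj[[length(st$traj) + 1L]] <- tibble::tibble(
      t = st$t, id = st$cells$id, x = st$cells$x, y = st$cells$y,
      phase = st$cells$phase, status = st$cells$status)
  }
  st
}

#' Advance the hybrid state by one cell step
#'
#' Fixed update order: sense (sample fields at cell centres, map glucose to
#' the switch input), intracellular dynamics, phase reclassification,
#' traction/contact forces, velocity solve and movement, growth / cycle /
#' division / drug deaths, then field advancement on the updated indicators.
#'
#' @param st A [sim_state()][initialize_sim()].
#' @return The advanced state.
#' @export
sim_step <- function(st) {
  cfg <- st$config
  mp <- cfg$mechanics; sp <- cfg$signaling; fp <- st$fields$params
  dt <- cfg$dt_cell
  cells <- st$cells
  alive <- cells$status == "alive"
  n <- nrow(cells)
  xmm <- cells$x / 1000; ymm <- cells$y / 1000

  # (1) sense
  G_loc <- sample_field(st$fields, "G", xmm, ymm)
  cells$G_signal <- glucose_to_signal(G_loc, st$G_ref, fp$G_cap)
  grad_G <- sample_gradient(st$fields, "G", xmm, ymm) / st$G_ref
  grad_C <- sample_gradient(st$fields, "C", xmm, ymm) / st$C_scale

  # (2) intracellular switch (dimensionless time = hours / tau_hours)
  if (any(alive)) {
    adv <- signal_advance(cells$M[alive], cells$A[alive], cells$R[alive],
                          cells$G_signal[alive], sp,
                          dt_total = dt / sp$tau_hours)
    cells$M[alive] <- adv$M; cells$A[alive] <- adv$A; cells$R[alive] <- adv$R
  }

  # (3) phase
  old_phase <- cells$phase
  cells$phase <- classify_phase(cells, sp)
  switched <- which(alive & cells$phase != old_phase)
  if (length(switched)) {
    st$events[[length(st$events) + 1L]] <- list(
      t = st$t, event = paste0("phase:", cells$phase[switched]),
      id = cells$id[switched])
  }

  # (4) random-walk persistence, traction and contact forces
  cells$dr_age <- cells$dr_age + dt
  redraw <- alive & cells$dr_age >= mp$tau_persist
  if (any(redraw)) {
    ang <- stats::runif(sum(redraw), 0, 2 * pi)
    cells$dr_x[redraw] <- cos(ang); cells$dr_y[redraw] <- sin(ang)
    cells$dr_age[redraw] <- 0
  }
  pairs <- neighbor_pairs(cells, mp$d_n)
  ecm_factor <- 1
  if (cfg$ecm_block) {
    rho_loc <- sample_field(st$fields, "rho", xmm, ymm)
    ecm_factor <- pmax(0, 1 - rho_loc / (0.85 * fp$rho_star))
  }
  tr <- traction_forces(cells, pairs, grad_G, grad_C, mp, sp, ecm_factor)
  rf <- reactive_forces(cells, pairs, mp)
  cells$sigma <- rf$sigma

  # (5) velocities and movement (displacement capped at one resting radius)
  vel <- solve_velocities(cells,
                          list(fx = tr$tx + rf$fx, fy = tr$ty + rf$fy),
                          pairs, mp)
  vel[!alive, ] <- 0
  disp <- sqrt(vel[, 1]^2 + vel[, 2]^2) * dt
  scale <- ifelse(disp > mp$v_cap, mp$v_cap / disp, 1)
  cells$vx <- vel[, 1] * scale; cells$vy <- vel[, 2] * scale
  cells$x <- pmin(pmax(cells$x + cells$vx * dt, 0), cfg$L * 1000)
  cells$y <- pmin(pmax(cells$y + cells$vy * dt, 0), cfg$L * 1000)

  # (6) growth, cycle, division, drug kill
  gate <- growth_gate(cells, cells$G0_flag, sp) * as.integer(alive)
  cells$ug <- cells$ug + dt * growth_rate(cells$sigma, gate, mp)
  cells <- advance_cycle(cells, dt, gate, mp)
  V0 <- 4 / 3 * pi * mp$b0^3
  vol <- cell_volume(cells, mp)
  ready <- which(alive & gate == 1L & cells$cycle_clock >= mp$T_cyc &
                   vol >= 2 * V0 * 0.99)
  if (length(ready)) {
    room <- max(cfg$max_cells - nrow(cells), 0L)
    if (length(ready) > room) {
      capped <- ready[(room + 1L):length(ready)]
      st$events[[length(st$events) + 1L]] <- list(
        t = st$t, event = "division_capped", id = cells$id[capped])
      ready <- ready[seq_len(room)]
    }
    if (length(ready)) {
      k <- length(ready)
      theta <- stats::runif(k, 0, 2 * pi)
      offx <- cos(theta) * mp$b0; offy <- sin(theta) * mp$b0
      d1 <- cells[ready, ]; d2 <- cells[ready, ]
      d1$x <- d1$x + offx; d1$y <- d1$y + offy
      d2$x <- d2$x - offx; d2$y <- d2$y - offy
      d2$id <- st$next_id + seq_len(k) - 1L
      for (col in c("u0_a", "u0_b", "u0_c", "ug", "cycle_clock")) {
        d1[[col]] <- 0; d2[[col]] <- 0
      }
      d1$cycle_phase <- "G1"; d2$cycle_phase <- "G1"
      st$events[[length(st$events) + 1L]] <- list(
        t = st$t, event = "division", id = cells$id[ready])
      st$next_id <- st$next_id + k
      st$n_divisions <- st$n_divisions + k
      cells <- dplyr::bind_rows(cells[-ready, ], d1, d2)
    }
  }
  if (!is.null(cfg$drug) && st$t >= cfg$drug$start) {
    D_loc <- sample_field(st$fields, "D", cells$x / 1000, cells$y / 1000)
    before <- cells$status == "alive"
    cells <- apply_drug_kill(cells, D_loc, st$th_D,
                             targeting = cfg$drug$targeting)
    died <- which(before & cells$status == "apoptotic")
    if (length(died)) {
      st$n_deaths <- st$n_deaths + length(died)
      st$events[[length(st$events) + 1L]] <- list(
        t = st$t, event = "death", id = cells$id[died])
    }
  }

  # (7) fields on the updated configuration (implicit update every
  # field_every-th cell step)
  st$step_count <- st$step_count + 1L
  if (st$step_count %% cfg$field_every == 0L) {
  rast <- rasterize_cells(cells, st$fields)
  counts_mat <- matrix(0, st$fields$n, st$fields$n)
  al <- cells$status == "alive"
  if (any(al)) {
    tb <- table(rast$node_i[al], rast$node_j[al])
    counts_mat[cbind(as.integer(rep(rownames(tb), ncol(tb))),
                     as.integer(rep(colnames(tb), each = nrow(tb))))] <-
      as.numeric(tb)
  }
  dtf <- dt * cfg$field_every / cfg$field_substeps
  if (is.null(st$solvers) || st$solvers$dt != dtf) {
    st$solvers <- field_solvers(st$fields, dtf)
  }
  inj <- cfg$injection
  t_base <- st$t - dt * (cfg$field_every - 1)
  for (s in seq_len(cfg$field_substeps)) {
    st$fields <- step_fields(st$fields, rast, st$vessels, st$solvers,
                             dt = dtf, t = t_base + (s - 1) * dtf,
                             injection = inj, n_cells_per_node = counts_mat)
  }
  }

  st$cells <- cells
  st$t <- st$t + dt
  st
}

#' Run a configured scenario
#'
#' Initialises (or continues) a state and advances it to `t_end`, recording
#' population metrics (and optionally trajectories) on the configured
#' interval.
#'
#' @param config A [sim_config()]; ignored when `state` is supplied.
#' @param state Optional existing `sim_state` to continue (restart).
#' @param t_end Override end time (h).
#' @return The final `sim_state`; tidy accessors: [sim_metrics()],
#'   [sim_trajectories()].
#' @export
run_scenario <- function(config = sim_config(), state = NULL, t_end = NULL) {
  st <- if (is.null(state)) initialize_sim(config) else state
  if (!is.null(state)) assign(".Random.seed", st$rng, envir = globalenv())
  cfg <- st$config
  if (is.null(t_end)) t_end <- cfg$t_end
  if (st$t == 0) st <- .record(st)
  next_rec <- st$t + cfg$record_every
  while (st$t < t_end - 1e-9) {
    st <- sim_step(st)
    if (st$t >= next_rec - 1e-9) {
      st <- .record(st)
      next_rec <- next_rec + cfg$record_every
    }
  }
  st$rng <- get(".Random.seed", envir = globalenv())
  st$solvers <- NULL  # factorisations are rebuilt on continue
  st
}

#' Population metrics recorded during a run
#' @param st A `sim_state` returned by [run_scenario()].
#' @return Tibble with one row per record time.
#' @export
sim_metrics <- function(st) dplyr::bind_rows(st$metrics)

#' Event log of a run (divisions, deaths, phase switches)
#' @param st A `sim_state` returned by [run_scenario()].
#' @return Tibble (t, event, id).
#' @export
sim_events <- function(st) {
  if (!length(st$events)) {
    return(tibble::tibble(t = numeric(), event = character(), id = integer()))
  }
  lens <- vapply(st$events, function(e) length(e$id), integer(1))
  tibble::tibble(
    t = rep(vapply(st$events, `[[`, numeric(1), "t"), lens),
    event = unlist(lapply(st$events, function(e) rep_len(e$event, length(e$id)))),
    id = unlist(lapply(st$events, `[[`, "id")))
}

#' Recorded trajectories of a run
#' @param st A `sim_state` returned by [run_scenario()].
#' @return Tibble (t, id, x, y, phase, status); positions in um.
#' @export
sim_trajectories <- function(st) dplyr::bind_rows(st$traj)

#' Scenario presets matching the published experiments
#'
#' * `"postsurgery_bv"`: residual invasive cells respond to glucose
#'   gradients and random motility; vessel-density sweeps (164 h horizon).
#' * `"localization"`: chemoattractant injected at the cavity centre from
#'   `t = 0` (240 h).
#' * `"injection_sweep"`: four peri-cavity injection sites; rate is swept
#'   over multiples of the base rate (240 h).
#' * `"chemo"`: S-G2-M-targeting drug infused from `t = 150` h (165 h).
#' * `"heterogeneous"`: left-half diffusion reduced by `diff_left`,
#'   peri-cavity injection (240 h).
#'
#' @param name Preset name.
#' @param seed Master seed.
#' @param N_b Vessel count.
#' @param psi1 Random-motility weight; the remaining weight goes to the
#'   glucose gradient (`postsurgery_bv`, `chemo`) or the chemoattractant
#'   gradient (injection presets).
#' @param injection_rate Injection-rate multiplier (injection presets).
#' @param drug_rate Drug infusion multiplier (`chemo`).
#' @param diff_left Left-half diffusion multiplier (`heterogeneous`).
#' @param ... Further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
preset_config <- function(name = c("postsurgery_bv", "localization",
                                   "injection_sweep", "chemo",
                                   "heterogeneous"),
                          seed = 1, N_b = 47, psi1 = 0.2,
                          injection_rate = 567, drug_rate = 22.7,
                          diff_left = 0.1, ...) {
  name <- match.arg(name)
  L <- 10
  center <- c(L / 2, L / 2)
  peri <- rbind(c(0.58, 0.5), c(0.5, 0.58), c(0.42, 0.5), c(0.5, 0.42)) * L
  always <- cbind(0, Inf)
  args <- switch(name,
    postsurgery_bv = list(
      seed = seed, N_b = N_b, t_end = 164,
      psi = c(psi1, 1 - psi1, 0)),
    localization = list(
      seed = seed, N_b = N_b, t_end = 240,
      psi = c(psi1, 0, 1 - psi1),
      injection = list(sites = matrix(center, 1, 2), windows = always,
                       rate = injection_rate)),
    injection_sweep = list(
      seed = seed, N_b = N_b, t_end = 240,
      psi = c(psi1, 0, 1 - psi1),
      injection = list(sites = peri, windows = always,
                       rate = injection_rate)),
    chemo = list(
      seed = seed, N_b = N_b, t_end = 165,
      psi = c(psi1, 1 - psi1, 0),
      drug = list(start = 150, rate = drug_rate, targeting = "S-G2-M"),
      fields = field_params(l_b_D = drug_rate)),
    heterogeneous = list(
      seed = seed, N_b = N_b, t_end = 240,
      psi = c(psi1, 0, 1 - psi1),
      injection = list(sites = peri, windows = always, rate = injection_rate),
      diff_left = diff_left)
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}
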