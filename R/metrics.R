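#' Windowed cell speeds from a trajectory table
#'
#' Net displacement over an observation window divided by the window length,
#' per cell, in um/h.
#'
#' @param traj Trajectory tibble (`t` in h, `x`, `y` in um, `id`), e.g. from
#'   [sim_trajectories()].
#' @param window Observation window (h).
#' @return Tibble with `id`, `t` (window end) and `speed` (um/h).
#' @export
cell_speed <- function(traj, window = 1) {
  traj |>
    dplyr::group_by(.data$id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) return(tibble::tibble(t = numeric(), speed = numeric()))
      # resample on the window grid
      tw <- seq(min(df$t), max(df$t), by = window)
      if (length(tw) < 2) return(tibble::tibble(t = numeric(), speed = numeric()))
      xw <- stats::approx(df$t, df$x, tw)$y
      yw <- stats::approx(df$t, df$y, tw)$y
      tibble::tibble(t = tw[-1],
                     speed = sqrt(diff(xw)^2 + diff(yw)^2) / window)
    }) |>
    dplyr::ungroup()
}

#' Turning angles along trajectories
#'
#' Angle (degrees, in `[0, 180]`) between successive displacement vectors on
#' the observation-window grid. Windows whose displacement falls below the
#' noise floor are flagged `NA` (direction undefined).
#'
#' @inheritParams cell_speed
#' @param noise_floor Minimum displacement (um) for a defined direction.
#' @return Tibble with `id`, `t` and `angle` (degrees).
#' @export
direction_change <- function(traj, window = 1, noise_floor = 0.5) {
  traj |>
    dplyr::group_by(.data$id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) return(tibble::tibble(t = numeric(), angle = numeric()))
      tw <- seq(min(df$t), max(df$t), by = window)
      if (length(tw) < 3) return(tibble::tibble(t = numeric(), angle = numeric()))
      dx <- diff(stats::approx(df$t, df$x, tw)$y)
      dy <- diff(stats::approx(df$t, df$y, tw)$y)
      len <- sqrt(dx^2 + dy^2)
      k <- seq_len(length(dx) - 1)
      cosang <- (dx[k] * dx[k + 1] + dy[k] * dy[k + 1]) /
        (len[k] * len[k + 1])
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      ang[len[k] < noise_floor | len[k + 1] < noise_floor] <- NA_real_
      tibble::tibble(t = tw[-(1:2)], angle = ang)
    }) |>
    dplyr::ungroup()
}

#' Compartment population counts
#'
#' A living cell is "at a vessel" when within `r_bv` of a vessel site and in
#' the proliferative phase; "invasive away" when migratory and farther than
#' `r_bv` from every vessel.
#'
#' @param cells Cell tibble (positions in um).
#' @param vessels Vessel map from [make_vessels()] (sites in mm), or `NULL`.
#' @param r_bv At-vessel radius (um).
#' @return One-row tibble: `alive`, `proliferative_at_BV`, `invasive_away`,
#'   `dead`.
#' @export
population_counts <- function(cells, vessels, r_bv = 200) {
  alive <- cells$status == "alive"
  if (is.null(vessels) || nrow(cells) == 0 || !any(alive)) {
    near <- rep(FALSE, nrow(cells))
  } else {
    vs <- vessels$sites * 1000  # mm -> um
    d2min <- rep(Inf, nrow(cells))
    for (k in seq_len(nrow(vs))) {
      d2 <- (cells$x - vs[k, 1])^2 + (cells$y - vs[k, 2])^2
      d2min <- pmin(d2min, d2)
    }
    near <- d2min <= r_bv^2
  }
  tibble::tibble(
    alive = sum(alive),
    proliferative_at_BV = sum(alive & near & cells$phase == "Tp"),
    invasive_away = sum(alive & !near & cells$phase == "Tm"),
    dead = sum(cells$status == "apoptotic")
  )
}

#' Count invasive cells localized in the peri-cavity strip
#'
#' The strip is the band of width `w_th` around the resection cavity:
#' `0 < dist(P, cavity) < w_th`. Cells inside the cavity are excluded, and by
#' default only *invasive* (migratory-phase) cells are counted -- the
#' localization strategy draws migratory cells back, whereas proliferative
#' colonies at vessels that happen to fall inside the strip are a different
#' compartment. Pass `phase = NULL` to count every living cell.
#'
#' @param cells Cell tibble (positions in um).
#' @param cavity List with `center` (mm) and `radius` (mm).
#' @param w_th Strip width (mm).
#' @param half `NULL`, `"left"` or `"right"`: restrict to one half of the
#'   domain of side `L` (mm).
#' @param L Domain side (mm), needed when `half` is set.
#' @param phase Phase filter (default `"Tm"`), or `NULL` for all living
#'   cells.
#' @param vessels Optional vessel map: cells within `r_bv` of a vessel site
#'   are excluded (they belong to the at-vessel compartment, which the
#'   localization count is disjoint from).
#' @param r_bv At-vessel exclusion radius (um).
#' @return Integer count of localized cells.
#' @export
localized_count <- function(cells, cavity, w_th, half = NULL, L = 10,
                            phase = "Tm", vessels = NULL, r_bv = 200) {
  if (w_th <= 0) return(0L)
  alive <- cells$status == "alive"
  if (!is.null(phase)) alive <- alive & cells$phase == phase
  if (!is.null(vessels) && nrow(cells) > 0) {
    vs <- vessels$sites * 1000
    d2min <- rep(Inf, nrow(cells))
    for (k in seq_len(nrow(vs))) {
      d2min <- pmin(d2min, (cells$x - vs[k, 1])^2 + (cells$y - vs[k, 2])^2)
    }
    alive <- alive & d2min > r_bv^2
  }
  xmm <- cells$x / 1000; ymm <- cells$y / 1000
  d <- sqrt((xmm - cavity$center[1])^2 + (ymm - cavity$center[2])^2) -
    cavity$radius
  inside <- alive & d > 0 & d < w_th
  if (!is.null(half)) {
    inside <- inside & if (half == "left") xmm < L / 2 else xmm >= L / 2
  }
  sum(inside)
}

#' Distribution of per-cell time-averaged speeds
#'
#' @param traj Trajectory tibble.
#' @param window Observation window (h) for the speed series.
#' @param phase_filter Optional phase label (e.g. `"Tm"`): average only over
#'   windows spent in that phase.
#' @param breaks Passed to [graphics::hist()] semantics via [base::cut()];
#'   either a bin width (scalar) or a vector of break points (um/h).
#' @return Tibble with `id`, `mean_speed` and `bin` (factor).
#' @export
speed_distribution <- function(traj, window = 1, phase_filter = NULL,
                               breaks = 2) {
  if (!is.null(phase_filter)) {
    ids_keep <- traj |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(frac = mean(.data$phase == phase_filter)) |>
      dplyr::filter(.data$frac > 0.5) |>
      dplyr::pull(.data$id)
    traj <- dplyr::filter(traj, .data$id %in% ids_keep)
  }
  sp <- cell_speed(traj, window) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(mean_speed = mean(.data$speed))
  if (nrow(sp) == 0) {
    return(tibble::tibble(id = integer(), mean_speed = numeric(),
                          bin = factor()))
  }
  brks <- if (length(breaks) == 1) {
    seq(0, max(sp$mean_speed) + breaks, by = breaks)
  } else breaks
  sp$bin <- cut(sp$mean_speed, brks, include.lowest = TRUE)
  sp
}
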