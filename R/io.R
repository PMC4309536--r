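#' Load a scenario configuration from YAML
#'
#' The file may contain any subset of the [sim_config()] arguments plus
#' nested `signaling`, `mechanics` and `fields` blocks overriding individual
#' published defaults, or a single `preset` key (with preset arguments).
#' Unknown keys are rejected with their paths.
#'
#' @param path Path to a YAML file; an empty file yields the full defaults.
#' @return A [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("load_config: no such file: ", path, call. = FALSE)
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  if (!is.null(doc$preset)) {
    args <- doc[setdiff(names(doc), "preset")]
    ok <- names(args) %in% names(formals(preset_config))
    if (any(!ok)) {
      stop("load_config: unknown preset keys: ",
           paste(names(args)[!ok], collapse = ", "), call. = FALSE)
    }
    return(do.call(preset_config, c(list(name = doc$preset), args)))
  }
  top_ok <- names(doc) %in% names(formals(sim_config))
  if (any(!top_ok)) {
    stop("load_config: unknown configuration keys: ",
         paste(names(doc)[!top_ok], collapse = ", "), call. = FALSE)
  }
  for (block in c("signaling", "mechanics", "fields")) {
    if (!is.null(doc[[block]])) {
      ctor <- switch(block, signaling = signaling_params,
                     mechanics = mechanics_params, fields = field_params)
      bad <- setdiff(names(doc[[block]]), names(formals(ctor)))
      if (length(bad)) {
        stop("load_config: unknown keys in ", block, ": ",
             paste(paste0(block, "$", bad), collapse = ", "), call. = FALSE)
      }
      doc[[block]] <- do.call(ctor, doc[[block]])
    }
  }
  if (!is.null(doc$injection)) {
    doc$injection$sites <- matrix(unlist(doc$injection$sites),
                                  ncol = 2, byrow = TRUE)
    doc$injection$windows <- matrix(unlist(doc$injection$windows),
                                    ncol = 2, byrow = TRUE)
  }
  if (!is.null(doc$psi)) doc$psi <- unlist(doc$psi)
  if (!is.null(doc$annulus)) doc$annulus <- unlist(doc$annulus)
  do.call(sim_config, doc)
}

#' Write run artifacts to a directory
#'
#' Writes `cells.csv` (final snapshot), `metrics.csv`, `events.csv`,
#' `trajectories.csv` (when recorded), `state.rds` (full restartable state)
#' and `summary.json` (config hash, seed, final counts). Partial writes are
#' cleaned up on failure.
#'
#' @param st A `sim_state` from [run_scenario()].
#' @param dir Output directory (must exist or be creatable).
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(st, dir) {
  parent <- dirname(dir)
  if (!dir.exists(parent)) {
    stop("write_outputs: no such directory: ", parent, call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  wr <- function(obj, name, fun) {
    path <- file.path(dir, name)
    fun(obj, path)
    written <<- c(written, path)
    path
  }
  csv <- function(x, p) utils::write.csv(x, p, row.names = FALSE)
  cells_out <- dplyr::mutate(st$cells, t = st$t, .before = 1)
  cells_out <- cells_out[, c("id", "t", "x", "y", "phase", "cycle_phase",
                             "M", "A", "R", "status")]
  wr(cells_out, "cells.csv", csv)
  wr(sim_metrics(st), "metrics.csv", csv)
  wr(sim_events(st), "events.csv", csv)
  if (length(st$traj)) wr(sim_trajectories(st), "trajectories.csv", csv)
  wr(st, "state.rds", function(x, p) saveRDS(x, p))
  counts <- population_counts(st$cells, st$vessels,
                              r_bv = 0.02 * st$config$L * 1000)
  summary <- list(
    config_hash = config_hash(st$config),
    seed = st$config$seed,
    t = st$t,
    n_divisions = st$n_divisions,
    n_deaths = st$n_deaths,
    clamp_events = st$fields$clamp_events,
    final_counts = as.list(counts),
    package_version = as.character(utils::packageVersion("glioswitch"))
  )
  wr(summary, "summary.json", function(x, p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, pretty = TRUE)
  })
  ok <- TRUE
  invisible(written)
}

#' Reload a saved simulation state
#'
#' Refuses to continue a state whose configuration hash does not match the
#' supplied configuration (mismatched restarts).
#'
#' @param path Path to a `state.rds` written by [write_outputs()].
#' @param config Optional [sim_config()] to check against.
#' @return A `sim_state`.
#' @export
read_state <- function(path, config = NULL) {
  st <- readRDS(path)
  if (!inherits(st, "sim_state")) {
    stop("read_state: not a saved simulation state: ", path, call. = FALSE)
  }
  if (!is.null(config) &&
      !identical(config_hash(config), config_hash(st$config))) {
    stop("read_state: configuration hash mismatch; refusing to restart.",
         call. = FALSE)
  }
  st
}

#' Export the steady-state table of a bifurcation scan as CSV
#'
#' @param bd A `bifurcation_diagram` from [scan_bifurcation()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_bifurcation_csv <- function(bd, path) {
  eq <- bd$equilibria[, c("G", "M", "A", "R", "stability", "branch")]
  names(eq) <- c("G", "M_s", "A_s", "R_s", "stability", "branch")
  utils::write.csv(eq, path, row.names = FALSE)
  invisible(path)
}
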