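# Configuration and result serialization. Configs are JSON; curves are CSV,
# trajectories TSV, fit summaries JSON. Every output file carries the
# effective configuration and seed as '#'-prefixed comment lines so a run
# can be reproduced from any of its outputs.

config_keys <- c("pcm", "hill", "force_grid", "method", "n_events", "seed",
                 "output_dir", "N_sweep")

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, rejects unknown keys, fills defaults for
#' omitted ones, and validates every component invariant. The effective
#' (post-default) configuration can be written back with [save_config()]
#' and round-trips exactly.
#'
#' Recognized top-level keys: `pcm` (overrides for [pcm_params()]), `hill`
#' (overrides for [hill_params()]), `force_grid` (pN values to sweep),
#' `method` (`"master_eq"` or `"gillespie"`), `n_events`, `seed`,
#' `output_dir`, and optional `N_sweep` (ensemble sizes for multi-N
#' force-velocity studies).
#'
#' @param path path to a JSON configuration file.
#' @return An object of class `pcm_config`.
#' @examples
#' cfg <- load_config(system.file("extdata", "tiny.json", package = "pcmhill"))
#' cfg$pcm$N
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  check_sub <- function(given, builder, what) {
    allowed <- names(formals(builder))
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    given <- Filter(Negate(is.null), as.list(given))  # JSON null -> use default
    do.call(builder, given)
  }
  pcm <- check_sub(raw$pcm, pcm_params, "pcm")
  hill <- check_sub(raw$hill, hill_params, "hill")
  method <- if (is.null(raw$method)) "master_eq" else raw$method
  if (!method %in% c("master_eq", "gillespie"))
    stop("'method' must be \"master_eq\" or \"gillespie\"", call. = FALSE)
  force_grid <- if (is.null(raw$force_grid)) seq(0, 60, by = 2.5) else as.numeric(raw$force_grid)
  if (is.unsorted(force_grid, strictly = TRUE))
    stop("'force_grid' must be strictly increasing", call. = FALSE)
  n_events <- if (is.null(raw$n_events)) 20000L else as.integer(raw$n_events)
  if (n_events < 1) stop("'n_events' must be >= 1", call. = FALSE)
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  output_dir <- if (is.null(raw$output_dir)) "." else raw$output_dir
  N_sweep <- if (is.null(raw$N_sweep)) NULL else as.integer(raw$N_sweep)
  structure(list(pcm = pcm, hill = hill, force_grid = force_grid,
                 method = method, n_events = n_events, seed = seed,
                 output_dir = output_dir, N_sweep = N_sweep),
            class = "pcm_config")
}

#' Write the effective configuration as JSON
#'
#' @param config a `pcm_config` from [load_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- list(pcm = unclass(config$pcm), hill = unclass(config$hill),
              force_grid = config$force_grid, method = config$method,
              n_events = config$n_events, seed = config$seed,
              output_dir = config$output_dir)
  if (!is.null(config$N_sweep)) out$N_sweep <- config$N_sweep
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.pcm_config <- function(x, ...) {
  cat("pcmhill run configuration\n")
  cat(sprintf("  method = %s, n_events = %d, seed = %d, output_dir = %s\n",
              x$method, x$n_events, x$seed, x$output_dir))
  cat(sprintf("  force grid: %d points in [%g, %g] pN\n",
              length(x$force_grid), min(x$force_grid), max(x$force_grid)))
  if (!is.null(x$N_sweep))
    cat("  N sweep:", paste(x$N_sweep, collapse = ", "), "\n")
  print(x$pcm)
  print(x$hill)
  invisible(x)
}

config_json_line <- function(params, seed) {
  meta <- list(params = unclass(params), seed = seed)
  paste0("# config: ",
         jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Write a force-velocity curve as CSV
#'
#' Columns `force_pN`, `velocity_nm_s`, `velocity_se`, plus `fitted_v_hill`
#' when a fit is supplied; reproducibility metadata (effective parameters,
#' method, seed) as leading `#` comment lines.
#'
#' @param curve an `fv_curve` from [pcm_fv_sweep()].
#' @param path output path.
#' @param fit optional [fit_hill()] object whose predictions are added.
#' @return `path`, invisibly.
#' @export
write_fv_csv <- function(curve, path, fit = NULL) {
  df <- as.data.frame(curve)
  if (!is.null(fit))
    df$fitted_v_hill <- predict(fit, newdata = df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_json_line(attr(curve, "params"), attr(curve, "seed")), con)
  writeLines(paste0("# method: ", attr(curve, "method")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a force-velocity curve written by [write_fv_csv()]
#'
#' @param path CSV path.
#' @return A data frame with the curve columns; comment lines are skipped.
#' @export
read_fv_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a Gillespie trajectory as TSV
#'
#' Columns `time_s`, `i`, `Z_nm`, `event_type`, with reproducibility
#' metadata as leading `#` comment lines.
#'
#' @param traj a [pcm_simulate()] trajectory.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_json_line(attr(traj, "params"), attr(traj, "seed")), con)
  writeLines(paste0("# f_pN: ", attr(traj, "f")), con)
  utils::write.table(as.data.frame(traj), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_tsv()]
#'
#' @param path TSV path.
#' @return A data frame with the trajectory columns.
#' @export
read_trajectory_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a Hill-fit summary as JSON
#'
#' Keys: `v0`, `fs`, `beta`, `r_squared`, `n_points`, `method`, `seed`.
#'
#' @param fit a [fit_hill()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  cf <- coef(fit)
  out <- list(v0 = cf[["v0"]], fs = cf[["fs"]], beta = cf[["beta"]],
              r_squared = fit$r_squared, n_points = nrow(fit$data),
              method = if (is.null(fit$method)) NA else fit$method,
              seed = if (is.null(fit$seed)) NA else fit$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
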