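#' Default run configuration
#'
#' The canonical configuration dialect is YAML with five sections:
#' `params` (all 17 kinetic parameters), `totals`, `solver`, `sweep` and
#' `ensemble`. Every field has a default; unknown keys are rejected so that
#' typos fail fast. [write_config()] of this object produces a fully
#' documented reference config.
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  p <- unclass(kinetic_params())
  t <- unclass(pool_totals())
  t$U_total <- t$S_total <- NULL        # derived, not configurable
  cfg <- list(
    params = p,
    totals = t,
    solver = list(tol = 1e-10, max_iter = 200, n_starts = 5),
    sweep = list(x_axis = "ks/ku", family_axis = "Kps/Kpu",
                 x_min = 0.01, x_max = 100, x_points = 41,
                 family_grid = c(0.01, 0.1, 1, 10, 100)),
    ensemble = list(seed = 1, n_draws = 100, vary_ratios = TRUE,
                    sumo_fractions = c(0.01, 0.05, 0.10)),
    output = list(dir = ".", verbose = FALSE))
  structure(cfg, class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_config()] and validates the
#' result. Unknown keys at any level and out-of-range values raise an error
#' naming the offending key path. An empty file yields the defaults.
#'
#' @param path path to a YAML configuration file.
#' @return A validated `run_config` object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("totals:\n  sumo_fraction: 0.01", f)
#' cfg <- load_config(f)
#' cfg$totals$sumo_fraction
#' unlink(f)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config must be a YAML mapping")
  cfg <- unclass(default_config())
  check_keys <- function(user, ref, prefix) {
    unknown <- setdiff(names(user), names(ref))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(prefix, unknown, collapse = ", "))
    for (nm in names(user)) {
      if (is.list(ref[[nm]]) && !is.list(user[[nm]]))
        stop("config key ", prefix, nm, " must be a mapping")
      if (is.list(ref[[nm]]))
        check_keys(user[[nm]], ref[[nm]], paste0(prefix, nm, "."))
    }
  }
  check_keys(user, cfg, "")
  cfg <- utils::modifyList(cfg, user)
  # YAML round trips whole doubles through integers; normalize
  cfg <- rapply(cfg, function(x) if (is.integer(x)) as.numeric(x) else x,
                how = "replace")
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  # constructors carry the range checks; map failures to key paths
  try_field <- function(expr, section)
    tryCatch(expr, error = function(e)
      stop("invalid config in section '", section, "': ",
           conditionMessage(e), call. = FALSE))
  try_field(do.call(kinetic_params, cfg$params), "params")
  try_field(do.call(pool_totals, cfg$totals), "totals")
  try_field(do.call(solver_settings, cfg$solver), "solver")
  sw <- cfg$sweep
  try_field(sweep_spec(x_axis = sw$x_axis, family_axis = sw$family_axis,
                       x_grid = log_grid(sw$x_min, sw$x_max, sw$x_points),
                       family_grid = sw$family_grid), "sweep")
  try_field(ensemble_spec(seed = cfg$ensemble$seed,
                          n_draws = cfg$ensemble$n_draws,
                          sumo_fractions = cfg$ensemble$sumo_fractions,
                          vary_ratios = cfg$ensemble$vary_ratios),
            "ensemble")
  invisible(cfg)
}

#' Write a configuration to YAML
#'
#' @param config a `run_config` object.
#' @param path output path.
#' @return `path`, invisibly. `load_config(write_config(cfg, f))` round
#'   trips to an identical configuration.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# materialize the configured model objects
config_objects <- function(cfg) {
  list(params = do.call(kinetic_params, cfg$params),
       totals = do.call(pool_totals, cfg$totals),
       settings = do.call(solver_settings, cfg$solver))
}

#' Sweep specification from a configuration
#'
#' @param config a `run_config` object (see [load_config()]).
#' @return A [sweep_spec()] built from the configuration.
#' @export
config_sweep_spec <- function(config) {
  stopifnot(inherits(config, "run_config"))
  obj <- config_objects(config)
  sw <- config$sweep
  sweep_spec(x_axis = sw$x_axis, family_axis = sw$family_axis,
             x_grid = log_grid(sw$x_min, sw$x_max, sw$x_points),
             family_grid = sw$family_grid,
             params = obj$params, totals = obj$totals,
             settings = obj$settings)
}

#' Write a sweep result to CSV (with a JSON provenance sidecar)
#'
#' Writes the sweep table with the documented column order
#' (`family_ratio, x_ratio, ln_x_ratio, R_wt, R_scr, ratio, converged`) in
#' deterministic row order, plus a `<path>.json` sidecar recording the
#' effective configuration, package version and sweep axes.
#'
#' @param result a `sweep_result` (an empty result writes a header-only
#'   CSV).
#' @param path CSV output path.
#' @param config optional `run_config` recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(result, path, config = NULL) {
  cols <- c("family_ratio", "x_ratio", "ln_x_ratio", "R_wt", "R_scr",
            "ratio", "converged")
  if (!is.data.frame(result) || !all(cols %in% names(result)))
    stop("result must be a sweep result data.frame")
  utils::write.csv(as.data.frame(result)[, cols], path, row.names = FALSE)
  sidecar <- list(
    package = "sumodl",
    version = as.character(utils::packageVersion("sumodl")),
    x_axis = attr(result, "x_axis"),
    family_axis = attr(result, "family_axis"),
    sumo_fraction = attr(result, "sumo_fraction"),
    n_rows = nrow(result),
    config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a sweep result written by [write_sweep()]
#'
#' @param path CSV path.
#' @return A `sweep_result` data.frame (axis attributes restored from the
#'   JSON sidecar when present).
#' @export
read_sweep <- function(path) {
  res <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  at <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  structure(res, x_axis = at$x_axis, family_axis = at$family_axis,
            sumo_fraction = at$sumo_fraction,
            class = c("sweep_result", "data.frame"))
}

#' Plot a sweep result
#'
#' Reproduces the standard layout of the model's headline figure:
#' `ln(x ratio)` on the x axis, `R_SCR / R_WT` on the y axis, one curve per
#' family-ratio value, with a reference line at 1.
#'
#' @param x a `sweep_result`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sweep_result <- function(x, ...) {
  fams <- sort(unique(x$family_ratio))
  xs <- sort(unique(x$ln_x_ratio))
  m <- sapply(fams, function(f)
    x$ratio[x$family_ratio == f][order(x$ln_x_ratio[x$family_ratio == f])])
  pal <- grDevices::hcl.colors(max(length(fams), 2), "Zissou 1")
  graphics::matplot(xs, m, type = "l", lty = 1, lwd = 2, col = pal,
                    xlab = sprintf("ln(%s)", attr(x, "x_axis") %||% "ratio"),
                    ylab = "R_SCR / R_WT", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topright", legend = sprintf("%s = %g",
                                                attr(x, "family_axis") %||%
                                                  "family", fams),
                   col = pal[seq_along(fams)], lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
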