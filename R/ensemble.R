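#' Specification of a random parameter ensemble
#'
#' Because the original parameter table is not published, robustness of the
#' qualitative conclusions is checked on seeded random ensembles. Draws are
#' log-uniform (the exploration is multiplicative, over decades): each
#' unSUMOylated-side parameter and pool total is drawn within a decade
#' either side of its package default, and each SUMOylated/unSUMOylated
#' ratio within the hundred-fold range `[0.01, 100]`. The SUMOylated
#' fraction is drawn from a small set of plausible values. Each parameter
#' uses its own deterministic substream derived from the global seed, so
#' adding a parameter to the specification does not scramble earlier draws.
#'
#' @param seed integer seed (< 2^31).
#' @param n_draws number of parameter sets (>= 1).
#' @param u_ranges named list of `c(low, high)` ranges for unSUMOylated
#'   parameters and totals. Defaults: one decade either side of the package
#'   defaults for `KDu`, `Kiu`, `Ktu`, `Kpu`, `ku`, `DL_total`,
#'   `Cact_total`, `P_total`.
#' @param ratio_ranges named list of `c(low, high)` ranges for the s/u
#'   ratios (names as in [set_su_ratio()]); defaults `[0.01, 100]` each.
#'   Ignored when `vary_ratios = FALSE` (all ratios kept at 1).
#' @param sumo_fractions candidate SUMO fractions, sampled uniformly.
#' @param vary_ratios logical; draw the s/u ratios (default `TRUE`) or keep
#'   every SUMOylated parameter tied to its unSUMOylated value.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(seed = 1L, n_draws = 100,
                          u_ranges = NULL, ratio_ranges = NULL,
                          sumo_fractions = c(0.01, 0.05, 0.10),
                          vary_ratios = TRUE) {
  defaults <- kinetic_params()
  tot <- pool_totals()
  dec <- function(x) c(x / 10, x * 10)
  u_def <- list(KDu = dec(defaults$KDu), Kiu = dec(defaults$Kiu),
                Ktu = dec(defaults$Ktu), Kpu = dec(defaults$Kpu),
                ku = dec(defaults$ku),
                DL_total = dec(tot$DL_total),
                Cact_total = dec(tot$Cact_total),
                P_total = dec(tot$P_total))
  r_def <- stats::setNames(rep(list(c(0.01, 100)), length(su_axes)), su_axes)
  u_ranges <- utils::modifyList(u_def, as.list(u_ranges %||% list()))
  ratio_ranges <- utils::modifyList(r_def, as.list(ratio_ranges %||% list()))
  if (!all(names(u_ranges) %in% names(u_def)))
    stop("unknown u_ranges entries: ",
         paste(setdiff(names(u_ranges), names(u_def)), collapse = ", "))
  if (!all(names(ratio_ranges) %in% su_axes))
    stop("unknown ratio_ranges entries: ",
         paste(setdiff(names(ratio_ranges), su_axes), collapse = ", "))
  for (rg in c(u_ranges, ratio_ranges)) {
    if (length(rg) != 2 || any(!is.finite(rg)) || any(rg <= 0) ||
        rg[1] > rg[2])
      stop("each range must be positive c(low, high) with low <= high")
  }
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (!length(sumo_fractions) || any(sumo_fractions < 0) ||
      any(sumo_fractions >= 1))
    stop("sumo_fractions must lie in [0, 1)")
  if (abs(seed) >= 2^31) stop("seed must be a 32-bit integer")
  structure(list(seed = as.integer(seed), n_draws = as.integer(n_draws),
                 u_ranges = u_ranges, ratio_ranges = ratio_ranges,
                 sumo_fractions = sumo_fractions,
                 vary_ratios = isTRUE(vary_ratios)),
            class = "ensemble_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log-uniform draws from a dedicated substream; degenerate ranges return
# the value exactly (no exp/log round trip)
draw_stream <- function(seed, idx, n, range) {
  if (range[1] == range[2]) return(rep(range[1], n))
  with_preserved_seed({
    set.seed((seed + 104729L * idx) %% .Machine$integer.max)
    exp(stats::runif(n, log(range[1]), log(range[2])))
  })
}

with_preserved_seed <- function(expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  expr
}

#' Draw a seeded random parameter ensemble
#'
#' @param spec an [ensemble_spec()] object.
#' @return A list of `n_draws` members, each a list with elements `params`
#'   ([kinetic_params()]) and `totals` ([pool_totals()]). Identical specs
#'   give identical output.
#' @examples
#' ens <- sample_ensemble(ensemble_spec(seed = 7, n_draws = 3))
#' ens[[1]]$params$KDu
#' @export
sample_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$n_draws
  u_names <- names(spec$u_ranges)
  draws <- list()
  for (i in seq_along(u_names))
    draws[[u_names[i]]] <- draw_stream(spec$seed, i, n,
                                       spec$u_ranges[[u_names[i]]])
  off <- length(u_names)
  if (spec$vary_ratios) {
    for (j in seq_along(su_axes))
      draws[[su_axes[j]]] <- draw_stream(spec$seed, off + j, n,
                                         spec$ratio_ranges[[su_axes[j]]])
  }
  f_idx <- if (length(spec$sumo_fractions) == 1) rep(1L, n) else
    with_preserved_seed({
      set.seed((spec$seed + 104729L * (off + 6L)) %% .Machine$integer.max)
      sample.int(length(spec$sumo_fractions), n, replace = TRUE)
    })
  lapply(seq_len(n), function(k) {
    p <- kinetic_params(KDu = draws$KDu[k], Kiu = draws$Kiu[k],
                        Ktu = draws$Ktu[k], Kpu = draws$Kpu[k],
                        ku = draws$ku[k])
    if (spec$vary_ratios)
      for (ax in su_axes) p <- set_su_ratio(p, ax, draws[[ax]][k])
    list(params = p,
         totals = pool_totals(DL_total = draws$DL_total[k],
                              sumo_fraction =
                                spec$sumo_fractions[f_idx[k]],
                              Cact_total = draws$Cact_total[k],
                              P_total = draws$P_total[k]))
  })
}

#' Fraction of ensemble members upholding the necessity conclusion
#'
#' For each ensemble member, runs the primary sweep (x = `ks/ku`, families
#' = `Kps/Kpu`; the member's own `ks` and `Kps` ratios are overridden by
#' the grids, its other parameters kept) and checks the necessity property:
#' an `R_SCR / R_WT` ratio above `1 + margin` occurs only where
#' `ks/ku < 1`. Returns the fraction of members for which the property
#' holds, with a member-level breakdown.
#'
#' @param ensemble a list of members as returned by [sample_ensemble()].
#' @param margin exceedance margin (default 0.10, see [threshold_detect()]).
#' @param x_grid,family_grid sweep grids (kept deliberately coarse by
#'   default: the property is a sign pattern, not a curve shape).
#' @param settings a [solver_settings()] object.
#' @return A list with `fraction` (scalar in [0, 1]) and `members`
#'   (data.frame: member, sumo_fraction, holds, max_ratio_high_ks).
#' @export
qualitative_conclusion_rate <- function(ensemble, margin = 0.10,
                                        x_grid = log_grid(0.01, 100, 9),
                                        family_grid = c(0.01, 0.1, 1, 10,
                                                        100),
                                        settings = solver_settings()) {
  if (!is.list(ensemble) || !length(ensemble))
    stop("ensemble must be a non-empty list of members")
  rows <- lapply(seq_along(ensemble), function(k) {
    m <- ensemble[[k]]
    res <- run_sweep(sweep_spec(x_grid = x_grid, family_grid = family_grid,
                                params = m$params, totals = m$totals,
                                settings = settings))
    high <- res[res$x_ratio >= 1, ]
    data.frame(member = k, sumo_fraction = m$totals$sumo_fraction,
               holds = !any(high$ratio > 1 + margin),
               max_ratio_high_ks = max(high$ratio))
  })
  members <- do.call(rbind, rows)
  list(fraction = mean(members$holds), members = members)
}
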