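#' Log-spaced grid helper
#'
#' @param from,to strictly positive endpoints.
#' @param n number of points (>= 2, or 1 if `from == to`).
#' @return Numeric vector, log-spaced, sorted ascending.
#' @export
log_grid <- function(from = 0.01, to = 100, n = 41) {
  if (from <= 0 || to <= 0) stop("log_grid endpoints must be positive")
  if (from == to) return(rep(from, max(n, 1))[1])
  exp(seq(log(from), log(to), length.out = n))
}

#' Specification of a parameter-ratio sweep
#'
#' A sweep varies one SUMOylated/unSUMOylated parameter ratio (the x axis,
#' by default the relative transcription rate `ks/ku` over two orders of
#' magnitude each way) for each value of a second, family ratio (by default
#' the relative promoter binding affinity `Kps/Kpu` in {0.01, 0.1, 1, 10,
#' 100}). All ratios not being swept stay at 1 (SUMOylated parameters equal
#' their unSUMOylated counterparts), and sweeping any `s` parameter co-sets
#' the `us` heterodimer parameter (tying rule).
#'
#' @param x_axis,family_axis ratio names, each one of `"ks/ku"`,
#'   `"Kps/Kpu"`, `"KDs/KDu"`, `"Kts/Ktu"`, `"Kis/Kiu"`; must differ.
#' @param x_grid strictly positive ascending grid for the x ratio; the
#'   default 41 log-spaced points span `[0.01, 100]`, i.e. `ln` values from
#'   about -4.6 to +4.6.
#' @param family_grid strictly positive ascending grid for the family ratio.
#' @param params base [kinetic_params()]; its `s`/`us` entries for the two
#'   swept processes are overridden by the grids.
#' @param totals base [pool_totals()].
#' @param sumo_fraction optional override of `totals$sumo_fraction`.
#' @param settings a [solver_settings()] object.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(x_axis = "ks/ku", family_axis = "Kps/Kpu",
                       x_grid = log_grid(0.01, 100, 41),
                       family_grid = c(0.01, 0.1, 1, 10, 100),
                       params = kinetic_params(), totals = pool_totals(),
                       sumo_fraction = NULL,
                       settings = solver_settings()) {
  x_axis <- match.arg(x_axis, su_axes)
  family_axis <- match.arg(family_axis, su_axes)
  if (x_axis == family_axis)
    stop("x_axis and family_axis must name different parameter ratios")
  check_grid <- function(g, what) {
    if (!is.numeric(g) || !length(g) || any(!is.finite(g)) || any(g <= 0))
      stop(what, " must be a strictly positive numeric grid")
    if (is.unsorted(g, strictly = TRUE) && length(g) > 1)
      stop(what, " must be sorted strictly ascending")
  }
  check_grid(x_grid, "x_grid")
  check_grid(family_grid, "family_grid")
  stopifnot(inherits(params, "kinetic_params"),
            inherits(totals, "pool_totals"),
            inherits(settings, "solver_settings"))
  if (!is.null(sumo_fraction))
    totals <- pool_totals(totals$DL_total, sumo_fraction,
                          totals$Cact_total, totals$P_total)
  structure(list(x_axis = x_axis, family_axis = family_axis,
                 x_grid = x_grid, family_grid = family_grid,
                 params = params, totals = totals, settings = settings),
            class = "sweep_spec")
}

#' Reporter expression under WT and SCR conditions, and their ratio
#'
#' Solves the steady state twice: once for the wild type (a fraction `f` of
#' total Dorsal SUMOylated) and once for the SUMO-conjugation-resistant
#' condition (the SUMOylated sub-pool removed, the unSUMOylated sub-pool
#' kept at `(1 - f) * DL_total`, every parameter and other total
#' unchanged), and returns both reporter rates and the headline ratio
#' `R_SCR / R_WT`. At `f = 0` the two conditions are identical and the
#' ratio is exactly 1.
#'
#' @inheritParams oracle_solve
#' @return A list with `R_wt`, `R_scr`, `ratio`, `converged` (both solves),
#'   and the two `steady_state` objects (`wt`, `scr`).
#' @export
scr_wt_ratio <- function(params, totals, settings = solver_settings(),
                         assumptions = model_assumptions()) {
  wt <- solve_steady_state(params, totals, settings, assumptions)
  scr <- solve_steady_state(params, scr_totals(totals), settings,
                            assumptions)
  if (wt$R <= 0)
    stop("wild-type reporter rate is zero; ratio undefined ",
         "(check promoter and Dorsal totals)")
  list(R_wt = wt$R, R_scr = scr$R, ratio = scr$R / wt$R,
       converged = wt$converged && scr$converged, wt = wt, scr = scr)
}

#' Run a parameter-ratio sweep
#'
#' For every (family, x) grid pair, sets the two swept ratios on the base
#' parameters (tying the `us` heterodimer parameter to the `s` value),
#' solves the WT and SCR steady states and records the reporter rates and
#' their ratio. Per-row solver failures are recorded in the `converged`
#' column, never dropped.
#'
#' @param spec a [sweep_spec()] object.
#' @return A `sweep_result`: a data.frame with one row per (family, x) pair,
#'   ordered by (family, x), with columns `family_ratio`, `x_ratio`,
#'   `ln_x_ratio`, `R_wt`, `R_scr`, `ratio`, `converged`, and attributes
#'   `x_axis`, `family_axis`, `sumo_fraction`.
#' @examples
#' \donttest{
#' res <- run_sweep(sweep_spec(x_grid = log_grid(0.01, 100, 5)))
#' subset(res, family_ratio == 10)
#' }
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(x_ratio = spec$x_grid, family_ratio = spec$family_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$family_ratio, grid$x_ratio), ]
  n <- nrow(grid)
  R_wt <- R_scr <- ratio <- numeric(n)
  converged <- logical(n)
  for (i in seq_len(n)) {
    p <- set_su_ratio(spec$params, spec$family_axis, grid$family_ratio[i])
    p <- set_su_ratio(p, spec$x_axis, grid$x_ratio[i])
    out <- scr_wt_ratio(p, spec$totals, spec$settings)
    R_wt[i] <- out$R_wt; R_scr[i] <- out$R_scr
    ratio[i] <- out$ratio; converged[i] <- out$converged
  }
  res <- data.frame(family_ratio = grid$family_ratio,
                    x_ratio = grid$x_ratio,
                    ln_x_ratio = log(grid$x_ratio),
                    R_wt = R_wt, R_scr = R_scr, ratio = ratio,
                    converged = converged)
  rownames(res) <- NULL
  structure(res, x_axis = spec$x_axis, family_axis = spec$family_axis,
            sumo_fraction = spec$totals$sumo_fraction,
            class = c("sweep_result", "data.frame"))
}

#' Smallest family ratio producing a substantial expression increase
#'
#' Given a sweep over a family ratio at a single fixed x ratio (typically
#' `Kps/Kpu` families at a low `ks/ku`), returns the smallest family-grid
#' value whose `R_SCR / R_WT` ratio exceeds `1 + margin`, or `NA` if none
#' qualifies. The default 10% margin exceeds the composition artifact of
#' simply removing the low-activity SUMOylated dimers from the promoter
#' pool (about `(US + SS) / UU`, i.e. 6-8% at a 5% SUMO fraction), so only
#' increases driven by an occupancy-enhancing change qualify as
#' substantial.
#'
#' @param result a `sweep_result` (or data.frame with columns
#'   `family_ratio`, `x_ratio`, `ratio`) containing a single distinct
#'   `x_ratio`.
#' @param margin non-negative dimensionless exceedance margin (default
#'   0.10).
#' @return The smallest qualifying family ratio, or `NA_real_`.
#' @export
threshold_detect <- function(result, margin = 0.10) {
  if (!is.data.frame(result) ||
      !all(c("family_ratio", "x_ratio", "ratio") %in% names(result)))
    stop("result must contain family_ratio, x_ratio and ratio columns")
  if (!is.numeric(margin) || length(margin) != 1 || !is.finite(margin) ||
      margin < 0)
    stop("margin must be a single non-negative number")
  if (length(unique(result$x_ratio)) != 1)
    stop("threshold_detect expects a sweep at a single fixed x ratio")
  fam <- result$family_ratio
  if (is.unsorted(fam, strictly = TRUE))
    stop("family grid must be sorted strictly ascending")
  hit <- which(result$ratio > 1 + margin)
  if (!length(hit)) NA_real_ else fam[min(hit)]
}

#' Robustness grid over SUMO fraction and Cactus abundance
#'
#' Re-runs the primary sweep (x = `ks/ku`, families = `Kps/Kpu`) for each
#' SUMOylated fraction and each Cactus-total scaling factor, and summarizes
#' the model's two qualitative conclusions per condition:
#'
#' * `necessity_ks`: no grid point with `ks/ku >= 1` shows a ratio above
#'   `1 + margin` — reduced transcriptional activity of SUMOylated dimers
#'   is necessary for increased SCR expression.
#' * `enhancement_amplifies`: among points with `ks/ku < 1`, the largest
#'   ratio reached with enhanced SUMO-dimer promoter binding
#'   (`Kps/Kpu > 1`) strictly exceeds the largest ratio reached without it
#'   — an occupancy-enhancing change is what turns the small composition
#'   effect into a substantial increase.
#'
#' `threshold_family` additionally records, per condition, the smallest
#' `Kps/Kpu` with a `> 1 + margin` increase at the lowest `ks/ku` grid
#' value.
#'
#' @param params base [kinetic_params()].
#' @param totals base [pool_totals()]; its `sumo_fraction` and `Cact_total`
#'   are overridden condition by condition.
#' @param sumo_fractions SUMO fractions to test (the Cactus scan runs at
#'   `totals$sumo_fraction`).
#' @param cact_scales multiplicative factors applied to `Cact_total`.
#' @param x_grid x-ratio grid for the sweeps.
#' @param margin exceedance margin used for the qualitative flags.
#' @param settings a [solver_settings()] object.
#' @return A list with `results` (named list of `sweep_result`s, one per
#'   condition) and `summary` (data.frame: condition, sumo_fraction,
#'   cact_scale, necessity_ks, enhancement_amplifies, threshold_family,
#'   all_converged).
#' @export
robustness_grid <- function(params = kinetic_params(),
                            totals = pool_totals(),
                            sumo_fractions = c(0.01, 0.05, 0.10),
                            cact_scales = c(0.01, 0.1, 1, 10, 100),
                            x_grid = log_grid(0.01, 100, 17),
                            margin = 0.10,
                            settings = solver_settings()) {
  conditions <- rbind(
    data.frame(sumo_fraction = sumo_fractions, cact_scale = 1),
    data.frame(sumo_fraction = totals$sumo_fraction,
               cact_scale = cact_scales))
  conditions$condition <- sprintf("f=%g_cact_x%g",
                                  conditions$sumo_fraction,
                                  conditions$cact_scale)
  results <- vector("list", nrow(conditions))
  names(results) <- conditions$condition
  summ <- conditions
  summ$necessity_ks <- summ$enhancement_amplifies <- NA
  summ$threshold_family <- NA_real_
  summ$all_converged <- NA
  for (i in seq_len(nrow(conditions))) {
    tot_i <- pool_totals(totals$DL_total, conditions$sumo_fraction[i],
                         totals$Cact_total * conditions$cact_scale[i],
                         totals$P_total)
    res <- run_sweep(sweep_spec(x_grid = x_grid, params = params,
                                totals = tot_i, settings = settings))
    results[[i]] <- res
    lo_x <- res[res$x_ratio == min(res$x_ratio), ]
    summ$threshold_family[i] <- threshold_detect(lo_x, margin)
    summ$necessity_ks[i] <- !any(res$ratio > 1 + margin & res$x_ratio >= 1)
    low <- res[res$x_ratio < 1, ]
    summ$enhancement_amplifies[i] <-
      max(low$ratio[low$family_ratio > 1]) >
      max(low$ratio[low$family_ratio <= 1])
    summ$all_converged[i] <- all(res$converged)
  }
  list(results = results,
       summary = summ[, c("condition", "sumo_fraction", "cact_scale",
                          "necessity_ks", "enhancement_amplifies",
                          "threshold_family", "all_converged")])
}
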