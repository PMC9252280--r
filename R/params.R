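#' Kinetic parameters of the Dorsal SUMOylation model
#'
#' Bundles every equilibrium constant and rate constant of the model. All
#' binding constants are *association* constants (\eqn{[AB] = K [A][B]};
#' larger K = tighter binding), so statements such as "tighter promoter
#' binding, Kps/Kpu > 1" read directly. Nuclear partition coefficients
#' (`Kt*`, `Ktm_*`) are dimensionless nuclear/cytoplasmic concentration
#' ratios; `ku`, `kus`, `ks` are first-order reporter expression rate
#' constants for promoter sites occupied by each dimer type.
#'
#' The superscript convention follows the field: `u` marks the process for
#' the DL^U:DL^U homodimer, `s` for the DL^S:DL^S homodimer and `us` for the
#' DL^U:DL^S heterodimer. Under the model's tying assumption the `s` and
#' `us` parameters of the same process are equal (heterodimers behave like
#' SUMOylated homodimers); the defaults keep every s/u ratio at 1.
#'
#' Default values: the SUMO-free ("u") constants are order-of-magnitude
#' choices for a strongly expressed transcription factor pool (see the
#' methods vignette): `KDu = 0.01` per concentration unit (roughly half of
#' Dorsal dimeric at `DL_total = 100`), `Kiu = 0.1` (Cactus sequesters most
#' free dimers at `Cact_total = 100`), `Ktu = 1` and `Kpu = 10` (promoter
#' sites ~97% occupied at baseline, the saturated regime in which
#' target-gene output is robust to moderate changes in total Dorsal and in
#' which reporter expression is insensitive to SUMOylation unless the
#' SUMOylated dimers differ in specific activity).
#'
#' @param KDu,KDus,KDs association constants for dimerization (per
#'   concentration unit) of the UU, US and SS dimers.
#' @param Kiu,Kius,Kis association constants for Cactus binding each dimer.
#' @param Ktu,Ktus,Kts dimensionless nuclear partition coefficients of the
#'   free dimers.
#' @param Ktm_u,Ktm_s dimensionless nuclear partition coefficients of the
#'   free monomers (model-closure parameters; set to 0 under the 16-species
#'   closure, see [model_assumptions()]).
#' @param Kpu,Kpus,Kps association constants for promoter binding of each
#'   nuclear dimer.
#' @param ku,kus,ks reporter expression rate constants (per time unit) for
#'   promoter sites bound by each dimer.
#' @return An object of class `kinetic_params` (a validated named list).
#' @seealso [pool_totals()], [set_su_ratio()], [solve_steady_state()]
#' @examples
#' p <- kinetic_params()                  # package defaults, all ratios tied
#' p2 <- set_su_ratio(p, "ks/ku", 0.01)   # SUMOylated dimers 100x less active
#' @export
kinetic_params <- function(KDu = 0.01, KDs = KDu, KDus = KDs,
                           Kiu = 0.1,  Kis = Kiu, Kius = Kis,
                           Ktu = 1,    Kts = Ktu, Ktus = Kts,
                           Ktm_u = 1,  Ktm_s = 1,
                           Kpu = 10,   Kps = Kpu, Kpus = Kps,
                           ku = 1,     ks = ku,   kus = ks) {
  p <- list(KDu = KDu, KDus = KDus, KDs = KDs,
            Kiu = Kiu, Kius = Kius, Kis = Kis,
            Ktu = Ktu, Ktus = Ktus, Kts = Kts,
            Ktm_u = Ktm_u, Ktm_s = Ktm_s,
            Kpu = Kpu, Kpus = Kpus, Kps = Kps,
            ku = ku, kus = kus, ks = ks)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

# Ktm_* may be zero (16-species closure); everything else must be > 0.
validate_kinetic_params <- function(p) {
  vals <- unlist(p)
  if (!all(is.finite(vals)))
    stop("kinetic parameters must be finite: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  strict <- setdiff(names(p), c("Ktm_u", "Ktm_s"))
  bad <- strict[unlist(p[strict]) <= 0]
  if (length(bad))
    stop("kinetic parameters must be strictly positive: ",
         paste(bad, collapse = ", "))
  if (p$Ktm_u < 0 || p$Ktm_s < 0)
    stop("monomer partition coefficients Ktm_u/Ktm_s must be >= 0")
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (association constants; u/us/s variants)\n")
  m <- rbind(dimerization = c(x$KDu, x$KDus, x$KDs),
             cactus_binding = c(x$Kiu, x$Kius, x$Kis),
             nuclear_partition = c(x$Ktu, x$Ktus, x$Kts),
             promoter_binding = c(x$Kpu, x$Kpus, x$Kps),
             reporter_rate = c(x$ku, x$kus, x$ks))
  colnames(m) <- c("u", "us", "s")
  print(m, ...)
  cat(sprintf("monomer partition: Ktm_u = %g, Ktm_s = %g\n",
              x$Ktm_u, x$Ktm_s))
  invisible(x)
}

#' Conserved pool totals
#'
#' The model conserves four pools: total Dorsal (in monomer equivalents),
#' split into an unSUMOylated and a SUMOylated sub-pool by `sumo_fraction`;
#' total Cactus; and total promoter sites. In the wild type roughly 5% of
#' Dorsal is SUMOylated; the SUMO-conjugation-resistant (SCR) condition sets
#' the SUMOylated sub-pool to zero while leaving the unSUMOylated sub-pool
#' and everything else unchanged (see [scr_wt_ratio()]).
#'
#' @param DL_total total Dorsal concentration (monomer equivalents).
#' @param sumo_fraction fraction f of total Dorsal that is SUMOylated,
#'   in `[0, 1)`. `U_total = (1 - f) * DL_total`, `S_total = f * DL_total`.
#' @param Cact_total total Cactus concentration.
#' @param P_total total promoter-site concentration.
#' @return An object of class `pool_totals` with fields `DL_total`,
#'   `sumo_fraction`, `Cact_total`, `P_total`, `U_total`, `S_total`.
#' @examples
#' wt <- pool_totals()                   # 5% SUMOylated
#' scr <- scr_totals(wt)                 # SUMO pool removed, U pool unchanged
#' @export
pool_totals <- function(DL_total = 100, sumo_fraction = 0.05,
                        Cact_total = 100, P_total = 0.1) {
  if (!is.finite(DL_total) || DL_total < 0)
    stop("DL_total must be finite and >= 0")
  if (!is.finite(Cact_total) || Cact_total < 0)
    stop("Cact_total must be finite and >= 0")
  if (!is.finite(P_total) || P_total < 0)
    stop("P_total must be finite and >= 0")
  if (!is.finite(sumo_fraction) || sumo_fraction < 0 || sumo_fraction >= 1)
    stop("sumo_fraction must lie in [0, 1)")
  S_total <- sumo_fraction * DL_total
  structure(list(DL_total = DL_total, sumo_fraction = sumo_fraction,
                 Cact_total = Cact_total, P_total = P_total,
                 U_total = DL_total - S_total, S_total = S_total),
            class = "pool_totals")
}

#' @export
print.pool_totals <- function(x, ...) {
  cat(sprintf(paste0("Pool totals: DL = %g (U = %g, S = %g; f = %g), ",
                     "Cact = %g, P = %g\n"),
              x$DL_total, x$U_total, x$S_total, x$sumo_fraction,
              x$Cact_total, x$P_total))
  invisible(x)
}

#' SCR pool totals from a wild-type specification
#'
#' Removes the SUMOylated Dorsal sub-pool while keeping the unSUMOylated
#' sub-pool at `(1 - f) * DL_total` and all other totals unchanged. This is
#' the in-silico equivalent of the SUMO-conjugation-resistant mutant.
#'
#' @param totals a [pool_totals()] object describing the wild type.
#' @return A `pool_totals` object with `S_total = 0`.
#' @export
scr_totals <- function(totals) {
  stopifnot(inherits(totals, "pool_totals"))
  pool_totals(DL_total = totals$U_total, sumo_fraction = 0,
              Cact_total = totals$Cact_total, P_total = totals$P_total)
}

#' Set one SUMOylated/unSUMOylated parameter ratio
#'
#' Sets the SUMOylated-species parameters of one process to `ratio` times the
#' unSUMOylated value, honoring the tying rule (the heterodimer `us`
#' parameter always follows the SUMOylated homodimer `s` parameter, e.g.
#' `Kps = Kpus = ratio * Kpu`).
#'
#' @param params a [kinetic_params()] object.
#' @param axis one of `"ks/ku"`, `"Kps/Kpu"`, `"KDs/KDu"`, `"Kts/Ktu"`,
#'   `"Kis/Kiu"`.
#' @param ratio strictly positive scalar.
#' @return A modified `kinetic_params` object.
#' @export
set_su_ratio <- function(params, axis, ratio) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(ratio) || length(ratio) != 1 || !is.finite(ratio) ||
      ratio <= 0)
    stop("ratio must be a single finite positive number")
  ax <- su_axis_fields(axis)
  params[[ax["s"]]] <- ratio * params[[ax["u"]]]
  params[[ax["us"]]] <- params[[ax["s"]]]
  validate_kinetic_params(params)
  params
}

su_axes <- c("ks/ku", "Kps/Kpu", "KDs/KDu", "Kts/Ktu", "Kis/Kiu")

su_axis_fields <- function(axis) {
  fields <- switch(match.arg(axis, su_axes),
                   "ks/ku" = c(u = "ku", s = "ks", us = "kus"),
                   "Kps/Kpu" = c(u = "Kpu", s = "Kps", us = "Kpus"),
                   "KDs/KDu" = c(u = "KDu", s = "KDs", us = "KDus"),
                   "Kts/Ktu" = c(u = "Ktu", s = "Kts", us = "Ktus"),
                   "Kis/Kiu" = c(u = "Kiu", s = "Kis", us = "Kius"))
  fields
}
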