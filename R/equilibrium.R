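#' Dimer concentrations implied by free monomer concentrations
#'
#' Mass-action association equilibria for the three dimer compositions:
#' `[UU] = KDu * U^2`, `[US] = KDus * U * S`, `[SS] = KDs * S^2`. `KDus` is a
#' lumped constant (no explicit statistical factor of 2 for the
#' heterodimer).
#'
#' @param U_cyt,S_cyt free cytoplasmic monomer concentrations (must be
#'   non-negative; negative inputs indicate a solver bug and raise an
#'   error).
#' @param params a [kinetic_params()] object.
#' @return Named numeric vector `c(UU, US, SS)`.
#' @export
dimer_concentrations <- function(U_cyt, S_cyt, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.finite(U_cyt) || !is.finite(S_cyt) || U_cyt < 0 || S_cyt < 0)
    stop("monomer concentrations must be finite and non-negative ",
         sprintf("(got U = %g, S = %g)", U_cyt, S_cyt))
  c(UU = params$KDu * U_cyt^2,
    US = params$KDus * U_cyt * S_cyt,
    SS = params$KDs * S_cyt^2)
}

#' Free Cactus concentration from the Cactus conservation law
#'
#' Eliminates free Cactus analytically: with association constants `Ki*`,
#' `Cact_free = Cact_total / (1 + Kiu*[UU] + Kius*[US] + Kis*[SS])`, and the
#' bound forms follow as `Ki * Cact_free * [dimer]`, so bound + free Cactus
#' sums to `Cact_total` exactly.
#'
#' @param dimers_cyt named or positional numeric vector of the three free
#'   cytoplasmic dimer concentrations (UU, US, SS order).
#' @param params a [kinetic_params()] object.
#' @param Cact_total total Cactus concentration.
#' @return Free Cactus concentration (scalar).
#' @export
free_cactus <- function(dimers_cyt, params, Cact_total) {
  stopifnot(inherits(params, "kinetic_params"), length(dimers_cyt) == 3)
  if (any(!is.finite(dimers_cyt)) || any(dimers_cyt < 0) ||
      !is.finite(Cact_total) || Cact_total < 0)
    stop("free_cactus: inputs must be finite and non-negative")
  Cact_total / (1 + params$Kiu * dimers_cyt[[1]] +
                  params$Kius * dimers_cyt[[2]] +
                  params$Kis * dimers_cyt[[3]])
}

#' Free promoter concentration from the promoter conservation law
#'
#' Same elimination as [free_cactus()], for nuclear dimers competing for
#' promoter sites: `P_free = P_total / (1 + Kpu*[UU]n + Kpus*[US]n +
#' Kps*[SS]n)`; occupied sites follow as `Kp * P_free * [dimer]n`.
#'
#' @param dimers_nuc numeric vector of the three nuclear dimer
#'   concentrations (UU, US, SS order).
#' @param params a [kinetic_params()] object.
#' @param P_total total promoter-site concentration.
#' @return Free promoter-site concentration (scalar).
#' @export
free_promoter <- function(dimers_nuc, params, P_total) {
  stopifnot(inherits(params, "kinetic_params"), length(dimers_nuc) == 3)
  if (any(!is.finite(dimers_nuc)) || any(dimers_nuc < 0) ||
      !is.finite(P_total) || P_total < 0)
    stop("free_promoter: inputs must be finite and non-negative")
  P_total / (1 + params$Kpu * dimers_nuc[[1]] +
               params$Kpus * dimers_nuc[[2]] +
               params$Kps * dimers_nuc[[3]])
}

# Full species vector implied by the two free cytoplasmic monomer
# concentrations. Every downstream quantity (conservation residuals, the
# reporter rate, back-substitution checks) is derived from this one map.
state_concentrations <- function(U_cyt, S_cyt, params, totals,
                                 assumptions = model_assumptions()) {
  d <- dimer_concentrations(U_cyt, S_cyt, params)
  Cf <- free_cactus(d, params, totals$Cact_total)
  cb <- c(params$Kiu, params$Kius, params$Kis) * Cf * d
  dn <- c(params$Ktu, params$Ktus, params$Kts) * d
  Pf <- free_promoter(dn, params, totals$P_total)
  pb <- c(params$Kpu, params$Kpus, params$Kps) * Pf * dn
  conc <- c(U_cyt = U_cyt, S_cyt = S_cyt)
  if (assumptions$monomer_partitioning)
    conc <- c(conc, U_nuc = params$Ktm_u * U_cyt,
              S_nuc = params$Ktm_s * S_cyt)
  conc <- c(conc,
            UU = d[["UU"]], US = d[["US"]], SS = d[["SS"]],
            Cact_UU = cb[[1]], Cact_US = cb[[2]], Cact_SS = cb[[3]],
            nuc_UU = dn[[1]], nuc_US = dn[[2]], nuc_SS = dn[[3]],
            P_UU = pb[[1]], P_US = pb[[2]], P_SS = pb[[3]],
            Cact_free = Cf, P_free = Pf)
  if (any(!is.finite(conc)))
    stop("non-finite species concentration at U_cyt = ", U_cyt,
         ", S_cyt = ", S_cyt, ": ",
         paste(names(conc)[!is.finite(conc)], collapse = ", "))
  conc
}

# U- and S-subunit totals implied by free monomer concentrations; the core
# of the reduced 2-equation system.
implied_subunit_totals <- function(U_cyt, S_cyt, params, totals,
                                   assumptions = model_assumptions()) {
  conc <- state_concentrations(U_cyt, S_cyt, params, totals, assumptions)
  sp <- enumerate_species(assumptions)
  c(U = sum(sp$n_u * conc[sp$name]), S = sum(sp$n_s * conc[sp$name]))
}

#' Reporter expression rate of a steady state
#'
#' First-order reporter expression summed over occupied promoter sites,
#' each dimer composition contributing with its own rate constant:
#' `R = ku*[P:UU] + kus*[P:US] + ks*[P:SS]`.
#'
#' @param state a [steady_state] object (from [solve_steady_state()] or
#'   [oracle_solve()]) or a named concentration vector containing `P_UU`,
#'   `P_US`, `P_SS`.
#' @param params a [kinetic_params()] object.
#' @return Reporter expression rate (scalar, per time unit).
#' @export
reporter_rate <- function(state, params) {
  stopifnot(inherits(params, "kinetic_params"))
  conc <- if (inherits(state, "steady_state")) state$concentrations else state
  if (!all(c("P_UU", "P_US", "P_SS") %in% names(conc)))
    stop("state must provide promoter-bound concentrations P_UU, P_US, P_SS")
  unname(params$ku * conc[["P_UU"]] + params$kus * conc[["P_US"]] +
           params$ks * conc[["P_SS"]])
}

#' Per-form mass-balance and conservation residuals of a state
#'
#' Recomputes every molecular form from the state's free cytoplasmic
#' monomer concentrations through the equilibrium relations and reports the
#' relative discrepancy per form, together with the four pool conservation
#' residuals (U, S, Cactus, promoter). A valid steady state satisfies all of
#' them to solver tolerance, not just the reduced two-equation system.
#'
#' @param state a [steady_state] object.
#' @param params a [kinetic_params()] object.
#' @param totals a [pool_totals()] object.
#' @return Named vector: one relative residual per enumerated form, then
#'   `cons_U`, `cons_S`, `cons_Cact`, `cons_P`.
#' @export
mass_balance_residuals <- function(state, params, totals) {
  stopifnot(inherits(state, "steady_state"))
  assumptions <- state$assumptions
  conc <- state$concentrations
  ref <- state_concentrations(state$monomers[["U_cyt"]],
                              state$monomers[["S_cyt"]],
                              params, totals, assumptions)
  scale <- pmax(abs(ref), abs(conc[names(ref)]), .Machine$double.eps)
  per_form <- (conc[names(ref)] - ref) / scale
  sp <- enumerate_species(assumptions)
  pool <- function(w, total) {
    implied <- sum(w * conc[sp$name])
    (implied - total) / max(total, 1)
  }
  cact_w <- as.numeric(sp$role %in% c("Cactus-bound dimer", "free Cactus"))
  p_w <- as.numeric(sp$role %in% c("promoter-bound dimer", "free promoter"))
  c(per_form,
    cons_U = pool(sp$n_u, totals$U_total),
    cons_S = pool(sp$n_s, totals$S_total),
    cons_Cact = pool(cact_w, totals$Cact_total),
    cons_P = pool(p_w, totals$P_total))
}
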