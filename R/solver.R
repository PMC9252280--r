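#' Solver settings
#'
#' @param tol relative residual tolerance on the conservation laws that a
#'   returned steady state must satisfy. Default `1e-10`.
#' @param max_iter maximum iterations for the nested-bisection oracle per
#'   bisection level.
#' @param n_starts number of deterministic multistart points for the primary
#'   solver (the dilute-limit guess plus `n_starts - 1` log-spaced downward
#'   perturbations).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(tol = 1e-10, max_iter = 200, n_starts = 5) {
  if (!is.finite(tol) || tol <= 0) stop("tol must be > 0")
  if (max_iter < 1 || n_starts < 1)
    stop("max_iter and n_starts must be >= 1")
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts)),
            class = "solver_settings")
}

# Lean arithmetic version of the implied-subunit-total map used in the hot
# solver loops; algebraically identical to implied_subunit_totals() (which
# goes through the species table) and cross-checked against it in the tests.
imp_totals <- function(U, S, p, t, mp = TRUE) {
  UU <- p$KDu * U * U; US <- p$KDus * U * S; SS <- p$KDs * S * S
  Cf <- t$Cact_total / (1 + p$Kiu * UU + p$Kius * US + p$Kis * SS)
  nUU <- p$Ktu * UU; nUS <- p$Ktus * US; nSS <- p$Kts * SS
  Pf <- t$P_total / (1 + p$Kpu * nUU + p$Kpus * nUS + p$Kps * nSS)
  fUU <- UU * (1 + p$Kiu * Cf) + nUU * (1 + p$Kpu * Pf)
  fUS <- US * (1 + p$Kius * Cf) + nUS * (1 + p$Kpus * Pf)
  fSS <- SS * (1 + p$Kis * Cf) + nSS * (1 + p$Kps * Pf)
  mu <- if (mp) 1 + p$Ktm_u else 1
  ms <- if (mp) 1 + p$Ktm_s else 1
  out <- c(U = U * mu + 2 * fUU + fUS, S = S * ms + 2 * fSS + fUS)
  if (any(!is.finite(out)))
    stop(sprintf("non-finite implied totals at U_cyt = %g, S_cyt = %g", U, S))
  out
}

#' Conservation residuals of the reduced two-equation system
#'
#' The steady-state system reduces, after analytic elimination of the dimer,
#' Cactus-bound, nuclear and promoter-bound forms (free Cactus and free
#' promoter are explicit functions of the dimers through their conservation
#' laws), to two equations in the two free cytoplasmic monomer
#' concentrations: the U- and S-subunit totals implied by `(U_cyt, S_cyt)`
#' must equal the specified pool totals. This function returns
#' implied-minus-specified totals for both subunit pools.
#'
#' @param U_cyt,S_cyt free cytoplasmic monomer concentrations (>= 0).
#' @param params a [kinetic_params()] object.
#' @param totals a [pool_totals()] object.
#' @param assumptions a [model_assumptions()] object.
#' @param relative if `TRUE`, residuals are divided by the pool totals
#'   (pools with zero total use a unit scale).
#' @return Named numeric vector `c(U, S)`.
#' @export
conservation_residuals <- function(U_cyt, S_cyt, params, totals,
                                   assumptions = model_assumptions(),
                                   relative = FALSE) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(totals, "pool_totals"))
  if (!is.finite(U_cyt) || !is.finite(S_cyt) || U_cyt < 0 || S_cyt < 0)
    stop("monomer concentrations must be finite and non-negative")
  imp <- imp_totals(U_cyt, S_cyt, params, totals,
                    assumptions$monomer_partitioning)
  res <- c(U = imp[["U"]] - totals$U_total, S = imp[["S"]] - totals$S_total)
  if (relative)
    res <- res / c(max(totals$U_total, 1), max(totals$S_total, 1))
  res
}

# Assemble a steady_state object from solved monomer concentrations.
new_steady_state <- function(U, S, params, totals, assumptions,
                             method, iterations, converged) {
  conc <- state_concentrations(U, S, params, totals, assumptions)
  sp <- enumerate_species(assumptions)
  pool_res <- function(w, total)
    (sum(w * conc[sp$name]) - total) / max(total, 1)
  res <- c(U = pool_res(sp$n_u, totals$U_total),
           S = pool_res(sp$n_s, totals$S_total),
           Cact = pool_res(sp$role %in% c("Cactus-bound dimer", "free Cactus"),
                           totals$Cact_total),
           P = pool_res(sp$role %in% c("promoter-bound dimer",
                                       "free promoter"),
                        totals$P_total))
  structure(list(concentrations = conc,
                 monomers = c(U_cyt = U, S_cyt = S),
                 R = reporter_rate(conc, params),
                 residuals = res,
                 converged = converged,
                 iterations = iterations,
                 method = method,
                 assumptions = assumptions),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s, %s; max |rel residual| %.2e)\n",
              x$method, if (x$converged) "converged" else "NOT converged",
              max(abs(x$residuals))))
  cat(sprintf("  free monomers: U_cyt = %.6g, S_cyt = %.6g\n",
              x$monomers[["U_cyt"]], x$monomers[["S_cyt"]]))
  cat(sprintf("  reporter rate R = %.6g\n", x$R))
  print(round(x$concentrations, 6), ...)
  invisible(x)
}

# 1D bisection on a monotone residual with guaranteed bracket [0, hi].
bisect_root <- function(f, hi, max_iter) {
  if (hi <= 0) return(0)
  f_hi <- f(hi)
  if (f_hi < 0)
    stop("bisection bracket failure: residual negative at upper bound ",
         "(model-coding inconsistency)")
  lo <- 0
  for (i in seq_len(max_iter)) {
    mid <- 0.5 * (lo + hi)
    if (mid <= lo || mid >= hi) break   # interval at machine resolution
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

#' Steady-state solution by nested bisection (independent oracle)
#'
#' Solves the reduced two-unknown system by derivative-free nested
#' bisection: an outer bisection on `U_cyt` and, for each trial value, an
#' inner bisection on `S_cyt`, exploiting that each implied subunit total is
#' strictly increasing in its own free monomer concentration. Brackets are
#' analytic (`[0, U_total]` and `[0, S_total]`: the implied total equals
#' minus the pool total at 0 and is at least the pool total at the upper
#' bound), so convergence is guaranteed; a sign violation at a bracket end
#' raises an error, since it can only arise from a model-coding
#' inconsistency. Slower but assumption-free; used to cross-validate
#' [solve_steady_state()].
#'
#' @inheritParams conservation_residuals
#' @param settings a [solver_settings()] object.
#' @return A `steady_state` object (`method = "nested_bisection"`).
#' @export
oracle_solve <- function(params, totals, settings = solver_settings(),
                         assumptions = model_assumptions()) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(totals, "pool_totals"),
            inherits(settings, "solver_settings"))
  mp <- assumptions$monomer_partitioning
  inner_S <- function(U)
    bisect_root(function(S) imp_totals(U, S, params, totals, mp)[["S"]] -
                  totals$S_total,
                hi = totals$S_total, max_iter = settings$max_iter)
  U <- bisect_root(function(U) {
    S <- inner_S(U)
    imp_totals(U, S, params, totals, mp)[["U"]] - totals$U_total
  }, hi = totals$U_total, max_iter = settings$max_iter)
  S <- inner_S(U)
  st <- new_steady_state(U, S, params, totals, assumptions,
                         method = "nested_bisection",
                         iterations = settings$max_iter,
                         converged = TRUE)
  if (max(abs(st$residuals)) > settings$tol)
    st$converged <- FALSE
  st
}

#' Solve the model for its steady state
#'
#' Primary solver for the reduced two-unknown system (see
#' [conservation_residuals()]). Solving is done in log-concentration space
#' (which enforces positivity without constrained optimization) with a
#' quasi-Newton root finder ([pracma::fsolve()]), multistarting from the
#' dilute-limit guess `U = U_total / (1 + Ktm_u)`, `S = S_total /
#' (1 + Ktm_s)` and deterministic log-spaced downward perturbations of it.
#' Degenerate pools (`U_total = 0` or `S_total = 0`) are reduced to one
#' dimension and solved by bracketed root finding; both pools zero is
#' solved analytically. Every candidate solution is validated post hoc
#' against all per-form mass balances and all four conservation laws; on
#' failure of every start the nested-bisection oracle result is used and
#' flagged in the `method` field. If that also fails to meet tolerance, an
#' error reports the worst residual.
#'
#' @inheritParams oracle_solve
#' @return A `steady_state` object: the 18 (or 16) species concentrations,
#'   reporter rate `R`, relative conservation residuals for the four pools,
#'   and solver diagnostics (`method`, `iterations`, `converged`).
#' @examples
#' st <- solve_steady_state(kinetic_params(), pool_totals())
#' st$R                                  # steady-state reporter rate
#' max(abs(st$residuals))                # conservation residuals
#' @export
solve_steady_state <- function(params, totals, settings = solver_settings(),
                               assumptions = model_assumptions()) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(totals, "pool_totals"),
            inherits(settings, "solver_settings"))
  mp <- assumptions$monomer_partitioning
  mk <- function(U, S, method, iter) {
    st <- new_steady_state(U, S, params, totals, assumptions,
                           method = method, iterations = iter,
                           converged = TRUE)
    if (max(abs(st$residuals)) > settings$tol) st$converged <- FALSE
    st
  }

  if (totals$U_total == 0 && totals$S_total == 0)
    return(mk(0, 0, "analytic", 0L))

  if (totals$S_total == 0 || totals$U_total == 0) {
    # one free pool: single monotone equation, bracketed on [0, pool total]
    which_u <- totals$S_total == 0
    total <- if (which_u) totals$U_total else totals$S_total
    f <- function(x) {
      imp <- imp_totals(if (which_u) x else 0, if (which_u) 0 else x,
                        params, totals, mp)
      imp[[if (which_u) "U" else "S"]] - total
    }
    root <- if (f(total) <= 0) total else
      stats::uniroot(f, c(0, total), tol = 1e-15 * total)$root
    st <- mk(if (which_u) root else 0, if (which_u) 0 else root,
             "brent_1d", 1L)
    if (st$converged) return(st)
    root <- bisect_root(f, total, settings$max_iter)
    st <- mk(if (which_u) root else 0, if (which_u) 0 else root,
             "bisection_1d", 1L)
    if (!st$converged)
      stop("1-d solve failed; worst relative residual ",
           format(max(abs(st$residuals))))
    return(st)
  }

  scale_U <- max(totals$U_total, 1)
  scale_S <- max(totals$S_total, 1)
  g <- function(z) {
    imp <- imp_totals(exp(z[1]), exp(z[2]), params, totals, mp)
    c((imp[["U"]] - totals$U_total) / scale_U,
      (imp[["S"]] - totals$S_total) / scale_S)
  }
  U0 <- totals$U_total / (1 + params$Ktm_u)
  S0 <- totals$S_total / (1 + params$Ktm_s)
  facs <- 10^(-(seq_len(settings$n_starts) - 1))   # 1, 0.1, 0.01, ...
  for (i in seq_along(facs)) {
    z0 <- log(c(U0, S0) * facs[i])
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(g, z0, maxiter = settings$max_iter,
                                      tol = min(settings$tol, 1e-12))),
      error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol$x))) next
    st <- tryCatch(mk(exp(sol$x[1]), exp(sol$x[2]), "fsolve", i),
                   error = function(e) NULL)
    if (!is.null(st) && st$converged) return(st)
  }
  # all multistarts failed: fall back on the guaranteed-bracketed oracle
  st <- oracle_solve(params, totals, settings, assumptions)
  st$method <- "oracle_fallback"
  if (!st$converged)
    stop("steady-state solve failed (primary and oracle); worst relative ",
         "residual ", format(max(abs(st$residuals))))
  st
}
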