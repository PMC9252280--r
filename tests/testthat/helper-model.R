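# Shared test helpers: small fixture builders and independent oracles.

# largest relative discrepancy between two concentration vectors
rel_diff <- function(a, b, floor = 1e-12) {
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}

# seeded random parameter set in a decade around the defaults, optionally
# with random s/u ratios; built directly (not via sample_ensemble) so that
# solver tests do not depend on the ensemble module
random_params <- function(vary_ratios = TRUE) {
  d <- kinetic_params()
  jitter <- function(x) x * 10^stats::runif(1, -1, 1)
  p <- kinetic_params(KDu = jitter(d$KDu), Kiu = jitter(d$Kiu),
                      Ktu = jitter(d$Ktu), Kpu = jitter(d$Kpu),
                      ku = jitter(d$ku))
  if (vary_ratios)
    for (ax in c("ks/ku", "Kps/Kpu", "KDs/KDu", "Kts/Ktu", "Kis/Kiu"))
      p <- set_su_ratio(p, ax, 10^stats::runif(1, -2, 2))
  p
}

random_totals <- function() {
  pool_totals(DL_total = 100 * 10^stats::runif(1, -1, 1),
              sumo_fraction = sample(c(0.01, 0.05, 0.1), 1),
              Cact_total = 100 * 10^stats::runif(1, -1, 1),
              P_total = 0.1 * 10^stats::runif(1, -1, 1))
}

# Independent oracle for the single homodimerization reaction 2A <-> A2
# with association constant KD: given the total A (in monomer
# equivalents), find the free monomer by bisection on the conservation
# relation a + 2*KD*a^2 = A_total and return both.
dimer_equilibrium_bisect <- function(KD, A_total, iter = 200) {
  lo <- 0; hi <- A_total
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (mid + 2 * KD * mid^2 < A_total) lo <- mid else hi <- mid
  }
  a <- (lo + hi) / 2
  list(monomer = a, dimer = KD * a^2)
}
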