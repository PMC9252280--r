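---
title: "A steady-state model of Dorsal SUMOylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A steady-state model of Dorsal SUMOylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumodl)
```

## The model

Dorsal (DL), the *Drosophila* NF-κB ortholog, exists as an unSUMOylated
pool DL^U^ and a small SUMOylated pool DL^S^ (a few percent of the total).
The package models the signaling module as a chain of reversible
equilibria, all at (pseudo) steady state:

1. **Dimerization.** Monomers form UU, US and SS dimers with association
   constants `KDu`, `KDus`, `KDs` (`[UU] = KDu·[U]²`, `[US] = KDus·[U][S]`,
   `[SS] = KDs·[S]²`).
2. **Cactus sequestration.** Cytoplasmic dimers bind Cactus (IκB) with
   `Kiu`, `Kius`, `Kis`, removing them from the nuclear-import pool.
3. **Nuclear partitioning.** Free dimers distribute between cytoplasm and
   nucleus with partition coefficients `Ktu`, `Ktus`, `Kts`
   (nuclear/cytoplasmic concentration ratio); free monomers likewise with
   `Ktm_u`, `Ktm_s`.
4. **Promoter binding.** Nuclear dimers compete for a single class of
   promoter sites P with `Kpu`, `Kpus`, `Kps`.
5. **Expression.** Occupied sites drive first-order reporter expression:
   `R = ku·[P:UU] + kus·[P:US] + ks·[P:SS]`.

Four pools are conserved: DL^U^ subunits, DL^S^ subunits, Cactus, and
promoter sites. The wild type carries `sumo_fraction` (default 5%) of its
Dorsal as DL^S^; the SUMO-conjugation-resistant condition (SCR) removes
the DL^S^ sub-pool while keeping the DL^U^ sub-pool and everything else
unchanged. The headline output is the ratio `R_SCR / R_WT` computed by
`scr_wt_ratio()`.

Key structural assumptions:

* **Association convention.** All `K` are association constants, so
  "tighter binding" always means a larger number.
* **Tying rule.** Parameters for the heterodimer equal those for the
  SUMOylated homodimer (`Kps = Kpus`, `ks = kus`, ...): one SUMOylated
  subunit is assumed sufficient to confer the SUMOylated behavior.
  `set_su_ratio()` and the sweep machinery enforce this.
* **Lumped heterodimer constant.** `KDus` carries no statistical factor
  of 2. A consequence worth knowing: with *all* ratios tied at 1 the
  model is only approximately label-blind — total dimer mass is
  `KD(U² + U·S + S²)` rather than `KD(U + S)²` — so the tied wild type
  matches a uniform pool of the same total only to ~0.1% (the tests
  measure this bound).
* **No compartment volumes.** Partition coefficients are concentration
  ratios and conservation sums concentrations without volume weights;
  absolute totals can be read as volume-weighted abundances without
  changing any dimensionless result.
* **Reporter is a production rate.** `R` is the instantaneous synthesis
  rate; if reporter protein decays with any shared first-order rate, the
  steady-state *level* ratio equals the rate ratio reported here.

## Species closure: 18 forms

`enumerate_species()` lists the tracked molecular forms: 2 cytoplasmic
monomers, 2 nuclear monomers, and the three dimer compositions in each of
four contexts (free cytoplasmic, Cactus-bound, nuclear, promoter-bound),
plus free Cactus and free promoter — 18 forms, one steady-state mass
balance each, alongside the 4 conservation laws. Monomer partitioning is
a closure choice: the two nuclear monomer forms are inert mass (they
touch no downstream reaction), and `model_assumptions(FALSE)` removes
them for a 16-form variant with identical qualitative behavior. The
default keeps them, with `Ktm_u = Ktm_s = 1` (monomers small enough to
equilibrate freely across the nuclear envelope).

## Reduction and solvers

Because every complex is an explicit function of the free cytoplasmic
monomer pair `(U, S)` — dimers by mass action, free Cactus and free
promoter by analytic elimination of their conservation laws — the whole
system collapses to two equations: the implied U- and S-subunit totals
must match the specified pools (`conservation_residuals()`).

Two independent solvers attack this 2×2 system:

* `solve_steady_state()` (primary): quasi-Newton root finding in
  log-concentration space (positivity for free), multistarting from the
  dilute-limit guess `U₀ = U_total/(1+Ktm_u)` and four log-spaced
  downward perturbations, in a fixed deterministic order. Degenerate
  pools (`S_total = 0`, `U_total = 0`) reduce to one bracketed
  one-dimensional equation.
* `oracle_solve()`: nested bisection — outer on `U`, inner on `S` —
  justified by the monotonicity of each implied total in its own monomer
  concentration (a property the tests verify numerically). Brackets
  `[0, pool total]` are analytic, so the oracle cannot silently fail; a
  sign violation at a bracket end raises.

Every candidate solution is validated post hoc against *all* per-form
mass balances and all four conservation laws
(`mass_balance_residuals()`), at a default relative tolerance of 1e-10.
If every multistart fails, the oracle result is used and flagged in the
`method` field. The two solvers agree to better than 1e-6 relative on
every concentration across 100-member random ensembles (they typically
agree to ~1e-11; the acceptance suite checks this).

Tie-breaking: the reduced system's conservation functions are monotone,
so a unique positive root is expected; the solvers converge to the root
inside the analytic bracket and the back-substitution check would expose
any spurious solution.

## Parameters and defaults

Concentrations are in arbitrary units `c`; association constants in
`1/c`; partition coefficients and all ratios dimensionless; rate
constants in `1/time`. The exact kinetic constants of this system are
not known; the defaults are order-of-magnitude choices pinned down by
the regime the model is meant to describe, and every qualitative
conclusion is re-checked on random ensembles (below).

| parameter | default | why |
|---|---|---|
| `DL_total` | 100 | abundant maternal transcription factor; sets the concentration scale together with the binding constants |
| `sumo_fraction` | 0.05 | upper end of the 1–5% SUMOylated share seen on blots; 0.01 and 0.10 are standard robustness settings |
| `Cact_total` | 100 | comparable to total Dorsal, as expected for a stoichiometric inhibitor |
| `P_total` | 0.1 | promoter sites are trace relative to protein pools; `R` is linear in `P_total`, so the ratio is insensitive to it |
| `KDu` | 0.01 | roughly half of Dorsal dimeric at these totals |
| `Kiu` | 0.1 | Cactus sequesters the majority of free dimers (`Kiu·Cact_free ≈ 8`) |
| `Ktu`, `Ktm_u` | 1 | no net compartment preference before signaling asymmetries are imposed |
| `Kpu` | 10 | strong, near-saturating promoter binding (~97% baseline occupancy); see below |
| `ku` | 1 | defines the time unit |

**Why a saturated promoter?** Developmental Dorsal targets are robustly
activated: output should be buffered against moderate changes in total
Dorsal, which is exactly the saturated-promoter regime. This choice is
also what makes the model reproduce its two calibration behaviors
simultaneously: (i) at equal specific activity (`ks = ku`) the SCR/WT
ratio stays within a few percent of 1 across four orders of magnitude of
relative binding affinity (occupancy is full in both conditions, so
swapping strong for weak binders changes nothing as long as they are
equally active), and (ii) with weakly active SUMO-dimers
(`ks/ku = 0.01`) a substantial increase first appears at
`Kps/Kpu = 10`. With much weaker promoter binding, behavior (i)
collapses; the acceptance suite computes both curves.

**The substantiality margin (default 0.10).** Removing 5% of Dorsal as
low-activity dimers trivially raises the SCR/WT ratio by roughly the
SUMO-containing share of promoter-bound dimers,
`(US + SS)/UU ≈ f/(1−f) + (f/(1−f))²` amplified by the preferential
locking of U subunits into dimers — about 6–8% at `f = 0.05` regardless
of the other constants. A margin of 10% sits above this composition
artifact but far below the enhancement-driven increases (≥ 30% at
`Kps/Kpu = 10`, several-fold at 100), so `threshold_detect()` flags only
increases that require an occupancy-enhancing change. At `f = 0.10` the
artifact itself reaches the margin (the robustness summary records a
threshold of 1 there); the per-condition qualitative flags therefore
compare enhanced against unenhanced families rather than against a fixed
constant.

## Random ensembles

`sample_ensemble()` draws seeded log-uniform parameter sets: each
unSUMOylated constant and each pool total within one decade either side
of its default, each s/u ratio within the hundred-fold range
`[0.01, 100]`, and the SUMO fraction from {1%, 5%, 10%}. Log-uniform
sampling matches the multiplicative, per-decade character of the
exploration. Each parameter draws from its own substream (derived
deterministically from the global seed), so extending the specification
never scrambles existing draws.

What the ensembles emulate: ignorance of the true kinetic constants
within biologically sensible magnitudes. What they do not emulate: real
measurement noise, spatial gradients of nuclear import along the
dorso-ventral axis, temporal dynamics, or correlated uncertainties
between constants. A conclusion that survives the ensemble is robust to
parameter ignorance — not validated against data.

`qualitative_conclusion_rate()` re-runs the sweep per member and scores
the necessity property (no expression increase beyond the margin when
`ks/ku ≥ 1`); members forced to equal specific activity uphold it
universally (the parity argument above), which the tests verify on
seeded ensembles.

## Problem sizes and numerical choices

* Default sweep: 41 log-spaced `ks/ku` points × 5 `Kps/Kpu` families
  (410 steady-state solves, a few seconds).
* Robustness grid: 3 SUMO fractions + 5 Cactus scalings, each a sweep
  (17-point x-grid by default — the flags are sign patterns, not curve
  shapes, so a coarse grid suffices).
* Solver-equivalence checks: 100 random members, both solvers, full
  concentration vectors at 1e-6 relative.
* Bisection runs to interval exhaustion at machine resolution; the
  quasi-Newton residual tolerance is 1e-12, well inside the 1e-10
  acceptance tolerance on conservation laws.
* Degenerate inputs (`f = 0`, `f → 1`, zero totals) are handled by exact
  limits, never by division inside the generic path.

## Limitations

* Steady state only: the model cannot describe the dynamics of a Toll
  signaling pulse, SUMO conjugation/deconjugation cycling, or feedback
  on Cactus synthesis.
* One promoter class: no distinction among target genes, no
  cooperativity or repressor recruitment at the promoter.
* The parameter table is a calibrated reconstruction, not a measurement;
  only magnitude-robust, qualitative statements (which curves exceed 1,
  where thresholds sit on a decade grid) should be read out of it.
* SUMOylation is a static label: the SUMO fraction is a conserved pool
  property, not the outcome of a conjugation equilibrium.
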