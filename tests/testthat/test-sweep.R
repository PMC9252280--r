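test_that("without SUMOylation the SCR/WT ratio is exactly 1", {
  out <- scr_wt_ratio(kinetic_params(), pool_totals(sumo_fraction = 0))
  expect_identical(out$ratio, 1)
})

test_that("tied parameters make WT near-equivalent to a uniform Dorsal pool", {
  # with every s/us parameter equal to the u value the labels U/S are
  # almost interchangeable: WT at fraction f approximates a 0% system at
  # the same total, SCR one at (1-f) of the total. Equivalence is not
  # exact because the heterodimer constant is lumped (no statistical
  # factor of 2), which removes KD*U*S of dimer mass relative to a truly
  # uniform pool; the measured effect on R is ~5e-4 at defaults.
  p <- kinetic_params()    # defaults are fully tied
  out <- scr_wt_ratio(p, pool_totals(sumo_fraction = 0.05))
  uniform_full <- solve_steady_state(p, pool_totals(sumo_fraction = 0))
  uniform_95 <- solve_steady_state(p, pool_totals(DL_total = 95,
                                                  sumo_fraction = 0))
  expect_equal(out$R_wt, uniform_full$R, tolerance = 2e-3)
  expect_equal(out$R_scr, uniform_95$R, tolerance = 2e-3)
  # saturated promoter: removing 5% of Dorsal barely moves expression
  expect_lt(abs(out$ratio - 1), 0.02)
})

test_that("low SUMO-dimer activity plus tighter binding raises SCR expression", {
  p <- set_su_ratio(set_su_ratio(kinetic_params(), "ks/ku", 0.01),
                    "Kps/Kpu", 100)
  out <- scr_wt_ratio(p, pool_totals())
  expect_gt(out$ratio, 1)
})

test_that("sweep results have the documented shape and ordering", {
  spec <- sweep_spec(x_grid = log_grid(0.01, 100, 5),
                     family_grid = c(0.1, 1, 10))
  res <- run_sweep(spec)
  expect_s3_class(res, "sweep_result")
  expect_equal(nrow(res), 15)
  expect_equal(names(res), c("family_ratio", "x_ratio", "ln_x_ratio",
                             "R_wt", "R_scr", "ratio", "converged"))
  # sorted by (family, x)
  expect_false(is.unsorted(res$family_ratio))
  for (f in unique(res$family_ratio))
    expect_false(is.unsorted(res$x_ratio[res$family_ratio == f]))
  expect_true(all(res$converged))
  expect_true(all(is.finite(res$ratio) & res$ratio > 0))
})

test_that("the default sweep grid reproduces the printed axis geometry", {
  spec <- sweep_spec()
  expect_equal(length(spec$x_grid), 41)
  expect_equal(spec$family_grid, c(0.01, 0.1, 1, 10, 100))
  expect_equal(log(min(spec$x_grid)), -4.6, tolerance = 0.01)
  expect_equal(log(max(spec$x_grid)), 4.6, tolerance = 0.01)
})

test_that("a single-point sweep agrees with scr_wt_ratio", {
  spec <- sweep_spec(x_grid = 1, family_grid = 1)
  res <- run_sweep(spec)
  expect_equal(nrow(res), 1)
  direct <- scr_wt_ratio(kinetic_params(), pool_totals())
  expect_equal(res$ratio, direct$ratio, tolerance = 1e-12)
})

test_that("threshold detection finds the first substantial exceedance", {
  tab <- data.frame(family_ratio = c(0.01, 0.1, 1, 10, 100),
                    x_ratio = 0.01,
                    ratio = c(0.9, 1.0, 1.01, 1.5, 3.0))
  expect_equal(threshold_detect(tab, margin = 0.05), 10)
  expect_equal(threshold_detect(tab, margin = 0), 1)  # 1.01 > 1
  tab$ratio <- c(0.2, 0.5, 0.9, 0.95, 1.0)
  expect_true(is.na(threshold_detect(tab, margin = 0.05)))
  expect_error(threshold_detect(tab[c(2, 1, 3, 4, 5), ], margin = 0.05),
               "ascending")
  tab$x_ratio <- c(0.01, 0.01, 0.01, 1, 1)
  expect_error(threshold_detect(tab), "single fixed x ratio")
})

test_that("the expression ratio is non-increasing in relative SUMO-dimer activity", {
  # R_SCR does not depend on ks; R_WT is non-decreasing in it
  spec <- sweep_spec(x_grid = log_grid(0.01, 100, 9), family_grid = 10)
  res <- run_sweep(spec)
  expect_lt(max(abs(res$R_scr - res$R_scr[1])), 1e-9 * res$R_scr[1])
  expect_true(all(diff(res$R_wt) > -1e-12))
  expect_true(all(diff(res$ratio) < 1e-12))
})

test_that("no expression increase occurs when SUMO dimers are at least as active", {
  spec <- sweep_spec(x_grid = c(1, 10, 100), family_grid = c(0.01, 1, 100))
  res <- run_sweep(spec)
  expect_true(all(res$ratio <= 1.05))
})

test_that("nuclear partitioning or reduced sequestration also enable the increase", {
  p_low_ks <- set_su_ratio(kinetic_params(), "ks/ku", 0.01)
  t <- pool_totals()
  part <- scr_wt_ratio(set_su_ratio(p_low_ks, "Kts/Ktu", 100), t)
  seq_ <- scr_wt_ratio(set_su_ratio(p_low_ks, "Kis/Kiu", 0.01), t)
  expect_gt(part$ratio, 1.1)
  expect_gt(seq_$ratio, 1.1)
})

test_that("sweep specs reject malformed grids and repeated axes", {
  expect_error(sweep_spec(x_grid = c(1, -2)), "positive")
  expect_error(sweep_spec(x_grid = c(2, 1, 3)), "ascending")
  expect_error(sweep_spec(x_axis = "ks/ku", family_axis = "ks/ku"),
               "different")
})

test_that("robustness grid upholds both qualitative conclusions per condition", {
  rb <- robustness_grid(x_grid = log_grid(0.01, 100, 5))
  expect_equal(nrow(rb$summary), 8)    # 3 SUMO fractions + 5 Cactus scales
  expect_true(all(rb$summary$necessity_ks))
  expect_true(all(rb$summary$enhancement_amplifies))
  expect_true(all(rb$summary$all_converged))
  # no SUMOylated pool at all: every ratio is exactly 1
  rb0 <- robustness_grid(sumo_fractions = 0, cact_scales = 1,
                         x_grid = c(0.01, 1))
  expect_true(all(rb0$results[[1]]$ratio == 1))
})
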