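test_that("default species enumeration has 18 forms with the documented roles", {
  sp <- enumerate_species()
  expect_equal(nrow(sp), 18)
  counts <- table(sp$role)
  expect_equal(unname(counts[["monomer"]]), 4)          # 2 cyt + 2 nuc
  expect_equal(unname(counts[["free dimer"]]), 3)
  expect_equal(unname(counts[["Cactus-bound dimer"]]), 3)
  expect_equal(unname(counts[["nuclear dimer"]]), 3)
  expect_equal(unname(counts[["promoter-bound dimer"]]), 3)
  expect_equal(unname(counts[["free Cactus"]]), 1)
  expect_equal(unname(counts[["free promoter"]]), 1)
  # dimer compositions limited to UU, US, SS
  dim_rows <- sp[grepl("dimer", sp$role), ]
  expect_true(all(dim_rows$n_u + dim_rows$n_s == 2))
  expect_setequal(unique(paste(dim_rows$n_u, dim_rows$n_s)),
                  c("2 0", "1 1", "0 2"))
})

test_that("disabling monomer partitioning closes the system at 16 forms", {
  sp <- enumerate_species(model_assumptions(monomer_partitioning = FALSE))
  expect_equal(nrow(sp), 16)
  expect_false(any(sp$role == "monomer" & sp$compartment == "nucleus"))
  # ordering of the shared forms is unchanged
  expect_equal(sp$name, setdiff(enumerate_species()$name,
                                c("U_nuc", "S_nuc")))
})

test_that("dimer concentrations follow mass action", {
  p <- kinetic_params(KDu = 1)
  expect_equal(dimer_concentrations(0, 3, p)[c("UU", "US")],
               c(UU = 0, US = 0))
  expect_equal(dimer_concentrations(2, 0, p),
               c(UU = 4, US = 0, SS = 0))
  expect_error(dimer_concentrations(-1, 0, p), "non-negative")
})

test_that("dimer law agrees with a bisection solve of the binding equilibrium", {
  set.seed(11)
  for (i in 1:25) {
    KD <- 10^runif(1, -3, 1)
    A_total <- 10^runif(1, -1, 2.5)
    eq <- dimer_equilibrium_bisect(KD, A_total)
    d <- dimer_concentrations(eq$monomer, 0, kinetic_params(KDu = KD))
    # the dimer implied by mass action must equal the one implied by
    # conservation at the bisected free-monomer concentration
    expect_equal(d[["UU"]], (A_total - eq$monomer) / 2, tolerance = 1e-9)
  }
})

test_that("free Cactus and free promoter eliminate their conservation laws", {
  p <- kinetic_params(Kiu = 1, Kius = 1, Kis = 1,
                      Kpu = 1, Kpus = 1, Kps = 1)
  expect_equal(free_cactus(c(0, 0, 0), p, 50), 50)
  expect_equal(free_cactus(c(1, 0, 0), p, 2), 1)
  expect_equal(free_promoter(c(0, 0, 0), p, 7), 7)
  expect_equal(free_promoter(c(3, 0, 0), p, 4), 1)
  # conservation holds by construction for random inputs
  set.seed(21)
  for (i in 1:20) {
    pr <- random_params()
    d <- 10^runif(3, -3, 2)
    Ct <- 10^runif(1, -1, 3)
    Cf <- free_cactus(d, pr, Ct)
    bound <- c(pr$Kiu, pr$Kius, pr$Kis) * Cf * d
    expect_equal(Cf + sum(bound), Ct, tolerance = 1e-12)
    Pt <- 10^runif(1, -2, 1)
    Pf <- free_promoter(d, pr, Pt)
    expect_equal(Pf + sum(c(pr$Kpu, pr$Kpus, pr$Kps) * Pf * d), Pt,
                 tolerance = 1e-12)
  }
})

test_that("reporter rate sums first-order expression over bound promoters", {
  p <- kinetic_params(ku = 1, kus = 1, ks = 1)
  zero <- c(P_UU = 0, P_US = 0, P_SS = 0)
  expect_equal(reporter_rate(zero, p), 0)
  expect_equal(reporter_rate(c(P_UU = 0.5, P_US = 0, P_SS = 0), p), 0.5)
  # equal rate constants: R = k * total bound, regardless of composition
  p2 <- kinetic_params(ku = 2.5, kus = 2.5, ks = 2.5)
  bound <- c(P_UU = 0.1, P_US = 0.25, P_SS = 0.05)
  expect_equal(reporter_rate(bound, p2), 2.5 * sum(bound))
})

test_that("every state concentration maps to exactly one enumerated form", {
  st <- solve_steady_state(kinetic_params(), pool_totals())
  expect_setequal(names(st$concentrations), enumerate_species()$name)
  expect_true(all(st$concentrations >= 0))
})

test_that("equilibrium relations are scale invariant", {
  # concentrations x c with association constants / c leaves occupancies
  # and the SCR/WT ratio unchanged
  set.seed(31)
  for (c_scale in c(0.01, 7, 1000)) {
    p <- random_params()
    t <- random_totals()
    p2 <- p
    for (nm in c("KDu", "KDus", "KDs", "Kiu", "Kius", "Kis",
                 "Kpu", "Kpus", "Kps"))
      p2[[nm]] <- p[[nm]] / c_scale
    t2 <- pool_totals(t$DL_total * c_scale, t$sumo_fraction,
                      t$Cact_total * c_scale, t$P_total * c_scale)
    a <- scr_wt_ratio(p, t)
    b <- scr_wt_ratio(p2, t2)
    occ <- function(x) x$wt$concentrations[c("P_UU", "P_US", "P_SS")] /
      max(x$wt$concentrations[["P_free"]] +
            sum(x$wt$concentrations[c("P_UU", "P_US", "P_SS")]), 1e-300)
    expect_equal(occ(a), occ(b), tolerance = 1e-8)
    expect_equal(a$ratio, b$ratio, tolerance = 1e-8)
  }
})

test_that("parameter and total validation rejects bad input", {
  expect_error(kinetic_params(KDu = -1), "strictly positive")
  expect_error(kinetic_params(ks = 0), "strictly positive")
  expect_error(kinetic_params(Kpu = Inf), "finite")
  expect_error(pool_totals(sumo_fraction = 1), "\\[0, 1\\)")
  expect_error(pool_totals(DL_total = -5), "DL_total")
  # derived sub-pools always sum exactly to the total
  set.seed(41)
  for (f in runif(10, 0, 0.99)) {
    t <- pool_totals(sumo_fraction = f)
    expect_identical(t$U_total + t$S_total, t$DL_total)
  }
})

test_that("the tying rule co-sets heterodimer parameters", {
  p <- set_su_ratio(kinetic_params(), "Kps/Kpu", 37)
  expect_equal(p$Kps, 37 * p$Kpu)
  expect_identical(p$Kpus, p$Kps)
  p <- set_su_ratio(kinetic_params(), "ks/ku", 0.01)
  expect_identical(p$kus, p$ks)
  expect_error(set_su_ratio(kinetic_params(), "ks/ku", -2), "positive")
})
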