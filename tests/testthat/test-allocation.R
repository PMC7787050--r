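# Dose bookkeeping, gravimetric partition and the allocation equation.

test_that("ingested_dose follows the meal arithmetic", {
  d <- ingested_dose(200, dose_c_per_g_meal = 1e-3, dose_n_per_g_meal = 0,
                     meal_mass_g = 1.2)
  expect_equal(d$dose_c, 6.0e-6)
  expect_equal(d$dose_n, 0)
  # default meal: 0.6 % of body weight
  d2 <- ingested_dose(186.1, 1e-3, 1e-4)
  expect_equal(d2$meal_mass_g, 0.006 * 186.1)
  expect_equal(d2$meal_mass_g, 1.1166, tolerance = 1e-6)
  expect_error(ingested_dose(-1, 1e-3, 1e-4), "positive")
  expect_error(ingested_dose(200, 1e-3, 1e-4, meal_fraction_bw = 0.2), "0.05")
})

test_that("fraction_partition returns percentages of raw dry mass and water content", {
  fp <- fraction_partition(50, 41.2, 7.65, wet_mg = 500)
  expect_equal(fp$soluble_pct, 82.4)
  expect_equal(fp$insoluble_pct, 15.3)
  expect_equal(fp$water_pct, 90)
  expect_equal(fraction_partition(50, 50, 0)$soluble_pct, 100)
  expect_equal(fraction_partition(100, 0, 0, wet_mg = 1000)$water_pct, 90)
  expect_error(fraction_partition(50, 45, 10), "exceeds raw")
  expect_error(fraction_partition(50, 30, 10, wet_mg = 40), "wet")
})

test_that("allocation_percent is the quoted product and linear in each factor", {
  expect_equal(allocation_percent(1e-3, 0.8, 0.002, 6.4e-6), 25)
  expect_equal(allocation_percent(0, 0.8, 0.002, 6.4e-6), 0)
  base <- allocation_percent(2e-4, 0.5, 0.01, 1e-5)
  expect_equal(allocation_percent(2e-4, 0.5, 0.02, 1e-5), 2 * base)
  expect_equal(allocation_percent(4e-4, 0.5, 0.01, 1e-5), 2 * base)
  expect_equal(allocation_percent(2e-4, 1.0, 0.01, 1e-5), 2 * base)
  expect_error(allocation_percent(1e-3, 0.8, 0.002, 0, element = "C"), "C")
})

test_that("allocation is invariant under joint rescaling of meal and body mass", {
  # doubling body weight and meal mass together leaves dose/gbw and hence
  # allocation unchanged
  d1 <- ingested_dose(200, 2e-2, 2e-3, meal_mass_g = 1.2)
  d2 <- ingested_dose(400, 2e-2, 2e-3, meal_mass_g = 2.4)
  expect_equal(d1$dose_c, d2$dose_c)
  expect_equal(allocation_percent(1e-4, 0.1, 3e-3, d1$dose_c),
               allocation_percent(1e-4, 0.1, 3e-3, d2$dose_c))
})

test_that("pipeline recovers a hand-computed allocation for a single sample", {
  enr <- 294; d0 <- -21; frac_c <- 0.35
  tab <- make_sample_table(enriched_delta_c = enr, blank_delta_c = d0, n_lab = 1)
  fish <- make_fish_table(unique(tab$fish_id[tab$treatment == "timecourse"]))
  dose <- ingested_dose(186.1, 2e-2, 2e-3)
  out <- sample_allocations(tab, fish, dose)
  lab <- out[out$treatment == "timecourse" & out$element == "C", ]
  # independent hand computation through the chain of definitions
  ape_hand <- delta_to_atom_percent(d0 + enr, "C") - delta_to_atom_percent(d0, "C")
  exc_hand <- (ape_hand / 100) * (frac_c / 12.011) * 13.00335
  alloc_hand <- 100 * exc_hand * (51 / 510) * (510 / 1000 / 186.1) / dose$dose_c
  expect_equal(lab$enrichment_permil, enr, tolerance = 1e-10)
  expect_equal(lab$ape, ape_hand, tolerance = 1e-12)
  expect_equal(lab$percent_of_dose, alloc_hand, tolerance = 1e-12)
})

test_that("timecourse_summary reports group means, sems and single-sample NA sems", {
  tab <- make_sample_table(n_lab = 3)
  tab$delta_c_permil[tab$treatment == "timecourse"] <- c(229, 250, 271) - 21
  fish <- make_fish_table(tab$fish_id[tab$treatment == "timecourse"])
  dose <- ingested_dose(186.1, 2e-2, 2e-3)
  s <- timecourse_summary(tab, fish, dose)
  row <- s[s$element == "C" & s$time_h == 24, ]
  expect_equal(row$n, 3)
  expect_equal(row$enrichment_mean, 250)
  expect_equal(row$enrichment_sem, sd(c(229, 250, 271)) / sqrt(3))
  # single labelled sample: mean passes through, sem is absent
  one <- make_sample_table(n_lab = 1)
  s1 <- timecourse_summary(one, make_fish_table(one$fish_id[one$treatment == "timecourse"]), dose)
  expect_true(all(is.na(s1$enrichment_sem)))
  expect_equal(s1$enrichment_mean[s1$element == "C"], 250)
})

test_that("blanks-only input yields near-zero enrichment and missing blanks error", {
  p <- preset_paper()
  sim <- simulate_timecourse(p, seed = 3)
  blanks_only <- sim$samples[sim$samples$treatment == "blank", ]
  out <- sample_allocations(blanks_only, sim$fish, p$dose,
                            default_mass_model(c(liver = 0.013)))
  expect_lt(max(abs(out$enrichment_permil)), 5)  # baseline noise only
  # labelled samples with no blank group for their compartment
  lab <- sim$samples[sim$samples$treatment != "blank", ]
  some_blanks <- sim$samples[sim$samples$treatment == "blank" &
                               sim$samples$compartment == "liver", ]
  expect_error(
    sample_allocations(dplyr::bind_rows(lab, some_blanks), sim$fish, p$dose,
                       default_mass_model(c(liver = 0.013))),
    "no blank group"
  )
})

test_that("allocation estimates are unbiased over many simulated cohorts", {
  # ground truth: noiseless 24 h raw-mucus 13C allocation of the preset
  p <- preset_paper()
  mm <- default_mass_model(c(liver = 0.013))
  kin_tm <- p$kinetics[p$kinetics$compartment == "total_mucus", ]
  small <- p
  small$kinetics <- kin_tm
  truth <- 0.25
  ests <- vapply(1:200, function(s) {
    sim <- simulate_timecourse(small, seed = 1000 + s)
    keep <- sim$samples$compartment == "total_mucus" &
      sim$samples$time_h %in% c(0, 24)
    out <- sample_allocations(sim$samples[keep, ], sim$fish, p$dose, mm)
    mean(out$percent_of_dose[out$treatment == "timecourse" &
                               out$element == "C" & out$time_h == 24])
  }, 1)
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 3 * mc_se + 1e-12)
})
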