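# The pulse-chase cohort generator.

test_that("mean curves follow their functional forms", {
  sat <- kinetics("total_mucus", "C", "saturating", plateau = 489, rate_k = 0.15)
  t <- c(0, 3, 6, 12, 24, 48)
  expect_equal(mean_enrichment(sat, t), 489 * (1 - exp(-0.15 * t)))
  expect_true(all(diff(mean_enrichment(sat, 0:100)) >= 0))   # monotone
  tp <- kinetics("plasma", "C", "transit_peak", plateau = 30, peak_tau = 6)
  m <- mean_enrichment(tp, seq(0, 48, by = 0.1))
  expect_equal(max(m), 30, tolerance = 1e-9)                 # peak height A
  expect_equal(seq(0, 48, by = 0.1)[which.max(m)], 6)        # peak at tau
  anc <- kinetics("liver", "C", "anchors",
                  anchors = data.frame(time_h = c(0, 6, 12), mean = c(0, 10, 30)))
  expect_equal(mean_enrichment(anc, c(0, 6, 12)), c(0, 10, 30))
  expect_equal(mean_enrichment(anc, 3), 5)                   # linear between anchors
  expect_error(kinetics("x", "C", "saturating", plateau = -1, rate_k = 1), "plateau")
})

test_that("a fixed seed reproduces the cohort exactly and seeds differ", {
  p <- preset_paper()
  s1 <- simulate_timecourse(p, seed = 5)
  s2 <- simulate_timecourse(p, seed = 5)
  expect_identical(s1, s2)
  s3 <- simulate_timecourse(p, seed = 6)
  expect_false(identical(s1$samples$delta_c_permil, s3$samples$delta_c_permil))
  r1 <- simulate_renewal(p, seed = 5)
  r2 <- simulate_renewal(p, seed = 5)
  expect_identical(r1, r2)
})

test_that("noiseless preset cohorts hit the calibrated group means exactly", {
  p <- preset_paper()
  mm <- default_mass_model(c(liver = 0.013))
  sim <- simulate_timecourse(p, seed = 1, noiseless = TRUE)
  s <- timecourse_summary(sim$samples, sim$fish, p$dose, mm)
  g <- function(cp, el, t, col) s[[col]][s$compartment == cp & s$element == el & s$time_h == t]
  expect_equal(g("soluble_mucus", "C", 12, "enrichment_mean"), 489, tolerance = 1e-6)
  expect_equal(g("soluble_mucus", "C", 6, "enrichment_mean"), 240, tolerance = 1e-6)
  expect_equal(g("insoluble_mucus", "C", 12, "enrichment_mean"), 165, tolerance = 1e-6)
  expect_equal(g("total_mucus", "C", 24, "allocation_mean"), 0.25, tolerance = 1e-8)
  expect_equal(g("total_mucus", "N", 24, "allocation_mean"), 0.11, tolerance = 1e-8)
  expect_equal(g("liver", "C", 12, "allocation_mean"), 45, tolerance = 1e-6)
  rsim <- simulate_renewal(p, seed = 1, noiseless = TRUE)
  ren <- analyze_renewal(rsim$samples, rsim$fish, p$dose, mm)
  expect_equal(ren$renewal_mean[ren$metric == "total_mucus_C_enrichment_permil"],
               638, tolerance = 1e-6)
  expect_equal(ren$control_mean[ren$metric == "collected_mucus_mg"], 510,
               tolerance = 1e-6)
  expect_equal(ren$renewal_mean[ren$metric == "collected_mucus_mg"], 290,
               tolerance = 1e-6)
})

test_that("time zero is baseline and blanks scatter around natural abundance", {
  p <- preset_paper()
  sim <- simulate_timecourse(p, seed = 9)
  tm0 <- sim$samples[sim$samples$compartment == "total_mucus" &
                       sim$samples$time_h == 0, ]
  expect_lt(max(abs(tm0$delta_c_permil - (-21))), 5)  # within baseline noise
  blanks <- sim$samples[sim$samples$treatment == "blank" &
                          sim$samples$compartment == "total_mucus", ]
  expect_gt(sd(blanks$delta_n_permil), 0)
  expect_lt(abs(mean(blanks$delta_n_permil) - 8), 3)
})

test_that("renewal factors of one make control and renewal exchangeable", {
  p <- preset_paper()
  p$config$renewal$mass_reduction_factor <- 1
  p$config$renewal$mass_cv <- p$config$mucus_ratio_cv
  p$config$renewal$kinetics <- p$kinetics
  sim <- simulate_renewal(p, seed = 21, n = 40)
  fr <- sim$fish[sim$fish$treatment != "blank", ]
  rc <- renewal_contrast(fr)
  expect_false(any(rc$significant))
  expect_equal(rc$ratio[rc$metric == "collected_mucus_mg"], 1, tolerance = 0.2)
})

test_that("a mass-balanced configuration keeps fraction allocations below raw", {
  # raw-mucus enrichment equals the dry-mass-weighted mean of the fractions,
  # so soluble + insoluble allocation cannot exceed raw within noise
  p <- preset_paper()
  mm <- default_mass_model(c(liver = 0.013))
  mk <- function(cp, el, means) {
    kinetics(cp, el, "anchors",
             anchors = data.frame(time_h = c(0, 6, 12, 24), mean = means,
                                  sem = 0.05 * means))
  }
  sol <- c(0, 240, 489, 437); ins <- c(0, 45, 165, 213)
  tot <- 0.824 * sol + 0.153 * ins + (1 - 0.824 - 0.153) * sol
  bal <- p
  bal$kinetics <- dplyr::bind_rows(
    mk("soluble_mucus", "C", sol), mk("insoluble_mucus", "C", ins),
    mk("total_mucus", "C", tot),
    mk("soluble_mucus", "N", sol / 4), mk("insoluble_mucus", "N", ins / 4),
    mk("total_mucus", "N", tot / 4)
  )
  sim <- simulate_timecourse(bal, seed = 31, n = 30)
  s <- timecourse_summary(sim$samples, sim$fish, p$dose, mm)
  for (el in c("C", "N")) {
    at24 <- s[s$element == el & s$time_h == 24, ]
    raw <- at24[at24$compartment == "total_mucus", ]
    frs <- at24[at24$compartment %in% c("soluble_mucus", "insoluble_mucus"), ]
    combined_sem <- sqrt(sum(frs$allocation_sem^2) + raw$allocation_sem^2)
    expect_lt(sum(frs$allocation_mean) - raw$allocation_mean, 2 * combined_sem)
  }
})

test_that("the calibration declares itself group-level only", {
  p <- preset_paper()
  expect_match(p$calibration_note, "group-level")
  expect_match(p$calibration_note, "not deposited|not.*reproduc|synthetic")
})
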