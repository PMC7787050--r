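# Pulse-chase cohort generator.
#
# The generator works in enrichment space: for every compartment x element it
# draws per-fish blank-subtracted enrichment (permil) around a mean kinetic
# curve, adds natural-abundance baseline noise on the delta scale, and emits
# the same CSV schemas the analysis functions consume. Three mean-curve
# models are supported:
#   saturating:   A (1 - exp(-k t))
#   transit_peak: A (t/tau) exp(1 - t/tau)   (peaks at A when t = tau)
#   anchors:      interpolation through (time, mean, sem) calibration points
# Enriched noise is multiplicative lognormal (enrichments are positive and
# skewed); baseline noise is additive normal on delta, so blanks scatter
# symmetrically around natural abundance.

rln_mean_cv <- function(n, mean, cv) {
  if (length(mean) == 1) mean <- rep(mean, n)
  out <- mean
  pos <- mean > 0 & cv > 0
  if (any(pos)) {
    s2 <- log(1 + cv^2)
    out[pos] <- rlnorm(sum(pos), log(mean[pos]) - s2 / 2, sqrt(s2))
  }
  out
}

#' Kinetic model for one compartment and element
#'
#' @param compartment,element Compartment and element labels.
#' @param model `"saturating"`, `"transit_peak"` or `"anchors"`.
#' @param plateau Asymptotic (saturating) or peak (transit_peak) enrichment
#'   in permil; ignored for `"anchors"`.
#' @param rate_k First-order rate constant (1/h), saturating model.
#' @param peak_tau Time of the peak (h), transit_peak model.
#' @param cv Coefficient of variation of the per-fish multiplicative noise.
#' @param anchors Data frame with columns `time_h`, `mean` and optionally
#'   `sem` (anchors model); per-anchor cv is derived as `sem * sqrt(5) / mean`
#'   when `sem` is given.
#' @return A one-row tibble (anchors held in a list column).
#' @export
kinetics <- function(compartment, element, model,
                     plateau = NA_real_, rate_k = NA_real_,
                     peak_tau = NA_real_, cv = 0, anchors = NULL) {
  model <- match.arg(model, c("saturating", "transit_peak", "anchors"))
  if (model == "saturating" && (is.na(plateau) || plateau < 0 || is.na(rate_k) || rate_k <= 0)) {
    abort("saturating model needs plateau >= 0 and rate_k > 0.")
  }
  if (model == "transit_peak" && (is.na(plateau) || plateau < 0 || is.na(peak_tau) || peak_tau <= 0)) {
    abort("transit_peak model needs plateau >= 0 and peak_tau > 0.")
  }
  if (model == "anchors") {
    if (is.null(anchors) || !all(c("time_h", "mean") %in% names(anchors))) {
      abort("anchors model needs a data frame with columns time_h and mean.")
    }
    anchors <- as_tibble(anchors)[order(anchors$time_h), ]
    if (!"sem" %in% names(anchors)) anchors$sem <- NA_real_
  }
  tibble(compartment = compartment, element = element, model = model,
         plateau = plateau, rate_k = rate_k, peak_tau = peak_tau,
         cv = cv, anchors = list(anchors))
}

#' Mean enrichment curve of a kinetic model
#'
#' @param kin One row of a kinetics table (see [kinetics()]).
#' @param time_h Numeric vector of times (h).
#' @return Mean blank-subtracted enrichment (permil) at each time.
#' @export
mean_enrichment <- function(kin, time_h) {
  switch(kin$model,
    saturating   = kin$plateau * (1 - exp(-kin$rate_k * time_h)),
    transit_peak = ifelse(time_h <= 0, 0,
                          kin$plateau * (time_h / kin$peak_tau) *
                            exp(1 - time_h / kin$peak_tau)),
    anchors = {
      a <- kin$anchors[[1]]
      if (nrow(a) == 1) rep(a$mean, length(time_h))
      else approx(a$time_h, a$mean, xout = time_h, rule = 2)$y
    }
  )
}

.cv_at <- function(kin, time_h) {
  if (kin$model != "anchors") return(rep(kin$cv, length(time_h)))
  a <- kin$anchors[[1]]
  cvs <- ifelse(!is.na(a$sem) & a$mean > 0, a$sem * sqrt(5) / a$mean, kin$cv)
  if (nrow(a) == 1) rep(cvs, length(time_h))
  else approx(a$time_h, cvs, xout = time_h, rule = 2)$y
}

.kin_row <- function(kin_tbl, compartment, element) {
  row <- kin_tbl[kin_tbl$compartment == compartment & kin_tbl$element == element, ]
  if (nrow(row) == 0) {
    abort(paste0("no kinetics for ", compartment, " / ", element))
  }
  row[1, ]
}

#' Cohort configuration for the pulse-chase generator
#'
#' Collects the study-design and biological parameters: group sizes, sampling
#' times, natural-abundance baselines, fish morphometry, mucus gravimetry,
#' label doses and the renewal perturbation. Defaults mirror the study design
#' the package emulates (n = 5 per group, sampling at 0/6/12/24 h); see
#' [preset_paper()] for the fully calibrated configuration.
#'
#' @param n_per_group Fish per compartment group and time point.
#' @param n_blank Blank (unlabelled) fish per compartment group.
#' @param time_points_h Sampling times (h), sorted, including 0.
#' @param baseline Tibble `compartment`, `element`, `delta0` of
#'   natural-abundance deltas (permil).
#' @param blank_sd_permil Named numeric `c(C = , N = )`: additive s.d. of the
#'   baseline delta noise.
#' @param elem_frac Tibble `compartment`, `frac_c`, `frac_n` of dry-sample
#'   elemental mass fractions; `frac_cv` their lognormal cv.
#' @param weight_mean_g,weight_cv Body-weight distribution.
#' @param mucus_ratio_mean,mucus_ratio_cv Collected mucus per body weight
#'   (mg/g) distribution.
#' @param area_mean_cm2,area_cv Mucus extraction area; areas scale
#'   allometrically as (bw / weight_mean)^(2/3).
#' @param dry_fraction_mean,dry_fraction_cv Dry mass fraction of collected
#'   (wet) mucus.
#' @param soluble_share_mean,soluble_share_sd Soluble dry mass as a share of
#'   recovered (soluble + insoluble) dry mass, in percent of raw dry mass
#'   terms; `loss_pct_mean`, `loss_pct_cv` the processing loss.
#' @param dose_c_per_g_meal,dose_n_per_g_meal,meal_fraction_bw Label dose.
#' @param tissue_per_bw Named overrides for [default_mass_model()]
#'   (the liver entry, the hepatosomatic index, is required for liver rows).
#' @param renewal List with `mass_reduction_factor`, `mass_cv` and a
#'   `kinetics` table of 24 h anchors for the renewal group.
#' @param frac_cv Lognormal cv of the elemental mass fractions.
#' @return A list of class `mt_cohort_config`.
#' @export
cohort_config <- function(n_per_group = 5,
                          n_blank = 5,
                          time_points_h = c(0, 6, 12, 24),
                          baseline,
                          blank_sd_permil = c(C = 0.9, N = 0.9),
                          elem_frac,
                          frac_cv = 0.05,
                          weight_mean_g = 186.1,
                          weight_cv = 0.20,
                          mucus_ratio_mean = 510 / 186.1,
                          mucus_ratio_cv = 0.095,
                          area_mean_cm2 = 70.8,
                          area_cv = 0.05,
                          dry_fraction_mean = 0.10,
                          dry_fraction_cv = 0.08,
                          soluble_share_mean = 82.4,
                          soluble_share_sd = 4.7,
                          loss_pct_mean = 2.3,
                          loss_pct_cv = 0.5,
                          dose_c_per_g_meal,
                          dose_n_per_g_meal,
                          meal_fraction_bw = 0.006,
                          tissue_per_bw = c(liver = 0.013),
                          renewal = NULL) {
  if (n_per_group < 2) abort("n_per_group must be at least 2.")
  time_points_h <- sort(unique(time_points_h))
  if (time_points_h[1] != 0) abort("time points must include 0.")
  structure(as.list(environment()), class = "mt_cohort_config")
}

#' Ingested dose implied by a cohort configuration
#'
#' @param cfg A [cohort_config()] object.
#' @return One-row dose tibble as from [ingested_dose()].
#' @export
config_dose <- function(cfg) {
  ingested_dose(cfg$weight_mean_g, cfg$dose_c_per_g_meal, cfg$dose_n_per_g_meal,
                meal_fraction_bw = cfg$meal_fraction_bw)
}

# Draw fish-level morphometry and mucus gravimetry for one group.
.draw_fish <- function(cfg, n, treatment, time_h, group_tag, with_mucus = TRUE,
                       with_partition = FALSE, mass_scale = 1, mass_cv = NULL) {
  bw <- rln_mean_cv(n, cfg$weight_mean_g, cfg$weight_cv)
  ratio <- rln_mean_cv(n, cfg$mucus_ratio_mean * mass_scale,
                       mass_cv %||% cfg$mucus_ratio_cv)
  collected <- if (with_mucus) bw * ratio else rep(NA_real_, n)
  area <- cfg$area_mean_cm2 * (bw / cfg$weight_mean_g)^(2 / 3) *
    rln_mean_cv(n, 1, cfg$area_cv)
  dryf <- rln_mean_cv(n, cfg$dry_fraction_mean, cfg$dry_fraction_cv)
  raw_dry <- collected * dryf
  sol_dry <- ins_dry <- rep(NA_real_, n)
  if (with_partition) {
    loss_pct <- rln_mean_cv(n, cfg$loss_pct_mean, cfg$loss_pct_cv)
    recovered_pct <- 100 - loss_pct
    share_mean <- cfg$soluble_share_mean / (100 - cfg$loss_pct_mean)
    share <- rnorm(n, share_mean, cfg$soluble_share_sd / (100 - cfg$loss_pct_mean))
    share <- pmin(pmax(share, 0.5), 1)
    sol_dry <- raw_dry * recovered_pct / 100 * share
    ins_dry <- raw_dry * recovered_pct / 100 * (1 - share)
  }
  tibble(
    fish_id = sprintf("%s_f%03d", group_tag, seq_len(n)),
    body_weight_g = bw,
    extraction_area_cm2 = if (with_mucus) area else NA_real_,
    collected_mucus_mg = collected,
    raw_dry_mg = raw_dry,
    soluble_dry_mg = sol_dry,
    insoluble_dry_mg = ins_dry,
    treatment = treatment,
    time_h = time_h
  )
}

# Draw per-sample delta values for one compartment group of fish.
.draw_samples <- function(cfg, kin_tbl, fish, compartment, time_h, enriched) {
  n <- nrow(fish)
  out <- tibble(
    sample_id = paste0(fish$fish_id, "_", compartment),
    fish_id = fish$fish_id,
    compartment = compartment,
    time_h = time_h,
    treatment = fish$treatment
  )
  ef <- cfg$elem_frac[cfg$elem_frac$compartment == compartment, ]
  if (nrow(ef) == 0) abort(paste0("no elemental fractions for ", compartment))
  for (el in c("C", "N")) {
    b <- cfg$baseline[cfg$baseline$compartment == compartment &
                        cfg$baseline$element == el, ]
    if (nrow(b) == 0) abort(paste0("no baseline delta for ", compartment, " / ", el))
    enr <- rep(0, n)
    if (enriched) {
      kin <- .kin_row(kin_tbl, compartment, el)
      mu <- mean_enrichment(kin, time_h)
      enr <- rln_mean_cv(n, rep(mu, n), .cv_at(kin, time_h))
    }
    delta <- b$delta0 + rnorm(n, 0, cfg$blank_sd_permil[[el]]) + enr
    out[[paste0("delta_", tolower(el), "_permil")]] <- delta
    out[[paste0("atpct_", tolower(el))]] <- NA_real_
    fr <- if (el == "C") ef$frac_c else ef$frac_n
    out[[paste0("frac_", tolower(el))]] <- rln_mean_cv(n, fr, cfg$frac_cv)
  }
  out$dry_mass_mg <- runif(n, 0.3, 0.6)
  out
}

.noiseless <- function(cfg) {
  cfg$weight_cv <- 0; cfg$mucus_ratio_cv <- 0; cfg$area_cv <- 0
  cfg$dry_fraction_cv <- 0; cfg$soluble_share_sd <- 0; cfg$loss_pct_cv <- 0
  cfg$frac_cv <- 0
  cfg$blank_sd_permil[] <- 0
  if (!is.null(cfg$renewal)) cfg$renewal$mass_cv <- 0
  cfg
}

.strip_kin_noise <- function(kin_tbl) {
  kin_tbl$cv <- 0
  kin_tbl$anchors <- lapply(kin_tbl$anchors, function(a) {
    if (!is.null(a)) a$sem <- 0
    a
  })
  kin_tbl
}

#' Simulate the time-course pulse-chase trial
#'
#' Generates blank (unlabelled) fish plus labelled fish at every sampling
#' time for each compartment with kinetics: raw-mucus fish, fraction fish
#' (one soluble and one insoluble sample per fish, with gravimetric
#' partition), and tissue fish. The same seed reproduces the output exactly.
#'
#' @param preset A list with elements `config` (a [cohort_config()]) and
#'   `kinetics` (a kinetics table), e.g. from [preset_paper()].
#' @param seed Integer master seed.
#' @param n Override for fish per group (default `config$n_per_group`).
#' @param noiseless If `TRUE`, all noise terms are switched off so group
#'   values equal the configured mean curves exactly.
#' @return A list with tibbles `samples` and `fish` in the CSV schemas of
#'   [read_samples()] / [read_fish()].
#' @export
simulate_timecourse <- function(preset, seed = 1L, n = NULL, noiseless = FALSE) {
  cfg <- preset$config
  kin_tbl <- preset$kinetics
  if (noiseless) {
    cfg <- .noiseless(cfg)
    kin_tbl <- .strip_kin_noise(kin_tbl)
  }
  n <- n %||% cfg$n_per_group
  set.seed(seed)
  mucus_cp <- intersect(c("total_mucus", "soluble_mucus", "insoluble_mucus"),
                        unique(kin_tbl$compartment))
  tissue_cp <- setdiff(unique(kin_tbl$compartment), mucus_cp)
  fish_all <- list(); samp_all <- list()
  emit <- function(fish, samples) {
    fish_all[[length(fish_all) + 1]] <<- fish
    samp_all[[length(samp_all) + 1]] <<- samples
  }

  gen_group <- function(treatment, time_h, nn, enriched) {
    tag0 <- sprintf("%s_t%02d", treatment, as.integer(time_h))
    if ("total_mucus" %in% mucus_cp) {
      f <- .draw_fish(cfg, nn, treatment, time_h, paste0(tag0, "_raw"))
      emit(f, .draw_samples(cfg, kin_tbl, f, "total_mucus", time_h, enriched))
    }
    if (any(c("soluble_mucus", "insoluble_mucus") %in% mucus_cp)) {
      f <- .draw_fish(cfg, nn, treatment, time_h, paste0(tag0, "_frc"),
                      with_partition = TRUE)
      s <- bind_rows(
        .draw_samples(cfg, kin_tbl, f, "soluble_mucus", time_h, enriched),
        .draw_samples(cfg, kin_tbl, f, "insoluble_mucus", time_h, enriched)
      )
      emit(f, s)
    }
    if (length(tissue_cp) > 0) {
      f <- .draw_fish(cfg, nn, treatment, time_h, paste0(tag0, "_tis"),
                      with_mucus = FALSE)
      s <- bind_rows(lapply(setdiff(tissue_cp, "diet"), function(cp) {
        .draw_samples(cfg, kin_tbl, f, cp, time_h, enriched)
      }))
      emit(f, s)
    }
  }

  # blanks: unlabelled-meal fish, sampled as 0 h
  gen_group("blank", 0, cfg$n_blank, enriched = FALSE)
  if ("diet" %in% cfg$baseline$compartment) {
    fd <- .draw_fish(cfg, 3, "blank", 0, "diet", with_mucus = FALSE)
    fd$body_weight_g <- NA_real_
    emit(fd, .draw_samples(cfg, kin_tbl, fd, "diet", 0, enriched = FALSE))
  }
  for (t in cfg$time_points_h) gen_group("timecourse", t, n, enriched = TRUE)

  list(samples = bind_rows(samp_all), fish = bind_rows(fish_all))
}

#' Simulate the mucus-renewal trial
#'
#' Control fish are a fresh draw from the 24 h time-course parameters;
#' renewal fish (mucus removed immediately before feeding) have their
#' collected mucus mass reduced by `renewal$mass_reduction_factor` and their
#' enrichment drawn from the renewal kinetics anchors. Blank fish are
#' included so the analysis can subtract natural abundance.
#'
#' @inheritParams simulate_timecourse
#' @return A list with tibbles `samples` and `fish`; treatments are
#'   `"control"`, `"renewal"` and `"blank"`.
#' @export
simulate_renewal <- function(preset, seed = 1L, n = NULL, noiseless = FALSE) {
  cfg <- preset$config
  if (is.null(cfg$renewal)) abort("configuration has no renewal block.")
  kin_ctrl <- preset$kinetics
  kin_renew <- cfg$renewal$kinetics
  if (noiseless) {
    cfg <- .noiseless(cfg)
    kin_ctrl <- .strip_kin_noise(kin_ctrl)
    kin_renew <- .strip_kin_noise(kin_renew)
  }
  n <- n %||% cfg$n_per_group
  set.seed(seed)
  mucus_cp <- intersect(c("total_mucus", "soluble_mucus", "insoluble_mucus"),
                        unique(kin_ctrl$compartment))
  fish_all <- list(); samp_all <- list()
  emit <- function(fish, samples) {
    fish_all[[length(fish_all) + 1]] <<- fish
    samp_all[[length(samp_all) + 1]] <<- samples
  }
  gen <- function(treatment, kin_tbl, mass_scale, mass_cv, enriched, nn) {
    tag0 <- sprintf("%s_t24", treatment)
    f <- .draw_fish(cfg, nn, treatment, 24, paste0(tag0, "_raw"),
                    mass_scale = mass_scale, mass_cv = mass_cv)
    emit(f, .draw_samples(cfg, kin_tbl, f, "total_mucus", 24, enriched))
    if (any(c("soluble_mucus", "insoluble_mucus") %in% mucus_cp)) {
      f <- .draw_fish(cfg, nn, treatment, 24, paste0(tag0, "_frc"),
                      with_partition = TRUE, mass_scale = mass_scale,
                      mass_cv = mass_cv)
      s <- bind_rows(
        .draw_samples(cfg, kin_tbl, f, "soluble_mucus", 24, enriched),
        .draw_samples(cfg, kin_tbl, f, "insoluble_mucus", 24, enriched)
      )
      emit(f, s)
    }
  }
  # blanks for baseline subtraction
  f <- .draw_fish(cfg, cfg$n_blank, "blank", 0, "blank_raw")
  emit(f, .draw_samples(cfg, kin_ctrl, f, "total_mucus", 0, enriched = FALSE))
  f <- .draw_fish(cfg, cfg$n_blank, "blank", 0, "blank_frc", with_partition = TRUE)
  emit(f, bind_rows(
    .draw_samples(cfg, kin_ctrl, f, "soluble_mucus", 0, enriched = FALSE),
    .draw_samples(cfg, kin_ctrl, f, "insoluble_mucus", 0, enriched = FALSE)
  ))
  gen("control", kin_ctrl, 1, cfg$mucus_ratio_cv, TRUE, n)
  gen("renewal", kin_renew, cfg$renewal$mass_reduction_factor,
      cfg$renewal$mass_cv, TRUE, n)
  list(samples = bind_rows(samp_all), fish = bind_rows(fish_all))
}
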