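# Percent-of-ingested-dose allocation and mucus-fraction bookkeeping.
#
# The allocation of tracer to a compartment is the chain of mass factors
#   100 * (g excess isotope / g fraction) * (g fraction / g tissue)
#       * (g tissue / g body weight) / (g ingested excess isotope / g b.w.)
# i.e. grams of excess heavy isotope recovered per 100 g ingested.

#' Ingested tracer dose per gram of body weight
#'
#' Builds a dose specification from the meal description. The meal mass
#' defaults to `meal_fraction_bw` of body weight (a single force-fed meal of
#' 0.6 % of body weight); the label specification gives grams of excess heavy
#' isotope per gram of meal for each element.
#'
#' @param body_weight_g Body weight in grams.
#' @param dose_c_per_g_meal,dose_n_per_g_meal Grams of excess \eqn{^{13}}C /
#'   \eqn{^{15}}N per gram of meal.
#' @param meal_mass_g Meal mass in grams; defaults to
#'   `meal_fraction_bw * body_weight_g`.
#' @param meal_fraction_bw Meal mass as a fraction of body weight
#'   (default 0.006).
#' @return A one-row tibble with `dose_c`, `dose_n` (g excess isotope per g
#'   body weight), `meal_mass_g`, `meal_fraction_bw`.
#' @examples
#' ingested_dose(200, dose_c_per_g_meal = 1e-3, dose_n_per_g_meal = 0,
#'               meal_mass_g = 1.2)
#' @export
ingested_dose <- function(body_weight_g, dose_c_per_g_meal, dose_n_per_g_meal,
                          meal_mass_g = NULL, meal_fraction_bw = 0.006) {
  if (body_weight_g <= 0) abort("body weight must be positive.")
  if (meal_fraction_bw <= 0 || meal_fraction_bw >= 0.05) {
    abort("meal_fraction_bw must lie in (0, 0.05).")
  }
  if (dose_c_per_g_meal < 0 || dose_n_per_g_meal < 0) {
    abort("label doses must be non-negative.")
  }
  meal_mass_g <- meal_mass_g %||% (meal_fraction_bw * body_weight_g)
  if (meal_mass_g <= 0) abort("meal mass must be positive.")
  tibble(
    dose_c = meal_mass_g * dose_c_per_g_meal / body_weight_g,
    dose_n = meal_mass_g * dose_n_per_g_meal / body_weight_g,
    meal_mass_g = meal_mass_g,
    meal_fraction_bw = meal_mass_g / body_weight_g
  )
}

#' Gravimetric partition of raw mucus into fractions
#'
#' Expresses the soluble (supernatant) and insoluble (pellet) dry masses as
#' percentages of the raw-mucus dry mass, plus the water content of the raw
#' mucus. Processing losses are allowed (percentages need not sum to 100),
#' but a soluble + insoluble dry mass exceeding the raw dry mass is an error.
#'
#' @param raw_dry_mg,soluble_dry_mg,insoluble_dry_mg Dry masses in mg.
#' @param wet_mg Wet (as-collected) mass in mg, or `NA` to skip water content.
#' @return A tibble with `soluble_pct`, `insoluble_pct`, `water_pct`.
#' @examples
#' fraction_partition(50, 41.2, 7.65, wet_mg = 500)
#' @export
fraction_partition <- function(raw_dry_mg, soluble_dry_mg, insoluble_dry_mg,
                               wet_mg = NA_real_) {
  if (any(c(raw_dry_mg, soluble_dry_mg, insoluble_dry_mg) < 0, na.rm = TRUE)) {
    abort("masses must be non-negative.")
  }
  if (any(raw_dry_mg <= 0)) abort("raw dry mass must be positive.")
  over <- soluble_dry_mg + insoluble_dry_mg > raw_dry_mg * (1 + 1e-9)
  if (any(over, na.rm = TRUE)) {
    abort("soluble + insoluble dry mass exceeds raw dry mass (inconsistent partition).")
  }
  if (any(!is.na(wet_mg) & raw_dry_mg > wet_mg)) {
    abort("dry mass cannot exceed wet mass.")
  }
  tibble(
    soluble_pct   = 100 * soluble_dry_mg / raw_dry_mg,
    insoluble_pct = 100 * insoluble_dry_mg / raw_dry_mg,
    water_pct     = ifelse(is.na(wet_mg), NA_real_, 100 * (wet_mg - raw_dry_mg) / wet_mg)
  )
}

#' Percent of ingested dose allocated to a compartment
#'
#' The allocation equation: grams of excess isotope per gram of (dry)
#' fraction, scaled by the fraction-per-tissue and tissue-per-body-weight
#' mass factors and divided by the ingested dose per gram of body weight,
#' times 100. Linear in every factor.
#'
#' @param excess_per_g Grams of excess heavy isotope per gram of dry fraction
#'   (from [excess_mass_per_gram()]).
#' @param fraction_per_tissue Grams of fraction per gram of tissue (1 for
#'   tissues analysed whole).
#' @param tissue_per_bw Grams of tissue per gram of body weight.
#' @param dose_per_g_bw Grams of ingested excess isotope per gram of body
#'   weight for the same element; must be positive.
#' @param element Element label used in error messages.
#' @return Percent of ingested dose (g isotope per 100 g ingested isotope).
#' @examples
#' allocation_percent(1e-3, 0.8, 0.002, 6.4e-6)  # 25 %
#' @export
allocation_percent <- function(excess_per_g, fraction_per_tissue,
                               tissue_per_bw, dose_per_g_bw,
                               element = "isotope") {
  if (any(dose_per_g_bw <= 0, na.rm = TRUE)) {
    abort(paste0("ingested dose for ", element,
                 " is zero or negative; allocation is undefined."))
  }
  100 * excess_per_g * fraction_per_tissue * tissue_per_bw / dose_per_g_bw
}

#' Default compartment mass model
#'
#' Mass factors `(g fraction / g tissue)` and `(g tissue / g body weight)` by
#' compartment. For mucus compartments `tissue_per_bw` is resolved per fish
#' from its own collected mucus mass over its own body weight, so the table
#' stores `NA` there; the `fraction_per_tissue` entries for mucus are dry-mass
#' fractions of the collected (wet) mucus and are likewise resolved per fish
#' when fish-level dry masses are available. White-muscle and plasma
#' tissue-per-body-weight default to literature-style values (0.45 and
#' 0.035 g/g) and should be overridden when better estimates exist; the liver
#' entry (hepatosomatic index) has no silent default and must be supplied.
#'
#' @param tissue_per_bw Named numeric overrides, e.g. `c(liver = 0.013)`.
#' @return A tibble with `compartment`, `fraction_per_tissue`, `tissue_per_bw`.
#' @export
default_mass_model <- function(tissue_per_bw = NULL) {
  mm <- tibble(
    compartment = c("total_mucus", "soluble_mucus", "insoluble_mucus",
                    "liver", "white_muscle", "plasma"),
    fraction_per_tissue = c(NA, NA, NA, 1, 1, 1),
    tissue_per_bw = c(NA, NA, NA, NA, 0.45, 0.035)
  )
  if (!is.null(tissue_per_bw)) {
    for (cp in names(tissue_per_bw)) {
      if (!cp %in% mm$compartment) abort(paste0("unknown compartment: ", cp))
      mm$tissue_per_bw[mm$compartment == cp] <- unname(tissue_per_bw[[cp]])
    }
  }
  mm
}

# Resolve per-sample mass factors by joining fish-level records.
# fish must carry body_weight_g, collected_mucus_mg and the per-fraction dry
# masses (raw_dry_mg, soluble_dry_mg, insoluble_dry_mg) for mucus fish.
.resolve_mass_factors <- function(long, fish, mass_model, blank_label = "blank") {
  long <- left_join(long, mass_model, by = "compartment")
  if (!is.null(fish) && "fish_id" %in% names(long)) {
    fish_cols <- intersect(
      c("fish_id", "body_weight_g", "collected_mucus_mg",
        "raw_dry_mg", "soluble_dry_mg", "insoluble_dry_mg"),
      names(fish)
    )
    long <- left_join(long, fish[fish_cols], by = "fish_id")
    mucus <- long$compartment %in% c("total_mucus", "soluble_mucus", "insoluble_mucus")
    tpb <- long$collected_mucus_mg / 1000 / long$body_weight_g
    long$tissue_per_bw <- ifelse(mucus & is.na(long$tissue_per_bw), tpb, long$tissue_per_bw)
    fpt <- dplyr::case_when(
      long$compartment == "total_mucus"     ~ long$raw_dry_mg / long$collected_mucus_mg,
      long$compartment == "soluble_mucus"   ~ long$soluble_dry_mg / long$collected_mucus_mg,
      long$compartment == "insoluble_mucus" ~ long$insoluble_dry_mg / long$collected_mucus_mg,
      TRUE ~ NA_real_
    )
    long$fraction_per_tissue <- ifelse(mucus & is.na(long$fraction_per_tissue),
                                       fpt, long$fraction_per_tissue)
  }
  # reference materials (e.g. diet) and blanks carry no allocation; only
  # labelled samples must have a resolvable mass model
  missing_mm <- long %>%
    dplyr::filter(.data$treatment != blank_label,
                  is.na(.data$tissue_per_bw) | is.na(.data$fraction_per_tissue)) %>%
    dplyr::distinct(.data$compartment)
  if (nrow(missing_mm) > 0) {
    abort(paste0("no mass model resolvable for compartment(s): ",
                 paste(missing_mm$compartment, collapse = ", "),
                 ". Supply tissue_per_bw (e.g. the hepatosomatic index for liver) ",
                 "or fish-level mucus masses."))
  }
  long
}

#' Per-sample enrichment, APE and allocation
#'
#' The core per-sample pipeline: converts deltas to atom percent, subtracts
#' the per-compartment blank baseline (giving both the per-mil enrichment
#' `delta - mean blank delta` and the APE in at.%), converts APE to grams of
#' excess isotope per gram of dry sample via the elemental mass fractions,
#' and applies the allocation equation with per-fish mucus mass factors.
#'
#' @param samples Sample tibble (see [read_samples()]).
#' @param fish Optional fish tibble (see [read_fish()]) used for per-fish
#'   mucus mass factors; required when mucus compartments are present and the
#'   mass model does not supply their factors.
#' @param dose One-row tibble from [ingested_dose()] (columns `dose_c`,
#'   `dose_n`).
#' @param mass_model Tibble from [default_mass_model()].
#' @param blank_label Treatment value marking blanks.
#' @param standards Standards table from [iso_standards()].
#' @return A tibble with one row per sample x element, carrying `enrichment_permil`,
#'   `ape`, `excess_per_g`, `percent_of_dose` and the resolved mass factors.
#' @export
sample_allocations <- function(samples, fish = NULL, dose,
                               mass_model = default_mass_model(),
                               blank_label = "blank",
                               standards = iso_standards()) {
  samples <- convert_isotopes(samples, standards)
  baseline <- blank_baseline(samples, blank_label, standards)
  long <- samples_long(samples)
  missing_blank <- setdiff(unique(paste(long$compartment, long$element)),
                           paste(baseline$compartment, baseline$element))
  if (length(missing_blank) > 0) {
    abort(paste0("no blank group for compartment/element: ",
                 paste(missing_blank, collapse = "; ")))
  }
  long <- left_join(long, baseline, by = c("compartment", "element"))
  long$enrichment_permil <- long$delta - long$blank_delta
  long$ape <- ape(long$atpct, long$blank_atpct, warn_negative = FALSE)
  std_m <- .std_row(long$element, standards)
  long$excess_per_g <- (long$ape / 100) * (long$elem_frac / std_m$m_mean) * std_m$m_heavy
  long <- .resolve_mass_factors(long, fish, mass_model, blank_label)
  dose_el <- ifelse(long$element == "C", dose$dose_c[1], dose$dose_n[1])
  zero_dose <- unique(long$element[dose_el <= 0])
  if (length(zero_dose) > 0) {
    abort(paste0("ingested dose is zero for element(s): ",
                 paste(zero_dose, collapse = ", ")))
  }
  long$percent_of_dose <- 100 * long$excess_per_g * long$fraction_per_tissue *
    long$tissue_per_bw / dose_el
  as_tibble(long)
}

.sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Group summary of enrichment and allocation over a time course
#'
#' Applies [sample_allocations()] and summarises labelled samples by
#' compartment, element and time point: group size, mean and s.e.m. of both
#' the blank-subtracted per-mil enrichment and the percent-of-dose
#' allocation. Blanks define the baseline and are excluded from the summary.
#'
#' @inheritParams sample_allocations
#' @return A tibble with columns `compartment`, `element`, `time_h`, `n`,
#'   `enrichment_mean`, `enrichment_sem`, `allocation_mean`, `allocation_sem`.
#' @export
timecourse_summary <- function(samples, fish = NULL, dose,
                               mass_model = default_mass_model(),
                               blank_label = "blank",
                               standards = iso_standards()) {
  per_sample <- sample_allocations(samples, fish, dose, mass_model,
                                   blank_label, standards)
  per_sample %>%
    dplyr::filter(.data$treatment != blank_label) %>%
    group_by(.data$compartment, .data$element, .data$time_h) %>%
    summarise(
      n = dplyr::n(),
      enrichment_mean = mean(.data$enrichment_permil, na.rm = TRUE),
      enrichment_sem  = .sem(.data$enrichment_permil),
      allocation_mean = mean(.data$percent_of_dose, na.rm = TRUE),
      allocation_sem  = .sem(.data$percent_of_dose),
      .groups = "drop"
    ) %>%
    arrange(.data$compartment, .data$element, .data$time_h)
}
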