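# CSV interfaces, validation and the two assembled analyses.

.sample_cols <- c("sample_id", "compartment", "time_h", "treatment",
                  "delta_c_permil", "delta_n_permil", "atpct_c", "atpct_n",
                  "frac_c", "frac_n", "dry_mass_mg")
.fish_cols <- c("fish_id", "body_weight_g", "extraction_area_cm2",
                "collected_mucus_mg", "treatment")

.validate_samples <- function(data) {
  miss <- setdiff(.sample_cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("sample table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad_row <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      abort(paste0(what, " in sample row(s): ",
                   paste(head(rows, 10), collapse = ", ")))
    }
  }
  bad_row(!is.na(data$delta_c_permil) & data$delta_c_permil <= -1000,
          "delta 13C at or below -1000 permil")
  bad_row(!is.na(data$delta_n_permil) & data$delta_n_permil <= -1000,
          "delta 15N at or below -1000 permil")
  for (col in c("frac_c", "frac_n")) {
    bad_row(!is.na(data[[col]]) & (data[[col]] < 0 | data[[col]] > 1),
            paste0(col, " outside [0, 1]"))
  }
  bad_row(!is.na(data$dry_mass_mg) & data$dry_mass_mg < 0, "negative dry mass")
  no_iso <- is.na(data$delta_c_permil) & is.na(data$atpct_c) &
    is.na(data$delta_n_permil) & is.na(data$atpct_n)
  bad_row(no_iso, "no isotope value (delta or at.%) for either element")
  invisible(data)
}

#' Read an EA-IRMS sample table
#'
#' Reads the sample CSV schema (one row per sample): `sample_id`,
#' `compartment`, `time_h`, `treatment`, `delta_c_permil`, `delta_n_permil`,
#' `atpct_c`, `atpct_n`, `frac_c`, `frac_n`, `dry_mass_mg`. Empty cells are
#' absent values; extra columns (e.g. `fish_id`) are preserved. Validation
#' is fail-fast with row numbers: deltas must exceed -1000 permil, elemental
#' fractions lie in [0, 1], and every row needs at least one isotope value.
#'
#' @param path Path to a CSV file (UTF-8, header row, decimal point).
#' @return A validated tibble.
#' @export
read_samples <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .validate_samples(as_tibble(data))
}

#' Read a fish-level table
#'
#' Schema: `fish_id`, `body_weight_g`, `extraction_area_cm2`,
#' `collected_mucus_mg`, `treatment`; optional dry-mass columns
#' (`raw_dry_mg`, `soluble_dry_mg`, `insoluble_dry_mg`) carry the gravimetric
#' partition when available.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_fish <- function(path) {
  data <- as_tibble(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  miss <- setdiff(.fish_cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("fish table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- which(!is.na(data$body_weight_g) & data$body_weight_g <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive body weight in fish row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  data
}

#' Read a run configuration file
#'
#' YAML key-value file with keys `dose_c_per_g_meal`, `dose_n_per_g_meal`,
#' `meal_fraction_bw`, `alpha` and an optional `tissue_per_bw` map.
#'
#' @param path Path to a YAML file.
#' @return A list with `dose` (one-row tibble), `alpha`, `tissue_per_bw`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("dose_c_per_g_meal", "dose_n_per_g_meal")) {
    if (is.null(cfg[[k]])) abort(paste0("config is missing key: ", k))
  }
  alpha <- cfg$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1).")
  list(
    dose = ingested_dose(
      body_weight_g = cfg$body_weight_g %||% 186.1,
      dose_c_per_g_meal = cfg$dose_c_per_g_meal,
      dose_n_per_g_meal = cfg$dose_n_per_g_meal,
      meal_fraction_bw = cfg$meal_fraction_bw %||% 0.006
    ),
    alpha = alpha,
    tissue_per_bw = unlist(cfg$tissue_per_bw)
  )
}

.write_table <- function(data, path) {
  num <- vapply(data, is.numeric, TRUE)
  data[num] <- lapply(data[num], signif, digits = 6)
  readr::write_csv(data, path, progress = FALSE)
}

#' Full time-course analysis
#'
#' Assembles the time-course trial: per-compartment enrichment and
#' allocation summaries, the homogeneity-gated time-course comparison with
#' compact letters per compartment and element, and the per-time-point
#' soluble-vs-insoluble Student's t contrasts (the "asterisks").
#'
#' @inheritParams timecourse_summary
#' @param alpha Significance level.
#' @param out_dir Optional directory; when given, writes
#'   `enrichment_summary.csv`, `allocation_summary.csv` and
#'   `tests_report.csv` (fixed column order, 6 significant digits, units in a
#'   units column).
#' @return A list with tibbles `summary`, `letters`, `fraction_contrasts`
#'   and `per_sample`.
#' @export
analyze_timecourse <- function(samples, fish = NULL, dose,
                               mass_model = default_mass_model(),
                               alpha = 0.05, blank_label = "blank",
                               standards = iso_standards(), out_dir = NULL) {
  per_sample <- sample_allocations(samples, fish, dose, mass_model,
                                   blank_label, standards)
  labelled <- dplyr::filter(per_sample, .data$treatment != blank_label)
  summary <- timecourse_summary(samples, fish, dose, mass_model,
                                blank_label, standards)

  letters_tbl <- labelled %>%
    dplyr::filter(!is.na(.data$enrichment_permil)) %>%
    group_by(.data$compartment, .data$element) %>%
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$time_h) < 2) return(tibble())
      cg <- compare_groups(
        tibble(value = d$enrichment_permil, group = paste0(d$time_h, " h")),
        value, group, alpha = alpha
      )
      mutate(cg$letters, method = cg$method,
             anova_p = cg$anova$p_value, levene_p = cg$levene$p_value)
    }) %>%
    ungroup()

  fraction_contrasts <- labelled %>%
    dplyr::filter(.data$compartment %in% c("soluble_mucus", "insoluble_mucus")) %>%
    group_by(.data$element, .data$time_h) %>%
    dplyr::group_modify(function(d, key) {
      a <- d$enrichment_permil[d$compartment == "soluble_mucus"]
      b <- d$enrichment_permil[d$compartment == "insoluble_mucus"]
      if (length(a) < 2 || length(b) < 2) return(tibble())
      tt <- student_t(a, b)
      tibble(soluble_mean = mean(a), insoluble_mean = mean(b),
             statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
             significant = tt$p_value < alpha)
    }) %>%
    ungroup()

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    enr <- summary %>%
      select("compartment", "element", "time_h", "n",
             mean = "enrichment_mean", sem = "enrichment_sem") %>%
      mutate(units = "permil")
    alc <- summary %>%
      select("compartment", "element", "time_h", "n",
             mean = "allocation_mean", sem = "allocation_sem") %>%
      mutate(units = "percent_of_dose")
    .write_table(enr, file.path(out_dir, "enrichment_summary.csv"))
    .write_table(alc, file.path(out_dir, "allocation_summary.csv"))
    tests <- bind_rows(
      letters_tbl %>%
        mutate(kind = "timecourse_letters") %>%
        rename(label = "group") %>%
        select("kind", "compartment", "element", "label", "n", "mean", "sem",
               "letters", "method", "levene_p", "anova_p"),
      fraction_contrasts %>%
        mutate(kind = "soluble_vs_insoluble",
               label = paste0(.data$time_h, " h")) %>%
        select("kind", "element", "label", "statistic", "df", "p_value",
               "significant")
    )
    .write_table(tests, file.path(out_dir, "tests_report.csv"))
  }

  list(summary = summary, letters = letters_tbl,
       fraction_contrasts = fraction_contrasts, per_sample = per_sample)
}

#' Renewal-trial analysis
#'
#' Mirrors the renewal-trial summary table: mucus exudation metrics
#' (collected mass, mass per area, mass per 100 g) and, per compartment and
#' element, the blank-subtracted enrichment and percent-of-dose allocation of
#' control vs renewal fish, each contrasted with Student's t-test.
#'
#' @inheritParams analyze_timecourse
#' @param control,renewal Treatment labels.
#' @return A tibble with one row per metric: control and renewal mean, sem
#'   and n, the renewal/control ratio, test statistic and p-value, and a
#'   `units` column.
#' @export
analyze_renewal <- function(samples, fish, dose,
                            mass_model = default_mass_model(),
                            alpha = 0.05, control = "control",
                            renewal = "renewal", blank_label = "blank",
                            standards = iso_standards(), out_dir = NULL) {
  for (g in c(control, renewal)) {
    if (!g %in% fish$treatment) abort(paste0("treatment group '", g, "' is absent."))
  }
  exu <- renewal_contrast(
    dplyr::filter(fish, .data$treatment %in% c(control, renewal)),
    control = control, renewal = renewal, alpha = alpha
  ) %>%
    mutate(units = dplyr::recode(.data$metric,
                                 collected_mucus_mg = "mg",
                                 mg_per_cm2 = "mg/cm2",
                                 mg_per_100g = "mg/100g"))

  per_sample <- sample_allocations(samples, fish, dose, mass_model,
                                   blank_label, standards)
  iso <- per_sample %>%
    dplyr::filter(.data$treatment %in% c(control, renewal)) %>%
    tidyr::pivot_longer(c("enrichment_permil", "percent_of_dose"),
                        names_to = "quantity", values_to = "value") %>%
    group_by(.data$compartment, .data$element, .data$quantity) %>%
    dplyr::group_modify(function(d, key) {
      a <- d$value[d$treatment == control]
      b <- d$value[d$treatment == renewal]
      if (length(a) < 2 || length(b) < 2) {
        abort("renewal analysis needs at least 2 fish per treatment and compartment.")
      }
      tt <- student_t(b, a)
      tibble(control_mean = mean(a), control_sem = .sem(a), n_control = length(a),
             renewal_mean = mean(b), renewal_sem = .sem(b), n_renewal = length(b),
             ratio = mean(b) / mean(a),
             statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
             significant = tt$p_value < alpha)
    }) %>%
    ungroup() %>%
    mutate(metric = paste(.data$compartment, .data$element, .data$quantity, sep = "_"),
           units = ifelse(.data$quantity == "enrichment_permil",
                          "permil", "percent_of_dose")) %>%
    select(-"compartment", -"element", -"quantity")

  out <- bind_rows(exu, iso)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_table(out, file.path(out_dir, "exudation_summary.csv"))
  }
  out
}
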