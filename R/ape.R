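# Atom percent excess and excess tracer mass.

#' Atom percent excess (APE)
#'
#' APE is the at.% of a labelled sample minus the natural-abundance (blank)
#' at.% of the same compartment: `APE = at.% sample - at.% blank`. Small
#' negative values can arise from measurement noise in unlabelled samples and
#' are preserved, not clipped; a warning is raised when any occur so they are
#' never silent.
#'
#' @param sample_atpct,blank_atpct Numeric vectors of atom percent values.
#' @param warn_negative Warn when the result is negative (default `TRUE`).
#' @return Numeric vector of APE values in percentage points.
#' @examples
#' ape(1.30, 1.10)  # 0.20 percentage points
#' @export
ape <- function(sample_atpct, blank_atpct, warn_negative = TRUE) {
  out <- sample_atpct - blank_atpct
  if (warn_negative && any(out < 0, na.rm = TRUE)) {
    warn("negative APE values present (measurement noise in unlabelled samples); reported as-is.")
  }
  out
}

#' Grams of excess heavy isotope per gram of dry sample
#'
#' Converts an APE value and the elemental mass fraction of the dry sample
#' into grams of excess heavy isotope per gram of sample:
#' \deqn{(APE/100) \times (f_{elem} / M_{mean}) \times M_{heavy}}
#' where \eqn{f_{elem}} is the elemental mass fraction (g C or N per g dry
#' sample), \eqn{M_{mean}} the conventional mean atomic mass of the element
#' (moles of element per gram) and \eqn{M_{heavy}} the heavy-isotope mass.
#' The result is linear in both APE and the elemental fraction.
#'
#' @param ape_value Numeric vector, atom percent excess (percentage points).
#' @param elem_frac Elemental mass fraction of the dry sample, in `[0, 1]`.
#' @param element `"C"` or `"N"`.
#' @param standards Standards table from [iso_standards()].
#' @return Grams of excess heavy isotope per gram of dry sample.
#' @examples
#' excess_mass_per_gram(1, 0.40, "C")   # 1 APE point in a 40 % C sample
#' @export
excess_mass_per_gram <- function(ape_value, elem_frac, element,
                                 standards = iso_standards()) {
  if (any(elem_frac < 0 | elem_frac > 1, na.rm = TRUE)) {
    abort("elemental mass fractions must lie in [0, 1].")
  }
  std <- .std_row(element, standards)
  (ape_value / 100) * (elem_frac / std$m_mean) * std$m_heavy
}

#' Natural-abundance blank baseline per compartment and element
#'
#' Averages the blank (unlabelled) samples of each compartment to give the
#' per-compartment, per-element natural-abundance baseline, both on the delta
#' scale and as atom percent. A global blank is never used: each compartment
#' is referenced to its own blank group.
#'
#' @param samples Sample tibble (see [read_samples()]); blanks are the rows
#'   with `treatment == blank_label`.
#' @param blank_label Treatment value marking blanks (default `"blank"`).
#' @param standards Standards table from [iso_standards()].
#' @return A tibble with one row per compartment x element: columns
#'   `compartment`, `element`, `n_blank`, `blank_delta`, `blank_atpct`.
#' @export
blank_baseline <- function(samples, blank_label = "blank",
                           standards = iso_standards()) {
  samples <- convert_isotopes(samples, standards)
  blanks <- dplyr::filter(samples, .data$treatment == blank_label)
  if (nrow(blanks) == 0) {
    abort(paste0("no blank samples found (treatment == '", blank_label, "')."))
  }
  long <- samples_long(blanks)
  long %>%
    group_by(.data$compartment, .data$element) %>%
    summarise(
      n_blank     = sum(!is.na(.data$atpct)),
      blank_delta = mean(.data$delta, na.rm = TRUE),
      blank_atpct = mean(.data$atpct, na.rm = TRUE),
      .groups = "drop"
    )
}

# Pivot a converted sample table to one row per sample x element, carrying
# delta, atom percent and the elemental mass fraction.
samples_long <- function(samples) {
  samples <- as_tibble(samples)
  base_cols <- intersect(
    c("sample_id", "fish_id", "compartment", "time_h", "treatment", "dry_mass_mg"),
    names(samples)
  )
  per_el <- function(el) {
    EL <- toupper(el)
    out <- samples[base_cols]
    out$element <- EL
    out$delta <- samples[[paste0("delta_", el, "_permil")]] %||% rep(NA_real_, nrow(samples))
    out$atpct <- samples[[paste0("atpct_", el)]] %||% rep(NA_real_, nrow(samples))
    out$elem_frac <- samples[[paste0("frac_", el)]] %||% rep(NA_real_, nrow(samples))
    out
  }
  bind_rows(per_el("c"), per_el("n")) %>%
    dplyr::filter(!is.na(.data$atpct) | !is.na(.data$delta))
}
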