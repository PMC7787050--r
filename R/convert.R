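# delta <-> ratio <-> atom percent conversions.
#
# All converters are vectorised over their first argument and recycle the
# element label. delta values are per-mil deviations from the element's
# standard ratio; atom percent counts heavy-isotope atoms per 100 atoms of
# the element.

#' Convert delta notation to an isotope ratio
#'
#' \eqn{R = R_{std} (1 + \delta / 1000)}. A delta of 0 returns the standard
#' ratio itself; values at or below -1000 would give a non-positive ratio and
#' are rejected.
#'
#' @param delta Numeric vector of delta values in per mil.
#' @param element `"C"` or `"N"` (recycled).
#' @param standards Standards table from [iso_standards()].
#' @return Numeric vector of heavy/light isotope ratios.
#' @examples
#' delta_to_ratio(0, "C")        # VPDB ratio
#' delta_to_ratio(-24.1, "C")    # a typical plant-based diet
#' @export
delta_to_ratio <- function(delta, element, standards = iso_standards()) {
  if (any(delta <= -1000, na.rm = TRUE)) {
    abort("delta values must exceed -1000 permil (ratio must stay positive).")
  }
  std <- .std_row(element, standards)
  std$r_std * (1 + delta / 1000)
}

#' Convert an isotope ratio back to delta notation
#'
#' Inverse of [delta_to_ratio()].
#'
#' @inheritParams delta_to_ratio
#' @param ratio Numeric vector of strictly positive heavy/light ratios.
#' @return Delta values in per mil.
#' @export
ratio_to_delta <- function(ratio, element, standards = iso_standards()) {
  if (any(ratio <= 0, na.rm = TRUE)) abort("isotope ratios must be positive.")
  std <- .std_row(element, standards)
  1000 * (ratio / std$r_std - 1)
}

#' Convert an isotope ratio to atom percent
#'
#' \eqn{at.\% = 100\, R / (1 + R)}: the heavy isotope as a percentage of all
#' atoms of the element.
#'
#' @param ratio Numeric vector of strictly positive heavy/light ratios.
#' @return Atom percent values in (0, 100).
#' @examples
#' ratio_to_atom_percent(1)  # 50 %
#' @export
ratio_to_atom_percent <- function(ratio) {
  if (any(ratio <= 0, na.rm = TRUE)) abort("isotope ratios must be positive.")
  100 * ratio / (1 + ratio)
}

#' Convert atom percent to an isotope ratio
#'
#' Inverse of [ratio_to_atom_percent()]; round-trips are exact to floating
#' point.
#'
#' @param atpct Numeric vector of atom percent values in (0, 100).
#' @return Heavy/light isotope ratios.
#' @export
atom_percent_to_ratio <- function(atpct) {
  if (any(atpct <= 0 | atpct >= 100, na.rm = TRUE)) {
    abort("atom percent must lie strictly between 0 and 100.")
  }
  atpct / (100 - atpct)
}

#' Convert delta notation directly to atom percent
#'
#' Composition of [delta_to_ratio()] and [ratio_to_atom_percent()];
#' strictly increasing in delta.
#'
#' @inheritParams delta_to_ratio
#' @return Atom percent values.
#' @examples
#' delta_to_atom_percent(0, "C")  # at.% of the VPDB standard
#' @export
delta_to_atom_percent <- function(delta, element, standards = iso_standards()) {
  ratio_to_atom_percent(delta_to_ratio(delta, element, standards))
}

#' Convert atom percent back to delta notation
#'
#' @inheritParams delta_to_ratio
#' @param atpct Numeric vector of atom percent values in (0, 100).
#' @return Delta values in per mil.
#' @export
atom_percent_to_delta <- function(atpct, element, standards = iso_standards()) {
  ratio_to_delta(atom_percent_to_ratio(atpct), element, standards)
}

#' Add ratio and atom-percent columns to a sample table
#'
#' Takes a sample table in the EA-IRMS CSV layout (see [read_samples()]) and
#' adds, for each element, the isotope ratio and atom percent derived from the
#' delta columns; rows that already carry measured `atpct_c`/`atpct_n` values
#' keep them. The operation is idempotent: re-running it on its own output
#' changes nothing.
#'
#' @param data A data frame with columns `delta_c_permil`, `delta_n_permil`
#'   and/or `atpct_c`, `atpct_n` (missing values allowed).
#' @param standards Standards table from [iso_standards()].
#' @return `data` as a tibble with columns `ratio_c`, `ratio_n`, `atpct_c`,
#'   `atpct_n` filled in where derivable.
#' @export
convert_isotopes <- function(data, standards = iso_standards()) {
  data <- as_tibble(data)
  for (el in c("c", "n")) {
    EL <- toupper(el)
    dcol <- paste0("delta_", el, "_permil")
    acol <- paste0("atpct_", el)
    rcol <- paste0("ratio_", el)
    dlt <- if (dcol %in% names(data)) data[[dcol]] else rep(NA_real_, nrow(data))
    atp <- if (acol %in% names(data)) data[[acol]] else rep(NA_real_, nrow(data))
    bad <- !is.na(dlt) & dlt <= -1000
    if (any(bad)) {
      abort(paste0("delta values <= -1000 permil in rows: ",
                   paste(head(which(bad), 5), collapse = ", ")))
    }
    from_delta <- !is.na(dlt)
    atp_new <- atp
    atp_new[is.na(atp) & from_delta] <-
      delta_to_atom_percent(dlt[is.na(atp) & from_delta], EL, standards)
    ratio <- rep(NA_real_, nrow(data))
    ok <- !is.na(atp_new)
    ratio[ok] <- atom_percent_to_ratio(atp_new[ok])
    fill_d <- is.na(dlt) & ok
    dlt[fill_d] <- atom_percent_to_delta(atp_new[fill_d], EL, standards)
    data[[acol]] <- atp_new
    data[[rcol]] <- ratio
    data[[dcol]] <- dlt
  }
  data
}
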