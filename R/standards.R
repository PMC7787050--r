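# International reference standards anchoring the delta scales.
#
# r_std values are the conventional heavy/light isotope abundance ratios of
# the international reference materials (VPDB for carbon, atmospheric N2 for
# nitrogen); atomic masses are the isotope masses in g/mol, m_mean the
# conventional mean atomic mass of the element used to count moles of element
# in a sample.

.standards <- tibble::tibble(
  element       = c("C", "N"),
  standard_name = c("VPDB", "AIR"),
  r_std         = c(0.0111802, 0.0036765),
  m_heavy       = c(13.00335, 15.00011),
  m_light       = c(12.00000, 14.00307),
  m_mean        = c(12.011, 14.007)
)

#' Isotope reference standards
#'
#' Returns the reference table anchoring the delta (\eqn{\delta}) scales:
#' VPDB for \eqn{^{13}}C/\eqn{^{12}}C and atmospheric N\eqn{_2} (AIR) for
#' \eqn{^{15}}N/\eqn{^{14}}N, together with isotope atomic masses and the
#' conventional mean atomic mass of each element.
#'
#' @param element Optional `"C"` or `"N"` to return a single-row table.
#' @param r_std Optional named numeric vector (names `"C"`/`"N"`) overriding
#'   the standard ratios for a run, e.g. `c(C = 0.011180, N = 0.0036765)`.
#'
#' @return A tibble with columns `element`, `standard_name`, `r_std`,
#'   `m_heavy`, `m_light`, `m_mean`.
#' @examples
#' iso_standards()
#' iso_standards("C")
#' @export
iso_standards <- function(element = NULL, r_std = NULL) {
  std <- .standards
  if (!is.null(r_std)) {
    if (is.null(names(r_std)) || !all(names(r_std) %in% std$element)) {
      abort("`r_std` overrides must be named with elements 'C' and/or 'N'.")
    }
    if (any(r_std <= 0)) abort("standard ratios must be strictly positive.")
    for (el in names(r_std)) std$r_std[std$element == el] <- unname(r_std[[el]])
  }
  if (!is.null(element)) {
    element <- match.arg(element, std$element)
    std <- std[std$element == element, ]
  }
  std
}

.std_row <- function(element, standards = iso_standards()) {
  i <- match(element, standards$element)
  if (anyNA(i)) {
    abort(paste0("unknown element(s): ",
                 paste(unique(element[is.na(i)]), collapse = ", "),
                 " (expected 'C' or 'N')"))
  }
  standards[i, ]
}
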