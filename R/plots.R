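# Summary figures built on ggplot2.

#' Plot a time-course summary
#'
#' Mean +/- s.e.m. of enrichment (permil) or allocation (percent of dose)
#' over the sampling times, one line per compartment, faceted by element.
#'
#' @param summary Tibble from [timecourse_summary()].
#' @param quantity `"enrichment"` or `"allocation"`.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(summary, quantity = c("enrichment", "allocation")) {
  quantity <- match.arg(quantity)
  mcol <- paste0(quantity, "_mean")
  scol <- paste0(quantity, "_sem")
  ylab <- if (quantity == "enrichment") "Enrichment (‰)" else "% of ingested dose"
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$time_h, y = .data[[mcol]], colour = .data$compartment
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data[[mcol]] - .data[[scol]],
      ymax = .data[[mcol]] + .data[[scol]]
    ), width = 0.5) +
    ggplot2::facet_wrap(~element, scales = "free_y") +
    ggplot2::labs(x = "Time post-feeding (h)", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a renewal-trial summary
#'
#' Control vs renewal group means with s.e.m. error bars, one panel per
#' metric, significant contrasts starred.
#'
#' @param contrast Tibble from [analyze_renewal()] or [renewal_contrast()].
#' @return A ggplot object.
#' @export
plot_renewal <- function(contrast) {
  long <- contrast %>%
    tidyr::pivot_longer(
      cols = c("control_mean", "renewal_mean"),
      names_to = "group", values_to = "mean"
    ) %>%
    mutate(
      group = sub("_mean$", "", .data$group),
      sem = ifelse(.data$group == "control", .data$control_sem, .data$renewal_sem),
      label = ifelse(.data$significant & .data$group == "renewal", "*", "")
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label,
                                    y = .data$mean + 2 * .data$sem)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_groups Plot group means with s.e.m. bars and compact
#'   letters.
#' @param object An `mt_comparison` object.
#' @method autoplot mt_comparison
#' @export
autoplot.mt_comparison <- function(object, ...) {
  d <- object$letters
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters,
                                    y = .data$mean + 2.5 * .data$sem)) +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = paste0(object$method, ", alpha = ", object$alpha)) +
    ggplot2::theme_minimal()
}
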