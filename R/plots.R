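#' Plot an all-image greenness series
#'
#' @param object A `roistats` tibble.
#' @param ... Unused.
#' @return A ggplot: per-image Gcc against date.
#' @export
autoplot.roistats <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$date, .data$gcc)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "Gcc",
                  title = sprintf("%s_%s_%s: all-image Gcc",
                                  attr(object, "sitename"),
                                  attr(object, "veg_type"),
                                  attr(object, "roi_id"))) +
    ggplot2::theme_minimal()
}

#' Plot a summary greenness product
#'
#' Shows the chosen Gcc statistic per window, flagged outliers, the
#' smoothed spline and its 1.96-sigma confidence ribbon.
#'
#' @param object A `pheno_summary` tibble.
#' @param statistic One of `"gcc_mean"`, `"gcc_50"`, `"gcc_75"`,
#'   `"gcc_90"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pheno_summary <- function(object, statistic = "gcc_90", ...) {
  stopifnot(statistic %in% GCC_SERIES)
  df <- tibble::tibble(
    date = object$date,
    value = object[[statistic]],
    smooth = object[[paste0("smooth_", statistic)]],
    ci = object[[paste0("smooth_ci_", statistic)]],
    flagged = factor(object[[paste0("outlierflag_", statistic)]],
                     levels = c(0, 1), labels = c("kept", "outlier")))
  ggplot2::ggplot(df, ggplot2::aes(.data$date)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$smooth - .data$ci,
                                      ymax = .data$smooth + .data$ci),
                         fill = "darkgreen", alpha = 0.15, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value,
                                     colour = .data$flagged),
                        size = 1, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), colour = "darkgreen",
                       na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(kept = "grey30",
                                            outlier = "red"),
                                 drop = FALSE, name = NULL) +
    ggplot2::labs(x = NULL, y = statistic,
                  title = sprintf("%d-day summary, %s", attr(object, "step"),
                                  attr(object, "sitename"))) +
    ggplot2::theme_minimal()
}

#' Plot extracted transition dates
#'
#' @param object A `pheno_transitions` tibble.
#' @param ... Unused.
#' @return A ggplot: transition dates with confidence-interval bars,
#'   one panel per Gcc statistic, rising stages in green and falling in
#'   red.
#' @export
autoplot.pheno_transitions <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, stage = dplyr::row_number()),
    cols = dplyr::all_of(c("transition_10", "transition_25",
                           "transition_50")),
    names_to = "threshold", values_to = "date")
  long$lower <- as.Date(NA)
  long$upper <- as.Date(NA)
  for (pct in c("10", "25", "50")) {
    sel <- long$threshold == paste0("transition_", pct)
    long$lower[sel] <- object[[paste0("transition_", pct, "_lower_ci")]]
    long$upper[sel] <- object[[paste0("transition_", pct, "_upper_ci")]]
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$threshold,
                                     colour = .data$direction)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper),
                            height = 0.2) +
    ggplot2::scale_colour_manual(values = c(rising = "darkgreen",
                                            falling = "firebrick")) +
    ggplot2::facet_wrap(~gcc_value) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Phenophase transition dates") +
    ggplot2::theme_minimal()
}
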