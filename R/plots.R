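# Basic visual checks: a night-trace panel (VO2 + temperatures with the
# night shaded) and a contrast plot. Unstyled by design.

#' Plot one nest-night: VO2 and temperature traces with the night shaded
#'
#' @param gas Gas-trace tibble for the night (optional).
#' @param nest,ambient Temperature-trace tibbles (optional).
#' @param sun One row of [sun_times()] output; used to shade
#'   sunset-to-sunrise.
#' @param events Optional drop events to mark (vertical lines at start and
#'   end).
#' @return A ggplot object.
#' @export
plot_night_trace <- function(gas = NULL, nest = NULL, ambient = NULL,
                             sun = NULL, events = NULL) {
  parts <- list()
  if (!is.null(gas)) {
    parts$vo2 <- tibble::tibble(timestamp = gas$timestamp, value = gas$vo2,
                                panel = "VO2 (ml/min)")
  }
  if (!is.null(nest)) {
    parts$nest <- tibble::tibble(timestamp = nest$timestamp,
                                 value = nest$temp_c, panel = "temperature (C)",
                                 series = "T_nest")
  }
  if (!is.null(ambient)) {
    parts$amb <- tibble::tibble(timestamp = ambient$timestamp,
                                value = ambient$temp_c,
                                panel = "temperature (C)", series = "T_a")
  }
  df <- dplyr::bind_rows(parts)
  if (nrow(df) == 0L) stop_invalid("Nothing to plot.")
  if (!"series" %in% names(df)) df$series <- "VO2"
  df$series[is.na(df$series)] <- "VO2"
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$timestamp, .data$value,
                                        colour = .data$series))
  if (!is.null(sun)) {
    p <- p + ggplot2::annotate("rect",
                               xmin = sun$sunset[1], xmax = sun$next_sunrise[1],
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p <- p + ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL)
  if (!is.null(events) && nrow(events) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = events$start_time, linetype = 2) +
      ggplot2::geom_vline(xintercept = events$end_time, linetype = 3)
  }
  p
}

#' @describeIn contrast_ambient Group means and confidence intervals per
#'   response.
#' @param object A `torpr_contrast`.
#' @method autoplot torpr_contrast
#' @export
autoplot.torpr_contrast <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$group, .data$mean,
                               ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "ambient temperature (C)")
}
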