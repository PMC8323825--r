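#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_errorbar
#'   geom_smooth labs facet_wrap theme_minimal geom_vline
#' @export
ggplot2::autoplot

#' Plot a force profile
#'
#' Force (and optionally dimpling) against insertion time, with contact and
#' retraction marked and any detected rupture point highlighted.
#'
#' @param object A `force_profile` from [convert_trace()].
#' @param channels Channels to draw.
#' @param mark_rupture Run [detect_rupture()] and mark the event.
#' @param ... Passed to [detect_rupture()].
#' @return A ggplot object.
#' @method autoplot force_profile
#' @export
autoplot.force_profile <- function(object,
                                   channels = c("force_mn", "dimpling_mm"),
                                   mark_rupture = TRUE, ...) {
  dt <- attr(object, "sample_period") %||% 0.002
  long <- object |>
    select("time_s", dplyr::all_of(channels)) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "value")
  p <- ggplot(long, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~ .data$channel, scales = "free_y", ncol = 1) +
    labs(x = "time (s)", y = NULL, title = "Insertion profile") +
    theme_minimal()
  start <- attr(object, "start_index")
  retract <- attr(object, "retraction_index")
  if (!is.null(start)) {
    p <- p + geom_vline(xintercept = object$time_s[start],
                        linetype = "dotted", colour = "grey40")
  }
  if (!is.null(retract)) {
    p <- p + geom_vline(xintercept = object$time_s[retract],
                        linetype = "dashed", colour = "grey40")
  }
  if (mark_rupture) {
    ev <- detect_rupture(object, ...)
    if (nrow(ev) == 1 && "force_mn" %in% channels) {
      p <- p + geom_point(
        data = tibble(time_s = ev$time_s, value = ev$rupture_force_mn,
                      channel = "force_mn"),
        colour = "red", size = 2)
    }
  }
  p
}

#' Plot a diameter-linearity fit
#'
#' Condition means with standard-error bars against microwire diameter,
#' with the fitted line -- the standard summary figure of the insertion
#' study.
#'
#' @param object A `diameter_fit` from [diameter_linearity_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diameter_fit
#' @export
autoplot.diameter_fit <- function(object, ...) {
  ggplot(object$means,
         aes(x = .data$diameter_um, y = .data$mean_response,
             colour = .data$tip, shape = .data$material)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$mean_response - .data$se_response,
                      ymax = .data$mean_response + .data$se_response),
                  width = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "grey30") +
    labs(x = "microwire diameter (um)",
         y = object$response,
         title = sprintf("%s vs diameter (%s), R^2 = %.3f",
                         object$response, object$membrane, object$r_squared)) +
    theme_minimal()
}

#' Plot per-condition study summaries
#'
#' Mean rupture force and dimpling depth by condition for a whole study
#' table, faceted by membrane.
#'
#' @param table A study table.
#' @param response `"rupture_force_mn"` or `"dimpling_mm"`.
#' @return A ggplot object.
#' @export
plot_study_summary <- function(table, response = c("rupture_force_mn", "dimpling_mm")) {
  response <- match.arg(response)
  cond <- table |>
    filter(.data$outcome == "penetrated") |>
    group_by(.data$membrane, .data$material, .data$tip, .data$diameter_um) |>
    summarise(m = mean(.data[[response]]),
              se = stats::sd(.data[[response]]) / sqrt(n()),
              .groups = "drop")
  ggplot(cond, aes(x = .data$diameter_um, y = .data$m,
                   colour = .data$tip, shape = .data$material)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se),
                  width = 2) +
    facet_wrap(~ .data$membrane, scales = "free_y") +
    labs(x = "microwire diameter (um)", y = response) +
    theme_minimal()
}
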