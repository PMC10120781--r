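# ggplot2 display methods for the result objects

km_step_data <- function(curve) {
  tab <- curve$table
  # prepend t = 0, S = 1 so the step starts at full survival
  tibble(time = c(0, tab$time), survival = c(1, tab$survival))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier curve
#'
#' Step curve with censor tick marks.
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  dat <- km_step_data(object)
  cens <- tibble(time = object$censor_times,
                 survival = km_survival_at(object, object$censor_times))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3, size = 1.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves for the ratio groups
#'
#' @param curves Named list of `km_curve` objects (e.g. the `curves`
#'   list-column entry of [survival_by_group()] output).
#' @param title Optional plot title.
#' @return A ggplot with one colored step per group and censor ticks.
#' @export
plot_km_groups <- function(curves, title = NULL) {
  steps <- imap(curves, function(cv, g) {
    dplyr::mutate(km_step_data(cv), group = g)
  })
  cens <- imap(curves, function(cv, g) {
    tibble(time = cv$censor_times,
           survival = km_survival_at(cv, cv$censor_times), group = g)
  })
  ggplot2::ggplot(list_rbind(steps),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = list_rbind(cens), shape = 3, size = 1.2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability",
                  color = "Group", title = title) +
    ggplot2::theme_minimal()
}

#' Plot a fiber orientation histogram
#'
#' @param hist Output of [orientation_histogram()].
#' @return A ggplot bar chart over \[-90, 90) degrees with the mode marked.
#' @export
plot_orientation_histogram <- function(hist) {
  ggplot2::ggplot(hist$histogram,
                  ggplot2::aes(x = .data$bin_center, y = .data$weight)) +
    ggplot2::geom_col(width = diff(hist$histogram$bin_center[1:2]) * 0.9) +
    ggplot2::geom_vline(xintercept = hist$mode_deg, linetype = "dashed") +
    ggplot2::labs(x = "Orientation (degrees)", y = "Energy weight") +
    ggplot2::theme_minimal()
}
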