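#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a univariate profile likelihood
#'
#' Normalized profile loglikelihood against the interest parameter, with the
#' likelihood-ratio threshold (dashed) and the MLE (vertical line). Values
#' below `floor` are clipped for readability.
#'
#' @param object A `profile_curve`.
#' @param floor Lower display limit (default -10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot profile_curve
#' @export
autoplot.profile_curve <- function(object, floor = -10, ...) {
  df <- object$profile
  df$value <- pmax(df$value, floor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$psi, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "red") +
    ggplot2::geom_vline(xintercept = object$mle[[object$interest]],
                        colour = "darkgreen") +
    ggplot2::labs(x = object$interest, y = "normalized profile loglikelihood") +
    ggplot2::coord_cartesian(ylim = c(floor, 0)) +
    ggplot2::theme_minimal()
}

#' Plot a bivariate profile likelihood
#'
#' Filled surface of the normalized bivariate profile with the threshold
#' contour and the MLE.
#'
#' @param object A `profile_surface`.
#' @param floor Lower display limit (default -10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot profile_surface
#' @export
autoplot.profile_surface <- function(object, floor = -10, ...) {
  df <- object$profile
  df$value <- pmax(df$value, floor)
  i1 <- object$interest[1]; i2 <- object$interest[2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[i1]], y = .data[[i2]])) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$value),
                          breaks = object$threshold, colour = "red") +
    ggplot2::annotate("point", x = object$mle[[i1]], y = object$mle[[i2]],
                      colour = "cyan", size = 2) +
    ggplot2::scale_fill_viridis_c(limits = c(floor, 0)) +
    ggplot2::labs(x = i1, y = i2, fill = "profile\nloglik") +
    ggplot2::theme_minimal()
}

#' Plot a prediction envelope
#'
#' Curvewise envelope as a ribbon with the MLE trajectory, optionally with
#' observations overlaid.
#'
#' @param object A `prediction_envelope`.
#' @param data Optional data frame with `time` and `observation` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prediction_envelope
#' @export
autoplot.prediction_envelope <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot(as.data.frame(object), ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "goldenrod", alpha = 0.5) +
    ggplot2::labs(x = "time (days)", y = "density",
                  subtitle = paste0("source: ", attr(object, "source"))) +
    ggplot2::theme_minimal()
  if (!all(is.na(object$mle))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$mle), colour = "cyan4")
  }
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = as.data.frame(data),
                                 ggplot2::aes(x = .data$time,
                                              y = .data$observation),
                                 colour = "darkorange")
  }
  p
}

#' Plot a fitted growth model
#'
#' Observations with the fitted mean trajectory.
#'
#' @param object A `growth_fit`.
#' @param times Prediction times (default: 201 points over the observation
#'   window).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- default_time_grid(object$data)
  curve <- predict(object, times)
  ggplot2::ggplot() +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$time, y = .data$density),
                       colour = "#2c7fb8") +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(x = .data$time, y = .data$observation),
                        colour = "darkorange") +
    ggplot2::labs(x = "time (days)", y = "density") +
    ggplot2::theme_minimal()
}

#' @export
plot.profile_curve <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.profile_surface <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.prediction_envelope <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.growth_fit <- function(x, ...) print(autoplot(x, ...))
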