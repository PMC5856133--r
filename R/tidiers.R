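#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns one row per term/coefficient,
#' `glance()` a one-row model summary.
#'
#' @param x a fitted or structured object from this package.
#' @param ... unused.
#' @return A tibble.
#' @name nanofield-tidiers
NULL

#' @rdname nanofield-tidiers
#' @export
tidy.discrete_tf <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname nanofield-tidiers
#' @export
glance.discrete_tf <- function(x, ...) {
  pz <- tf_poles_zeros(x)
  tibble::tibble(dc_gain = tf_dc_gain(x), Ts = x$Ts,
                 n_poles = length(pz$poles), n_zeros = length(pz$zeros),
                 stable = pz$stable)
}

#' @rdname nanofield-tidiers
#' @export
tidy.identification_result <- function(x, ...) tidy(x$model)

#' @rdname nanofield-tidiers
#' @export
glance.identification_result <- function(x, ...) {
  tibble::tibble(fit_percent = x$fit_percent, mse = x$mse,
                 n_samples = x$n_samples, converged = x$converged,
                 restarts_used = x$restarts_used,
                 stable = tf_poles_zeros(x$model)$stable)
}

#' @rdname nanofield-tidiers
#' @export
tidy.slope_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(suppressWarnings(summary(x$fit))$coefficients[1, 2],
                               x$stderr))
}

#' @rdname nanofield-tidiers
#' @export
glance.slope_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 stderr = x$stderr, r.squared = x$r2)
}

#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects: force and work versus
#' depth for traces and work curves, Bode magnitude/phase for frequency
#' responses, and the admissible (field, gradient) band for regions.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot.
#' @name nanofield-plots
NULL

#' @rdname nanofield-plots
#' @export
autoplot.force_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth, y = .data$force)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "penetration depth (Å)",
                  y = "pulling force (kcal/mol/Å)",
                  title = sprintf("v = %g Å/ps", attr(object, "velocity")))
}

#' @rdname nanofield-plots
#' @export
autoplot.work_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth, y = .data$work)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "penetration depth (Å)",
                  y = "work of penetration (kcal/mol)")
}

#' @rdname nanofield-plots
#' @export
autoplot.frequency_response <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("magnitude_db", "phase_deg"),
                              names_to = "panel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frequency, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL)
}

#' @rdname nanofield-plots
#' @export
autoplot.field_region <- function(object, ...) {
  if (object$empty) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "empty region") +
             ggplot2::labs(x = "b_z (T)", y = "db_z/dz (T/m)"))
  }
  ggplot2::ggplot(object$boundary, ggplot2::aes(x = .data$b, y = .data$g)) +
    ggplot2::geom_polygon(alpha = 0.4) +
    ggplot2::coord_cartesian(xlim = c(0, object$b_max),
                             ylim = c(0, object$g_max)) +
    ggplot2::labs(x = "b_z (T)", y = "db_z/dz (T/m)")
}
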