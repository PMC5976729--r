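#' Plot a trace
#'
#' @param object a [field_trace()] or [phase_trace()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.field_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ps, .data$field / 1e5)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "delay (ps)", y = "field (kV/cm)")
}

#' @rdname autoplot.field_trace
#' @export
autoplot.phase_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_ps, .data$phase_mrad)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "delay (ps)", y = expression(Delta * phi ~ "(mrad)"))
  if ("sigma_mrad" %in% names(object))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$phase_mrad - .data$sigma_mrad,
                   ymax = .data$phase_mrad + .data$sigma_mrad),
      alpha = 0.2)
  p
}

#' Plot a Kerr fit: data, total model, and components
#'
#' @param object a `kerr_fit`.
#' @param ... unused.
#' @return A ggplot overlaying the measured trace with the fitted total,
#'   electronic and molecular contributions.
#' @export
autoplot.kerr_fit <- function(object, ...) {
  comp <- tibble::tibble(
    time_ps = rep(object$fitted$time_ps, 3),
    phase_mrad = c(object$fitted$phase_mrad, object$fitted$electronic_mrad,
                   object$fitted$molecular_mrad),
    component = rep(c("total model", "electronic", "molecular"),
                    each = nrow(object$fitted)))
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = object$data,
      ggplot2::aes(.data$time_ps, .data$phase_mrad), size = 0.4,
      alpha = 0.4) +
    ggplot2::geom_line(
      data = comp,
      ggplot2::aes(.data$time_ps, .data$phase_mrad,
                   colour = .data$component)) +
    ggplot2::labs(x = "delay (ps)", y = expression(Delta * phi ~ "(mrad)"),
                  colour = NULL)
}

#' @rdname autoplot.field_trace
#' @export
autoplot.rotor_observables <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[c("time_ps", "mean_cos", "mean_cos2_excess")],
    -"time_ps", names_to = "observable")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ps, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ps)", y = NULL)
}
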