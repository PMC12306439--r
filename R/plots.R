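# ggplot2 views of the analysis outputs. Figures are derived artifacts;
# nothing downstream reads them back.

#' Plot a colony size series
#'
#' Mean cell area with a standard-error band and, on a free second panel, the
#' cell count; light phases are shaded.
#'
#' @param object output of [compute_size_series()].
#' @param schedule optional [light_schedule()] used to shade light phases.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot size_series
#' @export
autoplot.size_series <- function(object, schedule = NULL, ...) {
  long <- object |>
    tidyr::pivot_longer(c("mean_area", "n_cells"), names_to = "panel") |>
    mutate(panel = dplyr::recode(.data$panel, mean_area = "mean area (um2)",
                                 n_cells = "cell count"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$value,
                                          colour = .data$colony_id))
  if (!is.null(schedule)) {
    shade <- light_phases(schedule, range(object$time_h))
    p <- p + ggplot2::geom_rect(
      data = shade, ggplot2::aes(xmin = .data$on, xmax = .data$off,
                                 ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "gold", alpha = 0.15)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL, colour = "colony") +
    ggplot2::theme_minimal()
}

light_phases <- function(schedule, t_range) {
  k <- floor((t_range[1] - schedule$phase_offset_h) / schedule$period_h)
  ons <- schedule$phase_offset_h + seq(k, k + ceiling(diff(t_range) / schedule$period_h) + 1) *
    schedule$period_h
  tibble::tibble(on = pmax(ons, t_range[1]),
                 off = pmin(ons + schedule$light_h, t_range[2])) |>
    filter(.data$off > .data$on)
}

#' Plot a radial kymograph
#'
#' Heatmap of mean cell area over time and radial position.
#'
#' @param object a `kymograph` from [radial_kymograph()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, ...) {
  ref <- attr(object, "reference")
  ggplot2::ggplot(object, ggplot2::aes(.data$time_h, (.data$r_lo + .data$r_hi) / 2,
                                       fill = .data$mean_area)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~colony_id) +
    ggplot2::scale_fill_viridis_c(name = "mean area (um2)") +
    ggplot2::labs(x = "time (h)",
                  y = sprintf("distance from colony %s (um)", ref)) +
    ggplot2::theme_minimal()
}

#' Plot a binned mitotic-percentage curve
#'
#' @param object a `binned_stat` from [mitotic_percentage()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot binned_stat
#' @export
autoplot.binned_stat <- function(object, ...) {
  xlab <- switch(attr(object, "binning"),
                 size = "cell area (um2)",
                 radial = sprintf("distance from colony %s (um)",
                                  attr(object, "reference")),
                 "all cells")
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_mid, .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$se,
                                      ymax = .data$value + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "mitotic percentage (%)") +
    ggplot2::theme_minimal()
}

#' Plot a breakpoint fit
#'
#' @param object a `breakpoint_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot breakpoint_fit
#' @export
autoplot.breakpoint_fit <- function(object, ...) {
  d <- object$data
  xs <- seq(min(d$x), max(d$x), length.out = 200)
  pred <- object$intercept + object$slope_below * pmin(xs, object$breakpoint) +
    object$slope_above * pmax(xs - object$breakpoint, 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = tibble::tibble(x = xs, y = pred),
                       colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$breakpoint, linetype = 2) +
    ggplot2::labs(x = "cell size", y = "mitotic percentage (%)") +
    ggplot2::theme_minimal()
}

#' Plot a sizer fit
#'
#' Binned mean observed round count (+/- SEM) against the fitted
#' threshold-model staircase.
#'
#' @param object a `sizer_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot sizer_fit
#' @export
autoplot.sizer_fit <- function(object, ...) {
  b <- object$binned
  xs <- exp(seq(log(min(object$events$size)), log(max(object$events$size)),
                length.out = 400))
  stair <- tibble::tibble(x = xs,
                          y = predict_division_number(xs, object$params)$n)
  ggplot2::ggplot(b, ggplot2::aes(.data$size_mid, .data$mean_n)) +
    ggplot2::geom_step(data = stair, ggplot2::aes(.data$x, .data$y),
                       colour = "firebrick") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_n - .data$sem_n,
                                          ymax = .data$mean_n + .data$sem_n)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = sprintf("mother size (%s)",
                              if (object$params$mode == "area") "um2" else "um3"),
                  y = "fission rounds n") +
    ggplot2::theme_minimal()
}
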