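# Size-control model layer: ellipsoid volume extrapolation, the
# threshold-form mitotic sizer (prediction and data-driven fitting), and
# commitment-breakpoint estimation by continuous segmented regression.

#' Mitotic-sizer parameters
#'
#' The sizer maps a mother's size at division to a fission round count
#' `n = clamp(ceil(log2(size / div_target)), n_min, n_max)`, producing 2^n
#' uniformly sized daughters. Works in area (um^2) or volume (um^3) mode; the
#' mode is explicit in every output.
#'
#' @param div_target division size target (denominator of the sizer), um^2 or
#'   um^3 depending on `mode`.
#' @param n_min,n_max clipping bounds on the round count.
#' @param mode `"area"` or `"volume"`.
#' @return An object of class `sizer_params`.
#' @export
sizer_params <- function(div_target = 35, n_min = 1L, n_max = 5L,
                         mode = c("area", "volume")) {
  mode <- match.arg(mode)
  stopifnot(div_target > 0, n_min >= 1, n_min <= n_max)
  structure(list(div_target = div_target, n_min = as.integer(n_min),
                 n_max = as.integer(n_max), mode = mode),
            class = "sizer_params")
}

#' Ellipsoid volume from cross-sectional area and minor axis
#'
#' Cells are approximated as ellipsoids whose projected ellipse has the
#' measured area `A = pi a b` and whose z semi-axis is half the minor-axis
#' length: `V = (4/3) pi a b (minor/2) = (2/3) A minor`. When the minor axis
#' equals the equivalent diameter this reduces to the sphere volume.
#'
#' @param area_um2 cross-sectional area, um^2 (> 0).
#' @param minor_axis_um minor-axis length, um (> 0).
#' @return Volume in um^3.
#' @export
estimate_volume <- function(area_um2, minor_axis_um) {
  if (any(area_um2 <= 0) || any(minor_axis_um <= 0)) {
    stop("estimate_volume requires positive area and minor axis")
  }
  (2 / 3) * area_um2 * minor_axis_um
}

#' Predict the number of fission rounds from mother size
#'
#' `n = clamp(ceil(log2(size / div_target)), n_min, n_max)`; the daughter
#' count is 2^n. Nondecreasing and piecewise constant in size, with jumps at
#' `div_target * 2^k`.
#'
#' @param size mother size (same units/mode as `params`), > 0.
#' @param params a [sizer_params()].
#' @return Tibble: `size`, `n`, `n_daughters`.
#' @export
predict_division_number <- function(size, params = sizer_params()) {
  stopifnot(all(size > 0))
  n <- as.integer(clamp(ceiling(log2(size / params$div_target)),
                        params$n_min, params$n_max))
  tibble::tibble(size = size, n = n, n_daughters = 2L^n)
}

#' Fit the mitotic-sizer threshold to observed division events
#'
#' Chooses `div_target` minimising the sum of squared differences between
#' observed and predicted round counts over a log-spaced grid. Because the
#' objective is piecewise constant in the threshold, all equally optimal grid
#' points are reported as an interval; the point estimate is the geometric
#' midpoint. Also returns binned mean observed n (+/- SEM) with the model
#' curve for plotting.
#'
#' @param events tibble with columns `size` (mother area or volume) and `n`
#'   (observed round count); >= 5 events. A degenerate fit (all events share
#'   one n) is flagged.
#' @param params template [sizer_params()] supplying the clipping bounds and
#'   mode.
#' @param grid threshold grid; default 200 log-spaced points spanning
#'   `[min(size)/2, max(size)]`, augmented with the objective's exact knot
#'   points `size / 2^k` (the SSE is piecewise constant between those knots,
#'   so including them makes the grid search exact).
#' @param n_bins size bins for the observed-vs-predicted table.
#' @return Object of class `sizer_fit`: `params` (with fitted `div_target`),
#'   `interval` (equally optimal threshold range), `sse`, `degenerate` flag,
#'   `binned` tibble, `events`. Supports `tidy()`/`glance()`.
#' @export
fit_sizer <- function(events, params = sizer_params(), grid = NULL,
                      n_bins = 8) {
  stopifnot(all(c("size", "n") %in% names(events)))
  if (nrow(events) < 5) stop("fit_sizer needs at least 5 events")
  degenerate <- length(unique(events$n)) < 2
  if (is.null(grid)) {
    grid <- exp(seq(log(min(events$size) / 2), log(max(events$size)),
                    length.out = 200))
    knots <- outer(events$size, 2^seq_len(params$n_max), `/`)
    grid <- sort(unique(c(grid, knots[knots >= min(grid) & knots <= max(grid)])))
  }
  sse <- vapply(grid, function(thr) {
    p <- sizer_params(thr, params$n_min, params$n_max, params$mode)
    sum((events$n - predict_division_number(events$size, p)$n)^2)
  }, numeric(1))
  best <- which(sse == min(sse))
  interval <- range(grid[best])
  div_target <- exp(mean(log(interval)))
  fitted_params <- sizer_params(div_target, params$n_min, params$n_max,
                                params$mode)
  brk <- quantile(events$size, probs = seq(0, 1, length.out = n_bins + 1),
                  type = 7, names = FALSE)
  brk <- unique(brk)
  binned <- events |>
    mutate(bin = cut(.data$size, breaks = brk, include.lowest = TRUE)) |>
    group_by(.data$bin) |>
    summarise(
      size_mid = mean(.data$size),
      mean_n = mean(.data$n),
      sem_n = if (dplyr::n() > 1) sd(.data$n) / sqrt(dplyr::n()) else 0,
      n_events = dplyr::n(), .groups = "drop"
    ) |>
    mutate(pred_n = predict_division_number(.data$size_mid, fitted_params)$n)
  structure(
    list(params = fitted_params, interval = interval, sse = min(sse),
         degenerate = degenerate, binned = binned, events = events,
         grid = grid),
    class = "sizer_fit"
  )
}

#' @export
print.sizer_fit <- function(x, ...) {
  cat(sprintf("<sizer_fit> div_target = %.4g %s (optimal interval [%.4g, %.4g]), SSE = %g%s\n",
              x$params$div_target, if (x$params$mode == "area") "um2" else "um3",
              x$interval[1], x$interval[2], x$sse,
              if (x$degenerate) " [degenerate: single observed n]" else ""))
  invisible(x)
}

#' Fit a commitment breakpoint to a mitotic-percentage-vs-size curve
#'
#' Continuous two-segment linear regression: for each candidate breakpoint c
#' on the grid of interior bin midpoints, fits `y ~ min(x, c) + max(x - c,
#' 0)` by ordinary least squares (continuity at the knot is built into the
#' basis) and keeps the breakpoint with minimal SSE. When the SSE reduction
#' relative to a single line is below `min_sse_reduction` the fit is flagged
#' as showing no breakpoint evidence.
#'
#' @param curve a `binned_stat` (or any tibble with `bin_mid` and `value`)
#'   with at least 5 populated bins.
#' @param min_sse_reduction relative SSE reduction below which the breakpoint
#'   is flagged as unsupported.
#' @param min_denominator when the curve carries a `denominator` column
#'   (e.g. from [mitotic_percentage()]), bins estimated from fewer cells than
#'   this are excluded from the fit: a proportion from a handful of cells has
#'   no stable value and can dominate an unweighted segmented fit.
#' @return Object of class `breakpoint_fit`: `breakpoint`, `slope_below`,
#'   `slope_above`, `intercept`, `sse`, `sse_single`, `sse_reduction`,
#'   `no_evidence` flag, `grid`, `data`. Supports `tidy()`/`glance()`.
#' @export
fit_commitment_breakpoint <- function(curve, min_sse_reduction = 0.05,
                                      min_denominator = 10) {
  if ("denominator" %in% names(curve)) {
    curve <- curve[curve$denominator >= min_denominator, ]
  }
  d <- tibble::tibble(x = curve$bin_mid, y = curve$value) |>
    filter(is.finite(.data$x), is.finite(.data$y)) |>
    arrange(.data$x)
  if (nrow(d) < 5) stop("breakpoint fit needs at least 5 populated bins")
  single <- lm(y ~ x, data = d)
  sse_single <- sum(stats::residuals(single)^2)
  # need >= 2 bins strictly on each side of the knot
  grid <- d$x[3:(nrow(d) - 2)]
  fits <- purrr::map(grid, function(cc) {
    X <- cbind(1, pmin(d$x, cc), pmax(d$x - cc, 0))
    f <- stats::lm.fit(X, d$y)
    list(c = cc, coef = f$coefficients, sse = sum(f$residuals^2))
  })
  sses <- purrr::map_dbl(fits, "sse")
  best <- fits[[which.min(sses)]]
  # a single line that already fits to numerical precision leaves nothing
  # for a knot to explain
  tol <- 1e-10 * sum(d$y^2)
  reduction <- if (sse_single > tol) 1 - best$sse / sse_single else 0
  structure(
    list(
      breakpoint = best$c,
      intercept = unname(best$coef[1]),
      slope_below = unname(best$coef[2]),
      slope_above = unname(best$coef[3]),
      sse = best$sse, sse_single = sse_single, sse_reduction = reduction,
      no_evidence = reduction < min_sse_reduction,
      grid = grid, sse_grid = sses, data = d
    ),
    class = "breakpoint_fit"
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("<breakpoint_fit> breakpoint = %.4g, slopes %.4g -> %.4g, SSE %.4g (single-line %.4g)%s\n",
              x$breakpoint, x$slope_below, x$slope_above, x$sse, x$sse_single,
              if (x$no_evidence) " [no breakpoint evidence]" else ""))
  invisible(x)
}

#' Sizer-ready event table from a lineage forest
#'
#' Converts merged fission episodes into the `(size, n)` table consumed by
#' [fit_sizer()], in area mode (parent pre-division cross-section) or volume
#' mode (ellipsoid extrapolation using the parent's last observed minor
#' axis).
#'
#' @param forest a [reconstruct_lineage()] result.
#' @param frames the frame table the forest was built from (needed for minor
#'   axes in volume mode).
#' @param mode `"area"` or `"volume"`.
#' @return Tibble with `size`, `n`, `n_daughters`, `colony_id`.
#' @export
sizer_events <- function(forest, frames = NULL, mode = c("area", "volume")) {
  mode <- match.arg(mode)
  ep <- division_episodes(forest)
  if (mode == "area") {
    return(tibble::tibble(size = ep$parent_area_um2, n = ep$n_rounds,
                          n_daughters = ep$n_daughters,
                          colony_id = ep$colony_id))
  }
  stopifnot(!is.null(frames))
  fm <- forest$frame_map |>
    left_join(frames |> select("colony_id", "frame", "label", "minor_axis_um"),
              by = c("colony_id", "frame", "label"))
  minor <- fm |>
    inner_join(ep |> select("colony_id", pid = "root_pid",
                            frame = "onset_frame"),
               by = c("colony_id", "pid", "frame"))
  key <- paste(ep$colony_id, ep$root_pid, ep$onset_frame)
  mkey <- paste(minor$colony_id, minor$pid, minor$frame)
  mx <- minor$minor_axis_um[match(key, mkey)]
  tibble::tibble(size = estimate_volume(ep$parent_area_um2, mx),
                 n = ep$n_rounds, n_daughters = ep$n_daughters,
                 colony_id = ep$colony_id)
}
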