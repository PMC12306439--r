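# Colony-level cell-cycle phenology: mean-size time series, division-onset
# detection from peak/valley structure, parent/daughter bimodal decoupling,
# exponential growth-rate fits, and division timing relative to the
# light-dark transition.

#' Per-frame size summary of each colony
#'
#' @param frames a frame table.
#' @return Tibble per (colony_id, frame): `time_h`, `mean_area`,
#'   `median_area`, `se_area` (sd/sqrt(n), 0 for a single cell), `n_cells`.
#' @export
compute_size_series <- function(frames) {
  stopifnot(nrow(frames) >= 1)
  out <- frames |>
    group_by(.data$colony_id, .data$frame) |>
    summarise(
      time_h = .data$time_h[1],
      mean_area = mean(.data$area_um2),
      median_area = median(.data$area_um2),
      se_area = if (dplyr::n() > 1) sd(.data$area_um2) / sqrt(dplyr::n()) else 0,
      n_cells = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$colony_id, .data$frame)
  class(out) <- c("size_series", class(out))
  out
}

#' Detect colony-level division onsets
#'
#' Scans the mean-area series of each colony for local maxima followed by an
#' abrupt relative drop of at least `min_drop_frac`, concurrent (by default)
#' with a strict increase in cell count; consecutive onsets must be at least
#' `min_separation_h` apart. Onset time is the peak time; cycle indices are
#' 1-based in time order.
#'
#' @param series output of [compute_size_series()].
#' @param min_drop_frac minimum relative drop (peak - valley) / peak.
#' @param min_separation_h minimum spacing between onsets, hours.
#' @param require_count_increase require the cell count to step up across the
#'   drop (disable for single-cell series).
#' @return Tibble: `colony_id`, `cycle`, `onset_time_h`, `onset_frame`,
#'   `peak_area`, `valley_area`.
#' @export
detect_division_onsets <- function(series, min_drop_frac = 0.2,
                                   min_separation_h = 12,
                                   require_count_increase = TRUE) {
  one <- function(s) {
    s <- arrange(s, .data$frame)
    if (nrow(s) < 3) return(NULL)
    a <- s$mean_area; n <- s$n_cells; t <- s$time_h
    onsets <- list()
    peak_i <- 1L
    last_onset_t <- -Inf
    i <- 2L
    while (i <= length(a)) {
      if (a[i] >= a[peak_i]) {
        peak_i <- i
      } else if (a[i] <= a[peak_i] * (1 - min_drop_frac)) {
        # find the valley: descend until the series turns up
        v <- i
        while (v < length(a) && a[v + 1] <= a[v]) v <- v + 1L
        ok_count <- !require_count_increase || n[v] > n[peak_i]
        if (ok_count && t[peak_i] - last_onset_t >= min_separation_h) {
          onsets[[length(onsets) + 1L]] <- tibble::tibble(
            onset_time_h = t[peak_i], onset_frame = s$frame[peak_i],
            peak_area = a[peak_i], valley_area = a[v]
          )
          last_onset_t <- t[peak_i]
        }
        peak_i <- v
        i <- v
      }
      i <- i + 1L
    }
    if (!length(onsets)) return(NULL)
    bind_rows(onsets) |>
      mutate(colony_id = s$colony_id[1], cycle = dplyr::row_number(), .before = 1)
  }
  out <- series |> group_by(.data$colony_id) |> group_split() |>
    purrr::map(one) |> bind_rows()
  if (!nrow(out)) {
    out <- tibble::tibble(colony_id = character(), cycle = integer(),
                          onset_time_h = numeric(), onset_frame = integer(),
                          peak_area = numeric(), valley_area = numeric())
  }
  out
}

#' Split a cell-size sample into daughter and parent modes
#'
#' Default method fits a two-component univariate Gaussian mixture and places
#' the decision threshold where the component posteriors are equal; when
#' model selection (BIC, G = 1 vs 2) prefers a single component, or no valid
#' equal-posterior crossing exists between the component means, the sample is
#' flagged unimodal and no split is returned. `method = "otsu"` instead
#' maximises the between-class variance over a histogram.
#'
#' @param areas numeric vector of cell areas (>= 4 values).
#' @param method `"gmm"` (default) or `"otsu"`.
#' @return List with `threshold`, `daughters` (values below), `parents`
#'   (values above), `unimodal` flag.
#' @importFrom mclust Mclust mclustBIC
#' @export
split_bimodal <- function(areas, method = c("gmm", "otsu")) {
  method <- match.arg(method)
  stopifnot(length(areas) >= 4)
  unimodal <- list(threshold = NA_real_, daughters = numeric(0),
                   parents = numeric(0), unimodal = TRUE)
  if (sd(areas) == 0) return(unimodal)

  if (method == "gmm") {
    fit <- tryCatch(
      Mclust(areas, G = 1:2, modelNames = c("E", "V"), verbose = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$G < 2) return(unimodal)
    p <- fit$parameters
    mu <- p$mean
    sig <- sqrt(if (length(p$variance$sigmasq) == 1)
      rep(p$variance$sigmasq, 2) else p$variance$sigmasq)
    pro <- p$pro
    lo <- min(mu); hi <- max(mu)
    if (hi - lo < 1e-12) return(unimodal)
    # equal-posterior point between the component means
    grid <- seq(lo, hi, length.out = 2048)
    post1 <- pro[1] * dnorm(grid, mu[1], sig[1])
    post2 <- pro[2] * dnorm(grid, mu[2], sig[2])
    dlt <- post1 - post2
    if (mu[1] > mu[2]) dlt <- -dlt
    cross <- which(diff(sign(dlt)) != 0)
    if (!length(cross)) return(unimodal)
    thr <- grid[cross[1]]
  } else {
    thr <- otsu_threshold(areas)
    if (is.na(thr)) return(unimodal)
  }
  list(threshold = thr, daughters = areas[areas < thr],
       parents = areas[areas >= thr], unimodal = FALSE)
}

# Otsu's between-class-variance maximiser on a fixed-width histogram. The
# objective is flat across an empty gap between two modes; the midpoint of
# the maximal plateau is returned so the threshold sits mid-gap.
otsu_threshold <- function(x, nbins = 128) {
  br <- seq(min(x), max(x), length.out = nbins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  w <- cumsum(h); m <- cumsum(h * seq_len(nbins))
  wt <- w[nbins]; mt <- m[nbins]
  between <- (mt * w - m * wt)^2 / (w * (wt - w))
  between[!is.finite(between)] <- -Inf
  best <- max(between)
  if (!is.finite(best)) return(NA_real_)
  at <- which(between >= best * (1 - 1e-12))
  (br[min(at) + 1] + br[max(at) + 1]) / 2
}

#' Fit an exponential growth model A(t) = A0 exp(mu t)
#'
#' Log-linear least squares of `ln(area)` on time; `mu` is the slope and `A0`
#' the exponentiated intercept (intercept taken at the window start). For
#' multiplicative noise this is the maximum-likelihood fit of the exponential
#' model and is deterministic.
#'
#' @param data tibble with `time_h` and an area column (`mean_area` from a
#'   size series, or `area_um2` for single-cell data).
#' @param window optional `c(t_start, t_end)` restricting the fit to one G1
#'   interval (valley to next peak); default uses all rows.
#' @param area_col name of the area column; auto-detected by default.
#' @return Object of class `growth_fit` with fields `mu`, `A0`, `window`,
#'   `n`, `sigma` (residual sd on the log scale), `r_squared`, and the `lm`
#'   fit; supports [generics::tidy()] and [generics::glance()].
#' @export
fit_growth_rate <- function(data, window = NULL, area_col = NULL) {
  if (is.null(area_col)) {
    area_col <- intersect(c("mean_area", "area_um2", "area"), names(data))[1]
    if (is.na(area_col)) stop("no area column found in data")
  }
  d <- tibble::tibble(time_h = data$time_h, area = data[[area_col]])
  if (!is.null(window)) {
    d <- filter(d, .data$time_h >= window[1], .data$time_h <= window[2])
  } else {
    window <- range(d$time_h)
  }
  if (nrow(d) < 3) stop("growth fit needs at least 3 points in the window")
  if (any(d$area <= 0)) stop("non-positive areas in the growth-fit window")
  t0 <- window[1]
  fit <- lm(log(area) ~ I(time_h - t0), data = d)
  res <- suppressWarnings(summary(fit)) # noiseless input fits perfectly
  structure(
    list(
      mu = unname(coef(fit)[2]), A0 = exp(unname(coef(fit)[1])),
      window = window, n = nrow(d), sigma = res$sigma,
      r_squared = res$r.squared, fit = fit
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> mu = %.5g /h, A0 = %.5g um2 (n = %d, window [%g, %g] h)\n",
              x$mu, x$A0, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Per-cycle growth-rate fits for every colony
#'
#' Fits the exponential model within each G1 interval, delimited by the
#' detected division onsets: cycle 1 runs from the series start to the first
#' onset, cycle k from onset k-1 (exclusive of the fission frames, restarting
#' at the post-division valley) to onset k.
#'
#' @param series output of [compute_size_series()].
#' @param onsets output of [detect_division_onsets()].
#' @param min_points minimum frames per interval to attempt a fit.
#' @return Tibble: `colony_id`, `cycle`, `mu`, `A0`, `t_start`, `t_end`,
#'   `n`, `r_squared`.
#' @export
fit_growth_by_cycle <- function(series, onsets, min_points = 4) {
  one <- function(s) {
    cid <- s$colony_id[1]
    on <- filter(onsets, .data$colony_id == cid) |> arrange(.data$onset_time_h)
    if (!nrow(on)) return(NULL)
    starts <- c(min(s$time_h), purrr::map_dbl(seq_len(nrow(on) - 1), function(k) {
      # restart at the valley after onset k
      seg <- filter(s, .data$time_h > on$onset_time_h[k],
                    .data$time_h < on$onset_time_h[k + 1])
      if (!nrow(seg)) return(NA_real_)
      seg$time_h[which.min(seg$mean_area)]
    }))
    if (nrow(on) > 1 && any(is.na(starts))) return(NULL)
    ends <- on$onset_time_h
    purrr::map(seq_along(ends), function(k) {
      win <- c(starts[k], ends[k])
      d <- filter(s, .data$time_h >= win[1], .data$time_h <= win[2])
      if (nrow(d) < min_points) return(NULL)
      g <- fit_growth_rate(d, window = win, area_col = "mean_area")
      tibble::tibble(colony_id = cid, cycle = on$cycle[k], mu = g$mu, A0 = g$A0,
                     t_start = win[1], t_end = win[2], n = g$n,
                     r_squared = g$r_squared)
    }) |> bind_rows()
  }
  series |> group_by(.data$colony_id) |> group_split() |>
    purrr::map(one) |> bind_rows()
}

#' Division-timing shift relative to the light-dark transition
#'
#' For each event the shift is the onset time minus the nearest
#' preceding-or-equal light-to-dark transition when that lies within half a
#' period; otherwise the signed distance to the nearest transition (so an
#' onset shortly before lights-off gets a small negative shift).
#'
#' @param events tibble with `onset_time_h` and optionally `n_daughters`
#'   and/or a `condition` column for grouping.
#' @param schedule a [light_schedule()].
#' @return `events` with a `shift_h` column added, plus attribute `groups`: a
#'   tibble of group means and standard errors by (n_daughters, condition)
#'   where those columns exist (also available via [timing_shift_summary()]).
#' @export
division_timing_shift <- function(events, schedule) {
  first_off <- schedule$phase_offset_h + schedule$light_h
  shift <- purrr::map_dbl(events$onset_time_h, function(t) {
    k_prev <- floor((t - first_off) / schedule$period_h)
    d_prev <- t - (first_off + k_prev * schedule$period_h) # in [0, period)
    if (d_prev <= schedule$period_h / 2) d_prev
    else d_prev - schedule$period_h # nearest following transition, negative
  })
  out <- mutate(events, shift_h = shift)
  attr(out, "groups") <- timing_shift_summary(out)
  out
}

#' Group summary of division-timing shifts
#'
#' @param shifted output of [division_timing_shift()].
#' @return Tibble of group `mean_shift_h`, `se_shift_h`, `n` by whichever of
#'   `n_daughters` and `condition` are present.
#' @export
timing_shift_summary <- function(shifted) {
  gvars <- intersect(c("n_daughters", "condition"), names(shifted))
  shifted |>
    group_by(dplyr::across(dplyr::all_of(gvars))) |>
    summarise(
      mean_shift_h = mean(.data$shift_h),
      se_shift_h = if (dplyr::n() > 1) sd(.data$shift_h) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop"
    )
}

#' Coefficient of variation of colony size across colonies
#'
#' Sample (n-1) standard deviation over the mean; dimensionless and invariant
#' under uniform rescaling.
#'
#' @param sizes colony sizes (cell counts or areas) at one time point, one
#'   value per colony (>= 2).
#' @return CV as a plain number.
#' @export
colony_cv <- function(sizes) {
  stopifnot(length(sizes) >= 2)
  m <- mean(sizes)
  if (m == 0) stop("colony_cv undefined: mean size is zero")
  sd(sizes) / m
}
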