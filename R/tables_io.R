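#' @useDynLib microfission, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import dplyr
#' @importFrom stats lm coef median quantile sd setNames dnorm rexp rlnorm rnorm runif
#' @importFrom utils head tail
"_PACKAGE"

# Canonical column order for frame tables. `fluor` is optional on input but
# always present (possibly NA) after validation.
frame_table_cols <- c(
  "colony_id", "frame", "time_h", "label",
  "x_um", "y_um", "area_um2", "minor_axis_um", "fluor"
)

#' Default column-name dialect for frame tables
#'
#' Maps canonical column names to the names used in a particular CSV export.
#' Override individual entries to adapt to a segmentation pipeline's naming,
#' e.g. `frame_dialect(area_um2 = "AreaShape_Area")`.
#'
#' @param ... named character overrides, `canonical = "file column"`.
#' @return Named character vector mapping canonical names to file columns.
#' @export
frame_dialect <- function(...) {
  d <- setNames(frame_table_cols, frame_table_cols)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), frame_table_cols)
    if (length(bad)) {
      stop("unknown frame-table columns in dialect: ", paste(bad, collapse = ", "))
    }
    d[names(over)] <- over
  }
  d
}

#' Assemble and validate a frame table
#'
#' A frame table is a tibble with one row per segmented cell per frame:
#' `colony_id`, `frame` (integer index >= 0), `time_h` (hours since imaging
#' start), `label` (per-frame integer label >= 1), centroid `x_um`/`y_um`,
#' cross-sectional `area_um2`, `minor_axis_um`, and optional `fluor`.
#' Out-of-focus or otherwise excluded frames are simply absent: the
#' frame-to-time mapping is carried on every row, so gaps are representable.
#'
#' @param df data frame with the columns above (`fluor`, `time_h` optional;
#'   `time_h` defaults to `frame * frame_interval_h`).
#' @param frame_interval_h nominal imaging interval in hours (default 1).
#' @return A validated tibble ordered by (colony_id, frame, label), with the
#'   nominal interval attached as attribute `frame_interval_h`.
#' @export
frame_table <- function(df, frame_interval_h = 1.0) {
  df <- tibble::as_tibble(df)
  if (!"fluor" %in% names(df)) df$fluor <- NA_real_
  if (!"time_h" %in% names(df)) df$time_h <- df$frame * frame_interval_h
  missing <- setdiff(frame_table_cols, names(df))
  if (length(missing)) {
    stop("frame table is missing required columns: ", paste(missing, collapse = ", "))
  }
  df <- df[frame_table_cols]
  validate_frame_table(df)
  out <- arrange(df, .data$colony_id, .data$frame, .data$label)
  attr(out, "frame_interval_h") <- frame_interval_h
  out
}

#' Validate frame-table invariants
#'
#' Checks positivity of areas and minor axes, the geometric bound
#' minor axis <= equivalent diameter (with tolerance), per-(colony, frame)
#' label uniqueness, and that time is nondecreasing with frame index within
#' each colony. Violations raise an error naming the offending rows.
#'
#' @param df frame table candidate.
#' @param tol relative tolerance for the minor-axis bound.
#' @return `df`, invisibly.
#' @export
validate_frame_table <- function(df, tol = 1e-6) {
  bad_rows <- function(idx, what) {
    if (any(idx)) {
      stop("invalid frame table: ", what, " in row(s) ",
           paste(head(which(idx), 10L), collapse = ", "),
           if (sum(idx) > 10L) sprintf(" (and %d more)", sum(idx) - 10L) else "",
           call. = FALSE)
    }
  }
  bad_rows(!is.finite(df$area_um2) | df$area_um2 <= 0, "non-positive area_um2")
  bad_rows(!is.finite(df$minor_axis_um) | df$minor_axis_um <= 0, "non-positive minor_axis_um")
  eq_diam <- 2 * sqrt(df$area_um2 / pi)
  bad_rows(df$minor_axis_um > eq_diam * (1 + tol) + tol,
           "minor_axis_um exceeds equivalent diameter")
  bad_rows(df$frame < 0 | df$frame != floor(df$frame), "non-integer or negative frame")
  bad_rows(df$label < 1 | df$label != floor(df$label), "invalid label (< 1 or non-integer)")
  dup <- duplicated(df[c("colony_id", "frame", "label")])
  bad_rows(dup, "duplicate label within (colony_id, frame)")
  tchk <- df |>
    group_by(.data$colony_id, .data$frame) |>
    summarise(time_h = .data$time_h[1], n_t = dplyr::n_distinct(.data$time_h), .groups = "drop_last") |>
    arrange(.data$frame, .by_group = TRUE) |>
    summarise(ok = all(diff(.data$time_h) >= 0) && all(.data$n_t == 1), .groups = "drop")
  if (!all(tchk$ok)) {
    stop("invalid frame table: time_h is not a nondecreasing function of frame ",
         "within colony ", paste(tchk$colony_id[!tchk$ok], collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read a frame table from CSV
#'
#' @param path CSV file with a header row.
#' @param dialect column-name map from [frame_dialect()].
#' @param frame_interval_h nominal imaging interval in hours.
#' @return A validated frame table tibble.
#' @export
read_frame_table <- function(path, dialect = frame_dialect(), frame_interval_h = 1.0) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- setdiff(frame_table_cols, c("fluor", "time_h"))
  missing <- required[!dialect[required] %in% names(raw)]
  if (length(missing)) {
    stop("frame-table file ", path, " lacks required column(s): ",
         paste(sprintf("%s (expected header '%s')", missing, dialect[missing]),
               collapse = ", "), call. = FALSE)
  }
  present <- dialect[dialect %in% names(raw)]
  df <- raw[unname(present)]
  names(df) <- names(present)
  frame_table(df, frame_interval_h = frame_interval_h)
}

#' Write a frame table to CSV
#'
#' Stable canonical column order, full float precision; round-trips through
#' [read_frame_table()] up to float formatting.
#'
#' @param table frame table tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_table <- function(table, path) {
  validate_frame_table(table)
  readr::write_csv(table[frame_table_cols], path, progress = FALSE)
  invisible(path)
}

#' Diurnal light schedule
#'
#' A periodic light-dark clock: lights on at `phase_offset_h` (+ multiples of
#' `period_h`) for `light_h` hours. The default is the 12 h : 12 h cycle.
#'
#' @param period_h cycle period in hours.
#' @param light_h illuminated fraction of the cycle, hours.
#' @param phase_offset_h time of first lights-on relative to t = 0.
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(period_h = 24, light_h = 12, phase_offset_h = 0) {
  stopifnot(period_h > 0, light_h > 0, light_h < period_h)
  structure(
    list(period_h = period_h, light_h = light_h, phase_offset_h = phase_offset_h),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %g h light : %g h dark, lights-on at t = %g h (mod %g)\n",
              x$light_h, x$period_h - x$light_h, x$phase_offset_h %% x$period_h, x$period_h))
  invisible(x)
}

#' Is the light on at time t?
#'
#' @param schedule a [light_schedule()].
#' @param t_h time(s) in hours.
#' @return Logical vector.
#' @export
is_light <- function(schedule, t_h) {
  ((t_h - schedule$phase_offset_h) %% schedule$period_h) < schedule$light_h
}

#' Light-to-dark transition times
#'
#' All light-off ("LD12" for the default 12:12 schedule) transition times in
#' the half-open interval `[t_start, t_end)`, ascending.
#'
#' @param schedule a [light_schedule()].
#' @param t_start,t_end interval bounds in hours, `t_start < t_end`.
#' @return Numeric vector of transition times (hours).
#' @export
ld12_transitions <- function(schedule, t_start, t_end) {
  stopifnot(t_start < t_end)
  first_off <- schedule$phase_offset_h + schedule$light_h
  k_lo <- ceiling((t_start - first_off) / schedule$period_h)
  k_hi <- floor((t_end - first_off) / schedule$period_h)
  if (k_lo > k_hi) return(numeric(0))
  # k_hi lands on t_end for exact multiples; interval is half-open on the right
  ks <- seq(k_lo, k_hi, by = 1)
  out <- first_off + ks * schedule$period_h
  out[out >= t_start & out < t_end]
}

#' Convert label masks to a frame table
#'
#' Computes per-label centroid, area (pixel count x calibration^2) and
#' minor-axis length (from the second-central-moment ellipse, the regionprops
#' convention) from integer label images. The pixel size must be supplied
#' explicitly: calibration happens upstream at segmentation and there is no
#' safe default.
#'
#' @param labels list of integer matrices (one per frame), a 3-d integer
#'   array (frames along the third margin), or a path to a multi-page TIFF of
#'   label masks (requires the `tiff` package).
#' @param um_per_px pixel edge length in micrometres (required, no default).
#' @param times_h acquisition time of each frame in hours; defaults to
#'   `(seq_along(frames) - 1) * frame_interval_h`.
#' @param colony_id colony identifier attached to every row.
#' @param frame_interval_h nominal imaging interval in hours.
#' @return A validated frame table tibble.
#' @export
frames_from_labels <- function(labels, um_per_px, times_h = NULL,
                               colony_id = "colony1", frame_interval_h = 1.0) {
  if (missing(um_per_px) || !is.numeric(um_per_px) || um_per_px <= 0) {
    stop("um_per_px (pixel size in micrometres) must be supplied and positive")
  }
  if (is.character(labels)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF label masks requires the 'tiff' package")
    }
    pages <- tiff::readTIFF(labels, all = TRUE, as.is = TRUE)
    labels <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  } else if (is.array(labels) && length(dim(labels)) == 3L) {
    labels <- lapply(seq_len(dim(labels)[3]), function(k) labels[, , k])
  }
  stopifnot(is.list(labels), length(labels) >= 1L)
  if (is.null(times_h)) times_h <- (seq_along(labels) - 1) * frame_interval_h
  stopifnot(length(times_h) == length(labels))

  one_frame <- function(mask, fi) {
    ids <- sort(unique(mask[mask > 0]))
    if (!length(ids)) return(NULL)
    rows <- lapply(ids, function(id) {
      w <- which(mask == id, arr.ind = TRUE)
      # row index -> y, column index -> x; centroid at pixel centres
      xs <- w[, 2] - 0.5
      ys <- w[, 1] - 0.5
      n <- nrow(w)
      mx <- mean(xs); my <- mean(ys)
      # central second moments with the 1/12 pixel self-variance term
      # (regionprops ellipse convention)
      mxx <- mean((xs - mx)^2) + 1 / 12
      myy <- mean((ys - my)^2) + 1 / 12
      mxy <- mean((xs - mx) * (ys - my))
      common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
      lam_min <- (mxx + myy - common) / 2
      tibble::tibble(
        colony_id = colony_id, frame = fi, time_h = times_h[fi + 1L],
        label = as.integer(id),
        x_um = mx * um_per_px, y_um = my * um_per_px,
        area_um2 = n * um_per_px^2,
        minor_axis_um = 4 * sqrt(lam_min) * um_per_px
      )
    })
    bind_rows(rows)
  }
  df <- bind_rows(purrr::imap(labels, function(mask, i) one_frame(mask, i - 1L)))
  if (!nrow(df)) stop("label masks contain no labelled pixels")
  # moment ellipse of a rasterised disk can overshoot the area-equivalent
  # diameter by a fraction of a pixel; clamp into the valid range
  df$minor_axis_um <- pmin(df$minor_axis_um, 2 * sqrt(df$area_um2 / pi))
  frame_table(df, frame_interval_h = frame_interval_h)
}
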