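#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a growth fit
#'
#' @param x a `growth_fit` from [fit_growth_rate()].
#' @param ... unused.
#' @return One row per model term (`A0`, `mu`) with estimate and standard
#'   error.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("A0", "mu"),
    estimate = c(x$A0, x$mu),
    std.error = c(x$A0 * s[1, 2], s[2, 2]) # delta method for exp(intercept)
  )
}

#' @rdname tidy.growth_fit
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, A0 = x$A0, r.squared = x$r_squared,
                 sigma = x$sigma, nobs = x$n,
                 t_start = x$window[1], t_end = x$window[2])
}

#' Tidy a sizer fit
#'
#' @param x a `sizer_fit` from [fit_sizer()].
#' @param ... unused.
#' @return The binned observed-vs-predicted table (mean observed round count
#'   +/- SEM per size bin, with the model prediction at the bin centre).
#' @method tidy sizer_fit
#' @export
tidy.sizer_fit <- function(x, ...) x$binned

#' @rdname tidy.sizer_fit
#' @method glance sizer_fit
#' @export
glance.sizer_fit <- function(x, ...) {
  tibble::tibble(div_target = x$params$div_target, mode = x$params$mode,
                 interval_lo = x$interval[1], interval_hi = x$interval[2],
                 sse = x$sse, degenerate = x$degenerate,
                 nobs = nrow(x$events))
}

#' Tidy a breakpoint fit
#'
#' @param x a `breakpoint_fit` from [fit_commitment_breakpoint()].
#' @param ... unused.
#' @return One row per parameter (breakpoint, slopes, intercept).
#' @method tidy breakpoint_fit
#' @export
tidy.breakpoint_fit <- function(x, ...) {
  tibble::tibble(
    term = c("breakpoint", "slope_below", "slope_above", "intercept"),
    estimate = c(x$breakpoint, x$slope_below, x$slope_above, x$intercept)
  )
}

#' @rdname tidy.breakpoint_fit
#' @method glance breakpoint_fit
#' @export
glance.breakpoint_fit <- function(x, ...) {
  tibble::tibble(breakpoint = x$breakpoint, sse = x$sse,
                 sse_single = x$sse_single, sse_reduction = x$sse_reduction,
                 no_evidence = x$no_evidence, nobs = nrow(x$data))
}

#' Tidy a lineage forest
#'
#' @param x a `lineage_forest` from [reconstruct_lineage()].
#' @param ... unused.
#' @return The node table: one row per persistent cell identity.
#' @method tidy lineage_forest
#' @export
tidy.lineage_forest <- function(x, ...) x$nodes

#' @rdname tidy.lineage_forest
#' @method glance lineage_forest
#' @export
glance.lineage_forest <- function(x, ...) {
  tibble::tibble(
    n_tracks = nrow(x$nodes),
    n_colonies = dplyr::n_distinct(x$nodes$colony_id),
    n_events = nrow(x$events),
    n_flagged = sum(x$events$flagged)
  )
}

#' Export lineage and event tables as CSV
#'
#' Writes `lineage.csv` (persistent_id, colony_id, parent_id, birth_frame,
#' last_frame) and `events.csv` (parent_id, onset_frame, parent_area_um2,
#' n_rounds, daughter_ids semicolon-joined).
#'
#' @param forest a `lineage_forest`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_lineage <- function(forest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(
    forest$nodes |> select(persistent_id = "pid", "colony_id",
                           parent_id = "parent_pid", "birth_frame",
                           "last_frame"),
    file.path(dir, "lineage.csv"), progress = FALSE)
  ev <- forest$events |>
    mutate(daughter_ids = purrr::map_chr(.data$daughter_pids,
                                         paste, collapse = ";")) |>
    select("colony_id", parent_id = "parent_pid", "onset_frame",
           "parent_area_um2", "n_rounds", "daughter_ids")
  readr::write_csv(ev, file.path(dir, "events.csv"), progress = FALSE)
  invisible(dir)
}
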