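# Colony geometry and spatially binned statistics: radial ring assignment
# (from the colony edge or centre -- the reference is explicit in every
# output), binned mitotic percentage, radial kymographs, ring summaries and
# parent/daughter size correlation.

#' Geometry of a colony at one frame
#'
#' Centroid (unweighted mean of member centroids) and boundary: the convex
#' hull of cell centroids with each hull vertex pushed outward along its
#' vertex normal by the cell's equivalent radius, so the boundary is
#' determined by the hull cells alone. Degenerate colonies (one cell, or
#' collinear centroids) fall back to a bounding circle.
#'
#' @param cells observations of one colony at one frame (`x_um`, `y_um`,
#'   `area_um2`).
#' @return Object of class `colony_geometry`: list with `centroid`,
#'   `boundary` (two-column matrix of polygon vertices, or `NULL` for a
#'   circle), `radius`, `area`, `type` (`"polygon"` or `"circle"`).
#' @export
colony_geometry <- function(cells) {
  stopifnot(nrow(cells) >= 1)
  cx <- mean(cells$x_um); cy <- mean(cells$y_um)
  r_eq <- sqrt(cells$area_um2 / pi)
  if (nrow(cells) == 1) {
    return(circle_geometry(c(cx, cy), r_eq[1]))
  }
  hull <- grDevices::chull(cells$x_um, cells$y_um)
  if (length(unique(hull)) < 3) {
    return(circle_geometry(
      c(cx, cy),
      max(sqrt((cells$x_um - cx)^2 + (cells$y_um - cy)^2) + r_eq)
    ))
  }
  hx <- cells$x_um[hull]; hy <- cells$y_um[hull]
  # push each hull vertex outward along its vertex normal (mean of the two
  # adjacent edge normals), so the boundary depends only on the hull cells:
  # interior cells cannot perturb it
  m <- length(hx)
  nxt <- c(seq_len(m)[-1], 1L)
  prv <- c(m, seq_len(m)[-m])
  ex <- hx[nxt] - hx; ey <- hy[nxt] - hy
  el <- sqrt(ex^2 + ey^2); el[el < 1e-12] <- 1
  # edge normal, oriented away from the hull centroid
  nx_e <- ey / el; ny_e <- -ex / el
  mx <- (hx + hx[nxt]) / 2 - mean(hx); my <- (hy + hy[nxt]) / 2 - mean(hy)
  flip <- nx_e * mx + ny_e * my < 0
  nx_e[flip] <- -nx_e[flip]; ny_e[flip] <- -ny_e[flip]
  vx <- nx_e + nx_e[prv]; vy <- ny_e + ny_e[prv]
  vl <- sqrt(vx^2 + vy^2); vl[vl < 1e-12] <- 1
  bx <- hx + r_eq[hull] * vx / vl
  by <- hy + r_eq[hull] * vy / vl
  poly <- cbind(x = bx, y = by)
  structure(
    list(centroid = c(x = cx, y = cy), boundary = poly,
         radius = max(sqrt((bx - cx)^2 + (by - cy)^2)),
         area = polygon_area(bx, by), type = "polygon"),
    class = "colony_geometry"
  )
}

#' Circular colony boundary
#'
#' Degenerate / synthetic geometry: a disk of given radius. Used for
#' single-cell colonies and in tests of the radial identities.
#'
#' @param center `c(x, y)` in um.
#' @param radius disk radius in um.
#' @return A `colony_geometry` of type `"circle"`.
#' @export
circle_geometry <- function(center, radius) {
  stopifnot(radius > 0)
  structure(
    list(centroid = c(x = center[1], y = center[2]), boundary = NULL,
         radius = radius, area = pi * radius^2, type = "circle"),
    class = "colony_geometry"
  )
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

point_in_polygon <- function(px, py, bx, by) {
  n <- length(bx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (by[i] > py) != (by[j] > py)
    xi <- (bx[j] - bx[i]) * (py - by[i]) / (by[j] - by[i]) + bx[i]
    inside <- xor(inside, cross & (px < xi))
    j <- i
  }
  inside
}

point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- pmax(vx^2 + vy^2, 1e-24)
  t <- clamp(((px - x1) * vx + (py - y1) * vy) / L2, 0, 1)
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

#' Radial distance of cells within a colony
#'
#' `reference = "edge"`: shortest distance from the cell centroid to the
#' colony boundary. `reference = "centre"`: distance to the colony centroid.
#' Cells outside the boundary beyond `tol` are clamped to edge distance 0
#' with a warning.
#'
#' @param cells tibble with `x_um`, `y_um`.
#' @param geometry a [colony_geometry()].
#' @param reference `"edge"` or `"centre"`.
#' @param tol boundary tolerance in um.
#' @return Numeric vector of distances in um.
#' @export
radial_distances <- function(cells, geometry, reference = c("edge", "centre"),
                             tol = 1e-6) {
  reference <- match.arg(reference)
  px <- cells$x_um; py <- cells$y_um
  dc <- sqrt((px - geometry$centroid["x"])^2 + (py - geometry$centroid["y"])^2)
  if (reference == "centre") return(unname(dc))
  if (geometry$type == "circle") {
    d <- geometry$radius - dc
  } else {
    b <- geometry$boundary
    n <- nrow(b)
    nxt <- c(seq_len(n)[-1], 1L)
    d <- vapply(seq_along(px), function(i) {
      min(point_segment_distance(px[i], py[i], b[, 1], b[, 2],
                                 b[nxt, 1], b[nxt, 2]))
    }, numeric(1))
    inside <- point_in_polygon(px, py, b[, 1], b[, 2])
    d[!inside] <- -d[!inside]
  }
  if (any(d < -tol)) {
    warning(sum(d < -tol), " cell(s) outside the colony boundary; ",
            "edge distance clamped to 0")
  }
  pmax(d, 0)
}

# geometry + ring index per cell for every (colony, frame)
assign_rings <- function(frames, ring_width, reference) {
  frames |>
    group_by(.data$colony_id, .data$frame) |>
    group_modify(function(g, key) {
      geo <- colony_geometry(g)
      d <- radial_distances(g, geo, reference = reference)
      mutate(g, radial_um = d, ring = floor(d / ring_width))
    }) |>
    ungroup()
}

#' Mitotic percentage in spatial or size bins
#'
#' The mitotic percentage in a bin is 100 x (cells in the current frame whose
#' division onset lies between the current and the subsequent frame) / (all
#' cells in the bin at the current frame), aggregated over the selected
#' frames. By default the selected frames are those within `onset_window`
#' frames of any division onset in the colony. The standard error is computed
#' across colonies.
#'
#' @param frames a frame table.
#' @param forest the [reconstruct_lineage()] forest for `frames`.
#' @param binning `"size"` (parent area bins), `"radial"` (rings from the
#'   reference), or `"none"`.
#' @param frames_select optional explicit frame indices; overrides the
#'   onset-window default.
#' @param ring_width ring width in um (radial binning).
#' @param size_bin_width bin width in um^2 (size binning).
#' @param reference `"edge"` or `"centre"` for radial binning.
#' @param onset_window frames around each division onset included by default.
#' @return A `binned_stat` tibble: `bin_lo`, `bin_hi`, `bin_mid`,
#'   `numerator`, `denominator`, `value` (percent), `se`, `n_colonies`; empty
#'   bins are absent. Attributes record the binning and reference.
#' @export
mitotic_percentage <- function(frames, forest,
                               binning = c("size", "radial", "none"),
                               frames_select = NULL,
                               ring_width = 25, size_bin_width = 10,
                               reference = c("edge", "centre"),
                               onset_window = 1L) {
  binning <- match.arg(binning)
  reference <- match.arg(reference)
  ev <- forest$events
  fm <- forest$frame_map |>
    left_join(ev |> select("colony_id", pid = "parent_pid",
                           onset = "onset_frame") |> distinct(),
              by = c("colony_id", "pid"),
              relationship = "many-to-many") |>
    mutate(dividing = !is.na(.data$onset) & .data$onset == .data$frame) |>
    group_by(.data$colony_id, .data$frame, .data$label) |>
    summarise(dplyr::across(c("pid", "x_um", "y_um", "area_um2"), dplyr::first),
              dividing = any(.data$dividing), .groups = "drop")

  # frames usable as "current": a subsequent frame must exist
  have_next <- frames |> distinct(.data$colony_id, .data$frame) |>
    group_by(.data$colony_id) |>
    mutate(has_next = (.data$frame + 1L) %in% .data$frame) |> ungroup()

  if (is.null(frames_select)) {
    sel <- ev |> distinct(.data$colony_id, .data$onset_frame) |>
      tidyr::expand_grid(off = -onset_window:onset_window) |>
      mutate(frame = .data$onset_frame + .data$off) |>
      distinct(.data$colony_id, .data$frame)
  } else {
    sel <- tidyr::expand_grid(colony_id = unique(frames$colony_id),
                              frame = as.integer(frames_select))
  }
  sel <- sel |> inner_join(filter(have_next, .data$has_next),
                           by = c("colony_id", "frame"))
  if (!nrow(sel)) stop("no usable frames selected for mitotic percentage")

  cur <- fm |> inner_join(sel, by = c("colony_id", "frame"))
  cur <- switch(binning,
    none = mutate(cur, bin = 0),
    size = mutate(cur, bin = floor(.data$area_um2 / size_bin_width)),
    radial = {
      ringed <- assign_rings(
        frames |> inner_join(sel, by = c("colony_id", "frame")),
        ring_width, reference)
      cur |> left_join(
        ringed |> select("colony_id", "frame", "label", "ring"),
        by = c("colony_id", "frame", "label")) |>
        rename(bin = "ring")
    })
  width <- switch(binning, none = NA_real_, size = size_bin_width,
                  radial = ring_width)

  per_colony <- cur |>
    group_by(.data$colony_id, .data$bin) |>
    summarise(num = sum(.data$dividing), den = dplyr::n(), .groups = "drop") |>
    mutate(pct = 100 * .data$num / .data$den)
  out <- per_colony |>
    group_by(.data$bin) |>
    summarise(
      numerator = sum(.data$num), denominator = sum(.data$den),
      value = 100 * .data$numerator / .data$denominator,
      se = if (dplyr::n() > 1) sd(.data$pct) / sqrt(dplyr::n()) else 0,
      n_colonies = dplyr::n(), .groups = "drop"
    ) |>
    mutate(
      bin_lo = if (is.na(width)) -Inf else .data$bin * width,
      bin_hi = if (is.na(width)) Inf else (.data$bin + 1) * width,
      bin_mid = if (is.na(width)) NA_real_ else (.data$bin + 0.5) * width
    ) |>
    select("bin", "bin_lo", "bin_hi", "bin_mid", "numerator", "denominator",
           "value", "se", "n_colonies") |>
    arrange(.data$bin)
  attr(out, "binning") <- binning
  attr(out, "reference") <- if (binning == "radial") reference else NA_character_
  attr(out, "bin_width") <- width
  class(out) <- c("binned_stat", class(out))
  out
}

#' Radial kymograph of mean cell size
#'
#' Mean cell area per (frame, radial ring), rings of fixed width measured
#' from the chosen reference. Each cell contributes to exactly one (frame,
#' ring) bin per frame.
#'
#' @param frames a frame table (one or more colonies).
#' @param ring_width ring width in um.
#' @param reference `"edge"` or `"centre"`.
#' @return A `kymograph` tibble: `colony_id`, `frame`, `time_h`, `ring`,
#'   `r_lo`, `r_hi`, `mean_area`, `n_cells`.
#' @export
radial_kymograph <- function(frames, ring_width = 25,
                             reference = c("edge", "centre")) {
  reference <- match.arg(reference)
  stopifnot(ring_width > 0)
  out <- assign_rings(frames, ring_width, reference) |>
    group_by(.data$colony_id, .data$frame, .data$ring) |>
    summarise(time_h = .data$time_h[1], mean_area = mean(.data$area_um2),
              n_cells = dplyr::n(), .groups = "drop") |>
    mutate(r_lo = .data$ring * ring_width, r_hi = (.data$ring + 1) * ring_width) |>
    select("colony_id", "frame", "time_h", "ring", "r_lo", "r_hi",
           "mean_area", "n_cells")
  attr(out, "reference") <- reference
  attr(out, "ring_width") <- ring_width
  class(out) <- c("kymograph", class(out))
  out
}

#' Per-ring five-number summary at one time point
#'
#' Quartiles use linear interpolation (R quantile type 7).
#'
#' @param cells observations of one colony at one frame.
#' @param geometry the frame's [colony_geometry()]; computed if `NULL`.
#' @param ring_width ring width in um.
#' @param reference `"edge"` or `"centre"`.
#' @return Tibble per ring: `ring`, `r_lo`, `r_hi`, `min`, `q1`, `median`,
#'   `q3`, `max`, `mean`, `n`.
#' @export
ring_boxplot_summary <- function(cells, geometry = NULL, ring_width = 25,
                                 reference = c("edge", "centre")) {
  reference <- match.arg(reference)
  if (is.null(geometry)) geometry <- colony_geometry(cells)
  d <- radial_distances(cells, geometry, reference = reference)
  tibble::tibble(area = cells$area_um2, ring = floor(d / ring_width)) |>
    group_by(.data$ring) |>
    summarise(
      min = min(.data$area),
      q1 = quantile(.data$area, 0.25, type = 7, names = FALSE),
      median = median(.data$area),
      q3 = quantile(.data$area, 0.75, type = 7, names = FALSE),
      max = max(.data$area),
      mean = mean(.data$area),
      n = dplyr::n(), .groups = "drop"
    ) |>
    mutate(r_lo = .data$ring * ring_width, r_hi = (.data$ring + 1) * ring_width,
           .after = "ring") |>
    arrange(.data$ring)
}

#' Parent and daughter areas for every division event
#'
#' One row per daughter: the parent's pre-division (last observed) area and
#' the daughter's area at its first observation.
#'
#' @param forest a [reconstruct_lineage()] result.
#' @return Tibble: `colony_id`, `parent_pid`, `daughter_pid`,
#'   `parent_area_um2`, `daughter_area_um2`.
#' @export
parent_daughter_pairs <- function(forest) {
  ev <- forest$events
  if (!nrow(ev)) {
    return(tibble::tibble(colony_id = character(), parent_pid = integer(),
                          daughter_pid = integer(), parent_area_um2 = numeric(),
                          daughter_area_um2 = numeric()))
  }
  first_obs <- forest$frame_map |> group_by(.data$pid) |>
    slice_min(.data$frame, n = 1, with_ties = FALSE) |> ungroup() |>
    select("pid", "colony_id", daughter_area_um2 = "area_um2")
  ev |>
    select("colony_id", "parent_pid", "parent_area_um2", "daughter_pids") |>
    tidyr::unnest_longer("daughter_pids", values_to = "daughter_pid") |>
    left_join(select(first_obs, "pid", "daughter_area_um2"),
              by = c(daughter_pid = "pid"))
}

#' Rank correlation between parent and daughter sizes
#'
#' Spearman rank correlation with average ranks for ties. Degenerate input
#' (zero variance on either side) is flagged and returns `NA`.
#'
#' @param pairs tibble with `parent_area_um2` and `daughter_area_um2`
#'   (>= 3 rows), e.g. from [parent_daughter_pairs()].
#' @return Tibble: `rho`, `n`, `flagged`.
#' @export
parent_daughter_correlation <- function(pairs) {
  stopifnot(nrow(pairs) >= 3)
  x <- pairs$parent_area_um2; y <- pairs$daughter_area_um2
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, n = nrow(pairs), flagged = TRUE))
  }
  tibble::tibble(rho = stats::cor(x, y, method = "spearman"),
                 n = nrow(pairs), flagged = FALSE)
}
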