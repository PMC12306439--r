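# Shared fixtures and small oracles. Everything is generated in code; the
# expensive default-configuration cohort is built once per test run and
# reused by the tracker, phenology and acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

# 20 default-config colonies (seeds 1..20), their pooled frame table and the
# lineage forest reconstructed with default tracker parameters.
default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    sims <- simulate_colonies(20, sim_config(seed = 1))
    frames <- bind_sim_frames(sims)
    forest <- reconstruct_lineage(frames)
    .fixture_env$cohort <- list(sims = sims, frames = frames, forest = forest)
  }
  .fixture_env$cohort
}

# per-colony tracker scores against ground truth for the default cohort
cohort_tracking_scores <- function() {
  if (is.null(.fixture_env$scores)) {
    ch <- default_cohort()
    .fixture_env$scores <- dplyr::bind_rows(lapply(ch$sims, function(s) {
      sub <- list(
        nodes = dplyr::filter(ch$forest$nodes, colony_id == s$colony_id),
        frame_map = dplyr::filter(ch$forest$frame_map, colony_id == s$colony_id),
        events = dplyr::filter(ch$forest$events, colony_id == s$colony_id),
        params = ch$forest$params
      )
      class(sub) <- "lineage_forest"
      evaluate_tracking(sub, s)
    }), .id = "colony_id")
  }
  .fixture_env$scores
}

# quick toy frame-table builder: one colony, minor axis at 0.9 x equivalent
# diameter unless given
make_frames <- function(frame, label, x, y, area, colony = "c1", time_h = NULL) {
  frame_table(tibble::tibble(
    colony_id = colony, frame = frame,
    time_h = if (is.null(time_h)) frame else time_h,
    label = label, x_um = x, y_um = y, area_um2 = area,
    minor_axis_um = 0.9 * 2 * sqrt(area / pi)
  ))
}

# Brute-force matching oracle for continuation-only scenes: enumerate all
# injective prev -> next assignments among radius- and size-eligible pairs,
# maximise link count, then minimise total centroid displacement.
brute_force_continuations <- function(prev, nxt, params = tracker_params()) {
  radius <- params$radius_multiplier * sqrt(prev$area_um2 / pi)
  elig <- list()
  for (i in seq_len(nrow(prev))) {
    d <- sqrt((prev$x_um[i] - nxt$x_um)^2 + (prev$y_um[i] - nxt$y_um)^2)
    ok <- d <= radius[i] & nxt$area_um2 >= prev$area_um2 / params$min_size_drop_ratio
    elig[[i]] <- which(ok)
  }
  best <- list(count = -1, dist = Inf, assign = NULL)
  n_next <- nrow(nxt)
  recurse <- function(i, used, assign, dist) {
    if (i > nrow(prev)) {
      count <- sum(!is.na(assign))
      if (count > best$count ||
          (count == best$count && dist < best$dist - 1e-12)) {
        best <<- list(count = count, dist = dist, assign = assign)
      }
      return(invisible())
    }
    recurse(i + 1L, used, c(assign, NA_integer_), dist)
    for (j in elig[[i]]) {
      if (used[j]) next
      dj <- sqrt((prev$x_um[i] - nxt$x_um[j])^2 + (prev$y_um[i] - nxt$y_um[j])^2)
      used[j] <- TRUE
      recurse(i + 1L, used, c(assign, j), dist + dj)
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, n_next), integer(0), 0)
  tibble::tibble(
    prev_label = prev$label[which(!is.na(best$assign))],
    next_label = nxt$label[best$assign[!is.na(best$assign)]]
  ) |> dplyr::arrange(prev_label)
}
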