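# Lineage reconstruction from consecutive frame tables.
#
# Cells are matched frame to frame by spatial proximity: candidates for a
# parent P are the next-frame cells within radius_multiplier times half P's
# equivalent diameter of P's centroid. A candidate of comparable size is a
# continuation of the same cell; a candidate at least min_size_drop_ratio
# times smaller in area is a division daughter. A cell unseen for up to
# max_frame_gap frames can be re-linked to its prior identity when it
# reappears; the same window bounds how far apart successive fission rounds
# may lie and still be merged into one division episode.

#' Tracker parameters
#'
#' @param radius_multiplier search radius as a multiple of half the parent's
#'   equivalent diameter `sqrt(area/pi)`.
#' @param min_size_drop_ratio minimum parent/daughter area ratio for a
#'   division call; candidates above `area(parent)/min_size_drop_ratio` are
#'   continuation-eligible instead.
#' @param max_frame_gap maximum number of consecutive missing frames before a
#'   cell is disassociated from its prior identity; also the episode window
#'   for merging successive fission rounds.
#' @param gap_radius_growth per-missing-frame multiplier on the re-link
#'   search radius (1 = no inflation).
#' @return An object of class `tracker_params`.
#' @export
tracker_params <- function(radius_multiplier = 1.5,
                           min_size_drop_ratio = 1.5,
                           max_frame_gap = 5L,
                           gap_radius_growth = 1.0) {
  stopifnot(radius_multiplier > 0, min_size_drop_ratio >= 1,
            max_frame_gap >= 0, gap_radius_growth >= 1)
  structure(
    list(radius_multiplier = radius_multiplier,
         min_size_drop_ratio = min_size_drop_ratio,
         max_frame_gap = as.integer(max_frame_gap),
         gap_radius_growth = gap_radius_growth),
    class = "tracker_params"
  )
}

# All (prev, next) candidate pairs within the parent-scaled search radius,
# classified by the size rules. radius_scale inflates per-prev radii (gap
# re-linking). Returns a tibble sorted by the deterministic greedy order.
candidate_pairs <- function(prev, nxt, params, radius_scale = NULL) {
  if (!nrow(prev) || !nrow(nxt)) {
    return(tibble::tibble(pi = integer(), ni = integer(), dist = numeric(),
                          darea = numeric(), continuation = logical(),
                          daughter = logical()))
  }
  if (is.null(radius_scale)) radius_scale <- rep(1, nrow(prev))
  radius <- params$radius_multiplier * sqrt(prev$area_um2 / pi) * radius_scale
  dx <- outer(prev$x_um, nxt$x_um, `-`)
  dy <- outer(prev$y_um, nxt$y_um, `-`)
  dmat <- sqrt(dx^2 + dy^2)
  hit <- which(dmat <= radius, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(tibble::tibble(pi = integer(), ni = integer(), dist = numeric(),
                          darea = numeric(), continuation = logical(),
                          daughter = logical()))
  }
  pi <- hit[, 1]; ni <- hit[, 2]
  a_p <- prev$area_um2[pi]; a_n <- nxt$area_um2[ni]
  # at the exact threshold ratio the drop counts as a division, so the
  # continuation condition is strict
  out <- tibble::tibble(
    pi = pi, ni = ni, dist = dmat[hit], darea = abs(a_n - a_p),
    continuation = a_n * params$min_size_drop_ratio > a_p,
    daughter = a_p / a_n >= params$min_size_drop_ratio
  )
  arrange(out, .data$dist, .data$darea, prev$label[.data$pi], nxt$label[.data$ni])
}

#' Match cells between two frames
#'
#' Greedy mutual-nearest assignment by ascending centroid distance with
#' deterministic tie-break on (distance, |area change|, labels). Each
#' next-frame cell receives at most one match; a previous-frame cell gets one
#' continuation or (exclusively) any number of division-candidate daughters.
#'
#' @param prev,nxt observations of one colony at two frames: tibbles with
#'   `label`, `x_um`, `y_um`, `area_um2`.
#' @param params a [tracker_params()].
#' @return Tibble with `prev_label`, `next_label`, `type` (`"continuation"`
#'   or `"daughter"`) and `dist`.
#' @export
link_frames <- function(prev, nxt, params = tracker_params()) {
  cand <- candidate_pairs(prev, nxt, params)
  prev_cont <- rep(FALSE, nrow(prev)); prev_dau <- rep(FALSE, nrow(prev))
  next_used <- rep(FALSE, nrow(nxt))
  keep <- integer(0); type <- character(0)
  # continuations first: the identity-preserving reading of a near match
  cc <- cand[cand$continuation, ]
  for (k in seq_len(nrow(cc))) {
    i <- cc$pi[k]; j <- cc$ni[k]
    if (prev_cont[i] || next_used[j]) next
    prev_cont[i] <- TRUE; next_used[j] <- TRUE
    keep <- c(keep, which(cand$pi == i & cand$ni == j)[1]); type <- c(type, "continuation")
  }
  dd <- cand[cand$daughter, ]
  for (k in seq_len(nrow(dd))) {
    i <- dd$pi[k]; j <- dd$ni[k]
    if (prev_cont[i] || next_used[j]) next
    prev_dau[i] <- TRUE; next_used[j] <- TRUE
    keep <- c(keep, which(cand$pi == i & cand$ni == j)[1]); type <- c(type, "daughter")
  }
  res <- cand[keep, ]
  tibble::tibble(
    prev_label = prev$label[res$pi],
    next_label = nxt$label[res$ni],
    type = type,
    dist = res$dist
  ) |> arrange(.data$prev_label, .data$next_label)
}

#' Reconstruct a lineage forest from a frame table
#'
#' Assigns persistent identities greedily frame to frame, re-links cells that
#' reappear after up to `max_frame_gap` missing frames, and records a
#' division event whenever a parent is succeeded by two or more size-dropped
#' daughters. Raw events are per observed split; merged fission episodes are
#' available via [division_episodes()].
#'
#' @param frames a frame table (possibly several colonies).
#' @param params a [tracker_params()].
#' @return An object of class `lineage_forest` with elements `nodes` (one row
#'   per persistent cell: `pid`, `colony_id`, `parent_pid`, `birth_frame`,
#'   `last_frame`), `frame_map` (per-frame label to pid), `events` (raw
#'   division events) and `params`.
#' @export
reconstruct_lineage <- function(frames, params = tracker_params()) {
  stopifnot(nrow(frames) >= 1)
  pieces <- frames |> group_by(.data$colony_id) |> group_split()
  res <- purrr::map(pieces, function(fc) track_one_colony(fc, params))
  out <- list(
    nodes = bind_rows(purrr::map(res, "nodes")),
    frame_map = bind_rows(purrr::map(res, "frame_map")),
    events = bind_rows(purrr::map(res, "events")),
    params = params
  )
  # ids are per-colony locally; make them globally unique and stable
  if (length(res) > 1L) {
    key <- paste(out$nodes$colony_id, out$nodes$pid)
    out$nodes$pid <- match(key, key)
    fm_key <- paste(out$frame_map$colony_id, out$frame_map$pid)
    out$frame_map$pid <- match(fm_key, key)
    par_key <- paste(out$nodes$colony_id, bind_rows(purrr::map(res, "nodes"))$parent_pid)
    out$nodes$parent_pid <- match(par_key, key)
    ev_key <- paste(out$events$colony_id, out$events$parent_pid)
    out$events$parent_pid <- match(ev_key, key)
    out$events$daughter_pids <- purrr::map2(
      out$events$daughter_pids, out$events$colony_id,
      function(d, cid) match(paste(cid, d), key)
    )
  }
  class(out) <- "lineage_forest"
  out
}

track_one_colony <- function(fc, params) {
  cid <- fc$colony_id[1]
  fids <- sort(unique(fc$frame))
  if (any(diff(fids) <= 0)) stop("non-monotone frame indices")
  by_frame <- split(fc, fc$frame)[as.character(fids)]

  # active-track state
  tr <- tibble::tibble(pid = integer(), x_um = numeric(), y_um = numeric(),
                       area_um2 = numeric(), label = integer(),
                       last_frame = integer(), divided = logical())
  nodes <- tibble::tibble(pid = integer(), parent_pid = integer(),
                          birth_frame = integer(), last_frame = integer())
  fmap <- list(); events <- list()
  next_pid <- 1L

  new_node <- function(parent, frame) {
    nodes <<- bind_rows(nodes, tibble::tibble(
      pid = next_pid, parent_pid = parent, birth_frame = frame,
      last_frame = frame))
    next_pid <<- next_pid + 1L
    next_pid - 1L
  }

  for (fi in seq_along(fids)) {
    f <- fids[fi]
    nxt <- by_frame[[fi]]
    eligible <- tr[!tr$divided & (f - tr$last_frame) <= params$max_frame_gap + 1L, ]
    gap <- pmax(0L, f - eligible$last_frame - 1L)
    cand <- candidate_pairs(eligible, nxt, params,
                            radius_scale = params$gap_radius_growth^gap)
    # prefer recently seen tracks at equal distance
    if (nrow(cand)) {
      cand <- arrange(cand, .data$dist, gap[.data$pi], .data$darea,
                      eligible$label[.data$pi], nxt$label[.data$ni])
    }

    prev_cont <- rep(FALSE, nrow(eligible))
    prev_dau_of <- vector("list", nrow(eligible))
    next_pid_assigned <- rep(NA_integer_, nrow(nxt))
    next_parent_row <- rep(NA_integer_, nrow(nxt))

    cc <- cand[cand$continuation, ]
    for (k in seq_len(nrow(cc))) {
      i <- cc$pi[k]; j <- cc$ni[k]
      if (prev_cont[i] || length(prev_dau_of[[i]]) || !is.na(next_pid_assigned[j])) next
      prev_cont[i] <- TRUE
      next_pid_assigned[j] <- eligible$pid[i]
    }
    dd <- cand[cand$daughter, ]
    for (k in seq_len(nrow(dd))) {
      i <- dd$pi[k]; j <- dd$ni[k]
      if (prev_cont[i] || !is.na(next_pid_assigned[j])) next
      next_parent_row[j] <- i
      prev_dau_of[[i]] <- c(prev_dau_of[[i]], j)
      next_pid_assigned[j] <- -1L # placeholder until node created
    }

    # daughters and division events
    for (i in which(lengths(prev_dau_of) > 0)) {
      js <- prev_dau_of[[i]]
      dpids <- vapply(js, function(j) new_node(eligible$pid[i], f), integer(1))
      next_pid_assigned[js] <- dpids
      m <- length(dpids)
      if (m >= 2L) {
        events[[length(events) + 1L]] <- tibble::tibble(
          colony_id = cid, parent_pid = eligible$pid[i],
          onset_frame = eligible$last_frame[i],
          parent_area_um2 = eligible$area_um2[i],
          daughter_pids = list(dpids), n_daughters = m,
          n_rounds = floor(log2(m)),
          flagged = log2(m) != floor(log2(m))
        )
      }
      tr$divided[match(eligible$pid[i], tr$pid)] <- TRUE
    }

    # brand-new cells (no parent found)
    for (j in which(is.na(next_pid_assigned))) {
      next_pid_assigned[j] <- new_node(NA_integer_, f)
    }

    # update / append track state
    upd <- tibble::tibble(
      pid = next_pid_assigned, x_um = nxt$x_um, y_um = nxt$y_um,
      area_um2 = nxt$area_um2, label = nxt$label, last_frame = f,
      divided = FALSE
    )
    tr <- bind_rows(tr[!tr$pid %in% upd$pid, ], upd)
    nodes$last_frame[match(upd$pid, nodes$pid)] <-
      pmax(nodes$last_frame[match(upd$pid, nodes$pid)], f)

    fmap[[length(fmap) + 1L]] <- tibble::tibble(
      colony_id = cid, frame = f, time_h = nxt$time_h,
      label = nxt$label, pid = next_pid_assigned,
      x_um = nxt$x_um, y_um = nxt$y_um, area_um2 = nxt$area_um2
    )
  }

  fmap <- bind_rows(fmap)
  events <- if (length(events)) bind_rows(events) else tibble::tibble(
    colony_id = character(), parent_pid = integer(), onset_frame = integer(),
    parent_area_um2 = numeric(), daughter_pids = list(),
    n_daughters = integer(), n_rounds = numeric(), flagged = logical())
  if (nrow(events)) {
    tmap <- fmap |> distinct(.data$frame, .data$time_h)
    events$onset_time_h <- tmap$time_h[match(events$onset_frame, tmap$frame)]
  } else {
    events$onset_time_h <- numeric(0)
  }
  list(
    nodes = mutate(nodes, colony_id = cid, .before = 1),
    frame_map = fmap, events = events
  )
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("<lineage_forest> %d tracks, %d colonies, %d division events\n",
              nrow(x$nodes), dplyr::n_distinct(x$nodes$colony_id), nrow(x$events)))
  invisible(x)
}

#' Count successive divisions in one fission episode
#'
#' Starting from a raw division event, follows daughter divisions whose onset
#' lies within `max_frame_gap` frames of the split that produced them, and
#' returns the episode's round count `n = log2(terminal daughters)`. A
#' non-power-of-two terminal count (e.g. a segmentation artifact) is flagged
#' and floored.
#'
#' @param forest a [reconstruct_lineage()] result.
#' @param event one row of `forest$events`.
#' @return List with `n`, `n_daughters` (terminal count), `flagged`.
#' @export
count_successive_divisions <- function(forest, event) {
  ev <- forest$events
  terminal <- integer(0)
  frontier <- tibble::tibble(pid = event$daughter_pids[[1]],
                             from_frame = event$onset_frame)
  while (nrow(frontier)) {
    nxt <- list()
    for (k in seq_len(nrow(frontier))) {
      p <- frontier$pid[k]
      sub <- ev[ev$parent_pid == p &
                  ev$onset_frame - frontier$from_frame[k] <= forest$params$max_frame_gap, ]
      if (nrow(sub)) {
        nxt[[length(nxt) + 1L]] <- tibble::tibble(
          pid = sub$daughter_pids[[1]], from_frame = sub$onset_frame[1])
      } else {
        terminal <- c(terminal, p)
      }
    }
    frontier <- if (length(nxt)) bind_rows(nxt) else frontier[0, ]
  }
  m <- length(terminal)
  flagged <- isTRUE(event$flagged) || log2(m) != floor(log2(m))
  list(n = max(1L, floor(log2(m))), n_daughters = m, flagged = flagged)
}

#' Merge raw division events into fission episodes
#'
#' An episode starts at a division whose parent is not itself an
#' within-window daughter of an earlier division, and accumulates all
#' descendant splits within `max_frame_gap` frames of the round that produced
#' their parent. Episode rows carry the root parent's pre-division (last
#' observed) area and the terminal daughter count.
#'
#' @param forest a [reconstruct_lineage()] result.
#' @return Tibble: `colony_id`, `root_pid`, `onset_frame`, `onset_time_h`,
#'   `parent_area_um2`, `n_daughters`, `n_rounds`, `flagged`.
#' @export
division_episodes <- function(forest) {
  ev <- forest$events
  if (!nrow(ev)) {
    return(tibble::tibble(colony_id = character(), root_pid = integer(),
                          onset_frame = integer(), onset_time_h = numeric(),
                          parent_area_um2 = numeric(), n_daughters = integer(),
                          n_rounds = numeric(), flagged = logical()))
  }
  # roots: parents that are not themselves a within-window daughter of an
  # earlier split (the creating split lists parent_pid among its daughters)
  creator_onset <- purrr::map_dbl(ev$parent_pid, function(p) {
    w <- which(purrr::map_lgl(ev$daughter_pids, function(d) p %in% d))
    if (length(w)) ev$onset_frame[w[1]] else NA_real_
  })
  is_root <- is.na(creator_onset) |
    (ev$onset_frame - creator_onset > forest$params$max_frame_gap)
  roots <- which(is_root)
  out <- purrr::map(roots, function(k) {
    cnt <- count_successive_divisions(forest, ev[k, ])
    tibble::tibble(
      colony_id = ev$colony_id[k], root_pid = ev$parent_pid[k],
      onset_frame = ev$onset_frame[k], onset_time_h = ev$onset_time_h[k],
      parent_area_um2 = ev$parent_area_um2[k],
      n_daughters = cnt$n_daughters, n_rounds = cnt$n, flagged = cnt$flagged
    )
  })
  bind_rows(out)
}

#' Score tracker links against simulator ground truth
#'
#' Compares observation-level parent-to-daughter edges: an edge is identified
#' by the parent's last observation and the child's first observation
#' ((frame, label) pairs), computed identically for the tracker forest and
#' for the simulator's collapsed truth links.
#'
#' @param forest a [reconstruct_lineage()] result on `sim$frames`.
#' @param sim a `sim_colony` from [simulate_colony()].
#' @return Tibble with `n_truth`, `n_tracked`, `tp`, `precision`, `recall`,
#'   `f1`.
#' @export
evaluate_tracking <- function(forest, sim) {
  fm <- forest$frame_map
  nodes <- forest$nodes |> filter(!is.na(.data$parent_pid))
  key_first <- fm |> group_by(.data$pid) |>
    slice_min(.data$frame, n = 1, with_ties = FALSE) |> ungroup()
  key_last <- fm |> group_by(.data$pid) |>
    slice_max(.data$frame, n = 1, with_ties = FALSE) |> ungroup()
  tracked <- nodes |>
    left_join(select(key_first, "pid", child_frame = "frame", child_label = "label"),
              by = "pid") |>
    left_join(select(key_last, "pid", parent_frame = "frame", parent_label = "label"),
              by = c(parent_pid = "pid")) |>
    mutate(key = paste(.data$colony_id, .data$parent_frame, .data$parent_label,
                       .data$child_frame, .data$child_label))

  obs <- sim$obs
  t_first <- obs |> group_by(.data$cell_id) |>
    slice_min(.data$frame, n = 1, with_ties = FALSE) |> ungroup()
  t_last <- obs |> group_by(.data$cell_id) |>
    slice_max(.data$frame, n = 1, with_ties = FALSE) |> ungroup()
  truth <- sim$obs_links |>
    left_join(select(t_first, "cell_id", child_frame = "frame", child_label = "label"),
              by = c(child_id = "cell_id")) |>
    left_join(select(t_last, "cell_id", parent_frame = "frame", parent_label = "label"),
              by = c(parent_id = "cell_id")) |>
    mutate(key = paste(sim$colony_id, .data$parent_frame, .data$parent_label,
                       .data$child_frame, .data$child_label))

  tp <- sum(tracked$key %in% truth$key)
  tibble::tibble(
    n_truth = nrow(truth), n_tracked = nrow(tracked), tp = tp,
    precision = if (nrow(tracked)) tp / nrow(tracked) else NA_real_,
    recall = if (nrow(truth)) tp / nrow(truth) else NA_real_
  ) |> mutate(f1 = 2 * .data$precision * .data$recall /
                (.data$precision + .data$recall))
}
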