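# Agent-based generator of synthetic planar microcolonies with ground truth.
#
# Cells are disks growing exponentially in area while the light is on (and at
# a small fraction of that rate in the dark). Division commitment follows the
# measured size dependence of the mitotic rate: cells at or above the
# commitment threshold are fully committed, while at each lights-off an
# uncommitted cell enters that night's division round with probability
# ramping linearly from 0 at the division target to 1 at the commitment
# threshold. Division executes 1..n_max binary fission rounds anchored to the
# light-to-dark transition, the round count set by a mitotic sizer
# n = ceil(log2(area / A_div_target)). Crowding (residual disk overlap after
# mechanical relaxation) slows growth, which produces the centre-to-edge
# phase lag seen in confined colonies; a gel-stiffness factor scales growth
# down and delays division past the light-dark transition.

#' Simulation configuration
#'
#' @param seed RNG seed (integer).
#' @param duration_h simulated duration in hours.
#' @param frame_interval_h imaging interval in hours.
#' @param schedule a [light_schedule()].
#' @param n_founders number of founder cells.
#' @param mu0 base exponential growth rate in the light, per hour.
#' @param dark_growth_frac multiplier on `mu0` in the dark (heterotrophic
#'   acetate growth is slower but nonzero).
#' @param A_birth_um2 founder / mean daughter area, um^2.
#' @param A_commit_um2 commitment (primary-arrest) area threshold, um^2.
#' @param A_div_target_um2 mitotic-sizer division target A_d, um^2.
#' @param n_max maximum number of fission rounds per episode.
#' @param sm_round_h duration of one S/M fission round, hours.
#' @param gel_factor stiffness multiplier s in (0, 1] on growth; 1
#'   corresponds to the softest (0.5 percent) gel.
#' @param delay_scale_h mean post-transition division delay at full
#'   stiffness, hours; the realised mean is `delay_scale_h * (1 -
#'   gel_factor) * h(area)` with `h(A) = clamp(A_commit / A, 0.2, 1)`, so
#'   larger committed cells divide earlier.
#' @param crowding_kappa growth penalty per unit local overlap fraction.
#' @param noise lognormal-type sd applied to growth exponents, division
#'   delays and daughter-area partitions. Zero gives a fully deterministic
#'   trajectory.
#' @param placement_jitter_um positional jitter for newborn daughters, um.
#' @param relax_iterations,relax_step_frac mechanical relaxation sweeps per
#'   internal step and displacement fraction per sweep; fewer sweeps leave
#'   residual overlap, i.e. persistent crowding in the colony interior.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_h = 120,
                       frame_interval_h = 1.0,
                       schedule = light_schedule(),
                       n_founders = 1L,
                       mu0 = 0.07,
                       dark_growth_frac = 0.15,
                       A_birth_um2 = 32,
                       A_commit_um2 = 75,
                       A_div_target_um2 = 35,
                       n_max = 5L,
                       sm_round_h = 0.6,
                       gel_factor = 1.0,
                       delay_scale_h = 4,
                       crowding_kappa = 1.0,
                       noise = 0.05,
                       placement_jitter_um = 0.5,
                       relax_iterations = 6L,
                       relax_step_frac = 0.4) {
  cfg <- list(
    seed = as.integer(seed), duration_h = duration_h,
    frame_interval_h = frame_interval_h, schedule = schedule,
    n_founders = as.integer(n_founders), mu0 = mu0,
    dark_growth_frac = dark_growth_frac, A_birth_um2 = A_birth_um2,
    A_commit_um2 = A_commit_um2, A_div_target_um2 = A_div_target_um2,
    n_max = as.integer(n_max), sm_round_h = sm_round_h,
    gel_factor = gel_factor, delay_scale_h = delay_scale_h,
    crowding_kappa = crowding_kappa, noise = noise,
    placement_jitter_um = placement_jitter_um,
    relax_iterations = as.integer(relax_iterations),
    relax_step_frac = relax_step_frac
  )
  stopifnot(
    inherits(schedule, "light_schedule"),
    duration_h > 0, frame_interval_h > 0, cfg$n_founders >= 1L,
    mu0 >= 0, dark_growth_frac >= 0, A_birth_um2 > 0, A_commit_um2 > 0,
    A_div_target_um2 > 0, cfg$n_max >= 1L, sm_round_h > 0,
    gel_factor > 0, gel_factor <= 1, delay_scale_h >= 0,
    crowding_kappa >= 0, noise >= 0, placement_jitter_um >= 0
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %g h @ %g h/frame, seed %d\n",
    "  growth: mu0 %.3g/h (dark x%.2g), gel factor %.2g, crowding kappa %.2g\n",
    "  sizer: commit %.3g um2, A_d %.3g um2, n <= %d, S/M round %.2g h\n"),
    x$duration_h, x$frame_interval_h, x$seed, x$mu0, x$dark_growth_frac,
    x$gel_factor, x$crowding_kappa, x$A_commit_um2, x$A_div_target_um2,
    x$n_max, x$sm_round_h))
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names mirror [sim_config()]; `schedule` may be given as a nested
#' map of `period_h`, `light_h`, `phase_offset_h`.
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$schedule)) {
    vals$schedule <- do.call(light_schedule, vals$schedule)
  }
  do.call(sim_config, vals)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

mu_effective <- function(light, local_overlap, config) {
  config$mu0 * config$gel_factor *
    ifelse(light, 1, config$dark_growth_frac) *
    pmax(0, 1 - config$crowding_kappa * local_overlap)
}

#' Grow a cell over one time step
#'
#' Multiplicative-exponential growth `area <- area * exp(mu_eff * dt * (1 +
#' noise * z))` with `mu_eff = mu0 * gel_factor * (light ? 1 :
#' dark_growth_frac) * max(0, 1 - crowding_kappa * local_overlap)`. Marks the
#' cell committed once its area reaches the commitment threshold.
#'
#' @param cell list or one-row tibble with at least `area_um2` and
#'   `committed`.
#' @param dt step length, hours (> 0).
#' @param light logical light indicator.
#' @param local_overlap crowding proxy (>= 0), see [relax_overlaps()].
#' @param config a [sim_config()].
#' @param noise_z optional standard-normal draw; defaults to a fresh draw
#'   when `config$noise > 0`.
#' @return The updated cell (same shape as input).
#' @export
grow_step <- function(cell, dt, light, local_overlap, config, noise_z = NULL) {
  stopifnot(dt > 0, local_overlap >= 0)
  if (is.null(noise_z)) noise_z <- if (config$noise > 0) rnorm(1) else 0
  mu <- mu_effective(light, local_overlap, config)
  cell$area_um2 <- cell$area_um2 * exp(mu * dt * (1 + config$noise * noise_z))
  cell$committed <- isTRUE(cell$committed) || cell$area_um2 >= config$A_commit_um2
  cell
}

#' Schedule the division time of a committed cell
#'
#' Division anchors to the light-to-dark transition of the cycle in which
#' commitment happens: a cell committing during the light phase divides at
#' the next transition, while a cell crossing the threshold during the dark
#' phase (divisions extend hours past lights-off) divides immediately within
#' the same night. On top of the anchor comes a nonnegative delay with mean
#' `delay_scale_h * (1 - gel_factor) * h(area)` where `h(A) = clamp(A_commit
#' / A, 0.2, 1)`: stiffer gels delay division, larger cells divide earlier.
#' Uncommitted cells return `NULL`.
#'
#' @inheritParams grow_step
#' @param t_now current time, hours.
#' @param schedule a [light_schedule()].
#' @return Division time in hours, or `NULL` for an uncommitted cell.
#' @export
schedule_division <- function(cell, t_now, schedule, config, noise_z = NULL) {
  if (!isTRUE(cell$committed)) return(NULL)
  first_off <- schedule$phase_offset_h + schedule$light_h
  if (is_light(schedule, t_now)) {
    k <- ceiling((t_now - first_off) / schedule$period_h)
  } else {
    k <- floor((t_now - first_off) / schedule$period_h)
  }
  t_ld <- first_off + k * schedule$period_h
  h <- clamp(config$A_commit_um2 / cell$area_um2, 0.2, 1)
  mean_delta <- config$delay_scale_h * (1 - config$gel_factor) * h
  if (mean_delta > 0 && config$noise > 0) {
    if (is.null(noise_z)) noise_z <- rnorm(1)
    # mean-one lognormal multiplier keeps E[delta] = mean_delta
    mean_delta <- mean_delta * exp(config$noise * noise_z - config$noise^2 / 2)
  }
  max(t_ld + mean_delta, t_now)
}

sizer_rounds <- function(area, config) {
  as.integer(clamp(ceiling(log2(area / config$A_div_target_um2)), 1, config$n_max))
}

#' Divide a committed cell into 2^n daughters
#'
#' The mitotic sizer sets `n = clamp(ceil(log2(area / A_div_target)), 1,
#' n_max)`. Daughter areas are the parent area split into 2^n parts with
#' symmetric noise, renormalised so they sum exactly to the parent area;
#' daughters are placed within one parent radius of the parent centroid with
#' jitter. (Inside [simulate_colony()] the same episode is executed as
#' successive binary rounds `sm_round_h` apart, so fission can straddle frame
#' snapshots.)
#'
#' @param cell list or one-row tibble with `area_um2`, `x_um`, `y_um`,
#'   `committed`.
#' @param config a [sim_config()].
#' @return Tibble of 2^n daughter cells (`x_um`, `y_um`, `area_um2`).
#' @export
divide_cell <- function(cell, config) {
  stopifnot(isTRUE(cell$committed))
  n <- sizer_rounds(cell$area_um2, config)
  m <- 2L^n
  w <- rep(1, m)
  if (config$noise > 0) w <- pmax(0.2, 1 + config$noise * rnorm(m))
  areas <- cell$area_um2 * w / sum(w)
  r_parent <- sqrt(cell$area_um2 / pi)
  ang <- 2 * pi * (seq_len(m) - 1) / m + runif(1, 0, 2 * pi)
  d <- runif(m, 0, 0.6 * r_parent)
  tibble::tibble(
    x_um = cell$x_um + d * cos(ang) + config$placement_jitter_um * rnorm(m),
    y_um = cell$y_um + d * sin(ang) + config$placement_jitter_um * rnorm(m),
    area_um2 = areas
  )
}

#' Relax overlapping disk cells apart
#'
#' Iteratively separates overlapping disk pairs along their centre line by
#' `step_frac` times the overlap depth, split equally between the pair (the
#' unweighted colony centroid is preserved). Returns updated positions plus a
#' per-cell residual overlap fraction, the crowding proxy consumed by
#' [grow_step()].
#'
#' @param cells tibble with `x_um`, `y_um`, `area_um2` (radius =
#'   sqrt(area/pi)).
#' @param iterations relaxation sweeps.
#' @param step_frac displacement fraction per sweep, in (0, 1].
#' @return `cells` with updated `x_um`, `y_um` and a new `overlap` column.
#' @export
relax_overlaps <- function(cells, iterations = 50L, step_frac = 0.5) {
  stopifnot(all(cells$area_um2 > 0), iterations >= 0, step_frac > 0)
  r <- sqrt(cells$area_um2 / pi)
  res <- relax_overlaps_cpp(cells$x_um, cells$y_um, r,
                            as.integer(iterations), step_frac)
  cells$x_um <- res$x
  cells$y_um <- res$y
  cells$overlap <- res$overlap
  cells
}

#' Simulate one microcolony
#'
#' Runs founder cells forward with an internal step of at most `sm_round_h`,
#' emitting a frame-table snapshot at every imaging interval and recording
#' full ground truth: every binary fission link, observation-level collapsed
#' links (for tracker evaluation), and division episodes (root parent, onset,
#' pre-division area, round count). Commitment combines the hard threshold
#' (area >= `A_commit_um2` commits unconditionally) with the sub-threshold
#' mitotic-rate ramp: at each lights-off an uncommitted cell joins that
#' night's division with probability `(area - A_div_target) / (A_commit -
#' A_div_target)`, clamped to [0, 1]. Reproducible: identical config and seed
#' give identical output.
#'
#' @param config a [sim_config()].
#' @param colony_id identifier stamped on all frames.
#' @return An object of class `sim_colony`: list with elements `frames`
#'   (frame table), `obs` (frame, label, cell_id ground-truth map), `nodes`,
#'   `links`, `obs_links`, `events` (each binary split), `episodes`, and
#'   `config`.
#' @export
simulate_colony <- function(config, colony_id = "colony1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sched <- config$schedule

  n_sub <- max(1L, ceiling(config$frame_interval_h / config$sm_round_h))
  dt <- config$frame_interval_h / n_sub
  frame_times <- seq(0, config$duration_h, by = config$frame_interval_h)

  # state-of-the-colony vectors, indexed by cell id
  cap <- 256L
  id <- integer(0); parent <- integer(0)
  x <- numeric(0); y <- numeric(0); area <- numeric(0)
  committed <- logical(0); div_time <- numeric(0); rounds_left <- integer(0)
  commit_t <- numeric(0)
  eccf <- numeric(0); birth_t <- numeric(0); death_t <- numeric(0)
  alive <- logical(0); overlap <- numeric(0)

  add_cells <- function(par, xs, ys, areas, t, rl, dv) {
    m <- length(xs)
    ids <- length(id) + seq_len(m)
    id <<- c(id, ids); parent <<- c(parent, rep(par, m))
    x <<- c(x, xs); y <<- c(y, ys); area <<- c(area, areas)
    committed <<- c(committed, rep(FALSE, m))
    commit_t <<- c(commit_t, rep(NA_real_, m))
    div_time <<- c(div_time, rep(dv, m))
    rounds_left <<- c(rounds_left, rep(rl, m))
    eccf <<- c(eccf, runif(m, 0.8, 1.0))
    birth_t <<- c(birth_t, rep(t, m)); death_t <<- c(death_t, rep(NA_real_, m))
    alive <<- c(alive, rep(TRUE, m)); overlap <<- c(overlap, rep(0, m))
    ids
  }

  # founders around the origin
  f_area <- config$A_birth_um2 *
    (if (config$noise > 0) exp(config$noise * rnorm(config$n_founders)) else rep(1, config$n_founders))
  f_ang <- runif(config$n_founders, 0, 2 * pi)
  f_d <- if (config$n_founders > 1) 2 * sqrt(max(f_area) / pi) * sqrt(seq_len(config$n_founders)) else 0
  add_cells(NA_integer_, f_d * cos(f_ang), f_d * sin(f_ang), f_area,
            0, 0L, NA_real_)

  events <- list(); episodes <- list(); obs <- list()

  snapshot <- function(fi, t) {
    w <- which(alive)
    w <- w[order(id[w])]
    lab <- seq_along(w)
    obs[[length(obs) + 1L]] <<- tibble::tibble(
      frame = fi, time_h = t, label = lab, cell_id = id[w],
      x_um = x[w], y_um = y[w], area_um2 = area[w],
      minor_axis_um = 2 * sqrt(area[w] / pi) * eccf[w]
    )
  }

  split_one <- function(i, t_split) {
    if (rounds_left[i] == 0L) {
      n <- sizer_rounds(area[i], config)
      episodes[[length(episodes) + 1L]] <<- tibble::tibble(
        parent_id = id[i], onset_time_h = t_split,
        parent_area_um2 = area[i], n_rounds = n, n_daughters = 2L^n
      )
      rl <- n - 1L
    } else {
      rl <- rounds_left[i] - 1L
    }
    w <- 0.5
    if (config$noise > 0) w <- clamp(0.5 * (1 + config$noise * rnorm(1)), 0.3, 0.7)
    a2 <- area[i] * c(w, 1 - w)
    r_par <- sqrt(area[i] / pi)
    ang <- runif(1, 0, 2 * pi)
    off <- runif(1, 0.3, 0.6) * r_par
    jit <- config$placement_jitter_um * rnorm(4)
    ids <- add_cells(
      id[i],
      x[i] + c(off * cos(ang) + jit[1], -off * cos(ang) + jit[2]),
      y[i] + c(off * sin(ang) + jit[3], -off * sin(ang) + jit[4]),
      a2, t_split, rl,
      if (rl > 0L) t_split + config$sm_round_h else NA_real_
    )
    alive[i] <<- FALSE
    death_t[i] <<- t_split
    events[[length(events) + 1L]] <<- tibble::tibble(
      parent_id = id[i], time_h = t_split, parent_area_um2 = area[i],
      daughter_ids = list(ids), daughter_areas = list(a2)
    )
  }

  snapshot(0L, 0)
  t <- 0
  step_i <- 0L
  while (t < config$duration_h - 1e-9) {
    te <- t + dt
    step_i <- step_i + 1L
    light <- is_light(sched, (t + te) / 2)

    # G1 / committed-pre-fission growth (cells mid-fission do not grow)
    g <- which(alive & rounds_left == 0L & is.na(div_time))
    gc <- which(alive & rounds_left == 0L & !is.na(div_time)) # committed, scheduled
    grow_idx <- c(g, gc)
    if (length(grow_idx)) {
      z <- if (config$noise > 0) rnorm(length(grow_idx)) else numeric(length(grow_idx))
      mu <- mu_effective(light, overlap[grow_idx], config)
      area[grow_idx] <- area[grow_idx] * exp(mu * dt * (1 + config$noise * z))
      newc <- grow_idx[!committed[grow_idx] &
                         area[grow_idx] >= config$A_commit_um2]
      committed[newc] <- TRUE
      commit_t[newc] <- te
    }

    # at lights-off, uncommitted cells join the night's division round with
    # probability ramping linearly in area between A_div_target and A_commit
    # (the measured size dependence of the mitotic rate below the threshold)
    if (length(ld12_transitions(sched, t + 1e-9, te + 1e-9))) {
      fac <- which(alive & !committed & rounds_left == 0L & is.na(div_time))
      if (length(fac)) {
        p <- clamp((area[fac] - config$A_div_target_um2) /
                     (config$A_commit_um2 - config$A_div_target_um2), 0, 1)
        newc <- fac[runif(length(fac)) < p]
        committed[newc] <- TRUE
        commit_t[newc] <- te
      }
    }

    # newly committed cells get a division time anchored to this cycle's LD
    # transition
    ns <- which(alive & committed & rounds_left == 0L & is.na(div_time))
    for (i in ns) {
      div_time[i] <- schedule_division(
        list(area_um2 = area[i], committed = TRUE), te, sched, config
      )
    }

    # fission rounds due by the end of this step, in time order
    repeat {
      due <- which(alive & !is.na(div_time) & div_time <= te + 1e-9)
      if (!length(due)) break
      due <- due[order(div_time[due], id[due])]
      split_one(due[1L], div_time[due[1L]])
    }

    # mechanical relaxation + crowding measurement
    w <- which(alive)
    if (length(w) > 1L) {
      res <- relax_overlaps_cpp(x[w], y[w], sqrt(area[w] / pi),
                                config$relax_iterations, config$relax_step_frac)
      x[w] <- res$x; y[w] <- res$y; overlap[w] <- res$overlap
    } else {
      overlap[w] <- 0
    }

    if (step_i %% n_sub == 0L) snapshot(step_i %/% n_sub, te)
    t <- te
  }

  obs <- bind_rows(obs)
  frames <- frame_table(
    tibble::tibble(
      colony_id = colony_id, frame = obs$frame, time_h = obs$time_h,
      label = obs$label, x_um = obs$x_um, y_um = obs$y_um,
      area_um2 = obs$area_um2, minor_axis_um = obs$minor_axis_um
    ),
    frame_interval_h = config$frame_interval_h
  )
  nodes <- tibble::tibble(
    cell_id = id, parent_id = parent,
    birth_time_h = birth_t, death_time_h = death_t,
    commit_time_h = commit_t
  )
  links <- nodes |> filter(!is.na(.data$parent_id)) |>
    select(child_id = "cell_id", parent_id = "parent_id",
           birth_time_h = "birth_time_h")
  events <- bind_rows(events)
  episodes <- if (length(episodes)) bind_rows(episodes) else
    tibble::tibble(parent_id = integer(), onset_time_h = numeric(),
                   parent_area_um2 = numeric(), n_rounds = integer(),
                   n_daughters = integer())

  out <- list(
    frames = frames, obs = mutate(obs, colony_id = colony_id, .before = 1),
    nodes = nodes, links = links,
    obs_links = collapse_truth_links(nodes, obs),
    events = events, episodes = annotate_episode_frames(episodes, obs),
    config = config, colony_id = colony_id
  )
  class(out) <- "sim_colony"
  out
}

# Collapse ground-truth links through cells that never appear in a snapshot
# (fission rounds completing between frames), so each observed cell is linked
# to its nearest observed ancestor: the correspondence a tracker working on
# the frame tables alone could possibly recover.
collapse_truth_links <- function(nodes, obs) {
  observed <- unique(obs$cell_id)
  parent_of <- nodes$parent_id[match(seq_len(nrow(nodes)), nodes$cell_id)]
  obs_anc <- function(i) {
    p <- parent_of[i]
    while (!is.na(p) && !(p %in% observed)) p <- parent_of[p]
    p
  }
  kids <- intersect(nodes$cell_id[!is.na(nodes$parent_id)], observed)
  anc <- vapply(kids, obs_anc, NA_integer_)
  keep <- !is.na(anc)
  first_obs <- obs |> group_by(.data$cell_id) |>
    summarise(first_frame = min(.data$frame), .groups = "drop")
  last_obs <- obs |> group_by(.data$cell_id) |>
    summarise(last_frame = max(.data$frame), .groups = "drop")
  tibble::tibble(child_id = kids[keep], parent_id = anc[keep]) |>
    left_join(first_obs, by = c(child_id = "cell_id")) |>
    left_join(last_obs, by = c(parent_id = "cell_id")) |>
    rename(child_first_frame = "first_frame", parent_last_frame = "last_frame")
}

annotate_episode_frames <- function(episodes, obs) {
  if (!nrow(episodes)) {
    episodes$onset_frame <- integer(0)
    return(episodes)
  }
  last_obs <- obs |> group_by(.data$cell_id) |>
    summarise(onset_frame = max(.data$frame), .groups = "drop")
  left_join(episodes, last_obs, by = c(parent_id = "cell_id"))
}

#' @export
print.sim_colony <- function(x, ...) {
  cat(sprintf(
    "<sim_colony> '%s': %d frames, %d cells total, %d fission rounds, %d episodes\n",
    x$colony_id, dplyr::n_distinct(x$frames$frame), nrow(x$nodes),
    nrow(x$events), nrow(x$episodes)))
  invisible(x)
}

#' Simulate several colonies with derived seeds
#'
#' @param n_colonies number of colonies.
#' @param config base [sim_config()]; colony k runs with seed
#'   `config$seed + k - 1`.
#' @return List of `sim_colony` objects named by colony id. Combine their
#'   frame tables with [bind_sim_frames()].
#' @export
simulate_colonies <- function(n_colonies, config = sim_config()) {
  purrr::map(seq_len(n_colonies), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    simulate_colony(cfg, colony_id = sprintf("colony%02d", k))
  }) |> setNames(sprintf("colony%02d", seq_len(n_colonies)))
}

#' Bind the frame tables of several simulated colonies
#'
#' @param sims list of `sim_colony` objects (from [simulate_colonies()]).
#' @return One frame table covering all colonies.
#' @export
bind_sim_frames <- function(sims) {
  out <- bind_rows(purrr::map(sims, "frames"))
  attr(out, "frame_interval_h") <- attr(sims[[1]]$frames, "frame_interval_h")
  out
}
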