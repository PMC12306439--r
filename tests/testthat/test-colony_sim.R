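test_that("growth steps follow the exponential law with crowding and light gating", {
  cfg <- sim_config(noise = 0)
  cell <- list(area_um2 = 30, committed = FALSE)
  # full-rate growth over 22 h reproduces the 30 -> ~140 um2 trajectory
  g <- grow_step(cell, dt = 22, light = TRUE, local_overlap = 0, cfg)
  expect_equal(g$area_um2, 30 * exp(0.07 * 22), tolerance = 1e-12)
  expect_true(g$committed) # crossed the 75 um2 threshold
  # dark with zero dark growth: unchanged
  cfg0 <- sim_config(noise = 0, dark_growth_frac = 0)
  g0 <- grow_step(cell, dt = 5, light = FALSE, local_overlap = 0, cfg0)
  expect_equal(g0$area_um2, 30)
  # crowding floor: kappa * overlap >= 1 freezes growth
  gf <- grow_step(cell, dt = 5, light = TRUE, local_overlap = 1.2, cfg)
  expect_equal(gf$area_um2, 30)
})

test_that("division scheduling anchors to the cycle's light-dark transition", {
  sch <- light_schedule()
  # committed in the light at full stiffness: exactly at the next transition
  cfg <- sim_config(noise = 0)
  expect_equal(schedule_division(list(area_um2 = 80, committed = TRUE), 5, sch, cfg), 12)
  # uncommitted: no division time
  expect_null(schedule_division(list(area_um2 = 80, committed = FALSE), 5, sch, cfg))
  # gel 0.5, delay scale 4, area at threshold: delta = 4 * 0.5 * 1 = 2 h
  cfg2 <- sim_config(noise = 0, gel_factor = 0.5, delay_scale_h = 4)
  expect_equal(
    schedule_division(list(area_um2 = cfg2$A_commit_um2, committed = TRUE), 5, sch, cfg2),
    14)
  # committing in the dark divides within the same night, not a day later
  expect_equal(schedule_division(list(area_um2 = 80, committed = TRUE), 13.2, sch, cfg), 13.2)
  expect_equal(schedule_division(list(area_um2 = 80, committed = TRUE), 25, sch, cfg), 36)
})

test_that("the mitotic sizer divides committed cells into 2^n equal daughters", {
  cfg <- sim_config(noise = 0)
  d60 <- divide_cell(list(area_um2 = 60, x_um = 0, y_um = 0, committed = TRUE), cfg)
  expect_equal(nrow(d60), 2)
  expect_equal(d60$area_um2, c(30, 30))
  d90 <- divide_cell(list(area_um2 = 90, x_um = 0, y_um = 0, committed = TRUE), cfg)
  expect_equal(nrow(d90), 4)
  expect_equal(d90$area_um2, rep(22.5, 4))
  # at the target exactly: clipped to one round
  d35 <- divide_cell(list(area_um2 = 35, x_um = 0, y_um = 0, committed = TRUE), cfg)
  expect_equal(nrow(d35), 2)
  # with noise, areas still sum exactly to the parent and stay positive
  cfgn <- sim_config(noise = 0.2, seed = 3)
  set.seed(3)
  dn <- divide_cell(list(area_um2 = 90, x_um = 0, y_um = 0, committed = TRUE), cfgn)
  expect_equal(sum(dn$area_um2), 90, tolerance = 1e-9)
  expect_true(all(dn$area_um2 > 0))
  # daughters land within one parent radius (+ jitter allowance)
  r_par <- sqrt(90 / pi)
  expect_true(all(sqrt(dn$x_um^2 + dn$y_um^2) <= r_par + 4 * cfgn$placement_jitter_um))
})

test_that("overlap relaxation separates disks and preserves the centroid", {
  two <- tibble::tibble(x_um = c(0, 12), y_um = 0, area_um2 = pi * 25)
  out <- relax_overlaps(two, iterations = 1, step_frac = 1)
  expect_equal(out$x_um, two$x_um) # no overlap: untouched
  expect_equal(out$overlap, c(0, 0))

  two$x_um <- c(0, 6) # overlap depth 4
  out <- relax_overlaps(two, iterations = 1, step_frac = 1)
  expect_equal(out$x_um[2] - out$x_um[1], 10)
  expect_equal(mean(out$x_um), 3) # symmetric displacement
  expect_equal(out$overlap, c(0, 0))

  # a stack of coincident disks fans out to near-contact spacing
  n <- 6
  stack <- tibble::tibble(x_um = rep(0, n), y_um = rep(0, n), area_um2 = pi * 4)
  out <- relax_overlaps(stack, iterations = 400, step_frac = 0.5)
  dmat <- as.matrix(dist(cbind(out$x_um, out$y_um)))
  expect_true(all(dmat[upper.tri(dmat)] >= 0.9 * 4))
  expect_equal(mean(out$x_um), 0, tolerance = 1e-8)
  expect_equal(mean(out$y_um), 0, tolerance = 1e-8)
})

test_that("a noiseless founder follows the closed-form trajectory and sizer rule", {
  cfg <- sim_config(seed = 1, noise = 0, mu0 = 0.06, A_birth_um2 = 40,
                    duration_h = 14, crowding_kappa = 0)
  sim <- simulate_colony(cfg)
  s <- compute_size_series(sim$frames)
  # A(12) = 40 exp(0.72) = 82.2 >= 75: commits and divides at LD12
  expect_equal(s$mean_area[s$frame == 11], 40 * exp(0.06 * 11), tolerance = 1e-9)
  expect_equal(nrow(sim$episodes), 1)
  expect_equal(sim$episodes$n_rounds, 2) # ceil(log2(82.2 / 35)) = 2
  expect_equal(sim$episodes$n_daughters, 4)
  expect_equal(sim$episodes$parent_area_um2, 40 * exp(0.06 * 12), tolerance = 1e-9)
  expect_equal(sim$episodes$onset_time_h, 12)
  # four daughters of ~20.5 by frame 13 (fission rounds 0.6 h apart)
  expect_equal(s$n_cells[s$frame == 13], 4)
  expect_equal(s$mean_area[s$frame == 13], 40 * exp(0.06 * 12) / 4, tolerance = 1e-9)
})

test_that("degenerate and stochastic simulations satisfy the invariants", {
  # mu0 = 0: a single constant cell in every frame
  sim0 <- simulate_colony(sim_config(seed = 2, mu0 = 0, duration_h = 30))
  s0 <- compute_size_series(sim0$frames)
  expect_true(all(s0$n_cells == 1))
  expect_equal(diff(range(s0$mean_area)), 0)

  # determinism: identical config and seed give identical output
  a <- simulate_colony(sim_config(seed = 9, duration_h = 60))
  b <- simulate_colony(sim_config(seed = 9, duration_h = 60))
  expect_identical(a$frames, b$frames)
  expect_identical(a$nodes, b$nodes)

  # area conservation at every recorded fission round
  ev <- a$events
  resid <- vapply(seq_len(nrow(ev)), function(k) {
    abs(sum(ev$daughter_areas[[k]]) - ev$parent_area_um2[k])
  }, numeric(1))
  expect_true(all(resid < 1e-9))
  # episode daughter counts are powers of two within the allowed range
  ep <- a$episodes
  expect_true(all(ep$n_daughters == 2^ep$n_rounds))
  expect_true(all(ep$n_rounds >= 1 & ep$n_rounds <= sim_config()$n_max))
})

test_that("colony growth is monotone in gel stiffness across matched seeds", {
  n110 <- vapply(c(1, 0.8, 0.6, 0.4), function(g) {
    sim <- simulate_colony(sim_config(seed = 7, gel_factor = g, duration_h = 111))
    s <- compute_size_series(sim$frames)
    as.numeric(s$n_cells[s$frame == 110])
  }, numeric(1))
  expect_true(all(diff(n110) <= 0))
})

test_that("crowding produces a nonnegative centre-to-edge commitment lag", {
  ch <- default_cohort()
  pooled <- dplyr::bind_rows(lapply(ch$sims, function(sim) {
    nd <- dplyr::filter(sim$nodes, !is.na(commit_time_h), commit_time_h >= 72)
    if (!nrow(nd)) return(NULL)
    lastobs <- sim$obs |>
      dplyr::inner_join(nd, by = "cell_id") |>
      dplyr::filter(frame <= commit_time_h) |>
      dplyr::group_by(cell_id) |>
      dplyr::slice_max(frame, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    lastobs |>
      dplyr::group_by(frame) |>
      dplyr::group_modify(function(g, k) {
        allc <- sim$obs[sim$obs$frame == k$frame, ]
        geo <- colony_geometry(allc)
        g$rel <- radial_distances(g, geo, "edge") / geo$radius
        g
      }) |>
      dplyr::ungroup()
  }))
  pooled$phase <- pooled$commit_time_h %% 24
  inner <- pooled$phase[pooled$rel > 0.5]   # deep interior
  outer <- pooled$phase[pooled$rel <= 0.25] # near the edge
  expect_gt(length(inner), 20)
  expect_gte(mean(inner) - mean(outer), 0)
})

test_that("simulation configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 4", "duration_h: 48", "mu0: 0.05", "gel_factor: 0.8",
    "schedule:", "  period_h: 24", "  light_h: 12", "  phase_offset_h: 2"
  ), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$mu0, 0.05)
  expect_equal(cfg$schedule$phase_offset_h, 2)
})
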