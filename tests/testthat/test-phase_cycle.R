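test_that("size series aggregate per-frame statistics", {
  ft <- make_frames(0, 1, 0, 0, 30)
  s <- compute_size_series(ft)
  expect_equal(s$mean_area, 30)
  expect_equal(s$se_area, 0)
  ft3 <- make_frames(0, 1:3, c(0, 10, 20), 0, c(10, 20, 30))
  s3 <- compute_size_series(ft3)
  expect_equal(s3$mean_area, 20)
  expect_equal(s3$median_area, 20)
  expect_equal(s3$se_area, sd(c(10, 20, 30)) / sqrt(3))
  expect_equal(s3$se_area, 5.7735, tolerance = 1e-4)
})

test_that("division onsets require a peak, an abrupt drop and a count step", {
  mk_series <- function(t, area, n) {
    s <- tibble::tibble(colony_id = "c1", frame = t, time_h = t,
                        mean_area = area, median_area = area,
                        se_area = 0, n_cells = n)
    class(s) <- c("size_series", class(s))
    s
  }
  # monotone series: nothing
  up <- mk_series(0:10, 30 * 1.07^(0:10), rep(1, 11))
  expect_equal(nrow(detect_division_onsets(up)), 0)
  # sawtooth peaking at 22 h, 140 -> 35 with the count stepping 1 -> 4
  t <- 0:30
  area <- c(30 * exp(0.07 * 0:22), rep(35, 8))
  n <- c(rep(1, 23), rep(4, 8))
  on <- detect_division_onsets(mk_series(t, area, n))
  expect_equal(nrow(on), 1)
  expect_equal(on$onset_time_h, 22)
  expect_gt(on$peak_area, on$valley_area)
  # a drop without a count increase is not an onset...
  flat_n <- detect_division_onsets(mk_series(t, area, rep(1, 31)))
  expect_equal(nrow(flat_n), 0)
  # ...unless the count requirement is switched off (single-cell series)
  expect_equal(nrow(detect_division_onsets(mk_series(t, area, rep(1, 31)),
                                           require_count_increase = FALSE)), 1)
  # two well-separated onsets get 1-based cycle indices in time order
  t2 <- 0:40
  area2 <- c(60, 80, rep(30, 10) * 1.07^(0:9), 30 * 1.07^(0:22) * 2.3, rep(33, 6))
  area2 <- area2[1:41]
  n2 <- c(1, 1, rep(4, 22), rep(16, 17))
  on2 <- detect_division_onsets(mk_series(t2, area2, n2), min_separation_h = 12)
  if (nrow(on2) >= 2) expect_equal(on2$cycle, seq_len(nrow(on2)))
  # the documented counting convention: onsets at 2 h and 26 h = two cycles
  t3 <- 0:30
  area3 <- c(80, 90, 45, 45 * 1.07^(0:22), rep(40, 5))[1:31]
  n3 <- c(1, 1, rep(2, 24), rep(8, 5))[1:31]
  on3 <- detect_division_onsets(mk_series(t3, area3, n3))
  expect_equal(on3$cycle, c(1, 2))
  expect_equal(on3$onset_time_h, c(1, 25))
})

test_that("onsets on simulated colonies land within one frame of true division waves", {
  ch <- default_cohort()
  series <- compute_size_series(ch$frames)
  onsets <- detect_division_onsets(series)
  hits <- vapply(seq_len(nrow(onsets)), function(k) {
    sim <- ch$sims[[onsets$colony_id[k]]]
    any(abs(sim$episodes$onset_time_h - onsets$onset_time_h[k]) <= 1)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # median spacing matches the diurnal period within one frame
  spacing <- onsets |>
    dplyr::group_by(colony_id) |>
    dplyr::reframe(d = diff(onset_time_h))
  expect_lte(abs(median(spacing$d) - 24), 1)
})

test_that("bimodal size samples split at a sensible threshold", {
  sp <- split_bimodal(c(20, 21, 22, 80, 81, 82))
  expect_false(sp$unimodal)
  expect_gt(sp$threshold, 22)
  expect_lt(sp$threshold, 80)
  expect_length(sp$daughters, 3)
  expect_length(sp$parents, 3)
  # identical values: unimodal flag, no split
  expect_true(split_bimodal(rep(50, 6))$unimodal)
  # misclassification under a well-separated mixture stays below 1 percent
  set.seed(5)
  areas <- c(rnorm(200, 30, 2), rnorm(200, 90, 5))
  truth <- rep(c("d", "p"), each = 200)
  sp2 <- split_bimodal(areas)
  miscls <- mean((areas >= sp2$threshold) != (truth == "p"))
  expect_lte(miscls, 0.01)
  # Otsu fallback behaves on the same input
  sp3 <- split_bimodal(areas, method = "otsu")
  expect_gt(sp3$threshold, 40)
  expect_lt(sp3$threshold, 80)
})

test_that("exponential growth fits are exact on noiseless data", {
  d <- tibble::tibble(time_h = 0:22, area_um2 = 30 * exp(0.07 * (0:22)))
  g <- fit_growth_rate(d)
  expect_equal(g$mu, 0.07, tolerance = 1e-12)
  expect_equal(g$A0, 30, tolerance = 1e-12)
  td <- tidy(g)
  expect_equal(td$estimate[td$term == "mu"], 0.07, tolerance = 1e-12)
  expect_equal(glance(g)$r.squared, 1)
  # constant series: mu = 0
  g0 <- fit_growth_rate(tibble::tibble(time_h = 0:5, area_um2 = rep(40, 6)))
  expect_equal(g0$mu, 0)
  expect_error(fit_growth_rate(tibble::tibble(time_h = 0:5, area_um2 = c(1, 2, -3, 4, 5, 6))),
               "non-positive")
  expect_error(fit_growth_rate(d[1:2, ]), "at least 3 points")
})

test_that("fitted growth rates decrease with gel stiffness", {
  mus <- vapply(c(1, 0.8, 0.6, 0.4), function(g) {
    sim <- simulate_colony(sim_config(seed = 21, gel_factor = g, duration_h = 60))
    s <- compute_size_series(sim$frames)
    on <- detect_division_onsets(s)
    fits <- fit_growth_by_cycle(s, on)
    fits$mu[fits$cycle == 1][1]
  }, numeric(1))
  expect_true(all(diff(mus) < 0))
})

test_that("division timing shifts are signed hours from the nearest transition", {
  sch <- light_schedule()
  ev <- tibble::tibble(onset_time_h = c(12, 14, 11, 36, 47.9),
                       n_daughters = c(2, 4, 2, 4, 8))
  sh <- division_timing_shift(ev, sch)
  expect_equal(sh$shift_h, c(0, 2, -1, 0, 11.9))
  gr <- timing_shift_summary(sh)
  expect_equal(sort(gr$n_daughters), c(2, 4, 8))
  expect_equal(gr$mean_shift_h[gr$n_daughters == 2], mean(c(0, -1)))
})

test_that("timing shifts grow as the gel stiffens", {
  shifts <- vapply(c(1, 0.6), function(g) {
    sim <- simulate_colony(sim_config(seed = 13, gel_factor = g, duration_h = 90))
    sh <- division_timing_shift(sim$episodes, light_schedule())
    mean(sh$shift_h)
  }, numeric(1))
  expect_gt(shifts[2], shifts[1])
})

test_that("colony size CV is the sample-sd over mean and scale invariant", {
  expect_equal(colony_cv(c(100, 100, 100)), 0)
  expect_equal(colony_cv(c(100, 200)), sd(c(100, 200)) / 150)
  expect_equal(colony_cv(c(100, 200)), 0.4714, tolerance = 1e-4)
  expect_equal(colony_cv(c(100, 200) * 17), colony_cv(c(100, 200)))
  expect_error(colony_cv(c(0, 0)), "mean size is zero")
  expect_error(colony_cv(100))
})
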