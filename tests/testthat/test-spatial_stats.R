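test_that("colony geometry: hull pushed out by cell radii, degenerate disk", {
  one <- make_frames(0, 1, 0, 0, pi * 9) # radius 3
  g1 <- colony_geometry(one)
  expect_equal(g1$type, "circle")
  expect_equal(unname(g1$centroid), c(0, 0))
  expect_equal(g1$radius, 3)

  cross <- make_frames(0, 1:4, c(-10, 10, 0, 0), c(0, 0, -10, 10), pi) # radius 1
  g4 <- colony_geometry(cross)
  expect_equal(g4$type, "polygon")
  expect_equal(unname(g4$centroid), c(0, 0))
  expect_equal(g4$radius, 11)

  # adding an interior cell never changes the boundary polygon
  plus <- dplyr::bind_rows(cross, make_frames(0, 5, 1, 1, pi))
  g5 <- colony_geometry(plus)
  key <- function(b) b[order(b[, 1], b[, 2]), , drop = FALSE]
  expect_equal(key(g5$boundary), key(g4$boundary), tolerance = 1e-12)
})

test_that("edge and centre distances satisfy the circular identities", {
  geo <- circle_geometry(c(0, 0), 100)
  cells <- tibble::tibble(x_um = c(0, 60), y_um = c(0, 0))
  expect_equal(radial_distances(cells, geo, "centre"), c(0, 60))
  expect_equal(radial_distances(cells, geo, "edge"), c(100, 40))

  # polygonal approximation of a circular colony: edge + centre = radius
  ang <- seq(0, 2 * pi, length.out = 41)[-41]
  ring <- make_frames(0, 1:40, 90 * cos(ang), 90 * sin(ang), pi * 25) # r_eq 5
  geo2 <- colony_geometry(ring)
  inner <- tibble::tibble(x_um = c(10, -30, 0, 55), y_um = c(5, 20, -40, -10))
  d_e <- radial_distances(inner, geo2, "edge")
  d_c <- radial_distances(inner, geo2, "centre")
  expect_equal(d_e + d_c, rep(geo2$radius, 4), tolerance = 0.02 * geo2$radius)

  # outside cells warn and clamp to zero
  out <- tibble::tibble(x_um = 300, y_um = 0)
  expect_warning(d_out <- radial_distances(out, geo2, "edge"), "outside")
  expect_equal(d_out, 0)
})

test_that("mitotic percentage counts dividing cells over bin denominators", {
  # 8 cells in one frame; 4 divide before the next frame
  f0 <- make_frames(0, 1:8, seq(0, 70, by = 10), 0, rep(60, 8))
  kids <- make_frames(1, 1:12, c(seq(0, 30, by = 10) + rep(c(-1.5, 1.5), each = 4)[1:8],
                                 seq(40, 70, by = 10)),
                      0, c(rep(30, 8), rep(64.2, 4)))
  # cells 1-4 split into 30s; cells 5-8 continue (60 -> 64.2)
  kids$label <- 1:12
  ft <- dplyr::bind_rows(f0, kids)
  forest <- reconstruct_lineage(ft)
  expect_equal(nrow(forest$events), 4)
  mp <- mitotic_percentage(ft, forest, binning = "none", frames_select = 0)
  expect_equal(mp$numerator, 4)
  expect_equal(mp$denominator, 8)
  expect_equal(mp$value, 50)
  # nobody divides: 0 percent
  ft2 <- dplyr::bind_rows(f0, dplyr::mutate(f0, frame = 1, time_h = 1))
  f2 <- reconstruct_lineage(ft2)
  mp2 <- mitotic_percentage(ft2, f2, binning = "none", frames_select = 0)
  expect_equal(mp2$value, 0)
})

test_that("binned mitotic percentages partition the population", {
  ch <- default_cohort()
  one <- ch$sims$colony05
  forest <- reconstruct_lineage(one$frames)
  sel <- c(59, 60)
  mp <- mitotic_percentage(one$frames, forest, binning = "radial",
                           frames_select = sel, ring_width = 10)
  expect_true(all(mp$value >= 0 & mp$value <= 100))
  expect_true(all(mp$numerator <= mp$denominator))
  n_expected <- sum(one$frames$frame %in% sel)
  expect_equal(sum(mp$denominator), n_expected)
  # size binning partitions identically
  mps <- mitotic_percentage(one$frames, forest, binning = "size",
                            frames_select = sel)
  expect_equal(sum(mps$denominator), n_expected)
})

test_that("mitotic percentage vs size shows the commitment knee on simulations", {
  ch <- default_cohort()
  mp <- mitotic_percentage(ch$frames, ch$forest, binning = "size")
  ac <- sim_config()$A_commit_um2
  low <- mp$value[mp$bin_hi <= 30 & mp$denominator >= 50]
  high <- mp$value[mp$bin_lo >= ac & mp$denominator >= 50]
  mid <- mp$value[mp$bin_lo >= 35 & mp$bin_hi <= ac & mp$denominator >= 50]
  expect_true(all(low <= 5)) # far below the ramp: essentially no divisions
  expect_gt(mean(high), mean(mid)) # saturated region above the knee
  expect_gt(mean(mid), mean(low)) # rising section below it
})

test_that("kymographs bin every cell exactly once per frame", {
  # single-cell colony: a 1 x T kymograph equal to its area trace
  t <- 0:5
  single <- make_frames(t, 1, 0, 0, 30 * 1.1^t)
  ky1 <- radial_kymograph(single, ring_width = 25)
  expect_equal(nrow(ky1), 6)
  expect_equal(ky1$mean_area, 30 * 1.1^t)

  # constructed two-ring colony: inner cells 30, outer 60
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  ft <- dplyr::bind_rows(
    make_frames(0, 1:12, 50 * cos(ang), 50 * sin(ang), 60),
    make_frames(0, 13:16, c(4, -4, 0, 0), c(0, 0, 4, -4), 30)
  )
  ky <- radial_kymograph(ft, ring_width = 26, reference = "centre")
  expect_equal(ky$mean_area[ky$ring == 0], 30)
  expect_equal(ky$mean_area[ky$ring == 1], 60)

  # cell-count marginal over rings equals the colony count series
  sim <- simulate_colony(sim_config(seed = 2, duration_h = 60))
  ky2 <- radial_kymograph(sim$frames, ring_width = 10)
  marg <- ky2 |> dplyr::group_by(frame) |> dplyr::summarise(n = sum(n_cells))
  series <- compute_size_series(sim$frames)
  expect_equal(marg$n, series$n_cells)
})

test_that("radial size bands become nonmonotone under crowding", {
  ch <- default_cohort()
  sim <- ch$sims$colony01
  ky <- radial_kymograph(dplyr::filter(sim$frames, frame >= 72), ring_width = 10)
  prof <- ky |> dplyr::filter(n_cells >= 3) |>
    dplyr::group_by(frame) |> dplyr::filter(dplyr::n() >= 3) |>
    dplyr::arrange(ring, .by_group = TRUE) |>
    dplyr::summarise(nonmono = { d <- diff(mean_area); any(d > 0) && any(d < 0) })
  expect_gt(sum(prof$nonmono), 0)
})

test_that("ring summaries use interpolated quartiles and ignore row order", {
  cells <- make_frames(0, 1:4, c(1, 2, 3, 4), 0, c(10, 20, 30, 40))
  geo <- circle_geometry(c(2.5, 0), 10)
  rs <- ring_boxplot_summary(cells, geo, ring_width = 20)
  expect_equal(nrow(rs), 1)
  expect_equal(rs$median, 25)
  expect_equal(rs$q1, 17.5)
  expect_equal(rs$q3, 32.5)
  expect_equal(rs$n, 4)
  # all equal: five identical numbers
  eq <- ring_boxplot_summary(make_frames(0, 1:4, 1:4, 0, rep(7, 4)), geo, 20)
  expect_equal(unlist(eq[, c("min", "q1", "median", "q3", "max")]),
               setNames(rep(7, 5), c("min", "q1", "median", "q3", "max")))
  # permutation invariance
  perm <- cells[c(3, 1, 4, 2), ]
  expect_equal(ring_boxplot_summary(perm, geo, 20), rs)
})

test_that("parent-daughter rank correlation behaves at the extremes", {
  # daughter exactly parent/2: perfect monotone association
  p <- tibble::tibble(parent_area_um2 = c(40, 60, 80, 100),
                      daughter_area_um2 = c(20, 30, 40, 50))
  expect_equal(parent_daughter_correlation(p)$rho, 1)
  # constant daughters: flagged, undefined
  pc <- dplyr::mutate(p, daughter_area_um2 = 25)
  res <- parent_daughter_correlation(pc)
  expect_true(res$flagged)
  expect_true(is.na(res$rho))
  # independence construction: parent sizes from the sizer range, daughter
  # sizes drawn independently around a fixed birth size
  set.seed(99)
  ind <- tibble::tibble(
    parent_area_um2 = runif(500, 40, 160),
    daughter_area_um2 = 32 * exp(rnorm(500, 0, 0.15))
  )
  expect_lte(abs(parent_daughter_correlation(ind)$rho), 0.1)
})

test_that("tracked pairs feed the correlation machinery end to end", {
  ch <- default_cohort()
  pd <- parent_daughter_pairs(ch$forest)
  expect_gt(nrow(pd), 100)
  expect_true(all(pd$parent_area_um2 / pd$daughter_area_um2 >= 1.5))
  res <- parent_daughter_correlation(pd)
  expect_false(res$flagged)
  expect_true(res$rho >= -1 && res$rho <= 1)
})
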