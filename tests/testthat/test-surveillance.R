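# Pixel-change maps, surveillance/motility indices, cumulative and
# stationary areas, convex-hull territory.

test_that("pixel-change maps match the voxelwise set-difference oracle", {
  a <- array(FALSE, c(4, 4, 2)); b <- a
  expect_equal(pixel_change_maps(a, a)$n_pe, 0)
  expect_equal(pixel_change_maps(a, a)$n_pr, 0)
  b[2, 3, 1] <- TRUE
  pc <- pixel_change_maps(a, b)
  expect_equal(pc$n_pe, 1)
  expect_equal(pc$n_pr, 0)
  expect_error(pixel_change_maps(a, array(FALSE, c(4, 4, 3))), "shape")

  set.seed(31)
  for (rep in 1:20) {
    m1 <- random_mask(c(10, 10, 10))
    m2 <- random_mask(c(10, 10, 10))
    pc <- pixel_change_maps(m1, m2)
    # brute-force voxel loop
    pe <- pr <- 0L
    for (i in seq_along(m1)) {
      if (m2[i] && !m1[i]) pe <- pe + 1L
      if (m1[i] && !m2[i]) pr <- pr + 1L
    }
    expect_identical(pc$n_pe, pe)
    expect_identical(pc$n_pr, pr)
    expect_identical(pc$n_pe - pc$n_pr, sum(m2) - sum(m1))
    expect_false(any(pc$PE & pc$PR))
  }
})

test_that("surveillance trace normalizes the baseline to exactly one", {
  m <- build_cell_model(5, branch_prob = 0.2, length_scale = 18, seed = 21)
  sim <- simulate_surveillance(m, small_acq(n_frames = 12),
                               dynamics = list(speed = 2.5), seed = 22)
  tr <- surveillance_trace(sim$truth_masks, baseline_minutes = c(1, 10))
  bl <- tr$time_min >= 1 & tr$time_min <= 10
  expect_equal(mean(tr$norm[bl]), 1, tolerance = 1e-12)
  expect_true(all(tr$raw >= 0))
  # raw counts agree with the simulator's truth bookkeeping
  expect_equal(tr$raw, sim$truth$added + sim$truth$removed)
})

test_that("a static cell triggers the static-baseline failure", {
  m <- build_cell_model(4, branch_prob = 0, length_scale = 15, seed = 23)
  sim <- simulate_surveillance(m, small_acq(n_frames = 12),
                               dynamics = list(speed = 0), seed = 24)
  expect_error(surveillance_trace(sim$truth_masks), "static baseline")
})

test_that("effect index equals one over the baseline and tracks a planted slowdown", {
  m <- build_cell_model(6, branch_prob = 0.25, length_scale = 22, seed = 25)
  pat <- ifelse(seq_len(40) >= 20, 0.4, 1)
  sim <- simulate_surveillance(m, surv_acq(),
                               dynamics = list(speed = 2.5, pattern = pat),
                               seed = 26)
  tr <- surveillance_trace(sim$truth_masks)
  expect_equal(effect_index(tr, c(1, 10)), 1, tolerance = 1e-12)
  expect_lt(effect_index(tr, c(35, 40)), 0.6)
  expect_gt(effect_index(tr, c(35, 40)), 0.25)
  expect_error(effect_index(tr, c(200, 210)), "window")
})

test_that("motility index halves for a cell of twice the area at equal dynamics", {
  # identical |PE|+|PR|; cell B carries an extra static block doubling its area
  mk <- function(static_block) {
    masks <- array(FALSE, c(40, 20, 3, 3))
    for (t in 1:3) {
      masks[1:(10 + t), 1:5, 2, t] <- TRUE            # growing front, area 55/60/65
      if (static_block) masks[21:40, 10:12, 2, t] <- TRUE  # +60 um^2, immobile
    }
    mask_series(masks, NULL, 1, 1, 60)
  }
  trA <- surveillance_trace(mk(FALSE), baseline_minutes = c(1, 2))
  trB <- surveillance_trace(mk(TRUE), baseline_minutes = c(1, 2))
  expect_equal(trA$raw, trB$raw)
  expect_equal(motility_index(trB) / motility_index(trA), 0.5, tolerance = 1e-9)
})

test_that("motility index is size-invariant across simulated cells (+-10%)", {
  idx <- vapply(c(16, 24), function(len) {
    m <- build_cell_model(5, branch_prob = 0, length_scale = len,
                          seed = 40 + len)
    sim <- simulate_surveillance(m, small_acq(n_frames = 10),
                                 dynamics = list(speed = 2.5), seed = 50 + len)
    motility_index(surveillance_trace(sim$truth_masks,
                                      baseline_minutes = c(1, 9)))
  }, 0)
  expect_equal(idx[1], idx[2], tolerance = 0.10)
})

test_that("cumulative area is non-decreasing and static cells give area/duration rate", {
  m <- build_cell_model(4, branch_prob = 0, length_scale = 15, seed = 27)
  sim <- simulate_surveillance(m, small_acq(n_frames = 16),
                               dynamics = list(speed = 0), seed = 28)
  ca <- cumulative_area(sim$truth_masks, c(0, 15))
  expect_true(all(diff(ca$area_um2) >= 0))
  expect_equal(ca$area_um2[1], ca$area_um2[length(ca$area_um2)])
  expect_equal(ca$rate_um2_per_min, ca$area_um2[1] / 15)

  dyn <- simulate_surveillance(m, small_acq(n_frames = 16),
                               dynamics = list(speed = 2.5), seed = 29)
  ca2 <- cumulative_area(dyn$truth_masks, c(0, 15))
  expect_true(all(diff(ca2$area_um2) >= 0))
  expect_gte(ca2$area_um2[16], ca2$area_um2[1])
})

test_that("extrapolated delay matches the closed-form linear-growth model", {
  # growth at rate v vs 0.4 v: delay = (1/0.4 - 1) * 100% = 150%
  tt <- seq(0, 15, by = 1)
  fast <- structure(list(time_min = tt, area_um2 = 10 * tt,
                         rate_um2_per_min = 10), class = "cum_area")
  slow <- structure(list(time_min = tt, area_um2 = 4 * tt,
                         rate_um2_per_min = 4), class = "cum_area")
  expect_equal(cumulative_delay(slow, fast), 150, tolerance = 1e-9)
  expect_equal(cumulative_delay(fast, fast), 0)
})

test_that("stationary area: static cell gives cell-minus-soma, full remodeling gives zero", {
  m <- build_cell_model(4, branch_prob = 0, length_scale = 15, seed = 30)
  sim <- simulate_surveillance(m, small_acq(n_frames = 16),
                               dynamics = list(speed = 0), seed = 31)
  sa <- stationary_area(sim$truth_masks, c(0, 15))
  proj <- apply(mask_frame(sim$truth_masks, 1), c(1, 2), any)
  soma_proj <- apply(sim$truth_masks$soma, c(1, 2), any)
  expect_equal(sa, sum(proj & !soma_proj) * 1)

  # fully remodeling: disjoint footprints every frame
  masks <- array(FALSE, c(30, 10, 2, 3))
  for (t in 1:3) masks[(t * 8):(t * 8 + 3), 2:5, 1, t] <- TRUE
  ms <- mask_series(masks, NULL, 1, 1, 60 * 7.5)
  expect_equal(stationary_area(ms, c(0, 15)), 0)
})

test_that("territory: analytic squares, crosses, and the hull dominance invariant", {
  sq <- array(FALSE, c(20, 20, 1))
  sq[5:14, 5:14, 1] <- TRUE                     # 10 x 10 px
  expect_equal(territory(sq, 1), 100)

  # 4-armed cross, tips 40 um from the centre: hull is a rotated square,
  # area 2 * 40^2 = 3200 (pixel-corner granularity adds a thin margin)
  cr <- array(FALSE, c(101, 101, 1))
  cr[51, 11:91, 1] <- TRUE
  cr[11:91, 51, 1] <- TRUE
  a <- territory(cr, 1)
  expect_gte(a, 3200)
  # pixel corners widen the hull to an octagon: 2*40.5^2 plus the arm width
  expect_lt(a, 3200 * 1.06)

  set.seed(61)
  for (rep in 1:10) {
    m <- random_mask(c(15, 15, 3), p = 0.1)
    if (!any(m)) next
    hull_area <- territory(m, 1)
    proj_area <- sum(apply(m, c(1, 2), any))
    expect_gte(hull_area, proj_area)
  }
  expect_error(territory(array(FALSE, c(5, 5, 2))), "empty")
})

test_that("territory >= projected area >= stationary area for simulated cells", {
  m <- build_cell_model(5, branch_prob = 0.25, length_scale = 18, seed = 33)
  sim <- simulate_surveillance(m, small_acq(n_frames = 6),
                               dynamics = list(speed = 2), seed = 34)
  terr <- territory(mask_frame(sim$truth_masks, 1), 1)
  proj <- sum(apply(mask_frame(sim$truth_masks, 1), c(1, 2), any))
  stat_a <- stationary_area(sim$truth_masks, c(0, 5))
  expect_gte(terr, proj)
  expect_gte(proj, stat_a)
})
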