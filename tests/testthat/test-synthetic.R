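# Simulator ground truth: cell-model geometry, tip dynamics bookkeeping,
# chemotaxis closed form, artifact injection.

test_that("cell model honours primary count and exact nominal length", {
  m <- build_cell_model(5, branch_prob = 0, length_scale = 30, seed = 1)
  expect_equal(m$P_true, 5)
  expect_equal(m$n_branches, 5)
  expect_equal(m$L_true, 150)

  m1 <- build_cell_model(1, branch_prob = 0, length_scale = 40, seed = 2)
  expect_equal(m1$L_true, 40)
  # polyline arc of the nominal portion equals the nominal length exactly
  b <- m1$branches[[1]]
  seglen <- sqrt(rowSums(diff(b$nodes[seq_len(b$n_nom + 1L), ])^2))
  expect_equal(sum(seglen), 40, tolerance = 1e-9)
})

test_that("cell model rejects invalid arguments", {
  expect_error(build_cell_model(3, length_scale = 0), "length_scale")
  expect_error(build_cell_model(3, length_scale = -5), "length_scale")
  expect_error(build_cell_model(3, branch_prob = 1))
})

test_that("model generation is deterministic and replays the branching process", {
  m1 <- build_cell_model(4, branch_prob = 0.5, seed = 7)
  m2 <- build_cell_model(4, branch_prob = 0.5, seed = 7)
  expect_identical(m1, m2)

  # independent replay of the documented RNG draw order, counting branches
  # and nodes without any geometry
  replay <- function(n_primary, branch_prob, length_scale, seed, max_depth = 3) {
    n_branches <- 0L; n_nodes <- 0L
    grow <- function(nominal, depth) {
      n_nom <- max(3L, as.integer(ceiling(nominal / 4)))
      n_seg <- n_nom + as.integer(ceiling(0.6 * n_nom))
      for (i in seq_len(n_seg)) runif(2)      # per-segment direction jitter
      n_branches <<- n_branches + 1L
      n_nodes <<- n_nodes + n_seg + 1L
      if (depth < max_depth && branch_prob > 0) {
        for (k in 2:n_nom) {
          if (runif(1) < branch_prob) {
            runif(2)                           # child angle + orientation
            grow(nominal * 0.6, depth + 1L)
          }
        }
      }
    }
    set.seed(seed)
    for (i in seq_len(n_primary)) {
      runif(2)                                 # primary azimuth + tilt
      grow(length_scale, 0L)
    }
    list(n_branches = n_branches, n_nodes = n_nodes)
  }
  for (seed in c(7, 11, 23)) {
    m <- build_cell_model(4, branch_prob = 0.5, length_scale = 30, seed = seed)
    r <- replay(4, 0.5, 30, seed)
    expect_identical(m$n_branches, r$n_branches)
    expect_identical(m$n_nodes, r$n_nodes)
  }
})

test_that("static tips give identical truth masks and zero change counts", {
  m <- build_cell_model(4, branch_prob = 0, length_scale = 16, seed = 3)
  sim <- simulate_surveillance(m, small_acq(n_frames = 4),
                               dynamics = list(speed = 0), seed = 5)
  expect_true(all(sim$truth$added == 0))
  expect_true(all(sim$truth$removed == 0))
  for (t in 2:4)
    expect_identical(sim$truth_masks$masks[, , , t],
                     sim$truth_masks$masks[, , , 1])
})

test_that("truth added/removed counts obey the volume identity and soma is static", {
  m <- build_cell_model(5, branch_prob = 0.3, length_scale = 20, seed = 4)
  sim <- simulate_surveillance(m, small_acq(n_frames = 6),
                               dynamics = list(speed = 3), seed = 6)
  expect_equal(sim$truth$added - sim$truth$removed,
               diff(sim$truth$volume_voxels))
  soma <- sim$truth_masks$soma
  for (t in seq_len(6))
    expect_true(all(sim$truth_masks$masks[, , , t][soma]))
})

test_that("a single extending arm adds its rendered increment, removes nothing", {
  m <- build_cell_model(1, branch_prob = 0, length_scale = 15, seed = 8)
  sim <- simulate_surveillance(m, small_acq(n_frames = 4),
                               dynamics = list(speed = 2, p_extend = 1),
                               seed = 9)
  # pure extension: set-difference oracle on the truth masks
  for (t in 1:3) {
    a <- mask_frame(sim$truth_masks, t)
    b <- mask_frame(sim$truth_masks, t + 1)
    expect_equal(sim$truth$added[t], sum(b & !a))
    expect_equal(sim$truth$removed[t], 0)
    expect_true(all(a[b == FALSE] == FALSE))   # monotone growth
  }
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  m <- build_cell_model(3, branch_prob = 0.2, length_scale = 18, seed = 10)
  acq <- small_acq(n_frames = 3, noiseless = FALSE)
  s1 <- simulate_surveillance(m, acq, dynamics = list(speed = 2), seed = 42)
  s2 <- simulate_surveillance(m, acq, dynamics = list(speed = 2), seed = 42)
  expect_identical(unclass(s1$stack), unclass(s2$stack))
  expect_identical(s1$truth_masks$masks, s2$truth_masks$masks)
})

test_that("chemotaxis truth trace equals the closed form and tau=Inf freezes fronts", {
  acq <- chem_acq()
  sim <- simulate_chemotaxis(3, acq, seed = 2)
  tt <- sim$truth$trace$time_s
  expect_equal(sim$truth$trace$clear_area_um2,
               sim$truth$A_inf + (sim$truth$A0 - sim$truth$A_inf) *
                 exp(-tt / 180), tolerance = 1e-12)

  frozen <- simulate_chemotaxis(Inf, chem_acq(n_frames = 5), seed = 2)
  expect_equal(diff(frozen$truth$trace$clear_area_um2), rep(0, 4))
  for (t in 2:5)
    expect_identical(frozen$truth_masks$masks[, , , t],
                     frozen$truth_masks$masks[, , , 1])
  expect_error(simulate_chemotaxis(-1), "tau_true")
  expect_error(simulate_chemotaxis(3, chem_acq(), center = c(-5, 10, 10)),
               "center")
})

test_that("artifact injection: identity, pure drift, and bounds", {
  m <- build_cell_model(3, branch_prob = 0, length_scale = 14, seed = 5)
  sim <- simulate_surveillance(m, small_acq(n_frames = 11),
                               dynamics = list(speed = 0), seed = 3)
  clean <- sim$stack
  same <- inject_artifacts(clean, c(0, 0, 0), NULL, seed = 1)
  expect_equal(unclass(same), unclass(clean), ignore_attr = TRUE)

  drifted <- inject_artifacts(clean, c(0.5, 0, 0), NULL, seed = 1)
  sh <- attr(drifted, "true_shifts")
  expect_equal(sh[11, ], c(5L, 0L, 0L))
  expect_identical(get_frame(drifted, 11)[6:64, , ],
                   get_frame(clean, 11)[1:59, , ])

  expect_error(inject_artifacts(clean, c(10, 0, 0), NULL, seed = 1),
               "out of the volume")
})

test_that("stacks round-trip through TIFF with geometry intact", {
  m <- build_cell_model(3, branch_prob = 0, length_scale = 12, seed = 6)
  sim <- simulate_surveillance(m, small_acq(n_frames = 2), seed = 2)
  tf <- tempfile(fileext = ".tiff")
  write_stack(sim$stack, tf, extra = list(note = "fixture"))
  back <- read_stack(tf)
  expect_equal(dim(back), dim(sim$stack))
  expect_equal(attr(back, "spacing"), attr(sim$stack, "spacing"))
  # 16-bit storage: relative error bounded by the quantization step
  expect_lt(max(abs(back - sim$stack)) / max(sim$stack), 1 / 65000)
  unlink(c(tf, paste0(tf, ".json")))
})
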