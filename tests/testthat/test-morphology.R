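# Skeletonization, Sholl profiles, process length, volume, compartments.

star_skeleton <- function(k, arm_len = 30, n_nodes = 7) {
  # k straight arms in the xy-plane radiating from the origin
  nodes <- matrix(0, 1, 3)
  edges <- NULL
  for (i in seq_len(k)) {
    th <- 2 * pi * (i - 1) / k
    tpos <- seq(arm_len / n_nodes, arm_len, length.out = n_nodes)
    pts <- cbind(tpos * cos(th), tpos * sin(th), 0)
    rows <- nrow(nodes) + seq_len(n_nodes)
    nodes <- rbind(nodes, pts)
    edges <- rbind(edges, cbind(c(1, rows[-n_nodes]), rows))
  }
  skeleton_graph(nodes, edges, root = 1)
}

test_that("Sholl counts are exact on k-armed stars", {
  for (k in 1:8) {
    pr <- sholl(star_skeleton(k, arm_len = 30), step = 5)
    inside <- pr$radius_um <= 30
    expect_equal(pr$crossings[inside], rep(k, sum(inside)))
    expect_equal(pr$crossings[!inside], rep(0L, sum(!inside)))
    expect_equal(attr(pr, "n_processes"), k)
  }
})

test_that("a bifurcating arm doubles its crossings beyond the branch point", {
  nodes <- rbind(c(0, 0, 0), c(15, 0, 0), c(25, 5, 0), c(25, -5, 0))
  edges <- rbind(c(1, 2), c(2, 3), c(2, 4))
  pr <- sholl(skeleton_graph(nodes, edges, root = 1), step = 5)
  expect_equal(pr$crossings[pr$radius_um == 5], 1L)
  expect_equal(pr$crossings[pr$radius_um == 10], 1L)
  expect_equal(pr$crossings[pr$radius_um == 20], 2L)
})

test_that("Sholl crossings match a dense-sampling oracle on random model trees", {
  for (seed in c(3, 17, 29, 41, 53)) {
    set.seed(seed)
    m <- build_cell_model(sample(3:6, 1), branch_prob = 0.4,
                          length_scale = 25, seed = seed)
    sk <- skeleton_from_model(m)
    pr <- sholl(sk, step = 5)
    root <- sk$nodes[sk$root, ]
    for (r in pr$radius_um) {
      # oracle: walk each edge in 200 steps and count sign changes of
      # (distance from root) - r
      crossings <- 0L
      for (e in seq_len(nrow(sk$edges))) {
        p1 <- sk$nodes[sk$edges[e, 1], ]; p2 <- sk$nodes[sk$edges[e, 2], ]
        tt <- seq(0, 1, length.out = 200)
        dd <- sqrt(colSums((outer(p1, rep(1, 200)) +
                              outer(p2 - p1, tt) - root)^2))
        crossings <- crossings + sum(diff(dd < r) != 0)
      }
      expect_equal(pr$crossings[pr$radius_um == r], crossings)
    }
  }
})

test_that("total process length: 3-4-5 triangle, reordering and rerooting invariance", {
  nodes <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(total_process_length(skeleton_graph(nodes, rbind(c(1, 2)))), 5)

  m <- build_cell_model(4, branch_prob = 0.4, length_scale = 20, seed = 19)
  sk <- skeleton_from_model(m)
  perm <- sample(nrow(sk$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  sk2 <- skeleton_graph(sk$nodes[perm, ],
                        cbind(inv[sk$edges[, 1]], inv[sk$edges[, 2]]),
                        root = inv[sk$root])
  expect_equal(total_process_length(sk2), total_process_length(sk))
  sk3 <- skeleton_graph(sk$nodes, sk$edges, root = nrow(sk$nodes))
  expect_equal(total_process_length(sk3), total_process_length(sk))
})

test_that("image skeletonization recovers a straight tube's path and length", {
  mask <- array(microdyn:::cpp_rasterize_tubes(
    50, 11, 11, 1, 1, 1, matrix(c(5, 5.5, 5.5, 45, 5.5, 5.5, 1.2), 1)),
    c(50, 11, 11))
  sk <- skeletonize_cell(mask, 1, 1, prune_um = 2)
  g <- igraph::graph_from_edgelist(sk$edges, directed = FALSE)
  expect_equal(sum(igraph::degree(g) == 1), 2)      # a single path
  expect_true(all(igraph::degree(g) <= 2))
  expect_equal(total_process_length(sk), 40, tolerance = 0.05)
})

test_that("a 5-armed simulated cell yields 5 root-to-tip paths and a faithful length", {
  m <- build_cell_model(5, branch_prob = 0, length_scale = 18, seed = 9)
  sim <- simulate_surveillance(m, small_acq(n_frames = 2),
                               dynamics = list(speed = 0), seed = 12)
  sk <- skeletonize_cell(mask_frame(sim$truth_masks, 1), 1, 2, prune_um = 3,
                         root_um = sim$truth$soma_center)
  g <- igraph::graph_from_edgelist(sk$edges, directed = FALSE)
  expect_equal(sum(igraph::degree(g) == 1), 5)
  ref <- total_process_length(skeleton_from_model(m))
  expect_equal(total_process_length(sk), ref, tolerance = 0.05)
})

test_that("a soma-only sphere collapses to a near-point skeleton", {
  mask <- array(microdyn:::cpp_rasterize_tubes(
    21, 21, 21, 1, 1, 1, matrix(c(10.5, 10.5, 10.5, 10.5, 10.5, 10.5, 6), 1)),
    c(21, 21, 21))
  sk <- skeletonize_cell(mask, 1, 1, prune_um = 8)
  expect_lt(total_process_length(sk), 3)
})

test_that("cell volume is exact arithmetic and additive over disjoint masks", {
  cuboid <- array(FALSE, c(20, 20, 8))
  cuboid[1:10, 1:10, 1:5] <- TRUE
  expect_equal(cell_volume(cuboid, 0.5, 2), 10 * 10 * 5 * 0.5 * 0.5 * 2)

  other <- array(FALSE, c(20, 20, 8))
  other[15:18, 15:18, 6:8] <- TRUE
  expect_equal(cell_volume(cuboid | other, 0.5, 2),
               cell_volume(cuboid, 0.5, 2) + cell_volume(other, 0.5, 2))
  expect_error(cell_volume(array(FALSE, c(4, 4, 4))), "empty")

  # erosion shrinks volume
  m <- build_cell_model(4, branch_prob = 0.2, length_scale = 16, seed = 14)
  sim <- simulate_surveillance(m, small_acq(n_frames = 2),
                               dynamics = list(speed = 0), seed = 15)
  v_full <- cell_volume(mask_frame(sim$truth_masks, 1), 1, 2)
  eroded <- mask_frame(sim$truth_masks, 1) & !sim$truth_masks$soma
  expect_lt(cell_volume(eroded, 1, 2), v_full)
})

test_that("simulated cell volume matches the geometric truth within partial-volume error", {
  m <- build_cell_model(5, branch_prob = 0, length_scale = 18, seed = 16)
  sim <- simulate_surveillance(m, small_acq(n_frames = 2),
                               dynamics = list(speed = 0), seed = 17)
  v_mask <- cell_volume(mask_frame(sim$truth_masks, 1), 1, 2)
  # analytic: soma sphere + 5 capsule arms (ends inside the soma overlap)
  v_soma <- 4 / 3 * pi * m$soma_radius^3
  v_arms <- 5 * pi * 0.8^2 * 18
  expect_equal(v_mask, v_soma + v_arms, tolerance = 0.35)
  expect_equal(v_mask, sim$truth$V_true[1], tolerance = 1e-12)
})

test_that("compartment ratios: equal split, soma-only, and containment errors", {
  cell <- array(TRUE, c(10, 10, 4))
  soma <- array(FALSE, c(10, 10, 4)); soma[1:5, , ] <- TRUE
  sig_eq <- array(FALSE, c(10, 10, 4))
  sig_eq[3, , ] <- TRUE; sig_eq[8, , ] <- TRUE
  cs <- compartment_ratio(cell, soma, sig_eq, 1, 1)
  expect_equal(cs$ratio, 1)

  sig_soma <- array(FALSE, c(10, 10, 4)); sig_soma[2, , ] <- TRUE
  expect_equal(compartment_ratio(cell, soma, sig_soma)$ratio, 0)

  sig_proc <- array(FALSE, c(10, 10, 4)); sig_proc[9, , ] <- TRUE
  cs2 <- compartment_ratio(cell, soma, sig_proc)
  expect_false(cs2$ratio_defined)
  expect_true(is.na(cs2$ratio))

  bad_soma <- array(TRUE, c(10, 10, 4))
  cell2 <- cell; cell2[1, 1, 1] <- FALSE
  expect_error(compartment_ratio(cell2, bad_soma, sig_eq), "contained")
})

test_that("planted 3:1 puncta are recovered as a process-to-soma ratio near 3", {
  m <- build_cell_model(6, branch_prob = 0.3, length_scale = 20, seed = 18)
  sim <- simulate_surveillance(m, small_acq(n_frames = 2),
                               dynamics = list(speed = 0), seed = 19)
  cell <- mask_frame(sim$truth_masks, 1)
  soma <- sim$truth_masks$soma
  set.seed(20)
  proc_idx <- which(cell & !soma)
  soma_idx <- which(cell & soma)
  sig <- array(FALSE, dim(cell))
  sig[sample(proc_idx, 300)] <- TRUE
  sig[sample(soma_idx, 100)] <- TRUE
  cs <- compartment_ratio(cell, soma, sig, 1, 2)
  expect_equal(cs$ratio, 3, tolerance = 0.1)
  expect_equal(cs$normalized, 400 / sum(cell), tolerance = 1e-12)
})

test_that("skeletons serialize to well-formed SWC", {
  sk <- star_skeleton(3)
  tf <- tempfile(fileext = ".swc")
  write_swc(sk, tf)
  lines <- readLines(tf)
  body <- read.table(text = lines[!startsWith(lines, "#")])
  expect_equal(nrow(body), nrow(sk$nodes))
  expect_equal(sum(body$V7 == -1), 1)           # single root
  expect_true(all(body$V7[body$V7 != -1] < body$V1[body$V7 != -1]))
  unlink(tf)
})
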