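# Synthetic 4D microglia: renders cell models into noisy time-lapse stacks
# with exact ground-truth masks and metrics for validating the analysis chain.

#' Acquisition settings for the simulator
#'
#' Defaults mirror typical two-photon surveillance imaging: a 258-um square
#' field of view at 512 x 512 pixels, 2-um z-steps over a 50-um stack, one
#' frame per minute. Chemotaxis imaging uses 25-um stacks every 30 s
#' (pass `stack_depth = 25, frame_interval = 30`).
#'
#' @param fov_um lateral field of view (micrometres, square).
#' @param n_xy lateral grid size in pixels.
#' @param voxel_size_z z-step (micrometres).
#' @param stack_depth axial extent (micrometres).
#' @param frame_interval seconds between frames.
#' @param n_frames number of frames.
#' @param bg_level,cell_level two-level intensity model (arbitrary units).
#' @param photon_scale photons per intensity unit for Poisson shot noise;
#'   `NULL` disables shot noise.
#' @param read_noise_sd additive Gaussian read-noise SD; 0 disables.
#' @param drift_per_frame 3-vector, voxels of rigid drift per frame.
#' @return list of class `acq_config`.
#' @export
acquisition_config <- function(fov_um = 258, n_xy = 512, voxel_size_z = 2,
                               stack_depth = 50, frame_interval = 60,
                               n_frames = 41, bg_level = 10, cell_level = 110,
                               photon_scale = 0.2, read_noise_sd = 5,
                               drift_per_frame = c(0, 0, 0)) {
  stopifnot(fov_um > 0, n_xy >= 8, voxel_size_z > 0, stack_depth > 0,
            frame_interval > 0, n_frames >= 1, cell_level > bg_level)
  structure(list(fov_um = fov_um, n_xy = as.integer(n_xy),
                 voxel_size_xy = fov_um / n_xy, voxel_size_z = voxel_size_z,
                 stack_depth = stack_depth,
                 nz = as.integer(ceiling(stack_depth / voxel_size_z)),
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 bg_level = bg_level, cell_level = cell_level,
                 photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 drift_per_frame = drift_per_frame),
            class = "acq_config")
}

acq_dims <- function(acq) c(acq$n_xy, acq$n_xy, acq$nz)

acq_center <- function(acq) {
  d <- acq_dims(acq)
  c(d[1] * acq$voxel_size_xy, d[2] * acq$voxel_size_xy, d[3] * acq$voxel_size_z) / 2
}

# rasterize segment matrix into a logical volume on the acquisition grid
rasterize_segments <- function(segs, acq) {
  d <- acq_dims(acq)
  m <- cpp_rasterize_tubes(d[1], d[2], d[3],
                           acq$voxel_size_xy, acq$voxel_size_xy, acq$voxel_size_z,
                           segs)
  array(m, d)
}

check_inside <- function(segs, acq) {
  d <- acq_dims(acq)
  ext <- c(d[1] * acq$voxel_size_xy, d[2] * acq$voxel_size_xy, d[3] * acq$voxel_size_z)
  for (j in 1:3) {
    lo <- min(segs[, j] - segs[, 7], segs[, j + 3] - segs[, 7])
    hi <- max(segs[, j] + segs[, 7], segs[, j + 3] + segs[, 7])
    if (lo < 0 || hi > ext[j])
      stop("cell geometry leaves the simulated volume (axis ", c("x", "y", "z")[j], ")")
  }
  invisible(TRUE)
}

# per-branch maximum tip arc keeping the whole track inside the volume
# (tube radius margin included), so extension can never leave the stack
volume_tip_limits <- function(model, acq) {
  d <- acq_dims(acq)
  ext <- c(d[1] * acq$voxel_size_xy, d[2] * acq$voxel_size_xy, d[3] * acq$voxel_size_z)
  vapply(seq_along(model$branches), function(i) {
    b <- model$branches[[i]]
    inside <- apply(b$nodes, 1, function(p)
      all(p - b$radius >= 0) && all(p + b$radius <= ext))
    bad <- which(!inside)
    if (length(bad) == 0) (nrow(b$nodes) - 1L) * b$seg
    else (min(bad) - 2L) * b$seg
  }, 0)
}

# re-center a cell model so the soma sits at the middle of the volume
center_model <- function(model, acq) {
  off <- acq_center(acq) - model$soma_center
  model$soma_center <- model$soma_center + off
  model$branches <- lapply(model$branches, function(b) {
    b$nodes <- sweep(b$nodes, 2, off, "+")
    b
  })
  model
}

apply_noise <- function(vol, acq) {
  if (!is.null(acq$photon_scale) && acq$photon_scale > 0)
    vol <- stats::rpois(length(vol), pmax(vol, 0) * acq$photon_scale) / acq$photon_scale
  if (acq$read_noise_sd > 0)
    vol <- vol + stats::rnorm(length(vol), 0, acq$read_noise_sd)
  pmax(vol, 0)
}

#' Simulate a surveilling microglial cell
#'
#' Renders `model` into a time-lapse stack in which every process tip extends
#' or retracts along its track by `speed * frame_interval` per transition
#' (random sign, reflected at the track limits so processes neither detach
#' their children nor leave the track). The soma is static throughout. The
#' returned object carries exact ground truth: the noiseless binary masks,
#' per-transition added/removed voxel counts, and the model's `P_true` and
#' `L_true`.
#'
#' @param model a [build_cell_model()] cell (re-centred into the volume).
#' @param acq an [acquisition_config()].
#' @param dynamics list with `speed` (tip speed, micrometres/min),
#'   `pattern` (per-transition speed multiplier, recycled; default 1) and
#'   `p_extend` (probability a tip extends rather than retracts).
#' @param seed integer seed controlling tip choices and noise.
#' @return list of class `sim_result` with elements `stack` (an
#'   `image_stack`, noise and drift applied), `truth_masks` (a
#'   `mask_series` of the noiseless cell), and `truth` (ground-truth metrics).
#' @export
simulate_surveillance <- function(model, acq = acquisition_config(),
                                  dynamics = list(speed = 2.5, pattern = 1,
                                                  p_extend = 0.5),
                                  seed = 1) {
  stopifnot(acq$n_frames >= 2)
  speed <- if (is.null(dynamics$speed)) 2.5 else dynamics$speed
  p_ext <- if (is.null(dynamics$p_extend)) 0.5 else dynamics$p_extend
  pattern <- if (is.null(dynamics$pattern)) 1 else dynamics$pattern
  pattern <- rep_len(pattern, acq$n_frames - 1L)
  model <- center_model(model, acq)
  lo <- min_tip_arcs(model)
  hi <- pmin(max_tip_arcs(model), volume_tip_limits(model, acq))
  nom <- nominal_tip_arcs(model)
  if (any(hi < nom - 1e-9))
    stop("cell geometry leaves the simulated volume; use a larger field of view or stack depth")
  if (any(hi < lo)) stop("branch track shorter than its children allow")
  nb <- length(model$branches)
  dt_min <- acq$frame_interval / 60

  with_seed(seed, {
    arcs <- nominal_tip_arcs(model)
    arcs_hist <- matrix(0, acq$n_frames, nb)
    masks <- array(FALSE, c(acq_dims(acq), acq$n_frames))
    for (t in seq_len(acq$n_frames)) {
      if (t > 1) {
        disp <- speed * pattern[t - 1L] * dt_min
        sgn <- ifelse(stats::runif(nb) < p_ext, 1, -1)
        prop <- arcs + sgn * disp
        # reflect at track limits
        prop <- ifelse(prop > hi, 2 * hi - prop, prop)
        prop <- ifelse(prop < lo, 2 * lo - prop, prop)
        arcs <- pmin(pmax(prop, lo), hi)
      }
      arcs_hist[t, ] <- arcs
      segs <- cell_segments(model, arcs)
      check_inside(segs, acq)
      masks[, , , t] <- rasterize_segments(segs, acq)
    }
    soma <- rasterize_segments(
      matrix(c(model$soma_center, model$soma_center, model$soma_radius), 1), acq)
    vols <- apply(masks, 4, sum)
    added <- removed <- integer(acq$n_frames - 1L)
    for (t in seq_len(acq$n_frames - 1L)) {
      a <- masks[, , , t]; b <- masks[, , , t + 1L]
      added[t] <- sum(b & !a)
      removed[t] <- sum(a & !b)
    }
    clean <- array(acq$bg_level, dim(masks))
    clean[masks] <- acq$cell_level
    stack <- image_stack(clean, acq$voxel_size_xy, acq$voxel_size_z,
                         acq$frame_interval)
    stack <- inject_artifacts(stack, acq$drift_per_frame,
                              list(photon_scale = acq$photon_scale,
                                   read_sd = acq$read_noise_sd), seed = NULL)
    vox_vol <- acq$voxel_size_xy^2 * acq$voxel_size_z
    structure(list(
      stack = stack,
      truth_masks = mask_series(masks, soma, acq$voxel_size_xy, acq$voxel_size_z,
                                acq$frame_interval),
      truth = list(P_true = model$P_true, L_true = model$L_true,
                   added = added, removed = removed,
                   volume_voxels = vols, V_true = vols * vox_vol,
                   tip_arcs = arcs_hist,
                   soma_center = model$soma_center,
                   soma_radius = model$soma_radius),
      model = model, acq = acq, seed = seed),
      class = "sim_result")
  })
}

#' Simulate chemotactic front convergence toward an ablation site
#'
#' Process fronts advance radially toward `center` so that the true clear
#' area follows `A(t) = A_inf + (A0 - A_inf) * exp(-t / tau_true)` exactly:
#' at each frame the occupied region is the annulus between the front radius
#' `r(t) = sqrt(A(t)/pi)` and the analysis boundary. `tau_true = Inf` gives
#' stationary fronts.
#'
#' @param tau_true time constant in minutes (> 0, possibly `Inf`).
#' @param acq an [acquisition_config()]; chemotaxis defaults are 25-um
#'   stacks every 30 s.
#' @param center ablation site in micrometres (default: volume centre).
#' @param r_inf front radius at convergence (micrometres).
#' @param r0_frac initial front radius as a fraction of the distance from
#'   the centre to the nearest lateral edge.
#' @param seed integer seed (noise only; front geometry is deterministic).
#' @return a `sim_result`; `truth$trace` holds the closed-form clear-area
#'   trace (time in seconds, area in square micrometres) and `truth$tau_true`.
#' @export
simulate_chemotaxis <- function(tau_true, acq = acquisition_config(
                                  stack_depth = 25, frame_interval = 30,
                                  n_frames = 21),
                                center = NULL, r_inf = 4, r0_frac = 0.8,
                                seed = 1) {
  if (!(tau_true > 0)) stop("tau_true must be positive")
  d <- acq_dims(acq)
  ext <- c(d[1], d[2]) * acq$voxel_size_xy
  if (is.null(center)) center <- c(ext / 2, d[3] * acq$voxel_size_z / 2)
  if (any(center[1:2] <= 0) || center[1] >= ext[1] || center[2] >= ext[2])
    stop("ablation center outside the volume")
  r_max <- min(center[1], center[2], ext[1] - center[1], ext[2] - center[2]) - 1
  r0 <- r0_frac * r_max
  A0 <- pi * r0^2; A_inf <- pi * r_inf^2
  tt <- (seq_len(acq$n_frames) - 1L) * acq$frame_interval       # seconds
  A <- A_inf + (A0 - A_inf) * exp(-tt / (tau_true * 60))
  r_front <- sqrt(A / pi)

  xc <- (seq_len(d[1]) - 0.5) * acq$voxel_size_xy
  yc <- (seq_len(d[2]) - 0.5) * acq$voxel_size_xy
  dist2 <- outer((xc - center[1])^2, (yc - center[2])^2, "+")
  masks <- array(FALSE, c(d, acq$n_frames))
  for (t in seq_len(acq$n_frames)) {
    plane <- dist2 >= r_front[t]^2 & dist2 <= r_max^2
    masks[, , , t] <- array(rep(plane, d[3]), d)
  }
  clean <- array(acq$bg_level, dim(masks))
  clean[masks] <- acq$cell_level
  stack <- image_stack(clean, acq$voxel_size_xy, acq$voxel_size_z,
                       acq$frame_interval)
  with_seed(seed, {
    stack <- inject_artifacts(stack, acq$drift_per_frame,
                              list(photon_scale = acq$photon_scale,
                                   read_sd = acq$read_noise_sd), seed = NULL)
  })
  structure(list(
    stack = stack,
    truth_masks = mask_series(masks, NULL, acq$voxel_size_xy, acq$voxel_size_z,
                              acq$frame_interval),
    truth = list(trace = data.frame(time_s = tt, clear_area_um2 = A),
                 tau_true = tau_true, A0 = A0, A_inf = A_inf,
                 center = center, r_max = r_max),
    acq = acq, seed = seed),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  d <- dim(unclass(x$stack))
  cat(sprintf("<sim_result> %d frame(s) of %d x %d x %d voxels", d[4], d[1], d[2], d[3]))
  if (!is.null(x$truth$tau_true)) cat(sprintf("; chemotaxis tau_true=%g min", x$truth$tau_true))
  cat("\n")
  invisible(x)
}

shift_volume <- function(vol, sh, fill = 0) {
  sh <- as.integer(round(sh))
  if (all(sh == 0)) return(vol)
  d <- dim(vol)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (j in 1:3) {
    if (abs(sh[j]) >= d[j]) return(out)
    if (sh[j] >= 0) { src[[j]] <- 1:(d[j] - sh[j]); dst[[j]] <- (1 + sh[j]):d[j] }
    else            { src[[j]] <- (1 - sh[j]):d[j]; dst[[j]] <- 1:(d[j] + sh[j]) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Inject rigid drift and camera noise into a stack
#'
#' Frame `t` is translated by `(t-1) * drift_per_frame` voxels (zero-filled),
#' then Poisson shot noise and Gaussian read noise are applied. The injected
#' cumulative shifts are recorded in the `"true_shifts"` attribute for
#' round-trip validation against [correct_drift()].
#'
#' @param stack an `image_stack`.
#' @param drift_per_frame 3-vector, voxels per frame.
#' @param noise_model list with `photon_scale` and `read_sd`; `NULL` for none.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return an `image_stack` with attribute `true_shifts`
#'   (`n_frames` x 3 integer matrix).
#' @export
inject_artifacts <- function(stack, drift_per_frame = c(0, 0, 0),
                             noise_model = NULL, seed = NULL) {
  run <- function() {
    d <- dim(stack)
    nt <- d[4]
    shifts <- t(vapply(seq_len(nt) - 1L,
                       function(t) as.integer(round(t * drift_per_frame)),
                       integer(3)))
    if (any(abs(shifts) >= matrix(d[1:3], nt, 3, byrow = TRUE) / 2))
      stop("drift pushes the cell out of the volume")
    out <- unclass(stack)
    for (t in seq_len(nt))
      out[, , , t] <- get_frame(stack, t) |> shift_volume(shifts[t, ])
    if (!is.null(noise_model) &&
        ((!is.null(noise_model$photon_scale) && isTRUE(noise_model$photon_scale > 0)) ||
         isTRUE(noise_model$read_sd > 0))) {
      acqn <- list(photon_scale = noise_model$photon_scale,
                   read_noise_sd = if (is.null(noise_model$read_sd)) 0 else noise_model$read_sd)
      for (t in seq_len(nt))
        out[, , , t] <- array(apply_noise(out[, , , t], acqn), d[1:3])
    }
    res <- image_stack(out, attr(stack, "spacing")["x"], attr(stack, "spacing")["z"],
                       attr(stack, "frame_interval"))
    attr(res, "true_shifts") <- shifts
    res
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
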