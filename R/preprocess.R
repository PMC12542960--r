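# Image preprocessing: background subtraction, median filtering, rigid 4D
# drift correction, and seed-based per-cell binarization.

#' Background-subtract and median-filter a stack
#'
#' Per frame, a constant background (a low percentile of the frame's
#' intensities) is subtracted and clipped at zero; a 2D median filter is then
#' applied to each z-plane.
#'
#' @param stack an `image_stack`.
#' @param background_percentile percentile in `[0, 100)` used as the
#'   per-frame background estimate (default 10).
#' @param median_radius half-width of the square median window in pixels;
#'   0 disables filtering.
#' @return a preprocessed `image_stack`.
#' @export
preprocess_stack <- function(stack, background_percentile = 10, median_radius = 1) {
  stopifnot(background_percentile >= 0, background_percentile < 100,
            median_radius >= 0)
  d <- dim(stack)
  out <- unclass(stack)
  for (t in seq_len(d[4])) {
    vol <- get_frame(stack, t)
    bg <- stats::quantile(vol, background_percentile / 100, names = FALSE)
    vol <- pmax(vol - bg, 0)
    if (median_radius >= 1) {
      mx <- max(vol)
      if (mx > 0) {
        for (z in seq_len(d[3]))
          vol[, , z] <- EBImage::medianFilter(vol[, , z] / mx,
                                              as.integer(median_radius)) * mx
      }
    }
    out[, , , t] <- vol
  }
  res <- image_stack(out, attr(stack, "spacing")["x"], attr(stack, "spacing")["z"],
                     attr(stack, "frame_interval"))
  res
}

# circular cross-correlation lag of `a` relative to `b` via FFT; returns the
# translation s (in pixels per axis) maximizing sum a(x) b(x - s)
xcorr_lag <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  d <- dim(a)
  lag <- pk - 1L
  ifelse(lag > d / 2, lag - d, lag)
}

#' Rigid drift correction of a 4D stack
#'
#' Estimates an integer-voxel translation per frame by cross-correlating
#' maximum-z projections against a reference frame for lateral drift, then
#' maximum-y projections for z-drift, and translates each frame back. The
#' estimate for each frame is flagged low-confidence when the aligned
#' projections correlate poorly with the reference (e.g., pure noise).
#'
#' @param stack an `image_stack`.
#' @param reference_frame index of the reference frame (default 1).
#' @return list with `stack` (corrected), `shifts` (`n_frames` x 3 integer
#'   matrix of estimated drifts, voxels) and `low_confidence` (logical per
#'   frame). A warning is raised when an estimated shift exceeds 10% of the
#'   field of view.
#' @export
correct_drift <- function(stack, reference_frame = 1) {
  d <- dim(stack)
  nt <- d[4]
  stopifnot(reference_frame >= 1, reference_frame <= nt)
  ref <- get_frame(stack, reference_frame)
  ref_xy <- apply(ref, c(1, 2), max)
  ref_xz <- apply(ref, c(1, 3), max)
  shifts <- matrix(0L, nt, 3)
  lowconf <- logical(nt)
  out <- unclass(stack)
  for (t in seq_len(nt)) {
    vol <- get_frame(stack, t)
    if (t != reference_frame) {
      pxy <- apply(vol, c(1, 2), max)
      lag_xy <- xcorr_lag(pxy, ref_xy)
      pxz <- apply(vol, c(1, 3), max)
      lag_xz <- xcorr_lag(pxz, ref_xz)
      shifts[t, ] <- as.integer(c(lag_xy[1], lag_xy[2], lag_xz[2]))
      vol <- shift_volume(vol, -shifts[t, ])
    }
    aligned_proj <- apply(vol, c(1, 2), max)
    r <- suppressWarnings(stats::cor(as.vector(aligned_proj), as.vector(ref_xy)))
    lowconf[t] <- !is.finite(r) || r < 0.5
    out[, , , t] <- vol
  }
  if (any(abs(shifts) > 0.1 * matrix(d[1:3], nt, 3, byrow = TRUE)))
    warning("estimated drift exceeds 10% of the field of view")
  res <- image_stack(out, attr(stack, "spacing")["x"], attr(stack, "spacing")["z"],
                     attr(stack, "frame_interval"))
  list(stack = res, shifts = shifts, low_confidence = lowconf)
}

otsu_threshold <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(array(values, c(length(values), 1)), range = rng, levels = 256L)
}

#' Segment one cell across all frames
#'
#' Replaces manual cell selection with a reproducible rule: per frame the
#' stack is thresholded (Otsu within a dilated bounding box of the cell, or a
#' fixed percentile) and the 26-connected component containing the seed point
#' is kept. The soma submask is the largest inscribed sphere around the
#' intensity-weighted centroid of the frame-1 mask, intersected with every
#' frame's mask.
#'
#' @param stack an `image_stack` (ideally preprocessed).
#' @param seed_point integer voxel `c(x, y, z)` inside the cell at frame 1.
#' @param method list: `type` `"otsu"` (default) or `"percentile"` (with
#'   `p`, e.g. 99), and `dilate`, the bounding-box margin in voxels.
#' @return a `mask_series`.
#' @export
binarize_cell <- function(stack, seed_point,
                          method = list(type = "otsu", dilate = 10)) {
  d <- dim(stack)
  dims3 <- d[1:3]
  sp <- attr(stack, "spacing")
  seed_point <- as.integer(seed_point)
  stopifnot(length(seed_point) == 3, all(seed_point >= 1), all(seed_point <= dims3))
  dil <- if (is.null(method$dilate)) 10L else as.integer(method$dilate)
  # frame 1: locate the seed component with a global threshold, then refine
  # the threshold within its dilated bounding box
  vol1 <- get_frame(stack, 1)
  if (diff(range(vol1)) == 0)
    stop("binarize_cell: no cell component found at frame 1 (featureless stack)")
  thr0 <- if (identical(method$type, "percentile"))
    stats::quantile(vol1, method$p / 100, names = FALSE)
  else otsu_threshold(as.vector(vol1))
  m0 <- vol1 >= thr0
  lab0 <- array(cpp_label3d(m0, dims3, 26L), dims3)
  comp0 <- lab0[seed_point[1], seed_point[2], seed_point[3]]
  if (comp0 == 0L)
    stop("binarize_cell: no cell component found at frame 1")
  idx0 <- which(lab0 == comp0, arr.ind = TRUE)
  bbox <- rbind(pmax(apply(idx0, 2, min) - dil, 1L),
                pmin(apply(idx0, 2, max) + dil, dims3))
  masks <- array(FALSE, d)
  prev <- NULL
  for (t in seq_len(d[4])) {
    vol <- get_frame(stack, t)
    sub <- vol[bbox[1, 1]:bbox[2, 1], bbox[1, 2]:bbox[2, 2], bbox[1, 3]:bbox[2, 3]]
    thr <- if (identical(method$type, "percentile"))
      stats::quantile(sub, method$p / 100, names = FALSE)
    else otsu_threshold(as.vector(sub))
    m <- vol >= thr
    # restrict to the search box
    keep <- array(FALSE, dims3)
    keep[bbox[1, 1]:bbox[2, 1], bbox[1, 2]:bbox[2, 2], bbox[1, 3]:bbox[2, 3]] <- TRUE
    m <- m & keep
    lab <- array(cpp_label3d(m, dims3, 26L), dims3)
    comp <- lab[seed_point[1], seed_point[2], seed_point[3]]
    if (comp == 0L && !is.null(prev)) {
      ov <- tabulate(lab[prev], nbins = max(lab))
      if (length(ov) && max(ov) > 0) comp <- which.max(ov)
    }
    if (comp == 0L)
      stop("binarize_cell: no cell component found at frame ", t)
    cm <- lab == comp
    masks[, , , t] <- cm
    prev <- cm
    idx <- which(cm, arr.ind = TRUE)
    bbox <- rbind(pmax(apply(idx, 2, min) - dil, 1L),
                  pmin(apply(idx, 2, max) + dil, dims3))
  }
  soma <- estimate_soma(get_frame(stack, 1), masks[, , , 1], sp)
  for (t in seq_len(d[4])) soma <- soma & masks[, , , t]
  mask_series(masks, soma, sp["x"], sp["z"], attr(stack, "frame_interval"))
}

# soma = largest inscribed sphere near the intensity-weighted centroid
estimate_soma <- function(vol, mask, sp) {
  dims3 <- dim(mask)
  dt <- array(cpp_chamfer_dt(mask, dims3, sp["x"], sp["y"], sp["z"]), dims3)
  idx <- which(mask, arr.ind = TRUE)
  w <- vol[mask]
  cen <- colSums(idx * w) / sum(w)
  cen_um <- (cen - 0.5) * c(sp["x"], sp["y"], sp["z"])
  co_um <- sweep(sweep(idx, 2, 0.5, "-"), 2, c(sp["x"], sp["y"], sp["z"]), "*")
  d2 <- rowSums(sweep(co_um, 2, cen_um, "-")^2)
  near <- d2 <= (3 * max(sp))^2
  if (!any(near)) near <- rep(TRUE, nrow(idx))
  cand <- idx[near, , drop = FALSE]
  dvals <- dt[cand]
  best <- cand[which.max(dvals), ]
  r <- max(dvals)
  bc_um <- (best - 0.5) * c(sp["x"], sp["y"], sp["z"])
  d2all <- rowSums(sweep(co_um, 2, bc_um, "-")^2)
  soma <- array(FALSE, dims3)
  soma[mask] <- d2all <= r^2
  soma
}
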