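# Surveillance and motility metrics from per-frame cell masks: pixel-change
# (extension/retraction) maps, the baseline-normalized surveillance index,
# the size-independent motility index, cumulative surveyed area, stationary
# (non-motile) process area, and the convex-hull territory.

#' Pixel-change maps between two masks
#'
#' Voxels gained between consecutive frames are process extensions (PE),
#' voxels lost are process retractions (PR). By construction
#' `|PE| - |PR|` equals the change in mask volume, exactly.
#'
#' @param mask_t,mask_t1 logical 3D arrays of identical shape.
#' @return list of class `pixel_change` with `PE`, `PR` (logical arrays)
#'   and counts `n_pe`, `n_pr`.
#' @export
pixel_change_maps <- function(mask_t, mask_t1) {
  if (!identical(dim(mask_t), dim(mask_t1)))
    stop("masks have different shapes")
  pe <- mask_t1 & !mask_t
  pr <- mask_t & !mask_t1
  structure(list(PE = pe, PR = pr, n_pe = sum(pe), n_pr = sum(pr)),
            class = "pixel_change")
}

transition_times_min <- function(ms) {
  # a transition t -> t+1 is stamped with the time of the later frame
  (seq_len(dim(ms$masks)[4] - 1L)) * ms$frame_interval / 60
}

#' Surveillance index trace
#'
#' Per frame-to-frame transition, the raw index is `|PE| + |PR|` (voxels);
#' the normalized index divides by the mean raw index over the baseline
#' window (by convention the first 10 min of the recording). The projected
#' cell area per frame (square micrometres, max-z projection) is carried
#' along for the motility index.
#'
#' @param masks a `mask_series`.
#' @param baseline_minutes length-2 window (min) defining baseline
#'   transitions; default `c(1, 10)`.
#' @param mode `"3d"` (default) counts voxel changes in the full stacks;
#'   `"2d"` counts pixel changes on max-z projections.
#' @return data frame of class `surv_trace` with columns `time_min`,
#'   `n_pe`, `n_pr`, `raw`, `norm`, `area_um2`.
#' @export
surveillance_trace <- function(masks, baseline_minutes = c(1, 10), mode = "3d") {
  nt <- dim(masks$masks)[4]
  stopifnot(nt >= 2)
  tmin <- transition_times_min(masks)
  bl <- tmin >= baseline_minutes[1] & tmin <= baseline_minutes[2]
  if (!any(bl)) stop("baseline window covers no transition")
  n_pe <- n_pr <- integer(nt - 1L)
  for (t in seq_len(nt - 1L)) {
    if (mode == "2d") {
      a <- project_mask(mask_frame(masks, t))
      b <- project_mask(mask_frame(masks, t + 1L))
    } else {
      a <- mask_frame(masks, t)
      b <- mask_frame(masks, t + 1L)
    }
    n_pe[t] <- sum(b & !a)
    n_pr[t] <- sum(a & !b)
  }
  raw <- n_pe + n_pr
  base <- mean(raw[bl])
  if (base == 0)
    stop("static baseline: no pixel change during the baseline window")
  px_area <- masks$spacing["x"] * masks$spacing["y"]
  area <- vapply(seq_len(nt), function(t)
    sum(project_mask(mask_frame(masks, t))) * px_area, 0)
  out <- data.frame(time_min = tmin, n_pe = n_pe, n_pr = n_pr, raw = raw,
                    norm = raw / base,
                    area_um2 = (area[-1] + area[-nt]) / 2)
  attr(out, "baseline_minutes") <- baseline_minutes
  attr(out, "frame_area_um2") <- area
  class(out) <- c("surv_trace", "data.frame")
  out
}

#' Mean normalized surveillance index over a time window
#'
#' The standard effect readout: the mean normalized index during the drug
#' window (by convention minutes 35-40) relative to the baseline mean of 1.
#'
#' @param trace a `surv_trace`.
#' @param window_minutes length-2 window in minutes.
#' @return scalar.
#' @export
effect_index <- function(trace, window_minutes = c(35, 40)) {
  sel <- trace$time_min >= window_minutes[1] & trace$time_min <= window_minutes[2]
  if (!any(sel)) stop("window contains no transition")
  mean(trace$norm[sel])
}

#' Cell-size-independent motility index
#'
#' The raw surveillance index divided by the mean projected cell area over
#' the same window (voxels changed per square micrometre of cell per
#' transition), reflecting only the dynamic parts of the cell.
#'
#' @param trace a `surv_trace`.
#' @param window_minutes window in minutes; default the whole recording.
#' @return scalar (voxels / um^2 / transition).
#' @export
motility_index <- function(trace, window_minutes = NULL) {
  sel <- if (is.null(window_minutes)) rep(TRUE, nrow(trace))
  else trace$time_min >= window_minutes[1] & trace$time_min <= window_minutes[2]
  if (!any(sel)) stop("window contains no transition")
  a <- mean(trace$area_um2[sel])
  if (a <= 0) stop("zero cell area")
  mean(trace$raw[sel]) / a
}

#' Cumulative surveyed area
#'
#' Running union of the projected cell masks from the window start: the
#' total area the cell has touched up to each time point (non-decreasing).
#' The rate is the final cumulative area divided by the window duration.
#'
#' @param masks a `mask_series`.
#' @param window_minutes length-2 window (min), default `c(0, 15)`.
#' @return list of class `cum_area` with `time_min`, `area_um2`
#'   (cumulative trace) and `rate_um2_per_min`.
#' @export
cumulative_area <- function(masks, window_minutes = c(0, 15)) {
  nt <- dim(masks$masks)[4]
  tf <- (seq_len(nt) - 1L) * masks$frame_interval / 60
  sel <- which(tf >= window_minutes[1] & tf <= window_minutes[2])
  if (length(sel) < 2) stop("window contains fewer than 2 frames")
  px_area <- masks$spacing["x"] * masks$spacing["y"]
  acc <- project_mask(mask_frame(masks, sel[1]))
  area <- numeric(length(sel))
  area[1] <- sum(acc) * px_area
  for (i in seq_along(sel)[-1]) {
    acc <- acc | project_mask(mask_frame(masks, sel[i]))
    area[i] <- sum(acc) * px_area
  }
  dur <- tf[sel[length(sel)]] - tf[sel[1]]
  structure(list(time_min = tf[sel], area_um2 = area,
                 rate_um2_per_min = area[length(area)] / dur),
            class = "cum_area")
}

#' Delay for a slower cell to reach a reference cumulative area
#'
#' Extrapolates the slower trace's terminal slope (least-squares line over
#' its final third) to the time at which it would reach the faster trace's
#' value at `at_minutes`, and reports the delay as a percentage of
#' `at_minutes`.
#'
#' @param slow,fast `cum_area` traces.
#' @param at_minutes reference time (default 15 min).
#' @return delay in percent (0 when `slow` is not behind).
#' @export
cumulative_delay <- function(slow, fast, at_minutes = 15) {
  target <- stats::approx(fast$time_min, fast$area_um2, xout = at_minutes,
                          rule = 2)$y
  n <- length(slow$time_min)
  tail_idx <- seq.int(max(1L, ceiling(2 * n / 3)), n)
  fit <- stats::lm(area ~ t, data = data.frame(t = slow$time_min[tail_idx],
                                               area = slow$area_um2[tail_idx]))
  b <- stats::coef(fit)
  if (b[2] <= 0) return(Inf)
  t_reach <- (target - b[1]) / b[2]
  max(0, (t_reach - at_minutes) / at_minutes * 100)
}

#' Stationary (non-motile) process area
#'
#' Area occupied in every frame of the window, soma excluded: the temporal
#' intersection of the per-frame max-z projections, i.e. the minimum-
#' intensity projection over time of binary data.
#'
#' @param masks a `mask_series` with a soma submask.
#' @param window_minutes length-2 window (min), default `c(0, 15)`.
#' @return area in square micrometres.
#' @export
stationary_area <- function(masks, window_minutes = c(0, 15)) {
  nt <- dim(masks$masks)[4]
  tf <- (seq_len(nt) - 1L) * masks$frame_interval / 60
  sel <- which(tf >= window_minutes[1] & tf <= window_minutes[2])
  if (length(sel) < 2) stop("window contains fewer than 2 frames")
  acc <- NULL
  for (t in sel) {
    p <- project_mask(mask_frame(masks, t))
    acc <- if (is.null(acc)) p else acc & p
  }
  acc <- acc & !project_mask(masks$soma)
  unname(sum(acc) * masks$spacing["x"] * masks$spacing["y"])
}

# shoelace area of a polygon given vertex matrix (n x 2)
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Convex-hull surveillance territory
#'
#' Area of the smallest convex polygon enclosing the max-z projection of the
#' cell (all distal process tips). Computed on the outer corners of the
#' occupied pixels, so the hull area is never smaller than the projected
#' area.
#'
#' @param mask logical 3D (or 2D) array, a single-frame cell mask.
#' @param voxel_size_xy lateral pixel pitch in micrometres.
#' @return hull area in square micrometres.
#' @export
territory <- function(mask, voxel_size_xy = 1) {
  if (length(dim(mask)) == 3L) mask <- project_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  corners <- rbind(idx + matrix(c(-1, -1), nrow(idx), 2, byrow = TRUE),
                   idx + matrix(c(0, -1), nrow(idx), 2, byrow = TRUE),
                   idx + matrix(c(-1, 0), nrow(idx), 2, byrow = TRUE),
                   idx)
  corners <- corners * voxel_size_xy
  h <- grDevices::chull(corners)
  polygon_area(corners[h, , drop = FALSE])
}
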