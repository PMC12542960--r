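# Chemotaxis quantification: radial-sector clear area around an ablation
# site and the monoexponential time constant of its decay.

#' Clear area around an ablation site
#'
#' The max-z projection is divided into `n_sectors` radial sectors centred
#' on the ablation site. In each sector the process front is the minimum
#' distance from the centre to any occupied pixel (the analysis `radius`
#' when the sector is empty), and the clear area is the sum of the
#' circular-sector areas at the front distances:
#' `C = sum_s (pi / n_sectors) * d_s^2`.
#'
#' @param mask logical 3D (or 2D) array; 3D input is max-z projected.
#' @param center ablation site `c(x, y)` in micrometres.
#' @param n_sectors number of radial sectors (>= 4; default 36, i.e. 10
#'   degrees per sector).
#' @param radius analysis radius in micrometres.
#' @param voxel_size_xy lateral pixel pitch in micrometres.
#' @return clear area in square micrometres.
#' @export
clear_area <- function(mask, center, n_sectors = 36, radius, voxel_size_xy = 1) {
  stopifnot(n_sectors >= 4, radius > 0)
  if (length(dim(mask)) == 3L) mask <- project_mask(mask)
  d <- dim(mask)
  ext <- d * voxel_size_xy
  if (any(center <= 0) || center[1] >= ext[1] || center[2] >= ext[2])
    stop("center outside the image")
  if (center[1] - radius < 0 || center[1] + radius > ext[1] ||
      center[2] - radius < 0 || center[2] + radius > ext[2])
    stop("analysis radius exceeds the image bounds")
  idx <- which(mask, arr.ind = TRUE)
  fronts <- rep(radius, n_sectors)
  if (nrow(idx) > 0) {
    px <- (idx[, 1] - 0.5) * voxel_size_xy - center[1]
    py <- (idx[, 2] - 0.5) * voxel_size_xy - center[2]
    dist <- sqrt(px^2 + py^2)
    keep <- dist <= radius
    if (any(keep)) {
      ang <- atan2(py[keep], px[keep]) %% (2 * pi)
      sec <- pmin(floor(ang / (2 * pi / n_sectors)) + 1L, n_sectors)
      mins <- tapply(dist[keep], factor(sec, levels = seq_len(n_sectors)), min)
      fronts <- ifelse(is.na(mins), radius, pmin(mins, radius))
    }
  }
  sum(pi / n_sectors * fronts^2)
}

#' Clear-area trace over time
#'
#' Applies [clear_area()] to the max-z projection of every frame.
#'
#' @param masks a `mask_series` (use reduced 25-um chemotaxis stacks).
#' @param center ablation site `c(x, y)` in micrometres.
#' @param n_sectors,radius see [clear_area()].
#' @return data frame of class `clear_area_trace` with `time_s`,
#'   `time_min` and `clear_area_um2`.
#' @export
clear_area_trace <- function(masks, center, n_sectors = 36, radius) {
  nt <- dim(masks$masks)[4]
  stopifnot(nt >= 3)
  ca <- vapply(seq_len(nt), function(t)
    clear_area(mask_frame(masks, t), center, n_sectors, radius,
               masks$spacing["x"]), 0)
  tt <- (seq_len(nt) - 1L) * masks$frame_interval
  out <- data.frame(time_s = tt, time_min = tt / 60, clear_area_um2 = ca)
  attr(out, "center") <- center
  attr(out, "n_sectors") <- n_sectors
  attr(out, "radius") <- radius
  class(out) <- c("clear_area_trace", "data.frame")
  out
}

#' Monoexponential fit of the clear-area decay
#'
#' Least-squares fit of `C(t) = A_inf + (A0 - A_inf) * exp(-t / tau)` with
#' tau reported in minutes. Initialized with `A0` at the first value,
#' `A_inf` at the last, and tau at the time to half-decay; tau is bounded in
#' `(0, 10x recording length]`. Non-convergence (e.g. a flat trace) is
#' flagged, not raised.
#'
#' @param trace a `clear_area_trace`, or any data frame with `time_min` and
#'   `clear_area_um2` columns.
#' @param truncate_at_plateau drop time points after the trace minimum
#'   before fitting (default `FALSE`: fit the full trace).
#' @return object of class `tau_fit` with `print`, `coef`, `predict` and
#'   `residuals` methods; fields `tau_min`, `A0`, `A_inf`, `rss`,
#'   `converged`.
#' @export
fit_tau <- function(trace, truncate_at_plateau = FALSE) {
  tmin <- trace$time_min
  y <- trace$clear_area_um2
  if (truncate_at_plateau) {
    cut <- which.min(y)
    tmin <- tmin[seq_len(cut)]
    y <- y[seq_len(cut)]
  }
  if (length(y) < 5) stop("need at least 5 time points")
  dur <- max(tmin) - min(tmin)
  a0 <- y[1]; ainf <- y[length(y)]
  half <- a0 - (a0 - ainf) / 2
  below <- which(y <= half)
  tau0 <- if (length(below) && a0 > ainf) max(tmin[below[1]] / log(2), dur / 50)
  else dur / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ ainf_ + (a0_ - ainf_) * exp(-tmin / tau_),
      start = list(a0_ = a0, ainf_ = ainf, tau_ = tau0),
      lower = c(a0_ = 0, ainf_ = 0, tau_ = 1e-6),
      upper = c(a0_ = Inf, ainf_ = Inf, tau_ = 10 * max(dur, 1e-6)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res <- list(tau_min = NA_real_, A0 = a0, A_inf = ainf, rss = NA_real_,
                converged = FALSE, data = data.frame(time_min = tmin, area = y))
    class(res) <- "tau_fit"
    return(res)
  }
  cf <- stats::coef(fit)
  conv <- cf[["tau_"]] < 10 * dur * 0.999 &&       # at-bound tau: no decay seen
    (cf[["a0_"]] - cf[["ainf_"]]) > 0.01 * max(cf[["a0_"]], 1e-12)
  res <- list(tau_min = cf[["tau_"]], A0 = cf[["a0_"]], A_inf = cf[["ainf_"]],
              rss = sum(stats::residuals(fit)^2), converged = conv,
              fit = fit, data = data.frame(time_min = tmin, area = y))
  class(res) <- "tau_fit"
  res
}

#' @export
print.tau_fit <- function(x, ...) {
  if (isTRUE(x$converged))
    cat(sprintf("<tau_fit> tau = %.3f min (A0 = %.1f, A_inf = %.1f um^2; RSS = %.3g)\n",
                x$tau_min, x$A0, x$A_inf, x$rss))
  else
    cat("<tau_fit> did not converge (flat or non-exponential trace)\n")
  invisible(x)
}

#' @export
coef.tau_fit <- function(object, ...)
  c(tau_min = object$tau_min, A0 = object$A0, A_inf = object$A_inf)

#' @export
predict.tau_fit <- function(object, newdata = NULL, ...) {
  tmin <- if (is.null(newdata)) object$data$time_min else newdata$time_min
  object$A_inf + (object$A0 - object$A_inf) * exp(-tmin / object$tau_min)
}

#' @export
residuals.tau_fit <- function(object, ...)
  object$data$area - predict(object)
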