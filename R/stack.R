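#' 4D fluorescence image stack
#'
#' Container for a single-channel time-lapse z-stack, stored as a numeric
#' array indexed `[x, y, z, t]` together with its voxel geometry and frame
#' interval. All downstream metrics (areas, volumes, lengths) are reported in
#' micrometres using this geometry.
#'
#' @param data numeric array; either `[x, y, z, t]` or a single-frame
#'   `[x, y, z]` volume (promoted to one frame).
#' @param voxel_size_xy lateral pixel pitch in micrometres.
#' @param voxel_size_z z-step in micrometres.
#' @param frame_interval time between frames in seconds.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size_xy, voxel_size_z, frame_interval = 60) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  voxel_size_xy <- unname(voxel_size_xy); voxel_size_z <- unname(voxel_size_z)
  stopifnot(length(dim(data)) == 4L, voxel_size_xy > 0, voxel_size_z > 0,
            frame_interval > 0)
  if (any(data < 0)) stop("intensities must be non-negative")
  structure(data,
            spacing = c(x = voxel_size_xy, y = voxel_size_xy, z = voxel_size_z),
            frame_interval = frame_interval,
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing")
  cat(sprintf("<image_stack> %d x %d x %d voxels, %d frame(s)\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel %.3g x %.3g x %.3g um, frame interval %g s\n",
              sp["x"], sp["y"], sp["z"], attr(x, "frame_interval")))
  invisible(x)
}

spacing_of <- function(x) attr(x, "spacing")

n_frames <- function(x) dim(x)[4]

#' Extract one frame of an image stack as a 3D array
#' @param x an `image_stack`.
#' @param t frame index.
#' @return numeric 3D array `[x, y, z]`.
#' @export
get_frame <- function(x, t) {
  d <- dim(x)
  array(x[, , , t], dim = d[1:3])
}

set_frame <- function(x, t, frame) {
  x[, , , t] <- frame
  x
}

#' Per-frame binary cell masks with a soma submask
#'
#' @param masks logical array `[x, y, z, t]` (or `[x, y, z]`, promoted).
#' @param soma logical array `[x, y, z]`, the frame-invariant soma submask.
#' @param voxel_size_xy,voxel_size_z voxel pitch in micrometres.
#' @param frame_interval seconds between frames.
#' @return an object of class `mask_series`.
#' @export
mask_series <- function(masks, soma = NULL, voxel_size_xy, voxel_size_z,
                        frame_interval = 60) {
  if (length(dim(masks)) == 3L) dim(masks) <- c(dim(masks), 1L)
  voxel_size_xy <- unname(voxel_size_xy); voxel_size_z <- unname(voxel_size_z)
  stopifnot(is.logical(masks), length(dim(masks)) == 4L)
  if (is.null(soma)) soma <- array(FALSE, dim(masks)[1:3])
  stopifnot(identical(dim(soma), dim(masks)[1:3]))
  not_in <- FALSE
  for (t in seq_len(dim(masks)[4]))
    if (any(soma & !masks[, , , t])) { not_in <- TRUE; break }
  if (not_in) warning("soma submask is not contained in the cell mask at every frame")
  structure(list(masks = masks, soma = soma,
                 spacing = c(x = voxel_size_xy, y = voxel_size_xy, z = voxel_size_z),
                 frame_interval = frame_interval),
            class = "mask_series")
}

#' @export
print.mask_series <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<mask_series> %d frame(s) of %d x %d x %d voxels; soma %d voxels\n",
              d[4], d[1], d[2], d[3], sum(x$soma)))
  invisible(x)
}

#' Extract one frame of a mask series as a logical 3D array
#' @param ms a `mask_series`.
#' @param t frame index.
#' @return logical 3D array `[x, y, z]`.
#' @export
mask_frame <- function(ms, t) array(ms$masks[, , , t], dim = dim(ms$masks)[1:3])

#' Maximum-intensity z-projection of a 3D volume
#' @keywords internal
project_z <- function(vol) apply(vol, c(1, 2), max)

# logical projection: pixel occupied if any voxel in the column is
project_mask <- function(m3d) apply(m3d, c(1, 2), any)

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are written in TZYX order (all z-planes of frame 1, then frame 2,
#' ...). Geometry, frame interval and the intensity scale (intensities are
#' mapped to `[0, 1]` for storage) go into `<path>.json`, plus any extra
#' metadata supplied in `extra`.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @param extra optional named list stored verbatim in the sidecar.
#' @export
write_stack <- function(stack, path, extra = NULL) {
  d <- dim(stack)
  scale <- max(stack, 1e-12)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (t in seq_len(d[4])) for (z in seq_len(d[3])) {
    pages[[k]] <- t(stack[, , z, t]) / scale  # TIFF rows = y
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sp <- attr(stack, "spacing")
  meta <- list(axes = "TZYX", n_frames = d[4], n_z = d[3],
               voxel_size_xy = unname(sp["x"]), voxel_size_z = unname(sp["z"]),
               frame_interval = attr(stack, "frame_interval"),
               intensity_scale = scale)
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#' @param path TIFF path; `<path>.json` must exist alongside.
#' @return an `image_stack`.
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$n_z; nt <- meta$n_frames
  stopifnot(length(pages) == nz * nt)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(nx, ny, nz, nt))
  k <- 1L
  for (t in seq_len(nt)) for (z in seq_len(nz)) {
    arr[, , z, t] <- t(pages[[k]]) * meta$intensity_scale
    k <- k + 1L
  }
  image_stack(arr, meta$voxel_size_xy, meta$voxel_size_z, meta$frame_interval)
}

#' Write a mask series as 8-bit multi-page TIFF (TZYX)
#' @param ms a `mask_series`.
#' @param path output TIFF path.
#' @export
write_masks <- function(ms, path) {
  d <- dim(ms$masks)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (t in seq_len(d[4])) for (z in seq_len(d[3])) {
    pages[[k]] <- t(ms$masks[, , z, t]) * 1.0
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(axes = "TZYX", n_frames = d[4], n_z = d[3],
         voxel_size_xy = unname(ms$spacing["x"]),
         voxel_size_z = unname(ms$spacing["z"]),
         frame_interval = ms$frame_interval),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
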