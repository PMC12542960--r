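# Shared fixtures: small acquisition grids keep test runtimes low while
# preserving the anisotropic (2-um z) geometry of the real recordings.

small_acq <- function(n_frames = 4, noiseless = TRUE, ...) {
  args <- utils::modifyList(
    list(fov_um = 64, n_xy = 64, stack_depth = 20, frame_interval = 60,
         n_frames = n_frames),
    list(...))
  if (noiseless) {
    args["photon_scale"] <- list(NULL)
    args$read_noise_sd <- 0
  }
  do.call(acquisition_config, args)
}

surv_acq <- function(n_frames = 41, noiseless = TRUE, ...)
  small_acq(n_frames = n_frames, noiseless = noiseless,
            fov_um = 96, n_xy = 96, stack_depth = 30, ...)

chem_acq <- function(n_frames = 21, noiseless = TRUE)
  small_acq(n_frames = n_frames, noiseless = noiseless,
            fov_um = 96, n_xy = 96, stack_depth = 25, frame_interval = 30)

soma_seed_voxel <- function(sim) {
  sp <- sim$truth_masks$spacing
  as.integer(round(sim$truth$soma_center / sp + 0.5))
}

# random blob mask for set-operation oracles
random_mask <- function(dims, p = 0.3) array(stats::runif(prod(dims)) < p, dims)
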