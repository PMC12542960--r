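# Seeded end-to-end pipeline: simulate (or load) -> preprocess -> segment ->
# quantify -> test, with per-stage artifacts and a reproducible report.

#' Pipeline run configuration
#'
#' Bundles every stage parameter with its default: baseline window minutes
#' 1-10, effect window minutes 35-40, 36 chemotaxis sectors, 5-um Sholl
#' step. `groups` describes the simulated experimental arms; each element
#' may set `n_cells`, `speed_factor` (multiplier on tip speed after
#' `change_at_min`, e.g. 0.4 for a 60% slowdown) and, for chemotaxis,
#' `tau_true` (minutes).
#'
#' @param scenario `"surveillance"` or `"chemotaxis"`.
#' @param groups named list of group specs (see above).
#' @param acq an [acquisition_config()]; a scenario-appropriate default is
#'   chosen when `NULL`.
#' @param cell list of [build_cell_model()] arguments for simulated cells.
#' @param dynamics baseline tip dynamics (`speed`, micrometres/min).
#' @param change_at_min time at which `speed_factor` kicks in.
#' @param baseline_minutes,effect_window analysis windows (minutes).
#' @param n_sectors,analysis_radius chemotaxis clear-area settings
#'   (`analysis_radius = NULL`: 90% of the simulated front's start radius).
#' @param segment run preprocessing + seed-based segmentation on the noisy
#'   stack (`TRUE`) or quantify the simulator's truth masks (`FALSE`).
#' @param seed master seed; all per-cell seeds derive from it.
#' @param outdir optional output directory for CSV/JSON artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(scenario = c("surveillance", "chemotaxis"),
                       groups = list(control = list(n_cells = 8, speed_factor = 1),
                                     treated = list(n_cells = 8, speed_factor = 0.4)),
                       acq = NULL,
                       cell = list(n_primary = 6, branch_prob = 0.25,
                                   length_scale = 25),
                       dynamics = list(speed = 2.5),
                       change_at_min = 20,
                       baseline_minutes = c(1, 10),
                       effect_window = c(35, 40),
                       n_sectors = 36, analysis_radius = NULL,
                       segment = FALSE, seed = 1, outdir = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(acq)) {
    acq <- if (scenario == "surveillance")
      acquisition_config(fov_um = 96, n_xy = 96, stack_depth = 30,
                         frame_interval = 60, n_frames = 41)
    else
      acquisition_config(fov_um = 96, n_xy = 96, stack_depth = 25,
                         frame_interval = 30, n_frames = 21)
  }
  structure(list(scenario = scenario, groups = groups, acq = acq, cell = cell,
                 dynamics = dynamics, change_at_min = change_at_min,
                 baseline_minutes = baseline_minutes,
                 effect_window = effect_window, n_sectors = n_sectors,
                 analysis_radius = analysis_radius, segment = segment,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

cell_seed <- function(master, group_idx, cell_idx)
  (master * 10007L + group_idx * 7919L + cell_idx * 13L) %% 2000000011L

#' Execute a configured pipeline run
#'
#' Runs the stages for every simulated cell, collects per-cell metrics,
#' summarizes each group (mean, SEM, n) and applies the test-selection
#' decision tree to the first two groups. Deterministic for a fixed seed.
#'
#' @param config a [run_config()].
#' @return object of class `run_report` with `cells` (per-cell metric
#'   table), `summary`, `decision` and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  for (gi in seq_along(config$groups)) {
    gname <- names(config$groups)[gi]
    gspec <- config$groups[[gi]]
    n_cells <- if (!is.null(gspec$stacks)) length(gspec$stacks)
    else if (is.null(gspec$n_cells)) 8L else gspec$n_cells
    for (ci in seq_len(n_cells)) {
      sd_i <- cell_seed(config$seed, gi, ci)
      rows[[length(rows) + 1L]] <-
        if (config$scenario == "surveillance")
          run_surveillance_cell(config, gname, gspec, ci, sd_i)
        else
          run_chemotaxis_cell(config, gname, gspec, ci, sd_i)
    }
  }
  cells <- do.call(rbind, rows)
  metric <- if (config$scenario == "surveillance") "effect_index" else "tau_min"
  summary_tab <- summarize_groups(cells, metric, "group")
  decision <- NULL
  if (length(config$groups) >= 2) {
    g1 <- cells[[metric]][cells$group == names(config$groups)[1]]
    g2 <- cells[[metric]][cells$group == names(config$groups)[2]]
    g1 <- g1[is.finite(g1)]; g2 <- g2[is.finite(g2)]
    if (length(g1) >= 3 && length(g2) >= 3)
      decision <- decide_and_test(g1, g2)
  }
  report <- structure(list(cells = cells, summary = summary_tab,
                           decision = decision, config = config,
                           provenance = list(
                             seed = config$seed,
                             package_version = as.character(utils::packageVersion("microdyn")),
                             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
                      class = "run_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

run_surveillance_cell <- function(config, gname, gspec, ci, sd_i) {
  acq <- config$acq
  if (!is.null(gspec$stacks)) {
    # file-based arm: load -> preprocess -> segment
    p <- gspec$stacks[ci]
    if (!file.exists(p))
      stop('stage "segment": input stack not found: ', p)
    stack <- read_stack(p)
    pre <- preprocess_stack(stack)
    f1 <- get_frame(pre, 1)
    seedvox <- which(f1 == max(f1), arr.ind = TRUE)[1, ]
    masks <- binarize_cell(pre, seedvox)
    tr <- surveillance_trace(masks, config$baseline_minutes)
    return(data.frame(group = gname, cell = ci, seed = sd_i,
                      effect_index = effect_index(tr, config$effect_window),
                      motility = motility_index(tr),
                      territory_um2 = territory(mask_frame(masks, 1),
                                                masks$spacing["x"]),
                      volume_um3 = cell_volume(mask_frame(masks, 1),
                                               masks$spacing["x"],
                                               masks$spacing["z"])))
  }
  fac <- if (is.null(gspec$speed_factor)) 1 else gspec$speed_factor
  model <- do.call(build_cell_model, c(config$cell, list(seed = sd_i)))
  tmin <- seq_len(acq$n_frames - 1L) * acq$frame_interval / 60
  pattern <- ifelse(tmin >= config$change_at_min, fac, 1)
  sim <- simulate_surveillance(model, acq,
                               dynamics = c(config$dynamics,
                                            list(pattern = pattern)),
                               seed = sd_i)
  masks <- if (config$segment) {
    pre <- preprocess_stack(sim$stack)
    seedvox <- pmax(1L, pmin(acq_dims(acq), as.integer(round(
      sim$truth$soma_center / c(acq$voxel_size_xy, acq$voxel_size_xy,
                                acq$voxel_size_z) + 0.5))))
    binarize_cell(pre, seedvox)
  } else sim$truth_masks
  tr <- surveillance_trace(masks, config$baseline_minutes)
  data.frame(group = gname, cell = ci, seed = sd_i,
             effect_index = effect_index(tr, config$effect_window),
             motility = motility_index(tr),
             territory_um2 = territory(mask_frame(masks, 1),
                                       masks$spacing["x"]),
             volume_um3 = cell_volume(mask_frame(masks, 1),
                                      masks$spacing["x"], masks$spacing["z"]))
}

run_chemotaxis_cell <- function(config, gname, gspec, ci, sd_i) {
  tau <- if (is.null(gspec$tau_true)) 3 else gspec$tau_true
  sim <- simulate_chemotaxis(tau, config$acq, seed = sd_i)
  radius <- if (is.null(config$analysis_radius)) 0.9 * sim$truth$r_max
  else config$analysis_radius
  tr <- clear_area_trace(sim$truth_masks, sim$truth$center[1:2],
                         config$n_sectors, radius)
  ft <- fit_tau(tr)
  data.frame(group = gname, cell = ci, seed = sd_i, tau_true = tau,
             tau_min = if (isTRUE(ft$converged)) ft$tau_min else NA_real_,
             A0 = ft$A0, A_inf = ft$A_inf)
}

#' Group summary: mean, SEM, n
#'
#' @param table data frame of per-cell metrics.
#' @param value_col metric column name.
#' @param group_col grouping column name.
#' @return data frame with `group`, `n`, `mean`, `sem` (`NA` when n < 2).
#' @export
summarize_groups <- function(table, value_col, group_col = "group") {
  stopifnot(value_col %in% names(table), group_col %in% names(table))
  sp <- split(table[[value_col]], table[[group_col]])
  if (any(vapply(sp, length, 0L) == 0)) stop("empty group")
  out <- data.frame(group = names(sp),
                    n = vapply(sp, function(v) sum(is.finite(v)), 0L))
  out$mean <- vapply(sp, function(v) mean(v[is.finite(v)]), 0)
  out$sem <- vapply(sp, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  }, 0)
  rownames(out) <- NULL
  out
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cells, file.path(outdir, "cells.csv"), row.names = FALSE)
  utils::write.csv(report$summary, file.path(outdir, "summary.csv"), row.names = FALSE)
  dec <- if (is.null(report$decision)) NULL else
    list(test = report$decision$test, statistic = report$decision$statistic,
         p_value = report$decision$p_value)
  jsonlite::write_json(list(scenario = report$config$scenario,
                            decision = dec, provenance = report$provenance),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> scenario '%s', seed %d\n", x$config$scenario,
              x$config$seed))
  print(x$summary, digits = 4)
  if (!is.null(x$decision)) {
    cat("\n")
    print(x$decision)
  }
  invisible(x)
}
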