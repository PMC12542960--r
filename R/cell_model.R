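# Ground-truth geometric model of a ramified microglial cell: a spherical soma
# plus a rooted tree of tube-like processes, each a polyline "track" along
# which the tip can extend or retract during a simulation.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

unitv <- function(v) v / sqrt(sum(v^2))

# rotate `dir` by angle `ang` around a perpendicular axis at orientation `psi`
tilt_dir <- function(dir, ang, psi) {
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unitv(pracma_cross(dir, ref))
  v <- pracma_cross(dir, u)
  unitv(cos(ang) * dir + sin(ang) * (cos(psi) * u + sin(psi) * v))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Build a synthetic ramified-cell model
#'
#' Generates a rooted process tree around a spherical soma. Exactly
#' `n_primary` primary processes leave the soma; at each interior node of a
#' process a child branch is spawned with probability `branch_prob` (children
#' are 60% the length of their parent, recursively, up to `max_depth`).
#' Tracks extend ~60% beyond the nominal tip so simulated tips can grow.
#'
#' The RNG draw order is fixed and documented (per branch: direction draws,
#' then one two-value jitter per track segment, then one branching draw per
#' interior nominal node, with child branches built depth-first), so the
#' branching process can be replayed independently.
#'
#' @param n_primary number of primary processes (>= 1).
#' @param branch_prob per-node branching probability in `[0, 1)`.
#' @param length_scale nominal length of a primary process (micrometres).
#' @param seed integer seed; the model is a pure function of its arguments.
#' @param soma_center,soma_radius soma geometry (micrometres).
#' @param process_radius tube radius of primary processes (micrometres).
#' @param max_depth maximum branching depth below the primaries.
#' @param z_flatten factor damping the z-component of growth directions;
#'   values below 1 keep the cell quasi-planar, as for cells imaged in
#'   thin stacks.
#' @return an object of class `cell_model` with ground-truth fields
#'   `L_true` (total nominal process length, micrometres), `P_true`
#'   (number of primary processes) and `n_branches`.
#' @export
build_cell_model <- function(n_primary, branch_prob = 0.2, length_scale = 30,
                             seed = 1, soma_center = c(0, 0, 0), soma_radius = 4,
                             process_radius = 0.8, max_depth = 3,
                             z_flatten = 0.3) {
  stopifnot(n_primary >= 1, branch_prob >= 0, branch_prob < 1)
  if (length_scale <= 0) stop("length_scale must be positive")
  branches <- list()

  grow <- function(origin, dir, nominal, radius, depth, parent, parent_node) {
    seg_target <- 4                       # ~4 um between polyline nodes
    n_nom <- max(3L, as.integer(ceiling(nominal / seg_target)))
    seg <- nominal / n_nom
    n_extra <- as.integer(ceiling(0.6 * n_nom))
    n_seg <- n_nom + n_extra
    nodes <- matrix(0, n_seg + 1L, 3L)
    nodes[1L, ] <- origin
    d <- dir
    for (i in seq_len(n_seg)) {
      j <- stats::runif(2, -0.35, 0.35)
      d <- tilt_dir(d, abs(j[1]), atan2(j[2], j[1]))
      d <- unitv(d * c(1, 1, z_flatten))   # quasi-planar growth (thin stacks)
      nodes[i + 1L, ] <- nodes[i, ] + d * seg
    }
    branches[[length(branches) + 1L]] <<- list(
      nodes = nodes, seg = seg, n_nom = n_nom, nominal = nominal,
      radius = radius, depth = depth, parent = parent, parent_node = parent_node)
    me <- length(branches)
    if (depth < max_depth && branch_prob > 0) {
      for (k in 2:n_nom) {
        if (stats::runif(1) < branch_prob) {
          ang <- stats::runif(1, 0.6, 1.2)
          psi <- stats::runif(1, 0, 2 * pi)
          tang <- unitv(nodes[k + 1L, ] - nodes[k - 1L, ])
          grow(nodes[k, ], tilt_dir(tang, ang, psi), nominal * 0.6,
               radius * 0.8, depth + 1L, me, k)
        }
      }
    }
    me
  }

  with_seed(seed, {
    for (i in seq_len(n_primary)) {
      az <- 2 * pi * (i - 1) / n_primary + stats::runif(1, -0.3, 0.3)
      pol <- stats::runif(1, -0.25, 0.25)  # mostly in-plane (thin stacks)
      dir <- c(cos(pol) * cos(az), cos(pol) * sin(az), sin(pol))
      origin <- soma_center + dir * max(soma_radius - 0.5, 0)
      grow(origin, dir, length_scale, process_radius, 0L, 0L, 0L)
    }
  })

  L_true <- sum(vapply(branches, function(b) b$nominal, 0))
  structure(list(soma_center = soma_center, soma_radius = soma_radius,
                 branches = branches, L_true = L_true, P_true = n_primary,
                 n_branches = length(branches),
                 n_nodes = sum(vapply(branches, function(b) nrow(b$nodes), 0L))),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> soma r=%.1f um at (%.1f, %.1f, %.1f); %d branches (%d primary)\n",
              x$soma_radius, x$soma_center[1], x$soma_center[2], x$soma_center[3],
              x$n_branches, x$P_true))
  cat(sprintf("  total nominal process length %.1f um\n", x$L_true))
  invisible(x)
}

# nominal tip arc lengths (the initial state of a simulation)
nominal_tip_arcs <- function(model)
  vapply(model$branches, function(b) b$nominal, 0)

# polyline of branch b truncated at arc length `arc` (>= one segment)
truncate_branch <- function(b, arc) {
  arc <- max(arc, b$seg * 0.5)
  nfull <- min(floor(arc / b$seg), nrow(b$nodes) - 1L)
  pts <- b$nodes[seq_len(nfull + 1L), , drop = FALSE]
  rem <- arc - nfull * b$seg
  if (rem > 1e-9 && nfull + 2L <= nrow(b$nodes)) {
    d <- unitv(b$nodes[nfull + 2L, ] - b$nodes[nfull + 1L, ])
    pts <- rbind(pts, b$nodes[nfull + 1L, ] + d * rem)
  }
  pts
}

# segment matrix (x1 y1 z1 x2 y2 z2 r) for the whole cell at given tip arcs;
# the soma is a degenerate segment (a sphere)
cell_segments <- function(model, tip_arcs = nominal_tip_arcs(model)) {
  segs <- list(matrix(c(model$soma_center, model$soma_center, model$soma_radius), 1))
  for (i in seq_along(model$branches)) {
    b <- model$branches[[i]]
    pts <- truncate_branch(b, tip_arcs[i])
    n <- nrow(pts)
    if (n >= 2)
      segs[[length(segs) + 1L]] <-
        cbind(pts[-n, , drop = FALSE], pts[-1, , drop = FALSE], b$radius)
  }
  do.call(rbind, segs)
}

# minimum tip arc a branch may retract to without detaching its children
min_tip_arcs <- function(model) {
  arcs <- vapply(model$branches, function(b) b$seg, 0)  # at least one segment
  for (b in model$branches)
    if (b$parent > 0) {
      need <- b$parent_node * model$branches[[b$parent]]$seg
      arcs[b$parent] <- max(arcs[b$parent], need)
    }
  arcs
}

max_tip_arcs <- function(model)
  vapply(model$branches, function(b) (nrow(b$nodes) - 1L) * b$seg, 0)
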