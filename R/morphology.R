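# Skeleton-based 3D morphometrics: medial-axis skeletonization of cell
# masks, Sholl profiles, process counts, total process length, cell volume
# and compartmental (process vs soma) signal ratios.

#' Skeleton graph of a cell
#'
#' A rooted spatial graph: node coordinates in micrometres, edges between
#' consecutive skeleton points, root at the soma centre. Cycles (from
#' touching processes) are pruned to a spanning tree at construction.
#'
#' @param nodes numeric matrix `n x 3` (micrometres).
#' @param edges integer matrix `m x 2` of node indices.
#' @param root index of the root node.
#' @return object of class `skeleton_graph`.
#' @export
skeleton_graph <- function(nodes, edges, root = 1L) {
  stopifnot(ncol(nodes) == 3, ncol(edges) == 2, root >= 1, root <= nrow(nodes))
  w <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                     nodes[edges[, 2], , drop = FALSE])^2))
  if (any(w <= 0)) stop("zero-length skeleton edge")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < nrow(nodes))
    g <- igraph::add_vertices(g, nrow(nodes) - igraph::vcount(g))
  if (igraph::components(g)$no > 1)
    stop("skeleton graph is not connected")
  if (igraph::ecount(g) > nrow(nodes) - 1) {       # loop pruning
    g <- igraph::mst(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- matrix(as.integer(el), ncol = 2)
    w <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                       nodes[edges[, 2], , drop = FALSE])^2))
  }
  structure(list(nodes = nodes, edges = edges, lengths = w, root = as.integer(root)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d edges, total length %.1f um\n",
              nrow(x$nodes), nrow(x$edges), sum(x$lengths)))
  invisible(x)
}

#' Ground-truth skeleton of a simulated cell model
#'
#' Builds the skeleton graph directly from the model's polylines (nominal
#' tips), bypassing rasterization: the exact reference for Sholl and length
#' metrics.
#'
#' @param model a [build_cell_model()] cell.
#' @return a `skeleton_graph` rooted at the soma centre.
#' @export
skeleton_from_model <- function(model) {
  nodes <- matrix(model$soma_center, 1, 3)
  edges <- NULL
  offsets <- integer(model$n_branches)   # row index of each branch's node 1
  for (i in seq_along(model$branches)) {
    b <- model$branches[[i]]
    pts <- b$nodes[seq_len(b$n_nom + 1L), , drop = FALSE]
    attach_row <- if (b$parent == 0L) 1L else offsets[b$parent] + b$parent_node - 1L
    # skip the duplicated attachment point for child branches
    first <- if (b$parent == 0L) 1L else 2L
    start_row <- nrow(nodes) + 1L
    nodes <- rbind(nodes, pts[first:nrow(pts), , drop = FALSE])
    offsets[i] <- start_row - (first - 1L)
    rows <- seq(start_row, nrow(nodes))
    edges <- rbind(edges, cbind(c(attach_row, rows[-length(rows)]), rows))
  }
  skeleton_graph(nodes, edges, root = 1L)
}

# linear interpolation of a binary volume to an isotropic grid (threshold 0.5)
resample_isotropic <- function(mask, sp) {
  s_iso <- min(sp)
  vol <- mask * 1.0
  for (axis in 1:3) {
    if (abs(sp[axis] - s_iso) < 1e-9) next
    d <- dim(vol)
    n_new <- max(2L, as.integer(round(d[axis] * sp[axis] / s_iso)))
    pos <- ((seq_len(n_new) - 0.5) * s_iso) / sp[axis] + 0.5  # in source plane units
    lo <- pmin(pmax(floor(pos), 1L), d[axis])
    hi <- pmin(lo + 1L, d[axis])
    wgt <- pmin(pmax(pos - lo, 0), 1)
    slice <- function(v, ax, i) {
      if (ax == 1) v[i, , , drop = FALSE]
      else if (ax == 2) v[, i, , drop = FALSE]
      else v[, , i, drop = FALSE]
    }
    newd <- d; newd[axis] <- n_new
    out <- array(0, newd)
    for (k in seq_len(n_new)) {
      pl <- (1 - wgt[k]) * slice(vol, axis, lo[k]) + wgt[k] * slice(vol, axis, hi[k])
      if (axis == 1) out[k, , ] <- pl else if (axis == 2) out[, k, ] <- pl
      else out[, , k] <- pl
    }
    vol <- out
  }
  list(mask = vol >= 0.5, spacing = s_iso)
}

#' Skeletonize a 3D cell mask
#'
#' Topology-preserving medial-axis extraction: the mask is resampled to an
#' isotropic grid (so the coarse z-step does not bias the skeleton), thinned
#' to a 1-voxel-wide skeleton by distance-ordered simple-point deletion with
#' endpoint preservation, converted to a spatial graph and rooted at the
#' soma (the deepest point of the distance transform). Short spurs produced
#' by surface noise are pruned.
#'
#' @param mask logical 3D array (single connected component).
#' @param voxel_size_xy,voxel_size_z voxel pitch in micrometres.
#' @param prune_um remove terminal branches shorter than this (micrometres).
#' @param root_um optional root position in micrometres (default: distance-
#'   transform maximum, i.e. the soma centre).
#' @return a `skeleton_graph`.
#' @export
skeletonize_cell <- function(mask, voxel_size_xy = 1, voxel_size_z = 1,
                             prune_um = 3, root_um = NULL) {
  if (!any(mask)) stop("empty mask")
  sp <- c(voxel_size_xy, voxel_size_xy, voxel_size_z)
  lab <- array(cpp_label3d(mask, dim(mask), 26L), dim(mask))
  ncomp <- max(lab)
  if (ncomp > 1) {
    warning("mask has ", ncomp, " components; skeletonizing the largest")
    main <- which.max(tabulate(lab[lab > 0], nbins = ncomp))
    mask <- lab == main
  }
  iso <- resample_isotropic(mask, sp)
  m <- iso$mask; s <- iso$spacing
  dt <- array(cpp_chamfer_dt(m, dim(m), s, s, s), dim(m))
  if (is.null(root_um)) {
    rootvox <- which(dt == max(dt), arr.ind = TRUE)[1, ]
    root_um <- (rootvox - 0.5) * s
  }
  skel <- array(cpp_thin3d(m, dim(m)), dim(m))
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("skeleton is empty")
  coords <- sweep(idx - 0.5, 2, s, "*")
  if (nrow(idx) == 1)
    return(skeleton_graph(rbind(coords, coords + c(s, 0, 0) * 1e-3) * 1,
                          matrix(c(1L, 2L), 1), root = 1L))
  # edges between 26-adjacent skeleton voxels
  key <- (idx[, 1] - 1) + dim(m)[1] * ((idx[, 2] - 1) + dim(m)[2] * (idx[, 3] - 1))
  lookup <- new.env(hash = TRUE, size = nrow(idx))
  for (i in seq_len(nrow(idx))) assign(as.character(key[i]), i, envir = lookup)
  e1 <- e2 <- integer(0)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  dm <- dim(m)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nk <- (nb[ok, 1] - 1) + dm[1] * ((nb[ok, 2] - 1) + dm[2] * (nb[ok, 3] - 1))
    src <- which(ok)
    for (j in seq_along(nk)) {
      hit <- mget(as.character(nk[j]), envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(hit)) { e1 <- c(e1, src[j]); e2 <- c(e2, hit) }
    }
  }
  root <- which.min(colSums((t(coords) - root_um)^2))
  sg <- skeleton_graph(coords, cbind(e1, e2), root = root)
  sg <- prune_spurs(sg, prune_um)
  smooth_chains(sg)
}

# laplacian smoothing of degree-2 chain nodes: removes the voxel zigzag that
# inflates path lengths (junctions, leaves and the root stay fixed)
smooth_chains <- function(sg, iterations = 3) {
  n <- nrow(sg$nodes)
  deg <- tabulate(c(sg$edges[, 1], sg$edges[, 2]), nbins = n)
  nb1 <- nb2 <- integer(n)
  for (k in seq_len(nrow(sg$edges))) {
    a <- sg$edges[k, 1]; b <- sg$edges[k, 2]
    if (nb1[a] == 0L) nb1[a] <- b else nb2[a] <- b
    if (nb1[b] == 0L) nb1[b] <- a else nb2[b] <- a
  }
  movable <- deg == 2 & seq_len(n) != sg$root
  pts <- sg$nodes
  for (it in seq_len(iterations)) {
    new_pts <- pts
    new_pts[movable, ] <- 0.5 * pts[movable, , drop = FALSE] +
      0.25 * (pts[nb1[movable], , drop = FALSE] + pts[nb2[movable], , drop = FALSE])
    pts <- new_pts
  }
  sg$nodes <- pts
  sg$lengths <- sqrt(rowSums((pts[sg$edges[, 1], , drop = FALSE] -
                              pts[sg$edges[, 2], , drop = FALSE])^2))
  sg
}

# iteratively remove leaf branches shorter than `prune_um`
prune_spurs <- function(sg, prune_um) {
  if (prune_um <= 0) return(sg)
  repeat {
    g <- igraph::graph_from_edgelist(sg$edges, directed = FALSE)
    igraph::E(g)$weight <- sg$lengths
    if (igraph::vcount(g) < nrow(sg$nodes))
      g <- igraph::add_vertices(g, nrow(sg$nodes) - igraph::vcount(g))
    deg <- igraph::degree(g)
    leaves <- setdiff(which(deg == 1), sg$root)
    drop <- integer(0)
    for (lf in leaves) {
      path <- lf; cur <- lf; prev <- 0L; len <- 0
      repeat {
        nbrs <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nbrs) != 1) break
        nxt <- nbrs[1]
        len <- len + sqrt(sum((sg$nodes[cur, ] - sg$nodes[nxt, ])^2))
        if (igraph::degree(g, nxt) > 2 || nxt == sg$root) break
        prev <- cur; cur <- nxt; path <- c(path, cur)
      }
      if (len < prune_um) drop <- c(drop, path)
    }
    drop <- setdiff(unique(drop), sg$root)
    if (length(drop) == 0) return(sg)
    if (length(drop) >= nrow(sg$nodes) - 1) {
      # everything prunes away (soma-only cell): collapse to the root
      p <- sg$nodes[sg$root, , drop = FALSE]
      return(skeleton_graph(rbind(p, p + c(1e-3, 0, 0)),
                            matrix(c(1L, 2L), 1), root = 1L))
    }
    keep <- setdiff(seq_len(nrow(sg$nodes)), drop)
    remap <- integer(nrow(sg$nodes)); remap[keep] <- seq_along(keep)
    ekeep <- sg$edges[, 1] %in% keep & sg$edges[, 2] %in% keep
    edges <- cbind(remap[sg$edges[ekeep, 1]], remap[sg$edges[ekeep, 2]])
    sg <- skeleton_graph(sg$nodes[keep, , drop = FALSE], edges,
                         root = remap[sg$root])
  }
}

#' Sholl profile of a skeleton
#'
#' Counts skeleton edges crossing concentric spheres of increasing radius
#' centred at the root. The number of processes `P` is the crossing count at
#' the first shell outside the soma radius (primary processes).
#'
#' @param skeleton a `skeleton_graph`.
#' @param step shell spacing in micrometres (default 5).
#' @param soma_radius soma radius in micrometres used to place the first
#'   process-counting shell (default 0: the first shell).
#' @return data frame of class `sholl_profile` with columns `radius_um` and
#'   `crossings`; attributes `n_processes` and `total_length_um`.
#' @export
sholl <- function(skeleton, step = 5, soma_radius = 0) {
  stopifnot(step > 0)
  dists <- sqrt(colSums((t(skeleton$nodes) - skeleton$nodes[skeleton$root, ])^2))
  # stabilize shell-boundary comparisons: a node at radius r (up to floating-
  # point rounding) lies on the shell and its inbound edge counts as crossing
  dists <- round(dists, 9)
  d1 <- dists[skeleton$edges[, 1]]
  d2 <- dists[skeleton$edges[, 2]]
  rmax <- max(dists)
  radii <- seq(step, max(step, ceiling(rmax / step) * step), by = step)
  crossings <- vapply(radii, function(r) sum((d1 < r) != (d2 < r)), 0L)
  first_out <- which(radii > soma_radius)[1]
  p <- if (is.na(first_out)) 0L else crossings[first_out]
  out <- data.frame(radius_um = radii, crossings = crossings)
  attr(out, "n_processes") <- p
  attr(out, "total_length_um") <- sum(skeleton$lengths)
  class(out) <- c("sholl_profile", "data.frame")
  out
}

#' Total process length of a skeleton
#'
#' Sum of the Euclidean distances between consecutive skeleton nodes, in
#' micrometres. Invariant to node ordering and to the choice of root.
#'
#' @param skeleton a `skeleton_graph`.
#' @return length in micrometres.
#' @export
total_process_length <- function(skeleton) {
  stopifnot(nrow(skeleton$nodes) >= 2)
  sum(skeleton$lengths)
}

#' Cell volume from a binary mask
#'
#' @param mask logical 3D array.
#' @param voxel_size_xy,voxel_size_z voxel pitch in micrometres.
#' @return volume in cubic micrometres (voxel count x voxel volume).
#' @export
cell_volume <- function(mask, voxel_size_xy = 1, voxel_size_z = 1) {
  if (!any(mask)) stop("empty mask")
  sum(mask) * voxel_size_xy^2 * voxel_size_z
}

#' Compartmental signal quantification
#'
#' Assigns a binarized signal (e.g. mRNA puncta) to the soma or process
#' compartment of a cell and reports the process-to-soma volume ratio and
#' the total signal volume normalized to cell volume.
#'
#' @param cell_mask,soma_mask,signal_mask logical 3D arrays of one shape;
#'   `soma_mask` must be contained in `cell_mask`. Signal outside the cell
#'   is ignored.
#' @param voxel_size_xy,voxel_size_z voxel pitch in micrometres.
#' @return list of class `compartment_signal`: `soma_um3`, `process_um3`,
#'   `ratio` (process/soma; `NA` with `ratio_defined = FALSE` when the soma
#'   holds no signal), `normalized` (signal volume / cell volume).
#' @export
compartment_ratio <- function(cell_mask, soma_mask, signal_mask,
                              voxel_size_xy = 1, voxel_size_z = 1) {
  stopifnot(identical(dim(cell_mask), dim(soma_mask)),
            identical(dim(cell_mask), dim(signal_mask)))
  if (any(soma_mask & !cell_mask)) stop("soma_mask must be contained in cell_mask")
  vv <- voxel_size_xy^2 * voxel_size_z
  sig <- signal_mask & cell_mask
  soma_v <- sum(sig & soma_mask) * vv
  proc_v <- sum(sig & !soma_mask) * vv
  structure(list(soma_um3 = soma_v, process_um3 = proc_v,
                 ratio = if (soma_v > 0) proc_v / soma_v else NA_real_,
                 ratio_defined = soma_v > 0,
                 normalized = sum(sig) / sum(cell_mask)),
            class = "compartment_signal")
}

#' @export
print.compartment_signal <- function(x, ...) {
  cat(sprintf("<compartment_signal> soma %.1f um^3, processes %.1f um^3; P/S ratio %s; signal/cell %.3f\n",
              x$soma_um3, x$process_um3,
              if (x$ratio_defined) sprintf("%.2f", x$ratio) else "undefined",
              x$normalized))
  invisible(x)
}

#' Write a skeleton graph in SWC format
#'
#' Standard neuron-morphology text format: one node per line with
#' `id type x y z radius parent`. The root is written as type 1 (soma),
#' other nodes as type 3.
#'
#' @param skeleton a `skeleton_graph`.
#' @param path output file.
#' @param radius node radius column value (micrometres).
#' @export
write_swc <- function(skeleton, path, radius = 0.5) {
  g <- igraph::graph_from_edgelist(skeleton$edges, directed = FALSE)
  if (igraph::vcount(g) < nrow(skeleton$nodes))
    g <- igraph::add_vertices(g, nrow(skeleton$nodes) - igraph::vcount(g))
  bfs <- igraph::bfs(g, root = skeleton$root, father = TRUE)
  ord <- as.integer(bfs$order)
  parent <- as.integer(bfs$father)
  newid <- integer(nrow(skeleton$nodes)); newid[ord] <- seq_along(ord)
  lines <- character(length(ord))
  for (k in seq_along(ord)) {
    v <- ord[k]
    p <- if (v == skeleton$root || is.na(parent[v])) -1L else newid[parent[v]]
    ty <- if (v == skeleton$root) 1L else 3L
    lines[k] <- sprintf("%d %d %.4f %.4f %.4f %.3f %d", k, ty,
                        skeleton$nodes[v, 1], skeleton$nodes[v, 2],
                        skeleton$nodes[v, 3], radius, p)
  }
  writeLines(c("# SWC skeleton (micrometres)", lines), path)
  invisible(path)
}
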