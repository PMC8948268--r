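#' Rayburst parameters
#'
#' Controls the ray-casting local diameter estimator: `n_rays` evenly spaced
#' directions in the plane orthogonal to the local tangent; each opposed ray
#' pair contributes one chord, the boundary being located by sub-voxel linear
#' interpolation of the 0.5-level crossing of the trilinearly sampled mask.
#' The default aggregate, `"median_lower_band"`, is the rayburst rule: the
#' median of the chords at or below the overall median chord. On a circular
#' section all chords agree, so it reads the true diameter; on elongated or
#' fused sections (oblique cuts, branch junctions) it reads the minor axis
#' instead of being dragged up by the long chords. `"median_chord"` and
#' `"min_chord"` are plain alternatives.
#'
#' @param n_rays even integer >= 8.
#' @param aggregate `"median_lower_band"`, `"median_chord"` or `"min_chord"`.
#' @param max_ray_um search limit per ray; rays with no boundary within the
#'   limit make the chord unbounded, and points with no bounded chord are
#'   returned as `NA` and excluded from statistics.
#' @param step_um ray marching step (um).
#' @return An `hv_rayburst_params`.
#' @export
rayburst_params <- function(n_rays = 32L,
                            aggregate = c("median_lower_band", "median_chord",
                                          "min_chord"),
                            max_ray_um = 40, step_um = 0.25) {
  aggregate <- match.arg(aggregate)
  n_rays <- as.integer(n_rays)
  if (n_rays < 8L || n_rays %% 2L != 0L)
    stop("'n_rays' must be even and >= 8")
  if (max_ray_um <= 0) stop("'max_ray_um' must be > 0")
  structure(list(n_rays = n_rays, aggregate = aggregate,
                 max_ray_um = max_ray_um, step_um = step_um),
            class = "hv_rayburst_params")
}

#' Local vessel diameter at a point (rayburst-style ray casting)
#'
#' @param mask an `hv_mask`.
#' @param point_um (z, y, x) position in micrometres; must lie in foreground.
#' @param tangent_um nonzero (z, y, x) local tangent; rays are cast in the
#'   orthogonal plane.
#' @param params an [rayburst_params()].
#' @return Diameter in micrometres, or `NA` when every opposed ray pair is
#'   unbounded within `max_ray_um`.
#' @export
local_diameter <- function(mask, point_um, tangent_um,
                           params = rayburst_params()) {
  stopifnot(inherits(mask, "hv_mask"))
  if (sqrt(sum(tangent_um^2)) <= 0) stop("'tangent_um' must be nonzero")
  d <- ray_diameters(mask, rbind_vec(point_um), rbind_vec(tangent_um), params)
  if (is.na(d) && !point_in_mask(mask, point_um))
    stop("point lies in the background of the mask")
  d
}

point_in_mask <- function(mask, p) {
  i <- floor((p - mask$origin_um) / mask$voxel_size_um)
  n <- dim(mask$data)
  if (any(i < 0) || any(i >= n)) return(FALSE)
  mask$data[1 + i[1] + n[1] * (i[2] + n[2] * i[3])]
}

ray_diameters <- function(mask, points, tangents, params) {
  cpp_ray_diameters(mask$data, dim(mask$data), mask$voxel_size_um,
                    mask$origin_um, points, tangents,
                    params$n_rays, params$step_um, params$max_ray_um,
                    switch(params$aggregate, min_chord = 1L,
                           median_lower_band = 2L, 0L))
}

#' Measure local diameters along a skeleton graph
#'
#' The tangent at each node is the normalized central difference of its
#' neighbour positions along the branch (one-sided at endpoints); the
#' rayburst diameter is stored per node, and each branch gets the median
#' over its non-junction nodes. Nodes with unbounded rays are recorded as
#' `NA` and excluded from branch medians.
#'
#' @param sk an `hv_skeleton` derived from `mask`.
#' @param mask the `hv_mask` the skeleton came from.
#' @param params an [rayburst_params()].
#' @return `sk` with `nodes$radius_um`/`nodes$diameter_um` filled and a
#'   `branches` data.frame (branch id, n nodes, length, median diameter).
#' @export
measure_graph <- function(sk, mask, params = rayburst_params()) {
  stopifnot(inherits(sk, "hv_skeleton"), inherits(mask, "hv_mask"))
  nv <- igraph::vcount(sk$graph)
  if (nv == 0) return(sk)
  pts <- as.matrix(sk$nodes[, c("z", "y", "x")])
  nbr <- lapply(igraph::adjacent_vertices(sk$graph, seq_len(nv)), as.integer)
  tang <- matrix(0, nv, 3)
  for (v in seq_len(nv)) {
    nb <- nbr[[v]]
    tang[v, ] <- if (length(nb) == 0) {
      c(0, 0, 1)
    } else if (length(nb) == 1) {
      pts[nb, ] - pts[v, ]                       # one-sided at endpoints
    } else if (length(nb) == 2) {
      pts[nb[2], ] - pts[nb[1], ]                # central difference
    } else {
      # junction: dominant direction of incident edges
      dd <- sweep(pts[nb, , drop = FALSE], 2, pts[v, ])
      dd[which.max(rowSums(dd^2)), ]
    }
  }
  diam <- ray_diameters(mask, pts, tang, params)
  sk$nodes$diameter_um <- diam
  sk$nodes$radius_um <- diam / 2
  deg <- igraph::degree(sk$graph)
  paths <- branch_paths(sk)
  sk$branches <- do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    inner <- p[deg[p] < 3]                       # junction nodes excluded
    d <- diam[inner]
    data.frame(branch = i, n_nodes = length(p),
               length_um = path_length_um(sk, p),
               diameter_um = if (all(is.na(d))) NA_real_ else
                 stats::median(d, na.rm = TRUE))
  }))
  sk
}

#' Accompaniment parameters for vein classification
#'
#' @param companion_radius_um search distance from a vein centerline node to
#'   companion (HA/BD/LV) foreground.
#' @param min_companion_fraction fraction of a component's nodes that must
#'   have a companion nearby for a PV call (boundary inclusive: a fraction
#'   exactly at the threshold is PV).
#' @return An `hv_accompaniment_params`.
#' @export
accompaniment_params <- function(companion_radius_um = 30,
                                 min_companion_fraction = 0.5) {
  if (companion_radius_um <= 0) stop("'companion_radius_um' must be > 0")
  if (min_companion_fraction <= 0 || min_companion_fraction > 1)
    stop("'min_companion_fraction' must be in (0, 1]")
  structure(list(companion_radius_um = companion_radius_um,
                 min_companion_fraction = min_companion_fraction),
            class = "hv_accompaniment_params")
}

#' Classify vein components as portal or hepatic vein
#'
#' Implements the accompaniment principle: the portal vein runs with hepatic
#' artery, bile duct and lymphatic vessels while the hepatic vein runs
#' alone. For every connected component of the vein skeleton the fraction of
#' nodes with any companion foreground within `companion_radius_um` (one
#' Euclidean distance-transform lookup per companion mask) decides the
#' class: fraction >= `min_companion_fraction` is PV, otherwise HV.
#'
#' @param vein_sk vein `hv_skeleton` (geometry co-registered with the masks).
#' @param companion_masks named list of `hv_mask` (any of HA, BD, LV); empty
#'   or all-empty masks classify everything HV, with a warning.
#' @param params an [accompaniment_params()].
#' @return data.frame per component: `component`, `n_nodes`,
#'   `companion_fraction`, `class` ("PV"/"HV"); also attached to
#'   `vein_sk$nodes$vein_class` via the returned attribute `node_class`.
#' @export
classify_veins <- function(vein_sk, companion_masks,
                           params = accompaniment_params()) {
  stopifnot(inherits(vein_sk, "hv_skeleton"))
  nv <- igraph::vcount(vein_sk$graph)
  comp <- igraph::components(vein_sk$graph)
  have <- Filter(function(m) inherits(m, "hv_mask") && any(m$data), companion_masks)
  near <- rep(FALSE, nv)
  if (length(have) == 0) {
    warning("all companion masks empty: every vein component classified HV")
  } else {
    for (m in have) {
      dt <- cpp_edt3d(m$data, dim(m$data), m$voxel_size_um)
      dim(dt) <- dim(m$data)
      # distance lookup at each node voxel
      idx <- floor(sweep(as.matrix(vein_sk$nodes[, c("z", "y", "x")]),
                         2, m$origin_um) %*% diag(1 / m$voxel_size_um))
      idx <- pmin(pmax(idx, 0), matrix(dim(m$data) - 1L, nv, 3, byrow = TRUE))
      lin <- 1 + idx[, 1] + dim(m$data)[1] * (idx[, 2] + dim(m$data)[2] * idx[, 3])
      near <- near | dt[lin] <= params$companion_radius_um
    }
  }
  out <- do.call(rbind, lapply(seq_len(comp$no), function(ci) {
    vs <- comp$membership == ci
    fr <- mean(near[vs])
    data.frame(component = ci, n_nodes = sum(vs), companion_fraction = fr,
               class = if (fr >= params$min_companion_fraction) "PV" else "HV")
  }))
  attr(out, "node_class") <- out$class[comp$membership]
  out
}

#' Sinusoid diameter statistics with the 15 um cutoff
#'
#' Counts only vessels with diameter strictly less than `cutoff_um`
#' (structures of 15 um and above are terminal arterioles / terminal portal
#' venules, not sinusoids). Each block contributes its mean filtered
#' diameter; the headline mean and sample SD (n - 1) are computed across
#' block means, matching a blocks-as-replicates design; pooled per-node
#' statistics are reported alongside.
#'
#' @param block_diameters list with one numeric vector of node diameters
#'   (um) per block; `NA`s (unbounded rayburst points) are dropped.
#' @param cutoff_um strict upper cutoff (default 15).
#' @return An `hv_diameter_stats`: `mean_um`, `sd_um` (across blocks),
#'   `n_blocks`, `block_means_um`, `pooled_mean_um`, `pooled_sd_um`,
#'   `n_points` (after filtering), `n_excluded`, `cutoff_um`.
#' @export
sinusoid_stats <- function(block_diameters, cutoff_um = 15) {
  if (!is.list(block_diameters) || length(block_diameters) < 1)
    stop("need at least one block of diameters")
  filt <- lapply(block_diameters, function(d) {
    d <- d[!is.na(d)]
    d[d < cutoff_um]
  })
  n_points <- sum(lengths(filt))
  if (n_points == 0)
    stop("no diameters below the cutoff: empty result")
  bm <- vapply(filt, function(d) if (length(d)) mean(d) else NA_real_, numeric(1))
  bm_ok <- bm[!is.na(bm)]
  pooled <- unlist(filt)
  structure(list(
    mean_um = mean(bm_ok),
    sd_um = if (length(bm_ok) > 1) stats::sd(bm_ok) else NA_real_,
    n_blocks = length(bm_ok),
    block_means_um = bm,
    pooled_mean_um = mean(pooled),
    pooled_sd_um = if (length(pooled) > 1) stats::sd(pooled) else NA_real_,
    n_points = n_points,
    n_excluded = sum(lengths(block_diameters)) - n_points,
    cutoff_um = cutoff_um), class = "hv_diameter_stats")
}

#' @export
print.hv_diameter_stats <- function(x, ...) {
  cat(sprintf("<hv_diameter_stats> %.2f +/- %.2f um (n = %d blocks, %d points < %g um)\n",
              x$mean_um, x$sd_um, x$n_blocks, x$n_points, x$cutoff_um))
  cat(sprintf("  pooled: %.2f +/- %.2f um; %d excluded at/above cutoff\n",
              x$pooled_mean_um, x$pooled_sd_um, x$n_excluded))
  invisible(x)
}

#' Export per-node morphometry as CSV
#'
#' Columns: x, y, z (um), diameter_um, class (when available).
#'
#' @param sk measured `hv_skeleton` from [measure_graph()].
#' @param path output CSV.
#' @param node_class optional per-node class labels.
#' @return `path`, invisibly.
#' @export
write_node_csv <- function(sk, path, node_class = NULL) {
  df <- data.frame(x = sk$nodes$x, y = sk$nodes$y, z = sk$nodes$z,
                   diameter_um = sk$nodes$diameter_um)
  if (!is.null(node_class)) df$class <- node_class
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
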