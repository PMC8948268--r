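#' Phantom configuration
#'
#' Builds the configuration for the synthetic dual-channel liver phantom.
#' The default models a sinusoid-scale block (128 x 128 x 128 um, rasterized
#' on an anisotropic grid of 1 x 0.5 x 0.5 um, i.e. the native
#' 0.32 x 0.32 x 1 um xy-grid coarsened so desk-scale volumes stay small):
#' one portal-vein (PV) and one hepatic-vein (HV) stub entering from opposite
#' faces, companion hepatic artery / bile duct / lymphatic tubes along the PV
#' only, and a capillary sinusoid mesh whose log-normal diameters fall mostly
#' in the 7-15 um range (median 9.5 um => mean ~9.65 um). See
#' [phantom_config_veins()] for the large-vessel scene.
#'
#' @param volume_size_um (z, y, x) world extent.
#' @param voxel_size_um (z, y, x) raster grid.
#' @param seed integer; fully determines the generated scene.
#' @param vein_tree list: `root_radius_um`, `decay` (Murray-type child/parent
#'   radius ratio), `depth` (generations; 1 = unbranched root), `tortuosity`
#'   (relative jitter of the growth direction), `branch_angle_deg`,
#'   `branch_length_um` (root branch length; shrinks by 0.7 per generation),
#'   `taper` (end/start radius within one tube).
#' @param companion list: `radii_um` (named HA/BD/LV), `gap_um` clearance
#'   between the PV surface and each companion; companions run parallel to
#'   their PV tube at offset `local PV radius + gap + companion radius`.
#' @param sinusoid list: `enabled`, `junction_density_per_1000_um3`,
#'   `radius_median_um`, `radius_sigma_log` (log-normal), `max_edge_um`,
#'   `k_neighbors`.
#' @param pbp list: `enabled`, `radius_um`, `offset_um`, `pitch_um` — a
#'   peribiliary capillary helix around each bile duct.
#' @param noise list: `photon_gain` (Poisson counts per unit intensity; 0
#'   disables), `read_sd` (additive Gaussian SD).
#' @param intensity list: `wall`, `lumen`, `background`, `wall_thickness_um`
#'   (vessel channel); `cyto_background`, `nuclei`, `nuclei_radius_um`,
#'   `nuclei_density_per_1000_um3` (cytoarchitecture channel).
#' @return A validated `hv_phantom_config`.
#' @export
phantom_config <- function(volume_size_um = c(128, 128, 128),
                           voxel_size_um = c(1, 0.5, 0.5),
                           seed = 1L,
                           vein_tree = list(),
                           companion = list(),
                           sinusoid = list(),
                           pbp = list(),
                           noise = list(),
                           intensity = list()) {
  cfg <- list(
    volume_size_um = as.numeric(volume_size_um),
    voxel_size_um = as.numeric(voxel_size_um),
    seed = as.integer(seed),
    vein_tree = utils::modifyList(list(
      root_radius_um = 8, decay = 0.72, depth = 1L, tortuosity = 0.12,
      branch_angle_deg = 40, branch_length_um = 0.45 * max(volume_size_um),
      taper = 0.95), vein_tree),
    companion = utils::modifyList(list(
      enabled = TRUE, radii_um = c(HA = 3, BD = 2.5, LV = 3), gap_um = 2),
      companion),
    sinusoid = utils::modifyList(list(
      enabled = TRUE, junction_density_per_1000_um3 = 0.06,
      radius_median_um = 4.75, radius_sigma_log = 0.18,
      max_edge_um = 40, k_neighbors = 2L), sinusoid),
    pbp = utils::modifyList(list(
      enabled = TRUE, radius_um = 1.5, offset_um = 4, pitch_um = 12), pbp),
    noise = utils::modifyList(list(photon_gain = 50, read_sd = 0.01), noise),
    intensity = utils::modifyList(list(
      wall = 0.85, lumen = 0.02, background = 0.03, wall_thickness_um = 2,
      solid_max_radius_um = 8, cyto_background = 0.15, nuclei = 0.8,
      nuclei_radius_um = 3.5, nuclei_density_per_1000_um3 = 0.06), intensity)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "hv_phantom_config")
}

#' Large-vessel phantom configuration
#'
#' The vein-scale scene used for the 5 um working-resolution workflow:
#' branched PV and HV trees with companion tubes, no sinusoid mesh (sinusoids
#' are sub-resolution at 5 um), rasterized at 2.5 um isotropic.
#'
#' @param seed integer seed.
#' @param volume_size_um,voxel_size_um grid, as in [phantom_config()].
#' @param companions logical; generate HA/BD/LV companion tubes along the PV.
#' @param ... forwarded to [phantom_config()].
#' @return An `hv_phantom_config`.
#' @export
phantom_config_veins <- function(seed = 1L,
                                 volume_size_um = c(512, 512, 512),
                                 voxel_size_um = c(2.5, 2.5, 2.5),
                                 companions = TRUE,
                                 vein_tree = list(), companion = list(), ...) {
  phantom_config(volume_size_um = volume_size_um, voxel_size_um = voxel_size_um,
                 seed = seed,
                 vein_tree = utils::modifyList(
                   list(root_radius_um = 40, decay = 0.75, depth = 3L,
                        tortuosity = 0.08, branch_angle_deg = 35,
                        branch_length_um = 0.3 * max(volume_size_um)),
                   vein_tree),
                 companion = utils::modifyList(
                   list(enabled = companions,
                        radii_um = c(HA = 9, BD = 8, LV = 9), gap_um = 10),
                   companion),
                 sinusoid = list(enabled = FALSE),
                 pbp = list(enabled = FALSE),
                 ...)
}

validate_phantom_config <- function(cfg) {
  if (any(cfg$volume_size_um <= 0) || any(cfg$voxel_size_um <= 0))
    stop("volume and voxel sizes must be strictly positive")
  if (cfg$vein_tree$root_radius_um <= 0 || cfg$vein_tree$decay <= 0 ||
      cfg$vein_tree$depth < 1)
    stop("invalid vein_tree parameters")
  if (2 * cfg$vein_tree$root_radius_um >= min(cfg$volume_size_um))
    stop("volume too small to fit the root radius")
  if (cfg$sinusoid$enabled && cfg$sinusoid$radius_median_um >= 7.5)
    stop("sinusoid radius median must be < 7.5 um so diameters stay mostly ",
         "below the 15 um sinusoid cutoff")
  invisible(cfg)
}

#' Read a phantom configuration from a YAML file
#'
#' Keys mirror the arguments of [phantom_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file.
#' @return An `hv_phantom_config`.
#' @export
read_phantom_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(phantom_config)))]
  if (!is.null(seed)) args$seed <- seed
  do.call(phantom_config, args)
}

with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

unitize <- function(v) v / sqrt(sum(v^2))

rand_perp <- function(d) {
  # deterministic-by-RNG unit vector perpendicular to d
  repeat {
    r <- stats::rnorm(3)
    p <- r - sum(r * d) * d
    n <- sqrt(sum(p^2))
    if (n > 1e-6) return(p / n)
  }
}

rotate_about <- function(v, axis, angle) {
  # Rodrigues rotation
  axis <- unitize(axis)
  v * cos(angle) + cross3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

clamp_point <- function(p, margin, size) pmin(pmax(p, margin), size - margin)

clamp_box <- function(p, lo, hi) pmin(pmax(p, lo), hi)

# grow one tube as a jittered straight walk inside the box [lo, hi];
# returns polyline + end direction
grow_polyline <- function(start, dir, length_um, radius, tortuosity, lo, hi) {
  step <- max(2, length_um / 12)
  n <- max(3L, ceiling(length_um / step))
  pts <- matrix(0, n + 1, 3)
  pts[1, ] <- start
  d <- unitize(dir)
  for (i in seq_len(n)) {
    jit <- stats::rnorm(3) * tortuosity
    jit <- jit - sum(jit * d) * d          # jitter perpendicular to heading
    d <- unitize(d + jit)
    nxt <- pts[i, ] + d * (length_um / n)
    nxt <- clamp_box(nxt, lo, hi)
    # steer away from walls: recompute heading after clamping
    if (i > 1) d <- unitize(nxt - pts[i, ] + 1e-9)
    pts[i + 1, ] <- nxt
  }
  list(points = pts, end_dir = d)
}

#' Generate a ground-truth vessel tree
#'
#' Recursive bifurcation with Murray-type radius decay
#' (`r_child = decay * r_parent`) grows one PV and one interdigitated HV tree
#' from opposite faces; every PV tube carries parallel HA/BD/LV companion
#' tubes (the accompaniment structure of the portal triad), while HV tubes
#' have none; terminal PV and HV tips are connected through a random
#' geometric sinusoid mesh with log-normal radii; an optional peribiliary
#' helix wraps each bile duct. Deterministic given `config$seed`.
#'
#' @param config an [phantom_config()].
#' @return An `hv_vessel_tree`: list of tubes, each with `points` (n x 3
#'   matrix, (z, y, x) um), `radius_um` (per point), `class`
#'   (see [VESSEL_CLASSES]) and `parent` (tube index or NA).
#' @export
generate_tree <- function(config) {
  stopifnot(inherits(config, "hv_phantom_config"))
  with_local_seed(config$seed, {
    size <- config$volume_size_um
    vt <- config$vein_tree
    tubes <- list()
    tips <- list(PV = list(), HV = list())

    add_tube <- function(points, radius_um, class, parent = NA_integer_) {
      tubes[[length(tubes) + 1]] <<- list(points = points, radius_um = radius_um,
                                          class = class, parent = parent)
      length(tubes)
    }

    # PV and HV trees interdigitate but stay in disjoint bands of y so the
    # two lumen systems never touch (as in a real lobe, where parenchyma
    # separates portal tracts from central/hepatic veins)
    band <- 2 * vt$root_radius_um + 10
    bounds <- list(
      PV = list(lo = c(0, 0, 0), hi = c(size[1], max(size[2] / 2 - band / 2,
                                                     size[2] * 0.2), size[3])),
      HV = list(lo = c(0, min(size[2] / 2 + band / 2, size[2] * 0.8), 0),
                hi = size))
    if (bounds$PV$hi[2] - bounds$PV$lo[2] < 2 * vt$root_radius_um + 2)
      bounds <- list(PV = list(lo = c(0, 0, 0), hi = size),
                     HV = list(lo = c(0, 0, 0), hi = size))

    grow_branch <- function(start, dir, radius, gen, class, parent) {
      len <- vt$branch_length_um * 0.7^(gen - 1)
      bb <- bounds[[class]]
      pl <- grow_polyline(start, dir, len, radius, vt$tortuosity,
                          bb$lo + radius + 1, bb$hi - radius - 1)
      npt <- nrow(pl$points)
      radii <- seq(radius, radius * vt$taper, length.out = npt)
      id <- add_tube(pl$points, radii, class, parent)
      if (gen < vt$depth) {
        ax <- rand_perp(pl$end_dir)
        ang <- vt$branch_angle_deg * pi / 180
        for (sgn in c(1, -1)) {
          cdir <- rotate_about(pl$end_dir, ax, sgn * ang)
          grow_branch(pl$points[npt, ], cdir, vt$decay * radii[npt],
                      gen + 1, class, id)
        }
      } else {
        tips[[class]][[length(tips[[class]]) + 1]] <<- pl$points[npt, ]
      }
      id
    }

    r0 <- vt$root_radius_um
    pv_start <- clamp_box(c(size[1] / 2, 0.35 * size[2], 0),
                          bounds$PV$lo + r0 + 1, bounds$PV$hi - r0 - 1)
    hv_start <- clamp_box(c(size[1] / 2, 0.65 * size[2], size[3]),
                          bounds$HV$lo + r0 + 1, bounds$HV$hi - r0 - 1)
    grow_branch(pv_start, c(0, 0.1, 1), r0, 1, "PV", NA_integer_)
    grow_branch(hv_start, c(0, -0.1, -1), r0, 1, "HV", NA_integer_)

    # companions run parallel to each PV tube at a class-specific phase
    if (isTRUE(config$companion$enabled)) {
      radc <- config$companion$radii_um
      gap <- config$companion$gap_um
      pv_ids <- which(vapply(tubes, function(t) t$class == "PV", logical(1)))
      for (id in pv_ids) {
        tb <- tubes[[id]]
        npt <- nrow(tb$points)
        axis <- unitize(tb$points[npt, ] - tb$points[1, ] + 1e-9)
        base <- rand_perp(axis)
        phase0 <- stats::runif(1, 0, 2 * pi)
        for (j in seq_along(radc)) {
          cls <- names(radc)[j]
          u <- rotate_about(base, axis, phase0 + (j - 1) * 2 * pi / 3)
          off <- tb$radius_um + gap + radc[[j]]
          pts <- tb$points + outer(off, u)
          pts <- t(apply(pts, 1, clamp_point, margin = radc[[j]] + 0.5, size = size))
          add_tube(pts, rep(radc[[j]], npt), cls, id)
        }
      }
    }

    # sinusoid mesh: random geometric graph joining PV tips toward HV tips
    if (isTRUE(config$sinusoid$enabled)) {
      sn <- config$sinusoid
      vol_1000um3 <- prod(size) / 1000
      nj <- max(2L, round(sn$junction_density_per_1000_um3 * vol_1000um3))
      jcts <- cbind(stats::runif(nj, 4, size[1] - 4),
                    stats::runif(nj, 4, size[2] - 4),
                    stats::runif(nj, 4, size[3] - 4))
      ends <- rbind(do.call(rbind, tips$PV), do.call(rbind, tips$HV))
      allp <- rbind(jcts, ends)
      edges <- matrix(integer(0), 0, 2)
      dmat <- as.matrix(stats::dist(allp))
      for (i in seq_len(nj)) {
        ord <- order(dmat[i, ])
        ord <- ord[ord != i]
        near <- ord[seq_len(min(sn$k_neighbors, length(ord)))]
        near <- near[dmat[i, near] <= sn$max_edge_um]
        if (length(near))
          edges <- rbind(edges, cbind(pmin(i, near), pmax(i, near)))
      }
      # attach every vein tip to its nearest junction
      if (nrow(ends) > 0 && nj > 0) {
        for (i in nj + seq_len(nrow(ends))) {
          jn <- which.min(dmat[i, seq_len(nj)])
          edges <- rbind(edges, c(jn, i))
        }
      }
      edges <- unique(edges)
      radii <- stats::rlnorm(nrow(edges), log(sn$radius_median_um),
                             sn$radius_sigma_log)
      for (e in seq_len(nrow(edges))) {
        p <- rbind(allp[edges[e, 1], ], allp[edges[e, 2], ])
        add_tube(p, rep(radii[e], 2), "SINUSOID", NA_integer_)
      }
    }

    # peribiliary plexus: helical capillaries around each bile duct
    if (isTRUE(config$pbp$enabled)) {
      bd_ids <- which(vapply(tubes, function(t) t$class == "BD", logical(1)))
      for (id in bd_ids) {
        tb <- tubes[[id]]
        npt <- nrow(tb$points)
        arc <- c(0, cumsum(sqrt(rowSums(diff(tb$points)^2))))
        axis <- unitize(tb$points[npt, ] - tb$points[1, ] + 1e-9)
        base <- rand_perp(axis)
        for (phase in c(0, pi)) {
          ang <- phase + 2 * pi * arc / config$pbp$pitch_um
          off <- tb$radius_um + config$pbp$offset_um
          pts <- tb$points
          for (i in seq_len(npt))
            pts[i, ] <- tb$points[i, ] + off[i] * rotate_about(base, axis, ang[i])
          pts <- t(apply(pts, 1, clamp_point,
                         margin = config$pbp$radius_um + 0.5, size = size))
          add_tube(pts, rep(config$pbp$radius_um, npt), "PBP", id)
        }
      }
    }

    structure(list(tubes = tubes, config = config), class = "hv_vessel_tree")
  })
}

#' @export
print.hv_vessel_tree <- function(x, ...) {
  cls <- vapply(x$tubes, function(t) t$class, character(1))
  cat(sprintf("<hv_vessel_tree> %d tubes: %s\n", length(x$tubes),
              paste(sprintf("%s=%d", names(table(cls)), table(cls)),
                    collapse = ", ")))
  invisible(x)
}

#' Geometric tip points of a vessel tree
#'
#' Endpoints of the tree used only once across all tube polylines of the
#' given classes — i.e. the free ends the skeleton should reproduce.
#'
#' @param tree an `hv_vessel_tree`.
#' @param classes vessel classes to include.
#' @param tol_um endpoint matching tolerance.
#' @return Matrix of (z, y, x) tip coordinates.
#' @export
tree_tip_points <- function(tree, classes = c("PV", "HV"), tol_um = 1e-6) {
  keep <- vapply(tree$tubes, function(t) t$class %in% classes, logical(1))
  tubes <- tree$tubes[keep]
  ends <- do.call(rbind, lapply(tubes, function(t)
    rbind(t$points[1, ], t$points[nrow(t$points), ])))
  if (is.null(ends)) return(matrix(0, 0, 3))
  used <- rep(0L, nrow(ends))
  d <- as.matrix(stats::dist(ends))
  for (i in seq_len(nrow(ends)))
    used[i] <- sum(d[i, ] <= tol_um) - 1L
  ends[used == 0L, , drop = FALSE]
}

mask_array <- function(n) array(FALSE, n)

stamp_tube <- function(mask, tube, voxel, origin, n) {
  pts <- tube$points
  r <- tube$radius_um
  for (i in seq_len(nrow(pts) - 1))
    cpp_stamp_capsule(mask, n, voxel, origin, pts[i, ], pts[i + 1, ],
                      r[i], r[i + 1])
  mask
}

#' Rasterize a vessel tree into dual-channel volumes with ground truth
#'
#' Vessel channel: PV/HV/HA/LV are drawn as bright endothelial walls
#' (`wall_thickness_um`) around dark lumens; sinusoids and peribiliary
#' capillaries are solid bright tubes (their walls are unresolved at the
#' working voxel sizes); bile ducts are absent (biliary epithelium carries no
#' endothelial label). Cytoarchitecture channel: diffuse cytoplasmic stain
#' plus bright nuclei in the parenchyma, a ring of biliary epithelial nuclei
#' around each bile duct, and dark nuclei-free vessel lumens. Poisson shot
#' noise and additive Gaussian read noise are applied last; with
#' `photon_gain = 0` and `read_sd = 0` the output is noiseless and takes only
#' the configured intensity levels.
#'
#' @param tree an `hv_vessel_tree`.
#' @param config the matching `hv_phantom_config`.
#' @return List with elements `vessel` and `cyto` ([new_volume()] objects)
#'   and `truth`: `label_volume` (class-id grid; precedence
#'   PV/HV > HA/BD/LV > PBP > SINUSOID at overlaps), `class_masks` (one
#'   logical array per class, overlap-free per class), `centerline_points`
#'   (data.frame z, y, x, radius_um, class, tube).
#' @export
rasterize_tree <- function(tree, config = tree$config) {
  stopifnot(inherits(tree, "hv_vessel_tree"))
  n <- pmax(1L, as.integer(round(config$volume_size_um / config$voxel_size_um)))
  voxel <- config$voxel_size_um
  origin <- c(0, 0, 0)
  classes <- unique(vapply(tree$tubes, function(t) t$class, character(1)))
  masks <- setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    m <- mask_array(n)
    for (tb in tree$tubes[vapply(tree$tubes, function(t) t$class == cl, logical(1))])
      m <- stamp_tube(m, tb, voxel, origin, n)
    masks[[cl]] <- m
  }
  # composite label grid: veins override companions override capillaries
  precedence <- c("SINUSOID", "PBP", "HA", "BD", "LV", "PV", "HV")
  label <- array(0L, n)
  for (cl in intersect(precedence, classes))
    label[masks[[cl]]] <- VESSEL_CLASSES[[cl]]

  iv <- config$intensity
  vessel <- array(iv$background, n)
  # endothelial-labelled vessels: tubes thicker than solid_max_radius_um are
  # drawn as bright walls around a dark lumen; thinner ones (wall and lumen
  # unresolved at the working voxel) come out solid bright
  endo <- intersect(c("PV", "HV", "HA", "LV"), classes)
  if (length(endo)) {
    endo_tubes <- tree$tubes[vapply(tree$tubes, function(t)
      t$class %in% endo, logical(1))]
    is_walled <- vapply(endo_tubes, function(t)
      max(t$radius_um) > iv$solid_max_radius_um, logical(1))
    if (any(is_walled)) {
      walled <- mask_array(n)
      for (tb in endo_tubes[is_walled])
        walled <- stamp_tube(walled, tb, voxel, origin, n)
      depth <- cpp_edt3d(!walled, n, voxel)    # distance to background
      wall <- walled & depth <= iv$wall_thickness_um
      vessel[walled] <- iv$lumen
      vessel[wall] <- iv$wall
    }
    if (any(!is_walled)) {
      solid <- mask_array(n)
      for (tb in endo_tubes[!is_walled])
        solid <- stamp_tube(solid, tb, voxel, origin, n)
      vessel[solid] <- iv$wall
    }
  }
  for (cl in intersect(c("SINUSOID", "PBP"), classes))
    vessel[masks[[cl]]] <- iv$wall

  allmask <- Reduce(`|`, masks)
  cyto <- array(iv$cyto_background, n)
  cyto[allmask] <- iv$lumen

  with_local_seed(config$seed, {
    # parenchymal nuclei (outside vessels)
    nn <- round(iv$nuclei_density_per_1000_um3 * prod(config$volume_size_um) / 1000)
    if (nn > 0) {
      ctr <- cbind(stats::runif(nn, 0, config$volume_size_um[1]),
                   stats::runif(nn, 0, config$volume_size_um[2]),
                   stats::runif(nn, 0, config$volume_size_um[3]))
      idx <- pmin(pmax(floor(sweep(ctr, 2, voxel, "/")), 0),
                  matrix(n - 1L, nn, 3, byrow = TRUE))
      inside <- allmask[1 + idx[, 1] + n[1] * (idx[, 2] + n[2] * idx[, 3])]
      ctr <- ctr[!inside, , drop = FALSE]
      nucmask <- mask_array(n)
      for (i in seq_len(nrow(ctr)))
        cpp_stamp_capsule(nucmask, n, voxel, origin, ctr[i, ], ctr[i, ],
                          iv$nuclei_radius_um, iv$nuclei_radius_um)
      nucmask <- nucmask & !allmask                 # lumens stay nuclei-free
      cyto[nucmask] <- iv$nuclei
    }
    # biliary epithelial nuclei ring around each bile duct
    bd_ids <- which(vapply(tree$tubes, function(t) t$class == "BD", logical(1)))
    if (length(bd_ids)) {
      becmask <- mask_array(n)
      bec_r <- 2
      for (id in bd_ids) {
        tb <- tree$tubes[[id]]
        npt <- nrow(tb$points)
        arc <- c(0, cumsum(sqrt(rowSums(diff(tb$points)^2))))
        axis <- unitize(tb$points[npt, ] - tb$points[1, ] + 1e-9)
        base <- rand_perp(axis)
        samp <- which(c(TRUE, diff(floor(arc / 6)) > 0))   # every ~6 um
        for (i in samp) {
          for (a in seq(0, 2 * pi, length.out = 7)[-7]) {
            p <- tb$points[i, ] +
              (tb$radius_um[i] + bec_r * 0.6) * rotate_about(base, axis, a)
            cpp_stamp_capsule(becmask, n, voxel, origin, p, p, bec_r, bec_r)
          }
        }
      }
      becmask <- becmask & !(masks[["BD"]])          # keep the lumen dark
      cyto[becmask] <- iv$nuclei
    }
    # camera noise: Poisson(gain * signal)/gain + N(0, read_sd)
    nz <- config$noise
    for (nmv in c("vessel", "cyto")) {
      a <- get(nmv)
      if (nz$photon_gain > 0)
        a <- array(stats::rpois(length(a), nz$photon_gain * a) / nz$photon_gain,
                   dim = dim(a))
      if (nz$read_sd > 0)
        a <- a + array(stats::rnorm(length(a), 0, nz$read_sd), dim = dim(a))
      assign(nmv, pmin(pmax(a, 0), 1))
    }
  })

  ctrpts <- do.call(rbind, lapply(seq_along(tree$tubes), function(i) {
    tb <- tree$tubes[[i]]
    data.frame(z = tb$points[, 1], y = tb$points[, 2], x = tb$points[, 3],
               radius_um = tb$radius_um, class = tb$class, tube = i)
  }))
  list(vessel = new_volume(vessel, voxel, "vessel"),
       cyto = new_volume(cyto, voxel, "cyto"),
       truth = list(tree = tree,
                    label_volume = new_volume(label, voxel, "label"),
                    class_masks = masks,
                    centerline_points = ctrpts))
}

#' Generate a complete phantom (tree + rasterization)
#'
#' @param config an [phantom_config()].
#' @return As [rasterize_tree()], plus the `tree` and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  tree <- generate_tree(config)
  out <- rasterize_tree(tree, config)
  out$tree <- tree
  out$config <- config
  out
}

#' Write a phantom to disk
#'
#' Multi-page 16-bit TIFF per channel plus the label volume, one SWC file per
#' vessel class, and a JSON sidecar with the class codes and voxel size.
#'
#' @param ph result of [generate_phantom()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(ph$vessel, file.path(dir, "vessel.tif"))
  write_stack(ph$cyto, file.path(dir, "cyto.tif"))
  lab <- ph$truth$label_volume
  lab$data <- lab$data / max(1, max(lab$data))    # class ids scaled into [0,1]
  write_stack(lab, file.path(dir, "labels.tif"))
  cls <- vapply(ph$tree$tubes, function(t) t$class, character(1))
  for (cl in unique(cls)) {
    sk <- tree_as_skeleton(ph$tree, cl)
    write_swc(sk, file.path(dir, sprintf("truth_%s.swc", cl)),
              class_code = VESSEL_CLASSES[[cl]])
  }
  jsonlite::write_json(list(classes = as.list(VESSEL_CLASSES),
                            voxel_size_um = ph$config$voxel_size_um,
                            label_scale = max(1, max(ph$truth$label_volume$data)),
                            seed = ph$config$seed),
                       file.path(dir, "phantom.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

# ground-truth tubes of one class as an hv_skeleton (for SWC export)
tree_as_skeleton <- function(tree, class) {
  keep <- which(vapply(tree$tubes, function(t) t$class == class, logical(1)))
  nodes <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      radius_um = numeric(0))
  edges <- matrix(integer(0), 0, 2)
  for (id in keep) {
    tb <- tree$tubes[[id]]
    off <- nrow(nodes)
    nodes <- rbind(nodes, data.frame(z = tb$points[, 1], y = tb$points[, 2],
                                     x = tb$points[, 3], radius_um = tb$radius_um))
    npt <- nrow(tb$points)
    if (npt > 1)
      edges <- rbind(edges, cbind(off + seq_len(npt - 1), off + 2:npt))
  }
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  structure(list(graph = g, nodes = nodes, voxel_size_um = NULL),
            class = "hv_skeleton")
}
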