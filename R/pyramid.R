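#' Build a multiresolution pyramid
#'
#' A chunked multiresolution pyramid: level 0 is the source volume and level k is
#' obtained by mean-pooling level k-1 by `factor` (default 2 per axis).
#' Partial edge blocks average the voxels available, so every level covers
#' the source world box (to within one pooled voxel). Use [write_pyramid()]
#' for the chunked on-disk store.
#'
#' @param vol an `hv_volume`.
#' @param levels number of levels including level 0 (>= 1).
#' @param chunk_size (z, y, x) chunk shape in voxels for the disk store;
#'   clamped (with a warning) when larger than the volume.
#' @param factor integer pooling factor per axis between consecutive levels.
#' @return An `hv_pyramid` object.
#' @export
build_pyramid <- function(vol, levels = 3L, chunk_size = c(64L, 64L, 64L),
                          factor = c(2L, 2L, 2L)) {
  stopifnot(is_volume(vol))
  levels <- as.integer(levels)
  if (levels < 1L) stop("'levels' must be >= 1")
  factor <- as.integer(factor)
  if (any(chunk_size > dim(vol$data))) {
    warning("chunk_size larger than volume; clamped")
    chunk_size <- pmin(as.integer(chunk_size), dim(vol$data))
  }
  lv <- vector("list", levels)
  lv[[1]] <- vol
  for (k in seq_len(levels - 1L)) {
    prev <- lv[[k]]
    pooled <- cpp_pool_mean(as.numeric(prev$data), dim(prev$data), factor)
    lv[[k + 1]] <- new_volume(pooled, prev$voxel_size_um * factor,
                              vol$channel, vol$origin_um)
  }
  structure(list(levels = lv, chunk_size = as.integer(chunk_size),
                 factor = factor),
            class = "hv_pyramid")
}

#' @export
print.hv_pyramid <- function(x, ...) {
  cat(sprintf("<hv_pyramid> %d levels, chunk %s voxels\n", length(x$levels),
              paste(x$chunk_size, collapse = "x")))
  for (k in seq_along(x$levels)) {
    d <- dim(x$levels[[k]]$data)
    v <- x$levels[[k]]$voxel_size_um
    cat(sprintf("  level %d: %dx%dx%d vox @ %.3gx%.3gx%.3g um\n", k - 1,
                d[1], d[2], d[3], v[1], v[2], v[3]))
  }
  invisible(x)
}

#' Write / read the chunked pyramid store
#'
#' Directory layout: `manifest.json` plus one 16-bit TIFF stack per chunk
#' under `level<k>/z<i>_y<j>_x<l>.tif`. Partial edge chunks are padded by
#' edge replication and flagged in the manifest; [read_pyramid()] crops the
#' padding back off using the stored level shapes.
#'
#' @param pyr an `hv_pyramid`.
#' @param dir store directory (created if needed).
#' @return `dir` (for `write_pyramid`) or an `hv_pyramid` (for `read_pyramid`).
#' @export
write_pyramid <- function(pyr, dir) {
  stopifnot(inherits(pyr, "hv_pyramid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- pyr$chunk_size
  manifest <- list(chunk_size = cs, factor = pyr$factor,
                   channel = pyr$levels[[1]]$channel,
                   origin_um = pyr$levels[[1]]$origin_um,
                   levels = list())
  for (k in seq_along(pyr$levels)) {
    vol <- pyr$levels[[k]]
    d <- dim(vol$data)
    ldir <- file.path(dir, sprintf("level%d", k - 1L))
    dir.create(ldir, showWarnings = FALSE)
    nch <- ceiling(d / cs)
    padded <- any(nch * cs != d)
    for (ci in seq_len(nch[1])) for (cj in seq_len(nch[2])) for (cl in seq_len(nch[3])) {
      iz <- ((ci - 1L) * cs[1] + 1L):min(ci * cs[1], d[1])
      iy <- ((cj - 1L) * cs[2] + 1L):min(cj * cs[2], d[2])
      ix <- ((cl - 1L) * cs[3] + 1L):min(cl * cs[3], d[3])
      chunk <- vol$data[iz, iy, ix, drop = FALSE]
      # pad partial chunks by edge replication
      chunk <- chunk[pmin(seq_len(cs[1]), length(iz)),
                     pmin(seq_len(cs[2]), length(iy)),
                     pmin(seq_len(cs[3]), length(ix)), drop = FALSE]
      pages <- lapply(seq_len(cs[1]), function(z) {
        m <- chunk[z, , , drop = TRUE]; dim(m) <- cs[2:3]; pmin(pmax(m, 0), 1)
      })
      tiff::writeTIFF(pages, file.path(ldir, sprintf("z%d_y%d_x%d.tif", ci, cj, cl)),
                      bits.per.sample = 16L, compression = "none")
    }
    manifest$levels[[k]] <- list(shape = d, voxel_size_um = vol$voxel_size_um,
                                 n_chunks = nch, padded = padded)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname write_pyramid
#' @export
read_pyramid <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  cs <- as.integer(unlist(mf$chunk_size))
  lv <- vector("list", length(mf$levels))
  for (k in seq_along(lv)) {
    d <- as.integer(unlist(mf$levels[[k]]$shape))
    vox <- as.numeric(unlist(mf$levels[[k]]$voxel_size_um))
    nch <- as.integer(unlist(mf$levels[[k]]$n_chunks))
    a <- array(0, nch * cs)
    ldir <- file.path(dir, sprintf("level%d", k - 1L))
    for (ci in seq_len(nch[1])) for (cj in seq_len(nch[2])) for (cl in seq_len(nch[3])) {
      pages <- tiff::readTIFF(file.path(ldir, sprintf("z%d_y%d_x%d.tif", ci, cj, cl)),
                              all = TRUE)
      if (is.matrix(pages)) pages <- list(pages)
      for (z in seq_along(pages))
        a[(ci - 1L) * cs[1] + z, (cj - 1L) * cs[2] + seq_len(cs[2]),
          (cl - 1L) * cs[3] + seq_len(cs[3])] <- pages[[z]]
    }
    a <- a[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
    lv[[k]] <- new_volume(a, vox, unlist(mf$channel),
                          as.numeric(unlist(mf$origin_um)))
  }
  structure(list(levels = lv, chunk_size = cs,
                 factor = as.integer(unlist(mf$factor))),
            class = "hv_pyramid")
}

#' Specify a block to extract from a pyramid
#'
#' @param origin_um (z, y, x) world corner of the block, micrometres.
#' @param size_um (z, y, x) block extent, micrometres.
#' @param target_voxel_um (z, y, x) voxel size of the extracted block.
#' @return An `hv_blockspec`.
#' @export
block_spec <- function(origin_um, size_um, target_voxel_um) {
  stopifnot(length(origin_um) == 3L, length(size_um) == 3L,
            length(target_voxel_um) == 3L, all(size_um > 0),
            all(target_voxel_um > 0))
  structure(list(origin_um = as.numeric(origin_um), size_um = as.numeric(size_um),
                 target_voxel_um = as.numeric(target_voxel_um)),
            class = "hv_blockspec")
}

#' Extract a block from a pyramid at a requested resolution
#'
#' Chooses the finest level whose voxel size is <= the target on every axis,
#' crops the requested world box (with a margin for the interpolation
#' support) and resamples it to the target grid. The output grid covers the
#' requested box: shape = `ceiling(size_um / target_voxel_um)` per axis, so a
#' 2000 x 2000 x 2000 um block at 1.28 x 1.28 x 4 um comes out
#' 1563 x 1563 x 500 voxels. The block origin is recorded so it stays
#' aligned with the parent volume.
#'
#' @param pyr an `hv_pyramid`.
#' @param spec an [block_spec()].
#' @return An `hv_volume`.
#' @export
extract_block <- function(pyr, spec) {
  stopifnot(inherits(pyr, "hv_pyramid"), inherits(spec, "hv_blockspec"))
  src <- pyr$levels[[1]]
  ext <- volume_extent_um(src)
  if (any(spec$origin_um < src$origin_um - 1e-6) ||
      any(spec$origin_um + spec$size_um > src$origin_um + ext + 1e-6))
    stop("block outside the source extent")
  if (any(spec$target_voxel_um < src$voxel_size_um * (1 - 1e-9)))
    stop("target voxel smaller than the native voxel; only downsampling is supported")
  # finest level with voxel <= target on every axis
  lev <- 1L
  for (k in seq_along(pyr$levels)) {
    if (all(pyr$levels[[k]]$voxel_size_um <= spec$target_voxel_um * (1 + 1e-9)))
      lev <- k
  }
  vol <- pyr$levels[[lev]]
  d <- dim(vol$data)
  # crop margin covers the cubic support plus the anti-alias blur radius, so
  # overlapping extractions agree exactly on their overlap
  mar <- 2L + ceiling(3 * 0.5 * max(spec$target_voxel_um / vol$voxel_size_um))
  i0 <- pmax(0L, floor((spec$origin_um - vol$origin_um) / vol$voxel_size_um) - mar)
  i1 <- pmin(d - 1L,
             ceiling((spec$origin_um + spec$size_um - vol$origin_um) /
                     vol$voxel_size_um) + mar)
  crop <- vol$data[(i0[1] + 1):(i1[1] + 1), (i0[2] + 1):(i1[2] + 1),
                   (i0[3] + 1):(i1[3] + 1), drop = FALSE]
  cvol <- new_volume(crop, vol$voxel_size_um, vol$channel,
                     vol$origin_um + i0 * vol$voxel_size_um)
  out_n <- pmax(1, ceiling(spec$size_um / spec$target_voxel_um - 1e-9))
  method <- if (vol$channel == "label") "nearest" else "cubic"
  resample_to_grid(cvol, spec$origin_um, out_n, spec$target_voxel_um,
                   method = method)
}
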