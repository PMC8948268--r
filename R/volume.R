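#' Construct a 3D volume
#'
#' The package's universal container: a 3D scalar grid with per-axis voxel
#' size and a channel tag. One convention is used everywhere: arrays are
#' indexed `(z, y, x)` (first array index = z), all 3-vectors
#' (`voxel_size_um`, `origin_um`, sizes, point coordinates) are ordered
#' `(z, y, x)`, world coordinates are in micrometres, and the world position
#' of voxel `(i, j, k)` (0-based) is `origin_um + (index + 0.5) * voxel_size_um`
#' (voxel centres).
#'
#' @param data 3D numeric or logical array, dim = (nz, ny, nx).
#' @param voxel_size_um positive 3-vector (z, y, x), micrometres per voxel.
#' @param channel one of `"vessel"`, `"cyto"`, `"label"`.
#' @param origin_um world position of the corner of voxel (0,0,0); used to
#'   align extracted blocks with their parent volume.
#' @return An object of class `hv_volume`.
#' @export
new_volume <- function(data, voxel_size_um, channel = c("vessel", "cyto", "label"),
                       origin_um = c(0, 0, 0)) {
  channel <- match.arg(channel)
  if (length(dim(data)) != 3L)
    stop("not a 3D stack: 'data' must have exactly 3 dimensions")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("'voxel_size_um' must be a positive 3-vector (z, y, x)")
  if (length(origin_um) != 3L)
    stop("'origin_um' must be a 3-vector (z, y, x)")
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 channel = channel, origin_um = as.numeric(origin_um)),
            class = "hv_volume")
}

#' @export
print.hv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hv_volume> %s channel, %d x %d x %d voxels (z,y,x)\n",
              x$channel, d[1], d[2], d[3]))
  cat(sprintf("  voxel size: %.3g x %.3g x %.3g um, origin (%.3g, %.3g, %.3g) um\n",
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3],
              x$origin_um[1], x$origin_um[2], x$origin_um[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname new_volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "hv_volume")

#' World extent of a volume
#'
#' @param vol an `hv_volume`.
#' @return 3-vector (z, y, x), extent in micrometres.
#' @export
volume_extent_um <- function(vol) dim(vol$data) * vol$voxel_size_um

#' Convert between voxel indices and world coordinates
#'
#' Voxel centres: world = origin + (index + 0.5) * voxel size, 0-based indices.
#'
#' @param vol an `hv_volume`.
#' @param index n x 3 matrix (or 3-vector) of 0-based (z, y, x) indices.
#' @return n x 3 matrix of world coordinates in micrometres.
#' @export
index_to_um <- function(vol, index) {
  index <- rbind_vec(index)
  sweep(sweep(index + 0.5, 2, vol$voxel_size_um, "*"), 2, vol$origin_um, "+")
}

#' @rdname index_to_um
#' @param um n x 3 matrix (or 3-vector) of world coordinates (z, y, x) in um.
#' @return For `um_to_index`, n x 3 matrix of fractional 0-based indices.
#' @export
um_to_index <- function(vol, um) {
  um <- rbind_vec(um)
  sweep(sweep(um, 2, vol$origin_um, "-"), 2, vol$voxel_size_um, "/") - 0.5
}

rbind_vec <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

is_isotropic <- function(voxel_size_um, tol = 1e-6) {
  diff(range(voxel_size_um)) <= tol * mean(voxel_size_um)
}

stopifnot_isotropic <- function(vol, what) {
  if (!is_isotropic(vol$voxel_size_um))
    stop(what, " requires an isotropic grid; resample() the volume first ",
         sprintf("(voxel size %.3g x %.3g x %.3g um)", vol$voxel_size_um[1],
                 vol$voxel_size_um[2], vol$voxel_size_um[3]))
  invisible(TRUE)
}
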