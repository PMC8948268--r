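#' Median-filter a volume
#'
#' Per-voxel median over a cubic `(2r+1)^3` window with reflected edges;
#' radius 0 is a no-op. Used for denoising at the original resolution before
#' contrast adjustment and downsampling.
#'
#' @param vol an `hv_volume`.
#' @param radius non-negative integer window radius in voxels.
#' @return Filtered `hv_volume` with unchanged geometry.
#' @export
median_filter <- function(vol, radius = 1L) {
  stopifnot(is_volume(vol))
  radius <- as.integer(radius)
  if (radius < 0) stop("'radius' must be >= 0")
  if (radius == 0) return(vol)
  out <- cpp_median3d(as.numeric(vol$data), dim(vol$data), radius)
  dim(out) <- dim(vol$data)
  vol$data <- out
  vol
}

#' Gamma-correct a volume
#'
#' Intensities are normalized to `[0, 1]` by a percentile range (values
#' outside are clipped), raised to the power `gamma`, and returned on the
#' `[0, 1]` scale. The mapping is monotone non-decreasing for any
#' `gamma > 0`; `gamma < 1` brightens dim structures.
#'
#' @param vol an `hv_volume`.
#' @param gamma positive exponent (default 0.8, mild contrast enhancement).
#' @param normalize_range length-2 percentile vector in `[0, 100]` defining
#'   the intensity window mapped to `[0, 1]`.
#' @return Corrected `hv_volume`.
#' @export
gamma_correct <- function(vol, gamma = 0.8, normalize_range = c(0, 100)) {
  stopifnot(is_volume(vol))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a positive scalar")
  q <- stats::quantile(vol$data, normalize_range / 100, names = FALSE)
  if (q[2] <= q[1])
    stop("degenerate normalization range: low and high percentiles coincide")
  x <- (vol$data - q[1]) / (q[2] - q[1])
  x[x < 0] <- 0
  x[x > 1] <- 1
  vol$data <- x^gamma
  vol
}

# Catmull-Rom (bicubic, a = -1/2) kernel
cubic_kernel <- function(t) {
  t <- abs(t)
  ifelse(t < 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

# Interpolation weight matrix mapping source samples (centres at fractional
# index 0..n_in-1) to arbitrary fractional positions `s` (may be off-grid).
# Edge handling: index clamping (replication).
interp_matrix <- function(s, n_in, method = c("cubic", "nearest")) {
  method <- match.arg(method)
  m <- length(s)
  W <- matrix(0, m, n_in)
  if (method == "nearest") {
    idx <- pmin(pmax(round(s), 0), n_in - 1)
    W[cbind(seq_len(m), idx + 1)] <- 1
    return(W)
  }
  base <- floor(s)
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 0), n_in - 1)
    w <- cubic_kernel(s - (base + k))
    W[cbind(seq_len(m), idx + 1)] <- W[cbind(seq_len(m), idx + 1)] + w
  }
  # normalize rows (kernel sums to 1 off edges; exact at edges after clamping)
  W / rowSums(W)
}

# Gaussian blur matrix with reflected boundary, sigma in source voxels
blur_matrix <- function(n, sigma) {
  if (sigma <= 0.05 || n == 1) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  W <- matrix(0, n, n)
  for (k in -r:r) {
    idx <- vapply(seq_len(n) - 1L + k, function(i) {
      while (i < 0 || i >= n) { if (i < 0) i <- -i - 1L; if (i >= n) i <- 2L * n - i - 1L }
      as.integer(i)
    }, integer(1))
    W[cbind(seq_len(n), idx + 1)] <- W[cbind(seq_len(n), idx + 1)] + w[k + r + 1]
  }
  W
}

apply_axis <- function(a, W, axis) {
  d <- dim(a)
  if (axis == 1L) {
    out <- W %*% matrix(a, d[1], d[2] * d[3])
    dim(out) <- c(nrow(W), d[2], d[3])
  } else if (axis == 2L) {
    ap <- aperm(a, c(2, 1, 3))
    out <- W %*% matrix(ap, d[2], d[1] * d[3])
    dim(out) <- c(nrow(W), d[1], d[3])
    out <- aperm(out, c(2, 1, 3))
  } else {
    out <- matrix(a, d[1] * d[2], d[3]) %*% t(W)
    dim(out) <- c(d[1], d[2], ncol(t(W)))
  }
  out
}

# Resample a volume onto an explicit output grid (separable per axis).
# antialias: Gaussian pre-blur with sigma = 0.5 * decimation factor per axis.
resample_to_grid <- function(vol, out_origin_um, out_n, out_voxel_um,
                             method = c("cubic", "nearest"), antialias = TRUE) {
  method <- match.arg(method)
  a <- vol$data
  storage.mode(a) <- "double"
  d <- dim(a)
  factor <- out_voxel_um / vol$voxel_size_um
  if (antialias && method == "cubic") {
    for (ax in 1:3) {
      if (factor[ax] > 1 + 1e-9)
        a <- apply_axis(a, blur_matrix(dim(a)[ax], 0.5 * factor[ax]), ax)
    }
  }
  for (ax in 1:3) {
    centers <- out_origin_um[ax] + (seq_len(out_n[ax]) - 0.5) * out_voxel_um[ax]
    s <- (centers - vol$origin_um[ax]) / vol$voxel_size_um[ax] - 0.5
    a <- apply_axis(a, interp_matrix(s, d[ax], method), ax)
  }
  new_volume(a, out_voxel_um, vol$channel, out_origin_um)
}

#' Resample (downsample) a volume to a target voxel size
#'
#' Anti-aliased bicubic resampling: a Gaussian pre-blur (sigma = 0.5 x the
#' per-axis decimation factor, in source voxels) followed by separable
#' Catmull-Rom cubic interpolation at the new voxel centres. Only
#' downsampling is supported; the typical uses are the 5 x 5 x 5 um working
#' resolution for large veins and the 1 x 1 x 1 um isotropic grid for
#' sinusoid blocks. Label volumes are resampled nearest-neighbour so class
#' ids stay categorical.
#'
#' @param vol an `hv_volume`.
#' @param target_voxel_um (z, y, x) target voxel size, each >= the source
#'   voxel size.
#' @return Resampled `hv_volume` covering the same world extent (to within
#'   one target voxel).
#' @export
resample <- function(vol, target_voxel_um) {
  stopifnot(is_volume(vol))
  target_voxel_um <- as.numeric(target_voxel_um)
  if (length(target_voxel_um) != 3L || any(target_voxel_um <= 0))
    stop("'target_voxel_um' must be a positive 3-vector (z, y, x)")
  if (any(target_voxel_um < vol$voxel_size_um * (1 - 1e-9)))
    stop("upsampling requested (target voxel smaller than source); ",
         "only downsampling is supported")
  if (all(abs(target_voxel_um - vol$voxel_size_um) < 1e-12)) return(vol)
  ext <- volume_extent_um(vol)
  out_n <- pmax(1L, floor(ext / target_voxel_um + 1e-9))
  method <- if (vol$channel == "label") "nearest" else "cubic"
  resample_to_grid(vol, vol$origin_um, out_n, target_voxel_um, method = method)
}

#' Run the standard preprocessing chain
#'
#' Median filter, then gamma correction, then resampling — the order used for
#' the large-vessel workflow. Each step can be skipped via its parameter
#' (`median_radius = 0`, `gamma = 1` with full range, `target_voxel_um = NULL`).
#'
#' @param vol an `hv_volume`.
#' @param median_radius window radius in voxels (default 1).
#' @param gamma gamma exponent (default 0.8).
#' @param normalize_range percentile window for normalization.
#' @param target_voxel_um optional target voxel size for [resample()].
#' @return Preprocessed `hv_volume`.
#' @export
preprocess_volume <- function(vol, median_radius = 1L, gamma = 0.8,
                              normalize_range = c(0, 100), target_voxel_um = NULL) {
  vol <- median_filter(vol, median_radius)
  vol <- gamma_correct(vol, gamma, normalize_range)
  if (!is.null(target_voxel_um)) vol <- resample(vol, target_voxel_um)
  vol
}
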