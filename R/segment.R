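#' Segmentation parameters
#'
#' The paper-style "manually corrected" Otsu segmentation is captured by a
#' single documented knob: `correction_c`, a positive multiplier applied to
#' the Otsu level before thresholding, plus the morphological cleanup
#' parameters. `polarity = "dark_lumen"` inverts intensities first — large
#' vein lumens are nuclei-free and therefore dark in the cytoarchitecture
#' channel — while `"bright_signal"` keeps voxels at or above the corrected
#' level (sinusoids in the vessel channel).
#'
#' @param n_bins histogram bins for the Otsu level (default 256).
#' @param correction_c positive multiplier on the Otsu level.
#' @param polarity `"bright_signal"` or `"dark_lumen"`.
#' @param min_component_vox components smaller than this (26-connectivity)
#'   are removed by [morph_cleanup()].
#' @param closing_radius_vox ball radius (voxels) of the binary closing.
#' @param fill_holes fill background cavities (6-connectivity).
#' @return An `hv_segment_params`.
#' @export
segment_params <- function(n_bins = 256L, correction_c = 1.0,
                           polarity = c("bright_signal", "dark_lumen"),
                           min_component_vox = 64L, closing_radius_vox = 1L,
                           fill_holes = TRUE) {
  polarity <- match.arg(polarity)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  if (!is.numeric(correction_c) || correction_c <= 0)
    stop("'correction_c' must be > 0")
  structure(list(n_bins = n_bins, correction_c = correction_c,
                 polarity = polarity,
                 min_component_vox = as.integer(min_component_vox),
                 closing_radius_vox = as.integer(closing_radius_vox),
                 fill_holes = isTRUE(fill_holes)),
            class = "hv_segment_params")
}

#' Otsu threshold of a histogram
#'
#' Returns the level maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over all `n_bins - 1` splits; ties are broken by
#' the lowest level. The returned value is the boundary between the last bin
#' of the lower class and the first bin of the upper class, on the `mids`
#' scale when given; voxels `>= t*` fall in the upper class.
#'
#' @param counts non-negative histogram counts.
#' @param mids optional bin midpoints (defaults to `0:(n-1)`).
#' @return The threshold on the `mids` scale.
#' @export
otsu_level <- function(counts, mids = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L || sum(counts) <= 0)
    stop("degenerate histogram: need counts over >= 2 bins")
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: all mass in one bin")
  n <- length(counts)
  if (is.null(mids)) mids <- seq_len(n) - 1
  p <- counts / sum(counts)
  w0 <- cumsum(p)[-n]
  mu <- cumsum(p * mids)
  mu_t <- mu[n]
  mu0 <- mu[-n] / w0
  w1 <- 1 - w0
  mu1 <- (mu_t - mu[-n]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)                    # which.max takes the first (lowest) tie
  (mids[k] + mids[k + 1]) / 2            # boundary between classes
}

#' Segment a volume by parameter-corrected Otsu thresholding
#'
#' Builds a full-volume histogram (`n_bins` over the data range), finds the
#' Otsu level, multiplies it by `correction_c` and binarizes. In
#' `dark_lumen` mode intensities are inverted (`max - v`) before the
#' histogram and threshold, so dark nuclei-free lumens become the bright
#' class. Returns the raw mask; apply [morph_cleanup()] afterwards.
#'
#' @param vol an `hv_volume` (preprocessed).
#' @param params an [segment_params()].
#' @return An `hv_mask`: logical grid plus geometry and provenance.
#' @export
segment_volume <- function(vol, params = segment_params()) {
  stopifnot(is_volume(vol), inherits(params, "hv_segment_params"))
  v <- vol$data
  if (params$polarity == "dark_lumen") v <- max(v) - v
  rng <- range(v)
  if (rng[2] <= rng[1])
    stop("degenerate histogram: constant volume")
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = params$n_bins + 1),
                      plot = FALSE)
  t_star <- otsu_level(h$counts, h$mids)
  thr <- params$correction_c * t_star
  mask <- v >= thr
  new_mask(mask, vol, params, threshold = thr, otsu = t_star)
}

new_mask <- function(data, vol, params, ...) {
  structure(list(data = data, voxel_size_um = vol$voxel_size_um,
                 origin_um = vol$origin_um,
                 provenance = c(list(params = params), list(...))),
            class = "hv_mask")
}

#' @export
print.hv_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hv_mask> %d x %d x %d voxels (z,y,x), %.2f%% foreground\n",
              d[1], d[2], d[3], 100 * mean(x$data)))
  invisible(x)
}

#' Morphological cleanup of a binary mask
#'
#' Binary closing with a Euclidean ball (exact, via the distance transform),
#' optional 6-connectivity hole filling, then removal of 26-connected
#' components smaller than `min_component_vox`. The whole operation is
#' idempotent.
#'
#' @param mask an `hv_mask` (or logical array with a `voxel_size_um` attr via
#'   the params of the mask).
#' @param params an [segment_params()]; only the cleanup fields are used.
#' @return Cleaned `hv_mask`.
#' @export
morph_cleanup <- function(mask, params = mask$provenance$params) {
  stopifnot(inherits(mask, "hv_mask"))
  if (is.null(params)) params <- segment_params()
  m <- mask$data
  n <- dim(m)
  r <- params$closing_radius_vox
  if (r > 0 && any(m) && !all(m)) {
    # closing with a Euclidean ball of radius r (voxel units)
    unit <- c(1, 1, 1)
    dil <- cpp_edt3d(m, n, unit) <= r + 1e-6
    m <- !(cpp_edt3d(!dil, n, unit) <= r + 1e-6)   # erosion of the dilation
    dim(m) <- n
  }
  if (params$fill_holes && any(m)) {
    m <- cpp_fill_holes3d(m, n)
    dim(m) <- n
  }
  if (params$min_component_vox > 1 && any(m)) {
    lab <- cpp_label3d(m, n, 26L)
    sizes <- tabulate(lab)
    keep <- which(sizes >= params$min_component_vox)
    m <- array(lab %in% keep & lab > 0L, n)
  }
  out <- mask
  out$data <- m
  out$provenance$cleanup <- params
  out
}

#' Dice overlap of two binary grids
#'
#' @param a,b logical arrays of identical shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
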