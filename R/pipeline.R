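#' Reconstruct sinusoids in a vessel-channel block
#'
#' The standard sinusoid workflow on one block: median filter and gamma
#' correction at native resolution, resampling to an isotropic 1 um grid,
#' bright-tube Otsu segmentation with morphological cleanup, centerline
#' skeletonization with spur pruning, and rayburst diameter measurement.
#'
#' @param vol vessel-channel `hv_volume`.
#' @param target_voxel_um isotropic working voxel (default 1 um).
#' @param median_radius,gamma preprocessing parameters.
#' @param seg_params [segment_params()]; default bright-tube mode with a
#'   small-component filter.
#' @param min_spur_um spur-pruning threshold.
#' @param ray_params [rayburst_params()].
#' @return List: `volume` (preprocessed), `mask` (cleaned), `skeleton`
#'   (measured), `diameters_um` (per-node vector, NAs removed).
#' @export
reconstruct_sinusoids <- function(vol, target_voxel_um = c(1, 1, 1),
                                  median_radius = 1L, gamma = 0.8,
                                  seg_params = segment_params(
                                    polarity = "bright_signal",
                                    min_component_vox = 100L),
                                  min_spur_um = 5,
                                  ray_params = rayburst_params()) {
  pre <- preprocess_volume(vol, median_radius, gamma,
                           target_voxel_um = target_voxel_um)
  mask <- morph_cleanup(segment_volume(pre, seg_params))
  sk <- prune_spurs(skeletonize(mask), min_spur_um)
  sk <- measure_graph(sk, mask, ray_params)
  d <- sk$nodes$diameter_um
  list(volume = pre, mask = mask, skeleton = sk,
       diameters_um = d[!is.na(d)])
}

#' Wrap a logical array as a mask
#'
#' @param data logical 3D array, dim (nz, ny, nx).
#' @param voxel_size_um (z, y, x) voxel size in micrometres.
#' @param origin_um world corner of voxel (0,0,0).
#' @return An `hv_mask`.
#' @export
as_mask <- function(data, voxel_size_um, origin_um = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3L)
  structure(list(data = array(as.logical(data), dim(data)),
                 voxel_size_um = as.numeric(voxel_size_um),
                 origin_um = as.numeric(origin_um),
                 provenance = list(params = NULL)),
            class = "hv_mask")
}

#' Reconstruct and classify large veins from the cytoarchitecture channel
#'
#' The large-vessel workflow: dark-lumen Otsu segmentation of the
#' cytoarchitecture channel at the 5 um working resolution gives the vein
#' mask (vein lumens are nuclei-free voids); the mask is skeletonized and
#' each connected component classified PV/HV by the accompaniment rule
#' against the supplied companion (HA/BD/LV) masks. Companion masks are an
#' input — companion vessels are traced separately (manually in the original
#' workflow; from ground truth when validating on phantoms) — and must be
#' co-registered with the scene; they may be at a different voxel size.
#'
#' @param cyto cytoarchitecture-channel `hv_volume`.
#' @param companion_masks named list of `hv_mask` objects (HA/BD/LV); empty
#'   list means no companion evidence, so every component comes out HV.
#' @param target_voxel_um working voxel (default 5 um isotropic).
#' @param vein_params [segment_params()] for the dark-lumen vein mask.
#' @param acc_params [accompaniment_params()].
#' @param median_radius,gamma preprocessing parameters.
#' @return List: `vein_mask`, `skeleton`, `classes` (per-component
#'   data.frame from [classify_veins()]).
#' @export
reconstruct_veins <- function(cyto, companion_masks = list(),
                              target_voxel_um = c(5, 5, 5),
                              vein_params = segment_params(
                                polarity = "dark_lumen",
                                correction_c = 1.05,
                                min_component_vox = 200L,
                                closing_radius_vox = 1L),
                              acc_params = accompaniment_params(
                                companion_radius_um = 60),
                              median_radius = 1L, gamma = 0.8) {
  pre <- preprocess_volume(cyto, median_radius, gamma,
                           target_voxel_um = target_voxel_um)
  vein_mask <- segment_volume(pre, vein_params)
  # companion lumens are nuclei-free voids too; being separately traced, they
  # are removed from the vein mask before skeletonization
  for (m in companion_masks) {
    if (!inherits(m, "hv_mask") || !any(m$data)) next
    vein_mask$data <- vein_mask$data &
      !mask_on_grid(m, dim(vein_mask$data), vein_mask$voxel_size_um,
                    vein_mask$origin_um, dilate_um = max(target_voxel_um))
  }
  vein_mask <- morph_cleanup(vein_mask, vein_params)
  sk <- prune_spurs(skeletonize(vein_mask), min_spur_um = 2 * max(target_voxel_um))
  cls <- classify_veins(sk, companion_masks, acc_params)
  list(vein_mask = vein_mask, skeleton = sk, classes = cls)
}

# nearest-neighbour (optionally dilated) transfer of a mask onto another grid
mask_on_grid <- function(mask, ref_dim, ref_voxel_um, ref_origin_um,
                         dilate_um = 0) {
  dt <- cpp_edt3d(mask$data, dim(mask$data), mask$voxel_size_um)
  dim(dt) <- dim(mask$data)
  cz <- ref_origin_um[1] + (seq_len(ref_dim[1]) - 0.5) * ref_voxel_um[1]
  cy <- ref_origin_um[2] + (seq_len(ref_dim[2]) - 0.5) * ref_voxel_um[2]
  cx <- ref_origin_um[3] + (seq_len(ref_dim[3]) - 0.5) * ref_voxel_um[3]
  iz <- pmin(pmax(floor((cz - mask$origin_um[1]) / mask$voxel_size_um[1]), 0),
             dim(dt)[1] - 1)
  iy <- pmin(pmax(floor((cy - mask$origin_um[2]) / mask$voxel_size_um[2]), 0),
             dim(dt)[2] - 1)
  ix <- pmin(pmax(floor((cx - mask$origin_um[3]) / mask$voxel_size_um[3]), 0),
             dim(dt)[3] - 1)
  out <- dt[1 + outer(outer(iz, dim(dt)[1] * iy, "+"),
                      dim(dt)[1] * dim(dt)[2] * ix, "+")]
  array(out <= dilate_um + 1e-9, ref_dim)
}
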