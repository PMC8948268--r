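#' Read a multi-page TIFF stack as a volume
#'
#' Stacks are stored as 16-bit grayscale multi-page TIFF with a JSON sidecar
#' (`<path>.json`) carrying `voxel_size_um`, `channel` and `origin_um`.
#' Page k holds the z = k slice as a (y, x) matrix. Voxel size metadata is
#' mandatory: it comes from the sidecar or the `voxel_size_um` argument;
#' isotropy is never silently assumed.
#'
#' @param path TIFF file path.
#' @param voxel_size_um optional (z, y, x) voxel size, overriding the sidecar.
#' @param channel optional channel tag, overriding the sidecar.
#' @return An [new_volume()] object with intensities in `[0, 1]`.
#' @export
read_stack <- function(path, voxel_size_um = NULL, channel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("not a 3D stack: '", path, "' has a single page")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  if (is.null(voxel_size_um)) voxel_size_um <- meta$voxel_size_um
  if (is.null(voxel_size_um))
    stop("missing voxel-size metadata for '", path,
         "': no sidecar and no 'voxel_size_um' supplied")
  if (is.null(channel)) channel <- if (!is.null(meta$channel)) meta$channel else "vessel"
  origin <- if (!is.null(meta$origin_um)) meta$origin_um else c(0, 0, 0)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]]); nz <- length(pages)
  data <- array(0, dim = c(nz, ny, nx))
  for (k in seq_len(nz)) data[k, , ] <- pages[[k]]
  new_volume(data, voxel_size_um, channel, origin)
}

#' Write a volume as a multi-page TIFF stack
#'
#' Intensities are clipped to `[0, 1]` and quantized to 16 bits; the geometry
#' metadata goes to a `<path>.json` sidecar so that [read_stack()] round-trips
#' losslessly for 16-bit data.
#'
#' @param vol an `hv_volume`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path) {
  stopifnot(is_volume(vol))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[1]), function(k) {
    m <- vol$data[k, , , drop = TRUE]
    dim(m) <- d[2:3]
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(voxel_size_um = vol$voxel_size_um,
                            channel = vol$channel,
                            origin_um = vol$origin_um),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write a skeleton graph (or ground-truth tree) to SWC
#'
#' Standard 7-column SWC dialect: `id type x y z radius parent`, coordinates
#' and radii in micrometres. The `type` column carries the vessel class code
#' from [VESSEL_CLASSES] (0 when unknown). One file per connected component
#' set is standard practice; here all components go to one file with distinct
#' root records (`parent = -1`).
#'
#' @param g an `hv_skeleton` graph (see [skeletonize()]); node radii may be NA.
#' @param path output file.
#' @param class_code integer class code written to the `type` column.
#' @return `path`, invisibly.
#' @export
write_swc <- function(g, path, class_code = 0L) {
  stopifnot(inherits(g, "hv_skeleton"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ig <- g$graph
  n <- igraph::vcount(ig)
  parent <- rep(-1L, n)
  if (n > 0) {
    # BFS forest over each component gives the SWC parent links
    comp <- igraph::components(ig)
    for (cid in seq_len(comp$no)) {
      vs <- which(comp$membership == cid)
      bfs <- igraph::bfs(ig, root = vs[1], restricted = vs, father = TRUE,
                         unreachable = FALSE)
      fa <- as.integer(bfs$father)
      ok <- !is.na(fa) & seq_len(n) %in% vs
      parent[ok] <- fa[ok]
    }
  }
  pos <- g$nodes
  rad <- if (is.null(pos$radius_um)) rep(0, n) else ifelse(is.na(pos$radius_um), 0, pos$radius_um)
  df <- data.frame(id = seq_len(n), type = class_code,
                   x = pos$x, y = pos$y, z = pos$z,
                   radius = rad, parent = parent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export: id type x y z radius parent (um)", con)
  utils::write.table(format(df, trim = TRUE, digits = 8), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an SWC file
#'
#' @param path SWC file written by [write_swc()] or another tool using the
#'   7-column dialect.
#' @return data.frame with columns id, type, x, y, z, radius, parent.
#' @export
read_swc <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  df
}
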