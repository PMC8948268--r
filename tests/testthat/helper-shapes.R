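# Analytic binary shapes used across the suite. All masks are built in code;
# voxel centres sit at (index + 0.5) * voxel size.

cylinder_mask <- function(radius_um, length_um, n = c(32, 32, 128),
                          voxel_um = 1, pad_um = 4) {
  a <- array(FALSE, n)
  cz <- n[1] / 2 * voxel_um
  cy <- n[2] / 2 * voxel_um
  zz <- ((seq_len(n[1]) - 0.5) * voxel_um) - cz
  yy <- ((seq_len(n[2]) - 0.5) * voxel_um) - cy
  disk <- outer(zz^2, yy^2, "+") <= radius_um^2
  for (x in seq_len(n[3])) {
    xl <- (x - 0.5) * voxel_um
    if (xl > pad_um && xl < pad_um + length_um) a[, , x] <- disk
  }
  as_mask(a, rep(voxel_um, 3))
}

sphere_mask <- function(radius_um, n = c(32, 32, 32), voxel_um = 1) {
  ctr <- n / 2 * voxel_um
  a <- array(FALSE, n)
  yy <- ((seq_len(n[2]) - 0.5) * voxel_um) - ctr[2]
  xx <- ((seq_len(n[3]) - 0.5) * voxel_um) - ctr[3]
  for (z in seq_len(n[1])) {
    zz <- (z - 0.5) * voxel_um - ctr[1]
    a[z, , ] <- outer(yy^2, xx^2, "+") + zz^2 <= radius_um^2
  }
  as_mask(a, rep(voxel_um, 3))
}

torus_mask <- function(major_um = 20, minor_um = 4, n = c(24, 64, 64),
                       voxel_um = 1) {
  ctr <- n / 2 * voxel_um
  a <- array(FALSE, n)
  for (z in seq_len(n[1])) for (y in seq_len(n[2])) {
    zz <- (z - 0.5) * voxel_um - ctr[1]
    yy <- (y - 0.5) * voxel_um - ctr[2]
    xx <- ((seq_len(n[3]) - 0.5) * voxel_um) - ctr[3]
    rho <- sqrt(yy^2 + xx^2)
    a[z, y, ] <- (rho - major_um)^2 + zz^2 <= minor_um^2
  }
  as_mask(a, rep(voxel_um, 3))
}

# capsule-stamped mask on an arbitrary grid (wraps the rasterizer kernel)
capsule_mask <- function(p0, p1, r0, r1 = r0, n = c(40, 40, 40),
                         voxel_um = c(1, 1, 1)) {
  a <- array(FALSE, n)
  hepavasc:::cpp_stamp_capsule(a, as.integer(n), as.numeric(voxel_um),
                               c(0, 0, 0), as.numeric(p0), as.numeric(p1),
                               r0, r1)
  as_mask(a, voxel_um)
}

# small random blobby masks (smoothed noise above a quantile)
random_blob_mask <- function(seed, n = c(24, 24, 24), keep = 0.2) {
  set.seed(seed)
  v <- new_volume(array(runif(prod(n)), n), c(1, 1, 1), "vessel")
  s <- median_filter(v, 1L)
  as_mask(s$data >= quantile(s$data, 1 - keep), c(1, 1, 1))
}

# brute-force exhaustive Otsu scan: maximize between-class variance over all
# splits; ties to the lowest split
otsu_bruteforce <- function(counts, mids = seq_along(counts) - 1) {
  p <- counts / sum(counts)
  best <- -Inf; kbest <- NA
  for (k in seq_len(length(counts) - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):length(p)] * mids[(k + 1):length(p)]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-12) { best <- bcv; kbest <- k }
  }
  (mids[kbest] + mids[kbest + 1]) / 2
}

skeleton_path_graph <- function(n_nodes, spacing_um = 1) {
  g <- igraph::make_ring(n_nodes, circular = FALSE)
  nodes <- data.frame(z = rep(5, n_nodes), y = rep(5, n_nodes),
                      x = (seq_len(n_nodes) - 0.5) * spacing_um,
                      radius_um = NA_real_)
  structure(list(graph = g, nodes = nodes, voxel_size_um = c(1, 1, 1)),
            class = "hv_skeleton")
}
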