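test_that("rayburst recovers sphere and cylinder diameters on analytic shapes", {
  s <- sphere_mask(10, n = c(32, 32, 32))
  for (tang in list(c(0, 0, 1), c(0, 1, 0), c(1, 1, 1))) {
    d <- local_diameter(s, c(16, 16, 16), tang)
    expect_lt(abs(d - 20), 1)            # 2r within one voxel
  }

  m <- cylinder_mask(5, 100, n = c(32, 32, 128))
  d <- local_diameter(m, c(16, 16, 50), c(0, 0, 1))
  expect_lt(abs(d - 10), 1)
})

test_that("diameters are unchanged on an anisotropic native grid (unit handling)", {
  m <- capsule_mask(c(20, 19.2, 3), c(20, 19.2, 35), 5,
                    n = c(40, 120, 120), voxel_um = c(1, 0.32, 0.32))
  d <- local_diameter(m, c(20, 19.2, 19), c(0, 0, 1))
  expect_lt(abs(d - 10), 1)
})

test_that("background points raise an error and unbounded rays come back missing", {
  m <- cylinder_mask(5, 40, n = c(24, 24, 64))
  expect_error(local_diameter(m, c(2, 2, 2), c(0, 0, 1)), "background")

  full <- as_mask(array(TRUE, c(24, 24, 24)), c(1, 1, 1))
  d <- local_diameter(full, c(12, 12, 12), c(0, 0, 1),
                      rayburst_params(max_ray_um = 5))
  expect_true(is.na(d))
})

test_that("rayburst parameter validation enforces even ray counts", {
  expect_error(rayburst_params(n_rays = 7), "even")
  expect_error(rayburst_params(n_rays = 6), "even")
  expect_error(rayburst_params(max_ray_um = 0), "max_ray_um")
})

test_that("dilating the mask never shrinks any node diameter", {
  m <- cylinder_mask(4, 60, n = c(24, 24, 96))
  sk <- prune_spurs(skeletonize(m), 5)
  d0 <- measure_graph(sk, m)$nodes$diameter_um
  dil <- m
  dt <- hepavasc:::cpp_edt3d(m$data, dim(m$data), m$voxel_size_um)
  dil$data <- array(dt <= 1 + 1e-9, dim(m$data))
  d1 <- measure_graph(sk, dil)$nodes$diameter_um
  ok <- !is.na(d0) & !is.na(d1)
  expect_true(all(d1[ok] >= d0[ok] - 1e-6))
})

test_that("measure_graph recovers cylinder diameters within 10% and handles endpoints", {
  m <- cylinder_mask(4, 80, n = c(24, 24, 96))
  sk <- prune_spurs(skeletonize(m), 5)
  ms <- measure_graph(sk, m)
  d <- ms$nodes$diameter_um
  expect_true(all(!is.na(d)))
  inner <- ms$nodes$x > 15 & ms$nodes$x < 75
  expect_true(all(abs(d[inner] - 8) / 8 < 0.10))
  # endpoint nodes (degree 1) get one-sided tangents and finite diameters
  ends <- which(igraph::degree(ms$graph) == 1)
  expect_true(all(is.finite(d[ends])))
  # branch summary table
  expect_equal(nrow(ms$branches), 1L)
  expect_lt(abs(ms$branches$diameter_um - 8) / 8, 0.10)
})

test_that("sinusoid-mesh node diameters recover generator radii within 10% for r >= 3 um", {
  # sparse mesh so tubes stay geometrically separate at 1 um voxels
  ph <- generate_phantom(phantom_config(seed = 23,
    sinusoid = list(radius_median_um = 4.5, radius_sigma_log = 0.12,
                    junction_density_per_1000_um3 = 0.03, max_edge_um = 50),
    noise = list(photon_gain = 0, read_sd = 0)))
  iso <- hepavasc:::mask_on_grid(
    as_mask(ph$truth$class_masks$SINUSOID, ph$config$voxel_size_um),
    c(128, 128, 128), c(1, 1, 1), c(0, 0, 0))
  m <- as_mask(iso, c(1, 1, 1))
  sk <- measure_graph(prune_spurs(skeletonize(m), 5), m)
  d <- sk$nodes$diameter_um
  deg <- igraph::degree(sk$graph)
  pts <- as.matrix(sk$nodes[, c("z", "y", "x")])
  jn <- which(deg >= 3)
  dj <- if (length(jn)) apply(pts, 1, function(p)
    min(sqrt(colSums((t(pts[jn, , drop = FALSE]) - p)^2)))) else
    rep(Inf, nrow(pts))
  sel <- deg == 2 & dj > 6          # away from junction thickening
  expect_gt(sum(sel), 200)
  med_meas <- median(d[sel], na.rm = TRUE)
  expect_lt(abs(med_meas - 9) / 9, 0.10)
})

test_that("vein classification follows the accompaniment rule and its boundary convention", {
  # synthetic skeletons: one component near a companion tube, one far away
  g <- igraph::disjoint_union(igraph::make_ring(5, circular = FALSE),
                              igraph::make_ring(5, circular = FALSE))
  nodes <- data.frame(z = rep(10, 10), y = rep(10, 10),
                      x = c(seq(5, 13, 2), seq(45, 53, 2)),
                      radius_um = NA_real_)
  sk <- structure(list(graph = g, nodes = nodes, voxel_size_um = c(1, 1, 1)),
                  class = "hv_skeleton")
  comp <- capsule_mask(c(10, 18, 5), c(10, 18, 15), 3, n = c(20, 24, 60))
  cls <- classify_veins(sk, list(HA = comp),
                        accompaniment_params(companion_radius_um = 10))
  expect_identical(cls$class, c("PV", "HV"))

  # empty companion masks: everything HV, with a warning
  expect_warning(cls2 <- classify_veins(sk, list()), "HV")
  expect_identical(cls2$class, c("HV", "HV"))

  # fraction exactly at the threshold counts as PV (>= rule): mark exactly
  # the voxels containing the first two of five nodes
  a <- array(FALSE, c(20, 24, 60))
  a[11, 11, 6] <- TRUE   # voxel of node (10, 10, 5)
  a[11, 11, 8] <- TRUE   # voxel of node (10, 10, 7)
  exact <- as_mask(a, c(1, 1, 1))
  cls3 <- classify_veins(sk, list(HA = exact),
                         accompaniment_params(companion_radius_um = 0.5,
                                              min_companion_fraction = 0.4))
  expect_equal(cls3$companion_fraction[1], 0.4)
  expect_identical(cls3$class[1], "PV")
})

test_that("classification is invariant to node order", {
  ph <- generate_phantom(phantom_config_veins(
    seed = 3, volume_size_um = c(320, 320, 320), voxel_size_um = c(4, 4, 4),
    vein_tree = list(root_radius_um = 25, branch_length_um = 96)))
  cm <- list(HA = as_mask(ph$truth$class_masks$HA, ph$config$voxel_size_um))
  res <- reconstruct_veins(ph$cyto, cm,
                           acc_params = accompaniment_params(companion_radius_um = 45))
  sk <- res$skeleton
  perm <- rev(seq_len(igraph::vcount(sk$graph)))
  g2 <- igraph::permute(sk$graph, perm)
  nodes2 <- sk$nodes
  nodes2[perm, ] <- sk$nodes
  sk2 <- structure(list(graph = g2, nodes = nodes2,
                        voxel_size_um = sk$voxel_size_um),
                   class = "hv_skeleton")
  c1 <- classify_veins(sk, cm, accompaniment_params(companion_radius_um = 45))
  c2 <- classify_veins(sk2, cm, accompaniment_params(companion_radius_um = 45))
  expect_identical(sort(paste(c1$n_nodes, c1$class)),
                   sort(paste(c2$n_nodes, c2$class)))
})

test_that("sinusoid statistics follow the strict cutoff and blocks-as-replicates design", {
  s1 <- sinusoid_stats(list(c(8, 10, 20)))
  expect_equal(s1$block_means_um, 9)
  expect_equal(s1$n_points, 2L)
  expect_equal(s1$n_excluded, 1L)
  expect_true(is.na(s1$sd_um))          # one block: no across-block SD

  s2 <- sinusoid_stats(list(c(9, 9, 9), c(10, 10)))
  expect_equal(s2$mean_um, 9.5)
  expect_equal(s2$sd_um, sqrt(0.5), tolerance = 1e-9)
  expect_equal(s2$n_blocks, 2L)

  # exactly-at-cutoff diameters are excluded (strict <)
  s3 <- sinusoid_stats(list(c(10, 15)))
  expect_equal(s3$n_points, 1L)

  expect_error(sinusoid_stats(list(c(20, 30))), "cutoff")
  expect_error(sinusoid_stats(list()), "at least one")
})

test_that("block means recover a known log-normal generator within 2 SEM", {
  set.seed(61)
  true_med <- 9.5; sdlog <- 0.18
  blocks <- lapply(1:8, function(i) rlnorm(400, log(true_med), sdlog))
  st <- sinusoid_stats(blocks)
  true_mean <- mean(unlist(lapply(blocks, function(b) mean(b[b < 15]))))
  sem <- st$sd_um / sqrt(st$n_blocks)
  expect_lt(abs(st$mean_um - true_mean), 2 * sem + 1e-9)
})

test_that("per-node CSV export writes coordinates and diameters", {
  dir <- withr::local_tempdir()
  m <- cylinder_mask(4, 40, n = c(20, 20, 64))
  sk <- measure_graph(prune_spurs(skeletonize(m), 5), m)
  p <- file.path(dir, "nodes.csv")
  write_node_csv(sk, p, node_class = rep("SINUSOID", nrow(sk$nodes)))
  df <- read.csv(p)
  expect_identical(names(df), c("x", "y", "z", "diameter_um", "class"))
  expect_equal(nrow(df), nrow(sk$nodes))
})
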