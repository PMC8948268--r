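test_that("a straight cylinder reduces to one centred branch with two endpoints", {
  m <- cylinder_mask(4, 100, n = c(32, 32, 128))
  sk <- prune_spurs(skeletonize(m), 5)
  st <- graph_stats(sk)
  expect_equal(st$components, 1L)
  expect_equal(st$branches, 1L)
  expect_equal(st$endpoints, 2L)
  expect_equal(st$cycles, 0L)
  # lateral deviation from the true axis (z = y = 16 um) within one voxel
  dev <- sqrt((sk$nodes$z - 16)^2 + (sk$nodes$y - 16)^2)
  expect_lte(max(dev), 1)
})

test_that("a torus keeps exactly one cycle in one component", {
  m <- torus_mask(20, 4)
  st <- graph_stats(skeletonize(m))
  expect_equal(st$components, 1L)
  expect_equal(st$cycles, 1L)
  expect_equal(st$endpoints, 0L)
})

test_that("empty masks give empty graphs; anisotropic masks are refused", {
  m <- as_mask(array(FALSE, c(8, 8, 8)), c(1, 1, 1))
  sk <- skeletonize(m)
  expect_equal(igraph::vcount(sk$graph), 0L)
  expect_equal(graph_stats(sk)$components, 0L)

  ma <- as_mask(array(TRUE, c(8, 8, 8)), c(1, 0.32, 0.32))
  expect_error(skeletonize(ma), "isotropic")
})

test_that("skeletonization preserves component count on random tube scenes", {
  for (seed in c(3, 9)) {
    ph <- generate_phantom(phantom_config(
      volume_size_um = c(48, 48, 48), voxel_size_um = c(1, 1, 1), seed = seed,
      vein_tree = list(root_radius_um = 5)))
    m <- as_mask(ph$truth$class_masks$SINUSOID, c(1, 1, 1))
    ncomp_mask <- max(hepavasc:::cpp_label3d(m$data, dim(m$data), 26L))
    sk <- skeletonize(m)
    expect_equal(graph_stats(sk)$components, ncomp_mask)
  }
})

test_that("short terminal spurs are pruned and the junction path merged", {
  # Y-shape: long arm plus a 2 um stub off the junction
  a <- array(FALSE, c(16, 16, 48))
  a[8, 8, 4:44] <- TRUE          # main line
  a[8, 9:10, 24] <- TRUE         # 2-voxel stub
  m <- as_mask(a, c(1, 1, 1))
  sk <- skeletonize(m)
  st0 <- graph_stats(sk)
  expect_equal(st0$endpoints, 3L)
  expect_equal(st0$junctions, 1L)
  pr <- prune_spurs(sk, 5)
  st <- graph_stats(pr)
  expect_equal(st$endpoints, 2L)
  expect_equal(st$junctions, 0L)
  expect_equal(st$branches, 1L)
})

test_that("pruning leaves loops untouched and is monotone and idempotent", {
  m <- torus_mask(16, 3, n = c(20, 48, 48))
  sk <- skeletonize(m)
  pr <- prune_spurs(sk, 10)
  expect_equal(graph_stats(pr)$cycles, 1L)
  expect_equal(igraph::vcount(pr$graph), igraph::vcount(sk$graph))

  ph <- generate_phantom(phantom_config(
    volume_size_um = c(48, 48, 48), voxel_size_um = c(1, 1, 1), seed = 31,
    vein_tree = list(root_radius_um = 5)))
  m2 <- as_mask(ph$truth$class_masks$SINUSOID, c(1, 1, 1))
  sk2 <- skeletonize(m2)
  p1 <- prune_spurs(sk2, 5)
  expect_lte(igraph::vcount(p1$graph), igraph::vcount(sk2$graph))
  p2 <- prune_spurs(p1, 5)
  expect_equal(igraph::vcount(p2$graph), igraph::vcount(p1$graph))
})

test_that("skeleton endpoints match ground-truth tube tips after 5 um pruning", {
  for (seed in 1:2) {
    cfg <- phantom_config_veins(
      seed = seed, volume_size_um = c(256, 256, 256), voxel_size_um = c(2, 2, 2),
      companions = FALSE,
      vein_tree = list(root_radius_um = 12, depth = 2L, branch_length_um = 90,
                       tortuosity = 0.06),
      noise = list(photon_gain = 0, read_sd = 0))
    ph <- generate_phantom(cfg)
    vein <- ph$truth$class_masks$PV | ph$truth$class_masks$HV
    sk <- prune_spurs(skeletonize(as_mask(vein, cfg$voxel_size_um)), 5)
    tips <- tree_tip_points(ph$tree, c("PV", "HV"))
    expect_equal(graph_stats(sk)$endpoints, nrow(tips))
  }
})

test_that("graph statistics are exact on hand-built graphs", {
  sk <- skeleton_path_graph(100)
  st <- graph_stats(sk)
  expect_equal(st$total_length_um, 99)
  expect_equal(st$branches, 1L)
  expect_equal(st$components, 1L)

  # two disjoint straight branches
  g2 <- igraph::disjoint_union(igraph::make_ring(5, circular = FALSE),
                               igraph::make_ring(4, circular = FALSE))
  nodes <- data.frame(z = rep(1, 9), y = rep(1, 9),
                      x = c(1:5, 21:24), radius_um = NA_real_)
  sk2 <- structure(list(graph = g2, nodes = nodes, voxel_size_um = c(1, 1, 1)),
                   class = "hv_skeleton")
  st2 <- graph_stats(sk2)
  expect_equal(st2$components, 2L)
  expect_equal(st2$branches, 2L)
  expect_equal(st2$total_length_um, 4 + 3)
})

test_that("cycle rank of a tube lattice with known first Betti number is preserved", {
  # 2 x 3 x 3 lattice of 3 um tubes, 24 um spacing: V = 18, E = 33,
  # beta1 = E - V + 1 = 16; junction and branch counts are also known exactly
  sp <- 24; rad <- 3
  nodes <- as.matrix(expand.grid(z = 0:1, y = 0:2, x = 0:2)) * sp + 8
  n <- c(40, 64, 64)
  a <- array(FALSE, n)
  E <- 0
  for (i in seq_len(nrow(nodes))) for (j in seq_len(nrow(nodes))) {
    if (j <= i) next
    d <- abs(nodes[i, ] - nodes[j, ])
    if (sum(d) == sp && max(d) == sp) {
      hepavasc:::cpp_stamp_capsule(a, n, c(1, 1, 1), c(0, 0, 0),
                                   nodes[i, ], nodes[j, ], rad, rad)
      E <- E + 1
    }
  }
  st <- graph_stats(prune_spurs(skeletonize(as_mask(a, c(1, 1, 1))), 5))
  expect_equal(st$cycles, E - nrow(nodes) + 1L)
  expect_equal(st$junctions, nrow(nodes))
  expect_equal(st$branches, E)
  expect_equal(st$components, 1L)
})
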