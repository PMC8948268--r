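test_that("degenerate config yields exactly one PV and one HV tube", {
  cfg <- phantom_config(seed = 1, vein_tree = list(depth = 1L),
                        companion = list(enabled = FALSE),
                        sinusoid = list(enabled = FALSE),
                        pbp = list(enabled = FALSE))
  tr <- generate_tree(cfg)
  cls <- sort(vapply(tr$tubes, function(t) t$class, character(1)))
  expect_identical(cls, c("HV", "PV"))
})

test_that("the same seed reproduces trees and volumes bit for bit", {
  cfg <- phantom_config(volume_size_um = c(48, 48, 48),
                        voxel_size_um = c(1, 0.5, 0.5), seed = 77,
                        vein_tree = list(root_radius_um = 6))
  t1 <- generate_tree(cfg)
  t2 <- generate_tree(cfg)
  expect_identical(t1$tubes, t2$tubes)

  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$vessel$data, p2$vessel$data)
  expect_identical(p1$cyto$data, p2$cyto$data)
  expect_identical(p1$truth$label_volume$data, p2$truth$label_volume$data)

  cfg2 <- phantom_config(volume_size_um = c(48, 48, 48),
                         voxel_size_um = c(1, 0.5, 0.5), seed = 78,
                         vein_tree = list(root_radius_um = 6))
  p3 <- generate_phantom(cfg2)
  expect_false(identical(p1$vessel$data, p3$vessel$data))
})

test_that("companion tubes stay within their configured offset of the PV centerline", {
  cfg <- phantom_config_veins(seed = 4)
  tr <- generate_tree(cfg)
  pv_pts <- do.call(rbind, lapply(tr$tubes, function(t)
    if (t$class == "PV") t$points else NULL))
  max_off <- cfg$vein_tree$root_radius_um + cfg$companion$gap_um +
    max(cfg$companion$radii_um)
  for (tb in tr$tubes) {
    if (!tb$class %in% c("HA", "BD", "LV")) next
    # brute-force nearest-PV-point search for every companion vertex
    for (i in seq_len(nrow(tb$points))) {
      dmin <- min(sqrt(rowSums(sweep(pv_pts, 2, tb$points[i, ])^2)))
      expect_lte(dmin, max_off + 2)
    }
  }
})

test_that("vein-tree radii never increase away from the root within a tube", {
  cfg <- phantom_config_veins(seed = 6)
  tr <- generate_tree(cfg)
  for (tb in tr$tubes)
    expect_true(all(diff(tb$radius_um) <= 1e-9 + 0.1 * tb$radius_um[-1]))
})

test_that("bile ducts are invisible in the vessel channel but ringed by nuclei in cyto", {
  size <- c(40, 40, 40)
  cfg <- phantom_config(volume_size_um = size, voxel_size_um = c(1, 1, 1),
                        seed = 5, noise = list(photon_gain = 0, read_sd = 0),
                        intensity = list(nuclei_density_per_1000_um3 = 0))
  tube <- list(points = rbind(c(20, 20, 4), c(20, 20, 36)),
               radius_um = c(4, 4), class = "BD", parent = NA_integer_)
  tr <- structure(list(tubes = list(tube), config = cfg),
                  class = "hv_vessel_tree")
  out <- rasterize_tree(tr, cfg)
  # vessel channel: background only (BEC are not endothelial-labelled)
  expect_equal(range(out$vessel$data),
               rep(cfg$intensity$background, 2))
  # cyto channel: a ring of BEC nuclei outside the dark lumen
  expect_gte(max(out$cyto$data), cfg$intensity$nuclei)
  expect_equal(out$cyto$data[20, 20, 20], cfg$intensity$lumen)
})

test_that("noiseless rasterization takes only the configured intensity levels", {
  cfg <- phantom_config(volume_size_um = c(40, 40, 40),
                        voxel_size_um = c(1, 1, 1), seed = 8,
                        vein_tree = list(root_radius_um = 5),
                        noise = list(photon_gain = 0, read_sd = 0))
  ph1 <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph1$vessel$data, ph2$vessel$data)
  iv <- cfg$intensity
  expect_true(all(ph1$vessel$data %in%
                  c(iv$background, iv$lumen, iv$wall)))
  expect_true(all(ph1$cyto$data %in%
                  c(iv$cyto_background, iv$lumen, iv$nuclei)))
})

test_that("a rasterized cylinder has the analytic capsule volume within 10%", {
  r <- 5; L <- 30
  m <- capsule_mask(c(20, 20, 5), c(20, 20, 35), r, n = c(40, 40, 40))
  expected <- pi * r^2 * L + 4 / 3 * pi * r^3   # cylinder plus two end caps
  expect_lt(abs(sum(m$data) - expected) / expected, 0.10)
})

test_that("ground-truth sinusoid diameters sit mostly below the 15 um cutoff", {
  ph <- generate_phantom(phantom_config(seed = 12))
  sin_pts <- subset(ph$truth$centerline_points, class == "SINUSOID")
  expect_gt(nrow(sin_pts), 100)
  expect_gte(mean(2 * sin_pts$radius_um < 15), 0.95)
})

test_that("HA walls are brighter than BD in the vessel channel, and ground truth is geometrically consistent", {
  ph <- generate_phantom(phantom_config(seed = 14,
    noise = list(photon_gain = 0, read_sd = 0)))
  masks <- ph$truth$class_masks
  expect_gt(mean(ph$vessel$data[masks$HA]), mean(ph$vessel$data[masks$BD]))

  expect_identical(dim(ph$truth$label_volume$data), dim(ph$vessel$data))

  # every centerline vertex lies inside its tube's rasterized class mask
  cp <- ph$truth$centerline_points
  n <- dim(ph$vessel$data)
  vox <- ph$config$voxel_size_um
  for (cl in unique(cp$class)) {
    pts <- cp[cp$class == cl, ]
    idx <- cbind(pmin(pmax(floor(pts$z / vox[1]), 0), n[1] - 1),
                 pmin(pmax(floor(pts$y / vox[2]), 0), n[2] - 1),
                 pmin(pmax(floor(pts$x / vox[3]), 0), n[3] - 1))
    lin <- 1 + idx[, 1] + n[1] * (idx[, 2] + n[2] * idx[, 3])
    expect_true(all(masks[[cl]][lin]))
  }
})

test_that("configs are validated and YAML round-trips", {
  expect_error(phantom_config(volume_size_um = c(0, 10, 10)), "positive")
  expect_error(phantom_config(vein_tree = list(root_radius_um = 200)),
               "too small")
  expect_error(phantom_config(sinusoid = list(radius_median_um = 8)), "7.5")

  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("volume_size_um: [40, 40, 40]",
               "voxel_size_um: [1, 1, 1]",
               "vein_tree:",
               "  root_radius_um: 5",
               "sinusoid:",
               "  radius_median_um: 4.0"), yml)
  cfg <- read_phantom_config(yml, seed = 99)
  expect_equal(cfg$volume_size_um, c(40, 40, 40))
  expect_equal(cfg$vein_tree$root_radius_um, 5)
  expect_equal(cfg$sinusoid$radius_median_um, 4.0)
  expect_equal(cfg$seed, 99L)
})

test_that("phantom export writes channels, labels, SWC and sidecar", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(phantom_config(
    volume_size_um = c(32, 32, 32), voxel_size_um = c(1, 1, 1), seed = 2,
    vein_tree = list(root_radius_um = 5)))
  write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "vessel.tif")))
  expect_true(file.exists(file.path(dir, "cyto.tif")))
  expect_true(file.exists(file.path(dir, "labels.tif")))
  expect_true(file.exists(file.path(dir, "phantom.json")))
  expect_true(file.exists(file.path(dir, "truth_PV.swc")))
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$voxel_size_um, c(1, 1, 1))
})
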