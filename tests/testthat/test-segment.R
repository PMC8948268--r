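test_that("Otsu level separates two delta peaks and rejects degenerate histograms", {
  counts <- numeric(256)
  counts[11] <- 500   # intensity 10 (0-based mids)
  counts[201] <- 500  # intensity 200
  t_star <- otsu_level(counts)
  expect_gt(t_star, 10)
  expect_lt(t_star, 200)

  one <- numeric(256); one[50] <- 1000
  expect_error(otsu_level(one), "degenerate")
})

test_that("Otsu level equals the exhaustive between-class-variance scan", {
  set.seed(101)
  for (k in 1:30) {
    nb <- sample(c(64L, 256L), 1)                  # 8-bit and 16-bit style bins
    mids <- if (k %% 2) seq_len(nb) - 1 else (seq_len(nb) - 1) * 257
    counts <- rpois(nb, lambda = runif(1, 0.5, 5))
    # add two modes so histograms look like images
    m1 <- sample(nb, 1); m2 <- sample(nb, 1)
    counts[m1] <- counts[m1] + rpois(1, 200)
    counts[m2] <- counts[m2] + rpois(1, 200)
    if (sum(counts > 0) < 2) next
    expect_equal(otsu_level(counts, mids), otsu_bruteforce(counts, mids))
  }
})

test_that("correction_c = 1 in bright mode reduces to plain Otsu binarization", {
  set.seed(111)
  v <- new_volume(array(c(rnorm(2000, 0.2, 0.03), rnorm(2000, 0.7, 0.05)),
                        c(20, 20, 10)), c(1, 1, 1))
  v$data <- pmin(pmax(v$data, 0), 1)
  m <- segment_volume(v, segment_params(correction_c = 1))
  h <- hist(v$data, breaks = seq(min(v$data), max(v$data), length.out = 257),
            plot = FALSE)
  t_star <- otsu_level(h$counts, h$mids)
  expect_identical(m$data, v$data >= t_star)
  expect_equal(m$provenance$otsu, t_star)
})

test_that("raising correction_c never adds foreground in bright mode", {
  set.seed(112)
  v <- new_volume(array(runif(16^3), c(16, 16, 16)), c(1, 1, 1))
  prev <- NULL
  for (cc in c(0.5, 0.8, 1, 1.3, 1.8)) {
    m <- segment_volume(v, segment_params(correction_c = cc))
    if (!is.null(prev)) expect_true(all(prev | !m$data))
    prev <- m$data
  }
})

test_that("dark-lumen mode recovers large-vein lumens from the cyto channel", {
  ph <- generate_phantom(phantom_config_veins(
    seed = 2, volume_size_um = c(320, 320, 320), voxel_size_um = c(4, 4, 4),
    vein_tree = list(root_radius_um = 25, branch_length_um = 96),
    noise = list(photon_gain = 0, read_sd = 0)))
  pre <- preprocess_volume(ph$cyto, 1L, 0.8, target_voxel_um = c(5, 5, 5))
  m <- morph_cleanup(segment_volume(pre, segment_params(
    polarity = "dark_lumen", correction_c = 1.05, min_component_vox = 100L)))
  lab5 <- resample(ph$truth$label_volume, c(5, 5, 5))
  truth <- lab5$data %in% VESSEL_CLASSES[c("PV", "HV", "HA", "BD", "LV")]
  dim(truth) <- dim(lab5$data)
  expect_gt(dice(m$data, truth), 0.85)
})

test_that("pure-noise volumes yield only a small noise-tail foreground", {
  set.seed(120)
  gain <- 50; bg <- 0.05; read_sd <- 0.01
  a <- rpois(32^3, gain * bg) / gain + rnorm(32^3, 0, read_sd)
  v <- new_volume(array(pmax(a, 0), c(32, 32, 32)), c(1, 1, 1))
  m <- segment_volume(v, segment_params(correction_c = 1))
  thr <- m$provenance$threshold
  expected_tail <- mean(pnorm(thr, mean = bg, sd = sqrt(bg / gain + read_sd^2),
                              lower.tail = FALSE))
  expect_lte(mean(m$data), 2 * expected_tail + 1e-4)
})

test_that("morphological cleanup removes specks, keeps clean cylinders, and is idempotent", {
  m <- cylinder_mask(4, 40, n = c(20, 20, 64))
  speck <- m
  speck$data[2, 2, 2] <- TRUE
  speck$data[2, 2, 3] <- TRUE
  cl <- morph_cleanup(speck, segment_params(min_component_vox = 10L,
                                            closing_radius_vox = 0L,
                                            fill_holes = FALSE))
  expect_identical(cl$data, m$data)

  solid <- morph_cleanup(m, segment_params(min_component_vox = 10L))
  expect_identical(solid$data, m$data)

  only_speck <- as_mask(array(FALSE, c(12, 12, 12)), c(1, 1, 1))
  only_speck$data[5, 5, 5:6] <- TRUE
  expect_equal(sum(morph_cleanup(only_speck,
    segment_params(min_component_vox = 10L))$data), 0)

  for (seed in 1:25) {
    b <- random_blob_mask(seed)
    p <- segment_params(min_component_vox = 30L, closing_radius_vox = 1L)
    once <- morph_cleanup(b, p)
    twice <- morph_cleanup(once, p)
    expect_identical(twice$data, once$data)
  }
})
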