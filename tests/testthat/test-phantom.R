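test_that("empty, noiseless phantom is piecewise-constant with no foci", {
  cfg <- test_phantom_config(n_foci = 0L, n_exudates = 0L, speckle_sigma = 0)
  p <- generate_oct_phantom(cfg)
  expect_false(any(p$foci_mask))
  # every voxel value is one of the six compartment intensities
  expect_true(all(p$oct$intensities %in% cfg$layer_intensities))
  # distinct mean intensity per layer along a central column
  col <- p$oct$intensities[64, 16, ]
  expect_gt(length(unique(col)), 3)
})

test_that("phantom generation is deterministic given the seed", {
  cfg <- test_phantom_config(n_foci = 4L, n_exudates = 2L, rng_seed = 11L)
  a <- generate_phantom_case(cfg, "a", "PDR")
  b <- generate_phantom_case(cfg, "a", "PDR")
  expect_identical(a$oct$intensities, b$oct$intensities)
  expect_identical(a$truth_foci_mask, b$truth_foci_mask)
  expect_identical(a$fundus$rgb, b$fundus$rgb)
  expect_identical(a$landmarks, b$landmarks)
})

test_that("foci mask has exactly n_foci 26-connected components", {
  for (seed in c(3L, 17L)) {
    cfg <- test_phantom_config(n_foci = 5L, n_exudates = 2L, rng_seed = seed)
    p <- generate_oct_phantom(cfg)
    lab <- oracle_flood3d(p$foci_mask)
    expect_equal(max(lab), 5L)
  }
})

test_that("config validation rejects impossible settings", {
  expect_error(phantom_config(n_exudates = 5L, n_foci = 2L), "exceed")
  expect_error(phantom_config(layer_depths_um = c(ilm = 300, nfl_lower = 260,
                                                  opl_onl = 500, isos = 700,
                                                  bm = 800)), "increasing")
  expect_error(phantom_config(he_axial_range_um = c(100, 400)), "band")
})

test_that("voxel pitch matches extent over grid", {
  cfg <- phantom_config()
  expect_equal(retmodal:::voxel_pitch(cfg), c(6000 / 512, 6000 / 128,
                                              2000 / 1024))
  expect_equal(round(retmodal:::voxel_pitch(cfg), 3), c(11.719, 46.875, 1.953))
})

test_that("fundus truth: identity transform puts the blob at the footprint", {
  cfg <- test_phantom_config(fundus_scale = 1, n_foci = 1L, n_exudates = 1L,
                             transform_params = list(theta_deg = 0, scale = 1,
                                                     tx = 0, ty = 0))
  tt <- phantom_truth_transform(cfg)
  expect_equal(tt$matrix, diag(3))
  he <- data.frame(cx = 100, cy = 16, ax_um = 250, ay_um = 250)
  f <- generate_fundus_phantom(cfg, tt, he)
  ctr <- which(f$he_mask > 0, arr.ind = TRUE)
  expect_equal(mean(ctr[, 1]), 100, tolerance = 0.1)
  expect_equal(mean(ctr[, 2]), 16, tolerance = 0.1)
  expect_gte(nrow(f$landmarks), 4)
})

test_that("fundus truth: pure translation shifts the blob centroid exactly", {
  cfg <- test_phantom_config(fundus_scale = 1, n_foci = 1L, n_exudates = 1L,
                             transform_params = list(theta_deg = 0, scale = 1,
                                                     tx = 0, ty = 0))
  he <- data.frame(cx = 60, cy = 16, ax_um = 250, ay_um = 250)
  f0 <- generate_fundus_phantom(cfg, phantom_truth_transform(cfg), he)
  cfg2 <- cfg; cfg2$transform_params$tx <- 10
  f1 <- generate_fundus_phantom(cfg2, phantom_truth_transform(cfg2), he)
  c0 <- colMeans(which(f0$he_mask > 0, arr.ind = TRUE))
  c1 <- colMeans(which(f1$he_mask > 0, arr.ind = TRUE))
  # transform maps fundus -> en-face with +10 x offset, so the fundus-frame
  # blob (the preimage of the same en-face ellipse) moves by -10
  expect_equal(unname(c0 - c1), c(10, 0), tolerance = 1e-8)
})

test_that("fundus he_mask component count equals n_exudates", {
  cfg <- test_phantom_config(n_foci = 8L, n_exudates = 4L, rng_seed = 5L)
  case <- generate_phantom_case(cfg)
  lab <- oracle_flood3d(array(case$truth_he_mask_fundus > 0,
                              dim = c(dim(case$truth_he_mask_fundus), 1)))
  expect_equal(max(lab), 4L)
})

test_that("every en-face HE truth blob overlaps a focus footprint", {
  cfg <- test_phantom_config(n_foci = 6L, n_exudates = 3L, rng_seed = 9L)
  case <- generate_phantom_case(cfg)
  fp <- apply(case$truth_foci_mask, c(1, 2), any)
  lab2 <- oracle_flood3d(array(case$truth_he_mask_enface > 0,
                               dim = c(dim(case$truth_he_mask_enface), 1)))
  for (k in seq_len(max(lab2)))
    expect_true(any(fp[lab2[, , 1] == k]))
})

test_that("cohort sizes, labels and class difference in foci counts", {
  expect_identical(generate_cohort(0, 0), list())
  cases <- generate_cohort(14, 19, rng_seed = 2L,
                           base_config = test_phantom_config())
  expect_length(cases, 33)
  labs <- vapply(cases, function(x) x$severity_label, character(1))
  expect_equal(sum(labs == "NPDR"), 14)
  expect_equal(sum(labs == "PDR"), 19)
  nf <- vapply(cases, function(x) nrow(x$foci), integer(1))
  expect_gt(mean(nf[labs == "PDR"]), mean(nf[labs == "NPDR"]))
})

test_that("phantom case writes round-trippable artifacts", {
  dir <- withr::local_tempdir()
  cfg <- test_phantom_config(n_foci = 3L, n_exudates = 1L)
  case <- generate_phantom_case(cfg, "rt", "NPDR")
  paths <- write_phantom_case(case, dir)
  vol2 <- read_volume(paths[["volume"]])
  expect_equal(vol2$intensities, case$oct$intensities)
  m2 <- read_mask(paths[["foci_mask"]])
  expect_equal(array(m2 > 0, dim = dim(m2)), case$truth_foci_mask)
})
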