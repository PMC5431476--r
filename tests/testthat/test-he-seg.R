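test_that("sRGB to CIELab endpoints behave as expected", {
  black <- array(0, dim = c(1, 1, 3))
  white <- array(255, dim = c(1, 1, 3))
  gray <- array(128, dim = c(1, 1, 3))
  expect_equal(rgb_to_lab(black)[1, 1, 1], 0, tolerance = 1e-6)
  expect_equal(rgb_to_lab(white)[1, 1, ], c(100, 0, 0), tolerance = 1e-4)
  # mid-gray: L from the sRGB transfer curve, a = b = 0
  lab_gray <- rgb_to_lab(gray)[1, 1, ]
  expect_equal(lab_gray[2:3], c(0, 0), tolerance = 1e-6)
  expect_equal(lab_gray[1], 53.585, tolerance = 1e-3)
  expect_error(rgb_to_lab(array(0, c(2, 2, 2))), "3 channels")
})

test_that("uniform images have identically zero saliency at any scale", {
  img <- array(rep(c(120, 80, 40), each = 100), dim = c(10, 10, 3))
  lab <- rgb_to_lab(img)
  for (h in c(1, 2, 3))
    expect_equal(max(abs(saliency_at_scale(lab, h))), 0)
  sm <- saliency_multiscale(lab, saliency_config(scales = c(1, 2, 3)))
  expect_equal(max(abs(sm$total)), 0)
})

test_that("saliency equals the Euclidean distance of mean Lab vectors", {
  # construct a Lab image directly: inner square L=60, annulus L=50
  lab <- array(0, dim = c(9, 9, 3))
  lab[, , 1] <- 50
  lab[4:6, 4:6, 1] <- 60
  s <- saliency_at_scale(lab, 1, 1)
  # at the center, v1 = [60,0,0], v2 = [50,0,0] -> C = 10
  expect_equal(s[5, 5], 10)
})

test_that("saliency matches the naive double-loop oracle", {
  set.seed(7)
  for (rep in 1:6) {
    lab <- array(runif(12 * 12 * 3, 0, 100), dim = c(12, 12, 3))
    h <- sample(1:3, 1); w <- sample(1:2, 1)
    expect_equal(saliency_at_scale(lab, h, w), oracle_saliency(lab, h, w),
                 tolerance = 1e-9)
  }
})

test_that("multiscale saliency is the elementwise sum over scales", {
  set.seed(8)
  lab <- array(runif(20 * 16 * 3, 0, 100), dim = c(20, 16, 3))
  cfg1 <- saliency_config(scales = 2L)
  expect_equal(saliency_multiscale(lab, cfg1)$total,
               saliency_at_scale(lab, 2, 2))
  cfg2 <- saliency_config(scales = c(2L, 4L))
  sm <- saliency_multiscale(lab, cfg2)
  expect_equal(sm$total, sm$per_scale[[1]] + sm$per_scale[[2]])
  expect_true(all(sm$total >= 0))
})

test_that("saliency is invariant to a constant Lab channel shift", {
  set.seed(9)
  lab <- array(runif(14 * 14 * 3, 0, 100), dim = c(14, 14, 3))
  shifted <- lab
  shifted[, , 2] <- shifted[, , 2] + 25
  cfg <- saliency_config(scales = c(1L, 3L))
  expect_equal(saliency_multiscale(lab, cfg)$total,
               saliency_multiscale(shifted, cfg)$total, tolerance = 1e-9)
})

test_that("thresholding: fixed threshold, Otsu failure, monotonicity", {
  zero <- matrix(0, 10, 10)
  cfg_fix <- saliency_config(scales = 1L, threshold_method = "fixed",
                             fixed_threshold = 0.5, min_area_px = 1L)
  expect_equal(sum(segment_he(zero, cfg_fix)), 0)
  expect_error(segment_he(zero, saliency_config(scales = 1L)), "constant")
  set.seed(10)
  smap <- matrix(runif(400, 0, 10), 20, 20)
  masks <- lapply(c(2, 5, 8), function(thr)
    segment_he(smap, saliency_config(scales = 1L, threshold_method = "fixed",
                                     fixed_threshold = thr,
                                     min_area_px = 1L)))
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
})

test_that("one bright disc on a dark fundus yields one component, Dice >= 0.8", {
  img <- array(0, dim = c(120, 100, 3))
  img[, , 1] <- 60; img[, , 2] <- 30; img[, , 3] <- 15
  xg <- matrix(1:120, 120, 100); yg <- matrix(1:100, 120, 100, byrow = TRUE)
  disc <- (xg - 60)^2 + (yg - 50)^2 <= 8^2
  for (ch in 1:3) {
    pl <- img[, , ch]; pl[disc] <- c(250, 240, 150)[ch]; img[, , ch] <- pl
  }
  sc <- saliency_config(scales = c(2L, 4L, 8L))
  mask <- segment_he(saliency_multiscale(rgb_to_lab(img), sc), sc)
  lab <- oracle_flood3d(array(mask > 0, dim = c(dim(mask), 1)))
  expect_equal(max(lab), 1L)
  expect_gte(dice2(mask > 0, disc), 0.8)
})

test_that("phantom with 4 exudates and vessels: 4 components after pseudo-HE
           correction at the vessel crossings", {
  for (seed in c(31L, 91L)) {
    cfg <- phantom_config(grid_dims = c(256L, 128L, 64L), n_foci = 6L,
                          n_exudates = 4L, rng_seed = seed,
                          layer_depths_um = c(ilm = 200, nfl_lower = 400,
                                              opl_onl = 900, isos = 1400,
                                              bm = 1600))
    case <- generate_phantom_case(cfg)
    sc <- saliency_config(scales = c(3L, 7L, 15L), min_area_px = 25L)
    mask <- segment_he(saliency_multiscale(rgb_to_lab(case$fundus$rgb), sc),
                       sc)
    # vessel crossings are salient pseudo-exudates; remove them the way
    # the clinical review step would, using the landmark coordinates
    d <- dim(mask)
    xg <- matrix(seq_len(d[1]), d[1], d[2])
    yg <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    rm <- matrix(0, d[1], d[2])
    for (i in seq_len(nrow(case$landmarks)))
      rm[(xg - case$landmarks$fundus_x[i])^2 +
           (yg - case$landmarks$fundus_y[i])^2 <= 12^2] <- 1
    corrected <- apply_correction(mask, remove_mask = rm)
    lab <- oracle_flood3d(array(corrected > 0, dim = c(d, 1)))
    expect_equal(max(lab), 4L)
    # every surviving component overlaps a true exudate
    for (k in seq_len(max(lab)))
      expect_gt(sum(case$truth_he_mask_fundus[lab[, , 1] == k]), 0)
  }
})

test_that("correction masks apply as (mask plus add) minus remove", {
  m <- matrix(rbinom(100, 1, 0.3), 10, 10)
  expect_equal(apply_correction(m), m)
  expect_equal(sum(apply_correction(m, remove_mask = m)), 0)
  add <- matrix(0, 10, 10); add[m == 0][1:5] <- 1
  expect_equal(sum(apply_correction(m, add_mask = add)), sum(m) + 5)
  expect_error(apply_correction(m, add_mask = matrix(0, 2, 2)), "shape")
})
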