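test_that("adaptive seeds follow the band mean + k SD rule", {
  b <- matrix(50, 10, 10)
  band <- matrix(TRUE, 10, 10)
  # constant band: sd = 0, nothing exceeds mean for k > 0
  expect_equal(sum(adaptive_seeds(b, band, 2)), 0)
  # 99 pixels at 50 plus one at 255: only that pixel exceeds mu + 2 sigma
  b2 <- b; b2[5, 5] <- 255
  expect_gte(mean(b2) + 2 * sd(b2), 50)   # oracle check of the cutoff
  seeds <- adaptive_seeds(b2, band, 2)
  expect_equal(which(seeds), which(b2 == 255))
  # very negative k seeds the whole band
  expect_equal(sum(adaptive_seeds(b2, band, -1e6)), 100)
  expect_error(adaptive_seeds(b, matrix(FALSE, 10, 10), 2), "empty")
})

test_that("region growing recovers a bright square from one seed", {
  img <- matrix(30, 20, 20)
  img[8:12, 8:12] <- 200
  band <- matrix(TRUE, 20, 20)
  seeds <- matrix(FALSE, 20, 20); seeds[10, 10] <- TRUE
  grown <- region_grow(img, seeds, band, delta = 10)
  expect_equal(sum(grown), 25)
  expect_true(all(grown[8:12, 8:12]))
  # empty seeds give an empty mask
  expect_equal(sum(region_grow(img, matrix(FALSE, 20, 20), band, 10)), 0)
})

test_that("growth never leaves the band", {
  set.seed(14)
  for (rep in 1:5) {
    img <- matrix(runif(400, 0, 255), 20, 20)
    band <- matrix(runif(400) < 0.6, 20, 20)
    seeds <- band & img > 200
    grown <- region_grow(img, seeds, band, delta = 50)
    expect_false(any(grown & !band))
  }
  expect_error(region_grow(matrix(0, 3, 3), matrix(TRUE, 3, 3),
                           matrix(FALSE, 3, 3), 1), "inside the band")
})

test_that("3D linking: single voxels, diagonal connectivity, oracle count", {
  m <- lapply(1:4, function(i) matrix(FALSE, 6, 8))
  m[[2]][3, 4] <- TRUE
  ls <- link_3d(m, min_voxels = 1L)
  expect_length(ls$lesions, 1)
  expect_equal(unname(ls$lesions[[1]]$centroid), c(3, 2, 4))
  # diagonal voxels in adjacent B-scans join under 26-connectivity
  m[[3]][4, 5] <- TRUE
  expect_length(link_3d(m, min_voxels = 1L)$lesions, 1)
  expect_error(link_3d(list(matrix(FALSE, 2, 2), matrix(FALSE, 3, 2))),
               "inconsistent")
})

test_that("label counts match the flood-fill oracle on random masks", {
  set.seed(15)
  for (rep in 1:5) {
    d <- c(sample(6:12, 1), sample(4:8, 1), sample(6:12, 1))
    mask <- array(runif(prod(d)) < 0.2, dim = d)
    masks <- lapply(seq_len(d[2]), function(y) mask[, y, ])
    ls <- link_3d(masks, min_voxels = 1L)
    expect_equal(length(ls$lesions), max(oracle_flood3d(mask)))
  }
})

test_that("phantom foci are recovered with matching count and good Dice", {
  cfg <- test_phantom_config(n_foci = 5L, n_exudates = 2L, rng_seed = 41L)
  p <- generate_oct_phantom(cfg)
  dvol <- denoise_volume(p$oct)
  dvol2 <- denoise_volume(dvol, 2, 12)
  s <- build_surfaces(dvol, layer_params(denoise = FALSE))
  band <- build_narrow_band(s, 3L, dim(p$oct$intensities)[3])
  les <- detect_hrf(dvol2, band)
  expect_length(les$lesions, 5)
  truth_lab <- oracle_flood3d(p$foci_mask)
  for (l in les$lesions) {
    det <- array(FALSE, dim = dim(truth_lab)); det[l$voxels] <- TRUE
    ids <- setdiff(unique(truth_lab[l$voxels]), 0)
    expect_length(ids, 1)
    expect_gte(dice2(det, truth_lab == ids), 0.7)
  }
})

test_that("height map converts per-column counts to micrometres", {
  m <- lapply(1:3, function(i) matrix(FALSE, 5, 30))
  m[[2]][2, 5:14] <- TRUE   # 10 voxels in one column
  ls <- link_3d(m, min_voxels = 1L)
  hm <- height_map(ls, 1.953)
  expect_equal(hm[2, 2], 19.53)
  expect_equal(sum(hm != 0), 1)
  # mass conservation: sum / pitch = total voxel count
  expect_equal(sum(hm) / 1.953, 10)
  empty <- link_3d(lapply(1:3, function(i) matrix(FALSE, 5, 30)),
                   min_voxels = 1L)
  expect_equal(max(height_map(empty, 2)), 0)
})

test_that("HE split partitions lesions by footprint overlap", {
  m <- lapply(1:2, function(i) matrix(FALSE, 10, 10))
  m[[1]][2:3, 4:5] <- TRUE   # lesion A footprint at x 2:3, y 1
  m[[2]][8, 7] <- TRUE       # lesion B at x 8, y 2
  ls <- link_3d(m, min_voxels = 1L)
  he_mask <- matrix(0, 10, 2)
  expect_length(split_by_he(ls, he_mask)$he$lesions, 0)
  he_mask[2:3, 1] <- 1
  sp <- split_by_he(ls, he_mask)
  expect_length(sp$he$lesions, 1)
  expect_length(sp$focus$lesions, 1)
  n_all <- length(ls$lesions)
  expect_equal(length(sp$he$lesions) + length(sp$focus$lesions), n_all)
  expect_error(split_by_he(ls, matrix(0, 3, 3)), "frame")
})

test_that("HE-destined phantom foci are classified HE from the truth mask", {
  cfg <- test_phantom_config(n_foci = 8L, n_exudates = 3L, rng_seed = 43L)
  case <- generate_phantom_case(cfg)
  dvol2 <- denoise_volume(denoise_volume(case$oct), 2, 12)
  s <- build_surfaces(denoise_volume(case$oct), layer_params(denoise = FALSE))
  band <- build_narrow_band(s, 3L, dim(case$oct$intensities)[3])
  les <- detect_hrf(dvol2, band)
  sp <- split_by_he(les, case$truth_he_mask_enface)
  # agreement with truth: HE lesions overlap HE-destined foci footprints
  truth_he_fp <- apply(case$truth_foci_mask, c(1, 2), any) &
    case$truth_he_mask_enface > 0
  correct <- vapply(sp$he$lesions, function(l)
    any(truth_he_fp[l$footprint]), logical(1))
  expect_gte(mean(correct), 0.9)
  expect_length(sp$he$lesions, 3)
})
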