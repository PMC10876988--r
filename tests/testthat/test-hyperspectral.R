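small_cube <- function(...) simulate_cube(height = 8, width = 8, grid_len = 256, ...)

test_that("cube containers round-trip bitwise and validate dimensions", {
  set.seed(90)
  cube <- hyperspectral_cube(seq(400, 3200, length.out = 128),
                             array(rnorm(4 * 4 * 128), c(4, 4, 128)))
  f <- withr::local_tempfile(fileext = ".txt")
  write_cube(cube, f)
  r <- read_cube(f)
  expect_identical(r$intensities, cube$intensities)
  expect_identical(r$axis, cube$axis)
  # 1 x 1 cube is a valid single-spectrum image
  c1 <- hyperspectral_cube(seq(400, 3200, length.out = 64),
                           array(rnorm(64), c(1, 1, 64)))
  f2 <- withr::local_tempfile()
  write_cube(c1, f2)
  expect_identical(read_cube(f2)$intensities, c1$intensities)
  # corrupt the header pixel count
  lines <- readLines(f)
  lines[2] <- sub('"H":4', '"H":5', lines[2])
  writeLines(lines, f)
  expect_error(read_cube(f), class = "ramanclean_parse_error")
  expect_error(hyperspectral_cube(1:10, array(0, c(2, 2, 9))),
               class = "ramanclean_validation_error")
})

test_that("per-pixel preprocessing is independent, order-preserving and permutation-equivariant", {
  cube <- small_cube(seed = 91)
  ident <- function(s) s
  same <- preprocess_cube(cube, ident)
  expect_identical(same$intensities, cube$intensities)
  # function preprocessors apply pixelwise: check against manual application
  wv <- preprocess_cube(cube, function(s) wavelet_preprocess(s, levels = 6))
  i <- 3; j <- 5
  manual <- wavelet_preprocess(spectrum(cube$axis, cube$intensities[i, j, ]),
                               levels = 6)
  expect_equal(wv$intensities[i, j, ], manual$intensity)
  # permuting pixels commutes with preprocessing
  perm <- cube
  perm$intensities <- cube$intensities[8:1, , , drop = FALSE]
  perm$signal_mask <- cube$signal_mask[8:1, ]
  perm$background_mask <- cube$background_mask[8:1, ]
  wp <- preprocess_cube(perm, function(s) wavelet_preprocess(s, levels = 6))
  expect_equal(wp$intensities[8, 1, ], wv$intensities[1, 1, ])
})

test_that("top-k mean spectrum ranks pixels by spectral SNR", {
  ax <- seq(400, 3200, length.out = 280)
  mk <- function(snr_db) {
    I <- numeric(280)
    I[ax >= 2800] <- 10^(snr_db / 10)
    I[ax >= 1800 & ax < 2800] <- 1
    I
  }
  arr <- array(0, c(1, 3, 280))
  arr[1, 1, ] <- mk(0); arr[1, 2, ] <- mk(10); arr[1, 3, ] <- mk(20)
  cube <- hyperspectral_cube(ax, arr)
  # k = 1: the single best pixel
  expect_equal(top_k_mean_spectrum(cube, 1)$intensity, mk(20))
  # k = 2: mean of the two best
  expect_equal(top_k_mean_spectrum(cube, 2)$intensity, (mk(10) + mk(20)) / 2)
  # k = N: the plain mean over all pixels
  expect_equal(top_k_mean_spectrum(cube, 3)$intensity,
               (mk(0) + mk(10) + mk(20)) / 3)
  expect_error(top_k_mean_spectrum(cube, 4), class = "ramanclean_validation_error")
})

test_that("channel maps pick nearest wavenumbers with low-index ties and band means", {
  ax <- c(100, 200, 300, 400)
  arr <- array(0, c(2, 2, 4))
  for (k in 1:4) arr[, , k] <- k
  cube <- hyperspectral_cube(ax, arr)
  expect_true(all(channel_map(cube, 300) == 3))
  # tie between 200 and 300 at shift 250: lower index wins
  expect_true(all(channel_map(cube, 250) == 2))
  # band covering three grid points averages their columns
  expect_true(all(channel_map(cube, 300, band = 100) == 3))
  expect_error(channel_map(cube, 9999), class = "ramanclean_range_error")
})

test_that("RGB merging scales channels independently", {
  m <- matrix(1:6, 2, 3)
  g <- merge_rgb(m, m, m)
  expect_equal(g[, , 1], g[, , 2])
  expect_equal(g[, , 1], g[, , 3])
  hot <- matrix(0, 2, 3); hot[1, 1] <- 5
  rgb <- merge_rgb(hot, matrix(0, 2, 3), matrix(0, 2, 3))
  expect_equal(rgb[1, 1, ], c(1, 0, 0))
  cst <- matrix(4, 2, 3)
  expect_true(all(merge_rgb(cst, cst, cst) == 0))
  expect_error(merge_rgb(m, m, matrix(0, 3, 2)),
               class = "ramanclean_validation_error")
})

test_that("PCA feature maps expose dominant structure", {
  # rank-1 cube: pixels are scalar multiples of one spectral profile
  ax <- seq(400, 3200, length.out = 64)
  v <- sin(seq(0, 4, length.out = 64))
  arr <- array(0, c(4, 4, 64))
  set.seed(92)
  for (i in 1:4) for (j in 1:4) arr[i, j, ] <- runif(1, 0.5, 2) * v
  cube <- hyperspectral_cube(ax, arr)
  pf <- pca_feature_maps(cube, 3)
  expect_gt(pf$explained_variance[1], 0.999)
  expect_true(all(diff(pf$explained_variance) <= 1e-12))
  expect_error(pca_feature_maps(cube, 65), class = "ramanclean_validation_error")
  cst <- hyperspectral_cube(ax, array(1, c(4, 4, 64)))
  expect_error(pca_feature_maps(cst, 2), class = "ramanclean_validation_error")
})

test_that("simulated cubes honour their construction", {
  cube <- small_cube(seed = 93)
  expect_true(all(xor(cube$signal_mask, cube$background_mask)))
  # lipid channel is brighter inside cells than over the background
  lipid <- channel_map(cube, 2850, band = 20)
  expect_gt(mean(lipid[cube$signal_mask]), mean(lipid[cube$background_mask]))
  # zero noise, zero baseline: silent zone exactly zero, SNR at the cap
  clean <- small_cube(seed = 94, noise_sd = 0, baseline_amp = 0)
  sil <- clean$axis >= 1800 & clean$axis < 2800
  cells <- which(clean$signal_mask, arr.ind = TRUE)
  px <- clean$intensities[cells[1, 1], cells[1, 2], ]
  expect_true(all(px[sil] == 0))
  expect_equal(snr_spec(spectrum(clean$axis, px)), 120)
})
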