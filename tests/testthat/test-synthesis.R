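test_that("assemble_ideal respects peak-count bounds, placement and manifests", {
  pools <- tiny_pools()
  cfg <- synthesis_config(n_spectra = 40, kmin = 5, kmax = 20, seed = 3)
  asm <- assemble_ideal(pools, cfg)
  expect_equal(nrow(asm$ideals), 40)
  ks <- vapply(asm$manifests, nrow, integer(1))
  expect_true(all(ks >= 5 & ks <= 20))
  # mask oracle: intensity outside every manifest interval is exactly zero
  for (i in c(1, 7, 40)) {
    mask <- rep(FALSE, cfg$grid_len)
    mf <- asm$manifests[[i]]
    for (j in seq_len(nrow(mf)))
      mask[(mf$position[j] + 1):(mf$position[j] + mf$length[j])] <- TRUE
    expect_true(all(asm$ideals[i, !mask] == 0))
    # ideal spectra have zero baseline off the peaks
    expect_identical(stats::median(asm$ideals[i, !mask]), 0)
  }
  # single fragment, fixed scale/position degenerates to a padded copy
  onecfg <- synthesis_config(n_spectra = 1, kmin = 1, kmax = 1, seed = 4,
                             amp_range = c(1, 1))
  pool1 <- pools; pool1$peaks <- pools$peaks[1]
  set.seed(9)
  asm1 <- assemble_ideal(pool1, onecfg)
  prof <- pool1$peaks[[1]]$profile
  pos <- asm1$manifests[[1]]$position
  expect_equal(asm1$ideals[1, (pos + 1):(pos + length(prof))], prof)
  expect_true(all(asm1$ideals[1, -((pos + 1):(pos + length(prof)))] == 0))
  # empty pool
  pool0 <- pools; pool0$peaks <- list()
  expect_error(assemble_ideal(pool0, cfg), class = "ramanclean_validation_error")
})

test_that("reference synthesis obeys the construction identity", {
  set.seed(5)
  y <- lorentz(512, c(100, 300), c(8, 10), c(1, 0.6))
  noise <- rnorm(512); baseline <- seq(0, 2, length.out = 512)
  p <- synthesize_reference(y, noise, baseline, alpha = 0.3, beta = 1.2)
  expect_identical(p$x, y + 0.3 * noise + 1.2 * baseline)
  expect_lt(max(abs((p$x - p$y) - (0.3 * noise + 1.2 * baseline))), 1e-12)
  p0 <- synthesize_reference(y, noise, baseline, 0, 0)
  expect_identical(p0$x, y)
  expect_error(synthesize_reference(y, noise[-1], baseline, 1, 1),
               class = "ramanclean_validation_error")
})

test_that("scale_to_target_snr solves the closed form", {
  # P_signal = 100, P_noise = 1, target 20 dB -> alpha = 1
  y <- rep(10, 64); noise <- rep(1, 64)
  expect_equal(scale_to_target_snr(y, noise, 20), 1)
  # homogeneity: doubling y doubles alpha
  expect_equal(scale_to_target_snr(2 * y, noise, 20), 2)
  # realized SNR matches the target within 1 dB for a dense ideal spectrum
  set.seed(6)
  yl <- lorentz(1024, c(200, 500, 800), c(10, 15, 8), c(1, 0.7, 0.9))
  nz <- rnorm(1024)
  a <- scale_to_target_snr(yl, nz, 10)
  p <- synthesize_reference(yl, nz, numeric(1024), a, 0)
  expect_lt(abs(p$snr_db - 10), 1)
  expect_error(scale_to_target_snr(y, noise, -Inf),
               class = "ramanclean_range_error")
  expect_error(scale_to_target_snr(numeric(10), rep(1, 10), 10),
               class = "ramanclean_validation_error")
})

test_that("the mathematical-simulation generator matches its declared laws", {
  cfg <- synthesis_config(n_spectra = 1, kmin = 1, kmax = 1, seed = 8)
  # single Lorentzian: unit max at the center, half-max span ~ 2x half-width
  set.seed(21)
  p <- generate_mathsim_pair(cfg, width_range = c(10, 10))
  ctr <- p$manifest$center; amp <- p$manifest$amp
  expect_equal(max(p$y), p$y[round(ctr)], tolerance = 1e-3)
  half <- which(p$y >= amp / 2)
  expect_equal(length(half), 2 * 10, tolerance = 0.2)
  # noise SD concentrates around its nominal value
  set.seed(22)
  sds <- replicate(30, sd(generate_mathsim_pair(cfg)$noise))
  expect_true(all(abs(sds - 1) < 3 / sqrt(2 * 1024) * 3))
  # alpha = beta = 0 gives x == y
  set.seed(23)
  p2 <- generate_mathsim_pair(cfg)
  p0 <- synthesize_reference(p2$y, p2$noise, p2$baseline, 0, 0)
  expect_identical(p0$x, p0$y)
})

test_that("build_dataset is deterministic and records provenance", {
  d1 <- tiny_dataset(n = 12, seed = 99)
  d2 <- tiny_dataset(n = 12, seed = 99)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  expect_equal(length(d1), 12)
  expect_equal(d1$meta$mode, "mathsim")
  # construction identity holds for every generated pair
  for (i in seq_len(12)) {
    resid <- d1$x[i, ] - d1$y[i, ]
    expect_true(all(is.finite(resid)))
  }
  # recombination mode with pools, and mode round-trip through I/O
  pools <- tiny_pools()
  cfg <- synthesis_config(n_spectra = 5, seed = 31)
  dr <- build_dataset(cfg, "recombination", pools = pools)
  expect_equal(dr$meta$mode, "recombination")
  f <- withr::local_tempfile()
  write_pairs(dr, f)
  expect_equal(read_pairs(f)$meta$mode, "recombination")
})
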