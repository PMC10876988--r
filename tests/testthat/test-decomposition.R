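test_that("periodized DWT reconstructs perfectly and preserves energy", {
  set.seed(10)
  for (n in c(256, 300, 1000, 1024)) {
    x <- rnorm(n) + 10 * sin(seq(0, 3, length.out = n))
    w <- dwt_periodic(x, 8)
    expect_lt(max(abs(idwt_periodic(w) - x)), 1e-10 * max(1, max(abs(x))))
  }
  # orthogonality: coefficient energy equals signal energy (extended domain)
  x <- rnorm(1024)
  xe <- ramanclean:::dwt_extend(x, 8)
  w <- dwt_periodic(x, 8)
  expect_equal(sum(xe^2),
               sum(w$a^2) + sum(unlist(lapply(w$d, function(d) sum(d^2)))),
               tolerance = 1e-12)
  expect_error(dwt_periodic(rnorm(100), 8), class = "ramanclean_validation_error")
})

test_that("band reconstructions sum to the original signal", {
  set.seed(11)
  x <- rnorm(777) + seq(0, 40, length.out = 777)
  w <- dwt_periodic(x, 8)
  parts <- wavelet_band_reconstruct(w, 1:2) +
    wavelet_band_reconstruct(w, 3:6) +
    wavelet_band_reconstruct(w, 7:8, keep_approx = TRUE)
  expect_lt(max(abs(parts - x)), 1e-10 * max(abs(x)))
})

test_that("decompose_spectrum partitions exactly and routes smooth trends to the baseline", {
  # zero in, zero out
  z <- decompose_spectrum(spectrum(fix_axis(256), numeric(256)))
  expect_true(all(z$signal == 0) && all(z$baseline == 0) && all(z$noise == 0))
  # partition identity on random spectra
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(512) * runif(1, 0.1, 100) + runif(1, -50, 50)
    comp <- decompose_spectrum(spectrum(fix_axis(512), x))
    expect_lt(max(abs(comp$signal + comp$baseline + comp$noise - x)),
              1e-8 * max(abs(x)))
  }
  # pure cubic polynomial: almost everything lands in the baseline
  t <- seq(0, 1, length.out = 1024)
  cub <- 5 * t^3 - 2 * t^2 + t
  comp <- decompose_spectrum(spectrum(fix_axis(1024), cub))
  rg <- diff(range(cub))
  expect_lt(max(abs(comp$baseline - cub)), 0.01 * rg)
  expect_lt(max(abs(comp$signal)), 0.01 * rg)
})

test_that("the differential peak finder locates isolated peaks", {
  expect_identical(extract_peak_fragments(numeric(512)), list())
  # single Lorentzian apex at index 300 (0-based)
  y <- lorentz(1024, 301, 8, 1)
  fr <- extract_peak_fragments(y)
  expect_length(fr, 1)
  expect_equal(fr[[1]]$apex, 300L)
  expect_true(fr[[1]]$start < fr[[1]]$apex && fr[[1]]$apex < fr[[1]]$end)
  expect_equal(fr[[1]]$profile[fr[[1]]$apex - fr[[1]]$start + 1],
               max(fr[[1]]$profile))
  expect_true(all(fr[[1]]$profile >= 0))
  # two well-separated Gaussians -> two disjoint fragments
  tt <- seq_len(1024)
  y2 <- exp(-((tt - 200) / 10)^2) + 0.7 * exp(-((tt - 700) / 12)^2)
  fr2 <- extract_peak_fragments(y2)
  expect_length(fr2, 2)
  expect_lte(fr2[[1]]$end, fr2[[2]]$start)
  # brute-force oracle: apexes are exactly the +/- sign changes of diff(y2)
  d <- diff(y2)
  brute <- which(d[-length(d)] > 0 & d[-1] < 0)
  expect_setequal(vapply(fr2, function(f) f$apex, integer(1)), brute)
})

test_that("component pools collect one noise/baseline per spectrum and the planted peaks", {
  pools <- tiny_pools(n_spectra = 10)
  expect_length(pools$noises, 10)
  expect_length(pools$baselines, 10)
  # 6 planted peaks per spectrum, 60 in total. At the default (permissive)
  # prominence the band-limited reconstruction also rings around sharp peaks,
  # so at least the planted count must be found; with a threshold above the
  # sidelobe level the count should be close to the planted one.
  expect_gte(length(pools$peaks), 54)
  set.seed(42)
  spectra <- lapply(seq_len(10), function(i) {
    centers <- seq(100, 924, length.out = 6) + round(stats::runif(6, -20, 20))
    y <- lorentz(1024, centers, stats::runif(6, 5, 12), stats::runif(6, 0.5, 1))
    spectrum(fix_axis(1024), y + 2 * (seq_len(1024) / 1024)^2 + 1 +
               stats::rnorm(1024, sd = 0.01))
  })
  strict <- build_component_pools(spectra, min_prominence = 0.1)
  expect_gte(length(strict$peaks), 50)
  expect_lte(length(strict$peaks), 75)
  p1 <- build_component_pools(list(spectrum(fix_axis(512),
                                            lorentz(512, 250, 8, 1) + 1)))
  expect_length(p1$noises, 1)
  expect_error(build_component_pools(list()),
               class = "ramanclean_validation_error")
})

test_that("planted apexes are recovered within +/-2 points at high prominence", {
  set.seed(13)
  hits <- 0; total <- 0
  for (rep in 1:10) {
    k <- 8
    centers <- sort(sample(seq(60, 960, by = 10), k))
    while (min(diff(centers)) < 60)
      centers <- sort(sample(seq(60, 960, by = 10), k))
    amps <- runif(k, 0.5, 1)
    y <- lorentz(1024, centers, runif(k, 5, 10), amps)
    noise_sd <- 0.02                       # prominence >= 5x noise SD for all
    baseline <- 1 + (seq_len(1024) / 1024)^2
    x <- y + baseline + rnorm(1024, sd = noise_sd)
    comp <- decompose_spectrum(spectrum(fix_axis(1024), x))
    fr <- extract_peak_fragments(comp$signal, min_prominence = 0.02)
    apexes <- vapply(fr, function(f) f$apex, integer(1)) + 1  # 1-based
    for (c0 in centers) {
      total <- total + 1
      if (any(abs(apexes - c0) <= 2)) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("component pools round-trip bitwise through the text container", {
  pools <- tiny_pools(n_spectra = 3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_pools(pools, f)
  r <- read_pools(f)
  expect_identical(r$noises, pools$noises)
  expect_identical(r$baselines, pools$baselines)
  expect_equal(length(r$peaks), length(pools$peaks))
  expect_identical(r$peaks[[1]]$profile, pools$peaks[[1]]$profile)
  expect_identical(r$peaks[[5]]$start, pools$peaks[[5]]$start)
  expect_identical(r$grid_len, pools$grid_len)
})
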