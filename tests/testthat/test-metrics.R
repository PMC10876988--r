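# Every metric is checked against an independent brute-force implementation
# written here with explicit loops.

brute_rmse <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (y[i] - x[i])^2
  sqrt(s / length(x))
}
brute_linf <- function(x, y) {
  m <- 0
  for (i in seq_along(x)) m <- max(m, abs(y[i] - x[i]))
  m
}
brute_auc <- function(pos, neg) {
  s <- 0
  for (m in pos) for (n in neg)
    s <- s + if (m > n) 1 else if (m == n) 0.5 else 0
  s / (length(pos) * length(neg))
}
brute_eq <- function(pred, actual) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (log10(actual[i]) - log10(pred[i]))^2
  sqrt(s)
}

test_that("RMSE and the infinity norm match hand values and brute force", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(linf(c(1, 2), c(4, 0)), 3)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(linf(1:5, 1:5), 0)
  # homogeneity
  set.seed(60)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(rmse(3 * x, 3 * y), 3 * rmse(x, y))
  # length-1 equality of the two norms
  expect_equal(linf(2, 5), rmse(2, 5))
  for (i in 1:100) {
    n <- sample(1:12, 1)
    a <- rnorm(n) * 10^sample(-2:2, 1); b <- rnorm(n)
    expect_equal(rmse(a, b), brute_rmse(a, b), tolerance = 1e-12)
    expect_equal(linf(a, b), brute_linf(a, b), tolerance = 1e-12)
  }
  expect_error(rmse(1:3, 1:4), class = "ramanclean_validation_error")
})

test_that("classification metrics match pair enumeration and count arithmetic", {
  expect_equal(classification_metrics(c(0.8, 0.4), c(0.6, 0.2))$auc, 0.75)
  expect_equal(classification_metrics(c(2, 3), c(0, 1))$auc, 1)
  cm <- confusion_metrics(tp = 3, fn = 1, fp = 1, tn = 3)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 0.75)
  expect_equal(cm$ppv, 0.75)
  expect_equal(cm$npv, 0.75)
  set.seed(61)
  for (i in 1:100) {
    pos <- rnorm(sample(2:8, 1)); neg <- rnorm(sample(2:8, 1))
    expect_equal(classification_metrics(pos, neg)$auc, brute_auc(pos, neg),
                 tolerance = 1e-12)
  }
  # AUC equals the Mann-Whitney U statistic / (M*N) on tie-free data
  pos <- rnorm(7); neg <- rnorm(9)
  U <- suppressWarnings(stats::wilcox.test(pos, neg)$statistic)
  expect_equal(classification_metrics(pos, neg)$auc, unname(U) / (7 * 9))
  expect_error(classification_metrics(numeric(0), rnorm(3)),
               class = "ramanclean_undefined_metric")
})

test_that("quantification error uses decade (log10) differences", {
  expect_equal(quantification_error(1e-5, 1e-4), 1)
  expect_equal(quantification_error(c(1e-5, 1e-6), c(1e-4, 1e-5)), sqrt(2))
  expect_equal(quantification_error(c(2, 3), c(2, 3)), 0)
  set.seed(62)
  for (i in 1:100) {
    p <- 10^runif(5, -7, -3); a <- 10^runif(5, -7, -3)
    expect_equal(quantification_error(p, a), brute_eq(p, a), tolerance = 1e-12)
  }
  expect_error(quantification_error(c(1, -1), c(1, 1)),
               class = "ramanclean_validation_error")
})

test_that("spectral SNR integrates the C-H and silent regions", {
  ax <- seq(400, 3200, length.out = 1400)
  I <- numeric(1400)
  I[ax >= 2800 & ax < 3200] <- 100
  I[ax >= 1800 & ax < 2800] <- 1
  s <- spectrum(ax, I)
  expect_equal(snr_spec(s), 20)
  I2 <- rep(7, 1400)
  expect_equal(snr_spec(spectrum(ax, I2)), 0)
  # exactly-zero silent zone is floored, result finite and capped
  I3 <- numeric(1400); I3[ax >= 2800] <- 5
  expect_equal(snr_spec(spectrum(ax, I3)), 120)
  expect_error(snr_spec(spectrum(seq(400, 1700, length.out = 200), rnorm(200))),
               class = "ramanclean_range_error")
})

test_that("image contrast metrics follow the masked-mean definitions", {
  sig <- matrix(FALSE, 4, 4); sig[1:2, 1:2] <- TRUE
  bg <- !sig
  img <- matrix(2, 4, 4); img[sig] <- 10
  img[bg] <- img[bg] + rep(c(-2, 2), 6)  # sd(bg) = 2 (approx)
  # construct exactly: background values alternate 0 and 4 -> mean 2, sd ~2.04
  r <- image_contrast_metrics(img, img, sig, bg)
  expect_equal(r$cnr_raw, (10 - 2) / stats::sd(img[bg]))
  expect_equal(r$normalized_cnr, 1)
  expect_equal(r$normalized_stdb, 1)
  # worked value: C_sig 10, C_bg 2, sd 2 -> CNR 4
  img2 <- matrix(0, 2, 4)
  sig2 <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE), 2, 4)
  bg2 <- !sig2
  img2[sig2] <- 10
  img2[bg2] <- c(0, 4, 0, 4, 2, 2)     # mean 2
  sd_bg <- stats::sd(img2[bg2])
  r2 <- image_contrast_metrics(img2, img2, sig2, bg2)
  expect_equal(r2$cnr_raw, (10 - 2) / sd_bg)
  cnst <- matrix(1, 2, 4)
  expect_error(image_contrast_metrics(cnst, cnst, sig2, bg2),
               class = "ramanclean_undefined_metric")
  expect_error(image_contrast_metrics(img2, img2, sig2, sig2),
               class = "ramanclean_validation_error")
})

test_that("rank tests agree with exact enumeration and handle degenerate input", {
  # n = 5, all differences positive: one-sided 1/32, two-sided 1/16
  a <- c(1.1, 2.3, 3.2, 4.4, 5.9); b <- a - c(0.1, 0.4, 0.2, 0.3, 0.5)
  expect_equal(paired_test(a, b, "signed_rank"), 2 / 32)
  # brute-force enumeration of all sign patterns for a random tie-free sample
  set.seed(63)
  d <- c(0.8, -0.3, 1.7, 0.6, -1.2, 0.9, 0.45)
  n <- length(d)
  r <- rank(abs(d))
  Wobs <- sum(r[d > 0])
  count <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[1:n]
    W <- sum(r[signs == 1])
    if (min(W, n * (n + 1) / 2 - W) <= min(Wobs, n * (n + 1) / 2 - Wobs))
      count <- count + 1
  }
  expect_equal(paired_test(d + 10, rep(10, n), "signed_rank"), count / 2^n)
  expect_error(paired_test(1:4, 1:5, "signed_rank"),
               class = "ramanclean_validation_error")
  expect_error(paired_test(1:5, 1:5, "signed_rank"),
               class = "ramanclean_degenerate_input")
  # Mann-Whitney against enumeration of group assignments
  x <- c(1.2, 3.4, 2.2); y <- c(0.3, 0.9, 4.1, 1.8)
  pooled <- c(x, y)
  combs <- utils::combn(7, 3)
  Uobs <- sum(outer(x, y, `>`))
  cnt <- 0
  for (k in seq_len(ncol(combs))) {
    xs <- pooled[combs[, k]]; ys <- pooled[-combs[, k]]
    U <- sum(outer(xs, ys, `>`))
    if (min(U, 12 - U) <= min(Uobs, 12 - Uobs)) cnt <- cnt + 1
  }
  expect_equal(paired_test(x, y, "mann_whitney"), cnt / ncol(combs))
  # large-sample calibration: p-values under the null are roughly uniform
  set.seed(64)
  ps <- replicate(200, {
    z <- rnorm(30)
    paired_test(z + 10, rep(10, 30), "signed_rank")
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 1e-3)
})
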