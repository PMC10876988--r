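test_that("make_patches tiles the spectrum and inverts by overlap-averaging", {
  x <- as.numeric(1:16)
  P <- make_patches(x, window = 8, step = 4)
  expect_equal(nrow(P), 3)
  expect_equal(P[1, ], x[1:8])
  expect_equal(P[2, ], x[5:12])
  expect_equal(P[3, ], x[9:16])
  expect_lt(max(abs(assemble_patches(P) - x)), 1e-12)
  # window == step == L: single patch equal to the input
  P1 <- make_patches(x, 16, 16)
  expect_equal(nrow(P1), 1)
  expect_equal(P1[1, ], x)
  # replicate padding when (L - window) is not divisible by step
  set.seed(40)
  x2 <- rnorm(21)
  P2 <- make_patches(x2, window = 8, step = 5)
  expect_lt(max(abs(assemble_patches(P2) - x2)), 1e-12)
  expect_error(make_patches(x, 32, 4), class = "ramanclean_validation_error")
})

test_that("untrained background branch is exactly zero and shapes are kept", {
  m <- new_preprocessor(tiny_model_cfg())
  set.seed(41)
  x <- rnorm(64)
  expect_identical(estimate_background(x, m), rep(0, 64))
  p <- forward_preprocess(x, m)
  expect_length(p, 64)
  # with zero-initialized heads the model starts at the identity mapping
  expect_equal(p, x, tolerance = 1e-12)
})

test_that("loss functions satisfy their closed forms", {
  # Huber regimes via the background loss on single points
  expect_equal(loss_background(0.5, 0, 0), 0.125)   # r = -0.5 -> 0.5*0.25
  expect_equal(loss_background(2, 0, 0), 1.5)       # |r| = 2 -> 2 - 0.5
  x <- c(1, 2, 3); y <- c(0.5, 1, 2)
  expect_equal(loss_background(x, y, x - y), 0)
  expect_equal(loss_total(x, y, bx = x - y, px = y, lambda = 0.7), 0)
  # lambda extremes
  set.seed(42)
  px <- rnorm(3); bx <- rnorm(3)
  h <- function(r) mean(ifelse(abs(r) < 1, 0.5 * r^2, abs(r) - 0.5))
  expect_equal(loss_total(x, y, bx, px, lambda = 1), h(px - y))
  expect_equal(loss_total(x, y, bx, px, lambda = 0), h(bx - (x - y)))
  expect_error(loss_total(x, y, bx, px, lambda = 1.2),
               class = "ramanclean_validation_error")
  expect_gte(loss_background(x, y, bx), 0)
})

test_that("training is deterministic, converges, and checkpoints round-trip", {
  d <- tiny_dataset(n = 48, L = 64, seed = 50)
  cfg <- tiny_model_cfg(epochs_be = 2, epochs_full = 3)
  m1 <- train_preprocessor(d, cfg)
  m2 <- train_preprocessor(d, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_true(all(is.finite(m1$history$loss)))
  f <- withr::local_tempfile(fileext = ".rds")
  save_preprocessor(m1, f)
  m3 <- load_preprocessor(f)
  set.seed(51); x <- rnorm(64)
  expect_identical(forward_preprocess(x, m1), forward_preprocess(x, m3))
  expect_error(train_preprocessor(d[1:4], cfg),
               class = "ramanclean_validation_error")
})

test_that("background pretraining learns a trivially learnable constant background", {
  # pairs with x = y + 5: the BE branch must drive its loss down monotonely
  set.seed(52)
  L <- 64
  y <- t(replicate(48, lorentz(L, sample(10:50, 3), rep(4, 3), runif(3, .5, 1))))
  x <- y + 5
  d <- pair_collection(fix_axis(L), x, y)
  cfg <- tiny_model_cfg(epochs_be = 6, epochs_full = 2, seed = 9)
  m <- train_preprocessor(d, cfg)
  be_loss <- m$history$loss[m$history$phase == "background"]
  expect_true(all(diff(be_loss) < 0))
  # and the trained model reduces the reconstruction error vs raw input
  pred <- forward_preprocess(x, m)
  rm_model <- vapply(1:48, function(i) rmse(pred[i, ], y[i, ]), numeric(1))
  rm_raw <- vapply(1:48, function(i) rmse(x[i, ], y[i, ]), numeric(1))
  expect_lt(median(rm_model), median(rm_raw))
})

test_that("preprocessing is exactly scale-equivariant and axis-preserving", {
  d <- tiny_dataset(n = 32, L = 64, seed = 53)
  cfg <- tiny_model_cfg(epochs_be = 2, epochs_full = 2)
  m <- train_preprocessor(d, cfg)
  s <- spectrum(seq(500, 3100, length.out = 80), abs(rnorm(80)) + 1)
  out <- preprocess(s, m)
  expect_identical(out$axis, s$axis)
  for (c0 in c(0.5, 2)) {
    s2 <- spectrum(s$axis, c0 * s$intensity)
    out2 <- preprocess(s2, m)
    expect_equal(out2$intensity, c0 * out$intensity, tolerance = 1e-12)
  }
  # batch order preservation
  X <- d$x[1:5, ]
  batch <- forward_preprocess(X, m)
  for (i in 1:5)   # BLAS kernels may differ in blocking across batch widths
    expect_equal(batch[i, ], forward_preprocess(X[i, ], m), tolerance = 1e-12)
})

test_that("stage shapes follow the 1/4-then-halving feature plan", {
  tr <- stage_shapes(model_config(grid_len = 1024, channels = 4))
  get <- function(st) unlist(tr[tr$stage == st, c("channels", "features")])
  expect_equal(unname(get("stem")), c(16, 256))
  expect_equal(unname(get("reduction_a")), c(32, 128))
  expect_equal(unname(get("reduction_b")), c(64, 64))
  # inception stages preserve their input dimensionality
  expect_equal(unname(get("inception_a")), unname(get("stem")))
  expect_equal(unname(get("inception_b")), unname(get("reduction_a")))
  expect_equal(unname(get("inception_c")), unname(get("reduction_b")))
  expect_equal(unname(get("output")), c(1, 1024))
})
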