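#' GAN configuration for adversarial spectrum refinement
#'
#' The generator conditions on an ideal spectrum plus a Gaussian latent
#' channel and produces a refined reference spectrum; the discriminator is a
#' strided 1D convolutional classifier that sees candidate reference spectra
#' alone. The generator is built from three U-shaped 1D blocks
#' (strided conv down, transposed conv up, skip connection); training uses
#' the non-saturating binary cross-entropy adversarial loss plus an L1
#' consistency term anchoring generated spectra to the paired synthetic
#' references.
#'
#' @param grid_len spectral grid length (latent channel has the same length).
#' @param width base channel width (desk scale: 8).
#' @param epochs,batch,lr training schedule.
#' @param l1_weight weight of the L1 consistency term (default 10).
#' @param seed RNG seed.
#' @return list of class `gan_config`.
#' @export
gan_config <- function(grid_len = 1024, width = 8, epochs = 10, batch = 16,
                       lr = 1e-3, l1_weight = 10, seed = 1) {
  if (width < 1 || grid_len %% 8 != 0)
    validation_error("need width >= 1 and grid_len divisible by 8")
  structure(list(grid_len = grid_len, width = width, epochs = epochs,
                 batch = batch, lr = lr, l1_weight = l1_weight, seed = seed,
                 latent_len = grid_len),
            class = "gan_config")
}

build_gan_layers <- function(cfg) {
  L <- cfg$grid_len; w <- cfg$width
  g <- list(entry = nn_conv(2, w, 5, 1, L))
  for (i in 1:3) {
    g[[paste0("d", i)]] <- nn_conv(w, w, 9, 2, L)
    g[[paste0("u", i)]] <- nn_convt(w, w, 9, 2, L / 2)
    g[[paste0("m", i)]] <- nn_conv(w, w, 5, 1, L)
  }
  g$exit <- nn_conv(w, 1, 5, 1, L, zero_init = TRUE)
  d <- list(c1 = nn_conv(1, w, 9, 2, L),
            c2 = nn_conv(w, 2 * w, 9, 2, L / 2),
            c3 = nn_conv(2 * w, 4 * w, 9, 2, L / 4))
  d$dense_W <- matrix(stats::rnorm(4 * w, sd = 0.1), 1, 4 * w)
  d$dense_b <- 0
  list(gen = g, disc = d)
}

gen_forward <- function(gl, yz) {
  cc <- list(entry = conv_fwd(gl$entry, yz))
  h <- relu_fwd(cc$entry$out)
  for (i in 1:3) {
    di <- paste0("d", i); ui <- paste0("u", i); mi <- paste0("m", i)
    cc[[di]] <- conv_fwd(gl[[di]], h); e <- relu_fwd(cc[[di]]$out)
    cc[[ui]] <- convt_fwd(gl[[ui]], e); u <- relu_fwd(cc[[ui]]$out + h)
    cc[[mi]] <- conv_fwd(gl[[mi]], u); h <- relu_fwd(cc[[mi]]$out)
    cc[[paste0("a", i)]] <- e; cc[[paste0("s", i)]] <- u
    cc[[paste0("hin", i)]] <- h
  }
  cc$exit <- conv_fwd(gl$exit, h)
  list(out = cc$exit$out, cache = cc)
}

gen_backward <- function(gl, dout, fw) {
  cc <- fw$cache
  grads <- list()
  g <- conv_bwd(gl$exit, dout, cc$exit$Xc)
  grads$exit.W <- g$dW; grads$exit.b <- g$db
  dh <- g$dx
  for (i in 3:1) {
    di <- paste0("d", i); ui <- paste0("u", i); mi <- paste0("m", i)
    dh <- relu_bwd(dh, cc[[paste0("hin", i)]])
    g <- conv_bwd(gl[[mi]], dh, cc[[mi]]$Xc)
    grads[[paste0(mi, ".W")]] <- g$dW; grads[[paste0(mi, ".b")]] <- g$db
    du <- relu_bwd(g$dx, cc[[paste0("s", i)]])
    dskip <- du
    g <- convt_bwd(gl[[ui]], du, cc[[ui]]$Umat)
    grads[[paste0(ui, ".W")]] <- g$dW; grads[[paste0(ui, ".b")]] <- g$db
    de <- relu_bwd(g$dx, cc[[paste0("a", i)]])
    g <- conv_bwd(gl[[di]], de, cc[[di]]$Xc)
    grads[[paste0(di, ".W")]] <- g$dW; grads[[paste0(di, ".b")]] <- g$db
    dh <- g$dx + dskip
  }
  dh <- relu_bwd(dh, relu_fwd(cc$entry$out))
  g <- conv_bwd(gl$entry, dh, cc$entry$Xc, need_dx = FALSE)
  grads$entry.W <- g$dW; grads$entry.b <- g$db
  grads
}

disc_forward <- function(dl, x) {
  cc <- list(c1 = conv_fwd(dl$c1, x)); h1 <- lrelu_fwd(cc$c1$out)
  cc$c2 <- conv_fwd(dl$c2, h1); h2 <- lrelu_fwd(cc$c2$out)
  cc$c3 <- conv_fwd(dl$c3, h2); h3 <- lrelu_fwd(cc$c3$out)
  L3 <- dl$c3$Lout; C3 <- dl$c3$Cout; N <- ncol(x)
  pooled <- colMeans(array(h3, c(L3, C3, N)))           # (C3, N)
  logits <- drop(dl$dense_W %*% pooled + dl$dense_b)
  list(logits = logits, cache = list(cc = cc, h1 = h1, h2 = h2, h3 = h3,
                                     pooled = pooled, L3 = L3, C3 = C3))
}

disc_backward <- function(dl, dlogits, fw, need_dx = FALSE) {
  cc <- fw$cache
  N <- length(dlogits)
  grads <- list(dense_W = tcrossprod(matrix(dlogits, 1), cc$pooled),
                dense_b = sum(dlogits))
  dpooled <- crossprod(dl$dense_W, matrix(dlogits, 1))  # (C3, N)
  dh3 <- matrix(0, cc$L3 * cc$C3, N)
  for (n in seq_len(N))
    dh3[, n] <- rep(dpooled[, n], each = cc$L3) / cc$L3
  dh3 <- lrelu_bwd(dh3, cc$cc$c3$out)
  g <- conv_bwd(dl$c3, dh3, cc$cc$c3$Xc)
  grads$c3.W <- g$dW; grads$c3.b <- g$db
  dh2 <- lrelu_bwd(g$dx, cc$cc$c2$out)
  g <- conv_bwd(dl$c2, dh2, cc$cc$c2$Xc)
  grads$c2.W <- g$dW; grads$c2.b <- g$db
  dh1 <- lrelu_bwd(g$dx, cc$cc$c1$out)
  g <- conv_bwd(dl$c1, dh1, cc$cc$c1$Xc, need_dx = need_dx)
  grads$c1.W <- g$dW; grads$c1.b <- g$db
  grads$dx <- g$dx
  grads
}

# stable binary cross-entropy with logits; returns value and d/dlogit
bce_logits <- function(logits, target) {
  val <- mean(ifelse(logits > 0, logits, 0) - logits * target +
                log1p(exp(-abs(logits))))
  grad <- (stats::plogis(logits) - target) / length(logits)
  list(val = val, grad = grad)
}

gan_get <- function(lyrs) {
  out <- list()
  for (nm in names(lyrs)) {
    if (is.list(lyrs[[nm]]) && !is.null(lyrs[[nm]]$W)) {
      out[[paste0(nm, ".W")]] <- lyrs[[nm]]$W
      out[[paste0(nm, ".b")]] <- lyrs[[nm]]$b
    }
  }
  out
}

gan_set <- function(lyrs, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    lyrs[[parts[1]]][[parts[2]]] <- params[[nm]]
  }
  lyrs
}

#' Train the adversarial refinement model
#'
#' Alternating generator/discriminator updates. The generator input is the
#' (normalized) ideal spectrum concatenated channel-wise with a standard
#' Gaussian latent signal of the same length; its output is the ideal plus a
#' learned perturbation, so generation is anchored at the label. The
#' discriminator sees candidate reference spectra alone. Training aborts with
#' a `ramanclean_divergence` error if a loss becomes non-finite, carrying the
#' last finite checkpoint in the condition's `checkpoint` field.
#'
#' @param pairs a [pair_collection] (needs at least `2 * cfg$batch` pairs).
#' @param cfg a [gan_config()].
#' @param verbose print per-epoch losses.
#' @return list of class `gan_checkpoint`: layer parameters, config, axis,
#'   and per-epoch training curves.
#' @export
gan_train <- function(pairs, cfg = gan_config(), verbose = FALSE) {
  n <- nrow(pairs$x)
  if (ncol(pairs$x) != cfg$grid_len) validation_error("grid length mismatch")
  if (n < 2 * cfg$batch)
    validation_error("need at least 2*batch pairs")
  set.seed(cfg$seed)
  lyrs <- build_gan_layers(cfg)
  scale <- pmax(apply(abs(pairs$y), 1, max), .Machine$double.eps)
  Yn <- t(pairs$y / scale); Xn <- t(pairs$x / scale)
  L <- cfg$grid_len
  optG <- adam_init(gan_get(lyrs$gen))
  optD <- adam_init(gan_get(lyrs$disc))
  curves <- list()
  ckpt <- NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    dl_tot <- 0; gl_tot <- 0; nb <- 0
    for (b0 in seq(1, n - cfg$batch + 1, by = cfg$batch)) {
      sel <- ord[b0:(b0 + cfg$batch - 1)]
      yb <- Yn[, sel, drop = FALSE]; xb <- Xn[, sel, drop = FALSE]
      N <- ncol(yb)
      z <- matrix(stats::rnorm(L * N), L, N)
      yz <- rbind(yb, z)
      gfw <- gen_forward(lyrs$gen, yz)
      xhat <- yb + gfw$out
      # --- discriminator update
      dreal <- disc_forward(lyrs$disc, xb)
      dfake <- disc_forward(lyrs$disc, xhat)
      br <- bce_logits(dreal$logits, rep(1, N))
      bf <- bce_logits(dfake$logits, rep(0, N))
      d_loss <- br$val + bf$val
      gr_r <- disc_backward(lyrs$disc, br$grad, dreal)
      gr_f <- disc_backward(lyrs$disc, bf$grad, dfake)
      gd <- mapply(function(a, b) a + b,
                   gr_r[names(gr_r) != "dx"], gr_f[names(gr_f) != "dx"],
                   SIMPLIFY = FALSE)
      st <- adam_step(gan_get(lyrs$disc),
                      gd[names(gan_get(lyrs$disc))], optD, lr = cfg$lr)
      optD <- st$state; lyrs$disc <- gan_set(lyrs$disc, st$params)
      # --- generator update (non-saturating + L1 anchor)
      dfake2 <- disc_forward(lyrs$disc, xhat)
      bg <- bce_logits(dfake2$logits, rep(1, N))
      l1 <- mean(abs(xhat - xb))
      g_loss <- bg$val + cfg$l1_weight * l1
      if (!is.finite(d_loss) || !is.finite(g_loss)) {
        cond <- structure(
          class = c("ramanclean_divergence", "ramanclean_error", "error", "condition"),
          list(message = "GAN training diverged (non-finite loss)",
               call = sys.call(), checkpoint = ckpt))
        stop(cond)
      }
      gdisc <- disc_backward(lyrs$disc, bg$grad, dfake2, need_dx = TRUE)
      dxhat <- gdisc$dx + cfg$l1_weight * sign(xhat - xb) / length(xhat)
      gg <- gen_backward(lyrs$gen, dxhat, gfw)
      st <- adam_step(gan_get(lyrs$gen), gg[names(gan_get(lyrs$gen))],
                      optG, lr = cfg$lr)
      optG <- st$state; lyrs$gen <- gan_set(lyrs$gen, st$params)
      dl_tot <- dl_tot + d_loss; gl_tot <- gl_tot + g_loss; nb <- nb + 1
    }
    curves[[ep]] <- data.frame(epoch = ep, d_loss = dl_tot / nb,
                               g_loss = gl_tot / nb)
    ckpt <- structure(list(gen = lyrs$gen, disc = lyrs$disc, cfg = cfg,
                           axis = pairs$axis,
                           curves = do.call(rbind, curves)),
                      class = "gan_checkpoint")
    if (verbose) message(sprintf("[gan] epoch %d D %.4f G %.4f", ep,
                                 dl_tot / nb, gl_tot / nb))
  }
  ckpt
}

#' @export
print.gan_checkpoint <- function(x, ...) {
  cat(sprintf("<gan_checkpoint> grid %d, width %d, %d epochs\n",
              x$cfg$grid_len, x$cfg$width, nrow(x$curves)))
  invisible(x)
}

#' Generate refined reference spectra from ideal spectra
#'
#' Each output pair is `(generator(y, z_k), y)`: labels pass through
#' unmodified. `n_per_ideal` latent draws are taken per conditioning ideal.
#'
#' @param ckpt a `gan_checkpoint` from [gan_train()].
#' @param ideals matrix of ideal spectra (rows) or a [pair_collection]
#'   (its `y` matrix is used).
#' @param n_per_ideal latent draws per ideal (default 1).
#' @param seed RNG seed for the latent draws.
#' @return a [pair_collection] with `meta$mode == "gan"`.
#' @export
gan_generate <- function(ckpt, ideals, n_per_ideal = 1, seed = 1) {
  Y <- if (inherits(ideals, "pair_collection")) ideals$y else as.matrix(ideals)
  axis <- if (inherits(ideals, "pair_collection")) ideals$axis
          else ckpt$axis %||% seq_len(ncol(Y))
  if (ncol(Y) != ckpt$cfg$grid_len)
    validation_error("ideal grid length does not match the checkpoint")
  set.seed(seed)
  L <- ckpt$cfg$grid_len
  n_out <- nrow(Y) * n_per_ideal
  X <- matrix(0, n_out, L); YY <- matrix(0, n_out, L)
  row <- 0
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]
    s <- max(abs(y), .Machine$double.eps)
    for (k in seq_len(n_per_ideal)) {
      z <- matrix(stats::rnorm(L), L, 1)
      g <- gen_forward(ckpt$gen, rbind(matrix(y / s, L, 1), z))
      row <- row + 1
      X[row, ] <- s * (y / s + g$out[, 1])
      YY[row, ] <- y
    }
  }
  pair_collection(axis, X, YY,
                  coeffs = data.frame(alpha = rep(NA_real_, n_out),
                                      beta = rep(NA_real_, n_out),
                                      snr_db = rep(NA_real_, n_out)),
                  meta = list(mode = "gan", seed = seed,
                              config_hash = config_hash(unclass(ckpt$cfg))))
}
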