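#' Preprocessing model configuration
#'
#' Architecture and training hyperparameters for the two-branch
#' denoising/baseline-correction network. The grid length must be divisible
#' by 16 (the Stem compresses features 4x and each of the two Reduction
#' stages a further 2x). `lambda` balances the reconstruction loss against
#' the background-estimation loss; 0.2 is the default operating point.
#'
#' @param grid_len spectral grid length L (divisible by 16).
#' @param channels base channel width c (Stem expands to 4c).
#' @param window,step sliding-window patch parameters (points).
#' @param lambda loss weight in `[0, 1]`.
#' @param huber_delta Huber threshold (default 1, on normalized intensities).
#' @param epochs_be background-estimation pretraining epochs.
#' @param epochs_full full-model training epochs.
#' @param lr Adam learning rate. @param batch minibatch size.
#' @param seed RNG seed for initialization and batching.
#' @param preset `"desk"` (laptop-scale) or `"full"`; presets fill the other
#'   arguments unless explicitly overridden.
#' @return list of class `model_config`.
#' @export
model_config <- function(grid_len = 1024, channels = NULL, window = 64,
                         step = 32, lambda = 0.2, huber_delta = 1,
                         epochs_be = NULL, epochs_full = NULL, lr = 1e-3,
                         batch = 32, seed = 1,
                         preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (is.null(channels)) channels <- if (preset == "desk") 4 else 8
  if (is.null(epochs_be)) epochs_be <- if (preset == "desk") 8 else 40
  if (is.null(epochs_full)) epochs_full <- if (preset == "desk") 16 else 80
  if (lambda < 0 || lambda > 1) validation_error("lambda must be in [0, 1]")
  if (grid_len %% 16 != 0)
    validation_error("grid_len must be divisible by 16 (Stem 1/4, two Reductions 1/2 each)")
  if (!(step >= 1 && step <= window && window <= grid_len))
    validation_error("need 1 <= step <= window <= grid_len")
  structure(list(grid_len = grid_len, channels = channels, window = window,
                 step = step, lambda = lambda, huber_delta = huber_delta,
                 epochs_be = epochs_be, epochs_full = epochs_full, lr = lr,
                 batch = batch, seed = seed, preset = preset),
            class = "model_config")
}

#' Split a spectrum into sliding-window patches
#'
#' Patch `i` (0-based) covers the half-open index interval
#' `[i*step, i*step + window)`. The signal is right-edge replicate-padded so
#' that `(L_pad - window)` is divisible by `step`.
#'
#' @param x numeric vector.
#' @param window,step window length and step in points.
#' @return matrix `n_patches x window`; attributes `orig_len`, `window`, `step`.
#' @export
make_patches <- function(x, window, step) {
  L <- length(x)
  if (window > L) validation_error("window longer than the spectrum")
  if (step < 1 || step > window) validation_error("need 1 <= step <= window")
  n_p <- ceiling((L - window) / step) + 1
  Lpad <- (n_p - 1) * step + window
  xp <- c(x, rep(x[L], Lpad - L))
  starts <- (seq_len(n_p) - 1) * step
  P <- matrix(xp[outer(starts, seq_len(window), `+`)], n_p, window)
  attr(P, "orig_len") <- L; attr(P, "window") <- window; attr(P, "step") <- step
  P
}

#' Inverse of [make_patches()] by overlap-averaging
#' @param P patch matrix from [make_patches()].
#' @param orig_len,window,step geometry (defaults from attributes of `P`).
#' @return numeric vector of length `orig_len`.
#' @export
assemble_patches <- function(P, orig_len = attr(P, "orig_len"),
                             window = attr(P, "window"),
                             step = attr(P, "step")) {
  n_p <- nrow(P)
  Lpad <- (n_p - 1) * step + window
  acc <- numeric(Lpad); cov <- numeric(Lpad)
  for (i in seq_len(n_p)) {
    sel <- ((i - 1) * step + 1):((i - 1) * step + window)
    acc[sel] <- acc[sel] + P[i, ]
    cov[sel] <- cov[sel] + 1
  }
  (acc / cov)[seq_len(orig_len)]
}

# ---- internal geometry helpers -------------------------------------------

patch_geometry <- function(L, window, step) {
  n_p <- ceiling((L - window) / step) + 1
  Lpad <- (n_p - 1) * step + window
  starts <- (seq_len(n_p) - 1) * step
  lpad <- as.vector(outer(seq_len(window), starts, `+`))   # (w fastest, p)
  src <- pmin(lpad, L)                                     # replicate pad
  cov <- tabulate(lpad, nbins = Lpad)
  list(n_p = n_p, Lpad = Lpad, src = src, lpad = lpad, cov = cov)
}

# Build all layers. Channel plan (c = base width): pre-encoders produce c
# channels; Stem c -> 4c at L/4; Reduction_A 4c -> 8c at L/8; Reduction_B
# 8c -> 16c at L/16; symmetric transposed-conv upsampling path back to L.
build_layers <- function(cfg) {
  L <- cfg$grid_len; c0 <- cfg$channels; w <- cfg$window
  ly <- list()
  # patches branch pre-encoder (runs on individual patches)
  ly$pe_p1 <- nn_conv(1, c0, 5, 1, w)
  ly$pe_p2 <- nn_conv(c0, c0, 5, 1, w)
  ly$pe_p3 <- nn_conv(c0, c0, 5, 1, w)
  # background-estimation U-net
  ly$be_e1 <- nn_conv(1, c0, 9, 1, L)
  ly$be_e2 <- nn_conv(c0, 2 * c0, 9, 2, L)
  ly$be_e3 <- nn_conv(2 * c0, 4 * c0, 9, 2, L / 2)
  ly$be_e4 <- nn_conv(4 * c0, 8 * c0, 9, 2, L / 4)
  ly$be_d3 <- nn_convt(8 * c0, 4 * c0, 9, 2, L / 8)
  ly$be_d2 <- nn_convt(4 * c0, 2 * c0, 9, 2, L / 4)
  ly$be_d1 <- nn_convt(2 * c0, c0, 9, 2, L / 2)
  ly$be_head <- nn_conv(c0, 1, 1, 1, L, zero_init = TRUE)
  # background pre-encoder
  ly$pe_b1 <- nn_conv(1, c0, 5, 1, L)
  ly$pe_b2 <- nn_conv(c0, c0, 5, 1, L)
  ly$pe_b3 <- nn_conv(c0, c0, 5, 1, L)
  # down-sampling stack
  ly$stem <- nn_conv(c0, 4 * c0, 9, 4, L)
  ly$iA1 <- nn_conv(4 * c0, 2 * c0, 1, 1, L / 4)
  ly$iA3 <- nn_conv(4 * c0, c0, 3, 1, L / 4)
  ly$iA5 <- nn_conv(4 * c0, c0, 5, 1, L / 4)
  ly$redA <- nn_conv(4 * c0, 8 * c0, 9, 2, L / 4)
  ly$iB1 <- nn_conv(8 * c0, 4 * c0, 1, 1, L / 8)
  ly$iB3 <- nn_conv(8 * c0, 2 * c0, 3, 1, L / 8)
  ly$iB5 <- nn_conv(8 * c0, 2 * c0, 5, 1, L / 8)
  ly$redB <- nn_conv(8 * c0, 16 * c0, 9, 2, L / 8)
  ly$iC1 <- nn_conv(16 * c0, 8 * c0, 1, 1, L / 16)
  ly$iC3 <- nn_conv(16 * c0, 4 * c0, 3, 1, L / 16)
  ly$iC5 <- nn_conv(16 * c0, 4 * c0, 5, 1, L / 16)
  # up-sampling stack
  ly$up1 <- nn_convt(16 * c0, 8 * c0, 9, 2, L / 16)
  ly$up1c <- nn_conv(8 * c0, 8 * c0, 5, 1, L / 8)
  ly$up2 <- nn_convt(8 * c0, 4 * c0, 9, 2, L / 8)
  ly$up2c <- nn_conv(4 * c0, 4 * c0, 5, 1, L / 4)
  ly$up3 <- nn_convt(4 * c0, c0, 9, 4, L / 4)
  ly$out_head <- nn_conv(c0, 1, 5, 1, L, zero_init = TRUE)
  ly
}

BE_LAYERS <- c("be_e1", "be_e2", "be_e3", "be_e4", "be_d3", "be_d2",
               "be_d1", "be_head")

get_params <- function(layers, which = names(layers)) {
  out <- list()
  for (nm in which) {
    out[[paste0(nm, ".W")]] <- layers[[nm]]$W
    out[[paste0(nm, ".b")]] <- layers[[nm]]$b
  }
  out
}

set_params <- function(layers, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    layers[[parts[1]]][[parts[2]]] <- params[[nm]]
  }
  layers
}

#' Create an untrained preprocessing model
#'
#' @param cfg a [model_config()].
#' @param axis wavenumber axis of the model grid (length `cfg$grid_len`);
#'   defaults to a 400-3200 cm^-1 linear grid.
#' @return list of class `trained_preprocessor` (untrained until
#'   [train_preprocessor()] is run).
#' @export
new_preprocessor <- function(cfg = model_config(), axis = NULL) {
  if (is.null(axis)) axis <- seq(400, 3200, length.out = cfg$grid_len)
  if (length(axis) != cfg$grid_len)
    validation_error("axis length must equal cfg$grid_len")
  set.seed(cfg$seed)
  structure(list(cfg = cfg, axis = as.numeric(axis),
                 layers = build_layers(cfg),
                 pgeo = patch_geometry(cfg$grid_len, cfg$window, cfg$step),
                 history = NULL, trained = FALSE,
                 normalization = "per-spectrum max of |x|"),
            class = "trained_preprocessor")
}

#' @export
print.trained_preprocessor <- function(x, ...) {
  np <- sum(vapply(get_params(x$layers), length, integer(1)))
  cat(sprintf("<trained_preprocessor> grid %d, base width %d, %s; %d parameters; %s\n",
              x$cfg$grid_len, x$cfg$channels, x$cfg$preset, np,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- forward / backward ---------------------------------------------------

# Background-estimation branch. x: (L, N) single-channel matrix.
be_forward <- function(model, x) {
  ly <- model$layers
  cc <- list()
  cc$e1 <- conv_fwd(ly$be_e1, x);  a1 <- relu_fwd(cc$e1$out)
  cc$e2 <- conv_fwd(ly$be_e2, a1); a2 <- relu_fwd(cc$e2$out)
  cc$e3 <- conv_fwd(ly$be_e3, a2); a3 <- relu_fwd(cc$e3$out)
  cc$e4 <- conv_fwd(ly$be_e4, a3); a4 <- relu_fwd(cc$e4$out)
  cc$d3 <- convt_fwd(ly$be_d3, a4); h3 <- relu_fwd(cc$d3$out + a3)
  cc$d2 <- convt_fwd(ly$be_d2, h3); h2 <- relu_fwd(cc$d2$out + a2)
  cc$d1 <- convt_fwd(ly$be_d1, h2); h1 <- relu_fwd(cc$d1$out + a1)
  cc$head <- conv_fwd(ly$be_head, h1)
  list(B = cc$head$out, cache = c(cc, list(a1 = a1, a2 = a2, a3 = a3, a4 = a4,
                                           h3 = h3, h2 = h2, h1 = h1)))
}

be_backward <- function(model, dB, fw, grads) {
  ly <- model$layers; cc <- fw$cache
  g <- conv_bwd(ly$be_head, dB, cc$head$Xc)
  grads$be_head.W <- grads$be_head.W + g$dW; grads$be_head.b <- grads$be_head.b + g$db
  dh1 <- relu_bwd(g$dx, cc$h1)
  g <- convt_bwd(ly$be_d1, dh1, cc$d1$Umat)
  grads$be_d1.W <- grads$be_d1.W + g$dW; grads$be_d1.b <- grads$be_d1.b + g$db
  da1 <- dh1                                    # skip connection
  dh2 <- relu_bwd(g$dx, cc$h2)
  g <- convt_bwd(ly$be_d2, dh2, cc$d2$Umat)
  grads$be_d2.W <- grads$be_d2.W + g$dW; grads$be_d2.b <- grads$be_d2.b + g$db
  da2 <- dh2
  dh3 <- relu_bwd(g$dx, cc$h3)
  g <- convt_bwd(ly$be_d3, dh3, cc$d3$Umat)
  grads$be_d3.W <- grads$be_d3.W + g$dW; grads$be_d3.b <- grads$be_d3.b + g$db
  da3 <- dh3
  da4 <- relu_bwd(g$dx, cc$a4)
  g <- conv_bwd(ly$be_e4, da4, cc$e4$Xc)
  grads$be_e4.W <- grads$be_e4.W + g$dW; grads$be_e4.b <- grads$be_e4.b + g$db
  da3 <- da3 + g$dx
  da3 <- relu_bwd(da3, cc$a3)
  g <- conv_bwd(ly$be_e3, da3, cc$e3$Xc)
  grads$be_e3.W <- grads$be_e3.W + g$dW; grads$be_e3.b <- grads$be_e3.b + g$db
  da2 <- relu_bwd(da2 + g$dx, cc$a2)
  g <- conv_bwd(ly$be_e2, da2, cc$e2$Xc)
  grads$be_e2.W <- grads$be_e2.W + g$dW; grads$be_e2.b <- grads$be_e2.b + g$db
  da1 <- relu_bwd(da1 + g$dx, cc$a1)
  g <- conv_bwd(ly$be_e1, da1, cc$e1$Xc, need_dx = FALSE)
  grads$be_e1.W <- grads$be_e1.W + g$dW; grads$be_e1.b <- grads$be_e1.b + g$db
  grads
}

# Full model. x: (L, N). Returns P, B, caches.
full_forward <- function(model, x) {
  ly <- model$layers; pg <- model$pgeo
  L <- model$cfg$grid_len; c0 <- model$cfg$channels
  N <- ncol(x)
  # patches branch
  xp <- x[pg$src, , drop = FALSE]                    # (w*n_p, N)
  dim(xp) <- c(model$cfg$window, pg$n_p * N)
  cp1 <- conv_fwd(ly$pe_p1, xp); r1 <- relu_fwd(cp1$out)
  cp2 <- conv_fwd(ly$pe_p2, r1); r2 <- relu_fwd(cp2$out)
  cp3 <- conv_fwd(ly$pe_p3, r2)
  Fp <- patch_assemble_fwd(cp3$out, pg, model$cfg$window, c0, N, L)
  # background branch
  be <- be_forward(model, x)
  cb1 <- conv_fwd(ly$pe_b1, be$B); q1 <- relu_fwd(cb1$out)
  cb2 <- conv_fwd(ly$pe_b2, q1); q2 <- relu_fwd(cb2$out)
  cb3 <- conv_fwd(ly$pe_b3, q2)
  FF <- Fp - cb3$out
  # down-sampling
  cst <- conv_fwd(ly$stem, FF); st <- relu_fwd(cst$out)
  cA1 <- conv_fwd(ly$iA1, st); cA3 <- conv_fwd(ly$iA3, st); cA5 <- conv_fwd(ly$iA5, st)
  A <- relu_fwd(rbind(cA1$out, cA3$out, cA5$out) + st)
  crA <- conv_fwd(ly$redA, A); rA <- relu_fwd(crA$out)
  cB1 <- conv_fwd(ly$iB1, rA); cB3 <- conv_fwd(ly$iB3, rA); cB5 <- conv_fwd(ly$iB5, rA)
  Bm <- relu_fwd(rbind(cB1$out, cB3$out, cB5$out) + rA)
  crB <- conv_fwd(ly$redB, Bm); rB <- relu_fwd(crB$out)
  cC1 <- conv_fwd(ly$iC1, rB); cC3 <- conv_fwd(ly$iC3, rB); cC5 <- conv_fwd(ly$iC5, rB)
  Cm <- relu_fwd(rbind(cC1$out, cC3$out, cC5$out) + rB)
  # up-sampling
  cu1 <- convt_fwd(ly$up1, Cm); g1 <- relu_fwd(cu1$out + Bm)
  cu1c <- conv_fwd(ly$up1c, g1); v1 <- relu_fwd(cu1c$out)
  cu2 <- convt_fwd(ly$up2, v1); g2 <- relu_fwd(cu2$out + A)
  cu2c <- conv_fwd(ly$up2c, g2); v2 <- relu_fwd(cu2c$out)
  cu3 <- convt_fwd(ly$up3, v2); g3 <- relu_fwd(cu3$out + FF)
  chead <- conv_fwd(ly$out_head, g3)
  P <- chead$out + x - be$B                           # global residual
  if (any(!is.finite(P)))
    stop_rc("non-finite activations in forward pass", "ramanclean_divergence")
  list(P = P, B = be$B, be = be,
       cache = list(xp = xp, cp1 = cp1, r1 = r1, cp2 = cp2, r2 = r2, cp3 = cp3,
                    Fp = Fp, cb1 = cb1, q1 = q1, cb2 = cb2, q2 = q2, cb3 = cb3,
                    FF = FF, cst = cst, st = st, cA1 = cA1, cA3 = cA3, cA5 = cA5,
                    A = A, crA = crA, rA = rA, cB1 = cB1, cB3 = cB3, cB5 = cB5,
                    Bm = Bm, crB = crB, rB = rB, cC1 = cC1, cC3 = cC3, cC5 = cC5,
                    Cm = Cm, cu1 = cu1, g1 = g1, cu1c = cu1c, v1 = v1,
                    cu2 = cu2, g2 = g2, cu2c = cu2c, v2 = v2, cu3 = cu3,
                    g3 = g3, chead = chead))
}

patch_assemble_fwd <- function(pmat, pg, window, c0, N, L) {
  # pmat: (window*c0, n_p*N) -> overlap-average feature map (L*c0, N)
  dim(pmat) <- c(window * c0 * pg$n_p, N)
  grp <- patch_groups(pg, window, c0)
  acc <- rowsum(pmat, grp$g)
  full <- matrix(0, pg$Lpad * c0, N)
  full[grp$u, ] <- acc
  full <- full / grp$cov_full
  full[grp$crop, , drop = FALSE]
}

patch_assemble_bwd <- function(dout, pg, window, c0, N) {
  grp <- patch_groups(pg, window, c0)
  dfull <- matrix(0, pg$Lpad * c0, N)
  dfull[grp$crop, ] <- dout
  dfull <- dfull / grp$cov_full
  dp <- dfull[grp$g, , drop = FALSE]
  dim(dp) <- c(window * c0, pg$n_p * N)
  dp
}

# cached geometry for the in-network patch assembly
patch_groups <- function(pg, window, c0) {
  key <- paste0(".grp_", window, "_", c0)
  if (!is.null(pg_cache[[key]])) return(pg_cache[[key]])
  L <- length(pg$cov) - (pg$Lpad - length(pg$cov))  # Lpad == length(cov)
  wcp <- expand_wcp(pg, window, c0)
  u <- sort(unique(wcp))
  cov_full <- rep(pg$cov, times = c0)
  orig_len <- pg$Lpad - (pg$Lpad - max(pg$src))      # = max(src) = L
  crop <- as.vector(outer(seq_len(orig_len), (seq_len(c0) - 1) * pg$Lpad, `+`))
  val <- list(g = wcp, u = u, cov_full = cov_full, crop = crop)
  pg_cache[[key]] <- val
  val
}

pg_cache <- new.env(parent = emptyenv())

expand_wcp <- function(pg, window, c0) {
  # group index for element (w, c, p): lpad(w, p) + (c-1)*Lpad
  lp <- matrix(pg$lpad, window, pg$n_p)              # (w, p)
  g <- array(0L, c(window, c0, pg$n_p))
  for (ch in seq_len(c0)) g[, ch, ] <- lp + (ch - 1L) * pg$Lpad
  as.vector(g)
}

full_backward <- function(model, dP, dB_loss, fw) {
  ly <- model$layers; cc <- fw$cache; pg <- model$pgeo
  c0 <- model$cfg$channels; N <- ncol(dP)
  grads <- lapply(get_params(ly), function(p) p * 0)
  # head and global residual
  g <- conv_bwd(ly$out_head, dP, cc$chead$Xc)
  grads$out_head.W <- g$dW; grads$out_head.b <- g$db
  dB <- dB_loss - dP                                  # residual: P = head + x - B
  dg3 <- relu_bwd(g$dx, cc$g3)
  dFF_skip <- dg3
  g <- convt_bwd(ly$up3, dg3, cc$cu3$Umat)
  grads$up3.W <- g$dW; grads$up3.b <- g$db
  dv2 <- relu_bwd(g$dx, cc$v2)
  g <- conv_bwd(ly$up2c, dv2, cc$cu2c$Xc)
  grads$up2c.W <- g$dW; grads$up2c.b <- g$db
  dg2 <- relu_bwd(g$dx, cc$g2)
  dA_skip <- dg2
  g <- convt_bwd(ly$up2, dg2, cc$cu2$Umat)
  grads$up2.W <- g$dW; grads$up2.b <- g$db
  dv1 <- relu_bwd(g$dx, cc$v1)
  g <- conv_bwd(ly$up1c, dv1, cc$cu1c$Xc)
  grads$up1c.W <- g$dW; grads$up1c.b <- g$db
  dg1 <- relu_bwd(g$dx, cc$g1)
  dBm_skip <- dg1
  g <- convt_bwd(ly$up1, dg1, cc$cu1$Umat)
  grads$up1.W <- g$dW; grads$up1.b <- g$db
  # inception C
  dCm <- relu_bwd(g$dx, cc$Cm)
  LC <- ly$iC1$Lout
  d1 <- dCm[seq_len(LC * 8 * c0), , drop = FALSE]
  d3 <- dCm[LC * 8 * c0 + seq_len(LC * 4 * c0), , drop = FALSE]
  d5 <- dCm[LC * 12 * c0 + seq_len(LC * 4 * c0), , drop = FALSE]
  g1_ <- conv_bwd(ly$iC1, d1, cc$cC1$Xc); g3_ <- conv_bwd(ly$iC3, d3, cc$cC3$Xc)
  g5_ <- conv_bwd(ly$iC5, d5, cc$cC5$Xc)
  grads$iC1.W <- g1_$dW; grads$iC1.b <- g1_$db
  grads$iC3.W <- g3_$dW; grads$iC3.b <- g3_$db
  grads$iC5.W <- g5_$dW; grads$iC5.b <- g5_$db
  drB <- relu_bwd(g1_$dx + g3_$dx + g5_$dx + dCm, cc$rB)
  g <- conv_bwd(ly$redB, drB, cc$crB$Xc)
  grads$redB.W <- g$dW; grads$redB.b <- g$db
  # inception B
  dBm <- relu_bwd(g$dx + dBm_skip, cc$Bm)
  LB <- ly$iB1$Lout
  d1 <- dBm[seq_len(LB * 4 * c0), , drop = FALSE]
  d3 <- dBm[LB * 4 * c0 + seq_len(LB * 2 * c0), , drop = FALSE]
  d5 <- dBm[LB * 6 * c0 + seq_len(LB * 2 * c0), , drop = FALSE]
  g1_ <- conv_bwd(ly$iB1, d1, cc$cB1$Xc); g3_ <- conv_bwd(ly$iB3, d3, cc$cB3$Xc)
  g5_ <- conv_bwd(ly$iB5, d5, cc$cB5$Xc)
  grads$iB1.W <- g1_$dW; grads$iB1.b <- g1_$db
  grads$iB3.W <- g3_$dW; grads$iB3.b <- g3_$db
  grads$iB5.W <- g5_$dW; grads$iB5.b <- g5_$db
  drA <- relu_bwd(g1_$dx + g3_$dx + g5_$dx + dBm, cc$rA)
  g <- conv_bwd(ly$redA, drA, cc$crA$Xc)
  grads$redA.W <- g$dW; grads$redA.b <- g$db
  # inception A
  dA <- relu_bwd(g$dx + dA_skip, cc$A)
  LA <- ly$iA1$Lout
  d1 <- dA[seq_len(LA * 2 * c0), , drop = FALSE]
  d3 <- dA[LA * 2 * c0 + seq_len(LA * c0), , drop = FALSE]
  d5 <- dA[LA * 3 * c0 + seq_len(LA * c0), , drop = FALSE]
  g1_ <- conv_bwd(ly$iA1, d1, cc$cA1$Xc); g3_ <- conv_bwd(ly$iA3, d3, cc$cA3$Xc)
  g5_ <- conv_bwd(ly$iA5, d5, cc$cA5$Xc)
  grads$iA1.W <- g1_$dW; grads$iA1.b <- g1_$db
  grads$iA3.W <- g3_$dW; grads$iA3.b <- g3_$db
  grads$iA5.W <- g5_$dW; grads$iA5.b <- g5_$db
  dst <- relu_bwd(g1_$dx + g3_$dx + g5_$dx + dA, cc$st)
  g <- conv_bwd(ly$stem, dst, cc$cst$Xc)
  grads$stem.W <- g$dW; grads$stem.b <- g$db
  dFF <- g$dx + dFF_skip
  # background pre-encoder
  dFb <- -dFF
  g <- conv_bwd(ly$pe_b3, dFb, cc$cb3$Xc)
  grads$pe_b3.W <- g$dW; grads$pe_b3.b <- g$db
  dq2 <- relu_bwd(g$dx, cc$q2)
  g <- conv_bwd(ly$pe_b2, dq2, cc$cb2$Xc)
  grads$pe_b2.W <- g$dW; grads$pe_b2.b <- g$db
  dq1 <- relu_bwd(g$dx, cc$q1)
  g <- conv_bwd(ly$pe_b1, dq1, cc$cb1$Xc)
  grads$pe_b1.W <- g$dW; grads$pe_b1.b <- g$db
  dB <- dB + g$dx
  # BE branch (accumulates head/residual/pre-encoder contributions)
  grads <- be_backward(model, dB, fw$be, grads)
  # patches branch
  dFp <- dFF
  dp3 <- patch_assemble_bwd(dFp, pg, model$cfg$window, c0, N)
  g <- conv_bwd(ly$pe_p3, dp3, cc$cp3$Xc)
  grads$pe_p3.W <- g$dW; grads$pe_p3.b <- g$db
  dr2 <- relu_bwd(g$dx, cc$r2)
  g <- conv_bwd(ly$pe_p2, dr2, cc$cp2$Xc)
  grads$pe_p2.W <- g$dW; grads$pe_p2.b <- g$db
  dr1 <- relu_bwd(g$dx, cc$r1)
  g <- conv_bwd(ly$pe_p1, dr1, cc$cp1$Xc, need_dx = FALSE)
  grads$pe_p1.W <- g$dW; grads$pe_p1.b <- g$db
  grads
}

# ---- losses ---------------------------------------------------------------

#' Background-estimation loss
#'
#' Mean Huber penalty (threshold `delta`) on the residual
#' `B(x) - (x - y)`: the background branch should reproduce the noise plus
#' baseline contained in the reference spectrum.
#'
#' @param x reference spectrum (vector). @param y ideal spectrum.
#' @param bx background-branch output `B(x)`.
#' @param delta Huber threshold (default 1).
#' @return nonnegative scalar.
#' @export
loss_background <- function(x, y, bx, delta = 1) {
  if (length(x) != length(y) || length(x) != length(bx))
    validation_error("length mismatch")
  huber_val(bx - (x - y), delta)
}

#' Combined training loss
#'
#' `lambda * mean(Huber(P(x) - y)) + (1 - lambda) * L_BE(x, y, B(x))`.
#' `lambda = 1` reduces to the pure reconstruction Huber loss, `lambda = 0`
#' to the pure background-estimation loss.
#'
#' @param x,y reference and ideal spectra. @param bx,px branch outputs.
#' @param lambda weight in `[0, 1]` (default 0.2).
#' @param delta Huber threshold (default 1).
#' @return nonnegative scalar.
#' @export
loss_total <- function(x, y, bx, px, lambda = 0.2, delta = 1) {
  if (lambda < 0 || lambda > 1) validation_error("lambda must be in [0, 1]")
  lambda * huber_val(px - y, delta) + (1 - lambda) * loss_background(x, y, bx, delta)
}

# ---- training -------------------------------------------------------------

#' Train the preprocessing model on labelled pairs
#'
#' Two-step schedule: the background-estimation branch is first pretrained
#' alone with [loss_background()] for `cfg$epochs_be` epochs; the full model
#' is then trained with [loss_total()] (weight `cfg$lambda`) for
#' `cfg$epochs_full` epochs, using Adam. Inputs are normalized per spectrum
#' by the maximum absolute intensity of `x` (labels share the scale), and
#' the inverse scale is applied at inference. Deterministic for a fixed
#' `cfg$seed` when run single-threaded.
#'
#' @param pairs a [pair_collection] on grid `cfg$grid_len`.
#' @param cfg a [model_config()].
#' @param verbose print per-epoch losses.
#' @return a `trained_preprocessor` with a `history` data.frame
#'   (phase, epoch, loss).
#' @export
train_preprocessor <- function(pairs, cfg = model_config(), verbose = FALSE) {
  if (ncol(pairs$x) != cfg$grid_len)
    validation_error("pair grid length does not match cfg$grid_len")
  n <- nrow(pairs$x)
  if (n < 2 * cfg$batch)
    validation_error("need at least 2*batch training pairs")
  model <- new_preprocessor(cfg, axis = pairs$axis)
  scale <- pmax(apply(abs(pairs$x), 1, max), .Machine$double.eps)
  Xn <- t(pairs$x / scale)                      # (L, n)
  Yn <- t(pairs$y / scale)
  Tbe <- Xn - Yn
  hist <- list()
  # phase 1: background-estimation branch
  be_params <- get_params(model$layers, BE_LAYERS)
  opt <- adam_init(be_params)
  for (ep in seq_len(cfg$epochs_be)) {
    ord <- sample.int(n)
    tot <- 0; nb <- 0
    for (b0 in seq(1, n - cfg$batch + 1, by = cfg$batch)) {
      sel <- ord[b0:(b0 + cfg$batch - 1)]
      fw <- be_forward(model, Xn[, sel, drop = FALSE])
      r <- fw$B - Tbe[, sel, drop = FALSE]
      loss <- huber_val(r, cfg$huber_delta)
      if (!is.finite(loss)) stop_rc("training diverged (non-finite loss)",
                                    "ramanclean_divergence")
      grads <- lapply(be_params, function(p) p * 0)
      grads <- be_backward(model, huber_grad(r, cfg$huber_delta), fw, grads)
      st <- adam_step(get_params(model$layers, BE_LAYERS), grads[names(be_params)],
                      opt, lr = cfg$lr)
      opt <- st$state
      model$layers <- set_params(model$layers, st$params)
      tot <- tot + loss; nb <- nb + 1
    }
    hist[[length(hist) + 1]] <- data.frame(phase = "background", epoch = ep,
                                           loss = tot / nb)
    if (verbose) message(sprintf("[be] epoch %d loss %.6f", ep, tot / nb))
  }
  # phase 2: full model
  all_params <- get_params(model$layers)
  opt <- adam_init(all_params)
  for (ep in seq_len(cfg$epochs_full)) {
    ord <- sample.int(n)
    tot <- 0; nb <- 0
    for (b0 in seq(1, n - cfg$batch + 1, by = cfg$batch)) {
      sel <- ord[b0:(b0 + cfg$batch - 1)]
      xb <- Xn[, sel, drop = FALSE]; yb <- Yn[, sel, drop = FALSE]
      fw <- full_forward(model, xb)
      rz <- fw$P - yb
      rb <- fw$B - (xb - yb)
      loss <- cfg$lambda * huber_val(rz, cfg$huber_delta) +
        (1 - cfg$lambda) * huber_val(rb, cfg$huber_delta)
      if (!is.finite(loss)) stop_rc("training diverged (non-finite loss)",
                                    "ramanclean_divergence")
      dP <- cfg$lambda * huber_grad(rz, cfg$huber_delta)
      dBl <- (1 - cfg$lambda) * huber_grad(rb, cfg$huber_delta)
      grads <- full_backward(model, dP, dBl, fw)
      st <- adam_step(get_params(model$layers), grads, opt, lr = cfg$lr)
      opt <- st$state
      model$layers <- set_params(model$layers, st$params)
      tot <- tot + loss; nb <- nb + 1
    }
    hist[[length(hist) + 1]] <- data.frame(phase = "full", epoch = ep,
                                           loss = tot / nb)
    if (verbose) message(sprintf("[full] epoch %d loss %.6f", ep, tot / nb))
  }
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

# ---- inference ------------------------------------------------------------

#' Run the full model on grid-aligned spectra
#'
#' Low-level inference on vectors/matrices already on the model grid, with
#' per-spectrum max normalization applied and inverted internally.
#'
#' @param x numeric vector of length `grid_len`, or a matrix with one
#'   spectrum per row.
#' @param model a `trained_preprocessor`.
#' @return same shape as `x`: the preprocessed spectra `P(x)`.
#' @export
forward_preprocess <- function(x, model) {
  one <- is.null(dim(x))
  X <- if (one) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != model$cfg$grid_len) validation_error("grid length mismatch")
  scale <- pmax(apply(abs(X), 1, max), .Machine$double.eps)
  out <- matrix(0, nrow(X), ncol(X))
  bs <- max(model$cfg$batch, 1)
  for (b0 in seq(1, nrow(X), by = bs)) {
    sel <- b0:min(b0 + bs - 1, nrow(X))
    fw <- full_forward(model, t(X[sel, , drop = FALSE] / scale[sel]))
    out[sel, ] <- t(fw$P) * scale[sel]
  }
  if (one) drop(out) else out
}

#' Background-estimation branch output
#'
#' @param x grid-aligned vector or matrix (rows = spectra).
#' @param model a `trained_preprocessor`.
#' @return `B(x)` in the input's shape and scale.
#' @export
estimate_background <- function(x, model) {
  one <- is.null(dim(x))
  X <- if (one) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != model$cfg$grid_len) validation_error("grid length mismatch")
  scale <- pmax(apply(abs(X), 1, max), .Machine$double.eps)
  fw <- be_forward(model, t(X / scale))
  out <- t(fw$B) * scale
  if (one) drop(out) else out
}

#' Preprocess a spectrum with a trained model
#'
#' The spectrum is resampled onto the model grid, preprocessed, and mapped
#' back onto its native axis, so the output axis equals the input axis.
#' Because of the per-spectrum max normalization, preprocessing is exactly
#' scale-equivariant: `preprocess(c * x) == c * preprocess(x)` for `c > 0`.
#'
#' @param s a [spectrum]. @param model a `trained_preprocessor`.
#' @return the preprocessed [spectrum].
#' @export
preprocess <- function(s, model) {
  stopifnot(inherits(s, "spectrum"), inherits(model, "trained_preprocessor"))
  rg <- range(model$axis)
  rs <- resample_to_grid(s, model$cfg$grid_len, rg)
  p <- forward_preprocess(rs$intensity, model)
  back <- stats::approx(model$axis, p, xout = s$axis, rule = 2)$y
  meta <- s$meta
  meta$model_hash <- config_hash(unclass(model$cfg))
  meta$norm_scale <- max(abs(rs$intensity))
  spectrum(s$axis, back, meta = meta)
}

#' Stage shape trace of the down/up-sampling stack
#'
#' Returns the (channels, features) dimensions after every named stage,
#' computed from the layer geometry.
#'
#' @param model a `trained_preprocessor` (or [model_config()]).
#' @return data.frame with columns `stage`, `channels`, `features`.
#' @export
stage_shapes <- function(model) {
  cfg <- if (inherits(model, "model_config")) model else model$cfg
  L <- cfg$grid_len; c0 <- cfg$channels
  data.frame(
    stage = c("input", "stem", "inception_a", "reduction_a", "inception_b",
              "reduction_b", "inception_c", "up1", "up2", "up3", "output"),
    channels = c(c0, 4 * c0, 4 * c0, 8 * c0, 8 * c0, 16 * c0, 16 * c0,
                 8 * c0, 4 * c0, c0, 1),
    features = c(L, L / 4, L / 4, L / 8, L / 8, L / 16, L / 16,
                 L / 8, L / 4, L, L))
}

#' Save / load a trained preprocessor
#' @param model a `trained_preprocessor`. @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_preprocessor <- function(model, path) {
  saveRDS(list(format = "ramanclean_preprocessor", version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname save_preprocessor
#' @export
load_preprocessor <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ramanclean_preprocessor"))
    parse_error("not a saved preprocessor")
  obj$model
}
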