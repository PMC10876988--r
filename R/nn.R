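# Minimal 1D convolutional network engine.
#
# Feature maps are stored as (L*C, N) matrices, column-major with position
# fastest within channel: row (l, c) = l + (c-1)*L, one column per sample.
# Convolutions are evaluated as im2col gathers followed by BLAS GEMM; the
# backward pass mirrors them with col2im scatter-adds via rowsum(). All layer
# geometry (gather indices, scatter groups) is precomputed at build time, so
# a layer is reusable across batches of any size. Gradients are verified
# against central finite differences in the test suite.

nn_conv <- function(Cin, Cout, K, stride, Lin, zero_init = FALSE, scale = NULL) {
  stopifnot(K %% 2 == 1)
  pad <- (K - 1) %/% 2
  Lpad <- Lin + 2 * pad
  Lout <- (Lpad - K) %/% stride + 1
  cc <- rep(seq_len(Cin), times = K * Lout)
  kk <- rep(rep(seq_len(K), each = Cin), times = Lout)
  tt <- rep(seq_len(Lout), each = Cin * K)
  idx <- ((tt - 1) * stride + kk) + (cc - 1) * Lpad
  rows_idx <- as.vector(outer(pad + seq_len(Lin), (seq_len(Cin) - 1) * Lpad, `+`))
  grp <- sort(unique(idx))
  if (is.null(scale)) scale <- sqrt(2 / (Cin * K))
  W <- if (zero_init) matrix(0, Cout, Cin * K)
       else matrix(stats::rnorm(Cout * Cin * K, sd = scale), Cout, Cin * K)
  list(type = "conv", Cin = Cin, Cout = Cout, K = K, stride = stride,
       Lin = Lin, Lout = Lout, Lpad = Lpad, idx = idx, rows_idx = rows_idx,
       grp = grp, W = W, b = numeric(Cout))
}

conv_fwd <- function(ly, x) {
  N <- ncol(x)
  Xpad <- matrix(0, ly$Lpad * ly$Cin, N)
  Xpad[ly$rows_idx, ] <- x
  Xc <- Xpad[ly$idx, , drop = FALSE]
  dim(Xc) <- c(ly$Cin * ly$K, ly$Lout * N)
  Y <- ly$W %*% Xc + ly$b
  out <- aperm(array(Y, c(ly$Cout, ly$Lout, N)), c(2, 1, 3))
  dim(out) <- c(ly$Lout * ly$Cout, N)
  list(out = out, Xc = Xc)
}

conv_bwd <- function(ly, dout, Xc, need_dx = TRUE) {
  N <- ncol(dout)
  dY <- aperm(array(dout, c(ly$Lout, ly$Cout, N)), c(2, 1, 3))
  dim(dY) <- c(ly$Cout, ly$Lout * N)
  dW <- tcrossprod(dY, Xc)
  db <- rowSums(dY)
  dx <- NULL
  if (need_dx) {
    dXc <- crossprod(ly$W, dY)
    dim(dXc) <- c(ly$Cin * ly$K * ly$Lout, N)
    acc <- rowsum(dXc, ly$idx)
    dXpad <- matrix(0, ly$Lpad * ly$Cin, N)
    dXpad[ly$grp, ] <- acc
    dx <- dXpad[ly$rows_idx, , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# Transposed convolution mapping length Lin -> stride*Lin, Cin -> Cout
# channels; implemented as the adjoint of an nn_conv with swapped channel
# roles (weights shape (Cout_adj = Cin here) x (Cin_adj = Cout here)*K).
nn_convt <- function(Cin, Cout, K, stride, Lin, zero_init = FALSE) {
  Lout <- stride * Lin
  adj <- nn_conv(Cout, Cin, K, stride, Lout, zero_init = zero_init,
                 scale = sqrt(2 / (Cin * K)))
  stopifnot(adj$Lout == Lin)
  list(type = "convt", Cin = Cin, Cout = Cout, K = K, stride = stride,
       Lin = Lin, Lout = Lout, adj = adj, W = adj$W, b = numeric(Cout))
}

convt_fwd <- function(ly, u) {
  N <- ncol(u)
  a <- ly$adj
  Umat <- aperm(array(u, c(ly$Lin, ly$Cin, N)), c(2, 1, 3))
  dim(Umat) <- c(ly$Cin, ly$Lin * N)
  Xc <- crossprod(ly$W, Umat)              # (Cout*K, Lin*N)
  dim(Xc) <- c(ly$Cout * ly$K * ly$Lin, N)
  acc <- rowsum(Xc, a$idx)
  Vpad <- matrix(0, a$Lpad * ly$Cout, N)
  Vpad[a$grp, ] <- acc
  v <- Vpad[a$rows_idx, , drop = FALSE]
  v <- v + rep(ly$b, each = ly$Lout)
  list(out = v, Umat = Umat)
}

convt_bwd <- function(ly, dv, Umat, need_dx = TRUE) {
  N <- ncol(dv)
  a <- ly$adj
  dVpad <- matrix(0, a$Lpad * ly$Cout, N)
  dVpad[a$rows_idx, ] <- dv
  dXc <- dVpad[a$idx, , drop = FALSE]      # im2col of dv
  dim(dXc) <- c(ly$Cout * ly$K, ly$Lin * N)
  dW <- tcrossprod(Umat, dXc)
  dv3 <- aperm(array(dv, c(ly$Lout, ly$Cout, N)), c(2, 1, 3))
  dim(dv3) <- c(ly$Cout, ly$Lout * N)
  db <- rowSums(dv3)
  dx <- NULL
  if (need_dx) {
    dUmat <- ly$W %*% dXc                  # (Cin, Lin*N)
    dx <- aperm(array(dUmat, c(ly$Cin, ly$Lin, N)), c(2, 1, 3))
    dim(dx) <- c(ly$Lin * ly$Cin, N)
  }
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) x * (x > 0)
relu_bwd <- function(dout, x) dout * (x > 0)

lrelu_fwd <- function(x, a = 0.2) ifelse(x > 0, x, a * x)
lrelu_bwd <- function(dout, x, a = 0.2) dout * ifelse(x > 0, 1, a)

# Huber loss (delta = 1 unless stated): mean over all elements.
huber_val <- function(r, delta = 1) {
  a <- abs(r)
  mean(ifelse(a < delta, 0.5 * r^2, delta * (a - 0.5 * delta)))
}
huber_grad <- function(r, delta = 1) {
  g <- ifelse(abs(r) < delta, r, delta * sign(r))
  g / length(r)
}

# Adam optimizer state over a flat named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
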