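# Periodized orthogonal discrete wavelet transform.
#
# Implemented in-package: the decomposition/recombination scheme needs direct
# access to per-level detail bands, and the transform must be exactly
# invertible so that the signal/baseline/noise partition identity holds.
# Periodization (circular convolution) keeps the filter-bank matrix orthogonal
# at every level, including deep levels where the filter wraps around.

# Daubechies-8 (16-tap, 8 vanishing moments) decomposition low-pass filter.
DB8_DEC_LO <- c(
  -0.00011747678412476953, 0.0006754494064505693, -0.00039174037337694705,
  -0.004870352993451574, 0.008746094047405777, 0.013981027917398282,
  -0.044088253930794755, -0.017369301001807547, 0.12874742662047847,
  0.0004724845739132828, -0.2840155429615469, -0.015829105256349306,
  0.5853546836542067, 0.6756307362972898, 0.31287159091429995,
  0.05441584224310401)

wavelet_filters <- function(family = "db8") {
  if (!identical(family, "db8"))
    validation_error("only the Daubechies-8 ('db8') family is provided")
  h <- DB8_DEC_LO
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)  # QMF high-pass
  list(lo = h, hi = g, len = L)
}

# One analysis step: x (even length N) -> list(a, d) of length N/2.
dwt_step <- function(x, f) {
  N <- length(x)
  half <- N %/% 2
  # index matrix: row k (output position), col m (tap), circular
  idx <- (outer(2 * (seq_len(half) - 1), seq_len(f$len) - 1, `+`) %% N) + 1
  xm <- matrix(x[idx], half, f$len)
  list(a = drop(xm %*% f$lo), d = drop(xm %*% f$hi))
}

# One synthesis step (transpose of the orthogonal analysis step).
idwt_step <- function(a, d, f) {
  half <- length(a)
  N <- 2 * half
  x <- numeric(N)
  pos <- (outer(2 * (seq_len(half) - 1), seq_len(f$len) - 1, `+`) %% N) + 1
  contrib <- outer(a, f$lo) + outer(d, f$hi)
  # scatter-add contributions back onto the circle
  acc <- rowsum(as.vector(contrib), as.vector(pos))
  x[as.integer(rownames(acc))] <- acc
  x
}

# Analysis/synthesis on an already-periodic signal (length divisible by
# 2^levels); no extension, so band selection is an orthogonal projection.
dwt_core <- function(xp, levels, f) {
  d <- vector("list", levels)
  a <- xp
  for (j in seq_len(levels)) {
    s <- dwt_step(a, f)
    d[[j]] <- s$d
    a <- s$a
  }
  list(d = d, a = a, levels = levels)
}

idwt_core <- function(w, f) {
  a <- w$a
  for (j in rev(seq_len(w$levels))) a <- idwt_step(a, w$d[[j]], f)
  a
}

# Smooth periodic extension: append a C^1 cubic Hermite bridge running from
# the signal's right end back to its left end (slopes matched to the end
# differences). The periodized extension is then continuous with continuous
# first derivative at both joints, so smooth non-periodic trends do not leak
# into fine detail bands at the wrap point. Extended length is a multiple of
# 2^levels, at least 2n.
dwt_extend <- function(x, levels) {
  n <- length(x)
  block <- 2^levels
  pad_len <- ceiling(2 * n / block) * block
  m <- pad_len - n                     # bridge length (>= n)
  s0 <- x[n]; s1 <- x[1]
  d0 <- x[n] - x[n - 1]
  d1 <- x[2] - x[1]
  u <- seq_len(m) / (m + 1)
  bridge <- (2 * u^3 - 3 * u^2 + 1) * s0 +
    (u^3 - 2 * u^2 + u) * (d0 * (m + 1)) +
    (-2 * u^3 + 3 * u^2) * s1 +
    (u^3 - u^2) * (d1 * (m + 1))
  c(x, bridge)
}

#' Multi-level periodized wavelet decomposition
#'
#' Decomposes a signal into `levels` detail bands `d1` (finest) ... `dJ`
#' (coarsest) plus the level-`J` approximation, using circular boundary
#' handling. The transform is orthogonal and exactly invertible by
#' [idwt_periodic()]. Signals whose length is not divisible by `2^levels`
#' are symmetrically padded internally; `attr(, "orig_len")` records the
#' original length.
#'
#' @param x numeric vector, length >= 2^levels.
#' @param levels integer number of decomposition levels.
#' @param family wavelet family (only `"db8"`).
#' @return list with elements `d` (list of detail vectors, finest first),
#'   `a` (approximation), `levels`, `orig_len`, `pad_len`.
#' @export
dwt_periodic <- function(x, levels = 8, family = "db8") {
  f <- wavelet_filters(family)
  n <- length(x)
  if (n < 2^levels)
    validation_error(sprintf("signal of length %d too short for %d levels", n, levels))
  xp <- dwt_extend(x, levels)
  w <- dwt_core(xp, levels, f)
  w$orig_len <- n
  w$pad_len <- length(xp)
  w$family <- family
  w
}

#' Inverse of [dwt_periodic()]
#' @param w a decomposition as returned by [dwt_periodic()].
#' @return numeric vector of the original length.
#' @export
idwt_periodic <- function(w) {
  f <- wavelet_filters(w$family)
  a <- w$a
  for (j in rev(seq_len(w$levels))) a <- idwt_step(a, w$d[[j]], f)
  a[seq_len(w$orig_len)]
}

#' Reconstruct a signal from selected wavelet bands
#'
#' Zeroes all detail levels not in `keep_details` (1 = finest) and, unless
#' `keep_approx`, the approximation, then inverts the transform.
#'
#' @param w a decomposition from [dwt_periodic()].
#' @param keep_details integer vector of detail levels to retain.
#' @param keep_approx logical, retain the coarse approximation.
#' @return numeric vector of the original length.
#' @export
wavelet_band_reconstruct <- function(w, keep_details, keep_approx = FALSE) {
  w2 <- w
  for (j in seq_len(w$levels))
    if (!(j %in% keep_details)) w2$d[[j]] <- numeric(length(w$d[[j]]))
  if (!keep_approx) w2$a <- numeric(length(w$a))
  idwt_periodic(w2)
}
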