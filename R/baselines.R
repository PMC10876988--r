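#' Classical iterative polynomial-fitting preprocessing
#'
#' Baseline correction by iterative polynomial fitting: fit a polynomial of
#' the given order to the spectrum, clip points above the fit down to the
#' fit, and refit until the relative L2 change of the fitted baseline drops
#' below `tol` (5% by default) or `max_iter` is reached. The baseline is then
#' subtracted and the result denoised by local polynomial (quadratic)
#' smoothing over a moving window.
#'
#' @param s a [spectrum].
#' @param order polynomial order (default 5).
#' @param max_iter iteration cap (default 50).
#' @param window smoothing window in points (default 50).
#' @param tol relative-change stopping threshold (default 0.05).
#' @return preprocessed [spectrum] on the same axis.
#' @export
polynomial_preprocess <- function(s, order = 5, max_iter = 50, window = 50,
                                  tol = 0.05) {
  stopifnot(inherits(s, "spectrum"))
  if (order < 1) validation_error("order must be >= 1")
  if (window < 3) validation_error("window must be >= 3")
  n <- length(s$axis)
  if (n < window) validation_error("spectrum shorter than the smoothing window")
  t <- seq(-1, 1, length.out = n)  # scaled abscissa for numerical stability
  X <- stats::poly(t, degree = order, raw = FALSE)
  work <- s$intensity
  base_prev <- NULL
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(cbind(1, X), work)$fitted.values
    work <- pmin(work, fit)
    if (!is.null(base_prev)) {
      denom <- sqrt(sum(base_prev^2))
      rel <- if (denom > 0) sqrt(sum((fit - base_prev)^2)) / denom else 0
      if (rel < tol) { base_prev <- fit; break }
    }
    base_prev <- fit
  }
  corrected <- s$intensity - base_prev
  smoothed <- local_poly_smooth(corrected, window = window)
  spectrum(s$axis, smoothed, meta = c(s$meta, list(preprocess = "polyfit")))
}

# Local polynomial (Savitzky-Golay style) smoothing: for each point, fit a
# degree-`degree` polynomial over the surrounding window and take its value.
# Quartic fits preserve narrow band shapes much better than quadratic ones at
# the same window. Edges use shifted (asymmetric) windows.
local_poly_smooth <- function(x, window = 50, degree = 4) {
  n <- length(x)
  half <- floor(window / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    tt <- ((lo:hi) - i) / half          # scaled abscissa for conditioning
    A <- outer(tt, 0:degree, `^`)
    coef <- qr.solve(A, x[lo:hi])
    out[i] <- coef[1]
  }
  out
}

#' Classical wavelet-transform preprocessing
#'
#' Eight-level periodized db8 decomposition; detail levels `keep` (3-6 by
#' default) are retained as the Raman signal, the finest two levels are
#' treated as noise and the coarsest details plus the approximation as
#' baseline. The select-and-reconstruct cycle is repeated `cycles` times;
#' because pure level selection is a linear projection the output stabilizes
#' after the first cycle, but the loop is kept configurable.
#'
#' @param s a [spectrum].
#' @param family wavelet family (`"db8"`).
#' @param levels decomposition depth (default 8).
#' @param keep detail levels retained as signal (default 3:6).
#' @param cycles number of select-reconstruct iterations (default 100).
#' @return preprocessed [spectrum] on the same axis.
#' @export
wavelet_preprocess <- function(s, family = "db8", levels = 8, keep = 3:6,
                               cycles = 100) {
  stopifnot(inherits(s, "spectrum"))
  f <- wavelet_filters(family)
  n <- length(s$intensity)
  if (n < 2^levels)
    validation_error(sprintf("spectrum of length %d too short for %d levels",
                             n, levels))
  # iterate in the smoothly extended periodic domain, where selecting a set
  # of detail bands is an exact orthogonal projection; the cycles therefore
  # stabilize after the first pass and the loop exits at the fixed point
  out <- dwt_extend(s$intensity, levels)
  prev <- NULL
  for (cy in seq_len(cycles)) {
    w <- dwt_core(out, levels, f)
    for (j in seq_len(levels))
      if (!(j %in% keep)) w$d[[j]] <- numeric(length(w$d[[j]]))
    w$a <- numeric(length(w$a))
    out <- idwt_core(w, f)
    if (!is.null(prev) && max(abs(out - prev)) <= 1e-12 * max(abs(out), 1))
      break
    prev <- out
  }
  spectrum(s$axis, out[seq_len(n)],
           meta = c(s$meta, list(preprocess = "wavelet")))
}
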