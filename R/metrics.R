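#' Root mean squared error between two spectra
#' @param x,y equal-length numeric vectors.
#' @return `sqrt(mean((y - x)^2))`.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) validation_error("length mismatch")
  sqrt(mean((y - x)^2))
}

#' Infinity norm (maximum absolute deviation) between two spectra
#' @param x,y equal-length numeric vectors.
#' @return `max(abs(y - x))`.
#' @export
linf <- function(x, y) {
  if (length(x) != length(y)) validation_error("length mismatch")
  max(abs(y - x))
}

#' Classification accuracy metrics
#'
#' AUC is the fraction of (positive, negative) score pairs with
#' `pos > neg`, ties counted 0.5 (the Mann-Whitney statistic divided by
#' `M * N`). If a `threshold` is given, scores are dichotomized at
#' `score >= threshold` and sensitivity, specificity, PPV and NPV computed
#' from the confusion counts.
#'
#' @param pos_scores scores of the M true positives.
#' @param neg_scores scores of the N true negatives.
#' @param threshold optional decision threshold.
#' @return named list (class `metric_report`) with `auc` and, when a
#'   threshold is given, `sensitivity`, `specificity`, `ppv`, `npv`, and the
#'   confusion counts.
#' @export
classification_metrics <- function(pos_scores, neg_scores, threshold = NULL) {
  M <- length(pos_scores); N <- length(neg_scores)
  if (M < 1 || N < 1)
    stop_rc("need at least one positive and one negative score",
            "ramanclean_undefined_metric")
  cmp <- outer(pos_scores, neg_scores, `-`)
  auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (M * N)
  out <- list(auc = auc)
  if (!is.null(threshold)) {
    tp <- sum(pos_scores >= threshold); fn <- M - tp
    tn <- sum(neg_scores < threshold); fp <- N - tn
    out$sensitivity <- tp / (tp + fn)
    out$specificity <- tn / (tn + fp)
    out$ppv <- if (tp + fp > 0) tp / (tp + fp) else NaN
    out$npv <- if (tn + fn > 0) tn / (tn + fn) else NaN
    out$counts <- c(TP = tp, FN = fn, FP = fp, TN = tn)
  }
  structure(out, class = "metric_report")
}

#' Threshold classification metrics from confusion counts
#' @param tp,fn,fp,tn confusion-matrix counts.
#' @return named list with sensitivity, specificity, PPV and NPV.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

#' Quantification error over paired concentrations
#'
#' `sqrt(sum((log10(actual_i) - log10(pred_i))^2))`. Concentrations must be
#' positive; the base-10 logarithm matches decade-spaced calibration series.
#'
#' @param pred predicted concentrations. @param actual true concentrations.
#' @return scalar error.
#' @export
quantification_error <- function(pred, actual) {
  if (length(pred) != length(actual)) validation_error("length mismatch")
  if (any(pred <= 0) || any(actual <= 0))
    validation_error("concentrations must be positive")
  sqrt(sum((log10(actual) - log10(pred))^2))
}

#' Spectral signal-to-noise ratio (dB)
#'
#' `10 * log10(mean intensity over the C-H signal region / mean intensity
#' over the silent region)`. Region means are floored at
#' `eps_frac * max(intensity)` so spectra whose silent zone is exactly zero
#' after preprocessing still give a finite (capped) value.
#'
#' @param s a [spectrum].
#' @param signal_region,silent_region half-open wavenumber intervals
#'   (cm^-1); defaults 2800-3200 (C-H stretches) and 1800-2800 (silent zone).
#' @param eps_frac flooring fraction (default 1e-12).
#' @param cap_db cap for the returned value (default 120 dB).
#' @return scalar dB.
#' @export
snr_spec <- function(s, signal_region = c(2800, 3200),
                     silent_region = c(1800, 2800),
                     eps_frac = 1e-12, cap_db = 120) {
  ax <- s$axis
  sig_idx <- which(ax >= signal_region[1] & ax < signal_region[2])
  sil_idx <- which(ax >= silent_region[1] & ax < silent_region[2])
  if (!length(sig_idx))
    range_error(sprintf("axis lacks the signal region [%g, %g) cm^-1",
                        signal_region[1], signal_region[2]))
  if (!length(sil_idx))
    range_error(sprintf("axis lacks the silent region [%g, %g) cm^-1",
                        silent_region[1], silent_region[2]))
  eps <- eps_frac * max(abs(s$intensity))
  if (!is.finite(eps) || eps <= 0) eps <- .Machine$double.xmin
  i_n_raw <- mean(s$intensity[sil_idx])
  if (i_n_raw <= 0) return(cap_db)   # perfectly silent zone: capped SNR
  i_s <- max(mean(s$intensity[sig_idx]), eps)
  i_n <- max(i_n_raw, eps)
  max(min(10 * log10(i_s / i_n), cap_db), -cap_db)
}

#' Image contrast metrics (CNR and background SD)
#'
#' For a raw and a preprocessed channel map with shared signal/background
#' masks: `CNR = (mean(signal) - mean(background)) / sd(background)`,
#' `STDB = sd(background)`, `normalized CNR = CNR_raw / CNR_pre` and
#' `normalized STDB = STDB_raw / STDB_pre`.
#'
#' @param raw_map,pre_map numeric matrices (H x W).
#' @param signal_mask,background_mask logical matrices, nonempty, disjoint.
#' @return named list (class `metric_report`).
#' @export
image_contrast_metrics <- function(raw_map, pre_map, signal_mask, background_mask) {
  if (!any(signal_mask) || !any(background_mask))
    validation_error("masks must be nonempty")
  if (any(signal_mask & background_mask))
    validation_error("signal and background masks must be disjoint")
  cnr1 <- function(img) {
    c_sig <- mean(img[signal_mask]); c_bg <- mean(img[background_mask])
    s_bg <- stats::sd(img[background_mask])
    if (!is.finite(s_bg) || s_bg == 0)
      stop_rc("zero background SD: CNR undefined", "ramanclean_undefined_metric")
    list(cnr = (c_sig - c_bg) / s_bg, stdb = s_bg)
  }
  r <- cnr1(raw_map); p <- cnr1(pre_map)
  structure(list(cnr_raw = r$cnr, cnr_pre = p$cnr,
                 stdb_raw = r$stdb, stdb_pre = p$stdb,
                 normalized_cnr = r$cnr / p$cnr,
                 normalized_stdb = r$stdb / p$stdb),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  flat <- unlist(x[vapply(x, is.numeric, logical(1))])
  cat("<metric_report>\n")
  for (nm in names(flat)) cat(sprintf("  %s = %.6g\n", nm, flat[nm]))
  invisible(x)
}

#' Rank-based significance tests
#'
#' Two-sided Wilcoxon signed-rank test for paired samples
#' (`kind = "signed_rank"`) or Mann-Whitney U test for independent samples
#' (`kind = "mann_whitney"`). Exact distributions are used for small tie-free
#' samples (n <= 12 pairs), a normal approximation with continuity
#' correction otherwise.
#'
#' @param a,b numeric vectors (equal length for the paired test).
#' @param kind `"signed_rank"` or `"mann_whitney"`.
#' @return two-sided p-value.
#' @export
paired_test <- function(a, b, kind = c("signed_rank", "mann_whitney")) {
  kind <- match.arg(kind)
  if (kind == "signed_rank") {
    if (length(a) != length(b)) validation_error("paired test needs equal lengths")
    if (length(a) < 3) validation_error("need n >= 3")
    d <- a - b
    if (all(d == 0))
      stop_rc("all paired differences are zero: degenerate input",
              "ramanclean_degenerate_input")
    nz <- d[d != 0]
    use_exact <- length(nz) <= 12 && !any(duplicated(abs(nz)))
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = use_exact,
                                        correct = TRUE))$p.value
  } else {
    if (length(a) < 3 || length(b) < 3) validation_error("need n >= 3")
    use_exact <- (length(a) + length(b)) <= 24 && !any(duplicated(c(a, b)))
    suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                        correct = TRUE))$p.value
  }
}
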