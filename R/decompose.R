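#' Split a spectrum into signal, baseline and noise components
#'
#' Multi-level periodized db8 wavelet decomposition with a level-role split:
#' the finest detail levels carry noise, the coarsest details plus the
#' approximation carry the baseline, and the middle details carry the Raman
#' signal. Any reconstruction residual is assigned to the noise component so
#' that `signal + baseline + noise` equals the input exactly.
#'
#' @param s a [spectrum] (or numeric vector).
#' @param levels decomposition depth (default 8).
#' @param family wavelet family (only `"db8"`).
#' @param noise_levels detail levels assigned to noise (default 1:2).
#' @param signal_levels detail levels assigned to signal (default 3:6).
#' @return list of class `spectrum_components` with numeric vectors
#'   `signal`, `baseline`, `noise` and the `source` spectrum.
#' @export
decompose_spectrum <- function(s, levels = 8, family = "db8",
                               noise_levels = 1:2, signal_levels = 3:6) {
  x <- if (inherits(s, "spectrum")) s$intensity else as.numeric(s)
  w <- dwt_periodic(x, levels = levels, family = family)
  baseline_levels <- setdiff(seq_len(levels), c(noise_levels, signal_levels))
  signal <- wavelet_band_reconstruct(w, keep_details = signal_levels)
  baseline <- wavelet_band_reconstruct(w, keep_details = baseline_levels,
                                       keep_approx = TRUE)
  noise <- x - signal - baseline  # finest details + any numerical residual
  structure(list(signal = signal, baseline = baseline, noise = noise,
                 source = s),
            class = "spectrum_components")
}

#' @export
print.spectrum_components <- function(x, ...) {
  cat(sprintf("<spectrum_components> length %d; |signal| %.4g, |baseline| %.4g, |noise| %.4g (max abs)\n",
              length(x$signal), max(abs(x$signal)), max(abs(x$baseline)),
              max(abs(x$noise))))
  invisible(x)
}

#' Extract isolated Raman peak fragments by a differential method
#'
#' Candidate apexes are points where the first difference changes sign from
#' positive to negative. Fragment boundaries extend outward to the nearest
#' first-difference sign change (valley) or sub-threshold point. Fragments
#' narrower than `min_width` points or with prominence (apex height above the
#' endpoint chord) below `min_prominence * max(signal)` are discarded. The
#' stored profile is the signal over the fragment minus the linear chord
#' between its endpoints, floor-clipped at zero.
#'
#' @param signal numeric vector (baseline-free signal component).
#' @param min_prominence fraction of `max(signal)` (default 0.02).
#' @param min_width minimum fragment width in points (default 3).
#' @param source_id identifier recorded on each fragment.
#' @return list of `peak_fragment` objects, sorted by `start`. Each has
#'   0-based half-open indices `start`/`end`, 0-based `apex`, a nonnegative
#'   `profile` vector of length `end - start`, and `source_id`.
#' @export
extract_peak_fragments <- function(signal, min_prominence = 0.02,
                                   min_width = 3, source_id = NA_character_) {
  x <- as.numeric(signal)
  n <- length(x)
  if (!all(is.finite(x))) validation_error("signal contains non-finite values")
  mx <- max(x)
  if (n < 3 || mx <= 0) return(list())
  dx <- diff(x)
  sgn <- sign(dx)
  # apex: + -> - sign change of the first difference (0-length plateaus:
  # carry the previous nonzero sign forward so flat tops still count once)
  carry <- sgn
  for (i in seq_along(carry)[-1]) if (carry[i] == 0) carry[i] <- carry[i - 1]
  apexes <- which(carry[-length(carry)] > 0 & carry[-1] < 0) + 1
  thr <- min_prominence * mx
  frags <- list()
  for (ap in apexes) {
    # walk downhill from the apex; stop at the nearest first-difference sign
    # change (valley) or once the flank drops to the sub-threshold floor
    lo <- ap
    while (lo > 1 && x[lo - 1] < x[lo] && x[lo] > thr) lo <- lo - 1
    hi <- ap
    while (hi < n && x[hi + 1] < x[hi] && x[hi] > thr) hi <- hi + 1
    if (hi - lo + 1 < min_width) next
    seg <- x[lo:hi]
    chord <- seq(seg[1], seg[length(seg)], length.out = length(seg))
    prof <- pmax(seg - chord, 0)
    apex_rel <- which.max(prof)
    if (max(prof) < thr) next
    # re-anchor apex to the profile maximum (chord subtraction can shift it)
    frags[[length(frags) + 1]] <- structure(
      list(start = as.integer(lo - 1), end = as.integer(hi),
           apex = as.integer(lo - 2 + apex_rel),
           profile = prof, source_id = source_id),
      class = "peak_fragment")
  }
  frags[order(vapply(frags, function(f) f$start, integer(1)))]
}

#' Build component pools from a set of spectra
#'
#' Decomposes every spectrum and pools the per-spectrum noise and baseline
#' vectors together with all surviving peak fragments, forming the raw
#' material for recombination synthesis.
#'
#' @param spectra list of [spectrum] objects on a shared grid.
#' @param levels,family passed to [decompose_spectrum()].
#' @param min_prominence,min_width passed to [extract_peak_fragments()].
#' @return list of class `component_pools` with `noises`, `baselines`
#'   (lists of vectors), `peaks` (list of `peak_fragment`) and `grid_len`.
#' @export
build_component_pools <- function(spectra, levels = 8, family = "db8",
                                  min_prominence = 0.02, min_width = 3) {
  if (!length(spectra)) validation_error("empty input spectrum list")
  lens <- vapply(spectra, function(s) length(s$axis), integer(1))
  if (length(unique(lens)) != 1)
    validation_error("all spectra must share one grid")
  noises <- vector("list", length(spectra))
  baselines <- vector("list", length(spectra))
  peaks <- list()
  for (i in seq_along(spectra)) {
    comp <- decompose_spectrum(spectra[[i]], levels = levels, family = family)
    noises[[i]] <- comp$noise
    baselines[[i]] <- comp$baseline
    fr <- extract_peak_fragments(comp$signal, min_prominence = min_prominence,
                                 min_width = min_width,
                                 source_id = sprintf("s%04d", i))
    peaks <- c(peaks, fr)
  }
  structure(list(noises = noises, baselines = baselines, peaks = peaks,
                 grid_len = lens[1]),
            class = "component_pools")
}

#' @export
print.component_pools <- function(x, ...) {
  cat(sprintf("<component_pools> %d noises, %d baselines, %d peak fragments (grid %d)\n",
              length(x$noises), length(x$baselines), length(x$peaks), x$grid_len))
  invisible(x)
}

#' Write / read component pools as versioned plain text
#'
#' `ramanpools v1` layout: per-spectrum noise and baseline vectors, then one
#' line per peak fragment (start, end, apex, source id, profile values).
#' Floats use 17 significant digits, so the round trip is bitwise exact.
#'
#' @param pools a `component_pools` object. @param path file path.
#' @return `path` (write) or the pools (read).
#' @export
write_pools <- function(pools, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ramanpools v1",
               sprintf("# counts %d %d %d %d", length(pools$noises),
                       length(pools$baselines), length(pools$peaks),
                       pools$grid_len),
               "# noises"), con)
  writeLines(vapply(pools$noises, fmt_row, character(1)), con)
  writeLines("# baselines", con)
  writeLines(vapply(pools$baselines, fmt_row, character(1)), con)
  writeLines("# peaks start end apex source_id profile...", con)
  writeLines(vapply(pools$peaks, function(f)
    paste(f$start, f$end, f$apex, f$source_id, fmt_row(f$profile)),
    character(1)), con)
  invisible(path)
}

#' @rdname write_pools
#' @export
read_pools <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "# ramanpools v1")
    parse_error("not a ramanpools v1 container")
  cnt <- as.integer(strsplit(sub("^# counts ", "", lines[2]), " ")[[1]])
  num_row <- function(s) as.numeric(strsplit(s, " ", fixed = TRUE)[[1]])
  stopifnot(lines[3] == "# noises")
  noises <- lapply(lines[3 + seq_len(cnt[1])], num_row)
  off <- 4 + cnt[1]
  baselines <- lapply(lines[off + seq_len(cnt[2])], num_row)
  off <- off + cnt[2] + 1
  peaks <- lapply(lines[off + seq_len(cnt[3])], function(s) {
    tok <- strsplit(s, " ", fixed = TRUE)[[1]]
    structure(list(start = as.integer(tok[1]), end = as.integer(tok[2]),
                   apex = as.integer(tok[3]), source_id = tok[4],
                   profile = as.numeric(tok[-(1:4)])),
              class = "peak_fragment")
  })
  structure(list(noises = noises, baselines = baselines, peaks = peaks,
                 grid_len = cnt[4]),
            class = "component_pools")
}
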