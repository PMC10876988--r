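#' Synthesis configuration
#'
#' Parameters of the training-pair factory. Defaults reproduce the study
#' conditions: 10 000 ideal spectra, each a random superposition of 5-20
#' pooled peak fragments, with noise and baseline superposition coefficients
#' spanning signal-to-noise ratios of roughly 0-40 dB and baseline amplitudes
#' of 0-5 times the median peak height.
#'
#' @param n_spectra number of pairs to generate.
#' @param kmin,kmax inclusive bounds for peaks per ideal spectrum.
#' @param snr_db_range target SNR range in dB for noise scaling.
#' @param beta_range baseline amplitude range, as multiples of the median
#'   peak height of the ideal spectrum.
#' @param amp_range fragment amplitude jitter range (uniform).
#' @param grid_len spectral grid length (fixed model grid).
#' @param grid_range wavenumber span of the grid (cm^-1).
#' @param seed integer RNG seed recorded in provenance.
#' @return list of class `synthesis_config`.
#' @export
synthesis_config <- function(n_spectra = 10000, kmin = 5, kmax = 20,
                             snr_db_range = c(0, 40), beta_range = c(0, 5),
                             amp_range = c(0.5, 1.5), grid_len = 1024,
                             grid_range = c(400, 3200), seed = 1) {
  if (!(is_count(kmin) && is_count(kmax) && kmin <= kmax))
    validation_error("need 1 <= kmin <= kmax")
  if (!is_count(n_spectra)) validation_error("n_spectra must be >= 1")
  if (!all(is.finite(c(snr_db_range, beta_range, amp_range))))
    validation_error("ranges must be finite")
  structure(list(n_spectra = n_spectra, kmin = kmin, kmax = kmax,
                 snr_db_range = snr_db_range, beta_range = beta_range,
                 amp_range = amp_range, grid_len = grid_len,
                 grid_range = grid_range, seed = seed),
            class = "synthesis_config")
}

#' Assemble ideal (label) spectra from a peak-fragment pool
#'
#' For each spectrum, `k ~ Uniform{kmin..kmax}` fragments are drawn with
#' replacement, each placed at a uniformly random start position (fully
#' inside the grid), scaled by a `Uniform(amp_range)` amplitude factor and
#' summed additively. Ideal spectra therefore contain Raman peaks only:
#' no noise, no baseline.
#'
#' @param pools a `component_pools` object from [build_component_pools()].
#' @param cfg a [synthesis_config()].
#' @return list with `ideals` (n x L matrix) and `manifests` (per-spectrum
#'   list of data.frames with fragment id, position, scale).
#' @export
assemble_ideal <- function(pools, cfg) {
  if (!length(pools$peaks)) validation_error("peaks pool is empty")
  L <- cfg$grid_len
  frag_lens <- vapply(pools$peaks, function(f) length(f$profile), integer(1))
  usable <- which(frag_lens <= L)
  if (!length(usable)) validation_error("all fragments longer than the grid")
  if (length(usable) < length(frag_lens))
    warning(sprintf("%d fragment(s) longer than the grid skipped",
                    length(frag_lens) - length(usable)))
  n <- cfg$n_spectra
  ideals <- matrix(0, n, L)
  manifests <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(cfg$kmin:cfg$kmax, 1)
    ids <- usable[sample.int(length(usable), k, replace = TRUE)]
    pos <- integer(k); scl <- numeric(k)
    row <- numeric(L)
    for (j in seq_len(k)) {
      len <- frag_lens[ids[j]]
      p0 <- sample.int(L - len + 1, 1)            # 1-based start
      a <- stats::runif(1, cfg$amp_range[1], cfg$amp_range[2])
      row[p0:(p0 + len - 1)] <- row[p0:(p0 + len - 1)] +
        a * pools$peaks[[ids[j]]]$profile
      pos[j] <- p0 - 1L                           # record 0-based
      scl[j] <- a
    }
    ideals[i, ] <- row
    manifests[[i]] <- data.frame(fragment = ids, position = pos,
                                 length = frag_lens[ids], scale = scl)
  }
  list(ideals = ideals, manifests = manifests)
}

#' Closed-form noise scaling for a target SNR
#'
#' Returns `alpha` such that `10*log10(mean(y^2) / mean((alpha*noise)^2))`
#' equals `target_db`: `alpha = sqrt(P_y / (P_noise * 10^(target_db/10)))`.
#'
#' @param y ideal spectrum (signal).
#' @param noise noise vector (not identically zero).
#' @param target_db target SNR in dB, within [-10, 60].
#' @return scalar `alpha`.
#' @export
scale_to_target_snr <- function(y, noise, target_db) {
  if (!is.finite(target_db) || target_db < -10 || target_db > 60)
    range_error("target SNR outside supported range [-10, 60] dB")
  p_sig <- mean(y^2); p_noise <- mean(noise^2)
  if (p_sig <= 0 || p_noise <= 0)
    validation_error("zero-power signal or noise")
  sqrt(p_sig / (p_noise * 10^(target_db / 10)))
}

#' Synthesize a reference spectrum from components
#'
#' Builds `x = y + alpha * noise + beta * baseline` and records the realized
#' SNR, `10*log10(mean peak-region power / mean noise power)`, where the peak
#' region is where `y > 0`.
#'
#' @param y ideal spectrum. @param noise,baseline component vectors.
#' @param alpha,beta superposition coefficients.
#' @return list of class `training_pair` with `x`, `y`, `alpha`, `beta`,
#'   `snr_db`.
#' @export
synthesize_reference <- function(y, noise, baseline, alpha, beta) {
  if (length(y) != length(noise) || length(y) != length(baseline))
    validation_error("component length mismatch")
  x <- y + alpha * noise + beta * baseline
  peak_mask <- y > 0
  p_sig <- if (any(peak_mask)) mean(y[peak_mask]^2) else 0
  p_noise <- mean((alpha * noise)^2)
  snr_db <- if (p_sig > 0 && p_noise > 0) 10 * log10(p_sig / p_noise) else Inf
  structure(list(x = x, y = y, alpha = alpha, beta = beta, snr_db = snr_db),
            class = "training_pair")
}

# Smooth random baseline through m control points (monotone-free cubic
# spline), nonnegative, unit maximum.
random_baseline <- function(L, m = NULL) {
  if (is.null(m)) m <- sample(4:8, 1)
  cp_x <- seq(1, L, length.out = m)
  cp_y <- stats::runif(m)
  b <- stats::spline(cp_x, cp_y, xout = seq_len(L), method = "natural")$y
  b <- b - min(b)
  mx <- max(b)
  if (mx > 0) b / mx else b
}

#' Generate one mathematical-simulation training pair
#'
#' The ideal spectrum is a sum of `k` Lorentzian peaks with random center,
#' half-width and amplitude; the noise is i.i.d. Gaussian; the baseline is a
#' smooth spline through 4-8 random control points. The reference spectrum is
#' assembled exactly as in [synthesize_reference()].
#'
#' @param cfg a [synthesis_config()] (peak-count and severity ranges reused).
#' @param width_range Lorentzian half-width-at-half-maximum range, in grid
#'   points.
#' @return a `training_pair` with an extra `manifest` (peak parameters) and
#'   `noise`/`baseline` components.
#' @export
generate_mathsim_pair <- function(cfg, width_range = c(3, 25)) {
  L <- cfg$grid_len
  k <- sample(cfg$kmin:cfg$kmax, 1)
  center <- stats::runif(k, 1, L)
  width <- stats::runif(k, width_range[1], width_range[2])
  amp <- stats::runif(k, 0.2, 1)
  t <- seq_len(L)
  y <- numeric(L)
  for (j in seq_len(k))
    y <- y + amp[j] * width[j]^2 / ((t - center[j])^2 + width[j]^2)
  noise <- stats::rnorm(L)
  baseline <- random_baseline(L)
  target_db <- stats::runif(1, cfg$snr_db_range[1], cfg$snr_db_range[2])
  alpha <- scale_to_target_snr(y, noise, target_db)
  med_peak <- stats::median(amp)
  beta <- stats::runif(1, cfg$beta_range[1], cfg$beta_range[2]) * med_peak
  pair <- synthesize_reference(y, noise, baseline, alpha, beta)
  pair$manifest <- data.frame(center = center, width = width, amp = amp)
  pair$noise <- noise
  pair$baseline <- baseline
  pair
}

#' Build a full labelled dataset
#'
#' Deterministic given `cfg$seed`. In `"recombination"` mode, ideal spectra
#' are assembled from the component pools and paired with pooled noises and
#' baselines; in `"mathsim"` mode each pair comes from
#' [generate_mathsim_pair()].
#'
#' @param cfg a [synthesis_config()].
#' @param mode `"recombination"` or `"mathsim"`.
#' @param pools required `component_pools` for recombination mode.
#' @return a [pair_collection] with provenance in `meta`.
#' @export
build_dataset <- function(cfg, mode = c("recombination", "mathsim"),
                          pools = NULL) {
  mode <- match.arg(mode)
  set.seed(cfg$seed)
  L <- cfg$grid_len
  axis <- seq(cfg$grid_range[1], cfg$grid_range[2], length.out = L)
  n <- cfg$n_spectra
  x <- matrix(0, n, L); y <- matrix(0, n, L)
  coeffs <- data.frame(alpha = numeric(n), beta = numeric(n),
                       snr_db = numeric(n))
  manifests <- vector("list", n)
  if (mode == "recombination") {
    if (is.null(pools)) validation_error("recombination mode requires pools")
    asm <- assemble_ideal(pools, cfg)
    for (i in seq_len(n)) {
      yi <- asm$ideals[i, ]
      noise <- pools$noises[[sample.int(length(pools$noises), 1)]]
      baseline <- pools$baselines[[sample.int(length(pools$baselines), 1)]]
      if (length(noise) != L || length(baseline) != L)
        validation_error("pool component length does not match the grid")
      bl <- baseline - min(baseline)
      if (max(bl) > 0) bl <- bl / max(bl)
      target_db <- stats::runif(1, cfg$snr_db_range[1], cfg$snr_db_range[2])
      nz <- if (mean(noise^2) > 0) noise / sqrt(mean(noise^2)) else noise
      alpha <- if (any(yi > 0)) scale_to_target_snr(yi, nz, target_db) else 0
      apex_heights <- vapply(seq_len(nrow(asm$manifests[[i]])), function(j) {
        f <- asm$manifests[[i]][j, ]
        f$scale * max(pools$peaks[[f$fragment]]$profile)
      }, numeric(1))
      beta <- stats::runif(1, cfg$beta_range[1], cfg$beta_range[2]) *
        stats::median(apex_heights)
      pair <- synthesize_reference(yi, nz, bl, alpha, beta)
      x[i, ] <- pair$x; y[i, ] <- pair$y
      coeffs[i, ] <- c(pair$alpha, pair$beta, pair$snr_db)
      manifests[[i]] <- asm$manifests[[i]]
    }
  } else {
    for (i in seq_len(n)) {
      pair <- generate_mathsim_pair(cfg)
      x[i, ] <- pair$x; y[i, ] <- pair$y
      coeffs[i, ] <- c(pair$alpha, pair$beta, pair$snr_db)
      manifests[[i]] <- pair$manifest
    }
  }
  pair_collection(axis, x, y, coeffs,
                  meta = list(mode = mode, seed = cfg$seed,
                              config_hash = config_hash(unclass(cfg))),
                  manifests = manifests)
}
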