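# Shared fixtures. Everything is generated in code; small trainings use a
# short grid (64 points) so the whole non-acceptance suite stays fast.

fix_axis <- function(L = 1024) seq(400, 3200, length.out = L)

# deterministic Lorentzian ideal spectrum on an arbitrary grid
lorentz <- function(L, centers, widths, amps) {
  t <- seq_len(L)
  y <- numeric(L)
  for (j in seq_along(centers))
    y <- y + amps[j] * widths[j]^2 / ((t - centers[j])^2 + widths[j]^2)
  y
}

# a tiny component pool built from clean, well-separated peaks
tiny_pools <- function(n_spectra = 6, seed = 42, L = 1024) {
  set.seed(seed)
  spectra <- lapply(seq_len(n_spectra), function(i) {
    centers <- seq(100, L - 100, length.out = 6) +
      round(stats::runif(6, -20, 20))
    y <- lorentz(L, centers, stats::runif(6, 5, 12), stats::runif(6, 0.5, 1))
    baseline <- 2 * (seq_len(L) / L)^2 + 1
    noise <- stats::rnorm(L, sd = 0.01)
    spectrum(fix_axis(L), y + baseline + noise)
  })
  build_component_pools(spectra)
}

# small labelled dataset on a short grid for fast training smoke tests
tiny_dataset <- function(n = 64, L = 64, seed = 5, mode = "mathsim") {
  cfg <- synthesis_config(n_spectra = n, kmin = 2, kmax = 4,
                          snr_db_range = c(15, 30), beta_range = c(1, 3),
                          grid_len = L, seed = seed)
  build_dataset(cfg, mode)
}

tiny_model_cfg <- function(L = 64, seed = 7, epochs_be = 3, epochs_full = 4) {
  model_config(grid_len = L, channels = 2, window = 16, step = 8,
               epochs_be = epochs_be, epochs_full = epochs_full,
               batch = 8, seed = seed)
}

# shared state for the expensive acceptance fixtures (trained once, reused)
accept_env <- new.env(parent = emptyenv())

# full-scale trial data + trained model used by several acceptance checks
get_headline_trial <- function() {
  if (is.null(accept_env$headline)) {
    cfg <- trial_config(methods = c("raw", "wavelet", "cnn_recomb"),
                        n_train = 2000, n_val = 100, n_source = 1000,
                        severity = "baseline_dominated",
                        model_cfg = model_config(preset = "desk"), seed = 1)
    data <- build_trial_data(cfg)
    mcfg <- cfg$model_cfg; mcfg$seed <- cfg$seed
    model <- train_preprocessor(data$train_recomb, mcfg)
    pred <- forward_preprocess(data$val$x, model)
    n <- nrow(data$val$x)
    wav <- t(vapply(seq_len(n), function(i)
      wavelet_preprocess(spectrum(data$val$axis, data$val$x[i, ]))$intensity,
      numeric(ncol(data$val$x))))
    accept_env$headline <- list(cfg = cfg, data = data, model = model,
                                pred = pred, wav = wav)
  }
  accept_env$headline
}
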