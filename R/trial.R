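#' Configuration for the preprocessing comparison trial
#'
#' @param methods methods to score: any of `"raw"`, `"polyfit"`,
#'   `"wavelet"`, `"cnn_mathsim"` (model trained on mathematical-simulation
#'   pairs), `"cnn_recomb"` (model trained on recombination pairs).
#' @param n_train training pairs per model. @param n_val held-out validation
#'   pairs (never seen in training).
#' @param n_source source spectra decomposed into the component pools.
#' @param severity `"baseline_dominated"` (baselines 2-5x the median peak
#'   height, SNR 10-30 dB) or `"mixed"` (baselines 0-5x, SNR 0-40 dB).
#' @param model_cfg a [model_config()] for the trained methods.
#' @param seed master seed; all internal seeds derive from it.
#' @return list of class `trial_config`.
#' @export
trial_config <- function(methods = c("raw", "wavelet", "cnn_recomb"),
                         n_train = 2000, n_val = 100, n_source = 1000,
                         severity = c("baseline_dominated", "mixed"),
                         model_cfg = model_config(preset = "desk"),
                         seed = 1) {
  severity <- match.arg(severity)
  known <- c("raw", "polyfit", "wavelet", "cnn_mathsim", "cnn_recomb")
  if (!all(methods %in% known))
    validation_error(paste0("unknown method(s): ",
                            paste(setdiff(methods, known), collapse = ", ")))
  structure(list(methods = methods, n_train = n_train, n_val = n_val,
                 n_source = n_source, severity = severity,
                 model_cfg = model_cfg, seed = seed),
            class = "trial_config")
}

severity_ranges <- function(severity) {
  if (severity == "baseline_dominated")
    list(snr = c(10, 30), beta = c(2, 5))
  else
    list(snr = c(0, 40), beta = c(0, 5))
}

#' Build the trial datasets (pools, training sets, validation set)
#'
#' Deterministic given the seed; the validation pairs are generated in the
#' same run as the recombination training pairs and split off afterwards, so
#' train and validation are disjoint by construction (verified by a
#' fingerprint check on the pair rows).
#'
#' @param cfg a [trial_config()].
#' @return list with `pools`, `train_recomb`, `train_mathsim` (only if
#'   requested), `val`.
#' @export
build_trial_data <- function(cfg) {
  rg <- severity_ranges(cfg$severity)
  L <- cfg$model_cfg$grid_len
  scfg <- synthesis_config(n_spectra = cfg$n_source, seed = cfg$seed,
                           snr_db_range = rg$snr, beta_range = rg$beta,
                           grid_len = L)
  src <- build_dataset(scfg, "mathsim")
  spectra <- lapply(seq_len(cfg$n_source),
                    function(i) spectrum(src$axis, src$x[i, ]))
  pools <- build_component_pools(spectra)
  dcfg <- synthesis_config(n_spectra = cfg$n_train + cfg$n_val,
                           seed = cfg$seed + 1,
                           snr_db_range = rg$snr, beta_range = rg$beta,
                           grid_len = L)
  dat <- build_dataset(dcfg, "recombination", pools = pools)
  train <- dat[seq_len(cfg$n_train)]
  val <- dat[cfg$n_train + seq_len(cfg$n_val)]
  # disjointness fingerprint: no validation row may equal a training row
  fp <- function(m) apply(m, 1, function(r) fnv1a32(fmt_row(r[1:16])))
  if (any(fp(val$x) %in% fp(train$x)))
    stop_rc("train/validation overlap detected", "ramanclean_internal_error")
  out <- list(pools = pools, train_recomb = train, val = val)
  if ("cnn_mathsim" %in% cfg$methods) {
    mcfg <- synthesis_config(n_spectra = cfg$n_train, seed = cfg$seed + 2,
                             snr_db_range = rg$snr, beta_range = rg$beta,
                             grid_len = L)
    out$train_mathsim <- build_dataset(mcfg, "mathsim")
  }
  out
}

#' Run the preprocessing comparison trial
#'
#' Trains the requested models, preprocesses the held-out validation pairs
#' with every method, and reports per-spectrum RMSE and infinity-norm
#' distributions, percentage reductions of the mean (and median) error
#' between every pair of methods, and Wilcoxon signed-rank p-values.
#'
#' @param cfg a [trial_config()].
#' @param data optional precomputed [build_trial_data()] result.
#' @param verbose print progress.
#' @return list of class `trial_report`: `errors` (data.frame: method,
#'   pair, rmse, linf), `summary`, `reductions`, `tests`, `provenance`.
#' @export
run_preprocessing_trial <- function(cfg = trial_config(), data = NULL,
                                    verbose = FALSE) {
  if (is.null(data)) data <- build_trial_data(cfg)
  val <- data$val
  n <- nrow(val$x)
  axis <- val$axis
  preds <- list()
  for (mth in cfg$methods) {
    if (verbose) message("method: ", mth)
    preds[[mth]] <- switch(
      mth,
      raw = val$x,
      polyfit = t(vapply(seq_len(n), function(i)
        polynomial_preprocess(spectrum(axis, val$x[i, ]))$intensity,
        numeric(ncol(val$x)))),
      wavelet = t(vapply(seq_len(n), function(i)
        wavelet_preprocess(spectrum(axis, val$x[i, ]))$intensity,
        numeric(ncol(val$x)))),
      cnn_mathsim = {
        mcfg <- cfg$model_cfg; mcfg$seed <- cfg$seed
        model <- train_preprocessor(data$train_mathsim, mcfg, verbose = verbose)
        forward_preprocess(val$x, model)
      },
      cnn_recomb = {
        mcfg <- cfg$model_cfg; mcfg$seed <- cfg$seed
        model <- train_preprocessor(data$train_recomb, mcfg, verbose = verbose)
        forward_preprocess(val$x, model)
      })
  }
  errors <- do.call(rbind, lapply(cfg$methods, function(mth) {
    data.frame(method = mth, pair = seq_len(n),
               rmse = vapply(seq_len(n), function(i)
                 rmse(preds[[mth]][i, ], val$y[i, ]), numeric(1)),
               linf = vapply(seq_len(n), function(i)
                 linf(preds[[mth]][i, ], val$y[i, ]), numeric(1)))
  }))
  summarize <- function(metric) {
    do.call(rbind, lapply(cfg$methods, function(mth) {
      e <- errors[errors$method == mth, metric]
      data.frame(method = mth, metric = metric, mean = mean(e),
                 sd = stats::sd(e), median = stats::median(e))
    }))
  }
  summary <- rbind(summarize("rmse"), summarize("linf"))
  combos <- expand.grid(method = cfg$methods, comparator = cfg$methods,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$method != combos$comparator, ]
  reductions <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    a <- combos$method[k]; b <- combos$comparator[k]
    do.call(rbind, lapply(c("rmse", "linf"), function(metric) {
      ea <- errors[errors$method == a, metric]
      eb <- errors[errors$method == b, metric]
      data.frame(method = a, comparator = b, metric = metric,
                 reduction_mean_pct = 100 * (1 - mean(ea) / mean(eb)),
                 reduction_median_pct =
                   100 * (1 - stats::median(ea) / stats::median(eb)),
                 frac_better = mean(ea < eb))
    }))
  }))
  tests <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    a <- combos$method[k]; b <- combos$comparator[k]
    do.call(rbind, lapply(c("rmse", "linf"), function(metric) {
      ea <- errors[errors$method == a, metric]
      eb <- errors[errors$method == b, metric]
      p <- tryCatch(paired_test(ea, eb, "signed_rank"),
                    ramanclean_degenerate_input = function(e) NA_real_)
      data.frame(method = a, comparator = b, metric = metric,
                 p_value = p,
                 note = if (is.na(p)) "identical" else "")
    }))
  }))
  structure(list(errors = errors, summary = summary, reductions = reductions,
                 tests = tests,
                 provenance = list(seed = cfg$seed, severity = cfg$severity,
                                   n_train = cfg$n_train, n_val = cfg$n_val,
                                   n_source = cfg$n_source,
                                   config_hash = config_hash(
                                     unclass(cfg$model_cfg)))),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat("<trial_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Serialize a trial report to JSON
#' @param report a `trial_report`. @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a trial report written by [write_trial_report()]
#' @param path JSON path.
#' @return a `trial_report`.
#' @export
read_trial_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  need <- c("errors", "summary", "reductions", "tests", "provenance")
  if (!all(need %in% names(obj)))
    parse_error("not a trial report (missing sections)")
  structure(obj, class = "trial_report")
}

#' Bar plot of per-method mean errors
#' @param x a `trial_report`. @param metric `"rmse"` or `"linf"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.trial_report <- function(x, metric = "rmse", ...) {
  s <- x$summary[x$summary$metric == metric, ]
  graphics::barplot(s$mean, names.arg = s$method, ylab = paste("mean", metric),
                    ...)
  invisible(x)
}
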