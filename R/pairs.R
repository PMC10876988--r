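#' Construct a collection of training pairs
#'
#' A pair collection holds `n` reference spectra `x` (rows of a matrix) with
#' their ideal label spectra `y` on one shared wavenumber axis, plus the
#' superposition coefficients used to build each reference
#' (`alpha` for noise, `beta` for baseline, realized `snr_db`) and
#' provenance (generation mode, seed, config hash).
#'
#' @param axis shared wavenumber axis (cm^-1), strictly increasing.
#' @param x n x L matrix of reference spectra.
#' @param y n x L matrix of ideal (label) spectra.
#' @param coeffs data.frame with columns `alpha`, `beta`, `snr_db` (n rows).
#' @param meta named list; `mode` (one of `"recombination"`, `"mathsim"`,
#'   `"gan"`), `seed`, `config_hash` are conventional entries.
#' @param manifests optional list (one entry per pair) of per-spectrum peak
#'   manifests as returned by [assemble_ideal()] or [generate_mathsim_pair()].
#' @return An object of class `pair_collection`.
#' @export
pair_collection <- function(axis, x, y, coeffs = NULL, meta = list(), manifests = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) == 0) validation_error("pair collection must be nonempty")
  if (!all(dim(x) == dim(y)))
    validation_error("x and y dimensions differ (len(x) != len(y) for some pair)")
  if (ncol(x) != length(axis))
    validation_error("pairs do not share the collection axis")
  if (any(diff(axis) <= 0)) validation_error("axis must be strictly increasing")
  if (is.null(coeffs))
    coeffs <- data.frame(alpha = rep(NA_real_, nrow(x)),
                         beta = rep(NA_real_, nrow(x)),
                         snr_db = rep(NA_real_, nrow(x)))
  if (nrow(coeffs) != nrow(x))
    validation_error("coeffs must have one row per pair")
  structure(list(axis = as.numeric(axis), x = x, y = y,
                 coeffs = coeffs, meta = meta, manifests = manifests),
            class = "pair_collection")
}

#' @export
print.pair_collection <- function(x, ...) {
  cat(sprintf("<pair_collection> %d pairs, grid length %d, mode=%s\n",
              nrow(x$x), length(x$axis), x$meta$mode %||% "?"))
  invisible(x)
}

#' @export
length.pair_collection <- function(x) nrow(x$x)

#' Subset a pair collection
#' @param x a [pair_collection]. @param i pair indices. @param ... unused.
#' @export
`[.pair_collection` <- function(x, i, ...) {
  pair_collection(x$axis, x$x[i, , drop = FALSE], x$y[i, , drop = FALSE],
                  x$coeffs[i, , drop = FALSE], x$meta,
                  if (!is.null(x$manifests)) x$manifests[i])
}

#' Write a pair collection to a versioned plain-text container
#'
#' The `ramanpairs v1` layout stores the shared axis, the `x` and `y`
#' matrices (one row per line), the coefficient table and a JSON metadata
#' line. Floats are written with 17 significant digits, so the round trip
#' through [read_pairs()] is bitwise exact.
#'
#' @param pairs a [pair_collection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "pair_collection"))
  n <- nrow(pairs$x); L <- ncol(pairs$x)
  meta <- pairs$meta
  if (!is.null(pairs$manifests)) meta$.manifests <- pairs$manifests
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ramanpairs v1",
               paste0("# meta ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null")),
               sprintf("# dims %d %d", n, L),
               "# axis", fmt_row(pairs$axis),
               "# x"), con)
  writeLines(apply(pairs$x, 1, fmt_row), con)
  writeLines("# y", con)
  writeLines(apply(pairs$y, 1, fmt_row), con)
  writeLines(c("# coeffs alpha beta snr_db",
               paste(fmt_dbl(pairs$coeffs$alpha), fmt_dbl(pairs$coeffs$beta),
                     fmt_dbl(pairs$coeffs$snr_db))), con)
  invisible(path)
}

#' Read a pair collection written by [write_pairs()]
#' @param path path to a `ramanpairs v1` file.
#' @return A [pair_collection].
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) parse_error(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "# ramanpairs v1")
    parse_error("not a ramanpairs v1 container")
  meta <- jsonlite::fromJSON(sub("^# meta ", "", lines[2]), simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  dims <- as.integer(strsplit(sub("^# dims ", "", lines[3]), " ")[[1]])
  n <- dims[1]; L <- dims[2]
  stopifnot(lines[4] == "# axis", lines[6] == "# x")
  num_row <- function(s) as.numeric(strsplit(s, " ", fixed = TRUE)[[1]])
  axis <- num_row(lines[5])
  x <- do.call(rbind, lapply(lines[6 + seq_len(n)], num_row))
  stopifnot(lines[7 + n] == "# y")
  y <- do.call(rbind, lapply(lines[7 + n + seq_len(n)], num_row))
  cf <- do.call(rbind, lapply(lines[8 + 2 * n + seq_len(n)], num_row))
  coeffs <- data.frame(alpha = cf[, 1], beta = cf[, 2], snr_db = cf[, 3])
  manifests <- meta$.manifests
  meta$.manifests <- NULL
  pair_collection(axis, x, y, coeffs, meta, manifests)
}
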