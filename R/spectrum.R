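#' Construct a spectrum
#'
#' A spectrum is a Raman-shift axis (wavenumbers, cm^-1) plus an intensity
#' vector of matching length, with optional key/value metadata. The axis must
#' be strictly increasing and finite; intensities must be finite.
#'
#' @param axis numeric vector of Raman shifts (cm^-1), strictly increasing.
#' @param intensity numeric vector, same length as `axis`.
#' @param meta named list of scalar metadata (stored as character).
#' @return An object of class `spectrum`.
#' @examples
#' s <- spectrum(seq(400, 1800, length.out = 64), rnorm(64))
#' @export
spectrum <- function(axis, intensity, meta = list()) {
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) < 2)
    validation_error("axis must have length >= 2")
  if (length(axis) != length(intensity))
    validation_error("axis and intensity lengths differ")
  if (!all(is.finite(axis)))
    validation_error("axis contains non-finite values")
  if (!all(is.finite(intensity)))
    validation_error("intensity contains non-finite values")
  if (any(diff(axis) <= 0))
    validation_error("axis must be strictly increasing (duplicated or unordered wavenumbers)")
  structure(list(axis = axis, intensity = intensity, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.6g..%.6g cm^-1, intensity [%.4g, %.4g]\n",
              length(x$axis), min(x$axis), max(x$axis),
              min(x$intensity), max(x$intensity)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$axis)

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavenumber = x$axis, intensity = x$intensity)
}

#' @export
plot.spectrum <- function(x, ...) {
  graphics::plot(x$axis, x$intensity, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Intensity", ...)
}

#' Read a spectrum from two-column delimited text
#'
#' Accepts comma-, tab- or whitespace-separated files (auto-detected by
#' default). Lines starting with `#` are comments. The first two numeric
#' columns are taken as wavenumber and intensity; rows are sorted by
#' wavenumber (stable), duplicated wavenumbers are rejected.
#'
#' @param path file path.
#' @param dialect one of `"auto"`, `"comma"`, `"tab"`, `"whitespace"`.
#' @return A [spectrum].
#' @export
read_spectrum <- function(path, dialect = c("auto", "comma", "tab", "whitespace")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) parse_error(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) parse_error(paste0("no data rows in ", path))
  body <- lines[idx]
  sep_re <- switch(dialect,
                   auto = "[,\t ]+",
                   comma = ",",
                   tab = "\t",
                   whitespace = "[\t ]+")
  wn <- numeric(length(body)); it <- numeric(length(body))
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(body[i]), sep_re)[[1]]
    tok <- tok[nzchar(tok)]
    vals <- suppressWarnings(as.numeric(tok))
    bad <- is.na(vals[1:2]) & !is.nan(vals[1:2])   # NaN parses but is invalid
    if (length(vals) < 2 || any(bad))
      parse_error(sprintf("malformed row at line %d of %s: '%s'",
                          idx[i], path, body[i]))
    if (!all(is.finite(vals[1:2])))
      validation_error(sprintf("non-finite value at line %d of %s", idx[i], path))
    wn[i] <- vals[1]; it[i] <- vals[2]
  }
  ord <- order(wn)  # stable
  wn <- wn[ord]; it <- it[ord]
  if (anyDuplicated(wn))
    validation_error(paste0("duplicated wavenumbers in ", path))
  spectrum(wn, it, meta = list(source = path))
}

#' Write a spectrum to two-column delimited text
#'
#' Metadata are written as `# key: value` comment lines; data rows are
#' whitespace-separated with 17 significant digits so that
#' `read_spectrum(write_spectrum(s))` reproduces the spectrum exactly.
#'
#' @param s a [spectrum].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  hdr <- "# ramanclean spectrum v1"
  meta <- if (length(s$meta))
    sprintf("# %s: %s", names(s$meta), vapply(s$meta, function(v) paste(format(v), collapse = " "), character(1)))
  else character(0)
  rows <- paste(fmt_dbl(s$axis), fmt_dbl(s$intensity))
  ok <- tryCatch({ writeLines(c(hdr, meta, rows), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_rc(paste0("cannot write to ", path), "ramanclean_io_error")
  invisible(path)
}

#' Resample a spectrum onto a fixed linear grid
#'
#' Linear interpolation onto `grid_len` equally spaced wavenumbers on
#' `[range[1], range[2]]`. Grid points outside the native axis span are
#' filled with the nearest edge intensity. The original axis range is
#' recorded in `meta$orig_range` so the operation can be inverted.
#'
#' @param s a [spectrum].
#' @param grid_len positive integer, number of grid points.
#' @param range length-2 numeric `(lo, hi)` in cm^-1; defaults to the
#'   spectrum's own span.
#' @return A [spectrum] on the new grid.
#' @export
resample_to_grid <- function(s, grid_len, range = NULL) {
  stopifnot(inherits(s, "spectrum"), is_count(grid_len))
  if (is.null(range)) range <- c(s$axis[1], s$axis[length(s$axis)])
  lo <- range[1]; hi <- range[2]
  if (!(lo < hi)) range_error("range must satisfy lo < hi")
  if (hi < s$axis[1] || lo > s$axis[length(s$axis)])
    range_error(sprintf("grid range [%g, %g] does not overlap spectrum span [%g, %g]",
                        lo, hi, s$axis[1], s$axis[length(s$axis)]))
  grid <- seq(lo, hi, length.out = grid_len)
  out <- stats::approx(s$axis, s$intensity, xout = grid, method = "linear",
                       rule = 2, ties = "ordered")$y
  meta <- s$meta
  meta$orig_range <- c(s$axis[1], s$axis[length(s$axis)])
  spectrum(grid, out, meta = meta)
}
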