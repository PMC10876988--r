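#' Construct a hyperspectral cube
#'
#' An H x W image whose every pixel holds a full spectrum on a shared
#' wavenumber axis (an H x W x L array), with optional signal/background
#' masks for contrast metrics.
#'
#' @param axis wavenumber axis (length L, strictly increasing).
#' @param intensities H x W x L numeric array.
#' @param signal_mask,background_mask optional H x W logical matrices.
#' @return object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(axis, intensities,
                               signal_mask = NULL, background_mask = NULL) {
  d <- dim(intensities)
  if (length(d) != 3) validation_error("intensities must be an H x W x L array")
  if (d[3] != length(axis))
    validation_error("third array dimension must match the axis length")
  if (any(diff(axis) <= 0)) validation_error("axis must be strictly increasing")
  for (m in list(signal_mask, background_mask))
    if (!is.null(m) && !all(dim(m) == d[1:2]))
      validation_error("mask dimensions must be H x W")
  structure(list(axis = as.numeric(axis), intensities = intensities,
                 signal_mask = signal_mask, background_mask = background_mask),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<hyperspectral_cube> %d x %d pixels x %d wavenumbers (%.6g..%.6g cm^-1)\n",
              d[1], d[2], d[3], min(x$axis), max(x$axis)))
  invisible(x)
}

#' @export
dim.hyperspectral_cube <- function(x) dim(x$intensities)

# pixel spectra as (H*W) x L matrix, row-major pixel order (row i, col j) ->
# row (i-1)*W + j
cube_pixels <- function(cube) {
  d <- dim(cube$intensities)
  m <- matrix(aperm(cube$intensities, c(2, 1, 3)), d[1] * d[2], d[3])
  m
}

cube_from_pixels <- function(cube, m) {
  d <- dim(cube$intensities)
  arr <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  hyperspectral_cube(cube$axis, arr, cube$signal_mask, cube$background_mask)
}

#' Write / read a hyperspectral cube as versioned plain text
#'
#' `ramancube v1` layout: a JSON header line with dimensions, the axis line,
#' then H*W lines of L intensities in row-major pixel order. Floats use 17
#' significant digits (bitwise round trip).
#'
#' @param cube a [hyperspectral_cube]. @param path file path.
#' @return `path` (write) or the cube (read).
#' @export
write_cube <- function(cube, path) {
  d <- dim(cube$intensities)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- list(H = d[1], W = d[2], L = d[3],
              has_masks = !is.null(cube$signal_mask))
  writeLines(c("# ramancube v1",
               paste0("# dims ", jsonlite::toJSON(hdr, auto_unbox = TRUE)),
               "# axis", fmt_row(cube$axis), "# pixels"), con)
  writeLines(apply(cube_pixels(cube), 1, fmt_row), con)
  if (!is.null(cube$signal_mask)) {
    writeLines("# signal_mask", con)
    writeLines(apply(cube$signal_mask * 1, 1, fmt_row), con)
    writeLines("# background_mask", con)
    writeLines(apply(cube$background_mask * 1, 1, fmt_row), con)
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "# ramancube v1")
    parse_error("not a ramancube v1 container")
  hdr <- jsonlite::fromJSON(sub("^# dims ", "", lines[2]))
  num_row <- function(s) as.numeric(strsplit(s, " ", fixed = TRUE)[[1]])
  axis <- num_row(lines[4])
  if (length(axis) != hdr$L) parse_error("axis length does not match header")
  stopifnot(lines[5] == "# pixels")
  px_lines <- lines[5 + seq_len(hdr$H * hdr$W)]
  if (length(px_lines) != hdr$H * hdr$W || anyNA(px_lines))
    parse_error("pixel count does not match header H*W")
  m <- do.call(rbind, lapply(px_lines, num_row))
  if (ncol(m) != hdr$L) parse_error("pixel row length does not match axis")
  arr <- aperm(array(m, c(hdr$W, hdr$H, hdr$L)), c(2, 1, 3))
  sm <- bm <- NULL
  if (isTRUE(hdr$has_masks)) {
    off <- 5 + hdr$H * hdr$W
    sm <- do.call(rbind, lapply(lines[off + 1 + seq_len(hdr$H)], num_row)) > 0
    bm <- do.call(rbind, lapply(lines[off + 2 + hdr$H + seq_len(hdr$H)], num_row)) > 0
  }
  hyperspectral_cube(axis, arr, sm, bm)
}

#' Preprocess every pixel spectrum of a cube
#'
#' Applies a trained preprocessor (fast batched path) or any
#' `function(spectrum) -> spectrum` to each pixel independently, in
#' deterministic row-major order. The axis is preserved.
#'
#' @param cube a [hyperspectral_cube].
#' @param preprocessor a `trained_preprocessor` or a function.
#' @return the preprocessed [hyperspectral_cube].
#' @export
preprocess_cube <- function(cube, preprocessor) {
  m <- cube_pixels(cube)
  if (inherits(preprocessor, "trained_preprocessor")) {
    L <- preprocessor$cfg$grid_len
    rg <- range(preprocessor$axis)
    grid <- preprocessor$axis
    # resample all pixels onto the model grid, preprocess, map back
    res <- t(apply(m, 1, function(v)
      stats::approx(cube$axis, v, xout = grid, rule = 2)$y))
    out <- forward_preprocess(res, preprocessor)
    back <- t(apply(out, 1, function(v)
      stats::approx(grid, v, xout = cube$axis, rule = 2)$y))
    cube_from_pixels(cube, back)
  } else if (is.function(preprocessor)) {
    out <- m
    for (i in seq_len(nrow(m))) {
      s <- preprocessor(spectrum(cube$axis, m[i, ]))
      out[i, ] <- s$intensity
    }
    cube_from_pixels(cube, out)
  } else validation_error("preprocessor must be a trained model or a function")
}

#' Per-pixel spectral SNR map
#' @param cube a [hyperspectral_cube].
#' @param ... passed to [snr_spec()].
#' @return H x W numeric matrix of SNR (dB).
#' @export
cube_snr_map <- function(cube, ...) {
  m <- cube_pixels(cube)
  d <- dim(cube$intensities)
  v <- apply(m, 1, function(row) snr_spec(spectrum(cube$axis, row), ...))
  matrix(v, d[1], d[2], byrow = TRUE)
}

#' Mean spectrum of the k highest-SNR pixels
#'
#' Pixels are ranked by [snr_spec()]; the `k` best are averaged. With
#' `k = H*W` this is the plain mean spectrum.
#'
#' @param cube a [hyperspectral_cube].
#' @param k number of pixels (default `min(10000, H*W)`).
#' @return a [spectrum].
#' @export
top_k_mean_spectrum <- function(cube, k = NULL) {
  d <- dim(cube$intensities)
  npx <- d[1] * d[2]
  if (is.null(k)) k <- min(10000, npx)
  if (k < 1 || k > npx) validation_error("k must be in 1..H*W")
  snr <- as.vector(t(cube_snr_map(cube)))   # row-major pixel order
  m <- cube_pixels(cube)
  sel <- order(snr, decreasing = TRUE)[seq_len(k)]
  spectrum(cube$axis, colMeans(m[sel, , drop = FALSE]),
           meta = list(top_k = k))
}

#' Chemical channel map at a Raman shift
#'
#' Per-pixel intensity at the axis point nearest to `shift` (ties broken
#' toward the lower index); with `band > 0`, the mean over all axis points
#' within `shift +/- band`.
#'
#' @param cube a [hyperspectral_cube].
#' @param shift Raman shift (cm^-1), within the axis span.
#' @param band half-width (cm^-1) for band averaging (default 0).
#' @param scale min-max scale the map to [0, 1].
#' @return H x W numeric matrix; attribute `scaled` records the choice.
#' @export
channel_map <- function(cube, shift, band = 0, scale = FALSE) {
  ax <- cube$axis
  if (shift < ax[1] || shift > ax[length(ax)])
    range_error(sprintf("shift %g outside axis span [%g, %g]",
                        shift, ax[1], ax[length(ax)]))
  if (band > 0) {
    cols <- which(ax >= shift - band & ax <= shift + band)
    img <- apply(cube$intensities[, , cols, drop = FALSE], c(1, 2), mean)
  } else {
    idx <- which.min(abs(ax - shift))   # first (lower) index wins ties
    img <- cube$intensities[, , idx]
  }
  if (scale) img <- minmax01(img)
  attr(img, "scaled") <- scale
  img
}

minmax01 <- function(img) {
  rg <- range(img)
  if (rg[2] > rg[1]) (img - rg[1]) / (rg[2] - rg[1]) else img * 0
}

#' Merge three channel maps into an RGB image
#'
#' Each map is min-max scaled independently (a constant map becomes all
#' zeros) and stacked in R, G, B argument order.
#'
#' @param r,g,b H x W matrices.
#' @return H x W x 3 array with values in [0, 1].
#' @export
merge_rgb <- function(r, g, b) {
  if (!all(dim(r) == dim(g)) || !all(dim(r) == dim(b)))
    validation_error("channel map shapes differ")
  out <- array(0, c(dim(r), 3))
  out[, , 1] <- minmax01(r); out[, , 2] <- minmax01(g); out[, , 3] <- minmax01(b)
  out
}

#' PCA feature maps of a cube
#'
#' Pixels are observations and wavenumbers variables (mean-centered).
#' Component score images are min-max scaled; explained variance fractions
#' are non-increasing.
#'
#' @param cube a [hyperspectral_cube].
#' @param n_components number of components (default 3).
#' @return list with `maps` (list of H x W matrices) and
#'   `explained_variance` (fractions).
#' @export
pca_feature_maps <- function(cube, n_components = 3) {
  d <- dim(cube$intensities)
  if (n_components > d[3])
    validation_error("n_components exceeds the number of wavenumbers")
  if (d[1] * d[2] < n_components)
    validation_error("fewer pixels than components")
  m <- cube_pixels(cube)
  if (max(abs(sweep(m, 2, colMeans(m)))) == 0)
    validation_error("degenerate (constant) cube")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_components)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  maps <- lapply(seq_len(n_components), function(i)
    minmax01(matrix(pc$x[, i], d[1], d[2], byrow = TRUE)))
  list(maps = maps, explained_variance = ev[seq_len(n_components)])
}

#' Simulate a hyperspectral cell-imaging cube
#'
#' Elliptical "cell" regions carry distinct Raman peak sets: lipid-like
#' cells are dominated by the 2850 cm^-1 CH2 band, protein-like cells by the
#' 2928 cm^-1 CH3 band; both carry fingerprint-region peaks. A smooth random
#' baseline field (spatially modulated) and i.i.d. Gaussian noise are added.
#' Ground-truth signal/background masks are attached for contrast metrics.
#' The silent zone (1800-2800 cm^-1) carries no peaks, so with zero noise
#' and baseline its intensities are exactly zero.
#'
#' @param height,width image size in pixels.
#' @param grid_len spectral length (default 512).
#' @param grid_range axis span (default 400-3200 cm^-1).
#' @param n_cells number of elliptical cells.
#' @param noise_sd Gaussian noise SD (relative to unit peak height).
#' @param baseline_amp baseline field amplitude (0 disables).
#' @param seed RNG seed.
#' @return a [hyperspectral_cube] with masks.
#' @export
simulate_cube <- function(height = 32, width = 32, grid_len = 512,
                          grid_range = c(400, 3200), n_cells = 4,
                          noise_sd = 0.05, baseline_amp = 1, seed = 1) {
  set.seed(seed)
  ax <- seq(grid_range[1], grid_range[2], length.out = grid_len)
  lor <- function(center_cm, width_cm, amp) {
    amp * width_cm^2 / ((ax - center_cm)^2 + width_cm^2)
  }
  # spectral templates; band intensity is truncated inside the silent zone so
  # a noise- and baseline-free pixel is exactly zero there
  silent <- ax >= 1800 & ax < 2800
  lipid <- lor(2850, 15, 1) + lor(2928, 18, 0.45) + lor(1301, 10, 0.35) +
    lor(1440, 12, 0.4) + lor(1129, 8, 0.25)
  protein <- lor(2928, 18, 1) + lor(2850, 15, 0.3) + lor(1002, 6, 0.4) +
    lor(1658, 12, 0.35) + lor(1224, 9, 0.25)
  lipid[silent] <- 0
  protein[silent] <- 0
  sig_mask <- matrix(FALSE, height, width)
  amp_map <- matrix(0, height, width)
  kind_map <- matrix(0L, height, width)
  for (cell in seq_len(n_cells)) {
    cx <- stats::runif(1, 0.15, 0.85) * width
    cy <- stats::runif(1, 0.15, 0.85) * height
    rx <- stats::runif(1, 0.08, 0.2) * width
    ry <- stats::runif(1, 0.08, 0.2) * height
    kind <- if (cell %% 2 == 1) 1L else 2L
    for (i in seq_len(height)) for (j in seq_len(width)) {
      if (((j - cx) / rx)^2 + ((i - cy) / ry)^2 <= 1) {
        sig_mask[i, j] <- TRUE
        amp_map[i, j] <- amp_map[i, j] + stats::runif(1, 0.7, 1.3)
        kind_map[i, j] <- kind
      }
    }
  }
  arr <- array(0, c(height, width, grid_len))
  base_shape <- if (baseline_amp > 0) random_baseline(grid_len) else numeric(grid_len)
  bl_field <- matrix(stats::runif(height * width, 0.5, 1), height, width)
  for (i in seq_len(height)) for (j in seq_len(width)) {
    spec <- numeric(grid_len)
    if (sig_mask[i, j])
      spec <- amp_map[i, j] * (if (kind_map[i, j] == 1L) lipid else protein)
    if (baseline_amp > 0)
      spec <- spec + baseline_amp * bl_field[i, j] * base_shape
    if (noise_sd > 0)
      spec <- spec + stats::rnorm(grid_len, sd = noise_sd)
    arr[i, j, ] <- spec
  }
  hyperspectral_cube(ax, arr, signal_mask = sig_mask,
                     background_mask = !sig_mask)
}

#' Plot a channel map
#' @param img H x W matrix (e.g. from [channel_map()]).
#' @param ... passed to [graphics::image()].
#' @export
plot_channel_map <- function(img, ...) {
  graphics::image(t(img[nrow(img):1, , drop = FALSE]), axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(img)
}
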