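#' Assemble the spatiotemporal 2D map
#'
#' Stacks the per-ROI radial-distension time signals side by side into a
#' time-by-position matrix (one column per ROI), the pseudocolor "M-mode
#' like" map of wall motion; the ECG trace is carried along for rendering
#' alignment.
#'
#' @param signals `radial_signals` matrix from [extract_radial_signals()]
#'   (or any `n_frames x R` numeric matrix).
#' @param frame_rate Frames per second.
#' @param ecg Optional `ecg_trace`.
#' @return Object of class `spatiotemporal_map` with elements `values`,
#'   `frame_rate`, `ecg`.
#' @export
build_spatiotemporal <- function(signals, frame_rate = 30, ecg = NULL) {
  v <- unclass(signals)
  stopifnot(is.matrix(v), nrow(v) >= 1, ncol(v) >= 1)
  if (!is.null(ecg)) stopifnot(inherits(ecg, "ecg_trace"),
                               length(ecg$samples) == nrow(v))
  structure(list(values = v, frame_rate = frame_rate, ecg = ecg),
            class = "spatiotemporal_map")
}

#' Transform a spatiotemporal map into a spatiospectral map
#'
#' Replaces each ROI's time signal (map column) by the magnitude of its
#' Fourier spectrum: the column mean is removed, the discrete Fourier
#' transform applied, and the one-sided magnitudes for bins
#' `1..floor(n/2)` kept, normalized by the number of frames. The frequency
#' axis is normalized so that 1 is the Nyquist frequency.
#'
#' @param st_map A [build_spatiotemporal()] map (or a plain matrix).
#' @return Object of class `spatiospectral_map` with elements `values`
#'   (`F x R` nonnegative matrix), `freq_axis` (strictly increasing in
#'   `(0, 1]`) and `frame_rate`.
#' @export
build_spatiospectral <- function(st_map) {
  v <- if (inherits(st_map, "spatiotemporal_map")) st_map$values
       else unclass(st_map)
  stopifnot(is.matrix(v))
  n <- nrow(v)
  if (n < 8) stop("at least 8 frames are needed for the spectral map",
                  call. = FALSE)
  centered <- sweep(v, 2, colMeans(v))
  X <- mvfft(centered)
  Fbins <- n %/% 2
  mag <- Mod(X[2:(Fbins + 1), , drop = FALSE]) / n
  freq <- (1:Fbins) / (n / 2)
  fr <- if (inherits(st_map, "spatiotemporal_map")) st_map$frame_rate else NA
  structure(list(values = mag, freq_axis = freq, frame_rate = fr),
            class = "spatiospectral_map")
}

#' @export
print.spatiotemporal_map <- function(x, ...) {
  cat(sprintf("<spatiotemporal_map> %d frames x %d ROIs @ %g fps%s\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              if (is.null(x$ecg)) "" else " (with ECG)"))
  invisible(x)
}

#' @export
print.spatiospectral_map <- function(x, ...) {
  cat(sprintf("<spatiospectral_map> %d frequency bins x %d ROIs, f in (0, 1]\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
plot.spatiotemporal_map <- function(x, main = "Spatiotemporal map", ...) {
  tm <- (seq_len(nrow(x$values)) - 1) / x$frame_rate
  image(x = tm, y = seq_len(ncol(x$values)), z = x$values,
        col = hcl.colors(128, "viridis"),
        xlab = "time [s]", ylab = "ROI", main = main, ...)
  invisible(x)
}

#' @export
plot.spatiospectral_map <- function(x, main = "Spatiospectral map", ...) {
  image(x = x$freq_axis, y = seq_len(ncol(x$values)), z = x$values,
        col = hcl.colors(128, "viridis"),
        xlab = "normalized frequency", ylab = "ROI", main = main, ...)
  invisible(x)
}

#' Render a map to a PNG file
#'
#' Writes a min-max normalized pseudocolor (or grayscale) image of a
#' spatiotemporal or spatiospectral map. When the map carries an ECG trace,
#' a thin synchronized ECG strip is appended along the time axis.
#'
#' @param map A `spatiotemporal_map`, `spatiospectral_map` or plain matrix.
#' @param file Output PNG path.
#' @param palette `"viridis"` for pseudocolor or `"gray"` for grayscale.
#' @param ecg_width Width in pixels of the appended ECG strip.
#' @return The file path, invisibly.
#' @export
render_map <- function(map, file, palette = c("viridis", "gray"),
                       ecg_width = 24L) {
  palette <- match.arg(palette)
  v <- if (is.matrix(map)) map else map$values
  if (any(!is.finite(v))) stop("map contains non-finite values", call. = FALSE)
  rng <- range(v)
  norm <- if (diff(rng) > 0) (v - rng[1]) / diff(rng)
          else matrix(0.5, nrow(v), ncol(v))
  ecg <- if (!is.matrix(map)) map$ecg else NULL
  if (!is.null(ecg) && length(ecg$samples) == nrow(norm)) {
    strip <- matrix(0, nrow(norm), ecg_width)
    es <- ecg$samples
    pos <- 1L + round((es - min(es)) / max(diff(range(es)), 1e-12) *
                        (ecg_width - 1L))
    strip[cbind(seq_len(nrow(strip)), pos)] <- 1
    norm <- cbind(norm, 0.5, strip)
  }
  img <- if (palette == "gray") {
    norm
  } else {
    cols <- hcl.colors(256, "viridis")
    rgb <- col2rgb(cols) / 255
    idx <- 1L + floor(norm * 255.999)
    array(c(rgb[1, idx], rgb[2, idx], rgb[3, idx]), dim = c(dim(norm), 3))
  }
  ok <- try(png::writePNG(img, target = file), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop_cartwave(sprintf("failed to write '%s'", file), "cartwave_file_error")
  invisible(file)
}
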