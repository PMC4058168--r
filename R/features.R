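#' Mean spectrum across ROIs
#'
#' Averages the columns of a spatiospectral map (the spectra of all ROIs)
#' into a single spectral curve, with its normalized area (per-bin mean).
#'
#' @param ss_map A [build_spatiospectral()] map.
#' @return List with `curve` (length `F`) and `area`.
#' @export
mean_spectrum <- function(ss_map) {
  v <- ss_map$values
  stopifnot(is.matrix(v))
  if (ncol(v) < 1 || nrow(v) < 1)
    stop("spatiospectral map is empty", call. = FALSE)
  curve <- rowMeans(v)
  list(curve = curve, area = mean(curve))
}

#' FT-squared homogeneity feature
#'
#' Applies a second Fourier transform to the ROI-averaged spectral curve
#' ("computing the FT of the average of FTs") and reports the normalized
#' area under the resulting magnitude curve. Spectrally concentrated,
#' homogeneous wall motion produces a peaky mean spectrum and hence a large
#' feature value; broadband, heterogeneous motion flattens it.
#'
#' @param spectrum Numeric mean-spectrum vector (length `F >= 4`).
#' @param kappa Fixed reporting scale applied to the area (default 100).
#' @return List with `curve` (one-sided magnitudes of the mean-removed
#'   spectrum, normalized by `F`) and `area`
#'   (`kappa * (2 / F) * sum(curve)`).
#' @export
ft2_feature <- function(spectrum, kappa = 100) {
  Fb <- length(spectrum)
  if (Fb < 4) stop("spectrum too short for the FT2 feature", call. = FALSE)
  y <- spectrum - mean(spectrum)
  X <- fft(y)
  half <- Fb %/% 2
  curve <- Mod(X[2:(half + 1)]) / Fb
  list(curve = curve, area = kappa * (2 / Fb) * sum(curve))
}

#' Across-ROI standard deviation of the spectra
#'
#' Per frequency bin (map row), the population standard deviation across
#' ROIs. It is identically zero iff all ROI spectra coincide — the
#' operational meaning of spectrally homogeneous wall motion.
#'
#' @param ss_map A [build_spatiospectral()] map.
#' @return Numeric vector of length `F`.
#' @export
std_curve <- function(ss_map) {
  v <- ss_map$values
  stopifnot(is.matrix(v))
  if (ncol(v) < 2)
    stop("at least 2 ROIs are needed for the spectral standard deviation",
         call. = FALSE)
  mu <- rowMeans(v)
  sqrt(pmax(rowMeans(v^2) - mu^2, 0))
}

#' Upper envelope of a curve
#'
#' Max-normalizes the curve (an all-zero curve passes through unchanged;
#' curves whose maximum is below `zero_tol` are treated as zero), then
#' linearly interpolates through its strict local maxima with both endpoints
#' always included as knots, and finally enforces dominance by an
#' elementwise maximum with the normalized curve.
#'
#' @param curve Nonnegative numeric vector (length >= 3).
#' @param zero_tol Absolute tolerance below which the curve is considered
#'   zero.
#' @return Numeric envelope vector, `>=` the normalized curve everywhere.
#' @export
#' @examples
#' spectral_envelope(c(0, 1, 0, 1, 0))  # 0 1 1 1 0
spectral_envelope <- function(curve, zero_tol = 1e-12) {
  n <- length(curve)
  stopifnot(n >= 3)
  m <- max(curve)
  if (m <= zero_tol) return(curve * 0)
  y <- curve / m
  interior <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  knots <- sort(unique(c(1L, interior, n)))
  env <- approx(knots, y[knots], xout = seq_len(n))$y
  pmax(env, y)
}

#' Ramp-weighted envelope area feature
#'
#' Weighted, normalized area under the envelope of the across-ROI spectral
#' standard-deviation curve, with a ramp weight `w(f) = f` that emphasizes
#' high-frequency heterogeneity, reported on a natural-log scale:
#' `log(mean(f * envelope) + eps)`. Large values indicate spectrally
#' heterogeneous (pathological-like) motion along the wall; a zero envelope
#' yields the degenerate floor `log(eps)`.
#'
#' @param envelope Envelope vector from [spectral_envelope()].
#' @param freq_axis Normalized frequency axis of the same length.
#' @param eps Stabilizing offset inside the logarithm.
#' @return Scalar feature value.
#' @export
ramp_feature <- function(envelope, freq_axis, eps = 1e-6) {
  stopifnot(length(envelope) == length(freq_axis))
  log(mean(freq_axis * envelope) + eps)
}

#' Band-limited spectral area measures
#'
#' The two earlier-generation screening measures: normalized sums (per-bin
#' means) of the mean spectrum over the normalized-frequency bands
#' `0 < f <= 1` and `0 < f <= 0.15`. Computed here on the ROI-averaged
#' spectrum.
#'
#' @param spectrum Mean-spectrum vector.
#' @param freq_axis Normalized frequency axis (Nyquist = 1).
#' @return List with `area_full` and `area_low`.
#' @export
legacy_spectral_areas <- function(spectrum, freq_axis) {
  stopifnot(length(spectrum) == length(freq_axis))
  low <- freq_axis <= 0.15
  if (!any(low))
    stop("frequency axis has no bins at or below 0.15", call. = FALSE)
  list(area_full = mean(spectrum[freq_axis <= 1]),
       area_low = mean(spectrum[low]))
}

#' Compute all spectral homogeneity features of a case
#'
#' Bundles the full feature stage: ROI-averaged spectrum and its area, the
#' FT-squared curve and area, the across-ROI standard-deviation curve, its
#' envelope and the ramp-weighted envelope feature, plus the two legacy
#' band-limited spectral areas.
#'
#' @param ss_map A [build_spatiospectral()] map with at least 2 ROIs.
#' @param kappa Reporting scale for the FT2 area (see [ft2_feature()]).
#' @param eps Log offset for the ramp feature (see [ramp_feature()]).
#' @return An object of class `case_features`: list with `mean_spectrum`,
#'   `mean_spectrum_area`, `ft2_curve`, `ft2_area`, `std_curve`,
#'   `envelope`, `ramp_feature`, `legacy_area_full`, `legacy_area_low` and
#'   `freq_axis`.
#' @export
case_features <- function(ss_map, kappa = 100, eps = 1e-6) {
  stopifnot(inherits(ss_map, "spatiospectral_map"))
  ms <- mean_spectrum(ss_map)
  ft2 <- ft2_feature(ms$curve, kappa = kappa)
  sc <- std_curve(ss_map)
  env <- spectral_envelope(sc)
  rf <- ramp_feature(env, ss_map$freq_axis, eps = eps)
  leg <- legacy_spectral_areas(ms$curve, ss_map$freq_axis)
  structure(list(mean_spectrum = ms$curve,
                 mean_spectrum_area = ms$area,
                 ft2_curve = ft2$curve,
                 ft2_area = ft2$area,
                 std_curve = sc,
                 envelope = env,
                 ramp_feature = rf,
                 legacy_area_full = leg$area_full,
                 legacy_area_low = leg$area_low,
                 freq_axis = ss_map$freq_axis),
            class = "case_features")
}

#' @export
print.case_features <- function(x, ...) {
  cat("<case_features>\n")
  cat(sprintf("  ft2_area           %8.3f\n", x$ft2_area))
  cat(sprintf("  ramp_feature       %8.3f\n", x$ramp_feature))
  cat(sprintf("  mean_spectrum_area %8.4f\n", x$mean_spectrum_area))
  cat(sprintf("  legacy areas       %8.4f (f<=1)  %8.4f (f<=0.15)\n",
              x$legacy_area_full, x$legacy_area_low))
  invisible(x)
}
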