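#' Configuration for the synthetic pulsating-vessel phantom
#'
#' Builds a validated configuration for [generate_phantom()]. The phantom
#' renders a horizontal bright vessel-wall band over a dark lumen embedded in
#' speckle-textured tissue; the inner (lumen-facing) boundary of the band
#' performs class-specific radial wave motion travelling along the wall,
#' synchronized to a schematic ECG.
#'
#' Category presets for the motion phenomenology:
#' \describe{
#'   \item{young}{three damped longitudinal right-left oscillations per
#'     cardiac cycle, identical across cycles, homogeneous along the wall
#'     (`heterogeneity = 0`, `irregularity = 0`).}
#'   \item{elderly}{slow, strongly damped double oscillation, weak and
#'     near-regular (`heterogeneity = 0.5`, `irregularity = 0.1`,
#'     `amplitude = 1.2` px — elderly walls distend markedly less).}
#'   \item{cad}{double oscillation with cycle-to-cycle phase/amplitude
#'     jitter and locally broadband, heterogeneous motion along the wall
#'     (`heterogeneity = 1`, `irregularity = 0.5`).}
#' }
#'
#' @param category Phantom class: `"young"`, `"elderly"` or `"cad"`.
#' @param height,width Frame size in pixels.
#' @param n_frames Number of frames; must be at least `2 * n_cycles`.
#' @param frame_rate Frames per second.
#' @param n_cycles Cardiac cycles spanned by the sequence.
#' @param wall_row Baseline inner-boundary row (continuous row units; the
#'   value `v` denotes the interface between pixel rows `v` and `v + 1`).
#'   `NULL` places it at the same relative depth as the default geometry
#'   (row 60 of a 128-row frame).
#' @param wall_thickness Wall band thickness in pixels; `NULL` scales the
#'   default geometry (12 px of a 128-row frame) to `height`.
#' @param lumen_intensity,wall_intensity,tissue_intensity Mean gray levels
#'   in `[0, 1]` of the three regions.
#' @param speckle_scale Strength of the multiplicative speckle field applied
#'   to wall and tissue (0 disables it).
#' @param amplitude Peak radial displacement in pixels; `NULL` uses the
#'   category preset (2 px, except 1.2 px for `elderly`).
#' @param wave_speed Longitudinal phase velocity in pixels per frame.
#' @param heterogeneity Nonnegative scalar controlling amplitude and local
#'   bandwidth variation along the wall; `NULL` uses the category preset.
#' @param irregularity Nonnegative scalar controlling cycle-to-cycle
#'   phase/amplitude jitter; `NULL` uses the category preset.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical phantoms.
#' @return An object of class `phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config("young", seed = 1)
#' cfg$amplitude
phantom_config <- function(category = c("young", "elderly", "cad"),
                           height = 128L, width = 256L,
                           n_frames = 120L, frame_rate = 30,
                           n_cycles = 3L,
                           wall_row = NULL, wall_thickness = NULL,
                           lumen_intensity = 0.1, wall_intensity = 0.9,
                           tissue_intensity = 0.5,
                           speckle_scale = 0.05,
                           amplitude = NULL, wave_speed = 8,
                           heterogeneity = NULL, irregularity = NULL,
                           seed = 1L) {
  category <- match.arg(category)
  preset <- switch(category,
    young   = c(het = 0,   irr = 0,   amp = 2),
    elderly = c(het = 0.5, irr = 0.1, amp = 1.2),
    cad     = c(het = 1,   irr = 0.5, amp = 2))
  if (is.null(heterogeneity)) heterogeneity <- unname(preset["het"])
  if (is.null(irregularity))  irregularity  <- unname(preset["irr"])
  if (is.null(amplitude))     amplitude     <- unname(preset["amp"])
  if (is.null(wall_row))       wall_row       <- round(height * 60 / 128)
  if (is.null(wall_thickness)) wall_thickness <- max(3, round(height * 12 / 128))
  cfg <- list(category = category,
              height = as.integer(height), width = as.integer(width),
              n_frames = as.integer(n_frames), frame_rate = frame_rate,
              n_cycles = as.integer(n_cycles),
              wall_row = wall_row, wall_thickness = wall_thickness,
              lumen_intensity = lumen_intensity,
              wall_intensity = wall_intensity,
              tissue_intensity = tissue_intensity,
              speckle_scale = speckle_scale,
              amplitude = amplitude, wave_speed = wave_speed,
              heterogeneity = heterogeneity, irregularity = irregularity,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (cfg$n_cycles < 1L)
    stop("`n_cycles` must be at least 1", call. = FALSE)
  if (cfg$n_frames < 2L * cfg$n_cycles)
    stop("`n_frames` must be at least 2 * n_cycles", call. = FALSE)
  ints <- c(cfg$lumen_intensity, cfg$wall_intensity, cfg$tissue_intensity)
  if (any(ints < 0) || any(ints > 1))
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (cfg$wall_row + cfg$wall_thickness >= cfg$height)
    stop("`wall_row + wall_thickness` must be smaller than `height`",
         call. = FALSE)
  if (cfg$heterogeneity < 0 || cfg$irregularity < 0)
    stop("`heterogeneity` and `irregularity` must be nonnegative",
         call. = FALSE)
  if (cfg$amplitude < 0) stop("`amplitude` must be nonnegative", call. = FALSE)
  if (cfg$wave_speed <= 0) stop("`wave_speed` must be positive", call. = FALSE)
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %s, %dx%d px, %d frames @ %g fps, %d cycles\n",
              x$category, x$height, x$width, x$n_frames, x$frame_rate,
              x$n_cycles))
  cat(sprintf("  amplitude %g px, wave speed %g px/frame, heterogeneity %g, irregularity %g, seed %d\n",
              x$amplitude, x$wave_speed, x$heterogeneity, x$irregularity,
              x$seed))
  invisible(x)
}

#' Ultrasound sequence container
#'
#' A lightweight container for a stack of grayscale frames.
#'
#' @param frames Numeric array `height x width x n_frames` with values in
#'   `[0, 1]`.
#' @param frame_rate Frames per second.
#' @return An object of class `ultrasound_sequence` with elements `frames`
#'   and `frame_rate`.
#' @export
ultrasound_sequence <- function(frames, frame_rate = 30) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[3] < 8)
    stop("an ultrasound sequence needs at least 8 frames", call. = FALSE)
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "ultrasound_sequence")
}

#' @export
print.ultrasound_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ultrasound_sequence> %d frames of %dx%d px @ %g fps\n",
              d[3], d[1], d[2], x$frame_rate))
  invisible(x)
}

n_frames <- function(sequence) dim(sequence$frames)[3]

#' Generate a schematic ECG trace
#'
#' Produces a PQRST-like waveform with one sample per frame, repeated over
#' `n_cycles` uniform cardiac cycles. The R peak (cycle start) is the
#' per-cycle maximum, so downstream code can align wavy motion patterns to
#' heartbeats.
#'
#' @param n_frames Number of frames (samples).
#' @param n_cycles Number of cardiac cycles; must satisfy
#'   `n_frames >= 4 * n_cycles`.
#' @param frame_rate Frames per second.
#' @return An object of class `ecg_trace` with elements `samples` (length
#'   `n_frames`), `r_peaks` (1-based frame indices of cycle starts) and
#'   `frame_rate`.
#' @export
#' @examples
#' ecg <- generate_ecg(120, 3)
#' ecg$r_peaks
generate_ecg <- function(n_frames, n_cycles, frame_rate = 30) {
  if (n_cycles < 1) stop("`n_cycles` must be at least 1", call. = FALSE)
  if (n_frames < 4 * n_cycles)
    stop("`n_frames` must be at least 4 * n_cycles", call. = FALSE)
  Tf <- n_frames / n_cycles
  f <- seq_len(n_frames) - 1
  u <- (f %% Tf) / Tf
  d0 <- pmin(u, 1 - u)                    # distance to nearest R peak
  samples <- exp(-(d0 / 0.02)^2) +        # R
    0.12 * exp(-((u - 0.85) / 0.05)^2) +  # P (precedes next R)
    0.20 * exp(-((u - 0.25) / 0.07)^2) -  # T
    0.05 * exp(-((u - 0.05) / 0.02)^2)    # S dip
  r_peaks <- as.integer(floor(Tf * (seq_len(n_cycles) - 1))) + 1L
  structure(list(samples = samples, r_peaks = r_peaks,
                 frame_rate = frame_rate),
            class = "ecg_trace")
}

# Category-specific base oscillation parameters: number of right-left
# oscillations per cycle and exponential damping rate over the cycle.
waveform_pars <- function(category) {
  switch(category,
    young   = list(k = 3, damp = 1.0, jitter = 0),
    elderly = list(k = 2, damp = 2.5, jitter = 0.3),
    cad     = list(k = 2, damp = 0.8, jitter = 1),
    stop(sprintf("unknown category '%s'", category), call. = FALSE))
}

# Unit-peak normalization constant for sin(2*pi*k*u) * exp(-damp*u).
waveform_norm <- function(k, damp) {
  u <- seq(0, 1, length.out = 4096)
  max(abs(sin(2 * pi * k * u) * exp(-damp * u)))
}

#' Class-specific radial motion waveform
#'
#' Evaluates the noise-free radial displacement waveform of a phantom
#' category at times within a cardiac cycle. The young waveform makes three
#' damped oscillations per cycle (identical across cycles); the pathological
#' (cad) waveform makes two, with per-cycle random phase and amplitude jitter
#' proportional to `irregularity`; the elderly waveform makes two slow,
#' strongly damped oscillations with only a small fraction of the jitter.
#' Peak amplitude is 1 before any downstream scaling (exactly 1 when
#' `irregularity = 0`).
#'
#' @param category `"young"`, `"elderly"` or `"cad"`.
#' @param t Time(s) within the cycle, in `[0, period)`. Vectorized.
#' @param period Cycle duration in the units of `t`.
#' @param cycle_index Integer cycle number(s) (0-based), recycled against
#'   `t`; selects the per-cycle jitter draw.
#' @param irregularity Nonnegative jitter strength.
#' @param seed Integer seed for the per-cycle jitter draws.
#' @return Numeric vector of displacements (unit peak amplitude).
#' @export
#' @examples
#' u <- seq(0, 1, length.out = 200)
#' y <- motion_waveform("young", u)
motion_waveform <- function(category, t, period = 1, cycle_index = 0L,
                            irregularity = 0, seed = 1L) {
  pars <- waveform_pars(category)
  if (any(t < 0) || any(t >= period * (1 + 1e-12)))
    stop("`t` must lie within [0, period)", call. = FALSE)
  u <- t / period
  cyc <- as.integer(rep_len(cycle_index, length(u)))
  eff <- irregularity * pars$jitter
  nrm <- waveform_norm(pars$k, pars$damp)
  out <- numeric(length(u))
  for (ci in unique(cyc)) {
    jit <- cycle_jitter(ci, eff, seed)
    sel <- cyc == ci
    out[sel] <- jit$gain *
      sin(2 * pi * pars$k * u[sel] + jit$phase) *
      exp(-pars$damp * u[sel]) / nrm
  }
  out
}

# Deterministic per-cycle jitter draw: phase in +-(pi/2)*eff, gain in
# 1 +- 0.5*eff. Seed arithmetic kept well below 2^31.
cycle_jitter <- function(cycle_index, eff, seed) {
  if (eff <= 0) return(list(phase = 0, gain = 1))
  s <- (abs(as.integer(seed)) %% 1000003L) * 1009L + cycle_index * 13L + 7L
  with_seed(s, {
    list(phase = eff * runif(1, -1, 1) * pi / 2,
         gain = 1 + eff * runif(1, -0.5, 0.5))
  })
}

# Fixed smooth along-wall modulation profiles (x is a 0-based column offset
# scaled to [0, 1]). The amplitude profile is centered so heterogeneity
# spreads amplitudes without inflating total motion energy; the mixing
# profile trades base-waveform energy against a locally narrowband
# component whose frequency rises with heterogeneity (bandwidth variation).
het_amp_profile <- function(xs) 0.5 * sin(3 * pi * xs)
het_band_mix    <- function(xs) (1 + sin(4 * pi * xs + 2)) / 2
het_band_freq   <- function(xs, het) 4 + 6 * het * (1 + sin(3.4 * pi * xs + 4)) / 2
het_band_phase  <- function(xs) 2 * pi * xs

#' Generate a synthetic ultrasound sequence with ground truth
#'
#' Renders a pulsating-vessel phantom: dark lumen above a bright wall band in
#' speckled tissue. The inner boundary at column `x` and frame `f` is
#' `wall_row + amplitude * A(x) * (sqrt(1 - rho(x)^2) * s(u) + rho(x) * b(u, x))`
#' evaluated at the delayed cycle phase `u` of `f - x / wave_speed`, where
#' `s` is the category waveform of [motion_waveform()],
#' `A(x) = 1 + heterogeneity * h(x)` modulates amplitude along the wall with
#' a centered smooth profile `h`, and the mixing weight
#' `rho(x) = heterogeneity * g(x)` trades base-waveform energy against a
#' smooth locally narrowband component `b` whose frequency increases with
#' `heterogeneity` — heterogeneous walls vary in local bandwidth, not just
#' amplitude, without inflating total motion energy.
#' Sub-pixel boundaries are rendered by linear intensity interpolation at the
#' band edges. A multiplicative smoothed-uniform speckle field is applied to
#' wall and tissue; the field is scatterer-locked — sampled at wall-attached
#' coordinates inside the band and at rest coordinates in the tissue — so
#' the wall texture moves with the wall while the tissue texture is static,
#' as for real, tissue-bound speckle.
#'
#' @param config A [phantom_config()] object.
#' @return A list of class `cartwave_phantom` with elements
#'   \describe{
#'     \item{sequence}{an [ultrasound_sequence()].}
#'     \item{ecg}{an `ecg_trace` from [generate_ecg()].}
#'     \item{truth}{list with `wall_mask` (logical matrix at the temporal
#'       mean boundary position), `boundary` (`n_frames x width` matrix of
#'       continuous inner-boundary rows) and `radial` (the boundary with the
#'       per-column temporal mean removed).}
#'     \item{config}{the configuration.}
#'   }
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config("young", seed = 1))
#' dim(ph$sequence$frames)
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  validate_phantom_config(config)
  H <- config$height; W <- config$width
  Tn <- config$n_frames
  Tf <- Tn / config$n_cycles
  th <- config$wall_thickness
  xs <- (seq_len(W) - 1) / (W - 1)

  # --- true boundary grid -------------------------------------------------
  A <- 1 + config$heterogeneity * het_amp_profile(xs)
  rho <- pmin(config$heterogeneity * (0.55 + 0.45 * het_band_mix(xs)), 0.95)
  q <- het_band_freq(xs, config$heterogeneity)
  psi <- het_band_phase(xs)

  fgrid <- seq_len(Tn) - 1
  tau <- outer(fgrid, (seq_len(W) - 1) / config$wave_speed, "-")  # Tn x W
  u <- (tau %% Tf) / Tf
  cyc <- floor(tau / Tf) %% config$n_cycles
  s <- motion_waveform(config$category, as.vector(u), period = 1,
                       cycle_index = as.vector(cyc),
                       irregularity = config$irregularity,
                       seed = config$seed)
  s <- matrix(s, Tn, W)
  band <- sin(sweep(2 * pi * u, 2, q, "*") +
                matrix(psi, Tn, W, byrow = TRUE))
  mix <- sweep(s, 2, sqrt(1 - rho^2), "*") + sweep(band, 2, rho, "*")
  disp <- config$amplitude * sweep(mix, 2, A, "*")
  b <- config$wall_row + disp  # continuous boundary rows, Tn x W

  if (min(b) < 1 || max(b) + th > H - 1)
    stop("displacement pushes the wall boundary out of the frame",
         call. = FALSE)

  # --- render frames ------------------------------------------------------
  # The speckle field is scatterer-locked: one fixed smoothed-uniform field
  # is sampled at rest coordinates for static tissue and at wall-attached
  # (displaced) coordinates inside the wall band, so the wall texture rides
  # on the motion while the surrounding tissue stays static.
  lum <- config$lumen_intensity
  wal <- config$wall_intensity
  tis <- config$tissue_intensity
  rows <- seq_len(H)
  frames <- array(0, dim = c(H, W, Tn))
  Pv <- ceiling(max(abs(disp))) + 2L
  Hp <- H + 2L * Pv
  S0 <- NULL
  if (config$speckle_scale > 0) {
    S0 <- with_seed(config$seed, {
      U <- matrix(runif(Hp * W, -1, 1), Hp, W)
      1 + config$speckle_scale *
        box_sum(pad_symmetric(U, 1L), 3L, Hp, W) / 3
    })
  }
  colrep <- matrix(rep(seq_len(W), each = H), H, W)
  for (f in seq_len(Tn)) {
    bf <- b[f, ]
    rel <- outer(rows, bf, "-")
    top <- clamp01(rel)                           # lumen -> wall edge
    bot <- clamp01(rel - th)                      # wall -> tissue edge
    base <- lum + (wal - lum) * top - (wal - tis) * bot
    # double-line wall echo: bright intima and adventitia lines around a
    # darker media band, all riding on the wall motion
    base <- base - 0.45 * wal * sin(pi * clamp01(rel / th))^2 * (top - bot)
    if (!is.null(S0)) {
      wgt <- top - bot                             # wall coverage per pixel
      fs <- S0[cbind(rep(rows + Pv, W), as.vector(colrep))]
      fs <- matrix(fs, H, W)
      ridx <- outer(rows + Pv, bf - config$wall_row, "-")
      i0 <- floor(ridx); fr <- ridx - i0
      lin0 <- as.vector(i0) + (as.vector(colrep) - 1L) * Hp
      fw <- matrix(S0[lin0] * (1 - as.vector(fr)) +
                     S0[lin0 + 1L] * as.vector(fr), H, W)
      field <- (1 - wgt) * fs + wgt * fw
      spk <- base * field
      base <- ifelse(base > lum + 1e-9, spk, base)
    }
    frames[, , f] <- clamp01(base)
  }

  mb <- colMeans(b)
  wall_mask <- outer(rows, mb, function(i, m) (i - 0.5) >= m) &
    outer(rows, mb + th, function(i, m) (i - 0.5) < m)
  truth <- list(wall_mask = wall_mask,
                boundary = b,
                radial = sweep(b, 2, mb))
  structure(list(sequence = ultrasound_sequence(frames, config$frame_rate),
                 ecg = generate_ecg(Tn, config$n_cycles, config$frame_rate),
                 truth = truth,
                 config = config),
            class = "cartwave_phantom")
}

#' @export
print.cartwave_phantom <- function(x, ...) {
  print(x$config)
  invisible(x)
}
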