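#' Biphasic unipolar waveform template
#'
#' Evaluates a continuous-time template for a single unipolar activation at
#' times relative to the local activation instant. The default
#' `"gauss_deriv"` shape is the negative first derivative of a Gaussian,
#' scaled so the peak absolute amplitude equals `amplitude_uv`: a biphasic
#' R/S-like deflection, positive before the activation instant and negative
#' after, with exact odd symmetry about t = 0 (hence zero net area). The
#' width parameter is the Gaussian sigma in ms; the deflection is
#' effectively supported on about +/- 5 sigma.
#'
#' Evaluation is in continuous time, so sub-sample propagation delays are
#' represented exactly by the generator.
#'
#' @param t_ms numeric vector of times in ms relative to local activation.
#' @param shape template family; only `"gauss_deriv"` is built in.
#' @param amplitude_uv peak absolute amplitude in uV.
#' @param width_ms width parameter (Gaussian sigma) in ms, > 0.
#' @return Amplitudes in uV, same length as `t_ms`.
#'
#' @examples
#' unipolar_waveform(0)                      # 0 by odd symmetry
#' max(abs(unipolar_waveform(seq(-10, 10, 0.01))))  # ~1000 uV
#' @export
unipolar_waveform <- function(t_ms, shape = "gauss_deriv",
                              amplitude_uv = 1000, width_ms = 2) {
  if (width_ms <= 0) stop("configuration error: width_ms must be > 0")
  if (!identical(shape, "gauss_deriv")) {
    stop("configuration error: unknown waveform shape '", shape, "'")
  }
  # -d/dt exp(-t^2/2s^2) normalised to peak amplitude (peaks at t = -s)
  -amplitude_uv * (t_ms / width_ms) * exp(0.5 - t_ms^2 / (2 * width_ms^2))
}

#' Noise level for a target signal-to-noise ratio
#'
#' Returns the additive white-noise standard deviation giving a requested
#' SNR, with SNR defined conventionally on power:
#' `SNR(dB) = 10 log10(mean signal power over the analysis window /
#' noise variance)`. The signal is one activation of the unipolar template
#' inside a window of `window_ms`.
#'
#' @param snr_db target signal-to-noise ratio in dB.
#' @param amplitude_uv,width_ms,shape template, see [unipolar_waveform()].
#' @param window_ms analysis-window length over which signal power is
#'   averaged (default matches the 60 ms half-width beat window).
#' @return Noise standard deviation in uV.
#' @export
snr_noise_sd <- function(snr_db, amplitude_uv = 1000, width_ms = 2,
                         shape = "gauss_deriv", window_ms = 120) {
  t_ms <- seq(-window_ms / 2, window_ms / 2, by = width_ms / 50)
  w <- unipolar_waveform(t_ms, shape = shape, amplitude_uv = amplitude_uv,
                         width_ms = width_ms)
  sqrt(mean(w^2)) * 10^(-snr_db / 20)
}

#' Parameters for the synthetic wavefront generator
#'
#' @param psi_w_deg wavefront propagation direction in degrees
#'   (0 = +x, counterclockwise).
#' @param velocity_m_s conduction velocity in m/s (> 0). 0.5 m/s is a
#'   typical epicardial order of magnitude.
#' @param amplitude_uv,width_ms,shape waveform template, see
#'   [unipolar_waveform()].
#' @param pacing_hz pacing (stimulation) rate in Hz.
#' @param n_beats number of paced beats (>= 1).
#' @param noise_sd_uv additive white Gaussian noise SD per channel, uV.
#' @param common_mode_uv amplitude of an optional common-mode mains-like
#'   sinusoid added identically to every channel (0 disables).
#' @param common_mode_hz frequency of the common-mode sinusoid.
#' @param fs sampling rate in Hz.
#' @param seed integer RNG seed for the noise realisation.
#' @param source_mm optional length-2 numeric (x, y) in mm: when given, a
#'   circular wavefront radiating from this point source replaces the
#'   planar delay field.
#' @param t0_ms activation time of the zero-delay point on the first beat.
#' @param jitter_sd_ms SD of per-beat timing jitter in ms (0 = exact
#'   pacing).
#' @return A list of class `planar_wave_params`.
#' @export
planar_wave_params <- function(psi_w_deg = 0, velocity_m_s = 0.5,
                               amplitude_uv = 1000, width_ms = 2,
                               shape = "gauss_deriv",
                               pacing_hz = 4, n_beats = 1,
                               noise_sd_uv = 0,
                               common_mode_uv = 0, common_mode_hz = 50,
                               fs = 1000, seed = 1L,
                               source_mm = NULL, t0_ms = 50,
                               jitter_sd_ms = 0) {
  if (velocity_m_s <= 0) stop("velocity must be > 0")
  if (fs <= 0) stop("fs must be > 0")
  if (n_beats < 1) stop("n_beats must be >= 1")
  if (noise_sd_uv < 0) stop("noise_sd_uv must be >= 0")
  if (!is.null(source_mm) && length(source_mm) != 2) {
    stop("source_mm must be NULL or a length-2 (x, y) position in mm")
  }
  structure(as.list(environment()), class = "planar_wave_params")
}

#' Generate a synthetic unipolar recording
#'
#' Simulates a paced train of planar (or, with a point source, circular)
#' activation wavefronts crossing the array: every electrode receives the
#' same biphasic template delayed by its activation time, plus optional
#' per-channel white noise and an optional common-mode sinusoid.
#'
#' For a planar wave with direction `psi_w_deg` and conduction velocity `v`
#' the activation delay at position (x, y) mm is
#' `tau = (x cos(psi) + y sin(psi)) / v` ms (1 mm / (1 m/s) = 1 ms); for a
#' circular wave it is `|(x, y) - source| / v`. The template is evaluated
#' at the continuous delayed times, so no nearest-sample rounding occurs.
#' Beat k activates the zero-delay point at `t0_ms + k / pacing_hz`.
#'
#' @param grid an `electrode_grid`.
#' @param params a `planar_wave_params` list.
#' @param duration_ms total duration; default covers all beats plus margin.
#' @return A `unipolar_recording` whose `meta` records every generator
#'   parameter including the ground-truth `psi_w_deg`.
#'
#' @examples
#' g <- make_grid(8, 16, 1)
#' rec <- generate_planar_wave(g, planar_wave_params(psi_w_deg = 30))
#' rec
#' @export
generate_planar_wave <- function(grid, params, duration_ms = NULL) {
  stopifnot(inherits(grid, "electrode_grid"),
            inherits(params, "planar_wave_params"))
  p <- params
  pos <- grid$positions
  if (is.null(p$source_mm)) {
    psi <- p$psi_w_deg * pi / 180
    tau <- (pos$x * cos(psi) + pos$y * sin(psi)) / p$velocity_m_s
  } else {
    tau <- sqrt((pos$x - p$source_mm[1])^2 + (pos$y - p$source_mm[2])^2) /
      p$velocity_m_s
  }
  period_ms <- 1000 / p$pacing_hz
  support_ms <- 10 * p$width_ms
  if (period_ms < support_ms && p$n_beats > 1) {
    warning("beat period (", period_ms,
            " ms) shorter than waveform support; activations will overlap")
  }
  if (is.null(duration_ms)) {
    duration_ms <- p$t0_ms + (p$n_beats - 1) * period_ms +
      max(tau) + 6 * p$width_ms + p$t0_ms
  }
  n <- ceiling(duration_ms * p$fs / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / p$fs

  set.seed(p$seed)
  beat_t0 <- p$t0_ms + (seq_len(p$n_beats) - 1) * period_ms
  if (p$jitter_sd_ms > 0) {
    beat_t0 <- beat_t0 + stats::rnorm(p$n_beats, 0, p$jitter_sd_ms)
  }

  data <- matrix(0, nrow = n, ncol = nrow(pos))
  for (e in seq_len(nrow(pos))) {
    for (b in beat_t0) {
      data[, e] <- data[, e] +
        unipolar_waveform(t_ms - b - tau[e], shape = p$shape,
                          amplitude_uv = p$amplitude_uv,
                          width_ms = p$width_ms)
    }
  }
  if (p$common_mode_uv > 0) {
    cm <- p$common_mode_uv * sin(2 * pi * p$common_mode_hz * t_ms / 1000)
    data <- data + cm
  }
  if (p$noise_sd_uv > 0) {
    data <- data + matrix(stats::rnorm(length(data), 0, p$noise_sd_uv),
                          nrow = n)
  }
  colnames(data) <- pos$label

  meta <- list(
    generator = "generate_planar_wave",
    psi_w_deg = p$psi_w_deg, velocity_m_s = p$velocity_m_s,
    amplitude_uv = p$amplitude_uv, width_ms = p$width_ms, shape = p$shape,
    pacing_hz = p$pacing_hz, n_beats = p$n_beats,
    noise_sd_uv = p$noise_sd_uv, common_mode_uv = p$common_mode_uv,
    common_mode_hz = p$common_mode_hz, seed = p$seed,
    t0_ms = p$t0_ms, jitter_sd_ms = p$jitter_sd_ms,
    beat_t0_ms = beat_t0, mean_delay_ms = mean(tau),
    source_mm = p$source_mm
  )
  unipolar_recording(grid, data, p$fs, meta)
}
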