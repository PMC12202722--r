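#' RF pulse objects
#'
#' An `rf_pulse` stores a peak-normalized complex waveform (`samples`, with
#' phase in radians encoded as the complex argument), its duration in ms, the
#' nominal bandwidth in Hz, the nominal flip angle in degrees and a `kind`
#' (`"excitation"` or `"refocusing"`). Frequency-modulated pulses additionally
#' carry their instantaneous frequency sweep (`fm_hz`, one value per sample).
#' `peak_b1_mt` is optional and usually set at simulation time.
#'
#' @param samples Complex vector, `max(Mod(samples)) == 1`, length >= 64.
#' @param duration_ms Pulse duration in ms (> 0).
#' @param bandwidth_hz Nominal bandwidth in Hz (> 0).
#' @param flip_deg Nominal flip angle in degrees.
#' @param kind `"excitation"` or `"refocusing"`.
#' @param fm_hz Optional instantaneous frequency modulation in Hz per sample.
#' @param peak_b1_mt Optional peak B1 in mT.
#' @return An object of class `rf_pulse`.
#' @export
rf_pulse <- function(samples, duration_ms, bandwidth_hz, flip_deg,
                     kind = c("excitation", "refocusing"),
                     fm_hz = NULL, peak_b1_mt = NA_real_) {
  kind <- match.arg(kind)
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop_invalid("duration_ms must be > 0")
  if (!is.numeric(bandwidth_hz) || bandwidth_hz <= 0)
    stop_invalid("bandwidth_hz must be > 0")
  if (length(samples) < 64)
    stop_invalid("an rf_pulse needs at least 64 samples")
  samples <- as.complex(samples)
  pk <- max(Mod(samples))
  if (pk > 0) samples <- samples / pk
  structure(list(samples = samples, duration_ms = duration_ms,
                 bandwidth_hz = bandwidth_hz, flip_deg = flip_deg,
                 kind = kind, fm_hz = fm_hz, peak_b1_mt = peak_b1_mt),
            class = "rf_pulse")
}

#' @export
print.rf_pulse <- function(x, ...) {
  cat(sprintf("<rf_pulse> %s, %.3g ms, %.3g kHz nominal bandwidth, flip %g deg, %d samples\n",
              x$kind, x$duration_ms, x$bandwidth_hz / 1000, x$flip_deg,
              length(x$samples)))
  invisible(x)
}

# sample spacing in seconds
pulse_dt <- function(pulse) pulse$duration_ms * 1e-3 / (length(pulse$samples) - 1)

# cumulative trapezoid integral, same length as y, starting at 0
cumtrapz1 <- function(y, dx) c(0, cumsum((y[-1] + y[-length(y)]) / 2 * dx))

#' Hyperbolic-secant (HSn) adiabatic full-passage pulse
#'
#' Amplitude envelope `A(tau) = sech(beta * |tau|^n)` for `tau` in `[-1, 1]`,
#' with an antisymmetric frequency sweep. For `n = 1` the sweep is the tanh
#' companion of the sech envelope; for `n > 1` it is the normalized integral
#' of `A^2`, rescaled by a short Bloch-simulation calibration so that the full
#' width of the simulated inversion band matches `bandwidth_hz`. `beta` is the
#' truncation factor (the envelope edge amplitude is `sech(beta)`; the
#' conventional choice 5.3 truncates at ~1%), and `n` the HSn exponent.
#'
#' @param duration_ms Duration in ms (default 3.4).
#' @param beta Truncation factor (> 0, default 5.3).
#' @param n HSn exponent (>= 1, default 1).
#' @param bandwidth_hz Target inversion bandwidth in Hz (default 3200).
#' @param n_samples Number of waveform samples (default 513, odd so the midpoint is sampled).
#' @param calibrate Calibrate the sweep scale against the Bloch engine
#'   (default: only for `n > 1`, where no closed form exists).
#' @param gamma Gyromagnetic ratio in MHz/T used for calibration.
#' @return An `rf_pulse` of kind `"refocusing"`.
#' @export
#' @examples
#' p <- make_hs_pulse()
#' Mod(p$samples[1]) # sech(5.3), ~1% truncation
make_hs_pulse <- function(duration_ms = 3.4, beta = 5.3, n = 1,
                          bandwidth_hz = 3200, n_samples = 513,
                          calibrate = n > 1,
                          gamma = gyromagnetic_ratio("13C")) {
  if (duration_ms <= 0) stop_invalid("duration_ms must be > 0")
  if (bandwidth_hz <= 0) stop_invalid("bandwidth_hz must be > 0")
  if (beta <= 0) stop_invalid("beta must be > 0")
  if (n < 1) stop_invalid("n must be >= 1")
  tau <- seq(-1, 1, length.out = n_samples)
  amp <- 1 / cosh(beta * abs(tau)^n)

  sweep_shape <- if (n == 1) {
    tanh(beta * tau) / tanh(beta)
  } else {
    f <- cumtrapz1(amp^2, tau[2] - tau[1])
    f <- f - f[(n_samples + 1) %/% 2]          # zero at midpoint
    f <- (f - rev(f)) / 2                      # enforce antisymmetry
    f / max(abs(f))
  }

  build <- function(scale) {
    fm <- (scale * bandwidth_hz / 2) * sweep_shape
    dt <- duration_ms * 1e-3 / (n_samples - 1)
    ph <- 2 * pi * cumtrapz1(fm, dt)
    ph <- ph - ph[(n_samples + 1) %/% 2]
    rf_pulse(amp * exp(1i * ph), duration_ms, bandwidth_hz, 180,
             kind = "refocusing", fm_hz = fm)
  }

  scale <- 1
  pulse <- build(scale)
  if (calibrate) {
    for (it in 1:2) {
      w <- inversion_band_width(pulse, gamma = gamma)
      if (is.finite(w) && w > 0) scale <- scale * bandwidth_hz / w
      pulse <- build(scale)
    }
  }
  pulse
}

# Full width of the Bloch-simulated inversion band (Mz zero crossings) at a
# B1 comfortably above the adiabatic threshold.
inversion_band_width <- function(pulse, gamma = gyromagnetic_ratio("13C"),
                                 b1_mt = NULL, n_points = 201) {
  if (is.null(b1_mt)) b1_mt <- 2 * adiabatic_threshold(pulse, gamma = gamma)
  off <- seq(-pulse$bandwidth_hz, pulse$bandwidth_hz, length.out = n_points)
  M <- propagate(pulse, gradient_mt_m = 0, peak_b1_mt = b1_mt,
                 off_resonance_hz = off, gamma = gamma)
  crossing_width(off, -M[, 3], level = 0)
}

# width between the outermost crossings of y = level (linear interpolation)
crossing_width <- function(x, y, level) {
  s <- y - level
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (length(idx) < 2) return(NA_real_)
  xc <- vapply(idx, function(i) {
    x[i] + (x[i + 1] - x[i]) * (level - y[i]) / (y[i + 1] - y[i])
  }, numeric(1))
  max(xc) - min(xc)
}

#' Band-limited selective excitation/refocusing pulse
#'
#' Hamming-windowed sinc with time-bandwidth product `2 * sharpness`
#' (`sharpness` = number of zero-crossing pairs per side). The envelope is
#' real and symmetric; the on-resonance flip is exact by the area theorem when
#' the peak B1 from [peak_b1_for_flip()] is used, and the Bloch-simulated
#' excitation band full width matches `bandwidth_hz` to within 10%.
#'
#' @param flip_deg Nominal flip angle in degrees, in (0, 180].
#' @param bandwidth_hz Bandwidth in Hz (> 0).
#' @param sharpness Zero-crossing pairs per side (default 3).
#' @param duration_ms Duration in ms; default `2 * sharpness / bandwidth_hz`
#'   expressed in ms (fixed time-bandwidth product).
#' @param n_samples Number of samples (default 257).
#' @return An `rf_pulse`; kind `"refocusing"` for flip >= 135 deg, otherwise
#'   `"excitation"`.
#' @export
make_excitation_pulse <- function(flip_deg, bandwidth_hz, sharpness = 3,
                                  duration_ms = NULL, n_samples = 257) {
  if (!is.numeric(flip_deg) || flip_deg <= 0 || flip_deg > 180)
    stop_invalid("flip_deg must be in (0, 180]")
  if (bandwidth_hz <= 0) stop_invalid("bandwidth_hz must be > 0")
  if (is.null(duration_ms)) duration_ms <- 2 * sharpness / bandwidth_hz * 1e3
  t <- seq(-duration_ms / 2, duration_ms / 2, length.out = n_samples) * 1e-3
  x <- bandwidth_hz * t
  env <- ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  win <- 0.54 + 0.46 * cos(pi * t / max(abs(t)))  # Hamming
  env <- env * win
  env <- (env + rev(env)) / 2
  rf_pulse(as.complex(env), duration_ms, bandwidth_hz, flip_deg,
           kind = if (flip_deg >= 135) "refocusing" else "excitation")
}

#' Peak B1 achieving a pulse's nominal flip on resonance
#'
#' Rotations about a common axis commute, so the on-resonance flip of a pulse
#' with real symmetric envelope equals `2 pi gamma B1 integral(envelope) dt`
#' exactly; this solves that relation for B1.
#'
#' @param pulse An `rf_pulse`.
#' @param flip_deg Flip angle to calibrate for (default the pulse's nominal).
#' @param gamma Gyromagnetic ratio in MHz/T.
#' @return Peak B1 in mT.
#' @export
peak_b1_for_flip <- function(pulse, flip_deg = pulse$flip_deg,
                             gamma = gyromagnetic_ratio("13C")) {
  dt <- pulse_dt(pulse)
  area <- sum(Re(pulse$samples)) * dt      # s (envelope real for amplitude-modulated pulses)
  (flip_deg * pi / 180) / (2 * pi * gamma * 1e3 * area)
}

#' Export / import a pulse waveform as tabular text
#'
#' Columns: sample index, amplitude (peak-normalized), phase in degrees.
#' Header comment lines carry duration, bandwidth, flip, and kind so the file
#' is self-describing.
#'
#' @param pulse An `rf_pulse`.
#' @param path File path.
#' @return `write_pulse` returns `path` invisibly; `read_pulse` an `rf_pulse`.
#' @export
write_pulse <- function(pulse, path) {
  hdr <- c(sprintf("# duration_ms %.10g", pulse$duration_ms),
           sprintf("# bandwidth_hz %.10g", pulse$bandwidth_hz),
           sprintf("# flip_deg %.10g", pulse$flip_deg),
           sprintf("# kind %s", pulse$kind),
           "index\tamplitude\tphase_deg")
  ph <- Arg(pulse$samples) * 180 / pi
  body <- sprintf("%d\t%.12g\t%.12g", seq_along(pulse$samples) - 1L,
                  Mod(pulse$samples), ph)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_pulse
#' @export
read_pulse <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("# ", key, " "), "", hdr[grepl(paste0("^# ", key, " "), hdr)])
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE)
  rf_pulse(tab$amplitude * exp(1i * tab$phase_deg * pi / 180),
           duration_ms = as.numeric(get("duration_ms")),
           bandwidth_hz = as.numeric(get("bandwidth_hz")),
           flip_deg = as.numeric(get("flip_deg")),
           kind = get("kind"))
}
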