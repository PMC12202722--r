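#' Hard-pulse Bloch propagation of an isochromat set
#'
#' Piecewise-constant (hard-pulse) rotation of magnetization vectors through
#' an RF waveform, relaxation-free. Each isochromat sees an effective field
#' with transverse components set by the instantaneous complex B1 and a
#' longitudinal component from its gradient-induced and chemical off-resonance
#' frequency. Units: positions mm, gradient mT/m, B1 mT, gamma MHz/T, so the
#' gradient-induced offset is `gamma * G * x` Hz and the RF nutation rate
#' `gamma * B1 * 1e3` Hz.
#'
#' @param pulse An [rf_pulse()].
#' @param gradient_mt_m Slice gradient amplitude in mT/m.
#' @param peak_b1_mt Peak B1 in mT.
#' @param positions_mm Isochromat positions along the slice axis (mm).
#' @param off_resonance_hz Chemical off-resonance per isochromat (Hz);
#'   recycled against `positions_mm`.
#' @param M0 Initial magnetization, either a length-3 vector applied to all
#'   isochromats or an n x 3 matrix.
#' @param gamma Gyromagnetic ratio in MHz/T.
#' @return n x 3 matrix of (Mx, My, Mz).
#' @export
propagate <- function(pulse, gradient_mt_m = 0, peak_b1_mt,
                      positions_mm = 0, off_resonance_hz = 0,
                      M0 = c(0, 0, 1), gamma = gyromagnetic_ratio("13C")) {
  if (!inherits(pulse, "rf_pulse")) stop_invalid("pulse must be an rf_pulse")
  if (gamma <= 0) stop_invalid("gamma must be > 0")
  if (length(positions_mm) < 1 || length(off_resonance_hz) < 1)
    stop_invalid("empty isochromat grid")
  n <- max(length(positions_mm), length(off_resonance_hz))
  x <- rep_len(positions_mm, n)
  off <- rep_len(off_resonance_hz, n)
  if (is.matrix(M0)) {
    M <- M0
  } else {
    M <- matrix(rep(M0, each = n), n, 3)
  }
  dt <- pulse_dt(pulse)
  fz <- gamma * gradient_mt_m * x + off       # Hz, constant per isochromat
  b1 <- peak_b1_mt * pulse$samples
  f1 <- gamma * 1e3 * b1                      # Hz, complex nutation rate
  mx <- M[, 1]; my <- M[, 2]; mz <- M[, 3]
  for (k in seq_along(f1)) {
    ax <- Re(f1[k]); ay <- Im(f1[k])
    fn <- sqrt(ax * ax + ay * ay + fz * fz)
    ang <- 2 * pi * fn * dt
    nz <- fn > 0
    # unit rotation axis; where the field vanishes the rotation is identity
    ux <- ifelse(nz, ax / fn, 0)
    uy <- ifelse(nz, ay / fn, 0)
    uz <- ifelse(nz, fz / fn, 1)
    ca <- cos(ang); sa <- sin(ang); oc <- 1 - ca
    dot <- ux * mx + uy * my + uz * mz
    cx <- uy * mz - uz * my
    cy <- uz * mx - ux * mz
    cz <- ux * my - uy * mx
    mx2 <- mx * ca + cx * sa + ux * dot * oc
    my2 <- my * ca + cy * sa + uy * dot * oc
    mz2 <- mz * ca + cz * sa + uz * dot * oc
    mx <- mx2; my <- my2; mz <- mz2
  }
  cbind(Mx = mx, My = my, Mz = mz)
}

#' Simulated slice profile of a selective pulse
#'
#' Plays the pulse under its slice-selection gradient
#' `G = bandwidth / (gamma * thickness)` over a symmetric field of view and
#' returns the spatial response. For excitation pulses the relevant response
#' is `|Mxy|`; for refocusing pulses the inversion band of Mz (simulated from
#' equilibrium, crushers idealized elsewhere).
#'
#' @param pulse An [rf_pulse()].
#' @param thickness_mm Nominal slice thickness in mm (> 0).
#' @param fov_mm Simulated field of view in mm (must exceed 2 x thickness).
#' @param n_points Number of spatial samples (>= 101).
#' @param peak_b1_mt Peak B1 in mT; default calibrates the nominal flip for
#'   amplitude-modulated pulses and 1.5 x the adiabatic threshold for
#'   frequency-swept pulses.
#' @param gamma Gyromagnetic ratio in MHz/T.
#' @return A data.frame of class `bloch_profile` with columns `position_mm`,
#'   `mxy`, `phase`, `mz`, and attributes `thickness_mm`, `gradient_mt_m`,
#'   `flip_deg`, `kind`.
#' @export
slice_profile <- function(pulse, thickness_mm, fov_mm = 4 * thickness_mm,
                          n_points = 201, peak_b1_mt = NULL,
                          gamma = gyromagnetic_ratio("13C")) {
  if (thickness_mm <= 0) stop_invalid("thickness_mm must be > 0")
  if (fov_mm <= 2 * thickness_mm) stop_invalid("fov_mm must exceed 2 x thickness_mm")
  if (n_points < 101) n_points <- 101
  grad <- pulse$bandwidth_hz / (gamma * thickness_mm)
  if (is.null(peak_b1_mt)) {
    peak_b1_mt <- if (is.null(pulse$fm_hz)) {
      peak_b1_for_flip(pulse, gamma = gamma)
    } else {
      1.5 * adiabatic_threshold(pulse, gamma = gamma)
    }
    if (!is.finite(peak_b1_mt)) peak_b1_mt <- 0   # zero-area waveform
  }
  x <- seq(-fov_mm / 2, fov_mm / 2, length.out = n_points)
  M <- propagate(pulse, gradient_mt_m = grad, peak_b1_mt = peak_b1_mt,
                 positions_mm = x, gamma = gamma)
  out <- data.frame(position_mm = x,
                    mxy = sqrt(M[, 1]^2 + M[, 2]^2),
                    phase = atan2(M[, 2], M[, 1]),
                    mz = M[, 3])
  attr(out, "thickness_mm") <- thickness_mm
  attr(out, "gradient_mt_m") <- grad
  attr(out, "flip_deg") <- pulse$flip_deg
  attr(out, "kind") <- pulse$kind
  class(out) <- c("bloch_profile", "data.frame")
  out
}

#' On-resonance inversion versus B1 drive
#'
#' Simulates the final Mz after playing the pulse at each B1 amplitude with no
#' gradient, the numerical counterpart of an inversion-recovery power series.
#' Adiabatic pulses show a plateau near -1 above their threshold; linear-phase
#' 180s overshoot and come back up when overdriven.
#'
#' @param pulse An [rf_pulse()].
#' @param b1_range_mt Sorted ascending vector of peak B1 values (mT).
#' @param gamma Gyromagnetic ratio in MHz/T.
#' @return data.frame with columns `b1_mt`, `mz`.
#' @export
inversion_vs_b1 <- function(pulse, b1_range_mt,
                            gamma = gyromagnetic_ratio("13C")) {
  if (is.unsorted(b1_range_mt)) stop_invalid("b1_range_mt must be sorted ascending")
  mz <- vapply(b1_range_mt, function(b1) {
    propagate(pulse, gradient_mt_m = 0, peak_b1_mt = b1, gamma = gamma)[1, 3]
  }, numeric(1))
  data.frame(b1_mt = b1_range_mt, mz = mz)
}

#' Adiabatic threshold of a frequency-swept pulse
#'
#' Smallest B1 on a geometric scan at which the on-resonance inversion reaches
#' `Mz <= -0.95`.
#'
#' @param pulse An [rf_pulse()].
#' @param gamma Gyromagnetic ratio in MHz/T.
#' @param b1_grid_mt Candidate B1 values; default a geometric grid.
#' @return Threshold B1 in mT (NA if never reached on the grid).
#' @export
adiabatic_threshold <- function(pulse, gamma = gyromagnetic_ratio("13C"),
                                b1_grid_mt = NULL) {
  if (is.null(b1_grid_mt)) {
    # scale-invariant starting point: nutation comparable to the sweep rate
    b0 <- pulse$bandwidth_hz / (gamma * 1e3)
    b1_grid_mt <- b0 * 2^seq(-5, 3, by = 0.25)
  }
  curve <- inversion_vs_b1(pulse, sort(b1_grid_mt), gamma = gamma)
  hit <- which(curve$mz <= -0.95)
  if (!length(hit)) return(NA_real_)
  curve$b1_mt[hit[1]]
}

#' Full width at half maximum of a sampled response
#'
#' @param x Axis samples.
#' @param y Response samples.
#' @return FWHM in the units of `x` (NA if no half-maximum crossings).
#' @export
profile_fwhm <- function(x, y) crossing_width(x, y, max(y) / 2)

#' Slice-edge transition width (10 to 90 percent)
#'
#' Mean over both band edges of the distance between the 10% and 90% response
#' crossings; the response is `|Mxy|` for excitation profiles and the
#' inversion response `(1 - Mz) / 2` for refocusing profiles.
#'
#' @param profile A [slice_profile()] result.
#' @return Mean transition width (mm).
#' @export
transition_width <- function(profile) {
  resp <- if (attr(profile, "kind") == "refocusing") {
    (1 - profile$mz) / 2
  } else {
    profile$mxy
  }
  resp <- resp / max(resp)
  w90 <- crossing_width(profile$position_mm, resp, 0.9)
  w10 <- crossing_width(profile$position_mm, resp, 0.1)
  (w10 - w90) / 2
}

#' Idealized crusher: zero all transverse magnetization
#'
#' @param M n x 3 magnetization matrix.
#' @return Matrix with Mx = My = 0, Mz untouched.
#' @export
crush <- function(M) {
  M[, 1] <- 0
  M[, 2] <- 0
  M
}
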