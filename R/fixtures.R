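#' Noise sigma that yields a target spectral SNR for a Lorentzian peak
#'
#' Uses the closed-form height of a discretely sampled Lorentzian
#' (`~ A / (pi * w * dt)` for lines narrow relative to the acquisition) and
#' Rayleigh magnitude-noise statistics (`sd ~ sigma * sqrt(n) * sqrt(2 - pi/2)`
#' per magnitude bin) to choose the per-component time-domain noise sigma
#' giving approximately the requested [snr()] for that peak.
#'
#' @param amplitude Time-domain peak amplitude.
#' @param width_hz Lorentzian FWHM in Hz.
#' @param dwell_ms Dwell time in ms.
#' @param n Number of complex samples.
#' @param target_snr Desired SNR.
#' @return Noise sigma per real component.
#' @export
noise_sigma_for_snr <- function(amplitude, width_hz, dwell_ms, n, target_snr) {
  dt <- dwell_ms * 1e-3
  height <- amplitude * (1 - exp(-pi * width_hz * dt * n)) /
    (1 - exp(-pi * width_hz * dt))
  height / (target_snr * sqrt(n) * sqrt(2 - pi / 2))
}

#' Synthetic three-compartment kidney pH phantom FID
#'
#' One C1 reference peak plus three C5 components at the shift differences
#' corresponding to cortex-, medulla- and pelvis-like pH (7.32, 7.06, 6.58 by
#' default) with amplitude fractions 0.5 / 0.3 / 0.2, at a C5 SNR regime of
#' about 16. Entirely synthetic: the truths are generator inputs, not
#' measurements.
#'
#' @param seed Integer seed.
#' @param cal A [ph_calibration()].
#' @param ph_true Compartment pH values.
#' @param fractions Amplitude fractions of the C5 components (sum 1).
#' @param c1_ppm C1 reference position (ppm).
#' @param snr_c5 Approximate SNR of the dominant C5 component (per-peak SNR,
#'   matching how split-resonance SNR is quoted); smaller compartments scale
#'   down with their fractions.
#' @param n,dwell_ms Acquisition grid.
#' @return An [fid()].
#' @export
synth_kidney_ph_fid <- function(seed = 1, cal = ph_calibration(),
                                ph_true = c(7.32, 7.06, 6.58),
                                fractions = c(0.5, 0.3, 0.2),
                                c1_ppm = 160, snr_c5 = 16,
                                n = 1024, dwell_ms = 1 / 3) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(ph_true) == length(fractions))
  delta <- ph_to_delta(ph_true, cal)
  width <- 9
  c5_amp_total <- 1
  peaks <- data.frame(
    amplitude = c(2.2, fractions * c5_amp_total),
    ppm = c(c1_ppm, c1_ppm + delta),
    width_hz = width,
    phase_rad = 0)
  sigma <- noise_sigma_for_snr(c5_amp_total * max(fractions), width, dwell_ms,
                               n, snr_c5)
  synth_fid(peaks, dwell_ms = dwell_ms, n = n, noise_sigma = sigma,
            seed = seed, ppm_center = c1_ppm + 10)
}

#' Generate the packaged synthetic fixtures
#'
#' Writes four deterministic, fully synthetic stand-ins used by the examples
#' and the command line: a three-tube-style multi-peak proton spectrum FID, a
#' sphere-phantom single-resonance pyruvate FID, a two-kidney voxel plan
#' whose voxels share both refocusing-slab extents but are disjoint along the
#' excitation axis, and a three-compartment kidney pH FID. Bit-identical for
#' a fixed seed.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @return Named character vector of the written file paths.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    three_tube = file.path(dir, "synthetic_three_tube_fid.json"),
    sphere = file.path(dir, "synthetic_sphere_pyruvate_fid.json"),
    kidney_plan = file.path(dir, "synthetic_kidney_pair_plan.csv"),
    kidney_ph = file.path(dir, "synthetic_kidney_ph_fid.json"))

  # three-tube proton phantom stand-in: water / oil / ethanol-like lines
  tubes <- data.frame(amplitude = c(1.0, 0.8, 0.6),
                      ppm = c(4.7, 1.3, 3.7),
                      width_hz = c(6, 10, 8),
                      phase_rad = 0)
  f1 <- synth_fid(tubes, dwell_ms = 1000 / (10 * 298.04), n = 1024,
                  noise_sigma = noise_sigma_for_snr(0.6, 8, 1000 / (10 * 298.04),
                                                    1024, 200),
                  seed = seed, ref_mhz = 298.04, ppm_center = 3.5)
  write_fid(f1, paths["three_tube"])

  # hyperpolarized sphere phantom stand-in: single pyruvate resonance
  f2 <- synth_fid(data.frame(amplitude = 1, ppm = 171, width_hz = 8,
                             phase_rad = 0.2),
                  dwell_ms = 1 / 3, n = 1024,
                  noise_sigma = noise_sigma_for_snr(1, 8, 1 / 3, 1024, 1500),
                  seed = seed + 1L, ppm_center = 171)
  write_fid(f2, paths["sphere"])

  # two kidney voxels: identical refocusing extents, disjoint excitation axis
  plan <- voxel_plan(c("Kidney L", "Kidney R"),
                     rbind(c(-5, 0, 0), c(5, 0, 0)),
                     c(5.5, 4.5, 9.7))
  write_voxel_plan(plan, paths["kidney_plan"])

  f4 <- synth_kidney_ph_fid(seed = seed + 2L)
  write_fid(f4, paths["kidney_ph"])
  paths
}
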