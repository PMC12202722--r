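#' Minimal-TE semi-LASER inter-pulse timing
#'
#' The five inter-pulse intervals tau1..tau5 of a semi-LASER echo train must
#' satisfy the echo condition `tau1 + tau3 + tau5 = tau2 + tau4` while each
#' interval respects a lower bound set by the pulses, crushers and gradients
#' it has to accommodate. The minimal total is found in closed form: with
#' `L = b1 + b3 + b5` and `R = b2 + b4`, the minimum of `sum(tau)` subject to
#' the balance and `tau >= b` is `2 * max(L, R)`, achieved by topping up the
#' last interval of the deficient side. TE additionally counts the supplied
#' pulse durations.
#'
#' @param lower_bounds_ms Length-5 numeric vector of lower bounds (ms, >= 0).
#' @param pulse_durations_ms Durations of the RF pulses inside the echo train
#'   (ms); their sum is added to the reported TE.
#' @return list of class `sequence_timing`: `tau_ms` (length 5), `te_ms`,
#'   `residual_ms` (echo-condition residual).
#' @export
#' @examples
#' solve_slaser_timing(c(1, 2, 1.5, 2, 1))
solve_slaser_timing <- function(lower_bounds_ms, pulse_durations_ms = numeric(0)) {
  b <- as.numeric(lower_bounds_ms)
  if (length(b) != 5 || any(!is.finite(b)) || any(b < 0))
    stop_invalid("lower_bounds_ms must be 5 finite non-negative values")
  tau <- b
  L <- b[1] + b[3] + b[5]
  R <- b[2] + b[4]
  if (L > R) tau[4] <- b[4] + (L - R)
  if (R > L) tau[5] <- b[5] + (R - L)
  te <- sum(tau) + sum(pulse_durations_ms)
  structure(list(tau_ms = tau, te_ms = te,
                 residual_ms = (tau[1] + tau[3] + tau[5]) - (tau[2] + tau[4])),
            class = "sequence_timing")
}

#' @export
print.sequence_timing <- function(x, ...) {
  cat(sprintf("<sequence_timing> TE = %.3f ms; tau = %s ms\n", x$te_ms,
              paste(sprintf("%.3f", x$tau_ms), collapse = ", ")))
  invisible(x)
}

#' Scan time of a multi-voxel MRS or CSI acquisition
#'
#' Multi-voxel MRS acquires one shot per voxel (`n_voxels x TR`); 2D FID-CSI
#' phase-encodes a full matrix per slice (`Nx x Ny x TR x n_slices`).
#'
#' @param mode `"mrs"` or `"csi"`.
#' @param tr_ms Repetition time in ms.
#' @param n_voxels Number of voxels (mrs mode).
#' @param matrix_size Length-2 phase-encode matrix, e.g. `c(12, 8)` (csi mode).
#' @param n_slices Number of CSI slices (default 1).
#' @return Scan time in seconds.
#' @export
#' @examples
#' scan_time("csi", tr_ms = 230, matrix_size = c(12, 8)) # 22.08 s
scan_time <- function(mode = c("mrs", "csi"), tr_ms, n_voxels = NULL,
                      matrix_size = NULL, n_slices = 1) {
  mode <- match.arg(mode)
  if (tr_ms <= 0 || n_slices <= 0) stop_invalid("tr_ms and n_slices must be > 0")
  if (mode == "mrs") {
    if (is.null(n_voxels) || n_voxels <= 0) stop_invalid("mrs mode needs n_voxels > 0")
    n_voxels * tr_ms / 1000
  } else {
    if (is.null(matrix_size) || length(matrix_size) != 2 || any(matrix_size <= 0))
      stop_invalid("csi mode needs a positive length-2 matrix_size")
    prod(matrix_size) * tr_ms / 1000 * n_slices
  }
}

#' Spectral resolution of the digitized spectrum
#'
#' Receiver bandwidth is quoted in ppm; the acquisition samples `n_points`
#' complex points and the spectrum is conventionally zero-filled (factor 2 by
#' default) before the transform, giving
#' `bandwidth_ppm * frequency_mhz / (zero_fill * n_points)` Hz per point.
#'
#' @param bandwidth_ppm Receiver bandwidth in ppm.
#' @param n_points Number of acquired complex points.
#' @param frequency_mhz Nucleus frequency in MHz (default 13C at 7 T).
#' @param zero_fill Zero-fill factor (default 2).
#' @return Hz per point.
#' @export
#' @examples
#' spectral_resolution(30, 1024) # ~1.1 Hz/pt
spectral_resolution <- function(bandwidth_ppm, n_points,
                                frequency_mhz = carbon_frequency_7t(),
                                zero_fill = 2) {
  if (bandwidth_ppm <= 0 || n_points <= 0 || frequency_mhz <= 0 || zero_fill <= 0)
    stop_invalid("all spectral_resolution inputs must be > 0")
  bandwidth_ppm * frequency_mhz / (zero_fill * n_points)
}

#' Crusher gradient amplitude from a fraction of system maximum
#'
#' @param fraction Fraction of the maximal gradient strength, in `[0, 1]`.
#' @param g_max_mt_m Maximal gradient strength in mT/m.
#' @return Amplitude in mT/m.
#' @export
#' @examples
#' crusher_amplitude(0.40, 590) # 236 mT/m
crusher_amplitude <- function(fraction, g_max_mt_m) {
  if (fraction < 0 || fraction > 1) stop_invalid("fraction must be in [0, 1]")
  fraction * g_max_mt_m
}

#' Relative crusher-area scheme around the adiabatic refocusing train
#'
#' Five crusher events with per-axis relative gradient areas
#' Gx: 0, 0, 0, 1, 1; Gy: -1, 0, 0, 0, 1; Gz: 0, -1, 1, 0, 0 -- a simple
#' scheme that suppresses spurious echoes without phase cycling. Stored as
#' ordered events; all crushers share one amplitude and duration.
#'
#' @param amplitude_mt_m Common crusher amplitude (mT/m, default 236).
#' @param duration_ms Common crusher duration (ms, default 0.5).
#' @param g_max_mt_m System maximum (mT/m); amplitude must not exceed it.
#' @return list of class `crusher_scheme` with the 5 x 3 `relative_areas`
#'   matrix, `amplitude_mt_m`, `duration_ms`.
#' @export
crusher_scheme <- function(amplitude_mt_m = 236, duration_ms = 0.5,
                           g_max_mt_m = 590) {
  if (amplitude_mt_m > g_max_mt_m)
    stop_invalid("crusher amplitude exceeds system maximum")
  areas <- cbind(Gx = c(0, 0, 0, 1, 1),
                 Gy = c(-1, 0, 0, 0, 1),
                 Gz = c(0, -1, 1, 0, 0))
  rownames(areas) <- paste0("event", 1:5)
  structure(list(relative_areas = areas, amplitude_mt_m = amplitude_mt_m,
                 duration_ms = duration_ms), class = "crusher_scheme")
}

#' Coherence-pathway crusher areas between event pairs
#'
#' A spurious coherence that is transverse from crusher event `i` to crusher
#' event `j` and refocused by every intervening adiabatic pulse accumulates
#' the alternating-sign cumulative area
#' `sum_{k=i..j} (-1)^(k-i) area_k` per axis (the coherence order flips at
#' each refocusing pulse). For the scheme to leave no unwanted echo
#' refocused, these vectors must all be nonzero and pairwise distinct.
#'
#' @param scheme A [crusher_scheme()].
#' @return data.frame with columns `from`, `to`, `Gx`, `Gy`, `Gz`.
#' @export
crusher_pathway_areas <- function(scheme) {
  a <- scheme$relative_areas
  out <- list()
  for (i in 1:(nrow(a) - 1)) {
    for (j in (i + 1):nrow(a)) {
      sgn <- (-1)^(seq(i, j) - i)
      v <- colSums(a[i:j, , drop = FALSE] * sgn)
      out[[length(out) + 1]] <- data.frame(from = i, to = j,
                                           Gx = v[1], Gy = v[2], Gz = v[3])
    }
  }
  do.call(rbind, out)
}
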