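#' Chemical-shift pH calibration
#'
#' Maps the pH-sensitive C5-C1 chemical-shift difference of the Z-OMPD pH
#' sensor onto pH through a Henderson-Hasselbalch titration curve between the
#' acid- and base-limit shift differences. The shipped defaults
#' (pKa = 7.0, delta_acid = 18.0 ppm, delta_base = 21.0 ppm) are synthetic
#' placeholders for demonstration and testing; substitute measured titration
#' constants for real quantification.
#'
#' @param pKa Acid dissociation constant of the sensor.
#' @param delta_acid C5-C1 shift difference at the acid limit (ppm).
#' @param delta_base Shift difference at the base limit (ppm); must differ
#'   from `delta_acid`.
#' @return An object of class `ph_calibration`.
#' @export
ph_calibration <- function(pKa = 7.0, delta_acid = 18.0, delta_base = 21.0) {
  if (delta_acid == delta_base) stop_invalid("delta_acid must differ from delta_base")
  structure(list(pKa = pKa, delta_acid = delta_acid, delta_base = delta_base),
            class = "ph_calibration")
}

#' pH from a chemical-shift difference
#'
#' `pH = pKa + log10((delta - delta_acid) / (delta_base - delta))`, strictly
#' monotone between the two limits and equal to pKa exactly at the midpoint.
#'
#' @param delta Observed C5-C1 shift difference (ppm), strictly between the
#'   calibration limits.
#' @param cal A [ph_calibration()].
#' @return pH value(s).
#' @export
#' @examples
#' cal <- ph_calibration()
#' delta_to_ph((cal$delta_acid + cal$delta_base) / 2, cal) # == pKa
delta_to_ph <- function(delta, cal) {
  lo <- min(cal$delta_acid, cal$delta_base)
  hi <- max(cal$delta_acid, cal$delta_base)
  if (any(delta <= lo) || any(delta >= hi))
    stop_invalid("delta outside the open calibration interval (", lo, ", ", hi, ") ppm")
  cal$pKa + log10((delta - cal$delta_acid) / (cal$delta_base - delta))
}

#' @rdname delta_to_ph
#' @param ph pH value(s) to convert back to a shift difference.
#' @export
ph_to_delta <- function(ph, cal) {
  r <- 10^(ph - cal$pKa)
  (cal$delta_acid + cal$delta_base * r) / (1 + r)
}

# derivative of pH wrt delta, for uncertainty propagation
dph_ddelta <- function(delta, cal) {
  (cal$delta_base - cal$delta_acid) /
    (log(10) * (delta - cal$delta_acid) * (cal$delta_base - delta))
}

#' Multi-compartment pH fit of a split C5 resonance
#'
#' Jointly fits one pH-insensitive C1 reference peak plus `n_compartments`
#' C5 peaks to the FID (via [fit_fid()]) and converts each C5-C1 shift
#' difference to a pH. The C1 anchor is the tallest magnitude peak unless
#' `c1_ppm` is given; C5 candidates are picked inside the calibration window
#' `c1_ppm + (delta_acid, delta_base)`. Compartment fractions are the C5
#' amplitudes normalized to their sum; pH uncertainties are propagated from
#' the fit's local curvature. Compartments whose fitted frequencies are
#' closer than a quarter of the wider linewidth are merged with a degeneracy
#' warning.
#'
#' @param f An [fid()].
#' @param n_compartments Number of C5 components to fit (>= 1).
#' @param cal A [ph_calibration()].
#' @param c1_ppm Optional ppm position of the C1 reference peak.
#' @return list of class `ph_result`: `compartments` (data.frame with `ppm`,
#'   `delta_ppm`, `fraction`, `ph`, `ph_se`, `in_validity_window`), `c1_ppm`,
#'   `fit` (the underlying `fid_fit`), `merged` flag.
#' @export
multi_compartment_fit <- function(f, n_compartments, cal, c1_ppm = NULL) {
  if (n_compartments < 1) stop_invalid("n_compartments must be >= 1")
  # peak-pick on a matched-filtered (line-broadened) spectrum: smoothing by
  # roughly one linewidth suppresses noise maxima that would otherwise
  # compete with weak compartments
  sp <- fid_spectrum(line_broaden(f, 5))
  mag <- Mod(sp$spec)
  if (is.null(c1_ppm)) c1_ppm <- sp$ppm[which.max(mag)]
  lo <- c1_ppm + min(cal$delta_acid, cal$delta_base)
  hi <- c1_ppm + max(cal$delta_acid, cal$delta_base)
  win <- sp$ppm > lo & sp$ppm < hi
  if (!any(win)) stop_invalid("no C5 window inside the acquisition band")

  # initial candidates: top-n local maxima of the broadened spectrum in the
  # C5 window
  idx <- which(win)
  mw <- mag[idx]
  loc <- idx[which(diff(sign(diff(mw))) < 0) + 1]
  loc <- loc[order(mag[loc], decreasing = TRUE)]
  keep <- integer(0)
  for (i in loc) {
    if (!length(keep) || all(abs(i - keep) >= 6)) keep <- c(keep, i)
    if (length(keep) == n_compartments) break
  }
  c5_freq <- sp$freq_hz[keep]
  c5_width <- vapply(keep, function(i) peak_width_est(sp, i), numeric(1))
  if (!length(c5_freq)) {
    c5_freq <- sp$freq_hz[idx[which.max(mw)]]
    c5_width <- peak_width_est(sp, idx[which.max(mw)])
  }
  while (length(c5_freq) < n_compartments) {
    # fewer maxima than compartments: split the widest component found
    k <- which.max(c5_width)
    c5_freq <- c(c5_freq, c5_freq[k] + c5_width[k] / 2)
    c5_width <- c(c5_width, c5_width[k])
  }
  c1_freq <- (c1_ppm - f$ppm_center) * f$ref_mhz
  freq0 <- c(c1_freq, c5_freq)
  # the matched filter added ~5 Hz to every apparent width
  width0 <- pmax(c(peak_width_est(sp, which.min(abs(sp$freq_hz - c1_freq))),
                   c5_width) - 5, 2)
  do_fit <- function(freqs, widths) {
    li <- linear_init(f, freqs, widths)
    init <- data.frame(amplitude = pmax(li$amplitude, 1e-9),
                       frequency_hz = freqs, width_hz = widths,
                       phase_rad = li$phase_rad)
    fit_fid(f, n_peaks = n_compartments + 1, init = init)
  }
  fit <- do_fit(freq0, width0)

  # rescue collapsed components: a compartment fitted to ~zero amplitude
  # means its starting point sat on noise; re-seed it from the residual of
  # the converged fit (dominant peaks now cleanly removed) and keep the
  # refit when it lowers the residual sum of squares
  t <- fid_time_s(f)
  min_sep_hz <- 6 * (sp$freq_hz[2] - sp$freq_hz[1])
  for (try in 1:3) {
    amps <- fit$peaks$amplitude
    weak <- which(amps < 0.01 * sum(amps))
    if (!length(weak)) break
    model <- model_fid_samples(fit$peaks, t, fit$baseline)
    spr <- fid_spectrum(line_broaden(
      fid(f$samples - model, f$dwell_ms, f$ref_mhz, f$ppm_center), 5))
    strong_f <- fit$peaks$frequency_hz[-weak]
    cand <- win & !vapply(spr$freq_hz, function(fr)
      any(abs(fr - strong_f) < min_sep_hz), logical(1))
    if (!any(cand)) break
    i_new <- which(cand)[which.max(Mod(spr$spec)[cand])]
    freqs <- c(strong_f, spr$freq_hz[i_new])
    widths <- c(fit$peaks$width_hz[-weak],
                max(peak_width_est(sp, i_new) - 5, 2))
    if (length(weak) > 1) {
      keep_w <- fit$peaks[weak[-1], ]
      freqs <- c(freqs, keep_w$frequency_hz)
      widths <- c(widths, keep_w$width_hz)
    }
    refit <- do_fit(freqs, widths)
    # only accept a rescue that explains real structure; a noise bump buys
    # well under 1% of the residual
    if (refit$rss < 0.99 * fit$rss) fit <- refit else break
  }

  pk <- fit$peaks
  i_c1 <- which.min(abs(pk$frequency_hz - c1_freq))
  c1_hat <- pk$ppm[i_c1]
  c1_se <- pk$frequency_hz_se[i_c1] / f$ref_mhz
  comp <- pk[-i_c1, , drop = FALSE]

  # degeneracy: merge compartments whose separation is below width/4,
  # whose amplitude collapsed to nothing, or whose fitted shift difference
  # left the calibration window (unidentifiable split)
  merged <- FALSE
  lo_d <- min(cal$delta_acid, cal$delta_base)
  hi_d <- max(cal$delta_acid, cal$delta_base)
  repeat {
    if (nrow(comp) < 2) break
    d_now <- comp$ppm - c1_hat
    dead <- which(comp$amplitude < 0.01 * sum(comp$amplitude) |
                    d_now <= lo_d | d_now >= hi_d)
    if (length(dead)) {
      k <- dead[1]
      near <- setdiff(order(abs(comp$frequency_hz - comp$frequency_hz[k])), k)[1]
      comp$amplitude[near] <- comp$amplitude[near] + comp$amplitude[k]
      comp <- comp[-k, , drop = FALSE]
      merged <- TRUE
      next
    }
    comp <- comp[order(comp$frequency_hz), ]
    sep <- diff(comp$frequency_hz)
    lim <- pmax(comp$width_hz[-1], comp$width_hz[-nrow(comp)]) / 4
    k <- which(sep < lim)
    if (!length(k)) break
    k <- k[1]
    a <- comp$amplitude[k] + comp$amplitude[k + 1]
    comp$frequency_hz[k] <- sum(comp$frequency_hz[k:(k + 1)] *
                                  comp$amplitude[k:(k + 1)]) / a
    comp$amplitude[k] <- a
    comp$ppm[k] <- f$ppm_center + comp$frequency_hz[k] / f$ref_mhz
    comp <- comp[-(k + 1), , drop = FALSE]
    merged <- TRUE
  }
  if (merged)
    warning("unresolvable C5 components merged (separation below width/4)")

  delta <- comp$ppm - c1_hat
  ok <- delta > min(cal$delta_acid, cal$delta_base) &
    delta < max(cal$delta_acid, cal$delta_base)
  ph <- rep(NA_real_, length(delta))
  ph[ok] <- delta_to_ph(delta[ok], cal)
  delta_se <- sqrt((comp$frequency_hz_se / f$ref_mhz)^2 + c1_se^2)
  ph_se <- abs(dph_ddelta(pmin(pmax(delta, min(cal$delta_acid, cal$delta_base) + 1e-6),
                               max(cal$delta_acid, cal$delta_base) - 1e-6), cal)) * delta_se
  res <- data.frame(compartment = seq_along(delta), ppm = comp$ppm,
                    delta_ppm = delta,
                    fraction = comp$amplitude / sum(comp$amplitude),
                    ph = ph, ph_se = ph_se,
                    in_validity_window = !is.na(ph) &
                      ph >= cal$pKa - 2 & ph <= cal$pKa + 2)
  res <- res[order(-res$fraction), ]
  res$compartment <- seq_len(nrow(res))
  structure(list(compartments = res, c1_ppm = c1_hat, fit = fit,
                 merged = merged, calibration = cal),
            class = "ph_result")
}

#' @export
print.ph_result <- function(x, ...) {
  cat(sprintf("<ph_result> C1 reference at %.3f ppm, %d compartment(s)%s\n",
              x$c1_ppm, nrow(x$compartments),
              if (x$merged) " (degenerate components merged)" else ""))
  print(x$compartments, row.names = FALSE, digits = 4)
  invisible(x)
}
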