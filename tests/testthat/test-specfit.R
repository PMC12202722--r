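one_peak <- function(A = 1, f = 40, w = 10, ph = 0.3) {
  data.frame(amplitude = A, frequency_hz = f, width_hz = w, phase_rad = ph)
}

test_that("synthesized FIDs honor the stated signal model", {
  # long enough that the decay is complete and truncation ringing absent
  f <- synth_fid(one_peak(), dwell_ms = 0.25, n = 4096)
  sp <- fid_spectrum(f)
  m <- Mod(sp$spec)
  # a single Lorentzian gives exactly one significant local maximum
  loc <- which(diff(sign(diff(m))) < 0) + 1
  expect_equal(sum(m[loc] > 1e-9 * max(m)), 1)

  # two equal peaks mirrored about the center give a symmetric magnitude
  f2 <- synth_fid(data.frame(amplitude = 1, frequency_hz = c(-200, 200),
                             width_hz = 10, phase_rad = 0),
                  dwell_ms = 0.25, n = 512)
  m2 <- Mod(fid_spectrum(f2)$spec)
  fr <- fid_spectrum(f2)$freq_hz
  i_pos <- which.min(abs(fr - 200))
  i_neg <- which.min(abs(fr + 200))
  expect_equal(m2[i_pos], m2[i_neg], tolerance = 1e-9)
})

test_that("noise synthesis is deterministic in the seed", {
  a <- synth_fid(one_peak(), 0.25, 256, noise_sigma = 0.1, seed = 99)
  b <- synth_fid(one_peak(), 0.25, 256, noise_sigma = 0.1, seed = 99)
  c <- synth_fid(one_peak(), 0.25, 256, noise_sigma = 0.1, seed = 100)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("noiseless in-model data are fitted exactly", {
  f <- synth_fid(one_peak(), dwell_ms = 0.25, n = 1024)
  fit <- fit_fid(f, 1)
  expect_true(fit$converged)
  expect_equal(fit$peaks$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$peaks$frequency_hz, 40, tolerance = 1e-6)
  expect_equal(fit$peaks$width_hz, 10, tolerance = 1e-6)
  expect_equal(fit$peaks$phase_rad, 0.3, tolerance = 1e-6)
  # residual below 1e-10 of the signal energy
  expect_lt(fit$rss, 1e-10 * sum(Mod(f$samples)^2))
})

test_that("two close peaks are resolved with sub-bin frequency precision", {
  true_f <- c(-10, 10)                       # 20 Hz apart
  sigma <- noise_sigma_for_snr(1, 10, 0.25, 512, 50)
  errs <- matrix(NA_real_, 200, 2)
  for (r in 1:200) {
    f <- synth_fid(data.frame(amplitude = 1, frequency_hz = true_f,
                              width_hz = 10, phase_rad = 0),
                   dwell_ms = 0.25, n = 512, noise_sigma = sigma, seed = 1000 + r)
    fit <- fit_fid(f, 2)
    got <- sort(fit$peaks$frequency_hz)
    errs[r, ] <- got - true_f
  }
  rmse <- sqrt(colMeans(errs^2))
  expect_true(all(rmse < 0.5))
})

test_that("amplitude ratios are recovered at moderate SNR", {
  # lactate/pyruvate-style two-peak ratio 0.9, pyruvate SNR ~ 15
  sigma <- noise_sigma_for_snr(1, 10, 0.25, 1024, 15)
  ratios <- vapply(1:40, function(r) {
    f <- synth_fid(data.frame(amplitude = c(1, 0.9), frequency_hz = c(-150, 150),
                              width_hz = 10, phase_rad = 0),
                   dwell_ms = 0.25, n = 1024, noise_sigma = sigma, seed = 500 + r)
    fit <- fit_fid(f, 2)
    a <- fit$peaks$amplitude[order(fit$peaks$frequency_hz)]
    a[2] / a[1]
  }, numeric(1))
  expect_gt(mean(ratios), 0.85)
  expect_lt(mean(ratios), 0.95)
})

test_that("SNR follows the magnitude-noise closed form", {
  n <- 1024
  dwell <- 0.25
  A <- 1
  w <- 10
  sigma <- 0.1                       # noise floor well above dispersive tails
  dt <- dwell * 1e-3
  freq <- 154 / (2 * n * dt)         # on the zero-filled frequency grid
  rho <- exp(-pi * w * dt)
  # geometric-sum peak height with the halved first point
  height <- A * (1 - rho^n) / (1 - rho) - A / 2
  sd_mag <- sigma * sqrt(n) * sqrt(2 - pi / 2)
  expected <- height / sd_mag
  got <- vapply(1:100, function(r) {
    f <- synth_fid(one_peak(A = A, f = freq, w = w, ph = 0), dwell, n,
                   noise_sigma = sigma, seed = 2000 + r)
    fit <- fit_fid(f, 1)
    snr(f, fit, background_ppm = c(146, 152))$snr
  }, numeric(1))
  expect_equal(mean(got), expected, tolerance = 0.05)
})

test_that("SNR is invariant to a global phase of the FID", {
  f <- synth_fid(one_peak(ph = 0), 0.25, 1024, noise_sigma = 0.01, seed = 4)
  fit <- fit_fid(f, 1)
  s1 <- snr(f, fit, c(150, 160))$snr
  f2 <- f
  f2$samples <- f2$samples * exp(1i * 1.1)
  fit2 <- fit_fid(f2, 1)
  s2 <- snr(f2, fit2, c(150, 160))$snr
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("degenerate SNR inputs are flagged or rejected", {
  f <- synth_fid(one_peak(), 0.25, 1024)          # noiseless
  fit <- fit_fid(f, 1)
  res <- snr(f, fit, c(150, 160))
  expect_true(res$overflow)
  expect_error(snr(f, fit, c(171, 172)), class = "hpmrsim_invalid_parameter")
})

test_that("the magnitude background of pure noise reads approximately 2", {
  vals <- vapply(1:50, function(r) {
    f <- synth_fid(one_peak(A = 0), 0.25, 2048, noise_sigma = 1, seed = 300 + r)
    apparent_background_snr(f, c(150, 165))
  }, numeric(1))
  # Rayleigh mean/sd = sqrt(pi/2)/sqrt(2 - pi/2) ~ 1.91
  expect_equal(mean(vals), sqrt(pi / 2) / sqrt(2 - pi / 2), tolerance = 0.05)
  expect_equal(round(mean(vals)), 2)
})

test_that("line broadening adds to the Lorentzian width and composes", {
  f <- synth_fid(one_peak(w = 8), 0.25, 1024)
  expect_equal(line_broaden(f, 0)$samples, f$samples)
  fit <- fit_fid(line_broaden(f, 5), 1)
  expect_equal(fit$peaks$width_hz, 13, tolerance = 0.02 * 13)
  ab <- line_broaden(line_broaden(f, 2), 3)
  once <- line_broaden(f, 5)
  expect_equal(ab$samples, once$samples, tolerance = 1e-12)
})
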