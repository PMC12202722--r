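# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: the Bloch oracle integrates with a
# power-series matrix exponential at fine substeps instead of the package's
# closed-form axis-angle rotations, and the timing oracle searches a 0.01 ms
# TE grid with constructive feasibility checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

# matrix exponential by scaling-and-squaring power series
expm3 <- function(A) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 2L)
  As <- A / 2^s
  X <- diag(3)
  term <- diag(3)
  for (k in 1:20) {
    term <- term %*% As / k
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# dense-step Bloch integration: per waveform sample, exponentiate the
# generator of the Bloch rotation (no relaxation), with substeps
oracle_propagate <- function(pulse, gradient_mt_m, peak_b1_mt, positions_mm,
                             gamma = 10.708, M0 = c(0, 0, 1), substeps = 4) {
  dt <- pulse$duration_ms * 1e-3 / (length(pulse$samples) - 1)
  out <- matrix(NA_real_, length(positions_mm), 3)
  for (i in seq_along(positions_mm)) {
    fz <- gamma * gradient_mt_m * positions_mm[i]
    M <- M0
    for (k in seq_along(pulse$samples)) {
      b1 <- peak_b1_mt * pulse$samples[k]
      wx <- 2 * pi * gamma * 1e3 * Re(b1)
      wy <- 2 * pi * gamma * 1e3 * Im(b1)
      wz <- 2 * pi * fz
      A <- matrix(c(0, -wz, wy,
                    wz, 0, -wx,
                    -wy, wx, 0), 3, 3, byrow = TRUE)
      R <- expm3(A * dt / substeps)
      for (ss in seq_len(substeps)) M <- R %*% M
    }
    out[i, ] <- M
  }
  out
}

# brute-force minimal semi-LASER TE on a 0.01 ms grid: a TE is feasible when
# tau1 = b1, tau3 = b3, tau5 = TE/2 - b1 - b3 >= b5 on the odd side and
# tau2 = b2, tau4 = TE/2 - b2 >= b4 on the even side
brute_force_te <- function(bounds, step = 0.01) {
  te <- sum(bounds)
  te <- floor(te / step) * step
  repeat {
    half <- te / 2
    ok_odd <- half - bounds[1] - bounds[3] >= bounds[5] - 1e-9
    ok_even <- half - bounds[2] >= bounds[4] - 1e-9
    if (ok_odd && ok_even) return(te)
    te <- te + step
  }
}

# sign convention used by the rotation engine: a hard pulse along +x takes
# (0,0,1) to (0,-1,0); shared by a few tests
expect_vec_equal <- function(got, want, tol = 1e-6) {
  expect_lt(max(abs(got - want)), tol)
}
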