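small_grid <- function(t1 = Inf, ext = 10) {
  magnetization_grid(c(-ext, ext), c(-ext, ext), c(-ext, ext),
                     resolution_mm = 0.5, t1_s = t1)
}

test_that("excitation consumes the longitudinal pool by cos(flip) in-slab", {
  g <- small_grid()
  tot0 <- sum(g$mz)
  # 90 degrees over half the grid halves the total
  g1 <- apply_excitation(g, "z", c(0, 10), 90)
  expect_equal(sum(g1$mz) / tot0, 0.5, tolerance = 1e-12)
  # 35 degrees multiplies in-slab Mz by cos(35)
  g2 <- apply_excitation(g, "z", c(-10, 10), 35)
  expect_equal(mean(g2$mz), cos(35 * pi / 180), tolerance = 1e-12)
  expect_error(apply_excitation(g, "z", c(-10, 10), 200),
               class = "hpmrsim_invalid_parameter")
  expect_warning(apply_excitation(g, "z", c(50, 60), 90), "outside")
})

test_that("refocusing efficiency maps inversion, saturation and involution", {
  g <- small_grid()
  g1 <- apply_refocusing(g, "x", c(-10, 10), q = 1)
  expect_equal(mean(g1$mz), -1)
  g2 <- apply_refocusing(g1, "x", c(-10, 10), q = 1)
  expect_equal(g2$mz, g$mz)                     # perfect inversion twice
  g3 <- apply_refocusing(g, "x", c(-10, 10), q = 0.5)
  expect_true(all(abs(g3$mz) < 1e-12))          # full saturation
  expect_error(apply_refocusing(g, "x", c(0, 1), q = 1.2),
               class = "hpmrsim_invalid_parameter")
})

test_that("relaxation is mono-exponential and composes as a semigroup", {
  g <- small_grid(t1 = 3)
  expect_equal(mean(relax(g, 3)$mz), exp(-1), tolerance = 1e-12)
  expect_equal(relax(g, 0)$mz, g$mz)
  two <- relax(relax(g, 0.7), 1.1)
  one <- relax(g, 1.8)
  expect_equal(two$mz, one$mz, tolerance = 1e-12)
  expect_error(relax(g, -1), class = "hpmrsim_invalid_parameter")
})

test_that("non-overlapping voxels with perfect refocusing see full magnetization", {
  plan <- voxel_plan(c("a", "b", "c"),
                     rbind(c(-6, -6, -6), c(0, 0, 0), c(6, 6, 6)), c(3, 3, 3))
  acq <- simulate_acquisition(plan, small_grid(), flip_deg = 90, tr_ms = 500, q = 1)
  expect_equal(acq$record$available, rep(1, 3), tolerance = 1e-12)
  expect_true(all(diff(acq$record$time_s) > 0))
})

test_that("total magnetization is conserved under perfect refocusing without overlap", {
  plan <- voxel_plan(c("a", "b"), rbind(c(-6, -6, -6), c(6, 6, 6)), c(3, 3, 3))
  g <- small_grid()
  acq <- simulate_acquisition(plan, g, flip_deg = 1e-9, tr_ms = 100, q = 1)
  expect_equal(sum(abs(acq$grid$mz)), sum(abs(g$mz)), tolerance = 1e-6)
})

test_that("adiabatic refocusing preserves more magnetization than SLR under overlap", {
  plan <- voxel_plan(c("L", "R"), rbind(c(-5, 0, 0), c(5, 0, 0)), c(5.5, 4.5, 9.7))
  roles <- c(exc = "x", ref1 = "y", ref2 = "z")
  run <- function(refoc) {
    simulate_acquisition(plan, small_grid(), flip_deg = 90, tr_ms = 1000,
                         refocusing = refoc, roles = roles)
  }
  afp <- run("afp")
  slr <- run("slr")
  # the second voxel's first shot sees more magnetization under adiabatic
  # refocusing, and more total polarization is left afterwards
  expect_gt(afp$record$signal[2], slr$record$signal[2])
  expect_gt(afp$remaining / slr$remaining, 1)
})

test_that("semi-LASER remaining fraction dominates PRESS over random overlapping plans", {
  set.seed(13)
  for (i in 1:5) {
    ctrs <- matrix(stats::runif(9, -4, 4), 3, 3)
    plan <- voxel_plan(c("a", "b", "c"), ctrs, c(5, 5, 5))
    afp <- simulate_acquisition(plan, small_grid(), flip_deg = 90,
                                tr_ms = 500, refocusing = "afp")
    slr <- simulate_acquisition(plan, small_grid(), flip_deg = 90,
                                tr_ms = 500, refocusing = "slr")
    expect_gte(afp$remaining, slr$remaining)
  }
})

test_that("remaining fraction decreases with voxel count and flip angle", {
  mk_plan <- function(n) {
    ctr <- cbind(seq(-6, 6, length.out = n), 0, 0)
    voxel_plan(paste0("v", seq_len(n)), ctr, c(3, 3, 3))
  }
  rem_n <- vapply(1:3, function(n) {
    simulate_acquisition(mk_plan(n), small_grid(), flip_deg = 45,
                         tr_ms = 500, q = 0.9)$remaining
  }, numeric(1))
  expect_true(all(diff(rem_n) < 1e-12))
  rem_flip <- vapply(c(15, 45, 90), function(fl) {
    simulate_acquisition(mk_plan(2), small_grid(), flip_deg = fl,
                         tr_ms = 500, q = 0.9)$remaining
  }, numeric(1))
  expect_true(all(diff(rem_flip) < 1e-12))
})

test_that("a plan with zero voxels leaves only T1 decay", {
  g <- small_grid(t1 = 4)
  empty <- voxel_plan(character(0), matrix(numeric(0), 0, 3),
                      matrix(numeric(0), 0, 3))
  acq <- simulate_acquisition(empty, g, tr_ms = 1000)
  expect_equal(acq$remaining, 1)   # no shots, no elapsed time
})

test_that("Bloch-profile excitation is close to the ideal boxcar for a sharp pulse", {
  e <- make_excitation_pulse(90, 5400)
  prof <- slice_profile(e, thickness_mm = 5, fov_mm = 40, n_points = 401)
  g <- small_grid()
  ideal <- apply_excitation(g, "z", c(-2.5, 2.5), 90)
  real <- apply_excitation(g, "z", c(-2.5, 2.5), 90, profile = prof)
  expect_lt(abs(sum(real$mz) - sum(ideal$mz)) / sum(g$mz), 0.05)
})

test_that("effective T1 fits recover exact and closed-form decay constants", {
  t <- seq(0, 20, by = 2)
  fit <- effective_t1(t, exp(-t / 3))
  expect_equal(fit$t1eff_s, 3, tolerance = 1e-6)

  # repeated 35-degree excitation of one voxel every 2 s with intrinsic T1 5 s
  g <- magnetization_grid(c(-5, 5), c(-5, 5), c(-5, 5), 0.5, t1_s = 5)
  plan <- voxel_plan("v", c(0, 0, 0), c(4, 4, 4))
  acq <- simulate_acquisition(plan, g, flip_deg = 35, tr_ms = 2000, q = 1,
                              n_repeats = 10)
  t1eff <- effective_t1(acq)$t1eff_s
  closed <- 1 / (1 / 5 - log(cos(35 * pi / 180)) / 2)
  expect_equal(t1eff, closed, tolerance = 0.02)

  expect_error(effective_t1(t, exp(t / 3)), class = "hpmrsim_fit_failure")
})

test_that("saturating the paired voxel shortens the fitted effective T1", {
  plan <- voxel_plan("v", c(0, 0, 0), c(4, 4, 4))
  t1eff_q <- vapply(c(1, 0.9, 0.7), function(qq) {
    g <- magnetization_grid(c(-5, 5), c(-5, 5), c(-5, 5), 0.5, t1_s = 5)
    acq <- simulate_acquisition(plan, g, flip_deg = 35, tr_ms = 2000, q = qq,
                                n_repeats = 8)
    effective_t1(acq)$t1eff_s
  }, numeric(1))
  expect_true(all(diff(t1eff_q) < 0))
})
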