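test_that("centric ordering starts at the k-space center and covers the grid", {
  expect_equal(as.data.frame(centric_order(1, 1)),
               data.frame(j = 1L, kx = 0, ky = 0))

  for (sz in list(c(3, 5), c(12, 8), c(13, 11), c(4, 4))) {
    o <- centric_order(sz[1], sz[2])
    # permutation of the full grid
    expect_equal(nrow(o), prod(sz))
    expect_equal(nrow(unique(o[, c("kx", "ky")])), prod(sz))
    expect_true(all(o$kx >= 0 & o$kx < sz[1] & o$ky >= 0 & o$ky < sz[2]))
    # first acquired point is the center
    expect_equal(c(o$kx[1], o$ky[1]), c(sz[1] %/% 2, sz[2] %/% 2))
  }

  # corners of a 12 x 8 grid fall in the last quarter of the acquisition
  o <- centric_order(12, 8)
  corners <- o$j[(o$kx %in% c(0, 11)) & (o$ky %in% c(0, 7))]
  expect_true(all(corners > 0.75 * nrow(o)))
})

test_that("k-space weights equal a step-by-step longitudinal simulation", {
  o <- centric_order(12, 8)
  w <- kspace_weights(o, flip_deg = 10, tr_ms = 230, t1_s = 60)
  th <- 10 * pi / 180
  mz <- 1
  w_seq <- numeric(nrow(o))
  for (j in seq_len(nrow(o))) {
    w_seq[j] <- mz * sin(th)
    mz <- mz * cos(th) * exp(-0.230 / 60)
  }
  expect_lt(max(abs(w$weight - w_seq)), 1e-12)
  expect_equal(w$weight[1], sin(th))
  expect_true(all(diff(w$weight) < 0))
})

test_that("k-space weight limits: 90-degree burns everything, small tips are uniform", {
  o <- centric_order(6, 6)
  w90 <- kspace_weights(o, 90, 100, Inf)
  expect_equal(w90$weight[1], 1)
  expect_true(all(w90$weight[-1] < 1e-12))
  w0 <- kspace_weights(o, 0.1, 100, 1e9)
  expect_lt(diff(range(w0$weight)) / w0$weight[1], 1e-4)
})

test_that("uniform weights give a Dirichlet PSF with a one-voxel main lobe", {
  o <- centric_order(16, 16)
  o$weight <- 1
  class(o) <- c("weighted_kspace", "data.frame")
  p <- psf(o)
  expect_equal(max(Mod(p)), 1)
  ctr <- Mod(p[, 9])
  # half-maximum width of the central lobe ~ 1 voxel
  fw <- profile_fwhm(seq_len(16), ctr)
  expect_lt(abs(fw - 1), 0.3)
})

test_that("all weight on the k-space center gives a flat PSF", {
  o <- centric_order(8, 8)
  o$weight <- as.numeric(o$j == 1)
  class(o) <- c("weighted_kspace", "data.frame")
  p <- psf(o)
  expect_lt(diff(range(Mod(p))), 1e-12)
})

test_that("PSF energy satisfies Parseval against the weight energy", {
  w <- kspace_weights(centric_order(12, 8), 10, 230, 60)
  p <- psf(w)
  pk <- attr(p, "norm")
  lhs <- sum(Mod(p * pk)^2) * (12 * 8)
  rhs <- sum(w$weight^2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("centric weighting bleeds more along rows than columns", {
  w <- kspace_weights(centric_order(12, 8), 10, 230, 60)
  p <- psf(w)
  expect_gt(psf_sidelobe_energy(p, "x"), psf_sidelobe_energy(p, "y"))
})

test_that("convolution with the sampling PSF reproduces known limits", {
  nx <- 12; ny <- 8
  w <- kspace_weights(centric_order(nx, ny), 10, 230, 60)
  # delta object: image equals the (center-normalized) PSF
  dl <- matrix(0, nx, ny)
  dl[nx %/% 2 + 1, ny %/% 2 + 1] <- 1
  cv <- convolve_object(dl, w)
  p <- psf(w)
  ratio <- cv$image[nx %/% 2 + 1, ny %/% 2 + 1] / p[nx %/% 2 + 1, ny %/% 2 + 1]
  expect_lt(max(Mod(cv$image - p * ratio)), 1e-9)

  # uniform weights: identity up to numerical noise, flat interior
  wu <- w
  wu$weight <- 1
  obj <- matrix(0, nx, ny)
  obj[5:8, 3:6] <- 1
  cvu <- convolve_object(obj, wu)
  expect_lt(max(Mod(cvu$bleed)), 1e-9)

  # centric weights: bleeding is stronger left-right than up-down
  cvc <- convolve_object(obj, w)
  bl <- Mod(cvc$bleed)
  bleed_x <- max(bl[, 5][-(5:8)])
  bleed_y <- max(bl[6, ][-(3:6)])
  expect_gt(bleed_x, bleed_y)

  expect_error(convolve_object(matrix(0, 5, 5), w),
               class = "hpmrsim_invalid_parameter")
})

test_that("effective resolution is never better than the nominal voxel", {
  o <- centric_order(16, 16)
  fw_for <- function(weights) {
    o$weight <- weights
    class(o) <- c("weighted_kspace", "data.frame")
    profile_fwhm(seq_len(16), Mod(psf(o)[, 9]))
  }
  fw_uniform <- fw_for(rep(1, nrow(o)))
  fw_decay <- fw_for(kspace_weights(o, 10, 230, 5)$weight)
  expect_gte(fw_decay, fw_uniform - 1e-9)
})
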