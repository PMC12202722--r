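test_that("slabs realize the voxel box on the assigned axes", {
  plan <- voxel_plan("v", c(0, 0, 0), c(2, 2, 2))
  s <- slabs_of(plan[1, ], roles = c(exc = "z", ref1 = "x", ref2 = "y"))
  expect_equal(s$min, c(-1, -1, -1))
  expect_equal(s$max, c(1, 1, 1))
  expect_equal(s$axis[s$role == "exc"], "z")

  # 2.5 mm cube at (3, 0, 0): refocusing slab on x spans [1.75, 4.25]
  p2 <- voxel_plan("t", c(3, 0, 0), c(2.5, 2.5, 2.5))
  s2 <- slabs_of(p2[1, ])
  expect_equal(unlist(s2[s2$role == "ref1", c("min", "max")], use.names = FALSE),
               c(1.75, 4.25))

  expect_error(slabs_of(p2[1, ], roles = c(exc = "z", ref1 = "z", ref2 = "y")),
               class = "hpmrsim_invalid_parameter")
})

test_that("slab intersection reproduces the voxel box for random voxels", {
  set.seed(42)
  for (i in 1:20) {
    ctr <- stats::runif(3, -20, 20)
    sz <- stats::runif(3, 0.5, 12)
    plan <- voxel_plan("v", ctr, sz)
    s <- slabs_of(plan[1, ])
    for (ax in c("x", "y", "z")) {
      row <- s[s$axis == ax, ]
      expect_equal(c(row$min, row$max),
                   c(ctr[match(ax, c("x", "y", "z"))] - sz[match(ax, c("x", "y", "z"))] / 2,
                     ctr[match(ax, c("x", "y", "z"))] + sz[match(ax, c("x", "y", "z"))] / 2))
    }
  }
})

test_that("overlap report flags later voxels inside earlier slabs", {
  # disjoint on all slab axes: empty report
  p <- voxel_plan(c("a", "b"), rbind(c(0, 0, 0), c(20, 20, 20)), c(3, 3, 3))
  expect_equal(nrow(overlap_report(p)), 0)

  # identical voxel twice: all three roles at fraction 1
  p2 <- voxel_plan(c("a", "b"), rbind(c(0, 0, 0), c(0, 0, 0)), c(3, 3, 3))
  r2 <- overlap_report(p2)
  expect_equal(nrow(r2), 3)
  expect_equal(r2$fraction, rep(1, 3))
  expect_setequal(r2$role, c("exc", "ref1", "ref2"))

  # side-by-side kidneys: shared refocusing extents, disjoint excitation axis
  p3 <- voxel_plan(c("L", "R"), rbind(c(-5, 0, 0), c(5, 0, 0)), c(5.5, 4.5, 9.7))
  r3 <- overlap_report(p3, roles = c(exc = "x", ref1 = "y", ref2 = "z"))
  expect_setequal(r3$role, c("ref1", "ref2"))
  expect_equal(r3$fraction, c(1, 1))
})

test_that("overlap report is order-sensitive but geometrically symmetric", {
  p <- voxel_plan(c("a", "b"), rbind(c(0, 0, 0), c(1, 0, 0)), c(3, 3, 3))
  fwd <- overlap_report(p)
  rev_plan <- voxel_plan(c("b", "a"), rbind(c(1, 0, 0), c(0, 0, 0)), c(3, 3, 3))
  bwd <- overlap_report(rev_plan)
  expect_true(all(fwd$later == "b"))
  expect_true(all(bwd$later == "a"))
  expect_equal(sort(fwd$fraction), sort(bwd$fraction))
})

test_that("overlap fractions are bounded and monotone in slab thickness", {
  set.seed(7)
  for (i in 1:10) {
    ctrs <- matrix(stats::runif(6, -5, 5), 2, 3)
    fr <- vapply(c(2, 4, 8), function(sz) {
      p <- voxel_plan(c("a", "b"), ctrs, c(sz, sz, sz))
      r <- overlap_report(p)
      if (nrow(r)) sum(r$fraction) else 0
    }, numeric(1))
    expect_true(all(fr >= 0 & fr <= 3))
    expect_true(all(diff(fr) >= -1e-12))
  }
})

test_that("chemical shift displacement arithmetic reproduces the printed values", {
  expect_equal(round(csde(900, 3400)$fraction_pct), 26)
  expect_equal(round(csde(900, 3200)$fraction_pct), 28)
  expect_equal(round(csde(900, 5400)$fraction_pct), 17)
  z <- csde(0, 3400, thickness_mm = 5)
  expect_equal(z$fraction_pct, 0)
  expect_equal(z$displacement_mm, 0)
  expect_equal(csde(900, 3400, thickness_mm = 5)$displacement_mm,
               900 / 3400 * 5)
  expect_error(csde(900, 0), class = "hpmrsim_invalid_parameter")
})

test_that("voxel volume arithmetic", {
  expect_equal(voxel_volume_ul(c(2, 2, 2)), 8)
  expect_equal(voxel_volume_ul(c(5.5, 4.5, 9.7)), 5.5 * 4.5 * 9.7)
})

test_that("voxel plans round-trip through CSV", {
  p <- voxel_plan(c("a", "b"), rbind(c(0, 1, 2), c(3, 4, 5)), c(2, 3, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_voxel_plan(p, path)
  q <- read_voxel_plan(path)
  expect_equal(as.data.frame(q), as.data.frame(p))
})
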