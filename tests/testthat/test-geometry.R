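test_that("geometry construction: spacing, trivial angle sets, stored pitch", {
  g300 <- makeGeometry(views = 300)
  expect_equal(diff(viewAngles(g300))[1], 1.2)
  expect_equal(length(viewAngles(g300)), 300L)

  g4 <- makeGeometry(views = 4)
  expect_equal(viewAngles(g4), c(0, 90, 180, 270))

  gc <- clinicalGeometry(rows = 16L, cols = 16L)
  expect_identical(gc@detector_pitch_mm, 0.388)
  expect_equal(length(viewAngles(gc)), 300L)

  expect_error(makeGeometry(sid_mm = 900, sdd_mm = 800), "sdd")
})

test_that("forward projection of a zero volume is exactly zero", {
  g <- tiny_geometry(views = 4)
  p <- forwardProject(array(0, c(16, 16, 16)), g, voxel_pitch_mm = 2)
  expect_true(all(projData(p) == 0))
  expect_equal(dim(projData(p)), c(64L, 64L, 4L))
})

test_that("central ray through a unit voxel integrates its chord length", {
  # single voxel of mu = 1 /cm at the isocenter; the central ray crosses it
  # axis-aligned, so the exact Siddon intersection length is the voxel pitch
  pitch <- 2
  vol <- array(0, c(17, 17, 17)); vol[9, 9, 9] <- 1
  g <- makeGeometry(views = 1, rows = 5, cols = 5, detector_pitch_mm = 1,
                    sid_mm = 650, sdd_mm = 923)
  p <- suppressWarnings(forwardProject(vol, g, voxel_pitch_mm = pitch))
  expect_equal(projData(p)[3, 3, 1], pitch / 10, tolerance = 1e-6)
})

test_that("uniform cylinder: central ray matches the analytic chord", {
  n <- 32L; pitch <- 3; r_mm <- 30; mu <- 0.25
  vol <- cylinder_volume(n, pitch, r_mm, mu)
  g <- makeGeometry(views = 1, rows = 32, cols = 32, detector_pitch_mm = 5)
  p <- forwardProject(vol, g, voxel_pitch_mm = pitch)
  central <- projData(p)[16:17, 16:17, 1]
  chord_cm <- 2 * r_mm / 10
  expect_lt(max(abs(central - mu * chord_cm)) / (mu * chord_cm), 0.02)
})

test_that("the projector is linear", {
  g <- tiny_geometry(views = 6)
  set.seed(11)
  x <- array(runif(16^3), c(16, 16, 16))
  y <- array(runif(16^3), c(16, 16, 16))
  pa <- projData(forwardProject(2 * x + 3 * y, g, voxel_pitch_mm = 2))
  pb <- 2 * projData(forwardProject(x, g, voxel_pitch_mm = 2)) +
    3 * projData(forwardProject(y, g, voxel_pitch_mm = 2))
  expect_equal(pa, pb, tolerance = 1e-12)
})

test_that("forward and ray backprojection satisfy the adjoint identity", {
  set.seed(42)
  g <- makeGeometry(views = 8, rows = 24, cols = 24, detector_pitch_mm = 4)
  for (rep in 1:3) {
    x <- array(runif(16^3), c(16, 16, 16))
    y <- array(runif(24 * 24 * 8), c(24, 24, 8))
    Ax <- projData(forwardProject(x, g, voxel_pitch_mm = 2))
    Aty <- backprojectRays(y, c(16, 16, 16), 2, geometry = g)
    i1 <- sum(Ax * y); i2 <- sum(x * Aty)
    expect_lt(abs(i1 - i2) / abs(i1), 1e-4)
  }
})

test_that("ray backprojection of zero projections is zero; support is the ray footprint", {
  g1 <- makeGeometry(views = 1, rows = 16, cols = 16, detector_pitch_mm = 8)
  z <- backprojectRays(array(0, c(16, 16, 1)), c(16, 16, 16), 2,
                       geometry = g1)
  expect_true(all(z == 0))

  # a single nonzero detector cell smears along exactly one ray: the
  # touched voxels must match the gather footprint of the forward operator
  proj <- array(0, c(16, 16, 1)); proj[8, 8, 1] <- 1
  bp <- backprojectRays(proj, c(16, 16, 16), 2, geometry = g1)
  touched <- bp != 0
  # oracle: forward-project an indicator of each touched voxel; it must hit
  # detector cell (8,8). Spot-check the voxel of maximum weight.
  w <- which(bp == max(bp), arr.ind = TRUE)[1, ]
  ind <- array(0, c(16, 16, 16)); ind[w[1], w[2], w[3]] <- 1
  pf <- projData(forwardProject(ind, g1, voxel_pitch_mm = 2))
  expect_gt(pf[8, 8, 1], 0)
  expect_lt(mean(touched), 0.2)  # support is a thin tube, not the volume
})

test_that("Poisson noise: vanishing at high fluence, seeded, unbiased at p=0", {
  g <- makeGeometry(views = 2, rows = 50, cols = 100, detector_pitch_mm = 2)
  vol <- cylinder_volume(24L, 4, 40, 0.25)
  p <- forwardProject(vol, g, voxel_pitch_mm = 4)

  hi <- addPoissonNoise(p, 1e12, seed = 1)
  expect_lt(max(abs(projData(hi) - projData(p))) /
              max(projData(p)), 1e-3)

  n1 <- addPoissonNoise(p, 1e4, seed = 9)
  n2 <- addPoissonNoise(p, 1e4, seed = 9)
  expect_identical(projData(n1), projData(n2))
  n3 <- addPoissonNoise(p, 1e4, seed = 10)
  expect_false(identical(projData(n1), projData(n3)))

  # zero line integrals: sample mean of noisy integrals ~ 0 within 3 SE
  p0 <- forwardProject(array(0, c(8, 8, 8)), g, voxel_pitch_mm = 2)
  nz <- addPoissonNoise(p0, 1e4, seed = 5)
  vals <- as.numeric(projData(nz))      # 10000 rays
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-12)
})

test_that("projections of a centrally symmetric object are identical across views", {
  # a smooth Gaussian ball: rotationally symmetric up to interpolation, so
  # every view must agree (a hard-edged cylinder would add voxelization
  # staircase differences on top of the projector's own error)
  n <- 32L; pitch <- 3
  xs <- (seq_len(n) - (n + 1) / 2) * pitch
  r2 <- outer(outer(xs^2, xs^2, "+"), xs^2, "+")
  vol <- 0.25 * array(exp(-r2 / (2 * 15^2)), c(n, n, n))
  g <- makeGeometry(views = 8, rows = 48, cols = 48, detector_pitch_mm = 3)
  p <- projData(forwardProject(vol, g, voxel_pitch_mm = pitch))
  ref <- p[, , 1]
  for (k in 2:8)
    expect_lt(max(abs(p[, , k] - ref)), 0.02 * max(ref))
})

test_that("projection sets round-trip through NIfTI + JSON sidecar", {
  g <- tiny_geometry(views = 3)
  ph <- tiny_phantom(seed = 1)
  p <- addPoissonNoise(forwardProject(ph, g), 1e5, seed = 2)
  f <- tempfile(fileext = ".nii.gz")
  writeProjections(p, f)
  p2 <- readProjections(f)
  expect_equal(projData(p2), projData(p), tolerance = 1e-6)
  expect_identical(viewAngles(p2), viewAngles(p))
  expect_identical(p2@photons_per_ray, 1e5)
  expect_identical(p2@seed, 2)
})
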