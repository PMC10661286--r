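make_flat_projset <- function(value, nu = 16L, nv = 8L, views = 4L,
                              det_pitch = 2) {
  g <- makeGeometry(views = views, rows = nv, cols = nu,
                    detector_pitch_mm = det_pitch)
  new("ProjectionSet", data = array(value, c(nu, nv, views)), geometry = g,
      photons_per_ray = Inf, seed = NA_real_)
}

test_that("cosine weights: unity on axis, analytic off-axis, full-map oracle", {
  p <- make_flat_projset(1, nu = 17L, nv = 9L, views = 1L, det_pitch = 2)
  w <- projData(cosineWeight(p))
  # central element (u = v = 0) untouched
  expect_equal(w[9, 5, 1], 1)
  # element-wise oracle loop
  g <- scanGeometry(p)
  D <- g@sdd_mm
  for (iu in c(1L, 5L, 17L)) for (iv in c(1L, 9L)) {
    u <- (iu - 9) * 2; v <- (iv - 5) * 2
    expect_equal(w[iu, iv, 1], D / sqrt(D^2 + u^2 + v^2), tolerance = 1e-12)
  }
  # synthetic geometry in which an element sits at u = v with
  # u^2 + v^2 = 3 D^2: weight must be exactly 1/2
  gx <- makeGeometry(views = 1, rows = 3, cols = 3,
                     detector_pitch_mm = sqrt(1.5) * 923,
                     sid_mm = 650, sdd_mm = 923)
  px <- new("ProjectionSet", data = array(1, c(3, 3, 1)), geometry = gx,
            photons_per_ray = Inf, seed = NA_real_)
  wx <- projData(cosineWeight(px))
  expect_equal(wx[1, 1, 1], 0.5, tolerance = 1e-12)
})

test_that("ramp filter removes DC and reproduces the discrete kernel", {
  # constant rows: DC content is suppressed in the row interior (the
  # boxcar edges of a finite constant row ring by construction; real
  # projections taper to zero at the row ends)
  p <- make_flat_projset(5, nu = 256L, nv = 4L, views = 2L)
  f <- projData(rampFilter(p, window = "ramlak"))
  interior <- f[65:192, , ]
  # truncation tail of the band-limited kernel bounds the interior
  # residual at ~(2/pi^2)/nu of the input per unit pitch
  expect_lt(max(abs(interior)), 0.01 * 5)
  expect_lt(abs(mean(interior)), 0.005 * 5)

  # unit impulse: response equals pitch * analytic kernel
  # r(0) = 1/(4 d^2), r(odd k) = -1/(pi k d)^2, r(even k) = 0
  nu <- 16L
  p2 <- make_flat_projset(0, nu = nu, nv = 1L, views = 1L, det_pitch = 2)
  dat <- projData(p2); dat[8, 1, 1] <- 1
  p2@data <- dat
  out <- projData(rampFilter(p2, window = "ramlak"))[, 1, 1]
  d_cm <- 2 / 10
  expected <- vapply(seq_len(nu) - 8L, function(k) {
    if (k == 0L) 1 / (4 * d_cm^2)
    else if (k %% 2L != 0L) -1 / (pi * k * d_cm)^2
    else 0
  }, numeric(1)) * d_cm
  expect_equal(out, expected, tolerance = 1e-10)
})

test_that("ramp filtering is linear", {
  set.seed(3)
  pa <- make_flat_projset(0); pb <- make_flat_projset(0)
  da <- array(rnorm(length(projData(pa))), dim(projData(pa)))
  db <- array(rnorm(length(projData(pa))), dim(projData(pa)))
  pa@data <- da; pb@data <- db
  pc <- pa; pc@data <- 2 * da - 3 * db
  lhs <- projData(rampFilter(pc))
  rhs <- 2 * projData(rampFilter(pa)) - 3 * projData(rampFilter(pb))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("FDK of zero projections is zero; degenerate inputs fail", {
  p <- make_flat_projset(0, views = 8L)
  rec <- fdkReconstruct(p, c(12, 12, 12), 2)
  expect_true(all(muVolume(rec) == 0))
  expect_identical(methodTag(rec), "FDK")

  p1 <- make_flat_projset(0, views = 1L)
  expect_error(fdkReconstruct(p1, c(8, 8, 8), 2), "2 views")
  # non-uniform angles
  g <- makeGeometry(views = 4, rows = 8, cols = 16, detector_pitch_mm = 2)
  g@view_angles_deg <- c(0, 10, 180, 270)
  pbad <- new("ProjectionSet", data = array(0, c(16, 8, 4)), geometry = g,
              photons_per_ray = Inf, seed = NA_real_)
  expect_error(fdkReconstruct(pbad, c(8, 8, 8), 2), "uniformly spaced")
})

test_that("FDK recovers a uniform cylinder within 3% in the central ROI", {
  n <- 64L; pitch <- 1.5
  vol <- cached("cyl64", cylinder_volume(n, pitch, 30, 0.25))
  g <- makeGeometry(views = 120, rows = 96, cols = 96,
                    detector_pitch_mm = 2.2)
  p <- cached("cylproj", forwardProject(vol, g, voxel_pitch_mm = pitch))
  rec <- fdkReconstruct(p, c(n, n, n), pitch, window = "hann")
  roi <- disc_roi(n, pitch, 15)
  mid <- muVolume(rec)[, , n / 2]
  expect_lt(abs(mean(mid[roi]) - 0.25) / 0.25, 0.03)

  # ram-lak window also recovers the plateau
  rec2 <- fdkReconstruct(p, c(n, n, n), pitch, window = "ramlak")
  mid2 <- muVolume(rec2)[, , n / 2]
  expect_lt(abs(mean(mid2[roi]) - 0.25) / 0.25, 0.03)
})

test_that("the whole FDK chain is linear", {
  g <- tiny_geometry(views = 12)
  set.seed(8)
  a <- array(runif(16^3, 0, 0.3), c(16, 16, 16))
  b <- array(runif(16^3, 0, 0.3), c(16, 16, 16))
  pa <- forwardProject(a, g, voxel_pitch_mm = 4)
  pb <- forwardProject(b, g, voxel_pitch_mm = 4)
  pc <- forwardProject(2 * a + b, g, voxel_pitch_mm = 4)
  ra <- muVolume(fdkReconstruct(pa, c(16, 16, 16), 4))
  rb <- muVolume(fdkReconstruct(pb, c(16, 16, 16), 4))
  rc <- muVolume(fdkReconstruct(pc, c(16, 16, 16), 4))
  expect_equal(rc, 2 * ra + rb, tolerance = 1e-8)
})

test_that("phantom FDK beats a single-view smear on voxel RMSE", {
  ph <- cached("ph7", tiny_phantom(seed = 7))
  g <- tiny_geometry()
  p <- cached("ph7proj", forwardProject(ph, g))
  rec <- cached("ph7fdk", fdkReconstruct(p, dim(muVolume(ph)), 2.2))
  truth <- muVolume(ph)
  rmse_fdk <- sqrt(mean((muVolume(rec) - truth)^2))

  # baseline: unfiltered single-view ray smear, crudely normalized to the
  # attenuation scale
  one <- new("ProjectionSet", data = p@data[, , 1, drop = FALSE],
             geometry = cbbctVGF:::subset_geom(scanGeometry(p), 1L),
             photons_per_ray = Inf, seed = NA_real_)
  smear <- backprojectRays(one, dim(truth), 2.2)
  smear <- smear * mean(truth) / max(mean(smear), 1e-12)
  rmse_base <- sqrt(mean((smear - truth)^2))
  expect_lt(rmse_fdk, rmse_base)
})

test_that("FDK noise increases monotonically as fluence drops", {
  n <- 48L; pitch <- 2.2
  ph <- cached("ph7", tiny_phantom(seed = 7))
  g <- tiny_geometry()
  p0 <- cached("ph7proj", forwardProject(ph, g))
  roi <- adipose_core(ph)
  noiseless <- cached("ph7fdk", fdkReconstruct(p0, dim(muVolume(ph)), pitch))
  vars <- vapply(c(1e6, 1e5, 1e4), function(ph_per_ray) {
    pn <- addPoissonNoise(p0, ph_per_ray, seed = 13)
    rec <- fdkReconstruct(pn, dim(muVolume(ph)), pitch)
    var(muVolume(rec)[roi] - muVolume(noiseless)[roi])
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})
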