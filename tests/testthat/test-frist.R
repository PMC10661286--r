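# independently coded plain-SART step (the oracle for osSartPass with one
# subset): same operators, update written out directly
sart_oracle_step <- function(x, p, pitch, lambda) {
  g <- scanGeometry(p)
  W <- projData(forwardProject(array(1, dim(x)), g, voxel_pitch_mm = pitch))
  V <- backprojectRays(array(1, dim(projData(p))), dim(x), pitch,
                       geometry = g)
  r <- projData(p) - projData(forwardProject(x, g, voxel_pitch_mm = pitch))
  r <- ifelse(W > 1e-9, r / W, 0)
  u <- backprojectRays(r, dim(x), pitch, geometry = g)
  u <- ifelse(V > 1e-9, u / V, 0)
  x + lambda * u
}

test_that("one-subset OS-SART equals an independently coded SART step", {
  set.seed(21)
  g <- makeGeometry(views = 6, rows = 12, cols = 12, detector_pitch_mm = 8)
  x0 <- array(runif(8^3, 0, 0.3), c(8, 8, 8))
  truth <- array(runif(8^3, 0, 0.3), c(8, 8, 8))
  p <- forwardProject(truth, g, voxel_pitch_mm = 4)
  a <- osSartPass(x0, p, n_subsets = 1L, lambda = 0.8, voxel_pitch_mm = 4)
  b <- sart_oracle_step(x0, p, 4, 0.8)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("OS-SART leaves an exact solution fixed", {
  set.seed(22)
  g <- makeGeometry(views = 8, rows = 12, cols = 12, detector_pitch_mm = 8)
  truth <- array(runif(8^3, 0, 0.3), c(8, 8, 8))
  p <- forwardProject(truth, g, voxel_pitch_mm = 4)
  out <- osSartPass(truth, p, n_subsets = 4L, lambda = 1, voxel_pitch_mm = 4)
  expect_lt(max(abs(out - truth)) / max(truth), 1e-6)
})

test_that("data residual is non-increasing over OS-SART passes (noiseless)", {
  ph <- cached("ph7", tiny_phantom(seed = 7))
  g <- tiny_geometry()
  p <- cached("ph7proj", forwardProject(ph, g))
  x <- array(0, dim(muVolume(ph)))
  res <- function(x) {
    ax <- projData(forwardProject(x, g, voxel_pitch_mm = 2.2))
    sqrt(sum((projData(p) - ax)^2))
  }
  history <- res(x)
  for (i in 1:5) {
    x <- osSartPass(x, p, n_subsets = 10L, lambda = 1, voxel_pitch_mm = 2.2)
    history <- c(history, res(x))
  }
  expect_true(all(diff(history) <= 0))
})

test_that("total variation: constant, unit step, homogeneity", {
  const <- array(3.7, c(8, 8, 8))
  expect_lt(totalVariation(const), 1e-8 * length(const) + 1e-12)

  # a step along x between columns 4 and 5 exposes one 8x8 face
  stepv <- array(0, c(8, 8, 8)); stepv[5:8, , ] <- 1
  expect_equal(totalVariation(stepv), 64, tolerance = 1e-6)

  set.seed(5)
  x <- array(rnorm(8^3), c(8, 8, 8))
  expect_equal(totalVariation(2.5 * x), 2.5 * totalVariation(x),
               tolerance = 1e-3)
})

test_that("TV descent: no-op cases and monotone decrease", {
  const <- array(1, c(8, 8, 8))
  expect_identical(tvDescent(const, 10, 0.1), const)

  set.seed(6)
  x <- array(rep(c(0, 1), each = 256), c(8, 8, 8)) +
    array(rnorm(8^3, 0, 0.1), c(8, 8, 8))
  expect_identical(tvDescent(x, 5, 0), x)
  tvs <- totalVariation(x)
  y <- x
  for (i in 1:10) {
    y <- tvDescent(y, 1, 0.05)
    tvs <- c(tvs, totalVariation(y))
  }
  expect_true(all(diff(tvs) < 0))
  # each step moves exactly step_size in Euclidean norm
  z <- tvDescent(x, 1, 0.05)
  expect_equal(sqrt(sum((z - x)^2)), 0.05, tolerance = 1e-10)
})

test_that("ASD-POCS at an exact noiseless solution stays put", {
  set.seed(23)
  g <- makeGeometry(views = 8, rows = 12, cols = 12, detector_pitch_mm = 8)
  truth <- array(runif(8^3, 0, 0.3), c(8, 8, 8))
  p <- forwardProject(truth, g, voxel_pitch_mm = 4)
  rec <- fristReconstruct(p, fristConfig(n_iterations = 3, n_subsets = 2),
                          c(8, 8, 8), 4, init_volume = truth)
  expect_lt(max(abs(muVolume(rec) - truth)) / max(truth), 1e-5)
})

test_that("with no TV and one subset the full loop reduces to SART", {
  set.seed(24)
  g <- makeGeometry(views = 6, rows = 12, cols = 12, detector_pitch_mm = 8)
  truth <- array(runif(8^3, 0, 0.3), c(8, 8, 8))
  p <- forwardProject(truth, g, voxel_pitch_mm = 4)
  cfg <- fristConfig(n_iterations = 3, n_subsets = 1,
                     tv_steps_per_iteration = 0, init = "zeros",
                     nonneg = FALSE, stop_tol = 0)
  rec <- fristReconstruct(p, cfg, c(8, 8, 8), 4)
  x <- array(0, c(8, 8, 8))
  for (i in 1:3) x <- sart_oracle_step(x, p, 4, 1)
  expect_equal(muVolume(rec), x, tolerance = 1e-10)
})

test_that("iterative reconstruction denoises: lower ROI variance and RMSE than FDK", {
  ph <- cached("ph7", tiny_phantom(seed = 7))
  g <- tiny_geometry()
  p0 <- cached("ph7proj", forwardProject(ph, g))
  pn <- cached("ph7noisy", addPoissonNoise(p0, 1e4, seed = 3))
  grid <- dim(muVolume(ph))
  fdk <- cached("ph7fdknoisy", fdkReconstruct(pn, grid, 2.2))
  fr <- cached("ph7frist",
               fristReconstruct(pn, fristConfig(n_iterations = 10), grid, 2.2))
  expect_identical(methodTag(fr), "FRIST")
  expect_true(all(muVolume(fr) >= 0))
  truth <- muVolume(ph)
  roi <- adipose_core(ph)
  expect_lt(var(muVolume(fr)[roi]), var(muVolume(fdk)[roi]))
  expect_lte(sqrt(mean((muVolume(fr) - truth)^2)),
             sqrt(mean((muVolume(fdk) - truth)^2)))
  # iteration log is complete and finite
  log <- fr@params$log
  expect_identical(nrow(log), 10L)
  expect_true(all(is.finite(log$residual)) && all(is.finite(log$tv)))
})

test_that("configuration invariants are enforced", {
  expect_error(fristConfig(sart_relaxation = 2.5))
  expect_error(fristConfig(tv_step_ratio = 0))
  expect_error(fristConfig(alpha_red = 1.5))
  expect_identical(fristConfig(clinical = TRUE)$n_iterations, 100L)
})
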