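# Shared small fixtures, built once per test run.

# coarse desk-scale phantom + geometry used by several modules
tiny_phantom <- function(seed = 7, target = 0.2) {
  generatePhantom(phantomSpec(grid_shape = c(48L, 48L, 48L),
                              voxel_pitch_mm = 2.2, target_vgf = target,
                              seed = seed))
}

tiny_geometry <- function(views = 60L) {
  makeGeometry(views = views, rows = 64L, cols = 64L,
               detector_pitch_mm = 3.2)
}

# uniform cylinder of radius r_mm and attenuation mu filling the grid axially
cylinder_volume <- function(n = 64L, pitch = 1.5, r_mm = 30, mu = 0.25) {
  xs <- (seq_len(n) - (n + 1) / 2) * pitch
  r2 <- outer(xs^2, xs^2, "+")
  vol <- array(0, c(n, n, n))
  disc <- ifelse(r2 <= r_mm^2, mu, 0)
  for (k in seq_len(n)) vol[, , k] <- disc
  vol
}

# in-plane disc ROI mask on the central slice
disc_roi <- function(n, pitch, r_mm) {
  xs <- (seq_len(n) - (n + 1) / 2) * pitch
  outer(xs^2, xs^2, "+") <= r_mm^2
}

# uniform-interior ROI of a phantom: adipose voxels at least `margin`
# erosions away from any other tissue
adipose_core <- function(ph, margin = 2L) {
  adip <- labelVolume(ph) == tissueCodes()[["adipose"]]
  cbbctVGF:::erode_mask(adip, margin)
}

# memoize expensive fixtures within one test run
local_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = local_cache)) assign(key, expr, envir = local_cache)
  get(key, envir = local_cache)
}

# default-scale (96^3) fixtures shared between the end-to-end accuracy check
# and the segmentation tests
phantom96 <- function() {
  cached("ph96", generatePhantom(phantomSpec(seed = 7, target_vgf = 0.2)))
}
proj96 <- function() {
  cached("ph96proj", forwardProject(phantom96(), makeGeometry()))
}
fdk96_noiseless <- function() {
  cached("ph96fdk0",
         fdkReconstruct(proj96(), dim(muVolume(phantom96())),
                        voxelPitch(phantom96())))
}
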