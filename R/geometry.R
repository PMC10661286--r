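#' Construct a circular cone-beam scan geometry
#'
#' Builds a [ScanGeometry-class] with equally spaced view angles covering the
#' half-open interval [0, 360) degrees, the full-scan acquisition used by
#' dedicated breast CT (clinically, 300 views at 30 frames/s over a 10 s
#' rotation, with 0.388 mm detector elements). The desk-scale defaults (120
#' views, 128 x 128 detector at 1.6 mm) keep simulated studies at the
#' minutes scale while preserving typical breast-CT proportions; the
#' clinical profile is available through [clinicalGeometry()].
#'
#' @param views number of equally spaced views (default 120).
#' @param detector_pitch_mm detector element pitch in mm (default 1.6).
#' @param rows,cols detector grid; rows are axial (default 128 x 128).
#' @param sid_mm source-to-isocenter distance (default 650).
#' @param sdd_mm source-to-detector distance (default 923).
#' @return A [ScanGeometry-class].
#' @examples
#' makeGeometry(views = 4)@view_angles_deg  # 0 90 180 270
#' @export
makeGeometry <- function(views = 120L, detector_pitch_mm = 1.6,
                         rows = 128L, cols = 128L,
                         sid_mm = 650, sdd_mm = 923) {
  views <- as.integer(views)
  stopifnot(views >= 1L, rows >= 1L, cols >= 1L, detector_pitch_mm > 0)
  if (!(sdd_mm > sid_mm && sid_mm > 0))
    stop("distances must satisfy sdd_mm > sid_mm > 0")
  new("ScanGeometry", sid_mm = sid_mm, sdd_mm = sdd_mm,
      detector_rows = as.integer(rows), detector_cols = as.integer(cols),
      detector_pitch_mm = detector_pitch_mm,
      view_angles_deg = seq(0, 360, length.out = views + 1L)[seq_len(views)])
}

#' Clinical-profile geometry: 300 views, 0.388 mm detector elements
#'
#' The full-scan acquisition profile of the clinical prototype scanner: 300
#' projections over 360 degrees with 0.388 mm detector elements. Source and
#' detector distances are representative of breast-CT proportions, not
#' vendor-exact (they are unpublished).
#'
#' @param rows,cols detector grid (default 1024 x 1024).
#' @return A [ScanGeometry-class].
#' @export
clinicalGeometry <- function(rows = 1024L, cols = 1024L) {
  makeGeometry(views = 300L, detector_pitch_mm = 0.388,
               rows = rows, cols = cols, sid_mm = 650, sdd_mm = 923)
}

geom_angles_rad <- function(geom) geom@view_angles_deg * pi / 180

#' Cone-beam forward projection (line integrals)
#'
#' Computes the stack of dimensionless line integrals of attenuation along
#' every source-to-detector-cell ray, using ray-driven integration with
#' trilinear interpolation at a sampling step no larger than half the voxel
#' pitch. The volume is centered at the isocenter. Together with
#' [backprojectRays()] this forms an exactly matched (adjoint) operator
#' pair, which the algebraic reconstruction steps rely on.
#'
#' @param volume a [LabeledVolume-class], [ReconVolume-class], or plain 3D
#'   array of attenuation in 1/cm.
#' @param geometry a [ScanGeometry-class].
#' @param voxel_pitch_mm required if `volume` is a bare array.
#' @param step_mm ray sampling step; defaults to half the voxel pitch.
#' @return A noiseless [ProjectionSet-class].
#' @export
forwardProject <- function(volume, geometry, voxel_pitch_mm = NULL,
                           step_mm = NULL) {
  if (is(volume, "LabeledVolume")) {
    arr <- volume@mu; pitch <- volume@voxel_pitch_mm
  } else if (is(volume, "ReconVolume")) {
    arr <- volume@mu_hat; pitch <- volume@voxel_pitch_mm
  } else {
    stopifnot(is.array(volume), length(dim(volume)) == 3L,
              !is.null(voxel_pitch_mm))
    arr <- volume; pitch <- voxel_pitch_mm
  }
  if (is.null(step_mm)) step_mm <- pitch / 2
  stopifnot(step_mm > 0, step_mm <= pitch / 2 + 1e-12)
  g <- geometry
  ## field-of-view check: the volume's in-plane extent must project inside
  ## the detector at the isocenter magnification
  half_fov <- g@detector_cols * g@detector_pitch_mm / 2 * g@sid_mm / g@sdd_mm
  r_inplane <- sqrt(sum((dim(arr)[1:2] * pitch / 2)^2))
  if (r_inplane > half_fov * 1.45)
    warning("volume corners extend beyond the scannable field of view")
  dat <- cpp_forward_project(as.numeric(arr), dim(arr), pitch,
                             geom_angles_rad(g),
                             g@detector_cols, g@detector_rows,
                             g@detector_pitch_mm, g@detector_pitch_mm,
                             g@sid_mm, g@sdd_mm, step_mm)
  dim(dat) <- c(g@detector_cols, g@detector_rows,
                length(g@view_angles_deg))
  new("ProjectionSet", data = dat, geometry = g, photons_per_ray = Inf,
      seed = NA_real_)
}

#' Adjoint of the forward projector
#'
#' Applies the exact matrix transpose of [forwardProject()]: projection
#' values are scattered back along the same sampled rays with the same
#' trilinear weights. This is the smearing operator used inside OS-SART; it
#' is not the filtered FDK backprojection.
#'
#' @param p a [ProjectionSet-class] (or bare `cols x rows x views` array with
#'   `geometry` supplied).
#' @param grid_dim integer vector of 3: output volume dimensions.
#' @param voxel_pitch_mm isotropic output voxel pitch (mm).
#' @param geometry required if `p` is a bare array.
#' @param step_mm must match the forward step for exact adjointness;
#'   defaults to half the voxel pitch.
#' @return 3D numeric array.
#' @export
backprojectRays <- function(p, grid_dim, voxel_pitch_mm, geometry = NULL,
                            step_mm = NULL) {
  if (is(p, "ProjectionSet")) {
    dat <- p@data; g <- p@geometry
  } else {
    stopifnot(is.array(p), !is.null(geometry))
    dat <- p; g <- geometry
  }
  if (is.null(step_mm)) step_mm <- voxel_pitch_mm / 2
  vol <- cpp_backproject_ray(as.numeric(dat), as.integer(grid_dim),
                             voxel_pitch_mm, geom_angles_rad(g),
                             g@detector_cols, g@detector_rows,
                             g@detector_pitch_mm, g@detector_pitch_mm,
                             g@sid_mm, g@sdd_mm, step_mm)
  array(vol, grid_dim)
}

#' Add Poisson counting noise to line integrals
#'
#' Simulates transmission imaging at a given photon fluence: for each ray
#' with line integral p the transmitted count is drawn as
#' Poisson(photons_per_ray * exp(-p)), clamped below at 1 count, and
#' re-logged to a noisy line integral. Deterministic for a fixed seed. For
#' means above 1e7 photons a Gaussian approximation to the Poisson draw is
#' used.
#'
#' @param p a [ProjectionSet-class].
#' @param photons_per_ray incident photons per detector element (>= 1).
#' @param seed RNG seed.
#' @return A noisy [ProjectionSet-class] with noise metadata set.
#' @export
addPoissonNoise <- function(p, photons_per_ray, seed = 1L) {
  stopifnot(is(p, "ProjectionSet"), photons_per_ray >= 1)
  lam <- photons_per_ray * exp(-p@data)
  counts <- with_seed(seed, {
    big <- lam > 1e7
    out <- numeric(length(lam))
    if (any(!big))
      out[!big] <- stats::rpois(sum(!big), lam[!big])
    if (any(big))
      out[big] <- round(lam[big] + sqrt(lam[big]) * stats::rnorm(sum(big)))
    out
  })
  counts <- pmax(counts, 1)
  noisy <- log(photons_per_ray / counts)
  dim(noisy) <- dim(p@data)
  new("ProjectionSet", data = noisy, geometry = p@geometry,
      photons_per_ray = photons_per_ray, seed = as.numeric(seed))
}
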