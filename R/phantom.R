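#' Specify a synthetic pendant-breast phantom
#'
#' Builds a validated parameter record for [generatePhantom()]. The phantom
#' models an uncompressed pendant breast imaged on a dedicated cone-beam
#' breast CT table: a half-ellipsoid of adipose tissue hanging along the z
#' axis (chest wall at the top of the grid), wrapped in a thin skin shell,
#' with fibroglandular tissue laid down as a union of randomly placed
#' spheres until a requested volumetric glandular fraction is reached.
#'
#' Default shape parameters follow published clinical cohort statistics for
#' pendant-breast CT (chest-wall diameter about 13 cm, chest-wall-to-nipple
#' length about 10 cm), scaled to fit the default desk-scale grid.
#' Attenuation defaults (adipose 0.22, fibroglandular 0.28, skin 0.30 1/cm)
#' sit inside the display window conventionally used for breast CT
#' attenuation images, [0.21, 0.33] 1/cm.
#'
#' @param grid_shape integer vector of 3 voxel counts (default 96^3).
#' @param voxel_pitch_mm isotropic voxel pitch in mm (default 1.1, a
#'   desk-scale coarsening of the 0.273 mm clinical reconstruction pitch).
#' @param breast_radius_mm in-plane semi-axis of the outer surface.
#' @param chestwall_to_nipple_mm axial semi-axis of the outer surface.
#' @param skin_thickness_mm thickness of the skin shell.
#' @param target_vgf requested glandular fraction in [0, 1].
#' @param blob_count maximum number of fibroglandular spheres per placement
#'   attempt.
#' @param blob_radius_range_mm min/max sphere radius in mm.
#' @param mu_adipose,mu_gland,mu_skin linear attenuation coefficients (1/cm).
#' @param seed RNG seed controlling blob placement.
#' @return A list of class `"PhantomSpec"`.
#' @examples
#' spec <- phantomSpec(grid_shape = c(48, 48, 48), voxel_pitch_mm = 2.2,
#'                     target_vgf = 0.2, seed = 1)
#' @export
phantomSpec <- function(grid_shape = c(96L, 96L, 96L),
                        voxel_pitch_mm = 1.1,
                        breast_radius_mm = 45,
                        chestwall_to_nipple_mm = 80,
                        skin_thickness_mm = 1.5,
                        target_vgf = 0.2,
                        blob_count = 500L,
                        blob_radius_range_mm = c(3, 10),
                        mu_adipose = 0.22,
                        mu_gland = 0.28,
                        mu_skin = 0.30,
                        seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_pitch_mm = voxel_pitch_mm,
               breast_radius_mm = breast_radius_mm,
               chestwall_to_nipple_mm = chestwall_to_nipple_mm,
               skin_thickness_mm = skin_thickness_mm,
               target_vgf = target_vgf,
               blob_count = as.integer(blob_count),
               blob_radius_range_mm = blob_radius_range_mm,
               mu_adipose = mu_adipose, mu_gland = mu_gland,
               mu_skin = mu_skin, seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  stopifnot(length(spec$grid_shape) == 3L, all(spec$grid_shape >= 8L),
            voxel_pitch_mm > 0,
            target_vgf >= 0, target_vgf <= 1,
            skin_thickness_mm >= 0,
            skin_thickness_mm < breast_radius_mm,
            mu_adipose > 0, mu_gland > 0, mu_skin > 0,
            mu_adipose < mu_gland,
            blob_count >= 0L,
            length(blob_radius_range_mm) == 2L,
            blob_radius_range_mm[1] > 0,
            blob_radius_range_mm[1] <= blob_radius_range_mm[2])
  spec
}

#' Generate a labeled synthetic breast phantom
#'
#' Deterministically (for a fixed seed) generates a [LabeledVolume-class]
#' from a [phantomSpec()]. The outer surface is a half-ellipsoid aligned to
#' z; the skin shell is the set difference between the surface mask and its
#' morphological erosion by `round(skin_thickness_mm / voxel_pitch_mm)`
#' voxels (at least one); fibroglandular spheres are placed by
#' accept/reject until the realized VGF lies within 0.05 of `target_vgf`.
#' Sphere placements that would overshoot the band are rejected; if the band
#' cannot be reached the attempt is restarted with fresh draws, and after
#' 100 attempts the generator fails.
#'
#' @param spec a [phantomSpec()].
#' @param vgf_tol half-width of the acceptance band around `target_vgf`
#'   (default 0.05).
#' @param max_attempts restart cap before declaring the target unreachable.
#' @return A [LabeledVolume-class]; its `true_vgf` slot is the exact
#'   voxel-count ratio.
#' @examples
#' ph <- generatePhantom(phantomSpec(grid_shape = c(48, 48, 48),
#'                                   voxel_pitch_mm = 2.2, seed = 7))
#' trueVGF(ph)
#' @export
generatePhantom <- function(spec, vgf_tol = 0.05, max_attempts = 100L) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$grid_shape
  p <- spec$voxel_pitch_mm
  xs <- axis_coords(d[1], p)
  ys <- axis_coords(d[2], p)
  zs <- axis_coords(d[3], p)
  ## chest wall plane at the top of the grid (one voxel margin)
  z0 <- zs[d[3]] + p / 2
  a <- spec$breast_radius_mm
  cc <- spec$chestwall_to_nipple_mm

  r2xy <- outer(xs^2, ys^2, "+")        # nx x ny
  outer_mask <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    zz <- ((zs[k] - z0) / cc)^2
    outer_mask[, , k] <- (r2xy / a^2 + zz) <= 1
  }

  n_skin <- max(1L, as.integer(round(spec$skin_thickness_mm / p)))
  interior <- erode_mask(outer_mask, n_skin)
  skin <- outer_mask & !interior
  n_int <- sum(interior)
  if (n_int == 0L) stop("phantom interior is empty; enlarge the grid")

  gland <- place_gland_blobs(spec, interior, xs, ys, zs,
                             vgf_tol = vgf_tol, max_attempts = max_attempts)

  label <- array(LABEL_AIR, d)
  label[skin] <- LABEL_SKIN
  label[interior] <- LABEL_ADIPOSE
  label[gland] <- LABEL_GLAND

  mu <- array(0, d)
  mu[label == LABEL_SKIN] <- spec$mu_skin
  mu[label == LABEL_ADIPOSE] <- spec$mu_adipose
  mu[label == LABEL_GLAND] <- spec$mu_gland

  ng <- sum(label == LABEL_GLAND)
  na <- sum(label == LABEL_ADIPOSE)
  new("LabeledVolume", mu = mu, label = label, voxel_pitch_mm = p,
      true_vgf = ng / (ng + na), spec = unclass(spec))
}

## Accept/reject sphere placement. Returns a logical gland mask (subset of
## `interior`).
place_gland_blobs <- function(spec, interior, xs, ys, zs, vgf_tol,
                              max_attempts) {
  d <- dim(interior)
  p <- spec$voxel_pitch_mm
  n_int <- sum(interior)
  target <- spec$target_vgf

  if (target >= 1) return(interior)
  empty <- array(FALSE, d)
  if (target == 0) return(empty)
  if (spec$blob_count == 0L) {
    if (target > vgf_tol)
      stop("target_vgf ", target, " unreachable with blob_count = 0")
    return(empty)
  }

  idx_int <- which(interior)
  with_seed(spec$seed, {
    for (attempt in seq_len(max_attempts)) {
      gland <- empty
      n_gland <- 0L
      placed <- 0L
      rejected <- 0L
      repeat {
        vgf <- n_gland / n_int
        if (abs(vgf - target) <= vgf_tol &&
            (n_gland > 0L || target <= vgf_tol)) break
        if (placed >= spec$blob_count || rejected > 200L) break
        ctr <- idx_int[sample.int(length(idx_int), 1L)]
        ctr_ijk <- arrayInd(ctr, d)
        r <- stats::runif(1, spec$blob_radius_range_mm[1],
                          spec$blob_radius_range_mm[2])
        rv <- ceiling(r / p)
        ix <- max(1L, ctr_ijk[1] - rv):min(d[1], ctr_ijk[1] + rv)
        iy <- max(1L, ctr_ijk[2] - rv):min(d[2], ctr_ijk[2] + rv)
        iz <- max(1L, ctr_ijk[3] - rv):min(d[3], ctr_ijk[3] + rv)
        dx2 <- (xs[ix] - xs[ctr_ijk[1]])^2
        dy2 <- (ys[iy] - ys[ctr_ijk[2]])^2
        dz2 <- (zs[iz] - zs[ctr_ijk[3]])^2
        sph <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
        cand <- gland[ix, iy, iz] | (sph & interior[ix, iy, iz])
        n_new <- n_gland + sum(cand) - sum(gland[ix, iy, iz])
        if (n_new / n_int > target + vgf_tol) {
          rejected <- rejected + 1L
          next
        }
        gland[ix, iy, iz] <- cand
        n_gland <- n_new
        placed <- placed + 1L
      }
      if (abs(n_gland / n_int - target) <= vgf_tol &&
          (n_gland > 0L || target <= vgf_tol))
        return(gland)
    }
    stop("could not reach target_vgf = ", target, " within +/-", vgf_tol,
         " after ", max_attempts, " attempts; adjust blob parameters")
  })
}

#' Ground-truth volumetric glandular fraction of a labeled volume
#'
#' Ratio of fibroglandular voxels to all interior (fibroglandular plus
#' adipose) voxels. Skin and air are excluded from both numerator and
#' denominator, matching the definition of VGF as glandular volume over
#' total breast volume excluding skin.
#'
#' @param volume a [LabeledVolume-class].
#' @return Fraction in [0, 1].
#' @export
trueVGF <- function(volume) {
  stopifnot(is(volume, "LabeledVolume"))
  ng <- sum(volume@label == LABEL_GLAND)
  na <- sum(volume@label == LABEL_ADIPOSE)
  if (ng + na == 0L)
    stop("volume has no interior (adipose or fibroglandular) voxels")
  ng / (ng + na)
}
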