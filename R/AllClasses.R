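#' @import methods
NULL

## Integer tissue codes shared across the package (and written to NIfTI label
## volumes): 0 air, 1 skin, 2 adipose, 3 fibroglandular.
LABEL_AIR <- 0L
LABEL_SKIN <- 1L
LABEL_ADIPOSE <- 2L
LABEL_GLAND <- 3L

#' Tissue label codes
#'
#' Integer codes used in all label volumes: 0 air, 1 skin, 2 adipose,
#' 3 fibroglandular.
#'
#' @return Named integer vector of length four.
#' @export
tissueCodes <- function() {
  c(air = LABEL_AIR, skin = LABEL_SKIN, adipose = LABEL_ADIPOSE,
    fibroglandular = LABEL_GLAND)
}

#' ScanGeometry: circular cone-beam acquisition geometry
#'
#' Describes a full-scan circular cone-beam trajectory: a point source and a
#' flat-panel detector rotating about the isocenter. The source sits at
#' distance `sid_mm` from the isocenter; the detector, of
#' `detectorRows x detectorCols` elements at pitch `detectorPitch_mm`, is
#' centered on the source-isocenter ray at distance `sdd_mm` from the source.
#' View angles are in degrees over [0, 360).
#'
#' @slot sid_mm source-to-isocenter distance (mm).
#' @slot sdd_mm source-to-detector distance (mm).
#' @slot detector_rows,detector_cols detector grid (rows are axial).
#' @slot detector_pitch_mm detector element pitch (mm, square elements).
#' @slot view_angles_deg ordered view angles in degrees, strictly increasing,
#'   within [0, 360).
#' @export
setClass("ScanGeometry",
  representation(
    sid_mm = "numeric",
    sdd_mm = "numeric",
    detector_rows = "integer",
    detector_cols = "integer",
    detector_pitch_mm = "numeric",
    view_angles_deg = "numeric"
  )
)

setValidity("ScanGeometry", function(object) {
  msg <- character()
  if (!(object@sid_mm > 0)) msg <- c(msg, "sid_mm must be > 0")
  if (!(object@sdd_mm > object@sid_mm))
    msg <- c(msg, "sdd_mm must exceed sid_mm")
  if (object@detector_rows < 1L || object@detector_cols < 1L)
    msg <- c(msg, "detector grid must be positive")
  if (!(object@detector_pitch_mm > 0))
    msg <- c(msg, "detector_pitch_mm must be > 0")
  a <- object@view_angles_deg
  if (length(a) < 1L) msg <- c(msg, "need at least one view angle")
  if (any(a < 0 | a >= 360)) msg <- c(msg, "angles must lie in [0, 360)")
  if (length(a) > 1L && any(diff(a) <= 0))
    msg <- c(msg, "angles must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' LabeledVolume: voxel phantom with tissue labels and ground-truth VGF
#'
#' A 3D grid of linear attenuation coefficients (1/cm) together with a
#' congruent integer tissue-label array (see [tissueCodes()]) and the exact
#' volumetric glandular fraction implied by the labels.
#'
#' @slot mu 3D numeric array of attenuation (1/cm); exactly 0 where air.
#' @slot label 3D integer array of tissue codes.
#' @slot voxel_pitch_mm isotropic voxel pitch (mm).
#' @slot true_vgf fibroglandular voxels / (fibroglandular + adipose voxels).
#' @slot spec the generating PhantomSpec (list), for provenance.
#' @export
setClass("LabeledVolume",
  representation(
    mu = "array",
    label = "array",
    voxel_pitch_mm = "numeric",
    true_vgf = "numeric",
    spec = "list"
  )
)

setValidity("LabeledVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@mu), dim(object@label)))
    msg <- c(msg, "mu and label must be congruent")
  if (length(dim(object@mu)) != 3L) msg <- c(msg, "arrays must be 3D")
  if (!(object@voxel_pitch_mm > 0)) msg <- c(msg, "voxel pitch must be > 0")
  if (any(object@mu[object@label == LABEL_AIR] != 0))
    msg <- c(msg, "mu must be exactly 0 where label is air")
  ng <- sum(object@label == LABEL_GLAND)
  na <- sum(object@label == LABEL_ADIPOSE)
  if (ng + na > 0L) {
    if (abs(object@true_vgf - ng / (ng + na)) > 1e-12)
      msg <- c(msg, "true_vgf inconsistent with label counts")
  }
  if (length(msg)) msg else TRUE
})

#' ProjectionSet: stack of cone-beam line-integral images
#'
#' Dimensionless line integrals of attenuation (mu in 1/cm integrated over
#' path length in cm), one image per view, stored as an array of dimension
#' `c(detector_cols, detector_rows, n_views)` (in-plane detector coordinate
#' first, which is the ramp-filter direction).
#'
#' @slot data numeric array, `cols x rows x views`.
#' @slot geometry the [ScanGeometry-class] the data were computed under.
#' @slot photons_per_ray photon fluence used for Poisson noise, or `Inf` for
#'   noiseless data.
#' @slot seed RNG seed used for the noise draw (`NA` if noiseless).
#' @export
setClass("ProjectionSet",
  representation(
    data = "array",
    geometry = "ScanGeometry",
    photons_per_ray = "numeric",
    seed = "numeric"
  )
)

setValidity("ProjectionSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  g <- object@geometry
  if (length(d) != 3L) msg <- c(msg, "data must be 3D")
  else {
    if (d[1] != g@detector_cols || d[2] != g@detector_rows ||
        d[3] != length(g@view_angles_deg))
      msg <- c(msg, "data shape inconsistent with geometry")
  }
  if (length(msg)) msg else TRUE
})

#' ReconVolume: reconstructed attenuation volume with provenance
#'
#' @slot mu_hat 3D numeric array of reconstructed attenuation (1/cm).
#' @slot voxel_pitch_mm isotropic voxel pitch (mm).
#' @slot method_tag one of `"FDK"`, `"FRIST"`, `"SPLIT_ODD"`, `"SPLIT_EVEN"`,
#'   `"SPLIT_MEAN"`.
#' @slot params parameter record sufficient to re-run the reconstruction;
#'   iterative methods also store the per-iteration log here.
#' @export
setClass("ReconVolume",
  representation(
    mu_hat = "array",
    voxel_pitch_mm = "numeric",
    method_tag = "character",
    params = "list"
  )
)

setValidity("ReconVolume", function(object) {
  msg <- character()
  if (length(dim(object@mu_hat)) != 3L) msg <- c(msg, "mu_hat must be 3D")
  if (!all(is.finite(object@mu_hat))) msg <- c(msg, "mu_hat must be finite")
  if (!(object@voxel_pitch_mm > 0)) msg <- c(msg, "voxel pitch must be > 0")
  ok <- c("FDK", "FRIST", "SPLIT_ODD", "SPLIT_EVEN", "SPLIT_MEAN")
  if (!(object@method_tag %in% ok))
    msg <- c(msg, paste("method_tag must be one of:", paste(ok, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' KFCMResult: kernel fuzzy C-means fit on an intensity vector
#'
#' @slot membership numeric matrix, voxels x 2 clusters; rows sum to 1.
#' @slot centers length-2 numeric, ordered adipose < fibroglandular (1/cm).
#' @slot labels integer vector over the input voxels using [tissueCodes()]
#'   (adipose or fibroglandular).
#' @slot iterations_used number of alternating updates performed.
#' @slot converged logical; FALSE means max_iter was hit first.
#' @slot objective per-iteration kernel-FCM objective values.
#' @export
setClass("KFCMResult",
  representation(
    membership = "matrix",
    centers = "numeric",
    labels = "integer",
    iterations_used = "integer",
    converged = "logical",
    objective = "numeric"
  )
)

setValidity("KFCMResult", function(object) {
  msg <- character()
  if (ncol(object@membership) != 2L) msg <- c(msg, "two clusters expected")
  if (length(object@centers) != 2L) msg <- c(msg, "two centers expected")
  if (object@centers[1] > object@centers[2])
    msg <- c(msg, "centers must be ordered adipose < fibroglandular")
  if (nrow(object@membership) &&
      max(abs(rowSums(object@membership) - 1)) > 1e-8)
    msg <- c(msg, "memberships must sum to 1 per voxel")
  if (length(msg)) msg else TRUE
})

#' SegmentationResult: full-volume tissue segmentation plus VGF
#'
#' @slot label 3D integer array over [tissueCodes()].
#' @slot kfcm the interior [KFCMResult-class].
#' @slot vgf volumetric glandular fraction from the hard labels.
#' @slot vg_voxels,va_voxels fibroglandular and adipose voxel counts.
#' @slot voxel_pitch_mm isotropic voxel pitch (mm).
#' @export
setClass("SegmentationResult",
  representation(
    label = "array",
    kfcm = "KFCMResult",
    vgf = "numeric",
    vg_voxels = "integer",
    va_voxels = "integer",
    voxel_pitch_mm = "numeric"
  )
)

setValidity("SegmentationResult", function(object) {
  msg <- character()
  if (object@vgf < 0 || object@vgf > 1) msg <- c(msg, "vgf must be in [0,1]")
  if (object@vg_voxels + object@va_voxels > 0L &&
      abs(object@vgf -
          object@vg_voxels / (object@vg_voxels + object@va_voxels)) > 1e-12)
    msg <- c(msg, "vgf inconsistent with voxel counts")
  if (length(msg)) msg else TRUE
})

#' ComparisonReport: reproducibility statistics across reconstruction methods
#'
#' Holds the full decision trail of the VGF comparison: per-method summary
#' statistics, per-method Shapiro-Wilk normality p-values, the selected
#' omnibus test (repeated-measures ANOVA or Friedman) with its statistic and
#' p-value, and - when the Friedman path is taken - Dunn's post-hoc adjusted
#' p-values against the control method.
#'
#' @slot vgf_matrix numeric matrix, phantoms x methods.
#' @slot control control method column name (the reference reconstruction).
#' @slot summaries data.frame: method, median, q25, q75, min, max.
#' @slot normality data.frame: method, W, p.
#' @slot omnibus list: test ("RM_ANOVA" or "FRIEDMAN"), statistic, df, p.
#' @slot posthoc data.frame (possibly empty): method, z, p_unadjusted,
#'   p_adjusted, display.
#' @slot decision_trail character log of the decisions taken.
#' @export
setClass("ComparisonReport",
  representation(
    vgf_matrix = "matrix",
    control = "character",
    summaries = "data.frame",
    normality = "data.frame",
    omnibus = "list",
    posthoc = "data.frame",
    decision_trail = "character"
  )
)

setValidity("ComparisonReport", function(object) {
  msg <- character()
  m <- object@vgf_matrix
  if (is.null(colnames(m))) msg <- c(msg, "vgf_matrix needs method colnames")
  else if (!(object@control %in% colnames(m)))
    msg <- c(msg, "control must be a vgf_matrix column")
  if (any(m < 0 | m > 1)) msg <- c(msg, "VGF entries must be in [0,1]")
  if (anyNA(m)) msg <- c(msg, "matched design: no missing entries allowed")
  if (length(msg)) msg else TRUE
})
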