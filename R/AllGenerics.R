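#' @include AllClasses.R
NULL

#' Accessors for the package's data classes
#'
#' `muVolume` returns the attenuation array of a phantom or reconstruction;
#' `labelVolume` the tissue-label array; `voxelPitch` the isotropic voxel
#' pitch in mm; `methodTag` the reconstruction method of a [ReconVolume-class];
#' `projData` the line-integral array of a [ProjectionSet-class]; `scanGeometry`
#' its geometry; `viewAngles` the view angles in degrees.
#'
#' @param x an object of one of the package's classes.
#' @return The slot value; see Details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("muVolume", function(x) standardGeneric("muVolume"))
#' @rdname accessors
#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))
#' @rdname accessors
#' @export
setGeneric("voxelPitch", function(x) standardGeneric("voxelPitch"))
#' @rdname accessors
#' @export
setGeneric("methodTag", function(x) standardGeneric("methodTag"))
#' @rdname accessors
#' @export
setGeneric("projData", function(x) standardGeneric("projData"))
#' @rdname accessors
#' @export
setGeneric("scanGeometry", function(x) standardGeneric("scanGeometry"))
#' @rdname accessors
#' @export
setGeneric("viewAngles", function(x) standardGeneric("viewAngles"))

#' @rdname accessors
#' @export
setMethod("muVolume", "LabeledVolume", function(x) x@mu)
#' @rdname accessors
#' @export
setMethod("muVolume", "ReconVolume", function(x) x@mu_hat)
#' @rdname accessors
#' @export
setMethod("labelVolume", "LabeledVolume", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("labelVolume", "SegmentationResult", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("voxelPitch", "LabeledVolume", function(x) x@voxel_pitch_mm)
#' @rdname accessors
#' @export
setMethod("voxelPitch", "ReconVolume", function(x) x@voxel_pitch_mm)
#' @rdname accessors
#' @export
setMethod("voxelPitch", "SegmentationResult", function(x) x@voxel_pitch_mm)
#' @rdname accessors
#' @export
setMethod("methodTag", "ReconVolume", function(x) x@method_tag)
#' @rdname accessors
#' @export
setMethod("projData", "ProjectionSet", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("scanGeometry", "ProjectionSet", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("viewAngles", "ScanGeometry", function(x) x@view_angles_deg)
#' @rdname accessors
#' @export
setMethod("viewAngles", "ProjectionSet", function(x) x@geometry@view_angles_deg)

setMethod("show", "ScanGeometry", function(object) {
  a <- object@view_angles_deg
  cat("ScanGeometry:", length(a), "views over [",
      format(min(a)), ",", format(max(a)), "] deg\n")
  cat("  sid", object@sid_mm, "mm, sdd", object@sdd_mm, "mm; detector",
      object@detector_rows, "x", object@detector_cols, "@",
      object@detector_pitch_mm, "mm\n")
})

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@mu)
  cat("LabeledVolume:", paste(d, collapse = " x "), "voxels @",
      object@voxel_pitch_mm, "mm\n")
  tc <- tissueCodes()
  cnt <- vapply(tc, function(code) sum(object@label == code), numeric(1))
  cat("  voxels:", paste(names(tc), cnt, collapse = ", "), "\n")
  cat("  true VGF:", format(object@true_vgf, digits = 4), "\n")
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@data)
  cat("ProjectionSet:", d[3], "views of", d[1], "x", d[2], "line integrals\n")
  if (is.infinite(object@photons_per_ray)) cat("  noiseless\n")
  else cat("  Poisson noise at", object@photons_per_ray,
           "photons/ray (seed", object@seed, ")\n")
})

setMethod("show", "ReconVolume", function(object) {
  d <- dim(object@mu_hat)
  cat("ReconVolume [", object@method_tag, "]: ",
      paste(d, collapse = " x "), " voxels @ ",
      object@voxel_pitch_mm, " mm\n", sep = "")
  cat("  mu_hat range: [", format(min(object@mu_hat), digits = 4), ",",
      format(max(object@mu_hat), digits = 4), "] 1/cm\n")
})

setMethod("show", "KFCMResult", function(object) {
  cat("KFCMResult:", nrow(object@membership), "voxels,",
      object@iterations_used, "iterations",
      if (object@converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  centers:", format(object@centers, digits = 4), "1/cm\n")
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult: VGF =", format(object@vgf, digits = 4),
      "(Vg", object@vg_voxels, "/ Va", object@va_voxels, "voxels)\n")
})

setMethod("show", "ComparisonReport", function(object) {
  m <- object@vgf_matrix
  cat("ComparisonReport:", nrow(m), "phantoms x", ncol(m),
      "methods (control:", object@control, ")\n")
  o <- object@omnibus
  cat("  omnibus:", o$test, "statistic =", format(o$statistic, digits = 4),
      ", p =", format(o$p, digits = 4), "\n")
  if (nrow(object@posthoc)) {
    cat("  post-hoc vs", object@control, ":\n")
    for (r in seq_len(nrow(object@posthoc)))
      cat("    ", object@posthoc$method[r], ": p =",
          object@posthoc$display[r], "\n")
  }
})
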