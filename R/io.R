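#' Write and read volumes as NIfTI with JSON sidecars
#'
#' Volumes are stored as `.nii.gz` with the voxel pitch in the NIfTI
#' header; a JSON sidecar (same path with `.json`) carries everything the
#' header cannot: tissue-label legend and ground-truth VGF for phantoms,
#' method tag and parameter record for reconstructions.
#'
#' @param x a [LabeledVolume-class], [ReconVolume-class], or
#'   [SegmentationResult-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (is(x, "LabeledVolume")) {
    arr <- x@mu; pitch <- x@voxel_pitch_mm
    meta <- list(kind = "LabeledVolume", voxel_pitch_mm = pitch,
                 true_vgf = x@true_vgf, labels = as.list(tissueCodes()),
                 spec = x@spec)
    lab_path <- sub("\\.nii(\\.gz)?$", "_labels.nii.gz", path)
    img_lab <- RNifti::asNifti(x@label)
    RNifti::pixdim(img_lab) <- rep(pitch, 3)
    RNifti::writeNifti(img_lab, lab_path)
    meta$label_file <- basename(lab_path)
  } else if (is(x, "ReconVolume")) {
    arr <- x@mu_hat; pitch <- x@voxel_pitch_mm
    meta <- list(kind = "ReconVolume", voxel_pitch_mm = pitch,
                 method_tag = x@method_tag,
                 params = x@params[setdiff(names(x@params), "log")])
  } else if (is(x, "SegmentationResult")) {
    arr <- x@label; pitch <- x@voxel_pitch_mm
    meta <- list(kind = "SegmentationResult", voxel_pitch_mm = pitch,
                 vgf = x@vgf, vg_voxels = x@vg_voxels,
                 va_voxels = x@va_voxels, labels = as.list(tissueCodes()))
  } else stop("unsupported object")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(pitch, 3)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeVolume
#' @param path path previously written by [writeVolume()].
#' @return `readVolume`: a list with `data` (array), `meta` (sidecar list).
#' @export
readVolume <- function(path) {
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else NULL
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)), meta = meta)
}

#' Write and read projection sets
#'
#' Projection stacks are stored as NIfTI (views along the third axis) with
#' a JSON geometry sidecar carrying every [ScanGeometry-class] field
#' bit-exactly plus the noise metadata.
#'
#' @param p a [ProjectionSet-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeProjections <- function(p, path) {
  stopifnot(is(p, "ProjectionSet"))
  g <- p@geometry
  meta <- list(kind = "ProjectionSet",
               sid_mm = g@sid_mm, sdd_mm = g@sdd_mm,
               detector_rows = g@detector_rows,
               detector_cols = g@detector_cols,
               detector_pitch_mm = g@detector_pitch_mm,
               view_angles_deg = g@view_angles_deg,
               photons_per_ray = if (is.finite(p@photons_per_ray))
                 p@photons_per_ray else "noiseless",
               seed = if (is.na(p@seed)) NULL else p@seed)
  img <- RNifti::asNifti(p@data)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(meta, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeProjections
#' @export
readProjections <- function(path) {
  meta <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  g <- new("ScanGeometry", sid_mm = meta$sid_mm, sdd_mm = meta$sdd_mm,
           detector_rows = as.integer(meta$detector_rows),
           detector_cols = as.integer(meta$detector_cols),
           detector_pitch_mm = meta$detector_pitch_mm,
           view_angles_deg = as.numeric(meta$view_angles_deg))
  photons <- if (identical(meta$photons_per_ray, "noiseless")) Inf
             else as.numeric(meta$photons_per_ray)
  new("ProjectionSet", data = array(as.numeric(img), dim(img)),
      geometry = g, photons_per_ray = photons,
      seed = if (is.null(meta$seed)) NA_real_ else as.numeric(meta$seed))
}

#' Serialize a comparison report to JSON (and back)
#'
#' The JSON file round-trips every slot of the report; reading it back
#' reconstructs an equal [ComparisonReport-class].
#'
#' @param report a [ComparisonReport-class].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "ComparisonReport"))
  obj <- list(vgf_matrix = unname(report@vgf_matrix),
              methods = colnames(report@vgf_matrix),
              control = report@control,
              summaries = report@summaries,
              normality = report@normality,
              omnibus = report@omnibus,
              posthoc = report@posthoc,
              decision_trail = report@decision_trail)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.numeric(obj$vgf_matrix), ncol = length(obj$methods),
              dimnames = list(NULL, obj$methods))
  posthoc <- as.data.frame(obj$posthoc, stringsAsFactors = FALSE)
  if (!nrow(posthoc))
    posthoc <- data.frame(method = character(), z = numeric(),
                          p_unadjusted = numeric(), p_adjusted = numeric(),
                          display = character(), stringsAsFactors = FALSE)
  omnibus <- obj$omnibus
  omnibus$df <- as.numeric(omnibus$df)
  new("ComparisonReport", vgf_matrix = m, control = obj$control,
      summaries = as.data.frame(obj$summaries, stringsAsFactors = FALSE),
      normality = as.data.frame(obj$normality, stringsAsFactors = FALSE),
      omnibus = omnibus, posthoc = posthoc,
      decision_trail = as.character(obj$decision_trail))
}
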