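#' Split a projection set into even- and odd-indexed view halves
#'
#' Partition the views of a full scan into two disjoint halves by 0-based
#' acquisition index: even indices (the 1st, 3rd, ... acquired views) form
#' the first set, odd indices the second. This is the data-preparation step
#' of Noise-to-Noise self-supervised denoising, where the two halves provide
#' independent noise realizations of the same object; a clinical 300-view
#' scan splits into 150 + 150 views.
#'
#' @param p a [ProjectionSet-class] with at least 2 views.
#' @return List with elements `even` and `odd`, both [ProjectionSet-class],
#'   retaining their original view angles.
#' @examples
#' g <- makeGeometry(views = 4, rows = 8, cols = 8)
#' p <- forwardProject(array(0, c(8, 8, 8)), g, voxel_pitch_mm = 2)
#' sapply(splitProjections(p), function(s) viewAngles(s))
#' @export
splitProjections <- function(p) {
  stopifnot(is(p, "ProjectionSet"))
  n <- dim(p@data)[3]
  if (n < 2L) stop("need at least 2 views to split")
  even_idx <- seq(1L, n, by = 2L)   # 0-based even = 1-based odd positions
  odd_idx <- seq(2L, n, by = 2L)
  take <- function(idx) {
    new("ProjectionSet", data = p@data[, , idx, drop = FALSE],
        geometry = subset_geom(p@geometry, idx),
        photons_per_ray = p@photons_per_ray, seed = p@seed)
  }
  list(even = take(even_idx), odd = take(odd_idx))
}

#' Paired half-view FDK reconstructions
#'
#' Splits the projections with [splitProjections()] and reconstructs each
#' half with FDK. On noiseless data the two halves agree up to angular
#' undersampling; on noisy data their noise realizations are independent.
#'
#' @param p a [ProjectionSet-class].
#' @param grid_dim,voxel_pitch_mm,window as in [fdkReconstruct()].
#' @return List with [ReconVolume-class] elements `odd` and `even`, tagged
#'   `"SPLIT_ODD"` / `"SPLIT_EVEN"`.
#' @export
splitFDK <- function(p, grid_dim, voxel_pitch_mm, window = "hann") {
  halves <- splitProjections(p)
  half_fdk <- function(ph, tag) {
    ## each half is itself a uniform full-circle scan at twice the spacing
    fdkReconstruct(ph, grid_dim, voxel_pitch_mm, window = window,
                   method_tag = tag)
  }
  list(odd = half_fdk(halves$odd, "SPLIT_ODD"),
       even = half_fdk(halves$even, "SPLIT_EVEN"))
}

#' Voxel-wise mean of a split pair
#'
#' Averages the odd and even half-view reconstructions. This deterministic
#' average stands in for the trained Noise-to-Noise denoiser in the
#' method-comparison pipeline (the network maps the noisy half-pair to a
#' denoised estimate; training and inference of the network are outside
#' this package), and its `method_tag` `"SPLIT_MEAN"` records that
#' substitution.
#'
#' @param pair list with [ReconVolume-class] elements `odd` and `even` on
#'   the same grid.
#' @return A [ReconVolume-class] tagged `"SPLIT_MEAN"`.
#' @export
splitMean <- function(pair) {
  odd <- pair$odd; even <- pair$even
  stopifnot(is(odd, "ReconVolume"), is(even, "ReconVolume"))
  if (!identical(dim(odd@mu_hat), dim(even@mu_hat)) ||
      odd@voxel_pitch_mm != even@voxel_pitch_mm)
    stop("split pair grids do not match")
  new("ReconVolume", mu_hat = (odd@mu_hat + even@mu_hat) / 2,
      voxel_pitch_mm = odd@voxel_pitch_mm, method_tag = "SPLIT_MEAN",
      params = list(algorithm = "mean of half-view FDK pair",
                    odd = odd@params, even = even@params))
}
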