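#' Configuration for kernel fuzzy C-means segmentation
#'
#' KFCM clusters interior voxel intensities into two classes (adipose,
#' fibroglandular) using a Gaussian kernel on voxel intensity as the only
#' feature. `kernel_sigma = "auto"` sets the bandwidth to the standard
#' deviation of the interior intensities, which also makes the resulting
#' label map invariant to strictly increasing affine rescalings of the
#' intensities. Center initialization (25%/75% of the robust intensity
#' range) is deterministic, so the seed is unused by default.
#'
#' @param fuzzifier membership exponent m > 1 (default 2).
#' @param kernel_sigma Gaussian kernel bandwidth in intensity units (1/cm),
#'   or `"auto"`.
#' @param tol convergence threshold on the maximum membership change.
#' @param max_iter iteration cap (default 200).
#' @param seed reserved for stochastic initializations; unused by the
#'   default percentile initialization.
#' @return A list of class `"KFCMConfig"`.
#' @export
kfcmConfig <- function(fuzzifier = 2, kernel_sigma = "auto", tol = 1e-5,
                       max_iter = 200L, seed = 1L) {
  cfg <- list(n_clusters = 2L, fuzzifier = fuzzifier,
              kernel_sigma = kernel_sigma, tol = tol,
              max_iter = as.integer(max_iter), seed = as.integer(seed))
  class(cfg) <- "KFCMConfig"
  stopifnot(fuzzifier > 1, tol > 0, max_iter >= 1L,
            identical(kernel_sigma, "auto") ||
              (is.numeric(kernel_sigma) && kernel_sigma > 0))
  cfg
}

#' Breast mask from a reconstructed volume
#'
#' Thresholds the reconstruction against an air threshold, keeps the
#' largest 6-connected component, and closes it morphologically (one
#' dilation followed by one erosion) to fill thin gaps.
#'
#' @param vol a [ReconVolume-class] or 3D array.
#' @param air_threshold attenuation threshold separating tissue from air
#'   background (1/cm, default 0.1 - roughly half of adipose).
#' @return Logical 3D mask.
#' @export
breastMask <- function(vol, air_threshold = 0.1) {
  arr <- if (is(vol, "ReconVolume")) vol@mu_hat else vol
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  m <- arr > air_threshold
  if (!any(m)) stop("empty breast mask: no voxels above the air threshold")
  lab <- cpp_label_components(as.logical(m), dim(arr))
  ncomp <- attr(lab, "ncomp")
  if (ncomp > 1L) {
    sizes <- tabulate(lab, nbins = ncomp)
    keep <- which.max(sizes)
    m <- array(lab == keep, dim(arr))
  }
  erode_step(dilate_step(m), fill = TRUE)
}

#' Remove the skin shell from a breast mask
#'
#' Erodes the mask by `ceiling(skin_thickness_mm / voxel_pitch_mm)` voxels
#' with a discrete ball structuring element, leaving the interior (adipose
#' plus fibroglandular) region on which VGF is defined. A thickness of 0 is
#' the identity.
#'
#' @param mask logical 3D breast mask.
#' @param skin_thickness_mm skin shell thickness to remove.
#' @param voxel_pitch_mm isotropic voxel pitch (mm).
#' @param margin_voxels extra erosion steps beyond the thickness-derived
#'   count (default 0; the end-to-end wrapper [segmentVolume()] uses 1 to
#'   absorb the reconstruction kernel's edge spread).
#' @return Logical interior mask, strictly inside `mask`.
#' @export
removeSkin <- function(mask, skin_thickness_mm, voxel_pitch_mm,
                       margin_voxels = 0L) {
  stopifnot(is.array(mask), is.logical(mask), any(mask),
            skin_thickness_mm >= 0, voxel_pitch_mm > 0)
  k <- as.integer(ceiling(skin_thickness_mm / voxel_pitch_mm)) +
    as.integer(margin_voxels)
  if (k == 0L) return(mask)
  interior <- erode_mask(mask, k)
  if (!any(interior))
    stop("skin removal emptied the mask; skin thickness too large for ",
         "this volume")
  interior
}

#' Kernel fuzzy C-means clustering of interior voxel intensities
#'
#' Two-cluster KFCM with a Gaussian kernel K(x, v) = exp(-(x - v)^2 /
#' sigma^2) on voxel intensity. Alternates membership updates
#' `u_ik = (1 - K(x_k, v_i))^(-1/(m-1)) / sum_j (...)`
#' and kernel-weighted center updates
#' `v_i = sum_k u_ik^m K(x_k, v_i) x_k / sum_k u_ik^m K(x_k, v_i)`
#' until the maximum membership change falls below `tol` or `max_iter` is
#' reached (the latter flags `converged = FALSE`). Voxels coinciding
#' exactly with a center receive full membership in that cluster. Hard
#' labels are assigned by maximum membership with ties going to adipose
#' (the conservative, lower-density call); the cluster with the higher
#' center is fibroglandular.
#'
#' @param intensities numeric vector of interior voxel attenuations (1/cm);
#'   needs at least two distinct values.
#' @param cfg a [kfcmConfig()].
#' @return A [KFCMResult-class].
#' @examples
#' x <- c(rep(0.22, 50), rep(0.28, 50))
#' fit <- kfcmSegment(x, kfcmConfig())
#' fit@centers
#' @export
kfcmSegment <- function(intensities, cfg = kfcmConfig()) {
  stopifnot(inherits(cfg, "KFCMConfig"), is.numeric(intensities),
            all(is.finite(intensities)))
  x <- as.numeric(intensities)
  if (length(unique(x)) < 2L)
    stop("KFCM needs at least two distinct intensity values")
  sigma <- if (identical(cfg$kernel_sigma, "auto")) stats::sd(x)
           else cfg$kernel_sigma
  m <- cfg$fuzzifier
  ## deterministic center initialization at 25%/75% of the robust intensity
  ## range (1st-99th percentile). Positions in intensity space, not
  ## probability mass, so heavily imbalanced class sizes (e.g. almost
  ## entirely fatty breasts) still start one center near each mode.
  rng <- unname(stats::quantile(x, c(0.01, 0.99), type = 7))
  if (rng[1] >= rng[2]) rng <- range(x)
  v <- rng[1] + c(0.25, 0.75) * (rng[2] - rng[1])
  u <- matrix(0.5, length(x), 2L)
  obj <- numeric(0)
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    iters <- it
    K <- exp(-(outer(x, v, "-")^2) / sigma^2)
    d <- pmax(1 - K, 0)
    exact <- d <= 0
    w <- d^(-1 / (m - 1))
    u_new <- w / rowSums(w)
    ## voxels exactly at a center: full membership there
    hit <- rowSums(exact) > 0
    if (any(hit)) {
      u_new[hit, ] <- exact[hit, , drop = FALSE] /
        rowSums(exact[hit, , drop = FALSE])
    }
    um <- u_new^m
    wk <- um * K
    v_new <- colSums(wk * x) / colSums(wk)
    obj <- c(obj, 2 * sum(um * d))
    delta <- max(abs(u_new - u))
    u <- u_new
    v <- v_new
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("KFCM did not converge within max_iter = ", cfg$max_iter)
  ## order clusters: lower center = adipose, higher = fibroglandular
  ord <- order(v)
  v <- v[ord]
  u <- u[, ord, drop = FALSE]
  labels <- ifelse(u[, 2] > u[, 1], LABEL_GLAND, LABEL_ADIPOSE)
  new("KFCMResult", membership = u, centers = v,
      labels = as.integer(labels), iterations_used = iters,
      converged = converged, objective = obj)
}

#' VGF from a segmentation
#'
#' Volumetric glandular fraction: fibroglandular voxels over fibroglandular
#' plus adipose voxels. Skin and air never enter either count.
#'
#' @param seg a [SegmentationResult-class] or [KFCMResult-class].
#' @return Fraction in [0, 1].
#' @export
computeVGF <- function(seg) {
  if (is(seg, "SegmentationResult")) return(seg@vgf)
  stopifnot(is(seg, "KFCMResult"))
  ng <- sum(seg@labels == LABEL_GLAND)
  na <- sum(seg@labels == LABEL_ADIPOSE)
  if (ng + na == 0L) stop("no interior voxels to compute VGF from")
  ng / (ng + na)
}

#' End-to-end segmentation of a reconstructed breast volume
#'
#' Chains [breastMask()], [removeSkin()], and [kfcmSegment()], then
#' assembles the full label map and VGF. The default `margin_voxels = 1`
#' erodes one voxel beyond the skin-thickness-derived erosion because the
#' reconstruction kernel spreads the bright skin shell about one voxel
#' inward; set it to 0 for already-sharp (e.g. ground-truth) volumes.
#'
#' @param vol a [ReconVolume-class].
#' @param skin_thickness_mm assumed skin thickness (default 1.5 mm).
#' @param air_threshold see [breastMask()].
#' @param margin_voxels extra erosion; see Details.
#' @param cfg a [kfcmConfig()].
#' @return A [SegmentationResult-class].
#' @export
segmentVolume <- function(vol, skin_thickness_mm = 1.5, air_threshold = 0.1,
                          margin_voxels = 1L, cfg = kfcmConfig()) {
  stopifnot(is(vol, "ReconVolume"))
  mask <- breastMask(vol, air_threshold)
  interior <- removeSkin(mask, skin_thickness_mm, vol@voxel_pitch_mm,
                         margin_voxels = margin_voxels)
  fit <- kfcmSegment(vol@mu_hat[interior], cfg)
  label <- array(LABEL_AIR, dim(vol@mu_hat))
  label[mask & !interior] <- LABEL_SKIN
  label[interior] <- fit@labels
  ng <- sum(fit@labels == LABEL_GLAND)
  na <- sum(fit@labels == LABEL_ADIPOSE)
  new("SegmentationResult", label = label, kfcm = fit,
      vgf = ng / (ng + na), vg_voxels = as.integer(ng),
      va_voxels = as.integer(na),
      voxel_pitch_mm = vol@voxel_pitch_mm)
}
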