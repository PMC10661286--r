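#' Configuration for the total-variation iterative reconstruction
#'
#' Parameter record for [fristReconstruct()], an ASD-POCS scheme (adaptive
#' steepest descent - projection onto convex sets) whose data-fidelity step
#' is OS-SART (ordered-subsets simultaneous algebraic reconstruction) and
#' whose regularity step is steepest descent on smoothed isotropic total
#' variation, with a non-negativity projection and FDK initialization.
#'
#' Desk-scale defaults (20 iterations, 10 subsets) keep reconstruction at
#' the minutes scale; high-quality clinical-scale reconstructions use on
#' the order of 80-100 iterations (`clinical = TRUE` sets 100).
#'
#' @param n_iterations outer iterations (default 20).
#' @param n_subsets number of ordered view subsets (default 10).
#' @param sart_relaxation relaxation factor, in (0, 2) (default 1).
#' @param tv_steps_per_iteration TV descent sub-steps per iteration.
#' @param tv_step_ratio initial TV step budget as a fraction of the
#'   data-step image change (default 0.2).
#' @param alpha_red multiplicative reduction of the TV budget when the data
#'   residual stalls (default 0.95).
#' @param r_max residual-reduction band: the TV budget is reduced whenever
#'   residual_i > r_max * residual_{i-1} (default 0.95).
#' @param nonneg clamp negative voxels after each data step (default TRUE).
#' @param init `"FDK"` (default) or `"zeros"`.
#' @param stop_tol stop early when the relative image change per iteration
#'   falls below this (default 1e-6).
#' @param clinical use the clinical iteration count (100).
#' @return A list of class `"FristConfig"`.
#' @export
fristConfig <- function(n_iterations = 20L, n_subsets = 10L,
                        sart_relaxation = 1.0,
                        tv_steps_per_iteration = 10L,
                        tv_step_ratio = 0.2, alpha_red = 0.95,
                        r_max = 0.95, nonneg = TRUE,
                        init = c("FDK", "zeros"), stop_tol = 1e-6,
                        clinical = FALSE) {
  init <- match.arg(init)
  if (clinical) n_iterations <- 100L
  cfg <- list(n_iterations = as.integer(n_iterations),
              n_subsets = as.integer(n_subsets),
              sart_relaxation = sart_relaxation,
              tv_steps_per_iteration = as.integer(tv_steps_per_iteration),
              tv_step_ratio = tv_step_ratio, alpha_red = alpha_red,
              r_max = r_max, nonneg = isTRUE(nonneg), init = init,
              stop_tol = stop_tol)
  class(cfg) <- "FristConfig"
  stopifnot(cfg$n_iterations >= 1L, cfg$n_subsets >= 1L,
            sart_relaxation > 0, sart_relaxation < 2,
            tv_step_ratio > 0, tv_step_ratio <= 1,
            alpha_red > 0, alpha_red < 1, r_max > 0, r_max < 1,
            cfg$tv_steps_per_iteration >= 0L, stop_tol >= 0)
  cfg
}

## Round-robin view subsets by angle stride: subset s takes views
## s, s + n_subsets, s + 2 n_subsets, ... (1-based), giving each subset an
## angularly balanced fan. Fixed order for determinism.
view_subsets <- function(n_views, n_subsets) {
  n_subsets <- min(n_subsets, n_views)
  lapply(seq_len(n_subsets), function(s) seq(s, n_views, by = n_subsets))
}

## Geometry restricted to a view subset.
subset_geom <- function(g, idx) {
  new("ScanGeometry", sid_mm = g@sid_mm, sdd_mm = g@sdd_mm,
      detector_rows = g@detector_rows, detector_cols = g@detector_cols,
      detector_pitch_mm = g@detector_pitch_mm,
      view_angles_deg = g@view_angles_deg[idx])
}

## Per-subset SART normalizers: W (ray path lengths = forward projection of
## a unit volume) and V (voxel sensitivities = adjoint of unit projections).
sart_normalizers <- function(geom, subsets, grid_dim, pitch, step_mm) {
  ones_vol <- array(1, grid_dim)
  lapply(subsets, function(idx) {
    gs <- subset_geom(geom, idx)
    W <- forwardProject(ones_vol, gs, voxel_pitch_mm = pitch,
                        step_mm = step_mm)@data
    ones_proj <- array(1, dim(W))
    V <- backprojectRays(ones_proj, grid_dim, pitch, geometry = gs,
                         step_mm = step_mm)
    list(idx = idx, geom = gs, W = W, V = V,
         Wok = W > 1e-9, Vok = V > 1e-9)
  })
}

#' One OS-SART pass over all view subsets
#'
#' For each ordered subset s in turn updates
#' `x <- x + lambda * V^-1 * t(A_s) [ (p_s - A_s x) / W ]`,
#' where W are the subset ray path lengths (row sums of the subset system
#' matrix) and V the subset voxel sensitivities (column sums). Rays with
#' zero path length and voxels with zero sensitivity are skipped.
#'
#' @param x 3D attenuation array (1/cm).
#' @param p a [ProjectionSet-class].
#' @param n_subsets number of ordered subsets (1 = plain SART).
#' @param lambda relaxation factor in (0, 2).
#' @param voxel_pitch_mm voxel pitch of `x` (mm).
#' @param normalizers optional precomputed [sart_normalizers] result (used
#'   by the outer iteration to avoid recomputation).
#' @param step_mm ray sampling step (default half voxel pitch).
#' @return Updated 3D array.
#' @export
osSartPass <- function(x, p, n_subsets, lambda, voxel_pitch_mm,
                       normalizers = NULL, step_mm = NULL) {
  stopifnot(is.array(x), is(p, "ProjectionSet"), lambda > 0, lambda < 2)
  if (is.null(step_mm)) step_mm <- voxel_pitch_mm / 2
  g <- p@geometry
  n_views <- length(g@view_angles_deg)
  if (n_subsets < 1L || n_subsets > n_views)
    stop("n_subsets must be between 1 and the number of views")
  subsets <- view_subsets(n_views, n_subsets)
  if (any(lengths(subsets) == 0L)) stop("empty view subset")
  if (is.null(normalizers))
    normalizers <- sart_normalizers(g, subsets, dim(x), voxel_pitch_mm,
                                    step_mm)
  for (nrm in normalizers) {
    ax <- forwardProject(x, nrm$geom, voxel_pitch_mm = voxel_pitch_mm,
                         step_mm = step_mm)@data
    resid <- p@data[, , nrm$idx, drop = FALSE] - ax
    resid[nrm$Wok] <- resid[nrm$Wok] / nrm$W[nrm$Wok]
    resid[!nrm$Wok] <- 0
    upd <- backprojectRays(resid, dim(x), voxel_pitch_mm,
                           geometry = nrm$geom, step_mm = step_mm)
    upd[nrm$Vok] <- upd[nrm$Vok] / nrm$V[nrm$Vok]
    upd[!nrm$Vok] <- 0
    x <- x + lambda * upd
  }
  x
}

#' Smoothed isotropic total variation of a volume
#'
#' Sum over voxels of sqrt(dx^2 + dy^2 + dz^2 + eps^2) with forward
#' differences (zero beyond the far boundary); eps avoids a non-smooth
#' point at zero gradient.
#'
#' @param x 3D numeric array.
#' @param eps smoothing constant (default 1e-8).
#' @return Non-negative scalar.
#' @export
totalVariation <- function(x, eps = 1e-8) {
  stopifnot(is.array(x), length(dim(x)) == 3L, all(is.finite(x)))
  d <- dim(x)
  gx <- array(0, d); gx[-d[1], , ] <- x[-1, , ] - x[-d[1], , ]
  gy <- array(0, d); gy[, -d[2], ] <- x[, -1, ] - x[, -d[2], ]
  gz <- array(0, d); gz[, , -d[3]] <- x[, , -1] - x[, , -d[3]]
  sum(sqrt(gx^2 + gy^2 + gz^2 + eps^2))
}

## Gradient of totalVariation (same eps, forward differences).
tv_gradient <- function(x, eps = 1e-8) {
  d <- dim(x)
  gx <- array(0, d); gx[-d[1], , ] <- x[-1, , ] - x[-d[1], , ]
  gy <- array(0, d); gy[, -d[2], ] <- x[, -1, ] - x[, -d[2], ]
  gz <- array(0, d); gz[, , -d[3]] <- x[, , -1] - x[, , -d[3]]
  Dm <- sqrt(gx^2 + gy^2 + gz^2 + eps^2)
  g <- -(gx + gy + gz) / Dm
  t1 <- gx / Dm; t2 <- gy / Dm; t3 <- gz / Dm
  g[-1, , ] <- g[-1, , ] + t1[-d[1], , ]
  g[, -1, ] <- g[, -1, ] + t2[, -d[2], ]
  g[, , -1] <- g[, , -1] + t3[, , -d[3]]
  g
}

#' Normalized-gradient steepest descent on total variation
#'
#' Performs `steps` descent steps; each step moves the volume by exactly
#' `step_size` in Euclidean norm along the negative normalized TV gradient.
#' A zero gradient (constant volume) is a no-op.
#'
#' @param x 3D numeric array.
#' @param steps number of descent steps.
#' @param step_size Euclidean step length per step (>= 0).
#' @param eps TV smoothing constant.
#' @return Updated array.
#' @export
tvDescent <- function(x, steps, step_size, eps = 1e-8) {
  stopifnot(step_size >= 0, steps >= 0)
  if (step_size == 0 || steps == 0) return(x)
  for (s in seq_len(steps)) {
    g <- tv_gradient(x, eps)
    ng <- sqrt(sum(g^2))
    if (ng < 1e-12) return(x)
    x <- x - step_size * g / ng
  }
  x
}

#' ASD-POCS total-variation reconstruction (FRIST-style)
#'
#' Iterative compressed-sensing reconstruction: each outer iteration applies
#' one OS-SART pass over all view subsets (the data-fidelity projection),
#' clamps negative voxels when `nonneg`, then takes
#' `tv_steps_per_iteration` TV steepest-descent sub-steps whose total
#' Euclidean budget is `tv_step_ratio * ||data-step image change||`
#' (the ASD-POCS balance between data fidelity and regularity). Whenever the
#' data residual fails to shrink below `r_max` times its previous value the
#' TV budget ratio is multiplied by `alpha_red`, progressively handing
#' control back to the data term. Initialization is the FDK reconstruction
#' of the same data by default.
#'
#' @param p a [ProjectionSet-class].
#' @param cfg a [fristConfig()].
#' @param grid_dim integer vector of 3 output dimensions.
#' @param voxel_pitch_mm isotropic output voxel pitch (mm).
#' @param window FDK window used for initialization.
#' @param init_volume optional 3D array overriding `cfg$init` (e.g. a warm
#'   start from a previous run).
#' @return A [ReconVolume-class] tagged `"FRIST"`; `params$log` holds the
#'   per-iteration data residual and TV.
#' @export
fristReconstruct <- function(p, cfg = fristConfig(), grid_dim,
                             voxel_pitch_mm, window = "hann",
                             init_volume = NULL) {
  stopifnot(is(p, "ProjectionSet"), inherits(cfg, "FristConfig"))
  g <- p@geometry
  step_mm <- voxel_pitch_mm / 2
  n_views <- length(g@view_angles_deg)
  subsets <- view_subsets(n_views, cfg$n_subsets)
  normalizers <- sart_normalizers(g, subsets, grid_dim, voxel_pitch_mm,
                                  step_mm)
  x <- if (!is.null(init_volume)) {
    stopifnot(identical(dim(init_volume), as.integer(grid_dim)))
    init_volume
  } else if (cfg$init == "FDK") {
    fdkReconstruct(p, grid_dim, voxel_pitch_mm, window = window)@mu_hat
  } else {
    array(0, grid_dim)
  }
  if (cfg$nonneg) x[x < 0] <- 0

  resid_norm <- function(x) {
    ax <- forwardProject(x, g, voxel_pitch_mm = voxel_pitch_mm,
                         step_mm = step_mm)@data
    sqrt(sum((p@data - ax)^2))
  }
  r_prev <- resid_norm(x)
  r0 <- r_prev
  alpha <- cfg$tv_step_ratio
  log <- data.frame(iteration = integer(), residual = numeric(),
                    tv = numeric(), alpha = numeric())
  for (it in seq_len(cfg$n_iterations)) {
    x_old <- x
    x <- osSartPass(x, p, cfg$n_subsets, cfg$sart_relaxation,
                    voxel_pitch_mm, normalizers = normalizers,
                    step_mm = step_mm)
    if (cfg$nonneg) x[x < 0] <- 0
    dd <- sqrt(sum((x - x_old)^2))
    r_it <- resid_norm(x)
    if (r_it > 10 * r0)
      stop("FRIST diverged: residual exceeded 10x its initial value ",
           "(iteration ", it, ")")
    if (cfg$tv_steps_per_iteration > 0L && dd > 0) {
      ## each TV sub-step moves alpha * ||data-step change|| in Euclidean
      ## norm, the step balance of the original ASD-POCS scheme
      x <- tvDescent(x, cfg$tv_steps_per_iteration, alpha * dd)
      ## the non-negativity set is one of the convex sets projected onto;
      ## re-clamp so small TV-step undershoots cannot leave the output
      ## negative
      if (cfg$nonneg) x[x < 0] <- 0
    }
    ## damp the TV budget only when the data residual grows beyond the
    ## tolerated band (a fractional increase of 1/r_max), i.e. when the TV
    ## steps are overpowering the data steps
    if (r_it > r_prev / cfg$r_max) alpha <- alpha * cfg$alpha_red
    r_prev <- r_it
    log <- rbind(log, data.frame(iteration = it, residual = r_it,
                                 tv = totalVariation(x), alpha = alpha))
    rel_change <- dd / max(sqrt(sum(x_old^2)), 1e-12)
    if (rel_change < cfg$stop_tol) break
  }
  new("ReconVolume", mu_hat = x, voxel_pitch_mm = voxel_pitch_mm,
      method_tag = "FRIST",
      params = list(algorithm = "ASD-POCS/OS-SART", config = unclass(cfg),
                    views = n_views, log = log,
                    photons_per_ray = p@photons_per_ray,
                    noise_seed = p@seed))
}
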