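## Internal helpers shared across modules.

## Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
## stream. Every stochastic operation in the package routes through this so
## that fixed seeds give bit-identical results regardless of call order.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## World coordinates (mm) of voxel centers along one axis, isocenter at 0.
axis_coords <- function(n, pitch_mm) (seq_len(n) - (n + 1) / 2) * pitch_mm

## Shift a 3D logical array by (dx, dy, dz) voxels, padding with `fill`.
shift3 <- function(m, dx, dy, dz, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  sx <- seq(max(1, 1 + dx), min(d[1], d[1] + dx))
  sy <- seq(max(1, 1 + dy), min(d[2], d[2] + dy))
  sz <- seq(max(1, 1 + dz), min(d[3], d[3] + dz))
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}

NBR6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

## One 6-neighbourhood erosion step. `fill` sets what lies outside the
## array: FALSE (background, the default) shrinks masks touching the
## boundary; TRUE is used for the erosion half of a morphological closing,
## where the outside must not eat the mask edge.
erode_step <- function(m, fill = FALSE) {
  out <- m
  for (r in seq_len(nrow(NBR6)))
    out <- out & shift3(m, NBR6[r, 1], NBR6[r, 2], NBR6[r, 3], fill = fill)
  out
}

dilate_step <- function(m) {
  out <- m
  for (r in seq_len(nrow(NBR6)))
    out <- out | shift3(m, NBR6[r, 1], NBR6[r, 2], NBR6[r, 3], fill = FALSE)
  out
}

erode_mask <- function(m, k, fill = FALSE) {
  k <- as.integer(k)
  while (k > 0L) { m <- erode_step(m, fill = fill); k <- k - 1L }
  m
}

dilate_mask <- function(m, k) {
  k <- as.integer(k)
  while (k > 0L) { m <- dilate_step(m); k <- k - 1L }
  m
}

## Stage seeds for the pipeline: deterministic, documented scheme keeping the
## derived seed inside 32-bit integer range.
stage_seed <- function(global_seed, stage, id = 0L) {
  codes <- c(phantom = 1L, noise = 2L, fdk = 3L, frist = 4L, split = 5L,
             segment = 6L, stats = 7L)
  code <- codes[[stage]]
  as.integer((as.numeric(global_seed) * 7919 + code * 1299709 + id * 104729) %%
               2147483629)
}
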