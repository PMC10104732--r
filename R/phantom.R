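#' Rasterize a vessel geometry into a synthetic contrast-enhanced CT volume
#'
#' Emulates a contrast-enhanced coronary acquisition at desk scale: a bright
#' tubular lumen (the vessel geometry swept along the z axis) over a darker
#' soft-tissue background, with optional partial-volume supersampling and
#' seeded additive Gaussian noise. Identical arguments and seed give a
#' bit-identical volume.
#'
#' The voxel grid is sized to enclose the geometry: the z extent covers
#' `[0, L]` and the x/y extent covers the lumen plus `margin` mm on each
#' side. Voxel centers sit at `origin + (index - 1) * spacing`.
#'
#' @param geometry A [vessel_geometry()].
#' @param spacing Voxel spacing in mm, length 1 or 3.
#' @param lumen,background Lumen / background intensity (HU-like arbitrary
#'   units); `lumen` must exceed `background`.
#' @param noise_sd Standard deviation of additive Gaussian noise (same units).
#' @param margin Transverse padding around the vessel, mm.
#' @param supersample Integer >= 1; voxel occupancy is estimated from
#'   `supersample^3` sub-voxel points and the intensity blended accordingly.
#'   The default 1 classifies each voxel by its center (hard in/out), which
#'   keeps the noise-free volume an exact indicator of the lumen.
#' @param dims Optional explicit grid dimensions (length 3). Must be large
#'   enough to enclose the geometry at the given spacing.
#' @param seed Integer seed for the noise stream. Ignored when `noise_sd = 0`.
#' @return A [ct_volume()].
#' @examples
#' geom <- vessel_geometry(L = 20, R0 = 2, d = 0.5)
#' vol <- rasterize_ct(geom, spacing = 0.5, noise_sd = 5, seed = 1)
#' @export
rasterize_ct <- function(geometry, spacing = 0.5, lumen = 400, background = 50,
                         noise_sd = 0, margin = 2, supersample = 1L,
                         dims = NULL, seed = 1L) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) abort("`spacing` must be positive.")
  if (lumen <= background) abort("`lumen` intensity must exceed `background`.")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(margin, "margin", nonneg = TRUE)
  supersample <- as.integer(supersample)
  if (supersample < 1L) abort("`supersample` must be >= 1.")

  half_xy <- geometry$R0 + margin
  need <- c(
    ceiling(2 * half_xy / spacing[1]) + 1L,
    ceiling(2 * half_xy / spacing[2]) + 1L,
    ceiling(geometry$L / spacing[3]) + 1L
  )
  if (is.null(dims)) {
    dims <- need
  } else {
    dims <- as.integer(dims)
    if (length(dims) != 3L) abort("`dims` must have length 3.")
    if (any(dims < need)) {
      abort(sprintf(
        "volume extent %s too small for the geometry (needs at least %s voxels).",
        paste(dims, collapse = "x"), paste(need, collapse = "x")
      ))
    }
  }
  # center the vessel axis on the transverse grid
  origin <- c(-(dims[1] - 1) * spacing[1] / 2, -(dims[2] - 1) * spacing[2] / 2, 0)

  occ <- lumen_occupancy(geometry, dims, spacing, origin, supersample)
  vox <- background + occ * (lumen - background)

  if (noise_sd > 0) {
    rng <- local_rng(seed)
    vox <- vox + array(rng$rnorm(length(vox), sd = noise_sd), dim = dims)
  }
  ct_volume(vox, spacing, origin)
}

# fractional occupancy of each voxel by the lumen (0/1 when supersample == 1)
lumen_occupancy <- function(geometry, dims, spacing, origin, supersample) {
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  if (supersample == 1L) {
    sub <- cbind(0, 0, 0)
  } else {
    u <- (seq_len(supersample) - 0.5) / supersample - 0.5
    sub <- as.matrix(expand.grid(u * spacing[1], u * spacing[2], u * spacing[3]))
  }
  acc <- array(0, dim = dims)
  for (p in seq_len(nrow(sub))) {
    dx2 <- (xs + sub[p, 1])^2
    dy2 <- (ys + sub[p, 2])^2
    rad2 <- outer(dx2, dy2, `+`)
    z <- zs + sub[p, 3]
    rz <- vessel_radius(geometry, z)
    inz <- z >= 0 & z <= geometry$L
    # inside if radial distance <= r(z) and axial position within the vessel
    for (k in seq_len(dims[3])) {
      if (inz[k]) acc[, , k] <- acc[, , k] + (rad2 <= rz[k]^2)
    }
  }
  acc / nrow(sub)
}

#' Ground-truth lumen mask of a vessel geometry
#'
#' The exact voxel-center in/out indicator of the lumen on the same grid
#' [rasterize_ct()] uses — the reference standard for segmentation recovery
#' experiments on phantoms.
#'
#' @inheritParams rasterize_ct
#' @return A [ct_mask()].
#' @export
lumen_truth_mask <- function(geometry, spacing = 0.5, margin = 2, dims = NULL) {
  vol <- rasterize_ct(geometry,
    spacing = spacing, lumen = 1, background = 0,
    noise_sd = 0, margin = margin, supersample = 1L, dims = dims
  )
  ct_mask(vol$data > 0.5, vol$spacing, vol$origin)
}

# A private RNG stream: seeded draws that do not disturb the session RNG.
local_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  draw <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, globalenv())
      }
      out
    }
  }
  list(
    rnorm = draw(stats::rnorm),
    runif = draw(stats::runif),
    rbinom = draw(stats::rbinom)
  )
}
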