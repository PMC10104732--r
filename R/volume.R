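#' CT volume and binary mask containers
#'
#' A `ct_volume` wraps a 3-D numeric array with its voxel spacing (mm) and
#' origin (mm, physical coordinate of the center of voxel `[1,1,1]`). A
#' `ct_mask` is the same with a logical array, aligned voxel-for-voxel with
#' the volume it was derived from.
#'
#' @param data 3-D numeric (or logical for masks) array.
#' @param spacing Voxel spacing, mm; length-1 (isotropic) or length-3.
#' @param origin Physical position of the first voxel center, mm (length 3).
#' @return A `ct_volume` (or `ct_mask`) object.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array.")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 1 or 3 positive numbers (mm).")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite numbers (mm).")
  }
  structure(
    list(data = data, spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "ct_volume"
  )
}

#' @rdname ct_volume
#' @export
ct_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) abort("`data` must be a 3-D array.")
  storage.mode(data) <- "logical"
  out <- ct_volume(data, spacing, origin)
  class(out) <- c("ct_mask", "ct_volume")
  out
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<%s> %d x %d x %d voxels, spacing (%g, %g, %g) mm, range [%g, %g]\n",
    class(x)[1], d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

# physical coordinates of all voxel centers along one axis (1-based index)
axis_coords <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

#' Jaccard overlap of two binary masks
#'
#' Intersection over union of the foreground voxel sets; the standard
#' voxel-overlap score for segmentation agreement.
#'
#' @param a,b `ct_mask` objects or logical arrays of identical shape.
#' @return Scalar in `[0, 1]`; `NaN` if both masks are empty.
#' @export
mask_jaccard <- function(a, b) {
  am <- if (inherits(a, "ct_volume")) a$data else a
  bm <- if (inherits(b, "ct_volume")) b$data else b
  if (!identical(dim(am), dim(bm))) abort("masks must have identical shape.")
  inter <- sum(am & bm)
  uni <- sum(am | bm)
  inter / uni
}
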