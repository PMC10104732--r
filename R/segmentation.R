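#' Two-class statistics of a volume at a test threshold
#'
#' Partitions the voxels of a volume at a test threshold `t` into a
#' foreground class `B1` (intensity `>= t`; the bright contrast-filled lumen)
#' and a background class `B2` (intensity `< t`), and returns the class mean
#' vectors and counts
#' \deqn{\bar a_1 = \frac{1}{M_1}\sum_{p \in B_1} p, \qquad
#'       \bar a_2 = \frac{1}{M_2}\sum_{p \in B_2} p,}
#' together with the overall mean
#' \eqn{\bar a = (\sum_{p \in B} p) / (M_1 + M_2)}. CT intensities are
#' scalar, so the "vectors" are scalars here; the formulas generalise
#' unchanged. An empty class is flagged (`NaN` mean, zero count).
#'
#' @param volume A [ct_volume()] or 3-D numeric array.
#' @param t Test threshold (intensity units).
#' @return A list: `a1`, `a2` (class means), `M1`, `M2` (voxel counts),
#'   `abar` (overall mean), `empty_class` (logical).
#' @export
class_stats <- function(volume, t) {
  v <- as_voxels(volume)
  check_scalar(t, "t")
  fg <- v >= t
  M1 <- sum(fg)
  M2 <- length(v) - M1
  s1 <- sum(v[fg])
  s2 <- sum(v[!fg])
  list(
    a1 = if (M1 > 0) s1 / M1 else NaN,
    a2 = if (M2 > 0) s2 / M2 else NaN,
    M1 = M1, M2 = M2,
    abar = (s1 + s2) / (M1 + M2),
    empty_class = M1 == 0L || M2 == 0L
  )
}

#' Clustering-threshold objective: total within-class scatter
#'
#' The objective minimised by the clustering-threshold segmentation: the sum
#' over both classes of squared deviations from the class mean,
#' \deqn{G(t) = \sum_{p \in B_1} (p - \bar a_1)^2 + \sum_{p \in B_2} (p - \bar a_2)^2.}
#' This is the within-class sum of squares of two-class k-means / Otsu
#' thresholding; an empty class contributes zero scatter.
#'
#' @inheritParams class_stats
#' @return Scalar `G(t) >= 0`.
#' @export
objective_g <- function(volume, t) {
  v <- as_voxels(volume)
  check_scalar(t, "t")
  fg <- v >= t
  g <- 0
  if (any(fg)) g <- g + sum((v[fg] - mean(v[fg]))^2)
  if (any(!fg)) g <- g + sum((v[!fg] - mean(v[!fg]))^2)
  g
}

#' Optimal clustering threshold by exhaustive scan
#'
#' Evaluates `G(t)` over a discrete grid of test thresholds and returns the
#' minimiser, with ties broken toward the smallest `t` for determinism. The
#' default grid scans every integer intensity in the volume's range, so the
#' result is the exact argmin over that grid.
#'
#' @inheritParams class_stats
#' @param t_min,t_max Scan range; defaults to the integer span of the
#'   volume's intensities (`ceiling(min)` to `floor(max)`).
#' @param step Grid step (> 0), default 1 intensity unit.
#' @return A `threshold_result`: list with `t_star`, `G_star`, the scan
#'   table `curve` (tibble `t`, `G`), and the class statistics at `t_star`
#'   (`a1`, `a2`, `M1`, `M2`, `abar`).
#' @examples
#' vol <- array(c(rep(0, 20), rep(100, 12)), dim = c(4, 4, 2))
#' optimal_threshold(vol)$t_star
#' @export
optimal_threshold <- function(volume, t_min = NULL, t_max = NULL, step = 1) {
  v <- as_voxels(volume)
  check_scalar(step, "step", positive = TRUE)
  if (is.null(t_min)) t_min <- ceiling(min(v))
  if (is.null(t_max)) t_max <- floor(max(v))
  if (t_min > t_max) abort("empty scan range: `t_min` must be <= `t_max`.")
  ts <- seq(t_min, t_max, by = step)

  # G(t) for every scanned t via prefix sums over the sorted intensities:
  # G = S2_tot - M1*a1^2 - M2*a2^2 for the partition {v < t}, {v >= t}.
  sv <- sort(v)
  cs <- cumsum(sv)
  cs2 <- cumsum(sv^2)
  ntot <- length(sv)
  stot <- cs[ntot]
  s2tot <- cs2[ntot]
  nbg <- findInterval(ts, sv, left.open = TRUE) # count of v < t (sv[i] < t)
  sbg <- ifelse(nbg > 0, cs[pmax(nbg, 1L)], 0)
  s2bg <- ifelse(nbg > 0, cs2[pmax(nbg, 1L)], 0)
  nfg <- ntot - nbg
  sfg <- stot - sbg
  s2fg <- s2tot - s2bg
  G <- (s2fg - ifelse(nfg > 0, sfg^2 / nfg, 0)) +
    (s2bg - ifelse(nbg > 0, sbg^2 / nbg, 0))
  G <- pmax(G, 0) # guard tiny negative round-off

  i_star <- which.min(G) # first minimum = smallest t on ties
  t_star <- ts[i_star]
  st <- class_stats(v, t_star)
  structure(
    list(
      t_star = t_star, G_star = G[i_star],
      curve = tibble(t = ts, G = G),
      a1 = st$a1, a2 = st$a2, M1 = st$M1, M2 = st$M2, abar = st$abar,
      empty_class = st$empty_class
    ),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> t* = %g (G = %g); foreground M1 = %d (mean %.3g), background M2 = %d (mean %.3g)\n",
    x$t_star, x$G_star, x$M1, x$a1, x$M2, x$a2
  ))
  invisible(x)
}

#' Threshold a volume into a binary mask
#'
#' Foreground is intensity `>= t` (contrast-enhanced lumen is bright).
#'
#' @inheritParams class_stats
#' @return A [ct_mask()] aligned with the input volume.
#' @export
apply_threshold <- function(volume, t) {
  check_scalar(t, "t")
  if (inherits(volume, "ct_volume")) {
    ct_mask(volume$data >= t, volume$spacing, volume$origin)
  } else {
    ct_mask(volume >= t)
  }
}

#' Keep only the largest connected foreground component
#'
#' Removes noise specks before surface reconstruction. Components are found
#' under 6-, 18- or 26-connectivity by iterative minimum-label propagation;
#' ties in size are broken toward the component containing the lowest linear
#' voxel index, so the result is deterministic.
#'
#' @param mask A [ct_mask()] or logical array.
#' @param connectivity One of 6, 18, 26.
#' @return A mask of the same type with a single connected component. An
#'   all-false mask is returned unchanged with attribute `empty = TRUE` and
#'   a warning.
#' @export
largest_component <- function(mask, connectivity = 26) {
  m <- if (inherits(mask, "ct_volume")) mask$data else mask
  storage.mode(m) <- "logical"
  if (!sum(m)) {
    warn("mask has no foreground voxels; returned unchanged.")
    attr(mask, "empty") <- TRUE
    return(mask)
  }
  lab <- label_components(m, connectivity)
  sizes <- tabulate(lab[m])
  # labels are min linear indices, dense-ranked by label_components; ties in
  # size resolve to the smaller label, i.e. the lowest-linear-index component
  best <- which(sizes == max(sizes))[1]
  keep <- m & (lab == best)
  if (inherits(mask, "ct_volume")) ct_mask(keep, mask$spacing, mask$origin) else keep
}

# dense component labels (1..k, ordered by the component's minimum linear
# index) via iterative min-propagation over the chosen neighbourhood.
label_components <- function(m, connectivity = 26) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) abort("`connectivity` must be 6, 18 or 26.")
  d <- dim(m)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & switch(as.character(connectivity),
    "6" = nz == 1, "18" = nz <= 2, "26" = nz <= 3
  ), , drop = FALSE]

  lab <- array(Inf, dim = d)
  lab[m] <- which(m) # seed with linear index
  shift1 <- function(a, o) {
    # shift array by offset o, padding with Inf
    out <- array(Inf, dim = d)
    src <- list(
      x = seq_len(d[1]) - o[1], y = seq_len(d[2]) - o[2], z = seq_len(d[3]) - o[3]
    )
    okx <- src$x >= 1 & src$x <= d[1]
    oky <- src$y >= 1 & src$y <= d[2]
    okz <- src$z >= 1 & src$z <= d[3]
    out[okx, oky, okz] <- a[src$x[okx], src$y[oky], src$z[okz]]
    out
  }
  repeat {
    nb <- lab
    for (r in seq_len(nrow(offs))) {
      nb <- pmin(nb, shift1(lab, offs[r, ]))
    }
    nb[!m] <- Inf
    if (identical(nb, lab)) break
    lab <- nb
  }
  out <- array(0L, dim = d)
  out[m] <- match(lab[m], sort(unique(lab[m])))
  out
}

as_voxels <- function(volume) {
  v <- if (inherits(volume, "ct_volume")) volume$data else volume
  if (!is.numeric(v)) storage.mode(v) <- "double"
  as.vector(v)
}
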