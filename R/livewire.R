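#' Live-wire boundary extraction on a 2-D slice
#'
#' Interactive "intelligent scissors"-style boundary tracing, exposed as a
#' programmatic operation: the minimum-cumulative-cost 8-connected path from
#' a seed pixel to a target pixel over a local cost map built from the image.
#'
#' The local cost of entering pixel `q` is
#' \deqn{l(q) = w_g (1 - |\nabla I|_q / \max |\nabla I|) + w_z (1 - z(q)),}
#' where `z(q)` is the Laplacian zero-crossing indicator, so strong edges
#' (high gradient, zero-crossing of the Laplacian) are cheap. A step from
#' `p` into `q` costs `l(q)` for axial moves and `sqrt(2) * l(q)` for
#' diagonal moves. The path is found by Dijkstra's algorithm and is optimal
#' for that cost.
#'
#' @param image_slice 2-D numeric matrix (one CT slice).
#' @param seed_point,target_point Integer `(row, col)` coordinates inside the
#'   slice.
#' @param weights Named numeric: `gradient` and `zero_crossing` cost weights
#'   (defaults 0.8 and 0.2).
#' @return A `pixel_path`: list with `path` (n x 2 integer matrix of
#'   row/col coordinates from seed to target), `cost` (accumulated cost) and
#'   `cost_map` (the local cost matrix).
#' @examples
#' img <- outer(1:12, 1:12, function(i, j) as.numeric(j > 6) * 100)
#' lw <- live_wire(img, c(2, 2), c(11, 11))
#' lw$cost
#' @export
live_wire <- function(image_slice, seed_point, target_point,
                      weights = c(gradient = 0.8, zero_crossing = 0.2)) {
  if (!is.matrix(image_slice) || !is.numeric(image_slice)) {
    abort("`image_slice` must be a numeric matrix.")
  }
  nr <- nrow(image_slice)
  nc <- ncol(image_slice)
  chk_pt <- function(p, name) {
    p <- as.integer(p)
    if (length(p) != 2L || p[1] < 1L || p[1] > nr || p[2] < 1L || p[2] > nc) {
      abort(sprintf("`%s` must be a (row, col) pair inside the slice.", name))
    }
    p
  }
  seed_point <- chk_pt(seed_point, "seed_point")
  target_point <- chk_pt(target_point, "target_point")
  w_g <- weights[["gradient"]]
  w_z <- weights[["zero_crossing"]]

  l <- livewire_cost(image_slice, w_g, w_z)

  if (all(seed_point == target_point)) {
    return(structure(
      list(path = matrix(seed_point, 1, 2, dimnames = list(NULL, c("row", "col"))),
           cost = 0, cost_map = l),
      class = "pixel_path"
    ))
  }

  # Dijkstra over the 8-connected pixel graph
  n <- nr * nc
  dist <- rep(Inf, n)
  prev <- integer(n)
  done <- logical(n)
  id <- function(r, c) r + (c - 1L) * nr
  src <- id(seed_point[1], seed_point[2])
  dst <- id(target_point[1], target_point[2])
  dist[src] <- 0
  moves <- cbind(
    dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
    dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L),
    len = c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))
  )
  lv <- as.vector(l)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) abort("target unreachable.") # cannot happen on a grid
    if (u == dst) break
    done[u] <- TRUE
    ur <- ((u - 1L) %% nr) + 1L
    uc <- ((u - 1L) %/% nr) + 1L
    for (k in 1:8) {
      vr <- ur + moves[k, 1]
      vc <- uc + moves[k, 2]
      if (vr < 1L || vr > nr || vc < 1L || vc > nc) next
      v <- id(vr, vc)
      if (done[v]) next
      cand <- dist[u] + moves[k, 3] * lv[v]
      if (cand < dist[v]) {
        dist[v] <- cand
        prev[v] <- u
      }
    }
  }
  # trace back
  path <- dst
  while (path[1] != src) path <- c(prev[path[1]], path)
  coords <- cbind(
    row = ((path - 1L) %% nr) + 1L,
    col = ((path - 1L) %/% nr) + 1L
  )
  structure(list(path = coords, cost = dist[dst], cost_map = l), class = "pixel_path")
}

# local cost map: gradient-magnitude term + Laplacian zero-crossing term
livewire_cost <- function(img, w_g, w_z) {
  nr <- nrow(img)
  nc <- ncol(img)
  pad <- function(ri, ci) img[pmin(pmax(ri, 1L), nr), pmin(pmax(ci, 1L), nc), drop = FALSE]
  ri <- seq_len(nr)
  ci <- seq_len(nc)
  gx <- (pad(ri + 1L, ci) - pad(ri - 1L, ci)) / 2
  gy <- (pad(ri, ci + 1L) - pad(ri, ci - 1L)) / 2
  gmag <- sqrt(gx^2 + gy^2)
  gmax <- max(gmag)
  gterm <- if (gmax > 0) 1 - gmag / gmax else matrix(1, nr, nc)

  lap <- pad(ri + 1L, ci) + pad(ri - 1L, ci) + pad(ri, ci + 1L) + pad(ri, ci - 1L) - 4 * img
  zc <- matrix(FALSE, nr, nc)
  for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nbr <- matrix(Inf, nr, nc)
    rs <- ri + o[1]
    cs <- ci + o[2]
    okr <- rs >= 1L & rs <= nr
    okc <- cs >= 1L & cs <= nc
    nbr[okr, okc] <- lap[rs[okr], cs[okc]]
    # zero-crossing: opposite signs and this pixel closer to zero
    zc <- zc | (is.finite(nbr) & sign(lap) * sign(nbr) < 0 & abs(lap) <= abs(nbr))
  }
  w_g * gterm + w_z * (1 - zc)
}

#' @export
print.pixel_path <- function(x, ...) {
  cat(sprintf(
    "<pixel_path> %d pixels from (%d, %d) to (%d, %d), cost %.4g\n",
    nrow(x$path), x$path[1, 1], x$path[1, 2],
    x$path[nrow(x$path), 1], x$path[nrow(x$path), 2], x$cost
  ))
  invisible(x)
}
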