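#' Combinatorial and metric report on a triangle mesh
#'
#' Counts vertices, unique undirected edges and faces; computes the Euler
#' characteristic `chi = V - E + F`; flags watertightness (every edge
#' bordered by exactly two triangles — `chi = 2` then identifies a closed
#' genus-0 surface); and accumulates total surface area (summed triangle
#' areas) and enclosed volume (signed tetrahedron sum, meaningful for
#' closed, consistently wound meshes). Boundary edges (bordering one
#' triangle) are reported separately so an open-ended tube can be recognised
#' as "watertight up to its boundary rings".
#'
#' @param mesh A [triangle_mesh()].
#' @return A list: `n_vertices`, `n_edges`, `n_faces`, `chi`, `watertight`,
#'   `n_boundary_edges`, `area` (mm^2), `volume` (mm^3, signed).
#' @export
mesh_report <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  V <- nrow(mesh$vertices)
  F <- nrow(mesh$faces)
  if (!F) {
    return(list(
      n_vertices = V, n_edges = 0L, n_faces = 0L, chi = V,
      watertight = FALSE, n_boundary_edges = 0L, area = 0, volume = 0
    ))
  }
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  mult <- table(ekey)
  E <- length(mult)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cr <- vec_cross(v2 - v1, v3 - v1)
  area <- sum(sqrt(rowSums(cr^2))) / 2
  vol <- sum(
    v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  ) / 6
  list(
    n_vertices = V, n_edges = E, n_faces = F, chi = V - E + F,
    watertight = all(mult == 2L),
    n_boundary_edges = sum(mult == 1L),
    area = area, volume = vol
  )
}

#' Laplacian mesh smoothing
#'
#' Moves each vertex toward the mean of its edge-connected neighbours:
#' `v <- v + factor * (mean(neighbours) - v)`, repeated `iterations` times.
#' Vertex count and connectivity (hence topology) are preserved;
#' `iterations = 0` is the identity. Uniform Laplacian smoothing shrinks
#' closed surfaces slightly — acceptable for taming the voxel staircase of
#' binary-mask surfaces before geometric measurement.
#'
#' @param mesh A [triangle_mesh()].
#' @param iterations Number of smoothing passes (>= 0).
#' @param factor Step size in `(0, 1]`.
#' @return A [triangle_mesh()] with the same faces and smoothed vertices.
#' @export
smooth_mesh <- function(mesh, iterations = 5, factor = 0.5) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  iterations <- as.integer(iterations)
  if (iterations < 0L) abort("`iterations` must be >= 0.")
  if (iterations == 0L || !nrow(mesh$faces)) return(mesh)
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  adj_from <- c(e[, 1], e[, 2])
  adj_to <- c(e[, 2], e[, 1])
  V <- nrow(mesh$vertices)
  deg <- tabulate(adj_from, nbins = V) # counts each neighbour once per shared edge side
  ref <- deg > 0L # vertices referenced by at least one face move; others stay
  pos <- mesh$vertices
  for (it in seq_len(iterations)) {
    acc <- matrix(0, V, 3L)
    for (ax in 1:3) {
      s <- rowsum(pos[adj_to, ax], adj_from, reorder = TRUE)
      acc[as.integer(rownames(s)), ax] <- s
    }
    nbr_mean <- acc[ref, , drop = FALSE] / deg[ref]
    pos[ref, ] <- pos[ref, , drop = FALSE] +
      factor * (nbr_mean - pos[ref, , drop = FALSE])
  }
  triangle_mesh(pos, mesh$faces)
}

#' Lumen radius profile from a binary mask or surface mesh
#'
#' For a vessel roughly aligned with one grid axis, estimates the
#' equivalent-circle radius at each station along that axis from the
#' cross-sectional area: `r(s) = sqrt(A(s) / pi)`. With a mask, `A(s)` is
#' the foreground pixel count times the pixel area; with a mesh, `A(s)` is
#' the signed polygon area of the plane section at `s` (see
#' [mesh_section_area()]). Stations with empty cross-section strictly
#' between non-empty ones are flagged as gaps.
#'
#' @param x A [ct_mask()] or [triangle_mesh()].
#' @param axis Axis index the vessel runs along (1, 2 or 3; default 3 = z).
#' @param stations For meshes: station coordinates (mm) at which to section;
#'   for masks the stations are the voxel-center coordinates of the axis.
#' @return A tibble: `s` (mm), `area` (mm^2), `r` (mm), `gap` (logical).
#'   Leading/trailing empty stations are dropped.
#' @export
extract_lumen_profile <- function(x, axis = 3, stations = NULL) {
  axis <- as.integer(axis)
  if (!axis %in% 1:3) abort("`axis` must be 1, 2 or 3.")
  if (inherits(x, "ct_volume")) {
    m <- x$data
    storage.mode(m) <- "logical"
    other <- setdiff(1:3, axis)
    pix_area <- prod(x$spacing[other])
    counts <- apply(m, axis, sum)
    s <- axis_coords(x, axis)
    area <- counts * pix_area
  } else if (inherits(x, "triangle_mesh")) {
    if (is.null(stations)) {
      rng <- range(x$vertices[, axis])
      stations <- seq(rng[1], rng[2], length.out = 50L)
    }
    s <- stations
    area <- vapply(stations, function(z) abs(mesh_section_area(x, z, axis)), numeric(1))
  } else {
    abort("`x` must be a ct_mask or triangle_mesh.")
  }
  nonzero <- which(area > 0)
  if (!length(nonzero)) abort("no non-empty cross-section found.")
  idx <- seq(min(nonzero), max(nonzero))
  tibble(
    s = s[idx], area = area[idx], r = sqrt(area[idx] / pi),
    gap = area[idx] <= 0
  )
}

#' Cross-sectional polygon area of a closed mesh
#'
#' Slices the mesh with the plane `coordinate[axis] = at` and accumulates
#' the signed area of the section contour from the oriented crossing
#' segments of each triangle. For a closed, consistently wound mesh this is
#' the enclosed cross-sectional area (up to sign).
#'
#' @param mesh A [triangle_mesh()].
#' @param at Plane coordinate along `axis`, mm.
#' @param axis Sectioning axis (default 3).
#' @return Signed area, mm^2 (0 when the plane misses the mesh).
#' @export
mesh_section_area <- function(mesh, at, axis = 3) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  other <- setdiff(1:3, axis)
  Vx <- mesh$vertices[, axis]
  f <- mesh$faces
  area2 <- 0
  # per-triangle: find the two edge crossings in winding order
  h <- matrix(Vx[f], ncol = 3) - at
  crossed <- which((apply(h, 1, max) > 0) & (apply(h, 1, min) <= 0))
  for (i in crossed) {
    tri <- f[i, ]
    hh <- h[i, ]
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      ha <- hh[e[1]]
      hb <- hh[e[2]]
      if ((ha > 0) != (hb > 0)) {
        tt <- ha / (ha - hb)
        pa <- mesh$vertices[tri[e[1]], other]
        pb <- mesh$vertices[tri[e[2]], other]
        # entering vs leaving preserves contour orientation
        pt <- pa + tt * (pb - pa)
        pts[[length(pts) + 1L]] <- list(p = pt, from_above = ha > 0)
      }
    }
    if (length(pts) == 2L) {
      # orient segment from the crossing that leaves the upper half-space
      if (pts[[1]]$from_above) {
        p <- pts[[1]]$p
        q <- pts[[2]]$p
      } else {
        p <- pts[[2]]$p
        q <- pts[[1]]$p
      }
      area2 <- area2 + (p[1] * q[2] - q[1] * p[2])
    }
  }
  area2 / 2
}
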