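#' Triangle mesh container
#'
#' @param vertices n x 3 numeric matrix, physical coordinates in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices with
#'   consistent outward winding.
#' @return A `triangle_mesh` object.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    abort("face indices out of range.")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Isosurface extraction by marching cubes over a tetrahedral decomposition
#'
#' Extracts the triangle surface of the level set `field = isolevel` from a
#' 3-D scalar field. Each grid cell is split into six tetrahedra by the
#' translation-invariant Kuhn decomposition along the cell's main diagonal;
#' because neighbouring cells then share identical face diagonals, the
#' extracted surface is watertight by construction wherever the level set
#' does not touch the volume boundary, with no ambiguous configurations to
#' resolve. Within each tetrahedron the surface is the linear-interpolation
#' level set: vertices are placed along cut edges at the interpolated
#' crossing, and each tetrahedron contributes one or two triangles. Vertices
#' on shared edges are welded (computed once per global grid edge), and
#' triangles are oriented with outward normals (pointing from the
#' `> isolevel` side toward the `<= isolevel` side).
#'
#' Binary masks are surfaced as 0/1 fields at `isolevel = 0.5`, optionally
#' after a small box pre-smoothing of the field (off by default, matching
#' binary marching-cubes semantics).
#'
#' @param field A [ct_volume()], [ct_mask()] or 3-D numeric array, at least
#'   2 voxels in each dimension.
#' @param isolevel Iso-value; for masks use the default 0.5.
#' @param spacing,origin Used when `field` is a bare array (mm).
#' @param pre_smooth Integer >= 0: rounds of 3^3 box-filter smoothing applied
#'   to the field before extraction (reduces voxel staircase for binary
#'   input; 0 = off).
#' @return A [triangle_mesh()] in physical (mm) coordinates. Empty (0
#'   triangles) when the isolevel is outside the field's range.
#' @examples
#' f <- array(0, c(3, 3, 3)); f[2, 2, 2] <- 1
#' m <- marching_cubes(f, 0.5)
#' mesh_report(m)$chi # closed bubble: Euler characteristic 2
#' @export
marching_cubes <- function(field, isolevel = 0.5, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0), pre_smooth = 0L) {
  if (inherits(field, "ct_volume")) {
    spacing <- field$spacing
    origin <- field$origin
    field <- field$data
  }
  if (!is.array(field) || length(dim(field)) != 3L) abort("`field` must be a 3-D array.")
  storage.mode(field) <- "double"
  if (any(dim(field) < 2L)) abort("`field` must be at least 2 x 2 x 2.")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  check_scalar(isolevel, "isolevel")
  pre_smooth <- as.integer(pre_smooth)
  for (i in seq_len(pre_smooth)) field <- box_smooth3(field)

  dm <- dim(field)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  empty <- triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  if (isolevel >= max(field) || isolevel < min(field)) {
    if (!(any(field > isolevel) && any(field <= isolevel))) return(empty)
  }

  # cube origins and corner linear indices (corner bit order: x, y, z)
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  off <- cbind(
    x = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
    y = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
    z = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  )
  lin <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  ncube <- length(ci)
  corner_lin <- matrix(0L, ncube, 8L)
  for (c8 in 1:8) corner_lin[, c8] <- lin(ci + off[c8, 1], cj + off[c8, 2], ck + off[c8, 3])

  # Kuhn split: six tets (v0, va, vab, v7) along monotone paths 0 -> 7
  tets <- rbind(
    c(1L, 2L, 4L, 8L), c(1L, 2L, 6L, 8L), c(1L, 3L, 4L, 8L),
    c(1L, 3L, 7L, 8L), c(1L, 5L, 6L, 8L), c(1L, 5L, 7L, 8L)
  )
  TL <- do.call(rbind, lapply(1:6, function(t) corner_lin[, tets[t, ], drop = FALSE]))
  TV <- matrix(field[TL], nrow(TL), 4L)
  inside <- TV > isolevel
  caseid <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] + 8L * inside[, 4]
  keep <- caseid > 0L & caseid < 15L
  if (!any(keep)) return(empty)
  TL <- TL[keep, , drop = FALSE]
  inside <- inside[keep, , drop = FALSE]
  caseid <- caseid[keep]

  EP <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
  ctab <- tet_case_table()

  # per-triangle endpoint node ids (global linear indices) for the 3 edges
  blocks <- vector("list", 28L)
  nb <- 0L
  for (cs in 1:14) {
    idx <- which(caseid == cs)
    if (!length(idx)) next
    trs <- ctab[[cs]]
    for (r in seq_len(nrow(trs))) {
      e3 <- trs[r, ]
      nb <- nb + 1L
      blocks[[nb]] <- list(
        A = cbind(TL[idx, EP[e3[1], 1]], TL[idx, EP[e3[2], 1]], TL[idx, EP[e3[3], 1]]),
        B = cbind(TL[idx, EP[e3[1], 2]], TL[idx, EP[e3[2], 2]], TL[idx, EP[e3[3], 2]]),
        tet = idx
      )
    }
  }
  blocks <- blocks[seq_len(nb)]
  A <- do.call(rbind, lapply(blocks, `[[`, "A"))
  B <- do.call(rbind, lapply(blocks, `[[`, "B"))
  tet_of_tri <- unlist(lapply(blocks, `[[`, "tet"))

  # weld: one vertex per cut global grid edge, interpolated lo -> hi
  lo <- pmin(A, B)
  hi <- pmax(A, B)
  key <- lo + (nx * ny * nz + 1) * hi # unique double key, exact below 2^53
  ukey <- unique(as.vector(key))
  vid <- matrix(match(key, ukey), nrow(lo), 3L)
  first <- match(ukey, as.vector(key))
  lov <- as.vector(lo)[first]
  hiv <- as.vector(hi)[first]
  t01 <- (isolevel - field[lov]) / (field[hiv] - field[lov])
  toijk <- function(l) {
    l0 <- l - 1
    cbind(l0 %% nx, (l0 %/% nx) %% ny, l0 %/% (nx * ny))
  }
  P <- toijk(lov) + t01 * (toijk(hiv) - toijk(lov))
  verts <- sweep(P * rep(spacing, each = nrow(P)), 2, origin, `+`)
  faces <- vid

  good <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  faces <- faces[good, , drop = FALSE]
  tet_of_tri <- tet_of_tri[good]
  if (!nrow(faces)) return(empty)

  # orient outward: normal must point from the inside (> iso) corners of the
  # generating tetrahedron toward its outside corners
  tijk <- array(0, dim = c(nrow(TL), 4L, 3L))
  for (c4 in 1:4) tijk[, c4, ] <- toijk(TL[, c4])
  ins_n <- rowSums(inside)
  cen_in <- matrix(0, nrow(TL), 3L)
  cen_out <- matrix(0, nrow(TL), 3L)
  for (ax in 1:3) {
    cen_in[, ax] <- rowSums(tijk[, , ax] * inside) / ins_n
    cen_out[, ax] <- rowSums(tijk[, , ax] * !inside) / (4 - ins_n)
  }
  dir_out <- (cen_out - cen_in)[tet_of_tri, , drop = FALSE] *
    rep(spacing, each = length(tet_of_tri))
  v1 <- verts[faces[, 1], , drop = FALSE]
  v2 <- verts[faces[, 2], , drop = FALSE]
  v3 <- verts[faces[, 3], , drop = FALSE]
  nvec <- vec_cross(v2 - v1, v3 - v1)
  flip <- rowSums(nvec * dir_out) < 0
  faces[flip, ] <- faces[flip, c(1L, 3L, 2L)]

  triangle_mesh(verts, faces)
}

# triangles (as triples of tet-edge ids) for each of the 14 non-trivial
# sign patterns of a tetrahedron, derived by enumeration at call time
tet_case_table <- function() {
  EP <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
  out <- vector("list", 14L)
  for (cs in 1:14) {
    ins <- c(bitwAnd(cs, 1L) > 0, bitwAnd(cs, 2L) > 0, bitwAnd(cs, 4L) > 0, bitwAnd(cs, 8L) > 0)
    cut <- which(xor(ins[EP[, 1]], ins[EP[, 2]]))
    if (length(cut) == 3L) {
      out[[cs]] <- matrix(cut, 1L, 3L)
    } else {
      # 2-in/2-out: four cut edges form a quad; order so consecutive edges
      # share a tet vertex, then fan into two triangles
      ordq <- cut[1]
      rest <- cut[-1]
      while (length(rest)) {
        last <- ordq[length(ordq)]
        shared <- vapply(rest, function(x) length(intersect(EP[last, ], EP[x, ])) > 0, TRUE)
        nxt <- rest[shared][1]
        ordq <- c(ordq, nxt)
        rest <- setdiff(rest, nxt)
      }
      out[[cs]] <- rbind(ordq[c(1L, 2L, 3L)], ordq[c(1L, 3L, 4L)])
    }
  }
  out
}

vec_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# one round of 3x3x3 box smoothing with edge replication
box_smooth3 <- function(f) {
  d <- dim(f)
  out <- array(0, d)
  cnt <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sx <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    sy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    sz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out + f[sx, sy, sz]
    cnt <- cnt + 1
  }
  out / cnt
}
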