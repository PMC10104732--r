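#' Write a triangle mesh to STL (binary) or PLY (ascii)
#'
#' STL stores per-facet vertex coordinates in 32-bit floats (so a round trip
#' reproduces vertices to single precision and re-welds identical corners);
#' PLY stores the indexed vertex/face lists in full double precision text.
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output file path; format inferred from the extension when
#'   `format` is missing.
#' @param format `"stl"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply")) abort("cannot infer mesh format from extension.")
  }
  if (format == "stl") write_stl_binary(mesh, path) else write_ply_ascii(mesh, path)
  invisible(path)
}

#' Read a triangle mesh written by [write_mesh()]
#'
#' @param path STL (binary) or PLY (ascii) file.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = read_stl_binary(path),
    ply = read_ply_ascii(path),
    abort("unsupported mesh format (use .stl or .ply).")
  )
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "binary STL"))[1:80]
  writeBin(hdr, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  if (nf) {
    v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
    v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
    v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
    n <- vec_cross(v2 - v1, v3 - v1)
    len <- sqrt(rowSums(n^2))
    n <- n / ifelse(len > 0, len, 1)
    block <- t(cbind(n, v1, v2, v3)) # 12 floats per facet
    for (i in seq_len(nf)) {
      writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!nf) return(triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  tri <- matrix(0, nf * 3L, 3L)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "raw", 2))
    tri[(i - 1L) * 3L + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  # re-weld identical corners
  key <- paste(tri[, 1], tri[, 2], tri[, 3])
  ukey <- unique(key)
  ids <- match(key, ukey)
  verts <- tri[match(ukey, key), , drop = FALSE]
  triangle_mesh(verts, matrix(ids, ncol = 3, byrow = TRUE))
}

write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  writeLines(c(
    "ply", "format ascii 1.0", "comment ctffr mesh",
    sprintf("element vertex %d", nv),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  if (nv) {
    writeLines(sprintf("%.17g %.17g %.17g",
      mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  }
  if (nf) {
    writeLines(sprintf("3 %d %d %d",
      mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
}

read_ply_ascii <- function(path) {
  lines <- readLines(path)
  endh <- match("end_header", lines)
  if (is.na(endh)) abort("not an ascii PLY file.")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", lines, value = TRUE)))
  verts <- if (nv) {
    do.call(rbind, lapply(lines[endh + seq_len(nv)], function(l) as.numeric(strsplit(l, " ")[[1]])))
  } else {
    matrix(numeric(0), 0, 3)
  }
  faces <- if (nf) {
    do.call(rbind, lapply(lines[endh + nv + seq_len(nf)], function(l) {
      as.integer(strsplit(l, " ")[[1]][2:4]) + 1L
    }))
  } else {
    matrix(integer(0), 0, 3)
  }
  triangle_mesh(verts, faces)
}
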