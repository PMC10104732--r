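#' Read and write CT volumes (MetaImage and NIfTI)
#'
#' Volumes are exchanged in two standard formats: MetaImage (`.mhd` header +
#' `.raw` data, `MET_DOUBLE` for intensity volumes and `MET_UCHAR` for
#' masks) and NIfTI-1 (via the RNifti reader). Spacing is carried in the
#' header (`ElementSpacing` / `pixdim`), origin in `Offset` / the sform.
#'
#' @param volume A [ct_volume()] or [ct_mask()].
#' @param path Output path: `.mhd` (a sibling `.raw` is written), `.nii` or
#'   `.nii.gz`.
#' @return `path`, invisibly (writers); a [ct_volume()] / [ct_mask()]
#'   (readers).
#' @export
write_ct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "mhd") {
    write_metaimage(volume, path)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(volume$data * 1)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    abort("unsupported volume format (use .mhd, .nii or .nii.gz).")
  }
  invisible(path)
}

#' @rdname write_ct_volume
#' @param mask Logical: read as a [ct_mask()] (foreground = nonzero).
#' @export
read_ct_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  vol <- if (ext == "mhd") {
    read_metaimage(path)
  } else if (ext == "nii") {
    img <- RNifti::readNifti(path)
    ct_volume(array(as.numeric(img), dim = dim(img)), RNifti::pixdim(img), c(0, 0, 0))
  } else {
    abort("unsupported volume format (use .mhd, .nii or .nii.gz).")
  }
  if (mask) ct_mask(vol$data != 0, vol$spacing, vol$origin) else vol
}

write_metaimage <- function(volume, path) {
  rawfile <- sub("\\.mhd$", ".raw", path)
  is_mask <- inherits(volume, "ct_mask")
  d <- dim(volume$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
      volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    sprintf("Offset = %.17g %.17g %.17g",
      volume$origin[1], volume$origin[2], volume$origin[3]),
    sprintf("ElementType = %s", if (is_mask) "MET_UCHAR" else "MET_DOUBLE"),
    sprintf("ElementDataFile = %s", basename(rawfile))
  )
  writeLines(hdr, path)
  con <- file(rawfile, "wb")
  on.exit(close(con))
  if (is_mask) {
    writeBin(as.raw(as.integer(volume$data)), con)
  } else {
    writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  }
}

read_metaimage <- function(path) {
  hdr <- readLines(path)
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*= *", "", ln[1]))
  }
  d <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  off <- get("Offset")
  origin <- if (is.null(off)) c(0, 0, 0) else as.numeric(strsplit(off, " +")[[1]])
  etype <- get("ElementType")
  rawfile <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(d)
  con <- file(rawfile, "rb")
  on.exit(close(con))
  if (etype == "MET_UCHAR") {
    vals <- as.integer(readBin(con, "raw", n))
    ct_mask(array(vals != 0L, dim = d), spacing, origin)
  } else if (etype == "MET_DOUBLE") {
    vals <- readBin(con, "numeric", n, size = 8, endian = "little")
    ct_volume(array(vals, dim = d), spacing, origin)
  } else if (etype == "MET_FLOAT") {
    vals <- readBin(con, "numeric", n, size = 4, endian = "little")
    ct_volume(array(vals, dim = d), spacing, origin)
  } else {
    abort(sprintf("unsupported ElementType: %s", etype))
  }
}
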