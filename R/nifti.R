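# Minimal NIfTI-1 volume I/O. Only what lesion-load extraction needs:
# single-frame 3-D volumes, the common datatypes, scl_slope/scl_inter,
# native endianness detection via sizeof_hdr, plain or gzip files.
# Written in base R because no NIfTI package is available in this stack.

NIFTI_TYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),  # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

#' Read a NIfTI-1 volume
#'
#' Supports `.nii` and `.nii.gz`, 3-D single-frame images, datatypes
#' uint8/int16/uint16/int32/float32/float64, and applies `scl_slope`/
#' `scl_inter` when set.
#'
#' @param path file path.
#' @return numeric array with attributes `pixdim` (voxel sizes) and
#'   `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  if (rawToInt(hdr[1:4], endian) != 348L) {
    endian <- "big"
    if (rawToInt(hdr[1:4], endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic: ", magic)
  dims <- rawToShorts(hdr[41:56], endian)
  ndim <- dims[1]
  if (ndim < 1L || ndim > 7L) stop("bad dim[0] in NIfTI header")
  shape <- pmax(dims[2:(1 + max(ndim, 3L))], 1L)
  datatype <- rawToShorts(hdr[71:72], endian)[1]
  spec <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rawToFloats(hdr[77:108], endian)[2:4]
  scl_slope <- rawToFloats(hdr[113:116], endian)
  scl_inter <- rawToFloats(hdr[117:120], endian)
  vox_offset <- rawToFloats(hdr[109:112], endian)
  # gz connections cannot seek: consume bytes up to the data offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  nvox <- prod(shape)
  img <- readBin(con, spec$what, n = nvox, size = spec$size,
                 signed = spec$signed, endian = endian)
  if (length(img) < nvox) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    img <- img * scl_slope + scl_inter
  out <- array(img, dim = shape)
  attr(out, "pixdim") <- pixdim
  attr(out, "datatype") <- datatype
  out
}

#' Write a NIfTI-1 volume
#'
#' @param img numeric/integer array (up to 3-D).
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param datatype `"int32"` (default, for masks and atlases) or
#'   `"float32"`.
#' @param pixdim voxel sizes in mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, datatype = c("int32", "float32"),
                        pixdim = c(1, 1, 1)) {
  datatype <- match.arg(datatype)
  code <- if (datatype == "int32") 8L else 16L
  shape <- dim(img) %||% length(img)
  if (length(shape) > 3L) stop("only volumes up to 3-D are written")
  shape <- c(shape, rep(1L, 3L - length(shape)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  hdr <- raw(348)
  hdr <- insertInt(hdr, 1L, 348L)                       # sizeof_hdr
  hdr[40] <- as.raw(0)                                  # dim_info
  hdr <- insertShorts(hdr, 41L, c(3L, shape, 1L, 1L, 1L, 1L))
  hdr <- insertShorts(hdr, 71L, code)                   # datatype
  hdr <- insertShorts(hdr, 73L, if (code == 8L) 32L else 32L) # bitpix
  hdr <- insertFloats(hdr, 77L, c(1, pixdim, 1, 1, 1, 1))    # pixdim
  hdr <- insertFloats(hdr, 109L, 352)                   # vox_offset
  hdr <- insertFloats(hdr, 113L, 1)                     # scl_slope
  hdr <- insertFloats(hdr, 117L, 0)                     # scl_inter
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))        # magic
  writeBin(hdr, con)
  writeBin(raw(4), con)                                 # extension flag
  if (code == 8L) {
    writeBin(as.integer(round(img)), con, size = 4L)
  } else {
    writeBin(as.double(img), con, size = 4L)
  }
  invisible(path)
}

rawToInt <- function(r, endian)
  readBin(r, "integer", n = length(r) %/% 4L, size = 4L, endian = endian)
rawToShorts <- function(r, endian)
  readBin(r, "integer", n = length(r) %/% 2L, size = 2L, endian = endian)
rawToFloats <- function(r, endian)
  readBin(r, "double", n = length(r) %/% 4L, size = 4L, endian = endian)
insertInt <- function(hdr, at, x) {
  b <- writeBin(as.integer(x), raw(), size = 4L)
  hdr[at:(at + length(b) - 1L)] <- b
  hdr
}
insertShorts <- function(hdr, at, x) {
  b <- writeBin(as.integer(x), raw(), size = 2L)
  hdr[at:(at + length(b) - 1L)] <- b
  hdr
}
insertFloats <- function(hdr, at, x) {
  b <- writeBin(as.double(x), raw(), size = 4L)
  hdr[at:(at + length(b) - 1L)] <- b
  hdr
}
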