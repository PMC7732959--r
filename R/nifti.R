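# Minimal self-contained NIfTI-1 I/O.
#
# The analysis needs lossless round-tripping of 3D/4D float volumes; no
# NIfTI package is available in the target environment, so the fixed
# 348-byte single-file (.nii / .nii.gz) header is read and written here
# directly. Only the fields this package uses are populated: dimensions,
# datatype, voxel/temporal spacing, a diagonal sform, and scaling slope.

nifti_datatypes <- function() {
  # code, bytes, reader signed-ness
  list(`2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
       `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
       `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
       `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
       `64` = list(what = "double",  size = 8L, signed = TRUE))   # float64
}

open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D/4D array as a NIfTI-1 volume
#'
#' Little-endian single-file NIfTI-1 with a diagonal sform in mm. 4D arrays
#' store the frame spacing in `pixdim[5]` (seconds). `.nii.gz` paths are
#' gzip-compressed transparently.
#'
#' @param x 3D or 4D numeric array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size Voxel size per spatial axis, mm.
#' @param time_step Frame spacing in seconds (4D only; `NA` otherwise).
#' @param datatype `"float32"` (default), `"float64"`, `"int32"`,
#'   `"int16"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size = c(1, 1, 1), time_step = NA,
                        datatype = c("float32", "float64", "int32",
                                     "int16", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(is.array(x), length(dim(x)) %in% c(3L, 4L))
  code <- c(float32 = 16L, float64 = 64L, int32 = 8L, int16 = 4L,
            uint8 = 2L)[[datatype]]
  dt <- nifti_datatypes()[[as.character(code)]]
  d <- dim(x)
  nd <- length(d)
  dim8 <- as.integer(c(nd, d, rep(1L, 7 - nd)))
  pixdim8 <- c(1, voxel_size, if (nd == 4L && is.finite(time_step))
    time_step else 1, 1, 1, 1)
  con <- open_conn(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  wi(348L, 4)                   # sizeof_hdr
  wc("", 10); wc("", 18)        # data_type, db_name
  wi(0L, 4); wi(0L, 2)          # extents, session_error
  wc("r", 1); wc("", 1)         # regular, dim_info
  wi(dim8, 2)                   # dim[8]
  wf(c(0, 0, 0))                # intent_p1..p3
  wi(0L, 2)                     # intent_code
  wi(code, 2)                   # datatype
  wi(dt$size * 8L, 2)           # bitpix
  wi(0L, 2)                     # slice_start
  wf(pixdim8)                   # pixdim[8]
  wf(352)                       # vox_offset
  wf(1); wf(0)                  # scl_slope, scl_inter
  wi(0L, 2); wc("", 1)          # slice_end, slice_code
  writeBin(as.raw(2L + 8L), con)  # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)              # glmax, glmin
  wc("bbbleak", 80); wc("", 24) # descrip, aux_file
  wi(0L, 2); wi(1L, 2)          # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))  # quaternions, qoffsets
  wf(c(voxel_size[1], 0, 0, 0))
  wf(c(0, voxel_size[2], 0, 0))
  wf(c(0, 0, voxel_size[3], 0))
  wc("", 16)                    # intent_name
  wc("n+1", 4)                  # magic
  writeBin(raw(4), con)         # extension flag -> data at offset 352
  if (dt$what == "integer")
    writeBin(as.integer(round(x)), con, size = dt$size, endian = "little")
  else
    writeBin(as.numeric(x), con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the datatypes written by [write_nifti()] plus float64, either
#' endianness, and gzip-compressed files. Scaling (`scl_slope`/`scl_inter`)
#' is applied when present.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return Numeric array with attributes `voxel_size` (mm) and `time_step`
#'   (seconds, 4D only).
#' @export
read_nifti <- function(path) {
  con <- open_conn(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path)
  parse <- function(endian) {
    at <- function(off, n, what, size, signed = TRUE)
      readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
              signed = signed, endian = endian)
    list(sizeof = at(0, 1, "integer", 4),
         dim = at(40, 8, "integer", 2),
         datatype = at(70, 1, "integer", 2),
         pixdim = at(76, 8, "double", 4),
         vox_offset = at(108, 1, "double", 4),
         scl_slope = at(112, 1, "double", 4),
         scl_inter = at(116, 1, "double", 4))
  }
  endian <- "little"
  h <- parse(endian)
  if (h$sizeof != 348L) {
    endian <- "big"
    h <- parse(endian)
    if (h$sizeof != 348L) stop("not a NIfTI-1 file: ", path)
  }
  nd <- h$dim[1]
  if (!nd %in% 1:7) stop("unsupported NIfTI dimensionality: ", nd)
  d <- h$dim[1 + seq_len(nd)]
  dt <- nifti_datatypes()[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", h$datatype)
  skip <- as.integer(round(h$vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(d)
  x <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = endian)
  if (length(x) < n) stop("truncated NIfTI data: ", path)
  x <- as.numeric(x)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    x <- x * h$scl_slope + h$scl_inter
  out <- array(x, dim = d)
  attr(out, "voxel_size") <- h$pixdim[2:4]
  if (nd >= 4L) attr(out, "time_step") <- h$pixdim[5]
  out
}
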