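# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Implemented here because the analysis needs only dense voxel access to
# per-trial statistical maps and a binary ROI mask; no reorientation, no
# extensions. Header layout follows the NIfTI-1 standard (348-byte header).

.nifti_datatypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE))

#' Read a NIfTI-1 image
#'
#' Supports uncompressed `.nii` and gzipped `.nii.gz` single-file images
#' with datatypes uint8, int16, int32, float32 and float64. Scaling
#' (`scl_slope`/`scl_inter`) is applied when set. The affine is taken from
#' the srow fields (sform) when present, otherwise built from pixdim.
#'
#' @param path File path.
#' @return List of class `nifti_image`: `data` (numeric array), `dim`,
#'   `pixdim`, `affine` (4x4), `datatype`.
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, size = 4)
  endian <- "little"
  if (sizeof_hdr != 348L) {
    swapped <- readBin(
      writeBin(as.integer(sizeof_hdr), raw()), "integer", 1, size = 4,
      endian = "big")
    if (swapped == 348L) endian <- "big"
    else stop("read_nifti: not a NIfTI-1 file (sizeof_hdr=", sizeof_hdr, ")",
              call. = FALSE)
  }
  readBin(con, "raw", 36)                      # unused header fields
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "raw", 14)                      # intent params etc.
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)  # bitpix
  readBin(con, "integer", 1, size = 2, endian = endian)  # slice_start
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  readBin(con, "raw", 132)     # slice/cal fields, descrip, aux_file
  qform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "double", 6, size = 4, endian = endian)   # quaternions
  srow <- matrix(readBin(con, "double", 12, size = 4, endian = endian),
                 nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16)                      # intent_name
  magic <- rawToChar(readBin(con, "raw", 4)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop("read_nifti: bad magic '", magic, "'", call. = FALSE)
  nd <- dims[1]
  shape <- dims[2:(1 + max(nd, 1))]
  nvox <- prod(shape)
  spec <- .nifti_datatypes[.nifti_datatypes$code == datatype, ]
  if (nrow(spec) == 0)
    stop("read_nifti: unsupported datatype code ", datatype, call. = FALSE)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, spec$what, nvox, size = spec$size,
                  signed = spec$signed, endian = endian)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1)) else {
    a <- diag(4)
    diag(a)[1:3] <- pixdim[2:4]
    a
  }
  structure(list(data = array(vals, dim = shape), dim = shape,
                 pixdim = pixdim[seq_len(max(nd, 1)) + 1],
                 affine = affine, datatype = datatype,
                 qform_code = qform_code, sform_code = sform_code),
            class = "nifti_image")
}

#' Write a NIfTI-1 image
#'
#' Writes a float32 (default) or float64 single-file `.nii` (gzipped when
#' the path ends in `.gz`), with the affine stored in the sform rows.
#'
#' @param data Numeric array (up to 7 dimensions).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world matrix (default identity).
#' @param datatype "float32" or "float64".
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4),
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  code <- if (datatype == "float32") 16L else 64L
  size <- if (datatype == "float32") 4L else 8L
  data <- as.array(data)
  shape <- dim(data)
  if (length(shape) > 7) stop("write_nifti: too many dimensions",
                              call. = FALSE)
  dims <- integer(8)
  dims[1] <- length(shape)
  dims[seq_along(shape) + 1] <- shape
  dims[dims == 0] <- 1L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)
  writeBin(raw(36), con)
  writeBin(as.integer(dims), con, size = 2)
  writeBin(raw(14), con)
  writeBin(code, con, size = 2)                       # datatype
  writeBin(as.integer(8 * size), con, size = 2)       # bitpix
  writeBin(0L, con, size = 2)                         # slice_start
  writeBin(as.numeric(c(1, rep(1, 7))), con, size = 4)  # pixdim
  writeBin(352, con, size = 4)                        # vox_offset
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  writeBin(raw(132), con)      # slice/cal fields, descrip, aux_file
  writeBin(c(0L, 1L), con, size = 2)                  # qform=0, sform=1
  writeBin(numeric(6), con, size = 4)                 # quaternions
  writeBin(as.numeric(t(affine[1:3, ])), con, size = 4)  # srow_x/y/z
  writeBin(raw(16), con)
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)                               # pad to 352
  writeBin(as.numeric(data), con, size = size)
  invisible(path)
}

#' Extract a pattern store from per-trial NIfTI maps and an ROI mask
#'
#' Reads one statistical map per trial, restricts each to the voxels where
#' the mask exceeds 0.5, and assembles a [pattern_store()]. All maps must
#' share the mask's grid and affine. Voxels that are non-finite in any trial
#' are dropped consistently across trials, with the count logged. Optionally
#' divides each map by a residual-SD map (beta-to-t normalization).
#'
#' @param map_files Character vector of NIfTI paths, one per trial, aligned
#'   with `meta` rows.
#' @param mask Path to a binary ROI mask (NIfTI).
#' @param meta Trial metadata data frame (subject, phase, run, stimulus, ...).
#' @param resid_sd Optional path to a residual-SD map for normalization.
#' @return A [pattern_store()].
#' @export
extract_patterns <- function(map_files, mask, meta, resid_sd = NULL) {
  if (length(map_files) != nrow(meta))
    stop("extract_patterns: one map per metadata row required", call. = FALSE)
  mk <- read_nifti(mask)
  keep <- mk$data > 0.5
  if (!any(keep)) stop("extract_patterns: empty mask", call. = FALSE)
  sdvals <- NULL
  if (!is.null(resid_sd)) {
    sdimg <- read_nifti(resid_sd)
    if (!identical(dim(sdimg$data), dim(mk$data)))
      stop("extract_patterns: residual-SD map grid differs from mask",
           call. = FALSE)
    sdvals <- sdimg$data[keep]
  }
  rows <- lapply(map_files, function(f) {
    img <- read_nifti(f)
    if (!identical(dim(img$data), dim(mk$data)))
      stop("extract_patterns: grid mismatch between ", f, " and mask",
           call. = FALSE)
    if (max(abs(img$affine - mk$affine)) > 1e-4)
      stop("extract_patterns: affine mismatch between ", f, " and mask",
           call. = FALSE)
    v <- img$data[keep]
    if (!is.null(sdvals)) v <- v / sdvals
    v
  })
  pats <- do.call(rbind, rows)
  bad <- apply(pats, 2, function(col) any(!is.finite(col)))
  if (any(bad)) {
    message("extract_patterns: dropping ", sum(bad),
            " voxel(s) non-finite in at least one trial")
    pats <- pats[, !bad, drop = FALSE]
  }
  pattern_store(pats, meta)
}
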