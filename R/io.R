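## Readers and writers: NIfTI volumes (RNifti), FSL-style bval/bvec text
## files, MRtrix TCK streamline files, and tidy CSV tables. World
## coordinates are mm with the voxel-center convention; the NIfTI affine
## is diagonal (voxelSize) with a half-voxel offset so that NIfTI world
## coordinates match the package's.

#' Write / read a volume as NIfTI
#'
#' @param vol numeric or logical array (3D or 4D).
#' @param path output .nii or .nii.gz path.
#' @param voxelSize isotropic voxel edge (mm).
#' @return `path` (write) or a list `data`, `voxelSize` (read).
#' @export
writeVolume <- function(vol, path, voxelSize) {
  img <- RNifti::asNifti(vol * 1)
  nd <- length(dim(vol))
  RNifti::pixdim(img) <- c(rep(voxelSize, 3), rep(1, max(0L, nd - 3L)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  list(data = array(as.numeric(img), dim(img)), voxelSize = vs)
}

#' Write / read FSL-style bval and bvec files
#'
#' `bvals` as one whitespace-separated row; `bvecs` as three rows
#' (x, y, z components).
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param bvalPath,bvecPath file paths.
#' @param gridDim,voxelSize grid geometry to attach on read.
#' @return invisible paths (write) / an AcquisitionScheme (read).
#' @export
writeBvalBvec <- function(scheme, bvalPath, bvecPath) {
  writeLines(paste(format(scheme@bvals, trim = TRUE), collapse = " "),
             bvalPath)
  writeLines(apply(scheme@bvecs, 1, function(r)
    paste(format(r, digits = 10, trim = TRUE), collapse = " ")),
    bvecPath)
  invisible(c(bvalPath, bvecPath))
}

#' @rdname writeBvalBvec
#' @export
readBvalBvec <- function(bvalPath, bvecPath, gridDim, voxelSize = 2.55) {
  bv <- scan(bvalPath, quiet = TRUE)
  rows <- readLines(bvecPath)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3L)
    stop("malformed bvec file: expected 3 rows, got ", length(rows))
  g <- do.call(rbind, lapply(rows, function(r)
    scan(text = r, quiet = TRUE)))
  if (ncol(g) != length(bv))
    stop("bval/bvec mismatch: ", length(bv), " b-values vs ", ncol(g),
         " directions")
  new("AcquisitionScheme", bvals = bv, bvecs = g,
      voxelSize = voxelSize, gridDim = as.integer(gridDim))
}

#' Write / read streamlines in MRtrix TCK format
#'
#' Binary TCK (Float32LE triplets, NaN-separated tracks, Inf terminator)
#' with coordinates in mm scanner space.
#'
#' @param sset a [StreamlineSet-class] (write) or a list of matrices.
#' @param path .tck file path.
#' @param voxelSize,gridDim geometry attached to the read result.
#' @return invisible path (write) / a [StreamlineSet-class] (read).
#' @export
writeTck <- function(sset, path) {
  lines <- if (is(sset, "StreamlineSet")) sset@streamlines else sset
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", length(lines)))
  ## fixed-width offset field, patched after writing the header
  hdrTxt <- paste0(paste(hdr, collapse = "\n"), "\nfile: . ")
  offset <- nchar(hdrTxt, type = "bytes") + 20L
  hdrTxt <- paste0(hdrTxt, sprintf("%-10d", offset), "\nEND\n")
  writeChar(hdrTxt, con, eos = NULL)
  pad <- offset - nchar(hdrTxt, type = "bytes")
  if (pad > 0) writeBin(raw(pad), con)
  for (m in lines) {
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4L,
             endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4L,
           endian = "little")
  invisible(path)
}

#' @rdname writeTck
#' @export
readTck <- function(path, voxelSize = 1, gridDim = c(1L, 1L, 1L)) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^mrtrix tracks", magic)) stop("not a TCK file: ", path)
  offset <- NA_integer_
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || ln == "END") break
    if (grepl("^file:", ln))
      offset <- as.integer(sub("^file:\\s*\\.\\s*", "", ln))
    if (grepl("^datatype:", ln) && !grepl("Float32LE", ln))
      stop("unsupported TCK datatype")
  }
  if (is.na(offset)) stop("TCK header lacks a file offset")
  seek(con, where = offset, origin = "start")
  vals <- readBin(con, what = "numeric", size = 4L, endian = "little",
                  n = file.info(path)$size)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  isNaN3 <- rowSums(is.na(m)) > 0
  isInf3 <- rowSums(is.infinite(m)) > 0
  stop_at <- which(isInf3)[1]
  if (!is.na(stop_at)) m <- m[seq_len(stop_at - 1L), , drop = FALSE]
  brk <- which(rowSums(is.na(m)) > 0)
  starts <- c(1L, head(brk, -1) + 1L)
  ends <- brk - 1L
  if (!length(brk)) { starts <- 1L; ends <- nrow(m) }
  lines <- Map(function(s, e) m[seq.int(s, e), , drop = FALSE],
               starts, ends)
  lines <- lines[vapply(lines, nrow, 0L) > 0L]
  lens <- vapply(lines, function(x)
    sum(sqrt(rowSums(diff(x)^2))), numeric(1))
  new("StreamlineSet", streamlines = lines, voxelSize = voxelSize,
      dim = as.integer(gridDim), info = data.frame(length = lens),
      metadata = list(source = path))
}

#' Write a ground-truth record for a synthetic subject
#'
#' Structured YAML capture of the injected effect and demographics, so
#' every downstream recovery can be checked without re-deriving truth
#' from images.
#'
#' @param pair a [SubjectPair-class].
#' @param path output .yaml path.
#' @return invisible path.
#' @export
writeTruth <- function(pair, path) {
  yaml::write_yaml(list(subjectId = pair@subjectId, age = pair@age,
                        sex = pair@sex, truth = pair@truth,
                        speechIncrease = pair@speechIncrease), path,
                   precision = 12L)
  invisible(path)
}
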