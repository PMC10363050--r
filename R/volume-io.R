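# Volume readers/writers. NIfTI goes through RNifti; MetaImage (.mha/.mhd)
# is a simple keyword header + raw block, read/written directly here
# (uncompressed, axis-aligned LPS only).

#' Read a CT volume
#'
#' Supports NIfTI (.nii, .nii.gz) and MetaImage (.mha, or .mhd with a
#' sidecar .raw). Spacing and origin are taken from the header; a missing
#' spacing is an error, never silently defaulted.
#'
#' @param path file path.
#' @return A [CTVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    vox <- unclass(as.array(img))
    if (length(dim(vox)) != 3L) stop("expected a 3D volume, got ",
                                     length(dim(vox)), " dimensions")
    if (any(dim(vox) < 1L)) stop("volume has a zero-sized axis")
    sp <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop("volume header carries no usable voxel spacing")
    hdr <- RNifti::niftiHeader(img)
    # NIfTI stores RAS offsets; we keep LPS, so flip x and y
    org <- c(-hdr$qoffset_x, -hdr$qoffset_y, hdr$qoffset_z)
    ctVolume(vox, spacing = sp, origin = org)
  } else if (grepl("\\.(mha|mhd)$", lower)) {
    readMetaImage(path)
  } else {
    stop("unsupported volume format: '", sub("^.*\\.", ".", path),
         "' (expected .nii, .nii.gz, .mha or .mhd)")
  }
}

#' Write a CT volume
#'
#' Format chosen by extension: .nii/.nii.gz (NIfTI) or .mha/.mhd (MetaImage,
#' uncompressed; .mhd writes a sidecar .raw).
#'
#' @param volume a [CTVolume-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(volume@voxels)
    img <- RNifti::`pixdim<-`(img, volume@spacing)
    hdr <- list(qoffset_x = -volume@origin[1], qoffset_y = -volume@origin[2],
                qoffset_z = volume@origin[3], qform_code = 1L)
    img <- RNifti::updateNifti(img, hdr)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(mha|mhd)$", lower)) {
    writeMetaImage(volume, path)
  } else {
    stop("unsupported volume format: '", sub("^.*\\.", ".", path), "'")
  }
  invisible(path)
}

readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("MetaImage header ended before ElementDataFile")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L) stop("expected 3D MetaImage, DimSize = ", hdr$DimSize)
  if (any(dims < 1L)) stop("volume has a zero-sized axis")
  if (is.null(hdr$ElementSpacing))
    stop("MetaImage header carries no ElementSpacing; refusing to default")
  sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  org <- if (!is.null(hdr$Offset)) {
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
  } else if (!is.null(hdr$Position)) {
    as.numeric(strsplit(hdr$Position, "\\s+")[[1]])
  } else c(0, 0, 0)
  type <- hdr$ElementType
  if (is.null(type)) stop("MetaImage header carries no ElementType")
  n <- prod(dims)
  readBlock <- function(con) {
    switch(type,
      "MET_DOUBLE" = readBin(con, "double", n, size = 8, endian = "little"),
      "MET_FLOAT" = readBin(con, "double", n, size = 4, endian = "little"),
      "MET_SHORT" = readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
      "MET_USHORT" = readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"),
      "MET_INT" = readBin(con, "integer", n, size = 4, endian = "little"),
      "MET_UCHAR" = readBin(con, "integer", n, size = 1, signed = FALSE, endian = "little"),
      stop("unsupported MetaImage ElementType: ", type))
  }
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readBlock(con)
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawPath)) stop("MetaImage data file missing: ", rawPath)
    con2 <- file(rawPath, "rb")
    on.exit(close(con2), add = TRUE)
    vals <- readBlock(con2)
  }
  if (length(vals) != n) stop("MetaImage data truncated")
  ctVolume(array(as.numeric(vals), dim = dims), spacing = sp, origin = org)
}

writeMetaImage <- function(volume, path) {
  dims <- dim(volume@voxels)
  local <- grepl("\\.mha$", tolower(path))
  dataFile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("ElementSpacing = %.12g %.12g %.12g", volume@spacing[1],
            volume@spacing[2], volume@spacing[3]),
    sprintf("Offset = %.12g %.12g %.12g", volume@origin[1], volume@origin[2],
            volume@origin[3]),
    "ElementType = MET_DOUBLE",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste0("ElementDataFile = ", dataFile)
  )
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (local) {
    writeBin(as.numeric(volume@voxels), con, size = 8, endian = "little")
    close(con)
  } else {
    close(con)
    con2 <- file(file.path(dirname(path), dataFile), "wb")
    writeBin(as.numeric(volume@voxels), con2, size = 8, endian = "little")
    close(con2)
  }
  invisible(path)
}
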