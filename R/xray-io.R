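# Fluoroscopy frame persistence: 16-bit grayscale PNG plus a JSON sidecar
# carrying pixel spacing, intensity scaling, view, centre and any simulation
# ground truth. The PNG encoder is written here because the installed png
# package reads but does not write 16-bit depth; reading uses png::readPNG.

u32raw <- function(x) {
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
}

pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32raw(length(data)), body, u32raw(.crc32Cpp(body)))
}

writePNG16 <- function(ints, path) {
  # ints: integer matrix (u by v) in 0..65535; PNG scanlines are rows of the
  # displayed image, i.e. fixed v, increasing u
  nu <- nrow(ints); nv <- ncol(ints)
  stopifnot(all(ints >= 0L), all(ints <= 65535L))
  ihdr <- c(writeBin(as.integer(nu), raw(), size = 4, endian = "big"),
            writeBin(as.integer(nv), raw(), size = 4, endian = "big"),
            as.raw(c(16, 0, 0, 0, 0)))  # bit depth 16, grayscale, no interlace
  hi <- as.raw(ints %/% 256L)
  lo <- as.raw(ints %% 256L)
  scan <- raw(nv * (1 + 2 * nu))
  rowLen <- 1 + 2 * nu
  for (v in seq_len(nv)) {
    off <- (v - 1) * rowLen
    scan[off + 1] <- as.raw(0)  # filter type none
    idx <- ((v - 1) * nu + 1):(v * nu)
    scan[off + 1 + seq(1, 2 * nu, by = 2)] <- hi[idx]
    scan[off + 1 + seq(2, 2 * nu, by = 2)] <- lo[idx]
  }
  idat <- memCompress(scan, type = "gzip")
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           pngChunk("IHDR", ihdr), pngChunk("IDAT", idat),
           pngChunk("IEND", raw(0)))
  writeBin(out, path)
}

#' Write an X-ray frame as 16-bit PNG with JSON sidecar
#'
#' Pixel values are linearly mapped to the 16-bit range; the mapping and the
#' geometry metadata go into `<path>.json` so the frame round-trips.
#'
#' @param image an [XRayImage-class].
#' @param path output PNG path.
#' @param extra optional named list merged into the sidecar (e.g. simulation
#'   ground truth: true pose, marker points, landmarks).
#' @return `path`, invisibly.
#' @export
writeXRay <- function(image, path, extra = NULL) {
  px <- image@pixels
  lo <- min(px); hi <- max(px)
  scale <- if (hi > lo) 65535 / (hi - lo) else 0
  ints <- matrix(as.integer(round((px - lo) * scale)), nrow(px), ncol(px))
  writePNG16(ints, path)
  side <- list(pixel_spacing_mm = image@pixelSpacing,
               center_px = image@center, view_label = image@viewLabel,
               subtraction_applied = image@subtractionApplied,
               intensity_min = lo, intensity_max = hi)
  if (!is.null(extra)) side <- c(side, extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an X-ray frame written by [writeXRay()]
#'
#' @param path PNG path; `<path>.json` must exist (pixel spacing is never
#'   silently defaulted).
#' @return An [XRayImage-class].
#' @export
readXRay <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidePath <- paste0(path, ".json")
  if (!file.exists(sidePath))
    stop("missing sidecar ", sidePath, "; pixel spacing unknown")
  side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
  if (is.null(side$pixel_spacing_mm))
    stop("sidecar carries no pixel_spacing_mm")
  arr <- png::readPNG(path)
  # readPNG returns [row, col] with rows = our v scanlines
  px <- t(arr)
  lo <- side$intensity_min %||% 0
  hi <- side$intensity_max %||% 1
  px <- px * (hi - lo) + lo
  xrayImage(px, pixelSpacing = side$pixel_spacing_mm,
            center = side$center_px %||% NULL,
            viewLabel = side$view_label %||% "custom",
            subtractionApplied = isTRUE(side$subtraction_applied))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
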