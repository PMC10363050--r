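# Coordinate conventions (stated once, validated in tests):
#  * world coordinates are mm in patient LPS (x left, y posterior, z superior)
#  * the isocenter is the world origin
#  * primary angle rotates the source-detector axis about the patient z axis,
#    LAO positive / RAO negative; secondary angle tilts it cranially (positive)
#  * detector u axis is lateral, v increases caudally
#  * all rotations are degrees, order Rz * Ry * Rx about the structure centroid

crossProduct <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotationMatrix <- function(rotationDeg) {
  r <- rotationDeg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Source, detector centre and detector axes of a C-arm pose
#'
#' @param geom a [CArmGeometry-class].
#' @return List with `source`, `detectorCenter` (world mm), unit vectors
#'   `uhat`, `vhat` (detector axes) and `dhat` (ray axis).
#' @export
detectorBasis <- function(geom) {
  phi <- geom@primaryAngle * pi / 180
  th <- geom@secondaryAngle * pi / 180
  dhat0 <- c(-sin(phi), cos(phi), 0)
  uhat <- crossProduct(dhat0, c(0, 0, 1))
  uhat <- uhat / sqrt(sum(uhat^2))
  # cranial tilt: rotate the ray axis about the u axis (Rodrigues)
  dhat <- dhat0 * cos(th) + crossProduct(uhat, dhat0) * sin(th)
  vhat <- crossProduct(dhat, uhat)
  list(source = -geom@sid * dhat,
       detectorCenter = (geom@sdd - geom@sid) * dhat,
       uhat = uhat, vhat = vhat, dhat = dhat)
}

#' Apply an affine pose to 3D points
#'
#' Computes \code{center + scale * R (p - center) + T} with
#' \code{R = Rz Ry Rx} in degrees.
#'
#' @param params an [AffineParams-class].
#' @param points numeric length-3 vector or n x 3 matrix of world mm points.
#' @param center rotation/scaling centre, world mm (default the origin).
#' @return Transformed points, same shape as the input.
#' @export
applyAffine <- function(params, points, center = c(0, 0, 0)) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  R <- rotationMatrix(params@rotation)
  q <- sweep(p, 2, center) %*% t(R) * params@scale
  q <- sweep(q, 2, center + params@translation, FUN = "+")
  if (vec) drop(q) else q
}

#' Invert an affine pose
#'
#' Returns parameters that undo `params` about the same centre.
#' @param params an [AffineParams-class].
#' @param center rotation centre used with `params`.
#' @return An [AffineParams-class]; note the inverse of an Rz Ry Rx rotation
#'   is returned as an equivalent rotation matrix re-decomposed into
#'   Rz Ry Rx angles.
#' @export
invertAffine <- function(params, center = c(0, 0, 0)) {
  R <- rotationMatrix(params@rotation)
  Ri <- t(R)
  # decompose Ri = Rz Ry Rx
  ry <- asin(-Ri[3, 1])
  rx <- atan2(Ri[3, 2], Ri[3, 3])
  rz <- atan2(Ri[2, 1], Ri[1, 1])
  s <- 1 / params@scale
  tr <- as.numeric(-s * Ri %*% params@translation)
  affineParams(translation = tr, rotation = c(rx, ry, rz) * 180 / pi, scale = s)
}

#' Project a 3D point onto the detector
#'
#' Central (cone-beam) projection from the source through the point onto the
#' detector plane. For an AP view and a point at isocenter depth offset d
#' laterally, u = d * SDD / SID.
#'
#' @param points length-3 vector or n x 3 matrix of world mm points.
#' @param geom a [CArmGeometry-class].
#' @return Detector mm coordinates, length-2 vector or n x 2 matrix (u, v).
#' @export
projectPoint <- function(points, geom) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  b <- detectorBasis(geom)
  rel <- sweep(p, 2, b$source)
  depth <- as.numeric(rel %*% b$dhat)
  if (any(depth <= 1e-9)) {
    stop("point at or behind the X-ray source cannot be projected")
  }
  t <- geom@sdd / depth
  foot <- sweep(rel * t, 2, b$source, FUN = "+")
  relc <- sweep(foot, 2, b$detectorCenter)
  out <- cbind(u = as.numeric(relc %*% b$uhat), v = as.numeric(relc %*% b$vhat))
  if (vec) drop(out) else out
}

#' Convert detector mm coordinates to pixel indices of an image
#' @param uv length-2 vector or n x 2 matrix of detector mm coordinates.
#' @param image an [XRayImage-class] fixing grid and centre.
#' @return Pixel indices (1-based, fractional), same shape.
#' @export
detectorToPixel <- function(uv, image) {
  vec <- is.null(dim(uv))
  m <- if (vec) matrix(uv, 1, 2) else as.matrix(uv)
  out <- cbind(m[, 1] / image@pixelSpacing + image@center[1],
               m[, 2] / image@pixelSpacing + image@center[2])
  colnames(out) <- c("ui", "vi")
  if (vec) drop(out) else out
}

#' Convert pixel indices to detector mm coordinates
#' @param px length-2 vector or n x 2 matrix of 1-based pixel indices.
#' @param image an [XRayImage-class].
#' @return Detector mm coordinates, same shape.
#' @export
pixelToDetector <- function(px, image) {
  vec <- is.null(dim(px))
  m <- if (vec) matrix(px, 1, 2) else as.matrix(px)
  out <- cbind((m[, 1] - image@center[1]) * image@pixelSpacing,
               (m[, 2] - image@center[2]) * image@pixelSpacing)
  colnames(out) <- c("u", "v")
  if (vec) drop(out) else out
}

# --- pose and geometry persistence ------------------------------------------

#' Write a pose to JSON
#'
#' The schema carries explicit units (mm / deg) to prevent silent unit drift.
#' @param params an [AffineParams-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePose <- function(params, path) {
  obj <- list(Tx = params@translation[1], Ty = params@translation[2],
              Tz = params@translation[3], Rx = params@rotation[1],
              Ry = params@rotation[2], Rz = params@rotation[3],
              scale = params@scale,
              units = list(translation = "mm", rotation = "deg"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pose from JSON
#'
#' Rejects files missing the units block or using units other than mm/deg.
#' @param path JSON file written by [writePose()].
#' @return An [AffineParams-class].
#' @export
readPose <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz", "scale")
  if (!all(need %in% names(obj)))
    stop("pose file missing fields: ", paste(setdiff(need, names(obj)), collapse = ", "))
  if (is.null(obj$units))
    stop("pose file has no units block; refusing to guess units")
  if (!identical(obj$units$translation, "mm") ||
      !identical(obj$units$rotation, "deg")) {
    stop("pose units must be translation 'mm' and rotation 'deg', got: ",
         obj$units$translation, "/", obj$units$rotation)
  }
  affineParams(translation = c(obj$Tx, obj$Ty, obj$Tz),
               rotation = c(obj$Rx, obj$Ry, obj$Rz), scale = obj$scale)
}

#' Write C-arm geometry to JSON
#' @param geom a [CArmGeometry-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeometry <- function(geom, path) {
  obj <- list(source_to_isocenter_mm = geom@sid, source_to_detector_mm = geom@sdd,
              primary_angle_deg = geom@primaryAngle,
              secondary_angle_deg = geom@secondaryAngle)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read C-arm geometry from JSON
#' @param path JSON file written by [writeGeometry()].
#' @return A [CArmGeometry-class].
#' @export
readGeometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("source_to_isocenter_mm", "source_to_detector_mm")
  if (!all(need %in% names(obj)))
    stop("geometry file missing fields: ", paste(setdiff(need, names(obj)), collapse = ", "))
  cArmGeometry(sid = obj$source_to_isocenter_mm, sdd = obj$source_to_detector_mm,
               primaryAngle = if (is.null(obj$primary_angle_deg)) 0 else obj$primary_angle_deg,
               secondaryAngle = if (is.null(obj$secondary_angle_deg)) 0 else obj$secondary_angle_deg)
}
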