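# DRR rendering: line integrals (trapezoid rule, trilinear sampling) of
# clamped HU or of a binary mask indicator along source-to-pixel rays of the
# cone-beam geometry, with the volume under an affine pose.

#' Render a digital X-ray projection (DRR)
#'
#' @param volume a [CTVolume-class] (HU, or a 0/1 mask for
#'   `intensityMode = "binary_mask"`).
#' @param geom a [CArmGeometry-class].
#' @param pose an [AffineParams-class] applied to the volume about `center`.
#' @param config a [ProjectionConfig-class].
#' @param template an [XRayImage-class] fixing the pixel grid and spacing.
#' @param center rotation/scaling centre of the pose, world mm; default the
#'   geometric centre of the volume.
#' @param roi optional 1-based inclusive pixel ROI `c(u0, u1, v0, v1)`; only
#'   those pixels are rendered and returned.
#' @return An [XRayImage-class] on the template grid (or ROI sub-grid, with
#'   the centre index shifted accordingly).
#' @export
renderDRR <- function(volume, geom, pose = identityPose(),
                      config = projectionConfig(), template,
                      center = NULL, roi = NULL) {
  if (config@rayStep <= 0) stop("ray_step must be > 0")
  if (is.null(center)) center <- volumeCenter(volume)
  b <- detectorBasis(geom)
  d <- dim(template@pixels)
  if (is.null(roi)) roi <- c(1L, d[1], 1L, d[2])
  roi <- as.integer(roi)
  if (roi[1] > roi[2] || roi[3] > roi[4]) stop("empty ROI")
  mode <- if (config@intensityMode == "binary_mask") 1L else 0L
  m <- .renderDRRcpp(volume@voxels, volume@spacing, volume@origin,
                     b$source, b$detectorCenter, b$uhat, b$vhat,
                     template@center[1], template@center[2],
                     template@pixelSpacing, roi[1], roi[2], roi[3], roi[4],
                     pose@translation, pose@rotation, pose@scale,
                     as.numeric(center), config@rayStep, mode, config@huFloor)
  xrayImage(m, pixelSpacing = template@pixelSpacing,
            center = template@center - c(roi[1] - 1L, roi[3] - 1L),
            viewLabel = template@viewLabel)
}

#' Geometric centre of a volume in world mm
#' @param volume a [CTVolume-class].
#' @return Length-3 numeric.
#' @export
volumeCenter <- function(volume) {
  volume@origin + (dim(volume@voxels) - 1) * volume@spacing / 2
}

#' Project a binary mask to a silhouette
#'
#' The silhouette is the thresholded binary-mask DRR (> 0); the boundary is
#' the set of silhouette pixels with a non-silhouette 4-neighbour (image
#' border counts as outside).
#'
#' @param mask a [CTVolume-class] holding a 0/1 mask.
#' @param geom a [CArmGeometry-class].
#' @param pose an [AffineParams-class].
#' @param template an [XRayImage-class] grid.
#' @param center pose centre (world mm); default mask centroid.
#' @param rayStep sampling step, mm.
#' @return List with `silhouette` (logical matrix) and `boundary` (n x 2
#'   matrix of pixel indices, possibly empty).
#' @export
projectSilhouette <- function(mask, geom, pose = identityPose(), template,
                              center = NULL, rayStep = 1) {
  if (is.null(center)) center <- maskCentroid(mask)
  cfg <- projectionConfig(rayStep = rayStep, intensityMode = "binary_mask")
  drr <- renderDRR(mask, geom, pose, cfg, template, center = center)
  sil <- drr@pixels > 1e-6
  list(silhouette = sil, boundary = silhouetteBoundary(sil))
}

maskCentroid <- function(mask) {
  idx <- which(mask@voxels > 0.5, arr.ind = TRUE)
  if (!nrow(idx)) return(volumeCenter(mask))
  mask@origin + (colMeans(idx) - 1) * mask@spacing
}

silhouetteBoundary <- function(sil) {
  if (!any(sil)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("ui", "vi"))))
  nu <- nrow(sil); nv <- ncol(sil)
  pad <- matrix(FALSE, nu + 2, nv + 2)
  pad[2:(nu + 1), 2:(nv + 1)] <- sil
  inner <- pad[1:nu, 2:(nv + 1)] & pad[3:(nu + 2), 2:(nv + 1)] &
    pad[2:(nu + 1), 1:nv] & pad[2:(nu + 1), 3:(nv + 2)]
  b <- which(sil & !inner, arr.ind = TRUE)
  colnames(b) <- c("ui", "vi")
  b
}
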