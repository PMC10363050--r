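# Alignment measurement: the caliper protocol. Pigtail markers at known
# 10 mm spacing calibrate a mm-per-pixel scale; bone alignment Db is the
# per-side offset between corresponding lateral vertebral edges (averaged
# left/right per vertebra); vascular alignment Dv is the offset at the
# distal edge of the lowest renal artery orifice.

#' Calibrate a mm-per-pixel scale from pigtail markers
#'
#' With two markers the scale is `knownSpacing` over their pixel distance;
#' with three or more, a least-squares fit of cumulative pixel distance
#' against marker index is used.
#'
#' @param markerPointsPx ordered k x 2 matrix of marker pixel positions.
#' @param knownSpacing true marker spacing in mm (default 10).
#' @return Scale in mm per pixel.
#' @export
calibrateScale <- function(markerPointsPx, knownSpacing = 10) {
  m <- as.matrix(markerPointsPx)
  if (nrow(m) < 2) stop("calibration needs at least two marker points")
  d <- sqrt(rowSums(diff(m)^2))
  if (any(d < 1e-9)) stop("coincident marker points; cannot calibrate")
  if (nrow(m) == 2) return(knownSpacing / d)
  cum <- c(0, cumsum(d))
  idx <- seq_along(cum) - 1
  slope <- sum((idx - mean(idx)) * (cum - mean(cum))) / sum((idx - mean(idx))^2)
  knownSpacing / slope
}

#' Bone alignment (Db) from corresponding lateral edge points
#'
#' Per-side offset is the Euclidean pixel distance between the projected CT
#' edge point and the matching fluoroscopy edge point, times the calibrated
#' scale; the per-vertebra value is the left/right average. The measurement
#' is in-plane (one image). A missing side yields a partial result with a
#' warning, never a silent one-sided average.
#'
#' @param ctEdgePts named list per vertebra with `left`/`right` pixel points
#'   from the projected CT.
#' @param fluoroEdgePts matching structure with fluoroscopy pixel points.
#' @param scale mm per pixel from [calibrateScale()].
#' @param phase measurement phase label.
#' @return An [AlignmentMeasurement-class] (bone part; vascular is NA).
#' @export
boneAlignment <- function(ctEdgePts, fluoroEdgePts, scale, phase = "local") {
  labels <- names(ctEdgePts)
  rows <- lapply(labels, function(lb) {
    ct <- ctEdgePts[[lb]]
    fl <- fluoroEdgePts[[lb]]
    off <- c(left = NA_real_, right = NA_real_)
    for (side in c("left", "right")) {
      if (!is.null(ct[[side]]) && !is.null(fl[[side]])) {
        off[side] <- sqrt(sum((ct[[side]] - fl[[side]])^2)) * scale
      }
    }
    if (any(is.na(off))) {
      warning("vertebra ", lb, ": missing ", paste(names(off)[is.na(off)],
              collapse = "/"), " side; partial bone measurement")
    }
    data.frame(vertebra = lb, left = off["left"], right = off["right"],
               average = if (any(is.na(off))) NA_real_ else mean(off),
               row.names = NULL)
  })
  bone <- do.call(rbind, rows)
  if (is.null(bone)) bone <- data.frame(vertebra = character(0), left = numeric(0),
                                        right = numeric(0), average = numeric(0))
  new("AlignmentMeasurement", bone = bone, vascular = NA_real_,
      calibration = scale, phase = phase)
}

#' Project the vascular anatomy under a pose
#'
#' Transforms every centreline and orifice point by the pose and projects it
#' through the C-arm geometry. The lowest renal orifice is expanded into a
#' ring of `orificeRadius` around its point (in the plane orthogonal to the
#' lateral branch direction); the distal edge is the most caudal projected
#' ring point.
#'
#' @param vessels a [VesselTree-class].
#' @param pose an [AffineParams-class].
#' @param geom a [CArmGeometry-class].
#' @param center pose centre in world mm (use the same centre as the CT
#'   volume pose so bone and vessels move together).
#' @return List with `centerline` (n x 2 detector mm), `orifices` (m x 2),
#'   `orificeRing` (k x 2) and `orificeDistalEdge` (length-2 detector mm).
#' @export
projectVessels <- function(vessels, pose = identityPose(), geom,
                           center = c(0, 0, 0)) {
  cl <- projectPoint(applyAffine(pose, vessels@centerline, center), geom)
  orf <- projectPoint(applyAffine(pose, vessels@renalOrifices, center), geom)
  if (is.null(dim(orf))) orf <- matrix(orf, 1, 2)
  low <- vessels@renalOrifices[vessels@lowestRenalIndex, ]
  theta <- seq(0, 2 * pi, length.out = 25)[-25]
  ring3 <- cbind(low[1], low[2] + vessels@orificeRadius * cos(theta),
                 low[3] + vessels@orificeRadius * sin(theta))
  ring <- projectPoint(applyAffine(pose, ring3, center), geom)
  distal <- ring[which.max(ring[, 2]), ]  # v increases caudally
  list(centerline = cl, orifices = orf, orificeRing = ring,
       orificeDistalEdge = as.numeric(distal))
}

#' Vascular alignment (Dv)
#'
#' Euclidean pixel distance between the projected CT orifice distal edge and
#' the DSA orifice distal edge, times the calibrated scale.
#'
#' @param projectedOrificePx projected CT orifice point, pixels.
#' @param dsaOrificePx DSA orifice point, pixels (same grid).
#' @param scale mm per pixel.
#' @return Dv in mm (>= 0).
#' @export
vascularAlignment <- function(projectedOrificePx, dsaOrificePx, scale) {
  sqrt(sum((projectedOrificePx - dsaOrificePx)^2)) * scale
}

#' Measure bone and vascular alignment on a simulated case
#'
#' Applies the full caliper protocol to a [SimulatedCase-class] at a given
#' (e.g. recovered) pose: pigtail calibration, per-vertebra left/right bone
#' offsets against the ground-truth fluoroscopy edge positions, and Dv at
#' the lowest renal orifice distal edge against the (displaced) DSA
#' position.
#'
#' @param case a [SimulatedCase-class].
#' @param pose the pose to evaluate (e.g. a registration estimate).
#' @param phase phase label stored in the result.
#' @return An [AlignmentMeasurement-class].
#' @export
measureCase <- function(case, pose, phase = "local") {
  scale <- calibrateScale(case@markerPointsPx)
  pc <- volumeCenter(case@volume)
  geom <- case@geometry
  fl <- case@fluoro
  ctPts <- list(); flPts <- list()
  for (lb in names(case@landmarks)) {
    lm <- case@landmarks[[lb]]
    ctPts[[lb]] <- list(
      left = detectorToPixel(projectPoint(applyAffine(pose, lm$left, pc), geom), fl),
      right = detectorToPixel(projectPoint(applyAffine(pose, lm$right, pc), geom), fl))
    flPts[[lb]] <- list(
      left = detectorToPixel(projectPoint(applyAffine(case@truePose, lm$left, pc), geom), fl),
      right = detectorToPixel(projectPoint(applyAffine(case@truePose, lm$right, pc), geom), fl))
  }
  meas <- boneAlignment(ctPts, flPts, scale, phase = phase)
  proj <- projectVessels(case@vessels, pose, geom, center = pc)
  projPx <- detectorToPixel(proj$orificeDistalEdge, fl)
  meas@vascular <- vascularAlignment(projPx, case@dsaOrificePx, scale)
  meas
}
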