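#' @import methods
#' @importFrom stats cor median quantile rnorm runif sd pnorm setNames
#' @importFrom utils read.csv write.csv head combn
#' @importFrom Rcpp evalCpp
#' @useDynLib autofuse, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# CTVolume: HU voxel grid in patient (LPS) world coordinates, mm.
# World position of voxel (i,j,k) (0-based) = origin + index * spacing.
# ---------------------------------------------------------------------------

#' CT volume in patient coordinates
#'
#' An HU-valued voxel grid with millimetre spacing and origin in patient
#' LPS coordinates (x = left, y = posterior, z = superior). The world
#' position of 0-based voxel index \eqn{(i,j,k)} is
#' \code{origin + c(i,j,k) * spacing}.
#'
#' @slot voxels 3D numeric array of HU values.
#' @slot spacing numeric length-3, voxel spacing in mm (all > 0).
#' @slot origin numeric length-3, world mm position of voxel (0,0,0).
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
    if (any(dim(object@voxels) < 1L)) return("voxels must be non-empty")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0)) {
      return("spacing must be 3 positive finite values (mm)")
    }
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be 3 finite values (mm)")
    TRUE
  }
)

#' Construct a CTVolume
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing voxel spacing in mm (length 3).
#' @param origin world mm position of voxel (0,0,0); default centres the
#'   volume on the isocenter (world origin).
#' @return A [CTVolume-class] object.
#' @export
ctVolume <- function(voxels, spacing = c(1, 1, 1), origin = NULL) {
  if (is.null(origin)) origin <- -(dim(voxels) - 1) * spacing / 2
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %s mm, HU range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 4), collapse = " x "),
              min(object@voxels), max(object@voxels)))
})

# ---------------------------------------------------------------------------
# XRayImage: 2D detector frame. Detector mm coordinate of pixel (ui, vi)
# (1-based) is (index - center) * pixelSpacing; u is lateral, v increases
# caudally (image rows read top-of-patient to bottom).
# ---------------------------------------------------------------------------

#' Fluoroscopy / DRR frame
#'
#' A 2D scalar detector image. Pixels are indexed \code{[ui, vi]} with u the
#' lateral detector axis and v increasing caudally; the detector mm
#' coordinate of a pixel is \code{(index - center) * pixelSpacing}.
#'
#' @slot pixels numeric matrix (u by v).
#' @slot pixelSpacing isotropic pixel spacing, mm.
#' @slot center length-2 (possibly fractional) 1-based pixel index of the
#'   detector origin.
#' @slot viewLabel view annotation, e.g. "AP", "RAO30", "LAO30".
#' @slot subtractionApplied whether a DSA subtraction mask was applied.
#' @export
setClass("XRayImage",
  representation(pixels = "matrix", pixelSpacing = "numeric",
                 center = "numeric", viewLabel = "character",
                 subtractionApplied = "logical"),
  validity = function(object) {
    if (length(object@pixelSpacing) != 1L || object@pixelSpacing <= 0)
      return("pixelSpacing must be a single positive value (mm)")
    if (any(dim(object@pixels) < 1L)) return("pixels must be non-empty")
    if (length(object@center) != 2L) return("center must have length 2")
    TRUE
  }
)

#' Construct an XRayImage
#'
#' @param pixels numeric matrix (u by v).
#' @param pixelSpacing isotropic pixel spacing in mm.
#' @param center detector origin as 1-based pixel index; default image centre.
#' @param viewLabel view annotation.
#' @param subtractionApplied logical flag.
#' @return An [XRayImage-class] object.
#' @export
xrayImage <- function(pixels, pixelSpacing, center = NULL, viewLabel = "AP",
                      subtractionApplied = FALSE) {
  if (is.null(center)) center <- (dim(pixels) + 1) / 2
  new("XRayImage", pixels = pixels, pixelSpacing = as.numeric(pixelSpacing),
      center = as.numeric(center), viewLabel = viewLabel,
      subtractionApplied = subtractionApplied)
}

setMethod("show", "XRayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("XRayImage (%s): %d x %d px, %.4g mm/px, range [%.4g, %.4g]\n",
              object@viewLabel, d[1], d[2], object@pixelSpacing,
              min(object@pixels), max(object@pixels)))
})

# ---------------------------------------------------------------------------
# CArmGeometry: cone-beam acquisition model.
# ---------------------------------------------------------------------------

#' C-arm cone-beam geometry
#'
#' Source-to-isocenter (SID) and source-to-detector (SDD) distances plus the
#' primary (LAO positive, RAO negative, rotation about the craniocaudal axis)
#' and secondary (cranial positive) angulations in degrees. The isocenter is
#' the world origin; magnification of a structure at isocenter is SDD/SID.
#'
#' @slot sid source-to-isocenter distance, mm.
#' @slot sdd source-to-detector distance, mm.
#' @slot primaryAngle degrees, positive = LAO.
#' @slot secondaryAngle degrees, positive = cranial.
#' @export
setClass("CArmGeometry",
  representation(sid = "numeric", sdd = "numeric", primaryAngle = "numeric",
                 secondaryAngle = "numeric"),
  validity = function(object) {
    if (!(object@sid > 0 && object@sdd > object@sid))
      return("require 0 < SID < SDD")
    TRUE
  }
)

#' Construct a CArmGeometry
#'
#' @param sid source-to-isocenter distance, mm.
#' @param sdd source-to-detector distance, mm.
#' @param primaryAngle primary angulation, degrees (LAO positive).
#' @param secondaryAngle secondary angulation, degrees (cranial positive).
#' @return A [CArmGeometry-class] object.
#' @export
cArmGeometry <- function(sid = 800, sdd = 1200, primaryAngle = 0,
                         secondaryAngle = 0) {
  new("CArmGeometry", sid = sid, sdd = sdd, primaryAngle = primaryAngle,
      secondaryAngle = secondaryAngle)
}

setMethod("show", "CArmGeometry", function(object) {
  cat(sprintf("CArmGeometry: SID %g mm, SDD %g mm, primary %g deg, secondary %g deg\n",
              object@sid, object@sdd, object@primaryAngle, object@secondaryAngle))
})

# ---------------------------------------------------------------------------
# AffineParams: the registration's 7 pose parameters.
# ---------------------------------------------------------------------------

#' Affine pose parameters
#'
#' Translations Tx,Ty,Tz (mm along patient x,y,z), rotations Rx,Ry,Rz
#' (degrees, applied as Rz Ry Rx about the moving structure's centroid) and
#' an isotropic scale. The identity is all-zero with scale 1.
#'
#' @slot translation numeric length-3, mm.
#' @slot rotation numeric length-3, degrees.
#' @slot scale single positive number.
#' @export
setClass("AffineParams",
  representation(translation = "numeric", rotation = "numeric",
                 scale = "numeric"),
  validity = function(object) {
    if (length(object@translation) != 3L) return("translation must have length 3")
    if (length(object@rotation) != 3L) return("rotation must have length 3")
    if (length(object@scale) != 1L || object@scale <= 0)
      return("scale must be a single positive number")
    TRUE
  }
)

#' Construct AffineParams
#'
#' @param translation Tx, Ty, Tz in mm.
#' @param rotation Rx, Ry, Rz in degrees.
#' @param scale isotropic scale factor.
#' @return An [AffineParams-class] object.
#' @export
affineParams <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                         scale = 1) {
  new("AffineParams", translation = as.numeric(translation),
      rotation = as.numeric(rotation), scale = as.numeric(scale))
}

#' The identity pose
#' @return AffineParams with zero translation/rotation and scale 1.
#' @export
identityPose <- function() affineParams()

setMethod("show", "AffineParams", function(object) {
  cat(sprintf("AffineParams: T = (%s) mm, R = (%s) deg, scale %.4g\n",
              paste(signif(object@translation, 5), collapse = ", "),
              paste(signif(object@rotation, 5), collapse = ", "),
              object@scale))
})

# ---------------------------------------------------------------------------
# ProjectionConfig
# ---------------------------------------------------------------------------

#' DRR rendering configuration
#'
#' @slot rayStep sampling step along rays, mm (default 0.45, half the finest
#'   clinical slice dimension).
#' @slot intensityMode "hu_clamped" (integrate max(HU - huFloor, 0)/1000) or
#'   "binary_mask" (integrate a 0/1 indicator).
#' @slot huFloor HU below which voxels contribute nothing.
#' @export
setClass("ProjectionConfig",
  representation(rayStep = "numeric", intensityMode = "character",
                 huFloor = "numeric"),
  validity = function(object) {
    if (object@rayStep <= 0) return("rayStep must be > 0")
    if (!object@intensityMode %in% c("hu_clamped", "binary_mask"))
      return("intensityMode must be 'hu_clamped' or 'binary_mask'")
    TRUE
  }
)

#' Construct a ProjectionConfig
#' @param rayStep ray sampling step, mm.
#' @param intensityMode "hu_clamped" or "binary_mask".
#' @param huFloor HU floor for hu_clamped mode.
#' @return A [ProjectionConfig-class] object.
#' @export
projectionConfig <- function(rayStep = 0.45, intensityMode = "hu_clamped",
                             huFloor = 150) {
  new("ProjectionConfig", rayStep = rayStep, intensityMode = intensityMode,
      huFloor = huFloor)
}

# ---------------------------------------------------------------------------
# SearchBounds
# ---------------------------------------------------------------------------

#' Registration search bounds and step schedule
#'
#' Parameter ranges for the affine search together with the coarse (global
#' lattice) and initial local step sizes, the multiplicative step shrink
#' factor, the minimum steps at which refinement stops, and an evaluation
#' budget. Default ranges contain the parameter extremes observed clinically.
#'
#' @slot txRange,tyRange,tzRange translation ranges, mm.
#' @slot rxRange,ryRange,rzRange rotation ranges, degrees.
#' @slot scaleRange isotropic scale range.
#' @slot globalSteps coarse lattice steps: c(translation mm, rotation deg, scale).
#' @slot localSteps initial local steps, same layout.
#' @slot shrinkFactor multiplicative step shrink in (0,1).
#' @slot minSteps minimum steps, same layout as globalSteps.
#' @slot maxEvaluations score-evaluation budget per pair and phase.
#' @export
setClass("SearchBounds",
  representation(txRange = "numeric", tyRange = "numeric", tzRange = "numeric",
                 rxRange = "numeric", ryRange = "numeric", rzRange = "numeric",
                 scaleRange = "numeric", globalSteps = "numeric",
                 localSteps = "numeric", shrinkFactor = "numeric",
                 minSteps = "numeric", maxEvaluations = "numeric"),
  validity = function(object) {
    rng <- list(object@txRange, object@tyRange, object@tzRange, object@rxRange,
                object@ryRange, object@rzRange, object@scaleRange)
    for (r in rng) {
      if (length(r) != 2L || r[2] < r[1]) return("ranges must be c(lo, hi), hi >= lo")
    }
    if (!(object@shrinkFactor > 0 && object@shrinkFactor < 1))
      return("shrinkFactor must be in (0,1)")
    if (any(object@globalSteps <= object@localSteps) ||
        any(object@localSteps <= object@minSteps)) {
      return("require globalSteps > localSteps > minSteps componentwise")
    }
    if (object@maxEvaluations < 1) return("maxEvaluations must be >= 1")
    TRUE
  }
)

#' Construct SearchBounds
#'
#' Defaults are slightly widened versions of the clinically observed
#' parameter extremes; see [defaultSearchBounds()].
#'
#' @param txRange,tyRange,tzRange translation ranges, mm.
#' @param rxRange,ryRange,rzRange rotation ranges, degrees.
#' @param scaleRange scale range.
#' @param globalSteps,localSteps,minSteps c(translation mm, rotation deg, scale).
#' @param shrinkFactor step shrink factor in (0,1).
#' @param maxEvaluations evaluation budget per pair and phase.
#' @return A [SearchBounds-class] object.
#' @export
searchBounds <- function(txRange = c(-20, 60), tyRange = c(-145, 110),
                         tzRange = c(-230, 55), rxRange = c(-40, 10),
                         ryRange = c(-30, 12), rzRange = c(-5, 8),
                         scaleRange = c(0.9, 1.1),
                         globalSteps = c(8, 4, 0.05),
                         localSteps = c(4, 2, 0.02),
                         shrinkFactor = 0.5,
                         minSteps = c(0.1, 0.1, 0.001),
                         maxEvaluations = 20000) {
  new("SearchBounds", txRange = txRange, tyRange = tyRange, tzRange = tzRange,
      rxRange = rxRange, ryRange = ryRange, rzRange = rzRange,
      scaleRange = scaleRange, globalSteps = globalSteps,
      localSteps = localSteps, shrinkFactor = shrinkFactor,
      minSteps = minSteps, maxEvaluations = maxEvaluations)
}

#' Default search bounds
#' @return The default [SearchBounds-class].
#' @export
defaultSearchBounds <- function() searchBounds()

# ---------------------------------------------------------------------------
# VertebraPair
# ---------------------------------------------------------------------------

#' A registration vertebra pair
#'
#' Two craniocaudally adjacent vertebrae with their combined binary mask in
#' the CT frame. The registration runs per pair T12-L1, L2-L3, L4-L5.
#'
#' @slot label pair label, one of "T12-L1", "L2-L3", "L4-L5".
#' @slot members the two vertebra labels, cranial first.
#' @slot mask logical 3D array on the volume grid.
#' @slot centroid world mm centroid of the mask.
#' @slot landmarks named list per member vertebra with left/right lateral
#'   edge points (world mm), possibly empty.
#' @export
setClass("VertebraPair",
  representation(label = "character", members = "character", mask = "array",
                 centroid = "numeric", landmarks = "list"),
  validity = function(object) {
    if (!any(object@mask)) return("pair mask must be non-empty")
    if (length(object@members) != 2L) return("a pair has exactly two members")
    TRUE
  }
)

setMethod("show", "VertebraPair", function(object) {
  cat(sprintf("VertebraPair %s: %d voxels, centroid (%s) mm\n", object@label,
              sum(object@mask), paste(signif(object@centroid, 4), collapse = ", ")))
})

# ---------------------------------------------------------------------------
# RegistrationResult
# ---------------------------------------------------------------------------

#' Result of a registration phase
#'
#' @slot phase "global" or "local".
#' @slot pairLabel vertebra pair the pose was estimated on.
#' @slot params the estimated [AffineParams-class].
#' @slot score registration score in [-1, 1].
#' @slot feasible edge-visibility check outcome (NA until checked).
#' @slot manualAdjustmentNeeded TRUE when the visibility check failed at the
#'   selected global pose.
#' @slot evaluations number of score evaluations spent.
#' @slot trace data.frame of accepted optimizer moves (local phase).
#' @slot provenance list with seed and configuration digest.
#' @export
setClass("RegistrationResult",
  representation(phase = "character", pairLabel = "character",
                 params = "AffineParams", score = "numeric",
                 feasible = "logical", manualAdjustmentNeeded = "logical",
                 evaluations = "numeric", trace = "data.frame",
                 provenance = "list"),
  validity = function(object) {
    if (!object@phase %in% c("global", "local")) return("phase must be global|local")
    if (!is.na(object@score) && (object@score < -1 - 1e-9 || object@score > 1 + 1e-9))
      return("score must lie in [-1, 1]")
    TRUE
  }
)

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult [%s] pair %s: score %.4f, %d evaluations%s\n",
              object@phase, object@pairLabel, object@score,
              as.integer(object@evaluations),
              if (isTRUE(object@manualAdjustmentNeeded)) ", manual adjustment needed" else ""))
  show(object@params)
})

# ---------------------------------------------------------------------------
# VesselTree
# ---------------------------------------------------------------------------

#' Abdominal aortic vessel tree
#'
#' Aorta centreline with radii and renal orifice points; the lowest (most
#' caudal) renal orifice drives the vascular alignment measurement.
#'
#' @slot centerline n x 3 matrix of world mm points, cranial to caudal.
#' @slot aortaRadius aorta radius, mm.
#' @slot aneurysmRadius maximum aneurysm radius, mm.
#' @slot renalOrifices m x 3 matrix of orifice points (world mm).
#' @slot orificeSides character vector, "left"/"right" per orifice.
#' @slot orificeRadius renal orifice ring radius, mm.
#' @slot lowestRenalIndex index of the most caudal orifice.
#' @export
setClass("VesselTree",
  representation(centerline = "matrix", aortaRadius = "numeric",
                 aneurysmRadius = "numeric", renalOrifices = "matrix",
                 orificeSides = "character", orificeRadius = "numeric",
                 lowestRenalIndex = "integer"),
  validity = function(object) {
    if (nrow(object@renalOrifices) < 1L) return("need at least one renal orifice")
    z <- object@renalOrifices[, 3]
    if (object@lowestRenalIndex != which.min(z)[1])
      return("lowestRenalIndex must identify the most caudal orifice")
    # each orifice sits on the aorta wall: within one radius of the centreline
    for (i in seq_len(nrow(object@renalOrifices))) {
      d <- sqrt(colSums((t(object@centerline) - object@renalOrifices[i, ])^2))
      if (min(d) > object@aortaRadius + 1e-6)
        return(sprintf("orifice %d lies beyond one aorta radius of the centreline", i))
    }
    TRUE
  }
)

setMethod("show", "VesselTree", function(object) {
  cat(sprintf("VesselTree: %d centreline points, aorta r %g mm, %d renal orifices (lowest #%d)\n",
              nrow(object@centerline), object@aortaRadius,
              nrow(object@renalOrifices), object@lowestRenalIndex))
})

# ---------------------------------------------------------------------------
# SimulatedCase
# ---------------------------------------------------------------------------

#' A simulated fluoroscopy case with known ground truth
#'
#' @slot volume the phantom [CTVolume-class].
#' @slot vessels the [VesselTree-class].
#' @slot truePose ground-truth [AffineParams-class] of the acquisition.
#' @slot geometry the [CArmGeometry-class].
#' @slot fluoro the simulated [XRayImage-class] frame.
#' @slot markerPointsPx pigtail marker pixel positions (k x 2), 10 mm world
#'   spacing along the marker curve.
#' @slot dsaOrificePx pixel position of the lowest renal orifice distal edge
#'   on the (displaced) DSA.
#' @slot orificeDisplacement injected vascular deformation, mm.
#' @slot truncationFraction fraction of the vertebral silhouette cropped.
#' @slot noiseSigma additive Gaussian noise sigma on the frame.
#' @slot seed integer seed the case was generated with.
#' @slot landmarks per-vertebra lateral edge landmarks (world mm).
#' @export
setClass("SimulatedCase",
  representation(volume = "CTVolume", vessels = "VesselTree",
                 truePose = "AffineParams", geometry = "CArmGeometry",
                 fluoro = "XRayImage", markerPointsPx = "matrix",
                 dsaOrificePx = "numeric", orificeDisplacement = "numeric",
                 truncationFraction = "numeric", noiseSigma = "numeric",
                 seed = "numeric", landmarks = "list"),
  validity = function(object) {
    if (object@truncationFraction < 0 || object@truncationFraction > 1)
      return("truncationFraction must lie in [0, 1]")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    TRUE
  }
)

setMethod("show", "SimulatedCase", function(object) {
  cat(sprintf("SimulatedCase (seed %d): displacement %.2f mm, truncation %.2f, noise %.2f\n",
              as.integer(object@seed), object@orificeDisplacement,
              object@truncationFraction, object@noiseSigma))
  show(object@fluoro)
})

# ---------------------------------------------------------------------------
# AlignmentMeasurement
# ---------------------------------------------------------------------------

#' Bone and vascular alignment measurement
#'
#' Caliper-style offsets in mm: per-vertebra left/right lateral bone offsets
#' with their average (Db), and the vascular offset (Dv) at the lowest renal
#' artery orifice distal edge, using the pigtail-marker mm-per-pixel
#' calibration.
#'
#' @slot bone data.frame with columns vertebra, left, right, average (mm).
#' @slot vascular Dv in mm (NA when not measured).
#' @slot calibration mm-per-pixel used.
#' @slot phase "global", "local" or "manual".
#' @export
setClass("AlignmentMeasurement",
  representation(bone = "data.frame", vascular = "numeric",
                 calibration = "numeric", phase = "character"),
  validity = function(object) {
    if (nrow(object@bone)) {
      ok <- is.na(object@bone$left) | is.na(object@bone$right) |
        abs(object@bone$average - (object@bone$left + object@bone$right) / 2) < 1e-9
      if (!all(ok)) return("average must equal (left + right) / 2")
      vals <- unlist(object@bone[c("left", "right", "average")])
      if (any(vals < 0, na.rm = TRUE)) return("offsets must be >= 0")
    }
    if (!is.na(object@vascular) && object@vascular < 0)
      return("vascular offset must be >= 0")
    TRUE
  }
)

setMethod("show", "AlignmentMeasurement", function(object) {
  cat(sprintf("AlignmentMeasurement [%s]: Dv = %.2f mm, calibration %.4f mm/px\n",
              object@phase, object@vascular, object@calibration))
  if (nrow(object@bone)) print(object@bone, digits = 3)
})
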