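# Synthetic study material: a lumbar column (T12..L5) CT phantom built from
# elliptic-cylinder vertebral bodies with posterior pedicle cylinders, an
# abdominal aortic vessel tree with renal orifices, and simulated
# fluoroscopy frames at a known pose with pigtail markers, configurable
# vascular deformation and border truncation. All randomness is driven by
# explicit integer seeds; no global random state is consumed.

#' Spine phantom specification
#'
#' @slot nVertebrae number of vertebrae (default 6: T12..L5, cranial to caudal).
#' @slot vertebraPitch craniocaudal centre spacing, mm.
#' @slot bodyRadius lateral semi-axis of the vertebral body ellipse, mm.
#' @slot bodyHeight vertebral body height, mm.
#' @slot pedicleOffset lateral pedicle offset from the body centre, mm.
#' @slot boneHU vertebra intensity, HU.
#' @slot softTissueHU background intensity, HU.
#' @slot voxelSpacing mm triple.
#' @slot volumeShape voxel triple.
#' @slot seed integer seed (per-vertebra lateral jitter).
#' @export
setClass("SpinePhantomSpec",
  representation(nVertebrae = "numeric", vertebraPitch = "numeric",
                 bodyRadius = "numeric", bodyHeight = "numeric",
                 pedicleOffset = "numeric", boneHU = "numeric",
                 softTissueHU = "numeric", voxelSpacing = "numeric",
                 volumeShape = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@nVertebrae < 0) return("nVertebrae must be >= 0")
    geo <- c(object@vertebraPitch, object@bodyRadius, object@bodyHeight,
             object@pedicleOffset, object@voxelSpacing)
    if (any(geo <= 0)) return("all geometric fields must be > 0")
    if (object@boneHU <= object@softTissueHU)
      return("bone_hu must exceed soft_tissue_hu")
    if (length(object@volumeShape) != 3L || any(object@volumeShape < 1))
      return("volumeShape must be a positive voxel triple")
    TRUE
  }
)

#' Construct a SpinePhantomSpec
#'
#' Defaults emulate a lumbar CTA at clinical resolution: six vertebrae at
#' 30 mm pitch, cortex-bright bodies (700 HU) on soft tissue (40 HU),
#' 1 x 1 x 0.9 mm voxels.
#'
#' @param nVertebrae,vertebraPitch,bodyRadius,bodyHeight,pedicleOffset see slots.
#' @param boneHU,softTissueHU,voxelSpacing,volumeShape,seed see slots.
#' @return A [SpinePhantomSpec-class].
#' @export
spinePhantomSpec <- function(nVertebrae = 6, vertebraPitch = 30,
                             bodyRadius = 17, bodyHeight = 22,
                             pedicleOffset = 12, boneHU = 700,
                             softTissueHU = 40, voxelSpacing = c(1, 1, 0.9),
                             volumeShape = c(96, 96, 224), seed = 1) {
  new("SpinePhantomSpec", nVertebrae = nVertebrae, vertebraPitch = vertebraPitch,
      bodyRadius = bodyRadius, bodyHeight = bodyHeight,
      pedicleOffset = pedicleOffset, boneHU = boneHU,
      softTissueHU = softTissueHU, voxelSpacing = as.numeric(voxelSpacing),
      volumeShape = as.numeric(volumeShape), seed = seed)
}

#' Build a spine phantom volume
#'
#' Vertebrae are elliptic cylinders (lateral semi-axis `bodyRadius`,
#' anteroposterior semi-axis 0.72 * `bodyRadius`) with two posterior pedicle
#' cylinders, stacked along the craniocaudal axis with T12 most cranial.
#' Per-vertebra sub-millimetre lateral jitter (seeded) breaks exact column
#' symmetry. Ground-truth left/right lateral edge landmarks are returned per
#' vertebra in world mm.
#'
#' @param spec a [SpinePhantomSpec-class].
#' @return List with `volume` ([CTVolume-class]), `landmarks` (named list per
#'   vertebra with `left`/`right` world-mm points) and `spec`.
#' @export
buildSpinePhantom <- function(spec) {
  shape <- spec@volumeShape
  sp <- spec@voxelSpacing
  origin <- -(shape - 1) * sp / 2  # centred on the isocenter
  vox <- array(spec@softTissueHU, dim = shape)
  n <- spec@nVertebrae
  landmarks <- list()
  if (n >= 1) {
    set.seed(as.integer(spec@seed))
    jitterX <- runif(n, -1.5, 1.5)
    ped <- 4  # pedicle cylinder radius, mm
    cy <- 8   # column sits slightly posterior of the isocenter
    xw <- origin[1] + (seq_len(shape[1]) - 1) * sp[1]
    yw <- origin[2] + (seq_len(shape[2]) - 1) * sp[2]
    zw <- origin[3] + (seq_len(shape[3]) - 1) * sp[3]
    for (k in seq_len(n)) {
      label <- if (k <= length(VERTEBRA_LABELS)) VERTEBRA_LABELS[k] else sprintf("V%d", k)
      # lumbar bodies widen caudally; breaks the pitch periodicity that would
      # otherwise make vertebra-counting ambiguous for the registration
      a <- spec@bodyRadius * (1 + 0.05 * (k - 1))
      b <- 0.72 * a
      cx <- jitterX[k]
      cz <- ((n + 1) / 2 - k) * spec@vertebraPitch  # T12 (k=1) most cranial
      finLen <- 16  # spinous process length, mm
      lo <- c(cx - a - ped, cy - b, cz - spec@bodyHeight / 2)
      hi <- c(cx + a + ped, cy + b + ped * 0.6 + ped + finLen,
              cz + spec@bodyHeight / 2)
      bounds <- origin + (shape - 1) * sp
      if (any(lo < origin - 1e-9) || any(hi > bounds + 1e-9)) {
        stop("vertebra ", label, " exceeds the volume bounds; enlarge volume_shape")
      }
      zin <- which(abs(zw - cz) <= spec@bodyHeight / 2)
      ell <- outer((xw - cx)^2 / a^2, (yw - cy)^2 / b^2, "+") <= 1
      pedY <- cy + b + ped * 0.6
      p1 <- outer((xw - (cx - spec@pedicleOffset))^2, (yw - pedY)^2, "+") <= ped^2
      p2 <- outer((xw - (cx + spec@pedicleOffset))^2, (yw - pedY)^2, "+") <= ped^2
      # bars joining each pedicle to the body so a vertebra is one component
      yBar <- yw >= cy & yw <= pedY
      b1 <- outer(abs(xw - (cx - spec@pedicleOffset)) <= 2.5, yBar, "&")
      b2 <- outer(abs(xw - (cx + spec@pedicleOffset)) <= 2.5, yBar, "&")
      slice <- ell | p1 | p2 | b1 | b2
      vox[, , zin][rep(slice, length(zin))] <- spec@boneHU
      # spinous process: a posterior fin over the central half of the body
      # height; the posterior lever arm gives the out-of-plane pose
      # components a projected signature, as it does clinically
      fin <- outer(abs(xw - cx) <= 2.5,
                   yw >= pedY & yw <= pedY + ped + finLen, "&")
      lamina <- outer(abs(xw - cx) <= spec@pedicleOffset,
                      abs(yw - pedY) <= 2.5, "&")
      zfin <- which(abs(zw - cz) <= spec@bodyHeight * 0.3)
      vox[, , zfin][rep(fin | lamina, length(zfin))] <- spec@boneHU
      landmarks[[label]] <- list(left = c(cx + a, cy, cz),
                                 right = c(cx - a, cy, cz))
    }
  }
  list(volume = ctVolume(vox, spacing = sp, origin = origin),
       landmarks = landmarks, spec = spec)
}

#' Build an abdominal aortic vessel tree
#'
#' A gently curved aorta centreline anterior to the spine, an aneurysmal
#' dilatation caudal to the renal arteries, and `nOrifices` renal orifice
#' points on the aorta wall. Deterministic for a fixed seed.
#'
#' @param nOrifices number of renal orifices (>= 1).
#' @param seed integer seed.
#' @param aortaRadius aorta radius, mm.
#' @param aneurysmRadius maximum aneurysm radius, mm.
#' @param orificeRadius renal orifice ring radius, mm.
#' @param zRange craniocaudal extent of the centreline, mm.
#' @return A [VesselTree-class] with `lowestRenalIndex` resolved.
#' @export
buildVesselTree <- function(nOrifices = 2, seed = 1, aortaRadius = 10,
                            aneurysmRadius = 28, orificeRadius = 3,
                            zRange = c(-90, 90)) {
  if (nOrifices < 1) stop("at least one renal orifice is required")
  set.seed(as.integer(seed))
  z <- seq(zRange[2], zRange[1], by = -5)
  amp <- runif(1, 2, 6)
  phase <- runif(1, 0, pi)
  x <- 4 + amp * sin(pi * (z - zRange[1]) / diff(range(z)) + phase) * 0.5
  y <- -18 + 2 * cos(pi * (z - zRange[1]) / (2 * diff(range(z))))
  centerline <- cbind(x = x, y = y, z = z)
  # renal orifices near the cranial third, alternating sides
  zr <- sort(runif(nOrifices, 30, 55), decreasing = TRUE)
  sides <- rep(c("left", "right"), length.out = nOrifices)
  orf <- t(vapply(seq_len(nOrifices), function(i) {
    ci <- which.min(abs(z - zr[i]))
    dir <- if (sides[i] == "left") 1 else -1
    centerline[ci, ] + c(dir * aortaRadius, 0, 0)
  }, numeric(3)))
  colnames(orf) <- c("x", "y", "z")
  new("VesselTree", centerline = centerline, aortaRadius = aortaRadius,
      aneurysmRadius = aneurysmRadius, renalOrifices = orf,
      orificeSides = sides, orificeRadius = orificeRadius,
      lowestRenalIndex = as.integer(which.min(orf[, 3])[1]))
}

#' Default fluoroscopy detector template for simulated cases
#'
#' @param n detector size in pixels (square).
#' @param pixelSpacing mm per pixel.
#' @param viewLabel view annotation.
#' @return An [XRayImage-class] of zeros.
#' @export
defaultFluoroTemplate <- function(n = 384, pixelSpacing = 1, viewLabel = "AP") {
  xrayImage(matrix(0, n, n), pixelSpacing = pixelSpacing, viewLabel = viewLabel)
}

#' Simulate a fluoroscopy case with known ground truth
#'
#' Renders the phantom DRR at `truePose` (with zero noise and zero
#' truncation the frame equals that DRR pixel for pixel), adds Gaussian
#' noise, injects a vascular deformation by displacing the DSA position of
#' the lowest renal orifice by exactly `orificeDisplacement` mm in a random
#' in-plane direction, places pigtail markers every 10 mm along a catheter
#' line, and optionally crops the lateral field-of-view border so the given
#' fraction of the vertebral silhouette falls outside the frame.
#'
#' @param phantom result of [buildSpinePhantom()] (or a [CTVolume-class];
#'   then no landmarks are attached).
#' @param vessels a [VesselTree-class].
#' @param truePose ground-truth [AffineParams-class].
#' @param geom a [CArmGeometry-class].
#' @param orificeDisplacement injected vascular deformation, mm.
#' @param truncationFraction fraction of the vertebral silhouette cropped
#'   by the image border, in [0, 1].
#' @param noiseSigma additive Gaussian noise sigma (line-integral units).
#' @param seed integer seed.
#' @param template detector template; default [defaultFluoroTemplate()].
#' @param config a [ProjectionConfig-class] for rendering.
#' @param huThreshold bone threshold used to form the silhouette for
#'   truncation.
#' @return A [SimulatedCase-class].
#' @export
simulateCase <- function(phantom, vessels, truePose = identityPose(),
                         geom = cArmGeometry(), orificeDisplacement = 0,
                         truncationFraction = 0, noiseSigma = 0, seed = 1,
                         template = defaultFluoroTemplate(),
                         config = projectionConfig(), huThreshold = 200) {
  if (truncationFraction < 0 || truncationFraction > 1)
    stop("truncation_fraction must lie in [0, 1]")
  if (is(phantom, "CTVolume")) {
    volume <- phantom
    landmarks <- list()
  } else {
    volume <- phantom$volume
    landmarks <- phantom$landmarks
  }
  set.seed(as.integer(seed))
  poseCenter <- volumeCenter(volume)
  fluoro <- renderDRR(volume, geom, truePose, config, template,
                      center = poseCenter)
  fluoro@viewLabel <- template@viewLabel

  # pigtail markers: a catheter line at isocenter depth, 10 mm world spacing
  markerZ <- seq(-80, 80, by = 10)
  markerWorld <- cbind(-38, 0, markerZ)
  markerPx <- detectorToPixel(projectPoint(markerWorld, geom), fluoro)

  # lowest renal orifice distal edge on the (undeformed) DSA, then displaced
  proj <- projectVessels(vessels, truePose, geom, center = poseCenter)
  distalPx <- detectorToPixel(proj$orificeDistalEdge, fluoro)
  scaleCal <- calibrateScale(markerPx)  # mm per pixel
  theta <- runif(1, 0, 2 * pi)
  dsaOrificePx <- distalPx + orificeDisplacement / scaleCal * c(cos(theta), sin(theta))

  if (noiseSigma > 0) {
    fluoro@pixels <- fluoro@pixels +
      matrix(rnorm(length(fluoro@pixels), 0, noiseSigma), nrow(fluoro@pixels))
  }

  if (truncationFraction > 0) {
    boneMask <- ctVolume(array(as.numeric(volume@voxels >= huThreshold),
                               dim = dim(volume@voxels)),
                         spacing = volume@spacing, origin = volume@origin)
    sil <- projectSilhouette(boneMask, geom, truePose, template,
                             center = poseCenter)$silhouette
    us <- which(rowSums(sil) > 0)
    if (length(us)) {
      uIdx <- rep(seq_len(nrow(sil)), times = ncol(sil))[as.vector(sil)]
      cut <- as.numeric(quantile(uIdx, truncationFraction, type = 1))
      fluoro <- xrayImage(fluoro@pixels[-seq_len(cut), , drop = FALSE],
                          pixelSpacing = fluoro@pixelSpacing,
                          center = fluoro@center - c(cut, 0),
                          viewLabel = fluoro@viewLabel)
      markerPx[, 1] <- markerPx[, 1] - cut
      dsaOrificePx[1] <- dsaOrificePx[1] - cut
    }
  }

  new("SimulatedCase", volume = volume, vessels = vessels, truePose = truePose,
      geometry = geom, fluoro = fluoro, markerPointsPx = markerPx,
      dsaOrificePx = as.numeric(dsaOrificePx),
      orificeDisplacement = orificeDisplacement,
      truncationFraction = truncationFraction, noiseSigma = noiseSigma,
      seed = seed, landmarks = landmarks)
}
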