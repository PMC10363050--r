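# Vertebral column model: HU-threshold bone segmentation with a minimum
# component volume, positional cranial-to-caudal labelling T12..L5, the three
# registration pairs, and mm-normalised gradient edge maps.

VERTEBRA_LABELS <- c("T12", "L1", "L2", "L3", "L4", "L5")
PAIR_DEFS <- list("T12-L1" = c("T12", "L1"), "L2-L3" = c("L2", "L3"),
                  "L4-L5" = c("L4", "L5"))

#' Segment bone by HU threshold
#'
#' Voxels at or above the threshold, after removal of connected components
#' smaller than a minimum volume (speckle filter). An empty mask is allowed.
#'
#' @param volume a [CTVolume-class].
#' @param huThreshold bone threshold in HU (default 200).
#' @param minComponentCm3 minimum component volume in cm^3 (default 1).
#' @return Logical 3D array on the volume grid.
#' @export
segmentBone <- function(volume, huThreshold = 200, minComponentCm3 = 1) {
  mask <- volume@voxels >= huThreshold
  if (!any(mask)) return(mask)
  lab <- .labelComponentsCpp(mask)
  sizes <- attr(lab, "sizes")
  voxCm3 <- prod(volume@spacing) / 1000
  keep <- which(sizes * voxCm3 >= minComponentCm3)
  out <- array(lab %in% keep, dim = dim(mask))
  out
}

#' Label vertebrae cranial to caudal
#'
#' Connected components of the bone mask are ordered by centroid
#' craniocaudal (z) coordinate, most cranial first, and assigned positional
#' labels T12, L1, ..., L5. Fewer than six components get labels from T12
#' downward with a warning record; anatomical identity is not verified.
#'
#' @param mask logical 3D array from [segmentBone()].
#' @param volume the [CTVolume-class] the mask lives on (for spacing/origin).
#' @return List with `labels` (character), `centroids` (n x 3 world mm),
#'   `labelArray` (integer array, 1 = T12 ...), `warnings` (character).
#' @export
labelVertebrae <- function(mask, volume) {
  if (!any(mask)) {
    return(list(labels = character(0),
                centroids = matrix(numeric(0), 0, 3),
                labelArray = array(0L, dim = dim(mask)),
                warnings = character(0)))
  }
  lab <- .labelComponentsCpp(mask)
  ncomp <- max(lab)
  cent <- matrix(0, ncomp, 3)
  zlo <- numeric(ncomp); zhi <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k, arr.ind = TRUE)
    cent[k, ] <- volume@origin + (colMeans(idx) - 1) * volume@spacing
    zw <- volume@origin[3] + (range(idx[, 3]) - 1) * volume@spacing[3]
    zlo[k] <- zw[1]; zhi[k] <- zw[2]
  }
  ord <- order(-cent[, 3])  # most cranial (largest z) first
  # refuse to order components whose craniocaudal extents overlap > 50%
  for (i in seq_len(ncomp - 1)) {
    a <- ord[i]; b <- ord[i + 1]
    ov <- min(zhi[a], zhi[b]) - max(zlo[a], zlo[b])
    if (ov > 0) {
      shorter <- min(zhi[a] - zlo[a], zhi[b] - zlo[b])
      if (shorter > 0 && ov / shorter > 0.5) {
        stop("craniocaudal extents of two components overlap more than 50%; ",
             "cannot order vertebrae")
      }
    }
  }
  warnings <- character(0)
  labels <- character(ncomp)
  n6 <- min(ncomp, length(VERTEBRA_LABELS))
  labels[seq_len(n6)] <- VERTEBRA_LABELS[seq_len(n6)]
  if (ncomp < length(VERTEBRA_LABELS)) {
    warnings <- sprintf("only %d vertebral components found; labels assigned T12 downward",
                        ncomp)
  }
  if (ncomp > length(VERTEBRA_LABELS)) {
    labels[(n6 + 1):ncomp] <- sprintf("V%d", (n6 + 1):ncomp)
    warnings <- sprintf("%d components exceed the six expected vertebrae", ncomp)
  }
  relab <- array(0L, dim = dim(mask))
  for (i in seq_len(ncomp)) relab[lab == ord[i]] <- i
  list(labels = labels, centroids = cent[ord, , drop = FALSE],
       labelArray = relab, warnings = warnings)
}

#' Form the registration vertebra pairs
#'
#' Returns the pairs T12-L1, L2-L3, L4-L5 (in that order) whose both members
#' exist in the labelling.
#'
#' @param labeling result of [labelVertebrae()].
#' @param volume the [CTVolume-class].
#' @param landmarks optional named list (by vertebra label) with `left` and
#'   `right` lateral edge points (world mm), attached to each pair.
#' @return List of [VertebraPair-class] (possibly empty).
#' @export
makePairs <- function(labeling, volume, landmarks = NULL) {
  pairs <- list()
  for (lab in names(PAIR_DEFS)) {
    members <- PAIR_DEFS[[lab]]
    pos <- match(members, labeling$labels)
    if (any(is.na(pos))) next
    mask <- array(labeling$labelArray %in% pos, dim = dim(labeling$labelArray))
    idx <- which(mask, arr.ind = TRUE)
    centroid <- volume@origin + (colMeans(idx) - 1) * volume@spacing
    lms <- if (is.null(landmarks)) list() else landmarks[intersect(members, names(landmarks))]
    pairs[[lab]] <- new("VertebraPair", label = lab, members = members,
                        mask = mask, centroid = centroid,
                        landmarks = if (is.null(lms)) list() else lms)
  }
  unname(pairs)
}

#' Edge-strength map of an image
#'
#' Gradient magnitude by central differences (one-sided at the borders),
#' normalised by pixel spacing so strengths are per-mm, plus a binary mask of
#' pixels above the q-th percentile of the nonzero strengths. Constant
#' images give zero strength and an empty mask.
#'
#' @param image an [XRayImage-class].
#' @param q percentile in (0, 100) for the edge mask (default 85).
#' @return List with `strength` (matrix), `mask` (logical matrix) and
#'   `threshold`.
#' @export
edgeMap <- function(image, q = 85) {
  if (q <= 0 || q >= 100) stop("q must lie in (0, 100)")
  g <- gradientMagnitude(image@pixels, image@pixelSpacing)
  nz <- g[g > 0]
  if (!length(nz)) {
    return(list(strength = g, mask = array(FALSE, dim(g)), threshold = Inf))
  }
  thr <- as.numeric(quantile(nz, q / 100))
  list(strength = g, mask = g > thr, threshold = thr)
}

gradientMagnitude <- function(px, spacing) {
  nu <- nrow(px); nv <- ncol(px)
  gu <- px; gv <- px
  if (nu >= 3) {
    gu[2:(nu - 1), ] <- (px[3:nu, ] - px[1:(nu - 2), ]) / 2
    gu[1, ] <- px[2, ] - px[1, ]
    gu[nu, ] <- px[nu, ] - px[nu - 1, ]
  } else gu[] <- 0
  if (nv >= 3) {
    gv[, 2:(nv - 1)] <- (px[, 3:nv] - px[, 1:(nv - 2)]) / 2
    gv[, 1] <- px[, 2] - px[, 1]
    gv[, nv] <- px[, nv] - px[, nv - 1]
  } else gv[] <- 0
  sqrt(gu^2 + gv^2) / spacing
}
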