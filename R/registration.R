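# The registration core: an edge-strength correlation score between the
# vertebra-pair DRR and the fluoroscopy frame, a coarse global lattice
# search per pair (on a downsampled pyramid level, with the winning pose
# re-scored at full resolution), variable step-size coordinate-descent local
# refinement, a programmatic edge-visibility feasibility check, and the
# end-to-end register() pipeline.

PARAM_NAMES <- c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz", "scale")

# separable 3x3 binomial smoothing (kernel [1 2 1]/4 per axis)
blur3 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 3) return(m)
  m <- (2 * m + rbind(m[1, ], m[-n, ]) + rbind(m[-1, ], m[n, ])) / 4
  (2 * m + cbind(m[, 1], m[, -k]) + cbind(m[, -1], m[, k])) / 4
}

paramsToVector <- function(params) {
  c(params@translation, params@rotation, params@scale)
}

vectorToParams <- function(v) {
  affineParams(translation = v[1:3], rotation = v[4:6], scale = v[7])
}

boundsRanges <- function(bounds) {
  list(Tx = bounds@txRange, Ty = bounds@tyRange, Tz = bounds@tzRange,
       Rx = bounds@rxRange, Ry = bounds@ryRange, Rz = bounds@rzRange,
       scale = bounds@scaleRange)
}

withinBounds <- function(v, bounds) {
  rng <- boundsRanges(bounds)
  all(vapply(seq_along(rng), function(i) {
    v[i] >= rng[[i]][1] - 1e-9 && v[i] <= rng[[i]][2] + 1e-9
  }, logical(1)))
}

#' Edge-based similarity score between a DRR and a fluoroscopy frame
#'
#' Pearson correlation of the two mm-normalised edge-strength images over
#' the union of their edge masks within the region of interest. Returns 0
#' when the union is empty or either edge image is constant on it. The score
#' lies in [-1, 1] and is maximal when the projected vertebral edges
#' coincide with the fluoroscopic ones.
#'
#' @param drr an [XRayImage-class].
#' @param fluoro an [XRayImage-class] on the same pixel grid.
#' @param roi optional 1-based inclusive pixel ROI `c(u0, u1, v0, v1)`.
#' @param q edge-mask percentile (default 85).
#' @return Score in [-1, 1].
#' @export
similarityScore <- function(drr, fluoro, roi = NULL, q = 85) {
  if (!all(dim(drr@pixels) == dim(fluoro@pixels)) ||
      abs(drr@pixelSpacing - fluoro@pixelSpacing) > 1e-9) {
    stop("DRR and fluoroscopy frames must share one pixel grid")
  }
  d <- dim(drr@pixels)
  if (is.null(roi)) roi <- c(1L, d[1], 1L, d[2])
  ui <- roi[1]:roi[2]; vi <- roi[3]:roi[4]
  ea <- edgeMap(xrayImage(drr@pixels[ui, vi, drop = FALSE], drr@pixelSpacing), q)
  eb <- edgeMap(xrayImage(fluoro@pixels[ui, vi, drop = FALSE], fluoro@pixelSpacing), q)
  scoreFromEdges(ea$strength, ea$mask, eb$strength, eb$mask)
}

scoreFromEdges <- function(sa, ma, sb, mb) {
  un <- ma | mb
  n <- sum(un)
  if (n < 3) return(0)
  a <- sa[un]; b <- sb[un]
  if (sd(a) < 1e-12 || sd(b) < 1e-12) return(0)
  as.numeric(cor(a, b))
}

# Grid-aligned decimation of a frame by integer factor k (pyramid level).
# Kept pixels sit exactly on the fine grid so a DRR rendered on the coarse
# template samples the same detector positions as the retained fluoroscopy
# pixels (block averaging would smear the fluoroscopy edges relative to the
# point-sampled DRR and decorrelate the edge score).
downsampleImage <- function(image, k) {
  if (k <= 1) return(image)
  d <- dim(image@pixels)
  px <- image@pixels[seq(1, d[1], by = k), seq(1, d[2], by = k), drop = FALSE]
  xrayImage(px, pixelSpacing = image@pixelSpacing * k,
            center = 1 + (image@center - 1) / k,
            viewLabel = image@viewLabel)
}

# Masked, cropped pair subvolume plus score evaluators at full and coarse
# resolution. One rotation-centre convention (the volume centre) is used for
# simulation, search, visibility and measurement alike. The fluoroscopy edge
# map is computed once per level; the DRR edge map is computed per
# evaluation on the projected-bbox ROI. For speed the search evaluates rays
# at twice the configured step (the voxel scale); exported renderDRR /
# similarityScore keep the configured step.
makePairContext <- function(pair, volume, fluoro, geom, config, q = 85,
                            pyramid = 4, center = volumeCenter(volume),
                            background = -1000, rayFactor = 2) {
  idx <- which(pair@mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 2L, 1L)
  hi <- pmin(apply(idx, 2, max) + 2L, dim(volume@voxels))
  sub <- volume@voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk <- pair@mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub[!msk] <- background
  subOrigin <- volume@origin + (lo - 1) * volume@spacing
  subDim <- dim(sub)
  corners <- as.matrix(expand.grid(
    x = subOrigin[1] + c(0, (subDim[1] - 1) * volume@spacing[1]),
    y = subOrigin[2] + c(0, (subDim[2] - 1) * volume@spacing[2]),
    z = subOrigin[3] + c(0, (subDim[3] - 1) * volume@spacing[3])))
  basis <- detectorBasis(geom)
  mode <- if (config@intensityMode == "binary_mask") 1L else 0L

  # both sides of the score are smoothed with one binomial pass before the
  # gradient: the synthetic (and clinical) edges are sharper than a pixel,
  # and without smoothing the correlation basin is narrower than the search
  # lattice; smoothing is symmetric so the peak stays at the true pose
  mkLevel <- function(img, rayStep, nblur, pad) {
    px <- img@pixels
    for (i in seq_len(nblur)) px <- blur3(px)
    e <- edgeMap(xrayImage(px, img@pixelSpacing, center = img@center), q)
    list(strength = e$strength, mask = e$mask, rayStep = rayStep,
         d = dim(img@pixels), cu = img@center[1], cv = img@center[2],
         ps = img@pixelSpacing, nblur = nblur, pad = pad)
  }
  # the ray step does NOT scale with the pyramid (a coarse step comparable
  # to the body thickness adds integration jitter that corrupts the
  # gradient field); the coarse level is smoothed harder and scored over a
  # wide context window so the lattice sees a basin wider than its step
  rs0 <- config@rayStep * rayFactor
  levels <- list(
    full = mkLevel(fluoro, rs0, 0L, 4L),
    fine = mkLevel(fluoro, rs0, 2L, 6L),
    mid = mkLevel(downsampleImage(fluoro, max(1L, pyramid %/% 2L)),
                  rs0, 2L, 8L),
    coarse = mkLevel(downsampleImage(fluoro, pyramid), rs0, 3L, 12L))

  evalScore <- function(v, level = "full") {
    lv <- levels[[level]]
    pad <- lv$pad
    R <- rotationMatrix(v[4:6])
    pc <- sweep(corners, 2, center) %*% t(R) * v[7]
    pc <- sweep(pc, 2, center + v[1:3], FUN = "+")
    rel <- sweep(pc, 2, basis$source)
    depth <- as.numeric(rel %*% basis$dhat)
    if (any(depth <= 1)) return(0)
    t <- geom@sdd / depth
    foot <- rel * t
    pu <- as.numeric(foot %*% basis$uhat) / lv$ps + lv$cu
    pv <- as.numeric(foot %*% basis$vhat) / lv$ps + lv$cv
    u0 <- max(1, floor(min(pu)) - pad); u1 <- min(lv$d[1], ceiling(max(pu)) + pad)
    v0 <- max(1, floor(min(pv)) - pad); v1 <- min(lv$d[2], ceiling(max(pv)) + pad)
    if (u0 > u1 || v0 > v1) return(0)
    # fused render + blur + gradient + correlation in C++. The pyramid
    # levels rank poses by gradient correlation over the wide context
    # window (at the pyramid pixel size the percentile masks are a handful
    # of pixels and the union-restricted correlation degenerates); the full
    # level computes the reported edge-mask similarity score.
    .scoreDRRcpp(sub, volume@spacing, subOrigin, basis$source,
                 basis$detectorCenter, basis$uhat, basis$vhat,
                 lv$cu, lv$cv, lv$ps, u0, u1, v0, v1,
                 v[1:3], v[4:6], v[7], center, lv$rayStep, mode,
                 config@huFloor, lv$strength, lv$mask, lv$nblur,
                 if (level == "full") 1L else 0L, q / 100)
  }
  list(center = center, basis = basis, evalScore = evalScore)
}

latticeAxis <- function(range, step) {
  if (range[2] <= range[1]) return(range[1])
  seq(range[1], range[2], by = step)
}

nominalValue <- function(range) {
  if (range[1] <= 0 && range[2] >= 0) 0 else mean(range)
}

# Variable step-size coordinate descent: cycle the seven parameters, probe
# +/- the current step (walking while the score strictly improves), shrink
# all steps multiplicatively after a cycle without improvement, stop at the
# minimum steps or the evaluation budget. Shared by the local phase (full
# resolution) and the pyramid polish at the end of the global phase.
coordinateDescent <- function(evalFn, start, steps, minVec, rng, shrink,
                              maxEvals, startScore = NULL) {
  cur <- start
  curScore <- if (is.null(startScore)) evalFn(cur) else startScore
  evals <- if (is.null(startScore)) 1L else 0L
  trace <- list()
  repeat {
    improved <- FALSE
    for (j in seq_along(cur)) {
      for (dir in c(1, -1)) {
        repeat {
          cand <- cur
          cand[j] <- cand[j] + dir * steps[j]
          if (cand[j] < rng[[j]][1] - 1e-12 || cand[j] > rng[[j]][2] + 1e-12)
            break
          s <- evalFn(cand)
          evals <- evals + 1L
          if (s > curScore) {
            cur <- cand; curScore <- s; improved <- TRUE
            trace[[length(trace) + 1]] <- data.frame(
              parameter = PARAM_NAMES[j], step = dir * steps[j],
              value = cand[j], score = s)
          } else break
          if (evals >= maxEvals) break
        }
        if (evals >= maxEvals) break
      }
      if (evals >= maxEvals) break
    }
    if (evals >= maxEvals) break
    if (!improved) {
      newSteps <- steps * shrink
      if (all(newSteps < minVec)) break
      steps <- pmax(newSteps, minVec)
    }
  }
  traceDf <- if (length(trace)) do.call(rbind, trace) else
    data.frame(parameter = character(0), step = numeric(0),
               value = numeric(0), score = numeric(0))
  list(par = cur, score = curScore, evals = evals, trace = traceDf)
}

expandSteps <- function(triple) {
  c(triple[1], triple[1], triple[1], triple[2], triple[2], triple[2], triple[3])
}

# Full-factorial pose grid, ordered lexicographically (Tx most significant)
# so the first strict maximum is the lexicographically smallest tie-winner.
factorialGrid <- function(axes) {
  g <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, rev(seq_along(axes)), drop = FALSE])
}

#' Global lattice search over vertebra pairs
#'
#' The global phase anchors the column first: the similarity score of the
#' whole segmented column is evaluated on a coarse lattice over the search
#' bounds (ranges discretised by the global steps, deterministic
#' lexicographic order) at a downsampled pyramid level, using separable
#' sweeps (translations at the nominal rotation/scale, rotations at the
#' best translation, translations again, then the scale axis) whenever the
#' full factorial lattice exceeds `maxEvaluations`. The column envelope is
#' aperiodic, which resolves the vertebra-counting ambiguity a single pair
#' cannot. The lattice winner is polished by coordinate descent on the
#' smoothed coarse score, and each pair is then refined from that anchor at
#' the mid pyramid level and re-scored at full resolution. Results are
#' returned sorted by score (descending), ties broken by pair order
#' T12-L1 < L2-L3 < L4-L5.
#'
#' @param pairs list of [VertebraPair-class].
#' @param volume the [CTVolume-class].
#' @param fluoro the [XRayImage-class] frame.
#' @param geom the [CArmGeometry-class].
#' @param bounds a [SearchBounds-class].
#' @param seed integer seed (recorded in provenance; the search itself is
#'   deterministic).
#' @param config a [ProjectionConfig-class].
#' @param q edge-mask percentile.
#' @param pyramid integer downsampling factor for lattice scoring.
#' @param angleSweep optional vector of primary angles (degrees) to sweep
#'   when the acquisition angulation is unknown; the best angle is chosen
#'   on the column anchor and recorded in provenance.
#' @return List of [RegistrationResult-class], phase "global", ranked.
#' @export
globalSearch <- function(pairs, volume, fluoro, geom, bounds = defaultSearchBounds(),
                         seed = 1, config = projectionConfig(), q = 85,
                         pyramid = 4, angleSweep = NULL) {
  if (!length(pairs)) stop("global search needs at least one vertebra pair")
  rng <- boundsRanges(bounds)
  st <- bounds@globalSteps
  stepFor <- c(st[1], st[1], st[1], st[2], st[2], st[2], st[3])
  axes <- lapply(seq_along(rng), function(i) latticeAxis(rng[[i]], stepFor[i]))
  names(axes) <- PARAM_NAMES
  total <- prod(lengths(axes))
  if (total == 0) stop("empty search lattice; check bounds and steps")
  geoms <- if (is.null(angleSweep)) list(geom) else {
    lapply(angleSweep, function(a) cArmGeometry(geom@sid, geom@sdd, a,
                                                geom@secondaryAngle))
  }

  # column pseudo-pair: union of the pair masks, used as the lattice anchor
  colMask <- Reduce(`|`, lapply(pairs, function(p) p@mask))
  idx <- which(colMask, arr.ind = TRUE)
  colPair <- new("VertebraPair", label = "column",
                 members = c(pairs[[1]]@members[1],
                             pairs[[length(pairs)]]@members[2]),
                 mask = colMask,
                 centroid = volume@origin + (colMeans(idx) - 1) * volume@spacing,
                 landmarks = list())

  latticeStage <- function(ctx, g) {
    best <- NULL; bestScore <- -Inf
    nEv <- 0L
    if (total <= bounds@maxEvaluations) {
      grid <- factorialGrid(axes)
      for (r in seq_len(nrow(grid))) {
        s <- ctx$evalScore(grid[r, ], "coarse")
        nEv <- nEv + 1L
        if (s > bestScore) { bestScore <- s; best <- grid[r, ] }
      }
    } else {
      # separable sweeps under the evaluation budget; the translation axis
      # most aligned with the ray (depth) is sampled 4x coarser since it is
      # weakly observable from one view
      nom <- vapply(rng, nominalValue, numeric(1))
      depthAxis <- which.max(abs(detectorBasis(g)$dhat))
      inplane <- setdiff(1:3, depthAxis)
      tAxes <- lapply(1:3, function(i) latticeAxis(rng[[i]], stepFor[i]))
      nT <- prod(lengths(tAxes[inplane]))
      budget <- max(1, floor(0.4 * bounds@maxEvaluations / length(geoms)))
      if (nT > budget) {
        f <- ceiling(sqrt(nT / budget))
        tAxes[inplane] <- lapply(inplane, function(i)
          latticeAxis(rng[[i]], stepFor[i] * f))
      }
      gridT <- factorialGrid(tAxes[inplane])
      # translations staged: the in-plane pair factorial at the nominal
      # depth, then the depth axis alone (depth only rescales the
      # projection and is weakly observable from one view)
      sweepT <- function(rot, depth0) {
        bT <- rep(NA_real_, 3)
        bT[depthAxis] <- depth0
        bS <- -Inf
        for (r in seq_len(nrow(gridT))) {
          cand <- bT; cand[inplane] <- gridT[r, ]
          s <- ctx$evalScore(c(cand, rot), "coarse")
          nEv <<- nEv + 1L
          if (s > bS) { bS <- s; bT[inplane] <- gridT[r, ] }
        }
        for (dv in tAxes[[depthAxis]]) {
          cand <- bT; cand[depthAxis] <- dv
          s <- ctx$evalScore(c(cand, rot), "coarse")
          nEv <<- nEv + 1L
          if (s > bS) { bS <- s; bT[depthAxis] <- dv }
        }
        list(t = bT, s = bS)
      }
      swA <- sweepT(nom[4:7], nom[depthAxis])
      # rotations are scored at the mid level (the heavily smoothed coarse
      # level cannot separate mirror-image out-of-plane tilts). Because an
      # out-of-plane tilt and a translation error compensate each other,
      # the sweep winner and its out-of-plane mirror images all serve as
      # descent starts; every descended optimum is kept as an anchor.
      gridR <- factorialGrid(axes[4:6])
      rotScores <- numeric(nrow(gridR))
      for (r in seq_len(nrow(gridR))) {
        rotScores[r] <- ctx$evalScore(c(swA$t, gridR[r, ], nom[7]), "mid")
        nEv <- nEv + 1L
      }
      ordR <- order(-rotScores)
      rstar <- gridR[ordR[1], ]
      dh <- abs(detectorBasis(g)$dhat)
      outAx <- which(dh < 0.7)  # rotation axes not parallel to the ray
      combos <- factorialGrid(rep(list(c(1, -1)), length(outAx)))
      starts <- list()
      for (ci in seq_len(nrow(combos))) {
        cand <- rstar
        cand[outAx] <- cand[outAx] * combos[ci, ]
        for (j in seq_len(3)) {
          cand[j] <- min(max(cand[j], rng[[3 + j]][1]), rng[[3 + j]][2])
        }
        if (!any(vapply(starts, function(s0) max(abs(s0 - cand)) < 1,
                        logical(1)))) {
          starts[[length(starts) + 1]] <- cand
        }
      }
      anchors <- list()
      minV <- expandSteps(bounds@minSteps)
      for (s0 in starts) {
        cdm <- coordinateDescent(function(v) ctx$evalScore(v, "mid"),
                                 c(swA$t, s0, nom[7]),
                                 expandSteps(bounds@localSteps) * 2,
                                 pmax(expandSteps(bounds@localSteps) / 8, minV),
                                 rng, bounds@shrinkFactor,
                                 bounds@maxEvaluations)
        nEv <- nEv + cdm$evals
        anchors[[length(anchors) + 1]] <- list(par = cdm$par, score = cdm$score)
      }
      ordA <- order(-vapply(anchors, function(a) a$score, numeric(1)))
      anchors <- anchors[ordA]
      best <- anchors[[1]]$par
      bestScore <- anchors[[1]]$score
    }
    list(par = best, score = bestScore, evals = nEv,
         anchors = if (exists("anchors", inherits = FALSE)) anchors else
           list(list(par = best, score = bestScore)))
  }

  # column anchors (with optional primary-angle sweep)
  minV <- expandSteps(bounds@minSteps)
  anchors <- NULL; anchorScore <- -Inf; anchorEvals <- 0L
  bestAngle <- geom@primaryAngle
  for (g in geoms) {
    colCtx <- makePairContext(colPair, volume, fluoro, g, config, q, pyramid,
                              rayFactor = 4)
    lt <- latticeStage(colCtx, g)
    anchorEvals <- anchorEvals + lt$evals
    if (lt$score > anchorScore) {
      anchorScore <- lt$score
      anchors <- lt$anchors[seq_len(min(2L, length(lt$anchors)))]
      bestAngle <- g@primaryAngle
    }
  }
  gBest <- if (is.null(angleSweep)) geom else
    cArmGeometry(geom@sid, geom@sdd, bestAngle, geom@secondaryAngle)

  # per pair: refine from each retained column anchor at the mid level and
  # keep the candidate with the better full-resolution score
  results <- vector("list", length(pairs))
  for (pi in seq_along(pairs)) {
    pair <- pairs[[pi]]
    ctx <- makePairContext(pair, volume, fluoro, gBest, config, q, pyramid)
    bestPar <- NULL; bestFull <- -Inf; pEvals <- 0L
    for (a in anchors) {
      cd <- coordinateDescent(function(v) ctx$evalScore(v, "mid"), a$par,
                              expandSteps(bounds@localSteps) * 2,
                              pmax(expandSteps(bounds@localSteps) / 8, minV),
                              rng, bounds@shrinkFactor, bounds@maxEvaluations)
      fullScore <- ctx$evalScore(cd$par, "full")
      pEvals <- pEvals + cd$evals + 1L
      if (fullScore > bestFull) { bestFull <- fullScore; bestPar <- cd$par }
    }
    results[[pi]] <- new("RegistrationResult", phase = "global",
                         pairLabel = pair@label,
                         params = vectorToParams(bestPar),
                         score = bestFull, feasible = NA,
                         manualAdjustmentNeeded = FALSE,
                         evaluations = anchorEvals + pEvals,
                         trace = data.frame(),
                         provenance = list(seed = seed, pyramid = pyramid,
                                           primaryAngle = bestAngle))
  }
  labs <- vapply(results, function(r) r@pairLabel, "")
  ord <- order(-vapply(results, function(r) r@score, numeric(1)),
               match(labs, names(PAIR_DEFS)), seq_along(results))
  results[ord]
}

#' Local variable step-size refinement
#'
#' Coordinate descent over (Tx, Ty, Tz, Rx, Ry, Rz, scale): each parameter
#' is probed at plus/minus the current step (walking repeatedly while the
#' score strictly improves); after a full cycle without improvement all
#' steps shrink by the shrink factor, stopping at the minimum steps or the
#' evaluation budget. The returned score never falls below the start score.
#'
#' @param start a [RegistrationResult-class] (e.g. the top global result).
#' @param pair the [VertebraPair-class] the start refers to.
#' @param volume,fluoro,geom as in [globalSearch()].
#' @param bounds a [SearchBounds-class]; the start must lie inside.
#' @param config,q rendering and edge parameters (keep identical to the
#'   global phase so scores are comparable).
#' @return A [RegistrationResult-class], phase "local", with the accepted
#'   move log in `trace`.
#' @export
localRefine <- function(start, pair, volume, fluoro, geom,
                        bounds = defaultSearchBounds(),
                        config = projectionConfig(), q = 85) {
  v <- paramsToVector(start@params)
  if (!withinBounds(v, bounds)) stop("start pose lies outside the search bounds")
  rng <- boundsRanges(bounds)
  ls <- bounds@localSteps
  steps <- c(ls[1], ls[1], ls[1], ls[2], ls[2], ls[2], ls[3])
  minVec <- c(bounds@minSteps[1], bounds@minSteps[1], bounds@minSteps[1],
              bounds@minSteps[2], bounds@minSteps[2], bounds@minSteps[2],
              bounds@minSteps[3])
  ctx <- makePairContext(pair, volume, fluoro, geom, config, q)
  # two-stage local phase: descend the smoothed full-resolution gradient
  # correlation first (wide, well-conditioned), then sharpen on the
  # edge-mask similarity score the result is reported with
  cdA <- coordinateDescent(function(x) ctx$evalScore(x, "fine"), v, steps,
                           pmax(minVec, steps / 64), rng,
                           bounds@shrinkFactor, bounds@maxEvaluations)
  cdB <- coordinateDescent(function(x) ctx$evalScore(x, "full"), cdA$par,
                           steps / 2, minVec, rng, bounds@shrinkFactor,
                           bounds@maxEvaluations)
  # second V-cycle: a further smoothed pass at reduced steps un-sticks
  # plateau stalls of the sharp edge-mask score
  cdA2 <- coordinateDescent(function(x) ctx$evalScore(x, "fine"), cdB$par,
                            steps / 2, pmax(minVec, steps / 64), rng,
                            bounds@shrinkFactor, bounds@maxEvaluations)
  cdB2 <- coordinateDescent(function(x) ctx$evalScore(x, "full"), cdA2$par,
                            steps / 4, minVec, rng, bounds@shrinkFactor,
                            bounds@maxEvaluations)
  evals <- cdA$evals + cdB$evals + cdA2$evals + cdB2$evals
  cd <- if (cdB2$score >= cdB$score) cdB2 else cdB
  if (!is.na(start@score) && cdB$score < start@score) {
    # the smoothed stage wandered; fall back to pure ascent from the start
    cdC <- coordinateDescent(function(x) ctx$evalScore(x, "full"), v, steps,
                             minVec, rng, bounds@shrinkFactor,
                             bounds@maxEvaluations)
    evals <- evals + cdC$evals
    if (cdC$score > cdB$score) cd <- cdC
  }
  new("RegistrationResult", phase = "local", pairLabel = start@pairLabel,
      params = vectorToParams(cd$par),
      score = if (is.na(start@score)) cd$score else max(cd$score, start@score),
      feasible = start@feasible,
      manualAdjustmentNeeded = start@manualAdjustmentNeeded,
      evaluations = evals, trace = cd$trace,
      provenance = start@provenance)
}

#' Edge-visibility feasibility check
#'
#' Projects the pair's mask silhouette at the given pose onto the frame and
#' requires every silhouette boundary pixel to lie at least `marginPx`
#' inside the image bounds (and the silhouette to be non-empty). A failure
#' reproduces the clinical "manual adjustment needed" state: automatic
#' registration proceeds only from a user-supplied initial pose.
#'
#' @param pair a [VertebraPair-class].
#' @param volume the [CTVolume-class].
#' @param fluoroTemplate the frame (grid and centre define the field of view).
#' @param geom the [CArmGeometry-class].
#' @param pose the pose to check (typically the selected global pose).
#' @param marginPx margin in pixels (default 2).
#' @return Logical feasibility flag.
#' @export
checkVisibility <- function(pair, volume, fluoroTemplate, geom, pose,
                            marginPx = 2, center = volumeCenter(volume)) {
  maskVol <- ctVolume(array(as.numeric(pair@mask), dim = dim(pair@mask)),
                      spacing = volume@spacing, origin = volume@origin)
  sil <- projectSilhouette(maskVol, geom, pose, fluoroTemplate,
                           center = center,
                           rayStep = min(volume@spacing))
  if (!nrow(sil$boundary)) return(FALSE)
  d <- dim(fluoroTemplate@pixels)
  b <- sil$boundary
  all(b[, 1] > marginPx & b[, 1] <= d[1] - marginPx &
      b[, 2] > marginPx & b[, 2] <= d[2] - marginPx)
}

#' End-to-end registration pipeline
#'
#' Segments bone, labels vertebrae, forms the pairs, runs the global lattice
#' search, applies the visibility check to the top-ranked pair, and refines
#' locally. When the visibility check fails, automatic registration stops
#' ("manual adjustment needed") unless an initial pose is supplied, in which
#' case the local phase starts from it (the programmatic analogue of a
#' manual global match).
#'
#' @param volume a [CTVolume-class].
#' @param fluoro an [XRayImage-class].
#' @param geom a [CArmGeometry-class].
#' @param bounds a [SearchBounds-class].
#' @param seed integer seed (provenance).
#' @param initialPose optional [AffineParams-class] fallback start.
#' @param config a [ProjectionConfig-class].
#' @param huThreshold bone segmentation threshold, HU.
#' @param q edge-mask percentile.
#' @param pyramid global-phase downsampling factor.
#' @param marginPx visibility margin, pixels.
#' @param angleSweep optional primary-angle sweep, degrees.
#' @return List with `status` ("ok" or "manual_adjustment_needed"), `global`
#'   (ranked global results), `final` (local [RegistrationResult-class] or
#'   NULL), `labeling` and `pairs`.
#' @export
registerCase <- function(volume, fluoro, geom, bounds = defaultSearchBounds(),
                         seed = 1, initialPose = NULL,
                         config = projectionConfig(), huThreshold = 200,
                         q = 85, pyramid = 4, marginPx = 2,
                         angleSweep = NULL) {
  mask <- segmentBone(volume, huThreshold)
  labeling <- labelVertebrae(mask, volume)
  pairs <- makePairs(labeling, volume)
  if (!length(pairs)) stop("no vertebra pairs found; cannot register")
  globalRes <- globalSearch(pairs, volume, fluoro, geom, bounds, seed,
                            config, q, pyramid, angleSweep)
  top <- globalRes[[1]]
  pair <- pairs[[match(top@pairLabel, vapply(pairs, function(p) p@label, ""))]]
  feasible <- checkVisibility(pair, volume, fluoro, geom, top@params, marginPx)
  top@feasible <- feasible
  top@manualAdjustmentNeeded <- !feasible
  globalRes[[1]] <- top
  if (!feasible && is.null(initialPose)) {
    return(list(status = "manual_adjustment_needed", global = globalRes,
                final = NULL, labeling = labeling, pairs = pairs))
  }
  startRes <- top
  if (!feasible) {
    startRes <- new("RegistrationResult", phase = "global",
                    pairLabel = top@pairLabel, params = initialPose,
                    score = NA_real_, feasible = FALSE,
                    manualAdjustmentNeeded = TRUE, evaluations = 0,
                    trace = data.frame(), provenance = top@provenance)
  }
  final <- localRefine(startRes, pair, volume, fluoro, geom, bounds, config, q)
  list(status = "ok", global = globalRes, final = final, labeling = labeling,
       pairs = pairs)
}
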