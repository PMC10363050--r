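# Shared fixtures, built once per test run and memoised. The small phantom
# (three vertebrae, 1.5 mm voxels, 256 px detector) keeps the registration
# unit tests fast; the acceptance tests build full-size cases themselves.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

smallSpec <- function(seed = 11) {
  spinePhantomSpec(nVertebrae = 3, volumeShape = c(64, 64, 96),
                   voxelSpacing = c(1.5, 1.5, 1.5), seed = seed)
}

smallTemplate <- function() defaultFluoroTemplate(n = 256, pixelSpacing = 1)

smallPhantom <- function() memo("smallPhantom", function() {
  buildSpinePhantom(smallSpec())
})

smallTruePose <- function() affineParams(c(6, 10, -5), c(3, -2, 2), 1.005)

smallCase <- function() memo("smallCase", function() {
  simulateCase(smallPhantom(), buildVesselTree(seed = 12), smallTruePose(),
               cArmGeometry(), orificeDisplacement = 4, seed = 11,
               template = smallTemplate())
})

smallSegmentation <- function() memo("smallSegmentation", function() {
  case <- smallCase()
  mask <- segmentBone(case@volume, 200)
  lab <- labelVertebrae(mask, case@volume)
  list(mask = mask, labeling = lab,
       pairs = makePairs(lab, case@volume, smallPhantom()$landmarks))
})

fullPhantom <- function() memo("fullPhantom", function() {
  buildSpinePhantom(spinePhantomSpec(seed = 3))
})

# independent flood-fill component counter (6-connectivity queue BFS),
# deliberately separate from the package's compiled labelling
floodFillCount <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  idx <- which(mask)
  count <- 0L
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  for (start in idx) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k <- (cur - 1) %/% (d[1] * d[2])
      r <- (cur - 1) %% (d[1] * d[2])
      co <- cbind(r %% d[1] + 1, r %/% d[1] + 1, k + 1)
      for (o in seq_len(nrow(off))) {
        nb <- co + off[o, ]
        if (any(nb < 1) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (mask[li] && !seen[li]) {
          seen[li] <- TRUE
          queue <- c(queue, li)
        }
      }
    }
  }
  count
}

# 4x4 homogeneous-matrix oracle for the affine pose, built independently
homogeneousOracle <- function(params, point, center) {
  deg <- pi / 180
  r <- params@rotation * deg
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  S <- diag(3) * params@scale
  M <- diag(4)
  M[1:3, 1:3] <- (Rz %*% Ry %*% Rx) %*% S
  M[1:3, 4] <- center + params@translation - M[1:3, 1:3] %*% center
  as.numeric((M %*% c(point, 1))[1:3])
}

# exhaustive-enumeration Mann-Whitney oracle (independent of the package)
enumMWOracle <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- combn(length(r), n1)
  Us <- apply(sets, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
}
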