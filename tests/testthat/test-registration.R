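test_that("similarity score is maximal against itself and guards its inputs", {
  case <- smallCase()
  img <- case@fluoro
  expect_equal(similarityScore(img, img), 1.0, tolerance = 1e-12)
  other <- xrayImage(matrix(0, 10, 10), pixelSpacing = 2)
  expect_error(similarityScore(img, other), "pixel grid")
  flat <- xrayImage(matrix(1, 64, 64), pixelSpacing = 1)
  expect_equal(similarityScore(flat, flat), 0)  # constant images score 0
})

test_that("independent noise images never score as similar", {
  # restricting the correlation to the union of the percentile edge masks
  # biases the score of *independent* fields negative (each image is large
  # on its own mask pixels and typical on the other's), so the property to
  # guard is the absence of spurious positive similarity
  set.seed(61)
  for (i in 1:20) {
    a <- xrayImage(matrix(rnorm(64 * 64), 64, 64), pixelSpacing = 1)
    b <- xrayImage(matrix(rnorm(64 * 64), 64, 64), pixelSpacing = 1)
    s <- similarityScore(a, b)
    expect_lt(s, 0.1)
    expect_gt(s, -1)
  }
})

test_that("the score peaks at the true pose", {
  case <- smallCase()
  geom <- case@geometry
  tpl <- smallTemplate()
  ctr <- volumeCenter(case@volume)
  atTruth <- renderDRR(case@volume, geom, case@truePose, projectionConfig(),
                       tpl, center = ctr)
  s0 <- similarityScore(atTruth, case@fluoro)
  set.seed(62)
  for (i in 1:20) {
    dir <- rnorm(3); dir <- 10 * dir / sqrt(sum(dir^2))  # 10 mm displacement
    off <- affineParams(case@truePose@translation + dir,
                        case@truePose@rotation, case@truePose@scale)
    drr <- renderDRR(case@volume, geom, off, projectionConfig(), tpl,
                     center = ctr)
    expect_lt(similarityScore(drr, case@fluoro), s0)
  }
})

collapsedBounds <- function(pose) {
  v <- c(pose@translation, pose@rotation, pose@scale)
  searchBounds(txRange = rep(v[1], 2), tyRange = rep(v[2], 2),
               tzRange = rep(v[3], 2), rxRange = rep(v[4], 2),
               ryRange = rep(v[5], 2), rzRange = rep(v[6], 2),
               scaleRange = rep(v[7], 2))
}

test_that("a lattice collapsed onto the true pose returns it unchanged", {
  case <- smallCase()
  seg <- smallSegmentation()
  res <- globalSearch(seg$pairs, case@volume, case@fluoro, case@geometry,
                      collapsedBounds(case@truePose), seed = 1)
  top <- res[[1]]
  expect_equal(top@params@translation, case@truePose@translation)
  expect_equal(top@params@rotation, case@truePose@rotation)
  expect_gt(top@score, 0.25)
})

test_that("equal-scoring pairs are ranked in the fixed pair order", {
  case <- smallCase()
  seg <- smallSegmentation()
  p <- seg$pairs[[1]]
  twin <- new("VertebraPair", label = "L2-L3", members = c("L2", "L3"),
              mask = p@mask, centroid = p@centroid, landmarks = list())
  res <- globalSearch(list(twin, p), case@volume, case@fluoro, case@geometry,
                      collapsedBounds(case@truePose), seed = 1)
  expect_equal(res[[1]]@score, res[[2]]@score)
  expect_equal(res[[1]]@pairLabel, "T12-L1")
})

test_that("local refinement recovers a displaced start and logs its ascent", {
  case <- smallCase()
  seg <- smallSegmentation()
  pair <- seg$pairs[[1]]
  start <- affineParams(case@truePose@translation + c(4, 0, 3),
                        case@truePose@rotation + c(0, 3, 0),
                        case@truePose@scale)
  sres <- new("RegistrationResult", phase = "global", pairLabel = pair@label,
              params = start, score = NA_real_, feasible = NA,
              manualAdjustmentNeeded = FALSE, evaluations = 0,
              trace = data.frame(), provenance = list())
  out <- localRefine(sres, pair, case@volume, case@fluoro, case@geometry)
  expect_lt(poseInPlaneError(out@params, case@truePose, pair@centroid,
                             case@geometry, volumeCenter(case@volume)), 1)
  expect_lt(poseRotationError(out@params, case@truePose, case@geometry), 0.5)
  # accepted moves strictly increase the score
  expect_true(all(diff(out@trace$score) > 0))

  # refining again from the optimum keeps the score and barely moves
  out@feasible <- TRUE
  again <- localRefine(out, pair, case@volume, case@fluoro, case@geometry)
  expect_gte(again@score, out@score)
  expect_lt(poseInPlaneError(again@params, out@params, pair@centroid,
                             case@geometry, volumeCenter(case@volume)), 0.5)

  far <- affineParams(c(1000, 0, 0))
  sres@params <- far
  expect_error(localRefine(sres, pair, case@volume, case@fluoro,
                           case@geometry), "outside")
})

test_that("restricted two-parameter refinement matches exhaustive search", {
  case <- smallCase()
  seg <- smallSegmentation()
  pair <- seg$pairs[[1]]
  tp <- case@truePose
  v <- c(tp@translation, tp@rotation, tp@scale)
  b <- searchBounds(txRange = v[1] + c(-1, 1), tyRange = rep(v[2], 2),
                    tzRange = v[3] + c(-1, 1), rxRange = rep(v[4], 2),
                    ryRange = rep(v[5], 2), rzRange = rep(v[6], 2),
                    scaleRange = rep(v[7], 2))
  start <- new("RegistrationResult", phase = "global", pairLabel = pair@label,
               params = affineParams(tp@translation + c(-1, 0, 1),
                                     tp@rotation, tp@scale),
               score = NA_real_, feasible = NA,
               manualAdjustmentNeeded = FALSE, evaluations = 0,
               trace = data.frame(), provenance = list())
  out <- localRefine(start, pair, case@volume, case@fluoro, case@geometry, b)
  ctx <- autofuse:::makePairContext(pair, case@volume, case@fluoro,
                                    case@geometry, projectionConfig())
  grid <- expand.grid(tx = seq(v[1] - 1, v[1] + 1, 0.1),
                      tz = seq(v[3] - 1, v[3] + 1, 0.1))
  scores <- apply(grid, 1, function(g)
    ctx$evalScore(c(g[1], v[2], g[2], v[4:7]), "full"))
  # matching at minimum-step resolution: the refined score may sit within
  # one plateau quantum of the best grid node
  expect_gte(out@score, max(scores) - 0.01)
})

test_that("the visibility check flags border-crossing pairs", {
  case <- smallCase()
  seg <- smallSegmentation()
  pair <- seg$pairs[[1]]
  ok <- checkVisibility(pair, case@volume, case@fluoro, case@geometry,
                        case@truePose)
  expect_true(ok)
  trunc <- simulateCase(smallPhantom(), buildVesselTree(seed = 12),
                        smallTruePose(), cArmGeometry(), seed = 11,
                        truncationFraction = 0.3, template = smallTemplate())
  bad <- checkVisibility(pair, trunc@volume, trunc@fluoro, trunc@geometry,
                         trunc@truePose)
  expect_false(bad)
})

test_that("register() honours the manual-adjustment contract", {
  trunc <- simulateCase(smallPhantom(), buildVesselTree(seed = 12),
                        smallTruePose(), cArmGeometry(), seed = 11,
                        truncationFraction = 0.3, template = smallTemplate())
  reg <- registerCase(trunc@volume, trunc@fluoro, trunc@geometry, seed = 1)
  expect_equal(reg$status, "manual_adjustment_needed")
  expect_null(reg$final)
  expect_true(reg$global[[1]]@manualAdjustmentNeeded)

  # supplying the true pose as the manual initialisation rescues the case
  reg2 <- registerCase(trunc@volume, trunc@fluoro, trunc@geometry, seed = 1,
                       initialPose = trunc@truePose)
  expect_equal(reg2$status, "ok")
  expect_true(reg2$final@manualAdjustmentNeeded)
  pair <- reg2$pairs[[match(reg2$final@pairLabel,
                            vapply(reg2$pairs, function(p) p@label, ""))]]
  expect_lt(poseInPlaneError(reg2$final@params, trunc@truePose, pair@centroid,
                             trunc@geometry, volumeCenter(trunc@volume)), 1)
})

test_that("end-to-end registration recovers the small-case pose", {
  case <- smallCase()
  reg <- registerCase(case@volume, case@fluoro, case@geometry, seed = 5)
  expect_equal(reg$status, "ok")
  expect_gte(reg$final@score, reg$global[[1]]@score)
  pair <- reg$pairs[[match(reg$final@pairLabel,
                           vapply(reg$pairs, function(p) p@label, ""))]]
  expect_lt(poseInPlaneError(reg$final@params, case@truePose, pair@centroid,
                             case@geometry, volumeCenter(case@volume)), 1)
  expect_lt(poseRotationError(reg$final@params, case@truePose,
                              case@geometry), 0.5)
  # determinism: the identical call reproduces the identical result
  reg2 <- registerCase(case@volume, case@fluoro, case@geometry, seed = 5)
  expect_identical(paramsToVec <- c(reg$final@params@translation,
                                    reg$final@params@rotation,
                                    reg$final@params@scale),
                   c(reg2$final@params@translation,
                     reg2$final@params@rotation, reg2$final@params@scale))
})
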