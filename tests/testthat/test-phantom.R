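test_that("phantom spec validity and empty column", {
  expect_error(spinePhantomSpec(boneHU = 30, softTissueHU = 40), "bone_hu")
  expect_error(spinePhantomSpec(vertebraPitch = -5), "geometric")
  empty <- buildSpinePhantom(spinePhantomSpec(nVertebrae = 0))
  expect_true(all(empty$volume@voxels == 40))
  expect_length(empty$landmarks, 0)
})

test_that("a column too large for the volume names the offending vertebra", {
  spec <- spinePhantomSpec(nVertebrae = 6, volumeShape = c(96, 96, 96),
                           voxelSpacing = c(1, 1, 0.9))
  expect_error(buildSpinePhantom(spec), "T12")
})

test_that("phantom generation is deterministic per seed", {
  a <- buildSpinePhantom(smallSpec(seed = 21))
  b <- buildSpinePhantom(smallSpec(seed = 21))
  c <- buildSpinePhantom(smallSpec(seed = 22))
  expect_identical(a$volume@voxels, b$volume@voxels)
  expect_identical(a$landmarks, b$landmarks)
  expect_false(identical(a$volume@voxels, c$volume@voxels))
})

test_that("vessel trees resolve the lowest renal orifice deterministically", {
  t1 <- buildVesselTree(seed = 5)
  t2 <- buildVesselTree(seed = 5)
  expect_identical(t1@centerline, t2@centerline)
  expect_identical(t1@renalOrifices, t2@renalOrifices)
  z <- t1@renalOrifices[, 3]
  expect_equal(t1@lowestRenalIndex, which.min(z))
  expect_equal(buildVesselTree(nOrifices = 1, seed = 2)@lowestRenalIndex, 1L)
  expect_error(buildVesselTree(nOrifices = 0), "orifice")
  # regenerating ten trees bitwise-reproduces them
  for (s in 1:10) {
    expect_identical(buildVesselTree(seed = s), buildVesselTree(seed = s))
  }
})

test_that("manually misplaced orifices violate the vessel-tree validity", {
  t1 <- buildVesselTree(seed = 5)
  bad <- t1@renalOrifices
  bad[1, 1] <- bad[1, 1] + 50
  expect_error(new("VesselTree", centerline = t1@centerline,
                   aortaRadius = t1@aortaRadius, aneurysmRadius = 28,
                   renalOrifices = bad, orificeSides = t1@orificeSides,
                   orificeRadius = 3,
                   lowestRenalIndex = as.integer(which.min(bad[, 3]))),
               "aorta radius")
})

test_that("a noiseless untruncated case equals the DRR at the true pose", {
  case <- simulateCase(smallPhantom(), buildVesselTree(seed = 12),
                       smallTruePose(), cArmGeometry(), seed = 31,
                       template = smallTemplate())
  drr <- renderDRR(case@volume, case@geometry, case@truePose,
                   projectionConfig(), smallTemplate(),
                   center = volumeCenter(case@volume))
  expect_identical(case@fluoro@pixels, drr@pixels)
})

test_that("simulation is deterministic and validates truncation", {
  a <- smallCase()
  b <- simulateCase(smallPhantom(), buildVesselTree(seed = 12),
                    smallTruePose(), cArmGeometry(), orificeDisplacement = 4,
                    seed = 11, template = smallTemplate())
  expect_identical(a@fluoro@pixels, b@fluoro@pixels)
  expect_identical(a@dsaOrificePx, b@dsaOrificePx)
  expect_error(simulateCase(smallPhantom(), buildVesselTree(seed = 12),
                            truncationFraction = 1.2), "truncation")
})

test_that("pigtail markers are spaced 10 mm at the isocenter magnification", {
  case <- smallCase()
  px <- case@markerPointsPx
  d <- sqrt(rowSums(diff(px)^2))
  mag <- case@geometry@sdd / case@geometry@sid
  wantPx <- 10 * mag / case@fluoro@pixelSpacing
  expect_true(all(abs(d - wantPx) < 0.02 * wantPx))
})

test_that("truncation crops the stated fraction of the silhouette", {
  full <- simulateCase(smallPhantom(), buildVesselTree(seed = 12),
                       smallTruePose(), cArmGeometry(), seed = 11,
                       template = smallTemplate())
  trunc <- simulateCase(smallPhantom(), buildVesselTree(seed = 12),
                        smallTruePose(), cArmGeometry(), seed = 11,
                        truncationFraction = 0.25,
                        template = smallTemplate())
  expect_lt(nrow(trunc@fluoro@pixels), nrow(full@fluoro@pixels))
  # fraction of bright (bone) pixels removed is near the requested fraction
  thr <- max(full@fluoro@pixels) * 0.05
  nFull <- sum(full@fluoro@pixels > thr)
  cut <- nrow(full@fluoro@pixels) - nrow(trunc@fluoro@pixels)
  nKept <- sum(full@fluoro@pixels[-seq_len(cut), ] > thr)
  expect_lt(abs((nFull - nKept) / nFull - 0.25), 0.08)
})

test_that("the injected orifice displacement is recovered by measurement", {
  worst <- 0
  for (s in 1:20) {
    disp <- 1 + 13 * (s - 1) / 19
    case <- simulateCase(smallPhantom(), buildVesselTree(seed = 12),
                         smallTruePose(), cArmGeometry(),
                         orificeDisplacement = disp, seed = 100 + s,
                         template = smallTemplate())
    dv <- measureCase(case, case@truePose)@vascular
    worst <- max(worst, abs(dv - disp))
  }
  expect_lt(worst, 0.5)
})
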