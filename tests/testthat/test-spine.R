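test_that("segmentation threshold and size filter behave", {
  v <- ctVolume(array(40, c(10, 10, 10)), spacing = c(2, 2, 2))
  expect_false(any(segmentBone(v, 200)))

  case <- smallCase()
  mask <- segmentBone(case@volume, 200)
  expect_equal(floodFillCount(mask), 3)

  # sub-1-cm3 speckle is removed by the size filter
  vox <- case@volume@voxels
  vox[2, 2, 2] <- 900
  vox[2, 2, 3] <- 900
  noisy <- ctVolume(vox, case@volume@spacing, case@volume@origin)
  expect_equal(floodFillCount(segmentBone(noisy, 200)), 3)
  # without the size filter it would survive
  expect_equal(floodFillCount(segmentBone(noisy, 200, minComponentCm3 = 0)), 4)
})

test_that("vertebrae are labelled cranial to caudal with correct spacing", {
  seg <- smallSegmentation()
  lab <- seg$labeling
  expect_equal(lab$labels, c("T12", "L1", "L2"))
  z <- lab$centroids[, 3]
  expect_true(all(diff(z) < 0))  # most cranial first
  spec <- smallSpec()
  gaps <- -diff(z)
  expect_true(all(abs(gaps - spec@vertebraPitch) <=
                    spec@voxelSpacing[3] / 2 + 1e-9))
})

test_that("labelling handles truncated and empty columns", {
  case <- smallCase()
  v <- case@volume
  empty <- labelVertebrae(array(FALSE, dim(v@voxels)), v)
  expect_equal(empty$labels, character(0))

  two <- buildSpinePhantom(spinePhantomSpec(nVertebrae = 2,
                                            volumeShape = c(64, 64, 96),
                                            voxelSpacing = c(1.5, 1.5, 1.5)))
  lab2 <- labelVertebrae(segmentBone(two$volume, 200), two$volume)
  expect_equal(lab2$labels, c("T12", "L1"))
  expect_true(length(lab2$warnings) > 0)
})

test_that("labelling is invariant to craniocaudal translation", {
  case <- smallCase()
  v <- case@volume
  shifted <- ctVolume(v@voxels, v@spacing, v@origin + c(0, 0, 40))
  a <- labelVertebrae(segmentBone(v, 200), v)
  b <- labelVertebrae(segmentBone(shifted, 200), shifted)
  expect_equal(a$labels, b$labels)
  expect_equal(b$centroids[, 3] - a$centroids[, 3], rep(40, 3))
})

test_that("pairs follow the fixed pair plan and share no voxels", {
  full <- fullPhantom()
  lab <- labelVertebrae(segmentBone(full$volume, 200), full$volume)
  expect_equal(lab$labels, c("T12", "L1", "L2", "L3", "L4", "L5"))
  pairs <- makePairs(lab, full$volume, full$landmarks)
  expect_equal(vapply(pairs, function(p) p@label, ""),
               c("T12-L1", "L2-L3", "L4-L5"))
  overlap <- pairs[[1]]@mask & pairs[[2]]@mask | pairs[[1]]@mask & pairs[[3]]@mask |
    pairs[[2]]@mask & pairs[[3]]@mask
  expect_false(any(overlap))

  # a column missing L4-L5 yields only the first two pairs
  five <- buildSpinePhantom(spinePhantomSpec(nVertebrae = 5, seed = 4))
  lab5 <- labelVertebrae(segmentBone(five$volume, 200), five$volume)
  pairs5 <- makePairs(lab5, five$volume)
  expect_equal(vapply(pairs5, function(p) p@label, ""), c("T12-L1", "L2-L3"))
  expect_length(makePairs(list(labels = character(0)), full$volume), 0)
})

test_that("edge maps follow the finite-difference definition", {
  const <- xrayImage(matrix(5, 20, 20), pixelSpacing = 0.5)
  e <- edgeMap(const)
  expect_true(all(e$strength == 0))
  expect_false(any(e$mask))

  # vertical step of height h: central differences give h / (2 spacing)
  h <- 7
  ps <- 0.5
  px <- matrix(0, 30, 30)
  px[16:30, ] <- h
  e2 <- edgeMap(xrayImage(px, pixelSpacing = ps))
  expect_equal(max(e2$strength), h / (2 * ps))

  expect_error(edgeMap(const, q = 0), "q must")
})

test_that("edge mask is invariant to positive linear intensity rescaling", {
  set.seed(31)
  px <- matrix(runif(400), 20, 20)
  a <- edgeMap(xrayImage(px, 1), q = 80)
  b <- edgeMap(xrayImage(3.7 * px + 11, 1), q = 80)
  expect_identical(a$mask, b$mask)
})

test_that("edge mask cardinality tracks the percentile", {
  set.seed(32)
  px <- matrix(runif(90 * 90), 90, 90)
  e <- edgeMap(xrayImage(px, 1), q = 90)
  nz <- sum(e$strength > 0)
  expect_lt(abs(sum(e$mask) - 0.1 * nz), 0.01 * nz + 2)
})
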