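test_that("applyAffine handles identity and elementary rotations", {
  p <- c(3.2, -1.5, 7.9)
  expect_equal(applyAffine(identityPose(), p), p)
  q <- applyAffine(affineParams(rotation = c(0, 0, 90)), c(1, 0, 0))
  expect_equal(q, c(0, 1, 0), tolerance = 1e-12)
})

test_that("applyAffine matches a homogeneous-matrix oracle on random poses", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    par <- affineParams(translation = runif(3, -50, 50),
                        rotation = runif(3, -40, 40),
                        scale = runif(1, 0.8, 1.2))
    center <- runif(3, -30, 30)
    p <- runif(3, -100, 100)
    got <- applyAffine(par, p, center)
    want <- homogeneousOracle(par, p, center)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-9)
})

test_that("inverse parameters recover the start point", {
  set.seed(7)
  for (i in 1:20) {
    par <- affineParams(runif(3, -30, 30), runif(3, -30, 30), runif(1, 0.9, 1.1))
    center <- runif(3, -20, 20)
    p <- runif(3, -80, 80)
    back <- applyAffine(invertAffine(par, center), applyAffine(par, p, center),
                        center)
    expect_equal(back, p, tolerance = 1e-9)
  }
})

test_that("isotropic scale multiplies pairwise distances exactly", {
  set.seed(5)
  pts <- matrix(runif(30, -50, 50), 10, 3)
  s <- 1.07
  par <- affineParams(c(4, -2, 9), c(10, -5, 3), s)
  tp <- applyAffine(par, pts, center = c(1, 2, 3))
  expect_equal(as.numeric(dist(tp)), as.numeric(dist(pts)) * s,
               tolerance = 1e-12)
})

test_that("projectPoint obeys the magnification law", {
  geom <- cArmGeometry(sid = 800, sdd = 1200)
  expect_equal(unname(projectPoint(c(0, 0, 0), geom)), c(0, 0))
  expect_equal(unname(projectPoint(c(10, 0, 0), geom)), c(15, 0),
               tolerance = 1e-12)
  # doubling SDD at fixed SID doubles the projected offset
  g2 <- cArmGeometry(sid = 800, sdd = 2400)
  set.seed(3)
  for (i in 1:10) {
    p <- c(runif(2, -40, 40), 0)
    p <- c(p[1], 0, p[2])  # in the isocenter plane of the AP view
    expect_equal(unname(projectPoint(p, g2)),
                 2 * unname(projectPoint(p, geom)), tolerance = 1e-9)
  }
})

test_that("oblique projection matches a rotation-then-pinhole oracle", {
  geom <- cArmGeometry(sid = 780, sdd = 1190, primaryAngle = 30)
  ap <- cArmGeometry(sid = 780, sdd = 1190, primaryAngle = 0)
  rot <- function(p, a) {
    a <- a * pi / 180
    c(cos(a) * p[1] - sin(a) * p[2], sin(a) * p[1] + cos(a) * p[2], p[3])
  }
  set.seed(17)
  worst <- 0
  for (i in 1:50) {
    p <- runif(3, -80, 80)
    # LAO-30 view of p equals the AP view of the patient rotated by -30
    want <- projectPoint(rot(p, -30), ap)
    got <- projectPoint(p, geom)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-9)
})

test_that("rotating the volume equals counter-rotating the C-arm", {
  set.seed(23)
  alpha <- 12.5
  posed <- affineParams(rotation = c(0, 0, alpha))
  g0 <- cArmGeometry()
  gNeg <- cArmGeometry(primaryAngle = -alpha)
  for (i in 1:20) {
    p <- runif(3, -60, 60)
    expect_equal(projectPoint(applyAffine(posed, p), g0),
                 projectPoint(p, gNeg), tolerance = 1e-9)
  }
})

test_that("pose files round-trip and units are enforced", {
  f <- tempfile(fileext = ".json")
  writePose(identityPose(), f)
  expect_equal(readPose(f), identityPose())
  # clinically observed parameter extremes survive the round trip
  par <- affineParams(c(55.08, -140.39, -227.19), c(9.0, 10.78, 6.51), 1.0)
  writePose(par, f)
  got <- readPose(f)
  expect_equal(got@translation, c(55.08, -140.39, -227.19))
  expect_equal(got@rotation, c(9.0, 10.78, 6.51))

  bad <- jsonlite::read_json(f)
  bad$units$rotation <- "rad"
  jsonlite::write_json(bad, f, auto_unbox = TRUE)
  expect_error(readPose(f), "units")
  bad$units <- NULL
  jsonlite::write_json(bad, f, auto_unbox = TRUE)
  expect_error(readPose(f), "units")
})

test_that("geometry validity and file round trip", {
  expect_error(cArmGeometry(sid = 1300, sdd = 1200), "SID")
  f <- tempfile(fileext = ".json")
  g <- cArmGeometry(810, 1195, -30, 5)
  writeGeometry(g, f)
  g2 <- readGeometry(f)
  expect_equal(g2@sid, 810)
  expect_equal(g2@primaryAngle, -30)
})
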