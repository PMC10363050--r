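test_that("DRR of an empty volume is identically zero", {
  v <- ctVolume(array(0, c(10, 10, 10)), spacing = c(2, 2, 2))
  tpl <- xrayImage(matrix(0, 32, 32), pixelSpacing = 2)
  drr <- renderDRR(v, cArmGeometry(), identityPose(),
                   projectionConfig(huFloor = 0), tpl)
  expect_true(all(drr@pixels == 0))
})

test_that("a single bright voxel projects to its point projection", {
  vox <- array(0, c(21, 21, 21))
  vox[8, 12, 15] <- 5000
  v <- ctVolume(vox, spacing = c(2, 2, 2))
  geom <- cArmGeometry()
  tpl <- xrayImage(matrix(0, 128, 128), pixelSpacing = 1)
  drr <- renderDRR(v, geom, identityPose(), projectionConfig(huFloor = 0), tpl)
  world <- v@origin + (c(8, 12, 15) - 1) * v@spacing
  wantPx <- detectorToPixel(projectPoint(world, geom), tpl)
  gotPx <- which(drr@pixels == max(drr@pixels), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(gotPx - wantPx)), 1.0 + 0.5)
})

test_that("central slab integral matches the closed form", {
  n <- 40
  sp <- 1
  vox <- array(0, c(n, n, n))
  vox[11:30, 11:30, 11:30] <- 1150  # cube side 20 voxels
  v <- ctVolume(vox, spacing = rep(sp, 3))
  geom <- cArmGeometry()
  cfg <- projectionConfig(rayStep = 0.45, huFloor = 150)
  tpl <- xrayImage(matrix(0, 9, 9), pixelSpacing = 0.5)
  drr <- renderDRR(v, geom, identityPose(), cfg, tpl)
  centre <- drr@pixels[5, 5]
  L <- 20 * sp  # trilinear ramp adds half a voxel each side
  expect_equal(centre, L * (1150 - 150) / 1000, tolerance = 2 * cfg@rayStep / L)
})

test_that("sphere silhouette is a magnified disc and boundary is contained", {
  n <- 33
  sp <- 2
  grid <- ((1:n) - (n + 1) / 2) * sp
  r <- 20
  m <- array(0, c(n, n, n))
  for (k in 1:n) m[, , k] <- outer(grid^2, grid^2, "+") + grid[k]^2 <= r^2
  mask <- ctVolume(m, spacing = rep(sp, 3))
  geom <- cArmGeometry(sid = 800, sdd = 1200)
  tpl <- xrayImage(matrix(0, 128, 128), pixelSpacing = 1)
  sil <- projectSilhouette(mask, geom, identityPose(), tpl, rayStep = 1)
  area <- sum(sil$silhouette)
  rproj <- sqrt(area / pi)  # px at 1 mm/px
  # the > 0 threshold includes the half-voxel trilinear support fringe, so
  # the analytic disc radius is (r + spacing/2) times the magnification
  expect_lt(abs(rproj - (r + sp / 2) * 1200 / 800), 1)
  b <- sil$boundary
  expect_true(all(sil$silhouette[b]))
  # empty mask gives an empty silhouette, not an error
  empty <- ctVolume(array(0, c(4, 4, 4)), spacing = rep(2, 3))
  es <- projectSilhouette(empty, geom, identityPose(), tpl)
  expect_false(any(es$silhouette))
  expect_equal(nrow(es$boundary), 0)
})

test_that("binary-mask DRR is additive for disjoint masks", {
  a <- array(0, c(20, 20, 20)); a[3:8, 8:12, 8:12] <- 1
  b <- array(0, c(20, 20, 20)); b[13:18, 8:12, 8:12] <- 1
  sp <- c(2, 2, 2)
  geom <- cArmGeometry()
  tpl <- xrayImage(matrix(0, 64, 64), pixelSpacing = 1.5)
  cfg <- projectionConfig(rayStep = 0.5, intensityMode = "binary_mask")
  ctr <- c(0, 0, 0)
  dA <- renderDRR(ctVolume(a, sp), geom, identityPose(), cfg, tpl, center = ctr)
  dB <- renderDRR(ctVolume(b, sp), geom, identityPose(), cfg, tpl, center = ctr)
  dAB <- renderDRR(ctVolume(a + b, sp), geom, identityPose(), cfg, tpl,
                   center = ctr)
  expect_lt(max(abs(dAB@pixels - (dA@pixels + dB@pixels))), 0.15)
})

test_that("invalid projection configuration is rejected", {
  expect_error(projectionConfig(rayStep = 0), "rayStep")
  expect_error(projectionConfig(intensityMode = "fancy"), "intensityMode")
  v <- ctVolume(array(1, c(4, 4, 4)))
  tpl <- xrayImage(matrix(0, 8, 8), pixelSpacing = 1)
  cfg <- projectionConfig()
  cfg@rayStep <- -1
  expect_error(renderDRR(v, cArmGeometry(), identityPose(), cfg, tpl),
               "ray_step")
})
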