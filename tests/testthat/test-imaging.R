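test_that("stack TIFF IO is idempotent and validates input", {
  set.seed(2)
  fr <- array(runif(24 * 20 * 5), dim = c(24, 20, 5))
  stk <- imageStack(fr, times = 2.6 * (0:4) + 2, pixelSize = 0.2,
                    cellMask = matrix(TRUE, 24, 20))
  f <- tempfile(fileext = ".tif")
  writeStack(stk, f)
  r1 <- readStack(f)
  # storage quantizes at 2^-32; re-reading the same file is bit-identical
  expect_lt(max(abs(r1@frames - fr)), 1e-9)
  r2 <- readStack(f)
  expect_identical(r2@frames, r1@frames)
  expect_equal(r1@times, stk@times)
  expect_equal(r1@pixelSize, 0.2)
  expect_equal(r1@cellMask, stk@cellMask)

  expect_error(readStack(tempfile()), "no such file")
  # multi-channel input rejected
  rgb <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  frgb <- tempfile(fileext = ".tif")
  tiff::writeTIFF(rgb, frgb)
  expect_error(readStack(frgb), "single-channel")
  # 8-bit integer input is rescaled by the dtype maximum
  f8 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(128 / 255, 6, 6), f8, bits.per.sample = 8L)
  s8 <- readStack(f8)
  expect_equal(s8@frames[1, 1, 1], 128 / 255)
  expect_equal(s8@meta$bitsPerSample, 8L)
})

test_that("preconditioning blurs within the mask and normalizes the first frame", {
  set.seed(5)
  n <- 41
  mask <- matrix(FALSE, n, n); mask[6:36, 6:36] <- TRUE
  fr <- array(0.5, dim = c(n, n, 3))
  stk <- imageStack(fr, times = 1:3, pixelSize = 1, cellMask = mask)
  pc <- precondition(stk)
  # constant frame: unchanged by blur, normalized to exactly 1
  expect_equal(max(abs(pc@frames[, , 1][mask] - 1)), 0)
  expect_equal(max(pc@frames[, , 1][mask]), 1)

  # impulse at the mask centre: mass-preserving spread (interior support)
  fr2 <- array(0, dim = c(n, n, 3))
  fr2[21, 21, ] <- 1
  stk2 <- imageStack(fr2, times = 1:3, pixelSize = 1, cellMask = mask)
  b <- flipdg:::maskedBlur(fr2[, , 1], mask, 1)
  expect_equal(sum(b[mask]), 1, tolerance = 1e-10)
  # matches the normalized discrete Gaussian kernel at the centre
  k <- flipdg:::gaussianKernel(1)
  r <- (nrow(k) - 1) / 2
  expect_equal(b[(21 - r):(21 + r), (21 - r):(21 + r)], k, tolerance = 1e-12,
               ignore_attr = TRUE)

  # normalization is idempotent
  pc2 <- imageStack(pc@frames, pc@times, pc@pixelSize, pc@cellMask)
  nrm2 <- max(flipdg:::maskedBlur(pc2@frames[, , 1], mask, 1e-6)[mask])
  expect_equal(nrm2, 1, tolerance = 1e-9)

  expect_error(precondition(imageStack(fr, 1:3, 1)), "mask")
})

test_that("image-to-mesh interpolation reproduces constants and ramps", {
  setup <- coarseSetup()
  px <- 0.25
  nr <- 60; nc <- 60
  img <- matrix(0.42, nr, nc)
  co <- imageToMeshFunction(img, setup$space, px)
  expect_equal(co, rep(0.42, nDof(setup$space)))

  rows <- matrix(rep(seq_len(nr), nc), nr)
  cols <- matrix(rep(seq_len(nc), each = nr), nr)
  ramp <- 0.1 + 0.03 * ((cols - 0.5) * px) + 0.02 * ((nr - rows + 0.5) * px)
  co <- imageToMeshFunction(ramp, setup$space, px)
  xy <- dofCoordinates(setup$space)
  expect_equal(co, 0.1 + 0.03 * xy[, 1] + 0.02 * xy[, 2], tolerance = 1e-12)

  expect_error(imageToMeshFunction(matrix(0.5, 10, 10), setup$space, px),
               "outside the image")
})

test_that("rasterization shows membrane discontinuities and background fill", {
  setup <- coarseSetup()
  reg <- dofRegion(setup$space)
  field <- ifelse(reg == "nucleus", 0.9, 0.2)
  img <- rasterizeField(field, setup$space, 60, 60, 0.25, background = -1)
  expect_true(any(img == -1))                       # outside pixels
  inside <- img != -1
  expect_setequal(unique(round(img[inside], 6)), c(0.9, 0.2))
  # the nucleus pixels form a block of elevated value around the centre
  expect_equal(img[30, 30], 0.9)
  expect_equal(img[15, 30], 0.2)

  # rasterize-then-interpolate approaches identity on smooth fields (mesh
  # congruent with the raster field so no background bleeds in)
  sq <- dgSpace(rectangleMesh(12L, 12L, width = 4, height = 4))
  xy <- dofCoordinates(sq)
  smooth <- 0.4 + 0.2 * sin(xy[, 1]) * cos(xy[, 2])
  errAt <- function(n) {
    px <- 4 / n
    im <- rasterizeField(smooth, sq, n, n, px, background = 0)
    back <- imageToMeshFunction(im, sq, px)
    fieldL2Norm(sq, back - smooth) / fieldL2Norm(sq, smooth)
  }
  e1 <- errAt(64); e2 <- errAt(128)
  expect_lt(e2, 0.75 * e1)
  expect_lt(e2, 0.02)
})

test_that("synthetic stacks are seed-reproducible and show nuclear retention", {
  geo <- paperGeometry(pixelSize = 0.25)
  sch <- bleachSchedule(nFrames = 12L)
  syn <- synthesizeFlipStack(truthParams(), geo, sch, noiseSd = 0.005,
                             seed = 11, targetEdgeLength = 0.9)
  syn2 <- synthesizeFlipStack(truthParams(), geo, sch, noiseSd = 0.005,
                              seed = 11, targetEdgeLength = 0.9)
  expect_identical(syn$stack@frames, syn2$stack@frames)
  syn3 <- synthesizeFlipStack(truthParams(), geo, sch, noiseSd = 0.005,
                              seed = 12, targetEdgeLength = 0.9)
  expect_false(identical(syn$stack@frames, syn3$stack@frames))
  expect_equal(syn$stack@meta$groundTruth$alpha, 16.1)

  # nuclear mean decays slower than cytoplasmic for small p
  lab <- syn$labelMask
  fr <- syn$stack@frames
  nFr <- dim(fr)[3]
  nucRet <- mean(fr[, , nFr][lab == 2L]) / mean(fr[, , 1][lab == 2L])
  cytRet <- mean(fr[, , nFr][lab == 1L]) / mean(fr[, , 1][lab == 1L])
  expect_gt(nucRet, cytRet)
})

test_that("goal series validate their range and match trajectories", {
  setup <- coarseSetup()
  sys <- assembleSystem(setup$space, truthParams(), rateMaps(setup$c0, 0.319))
  sch <- bleachSchedule(nFrames = 4L)
  tr <- runFlip(initFieldsFromFrame(setup$c0), sys, sch)
  g <- goalSeriesFromTrajectory(tr)
  expect_equal(ncol(g@coefs), 4L)
  expect_equal(g@times, tr@times)
  bad <- tr
  bad@U[1, 1] <- 5
  expect_error(goalSeriesFromTrajectory(bad), "preconditioned")
})
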