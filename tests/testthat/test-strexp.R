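frameTimesFor <- function(n) 2.6 * (seq_len(n) - 1) + 2

test_that("noise-free StrExp decays are recovered across the h range", {
  tt <- frameTimesFor(50L)
  for (h in c(0.5, 0.7, 1.0, 1.3, 1.8)) {
    y <- strExpValue(tt, I0 = 0.8, tau = 30, h = h, Ib = 0.1)
    f <- fitStrExpPixel(y, tt)
    expect_true(f$converged)
    tolRel <- if (h == 1) 1e-6 else 1e-4
    expect_lt(relErr(f$I0, 0.8), tolRel)
    expect_lt(relErr(f$tau, 30), tolRel)
    expect_lt(relErr(f$h, h), tolRel)
    expect_lt(relErr(f$Ib, 0.1), tolRel)
    expect_lt(f$rmse, 1e-8)
  }
})

test_that("model value at t = 0 is I0 + Ib and degenerate input is flagged", {
  expect_equal(strExpValue(0, I0 = 0.7, tau = 12, h = 1.4, Ib = 0.2), 0.9)
  f <- fitStrExpPixel(rep(0.5, 20), frameTimesFor(20L))
  expect_true(f$degenerate)
  expect_equal(f$I0, 0)
  expect_error(fitStrExpPixel(1:5, 1:5), "8 time points")
})

test_that("stack fitting broadcasts the single-pixel fit and masks regions", {
  tt <- frameTimesFor(30L)
  nr <- 8; nc <- 10
  fr <- array(NA_real_, dim = c(nr, nc, 30L))
  # two-region stack: slow columns 1..5 ("nucleus"), fast columns 6..10
  for (i in seq_len(30L)) {
    fr[, 1:5, i] <- strExpValue(tt[i], I0 = 0.9, tau = 40, h = 0.8, Ib = 0.05)
    fr[, 6:10, i] <- strExpValue(tt[i], I0 = 0.5, tau = 8, h = 1.2, Ib = 0.02)
  }
  stk <- imageStack(fr, tt, pixelSize = 0.5)
  mask <- matrix(TRUE, nr, nc)
  maps <- fitStrExpStack(stk, mask)
  expect_true(all(maps@fitMask))
  # spatially constant maps per region, matching the pixel oracle
  oracleSlow <- fitStrExpPixel(fr[1, 1, ], tt)
  expect_equal(max(abs(maps@tau[, 1:5] - oracleSlow$tau)), 0)
  expect_equal(max(abs(maps@hHet[, 1:5] - oracleSlow$h)), 0)
  # tau changes abruptly across the region boundary
  expect_gt(min(maps@tau[, 1:5]), 4 * max(maps@tau[, 6:10]))
  expect_error(fitStrExpStack(stk, matrix(FALSE, nr, nc)), "empty mask")
})

test_that("rate coefficients have the sign structure of the heterogeneity", {
  mk <- function(h) new("StrExpMaps", I0 = matrix(1), tau = matrix(10),
                        hHet = matrix(h), Ib = matrix(0), rmse = matrix(0),
                        fitMask = matrix(TRUE))
  tt <- c(0.5, 2, 8, 32)
  kExp <- rateCoefficient(mk(1), tt)
  expect_equal(as.vector(kExp@kOfT), rep(0.1, 4))
  kComp <- rateCoefficient(mk(0.5), tt)
  expect_true(all(diff(as.vector(kComp@kOfT[1, 1, ])) > 0))
  kStr <- rateCoefficient(mk(2), tt)
  expect_true(all(diff(as.vector(kStr@kOfT[1, 1, ])) < 0))
  expect_error(rateCoefficient(mk(1.5), c(0, 1)), "positive")

  # closed form against the definition -d log(In)/dt by finite differences
  h <- 1.3; tau <- 10
  t0 <- 5; dt <- 1e-6
  In <- function(t) exp(-(t / tau)^(1 / h))
  fd <- -(log(In(t0 + dt)) - log(In(t0 - dt))) / (2 * dt)
  k0 <- rateCoefficient(mk(h), t0)@kOfT[1, 1, 1]
  expect_equal(k0, fd, tolerance = 1e-8)

  # integrating k recovers the normalized decay
  kk <- function(t) (1 / (h * tau)) * (t / tau)^(1 / h - 1)
  iv <- stats::integrate(kk, 0, 15)$value
  expect_equal(exp(-iv), In(15), tolerance = 1e-8)
})

test_that("heterogeneity classification uses the h = 1 band", {
  m <- new("StrExpMaps", I0 = matrix(1, 1, 4), tau = matrix(10, 1, 4),
           hHet = matrix(c(0.7, 1.0, 1.6, 1.03), 1, 4), Ib = matrix(0, 1, 4),
           rmse = matrix(0, 1, 4), fitMask = matrix(TRUE, 1, 4))
  cls <- classifyHeterogeneity(m)
  expect_equal(as.vector(cls), c("compressed", "exponential", "stretched",
                                 "exponential"))
  cls2 <- classifyHeterogeneity(m, tol = 0.01)
  expect_equal(cls2[1, 4], "stretched")
})

test_that("map export/import round trips through scaled TIFF", {
  set.seed(8)
  m <- new("StrExpMaps", I0 = matrix(runif(12), 3), tau = matrix(runif(12, 5, 80), 3),
           hHet = matrix(runif(12, 0.5, 2), 3), Ib = matrix(runif(12, 0, 0.2), 3),
           rmse = matrix(runif(12, 0, 0.01), 3), fitMask = matrix(TRUE, 3, 4))
  f <- tempfile(fileext = ".tif")
  writeStrExpMaps(m, f)
  back <- readScaledTIFF(f)
  expect_equal(back$tau, m@tau, tolerance = 1e-7)
  expect_equal(back$h, m@hHet, tolerance = 1e-7)
  expect_named(back, c("I0", "tau", "h", "Ib", "rmse"))
})
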