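# Calibration-scale fixtures: short schedules and a coarse mesh keep each
# misfit evaluation to a fraction of a second; the full-depth recovery runs
# live in test-acceptance.R.

calibGoals <- function(nFrames = 6L) {
  memo(paste0("calibGoals", nFrames), {
    setup <- coarseSetup()
    sch <- bleachSchedule(nFrames = nFrames)
    sys <- assembleSystem(setup$space, truthParams(),
                          rateMaps(setup$c0, truthParams()@gamma))
    tr <- runFlip(initFieldsFromFrame(setup$c0), sys, sch, refine = 0L)
    list(goals = goalSeriesFromTrajectory(tr), schedule = sch,
         trajectory = tr, setup = setup)
  })
}

test_that("misfit is zero at identity, quadratic in a constant offset, and
           matches a fine-quadrature oracle", {
  cg <- calibGoals()
  setup <- cg$setup
  expect_equal(misfit(cg$trajectory, cg$goals, setup$space), 0)

  # constant offset delta on all frames: E = delta^2 * |Omega|
  delta <- 0.07
  g2 <- cg$goals
  g2@coefs <- g2@coefs - delta
  area <- regionMeasures(setup$mesh)$areaCell
  expect_equal(misfit(cg$trajectory, g2, setup$space), delta^2 * area,
               tolerance = 1e-12)

  # random fields: element quadrature agrees with an independent high-order
  # quadrature oracle
  set.seed(21)
  g3 <- cg$goals
  g3@coefs <- matrix(runif(length(g3@coefs)), nrow(g3@coefs))
  E <- misfit(cg$trajectory, g3, setup$space)
  oracleFrame <- function(d) {
    mesh <- setup$mesh
    qp <- flipdg:::triQuadrature(4L)
    eg <- flipdg:::elementGeometry(mesh)
    tot <- 0
    base <- (seq_len(nElements(mesh)) - 1L) * 3L
    for (q in seq_len(nrow(qp))) {
      lam <- qp[q, 1:3]
      dv <- lam[1] * d[base + 1L] + lam[2] * d[base + 2L] + lam[3] * d[base + 3L]
      tot <- tot + qp[q, 4L] * sum(eg$A * dv^2)
    }
    tot
  }
  dmat <- cg$trajectory@U + cg$trajectory@Ub - g3@coefs
  Eo <- mean(vapply(seq_len(ncol(dmat)), function(i) oracleFrame(dmat[, i]),
                    numeric(1)))
  expect_equal(E, Eo, tolerance = 1e-12)

  # invariance under frame reordering with matched weights
  idx <- c(3L, 1L, 2L, 6L, 5L, 4L)
  cfgFwd <- misfitConfig(seq_len(6L))
  cfgPerm <- misfitConfig(idx)
  expect_equal(misfit(cg$trajectory, g3, setup$space, cfgPerm),
               misfit(cg$trajectory, g3, setup$space, cfgFwd))

  badTimes <- g3
  badTimes@times <- g3@times + 1
  expect_error(misfit(cg$trajectory, badTimes, setup$space), "times")
})

test_that("the simplex engine matches optim on a smooth test function", {
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  res <- flipdg:::nelderMead(rosen, c(-1.2, 1), step = 0.1,
                             xTol = 1e-8, fTol = 1e-8, maxIter = 2000L)
  ref <- stats::optim(c(-1.2, 1), rosen,
                      control = list(reltol = 1e-14, maxit = 5000L))
  expect_lt(max(abs(res$x - c(1, 1))), 1e-6)
  expect_lt(res$f, ref$value + 1e-10)
  expect_true(res$converged)
})

test_that("short calibration runs move toward the truth with a monotone trace", {
  cg <- calibGoals()
  res <- calibrateFlip(cg$goals, cg$setup$space, cg$schedule, cg$setup$c0,
                       initialGuess = c(alpha = 20, beta = 30, gamma = 0.4,
                                        p = 0.08),
                       xTol = 1e-2, fTol = 1e-6, maxIter = 60L)
  expect_s4_class(res, "CalibrationResult")
  expect_true(all(diff(res@trace$E_best) <= 1e-15))
  expect_lt(res@bestE, 1e-4)
  expect_gte(res@nEvaluations, res@nIterations)
  # deterministic: identical rerun gives the identical trace
  res2 <- calibrateFlip(cg$goals, cg$setup$space, cg$schedule, cg$setup$c0,
                        initialGuess = c(alpha = 20, beta = 30, gamma = 0.4,
                                         p = 0.08),
                        xTol = 1e-2, fTol = 1e-6, maxIter = 60L)
  expect_identical(res@trace, res2@trace)
})

test_that("calibration rejects invalid setups and honours default tolerances", {
  cg <- calibGoals()
  expect_error(calibrateFlip(cg$goals, cg$setup$space,
                             bleachSchedule(nFrames = 3L), cg$setup$c0),
               "frame count")
  expect_error(calibrateFlip(cg$goals, cg$setup$space, cg$schedule,
                             cg$setup$c0, initialGuess = c(alpha = -1, beta = 1,
                                                           gamma = 1, p = 1)),
               "positive")
  # defaults: initial guess (25, 20, 0.5, 0.05), tolerances 1e-4
  expect_equal(eval(formals(calibrateFlip)$initialGuess),
               c(alpha = 25, beta = 20, gamma = 0.5, p = 0.05))
  expect_equal(formals(calibrateFlip)$xTol, 1e-4)
  expect_equal(formals(calibrateFlip)$fTol, 1e-4)
})
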