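test_that("DG space is fully discontinuous with 3 dofs per triangle", {
  sp <- dgSpace(rectangleMesh(2L, 2L))
  expect_equal(nDof(sp), 3L * 8L)
  expect_equal(nrow(dofCoordinates(sp)), nDof(sp))
  expect_error(dgSpace(rectangleMesh(1L, 1L), degree = 2L), "degree")
})

test_that("assembled operators are symmetric and annihilate constants", {
  setup <- coarseSetup()
  sys <- assembleSystem(setup$space, truthParams(),
                        rateMaps(setup$c0, 0.319))
  bl <- systemMatrices(sys)
  ones <- rep(1, nDof(setup$space))
  expect_equal(max(abs(bl$D - Matrix::t(bl$D))), 0)
  expect_equal(max(abs(bl$P - Matrix::t(bl$P))), 0)
  expect_lt(max(abs(as.numeric(bl$D %*% ones))), 1e-10)
  expect_lt(max(abs(as.numeric(bl$P %*% ones))), 1e-12)
  # M is SPD: quadratic form positive on random vectors
  set.seed(4)
  for (k in 1:5) {
    v <- rnorm(nDof(setup$space))
    expect_gt(sum(v * as.numeric(bl$M %*% v)), 0)
  }
  # B acts only on bleach-element dofs
  bleachDofs <- rep(elementBleach(setup$mesh), each = 3L)
  expect_equal(max(abs(as.numeric(bl$B %*% as.numeric(!bleachDofs)))), 0)
  expect_error(assembleSystem(setup$space, truthParams(),
                              rateMaps(setup$c0, 0.319), sigma = -1), "sigma")
})

test_that("interior penalty energy vanishes on continuous interpolants", {
  sp <- dgSpace(rectangleMesh(5L, 4L))
  xy <- dofCoordinates(sp)
  u <- 1.5 + 2 * xy[, 1] - 0.7 * xy[, 2]   # globally continuous, linear
  core <- flipdg:::assembleCore(sp)
  expect_lt(abs(sum(u * as.numeric(core$Dpen1 %*% u))), 1e-12)
})

test_that("two-triangle IPDG matrix matches a hand-assembled oracle entrywise", {
  mesh <- rectangleMesh(1L, 1L)
  sp <- dgSpace(mesh)
  alpha <- 1.7; sigma <- 12.3
  rm0 <- new("RateMaps", kPlus = rep(0, 6), kMinus = 1, u0 = 1)
  sys <- assembleSystem(sp, modelParameters(alpha, 1, 1, 1), rm0,
                        sigma = sigma, checkCoercivity = FALSE)
  D <- as.matrix(systemMatrices(sys)$D)
  oracle <- handAssembledTwoTriangleD(mesh, alpha, sigma)
  expect_lt(max(abs(D - oracle)), 1e-12)
})

test_that("jump product identity holds for arbitrary one-sided data", {
  set.seed(9)
  for (k in 1:20) {
    n <- stats::rnorm(2); n <- n / sqrt(sum(n^2))
    r <- jumpIdentityCheck(stats::rnorm(2), stats::rnorm(2),
                           stats::rnorm(1), stats::rnorm(1), n)
    expect_lt(abs(r), 1e-14)
  }
  # continuous data: both sides zero
  q <- c(0.3, -1.2)
  expect_equal(jumpIdentityCheck(q, q, 2, 2, c(1, 0)), 0)
})

test_that("a uniform field on an all-bleach mesh decays as u/(1 + beta dt)", {
  mesh <- rectangleMesh(2L, 2L)
  mesh@elementBleach <- rep(TRUE, nElements(mesh))
  mesh@elementRegion <- rep("cytoplasm", nElements(mesh))
  sp <- dgSpace(mesh)
  beta <- 3.1
  sys <- assembleSystem(sp, modelParameters(1, beta, 1, 1),
                        new("RateMaps", kPlus = rep(0, nDof(sp)), kMinus = 1e-300, u0 = 1))
  sys <- updateSystem(sys, gamma = 0)
  st <- fieldState(u = rep(0.8, nDof(sp)), ub = rep(0.2, nDof(sp)))
  dt <- 0.25
  st1 <- stepBackwardEuler(st, sys, dt, bleaching = TRUE)
  expect_equal(freeIntensity(st1), rep(0.8 / (1 + beta * dt), nDof(sp)),
               tolerance = 1e-12)
  expect_equal(hinderedIntensity(st1), rep(0.2 / (1 + beta * dt), nDof(sp)),
               tolerance = 1e-12)
})

test_that("pure reaction relaxes to the 2x2 ODE solution", {
  # single triangle, uniform rates: nodewise linear ODE
  verts <- rbind(c(0, 0), c(1, 0), c(0, 1))
  mesh <- flipdg:::finalizeMesh(verts, rbind(c(1L, 2L, 3L)),
                                "cytoplasm", FALSE)
  sp <- dgSpace(mesh)
  kp <- 0.8; km <- 0.3
  rm_ <- new("RateMaps", kPlus = rep(kp, 3), kMinus = km, u0 = 1)
  sys <- assembleSystem(sp, modelParameters(1, 1, km, 1), rm_,
                        checkCoercivity = FALSE)
  u0 <- 0.9; ub0 <- 0.1
  st <- fieldState(u = rep(u0, 3), ub = rep(ub0, 3))
  dt <- 1e-3; nsteps <- 400L
  for (i in seq_len(nsteps)) st <- stepBackwardEuler(st, sys, dt, FALSE)
  # exact: decompose onto equilibrium + decaying mode exp(-(kp+km) t)
  tEnd <- dt * nsteps
  tot <- u0 + ub0
  uEq <- km / (kp + km) * tot
  uExact <- uEq + (u0 - uEq) * exp(-(kp + km) * tEnd)
  expect_equal(freeIntensity(st)[1], uExact, tolerance = 1e-3)
  expect_equal(totalIntensity(st), rep(tot, 3), tolerance = 1e-10)
  # and exact agreement with the scalar backward-Euler recursion
  uv <- c(u0, ub0)
  A2 <- matrix(c(1 / dt + kp, -kp, -km, 1 / dt + km), 2, 2)
  for (i in seq_len(nsteps)) uv <- solve(A2, uv / dt)
  expect_equal(freeIntensity(st)[1], uv[1], tolerance = 1e-12)
})

test_that("membrane jump vanishes monotonically as permeability grows", {
  setup <- coarseSetup()
  sysBase <- assembleSystem(setup$space, truthParams(),
                            rateMaps(setup$c0, 0.319))
  reg <- dofRegion(setup$space)
  st0 <- fieldState(u = ifelse(reg == "nucleus", 0.9, 0.3),
                    ub = rep(0, nDof(setup$space)))
  jumpNorm <- function(p) {
    sys <- updateSystem(sysBase, alpha = 5, beta = NULL, gamma = 1e-9, p = p)
    st <- st0
    for (i in 1:20) st <- stepBackwardEuler(st, sys, 0.1, FALSE)
    sum(freeIntensity(st) * as.numeric(sysBase@P1 %*% freeIntensity(st)))
  }
  jn <- vapply(c(1, 10, 100, 1000), jumpNorm, numeric(1))
  expect_true(all(diff(jn) < 0))
  expect_lt(jn[4] / jn[1], 1e-3)
})

test_that("backward Euler is monotone for large steps (no mass oscillation)", {
  setup <- coarseSetup()
  sys <- assembleSystem(setup$space, truthParams(), rateMaps(setup$c0, 0.319))
  st <- initFieldsFromFrame(setup$c0)
  for (dt in c(0.2, 2, 10)) {
    s <- st
    m <- numeric(12)
    for (i in 1:12) {
      s <- stepBackwardEuler(s, sys, dt, bleaching = TRUE)
      m[i] <- fieldMass(sys, s)["total"]
    }
    expect_true(all(diff(c(fieldMass(sys, st)["total"], m)) < 0))
  }
})

test_that("runFlip executes 4 bleach + 9 recovery steps and snapshots at step 10", {
  sch <- bleachSchedule(nFrames = 3L)
  expect_equal(unname(stepsPerFrame(sch)), c(4L, 9L))
  setup <- coarseSetup()
  sys <- assembleSystem(setup$space, truthParams(), rateMaps(setup$c0, 0.319))
  st <- initFieldsFromFrame(setup$c0)
  tr <- runFlip(st, sys, sch)
  expect_equal(tr@times, c(2.0, 4.6, 7.2))
  expect_equal(nrow(massSeries(tr)), 3L * 13L + 1L)
  # the snapshot is the state after step 10 of each frame: recompute frame 1
  s <- st
  for (k in 1:13) {
    s <- stepBackwardEuler(s, sys, 0.2, bleaching = k <= 4)
    if (k == 10) expect_equal(s@u, tr@U[, 1])
  }
  # snapshot times off the step grid are rejected at schedule construction
  expect_error(bleachSchedule(tOffset = 0.25, dt = 0.2), "grid")
})
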