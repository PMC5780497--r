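# Verification harnesses: manufactured-solution convergence studies and the
# exactly representable two-slab membrane steady state.

# int f(x,y) phi_l dx per dof, 6-point (order 4) quadrature.
loadVector <- function(space, f) {
  mesh <- space@mesh
  eg <- elementGeometry(mesh)
  qp <- triQuadrature(4L)
  tri <- mesh@triangles; v <- mesh@vertices
  rhs <- numeric(space@ndof)
  ne <- nrow(tri)
  base <- (seq_len(ne) - 1L) * 3L
  for (q in seq_len(nrow(qp))) {
    lam <- qp[q, 1:3]; w <- qp[q, 4L]
    x <- lam[1L] * v[tri[, 1L], 1L] + lam[2L] * v[tri[, 2L], 1L] + lam[3L] * v[tri[, 3L], 1L]
    y <- lam[1L] * v[tri[, 1L], 2L] + lam[2L] * v[tri[, 2L], 2L] + lam[3L] * v[tri[, 3L], 2L]
    fv <- f(x, y)
    for (l in 1:3)
      rhs[base + l] <- rhs[base + l] + w * eg$A * fv * lam[l]
  }
  rhs
}

# L2 error of a DG field against an exact function, order-4 quadrature.
l2ErrorAgainst <- function(space, coefs, exact) {
  mesh <- space@mesh
  eg <- elementGeometry(mesh)
  qp <- triQuadrature(4L)
  tri <- mesh@triangles; v <- mesh@vertices
  ne <- nrow(tri)
  base <- (seq_len(ne) - 1L) * 3L
  acc <- numeric(ne)
  for (q in seq_len(nrow(qp))) {
    lam <- qp[q, 1:3]; w <- qp[q, 4L]
    x <- lam[1L] * v[tri[, 1L], 1L] + lam[2L] * v[tri[, 2L], 1L] + lam[3L] * v[tri[, 3L], 1L]
    y <- lam[1L] * v[tri[, 1L], 2L] + lam[2L] * v[tri[, 2L], 2L] + lam[3L] * v[tri[, 3L], 2L]
    uh <- lam[1L] * coefs[base + 1L] + lam[2L] * coefs[base + 2L] + lam[3L] * coefs[base + 3L]
    acc <- acc + w * (uh - exact(x, y))^2
  }
  sqrt(sum(acc * eg$A))
}

# Nodal interpolant of a function into the DG space.
interpolateDG <- function(space, f) {
  xy <- dofCoordinates(space)
  f(xy[, 1L], xy[, 2L])
}

#' Spatial convergence study
#'
#' Solves the reaction-diffusion steady problem u - div(alpha grad u) = f on
#' the unit square with the manufactured solution
#' u = cos(pi x) cos(pi y) (compatible with the zero-flux boundary) on a
#' sequence of uniform meshes and reports L2 errors and observed orders
#' (expected ~2 for linear elements).
#'
#' @param resolutions vector of grid sizes (cells per side).
#' @param alpha diffusion coefficient.
#' @return data.frame with h, error, order.
#' @export
verifySpatialConvergence <- function(resolutions = c(8L, 16L, 32L), alpha = 1) {
  exact <- function(x, y) cos(pi * x) * cos(pi * y)
  f <- function(x, y) (1 + 2 * pi^2 * alpha) * exact(x, y)
  err <- numeric(length(resolutions))
  hs <- 1 / resolutions
  for (i in seq_along(resolutions)) {
    n <- resolutions[i]
    space <- dgSpace(rectangleMesh(n, n))
    core <- assembleCore(space)
    sigmaFactor <- 20 * (space@degree + 1)^2
    A <- core$M + alpha * core$Dgrad1 + sigmaFactor * alpha * core$Dpen1
    rhs <- loadVector(space, f)
    u <- as.numeric(Matrix::solve(A, rhs))
    err[i] <- l2ErrorAgainst(space, u, exact)
  }
  ord <- c(NA, -diff(log(err)) / diff(log(1 / resolutions)) * -1)
  ord <- c(NA, diff(log(err)) / diff(log(hs)))
  data.frame(h = hs, error = err, order = ord)
}

#' Temporal convergence study
#'
#' Advances the heat equation u_t = div(alpha grad u) with initial data
#' cos(pi x) cos(pi y) on a fixed mesh for several time steps and measures
#' the L2 difference at the final time against a small-step reference run on
#' the same mesh, isolating the time-discretization error (expected order 1
#' for backward Euler).
#'
#' @param dts time steps to test.
#' @param n fixed mesh resolution.
#' @param alpha diffusion coefficient.
#' @param tEnd final time.
#' @param refFactor the reference run uses min(dts)/refFactor.
#' @return data.frame with dt, error, order.
#' @export
verifyTemporalConvergence <- function(dts = c(0.1, 0.05, 0.025), n = 12L,
                                      alpha = 0.1, tEnd = 1, refFactor = 16L) {
  space <- dgSpace(rectangleMesh(n, n))
  core <- assembleCore(space)
  sigmaFactor <- 20 * (space@degree + 1)^2
  D <- alpha * core$Dgrad1 + sigmaFactor * alpha * core$Dpen1
  u0 <- interpolateDG(space, function(x, y) cos(pi * x) * cos(pi * y))
  advance <- function(dt) {
    nsteps <- round(tEnd / dt)
    stopifnot(abs(nsteps * dt - tEnd) < 1e-12)
    A <- core$M / dt + D
    f <- Matrix::lu(A)
    u <- u0
    for (k in seq_len(nsteps)) {
      rhs <- as.numeric(core$M %*% u) / dt
      u <- as.numeric(Matrix::solve(f, rhs))
      r <- rhs - as.numeric(A %*% u)
      u <- u + as.numeric(Matrix::solve(f, r))
    }
    u
  }
  uref <- advance(min(dts) / refFactor)
  err <- vapply(dts, function(dt) {
    d <- advance(dt) - uref
    sqrt(sum(d * as.numeric(core$M %*% d)))
  }, numeric(1))
  data.frame(dt = dts, error = err,
             order = c(NA, diff(log(err)) / diff(log(dts))))
}

#' Combined convergence verification
#'
#' @param spatialResolutions,temporalDts grids for the two studies.
#' @return list with the two tables and the fitted overall orders.
#' @export
verifyConvergence <- function(spatialResolutions = c(8L, 16L, 32L),
                              temporalDts = c(0.1, 0.05, 0.025)) {
  sp <- verifySpatialConvergence(spatialResolutions)
  tm <- verifyTemporalConvergence(temporalDts)
  fitOrder <- function(h, e) unname(stats::coef(stats::lm(log(e) ~ log(h)))[2L])
  list(spatial = sp, temporal = tm,
       spatialOrder = fitOrder(sp$h, sp$error),
       temporalOrder = fitOrder(tm$dt, tm$error))
}

#' Two-slab membrane steady state (degree-1 exactness check)
#'
#' On the rectangle [0, 1] x [0, H] with a straight membrane at x = a, the
#' steady state with constant horizontal flux J satisfies a piecewise-linear
#' profile with slope -J/alpha in each slab and a concentration jump J/p
#' across the membrane. That profile lies in the degree-1 DG space, so the
#' IPDG solution (driven by the matching boundary-flux data, with a mass term
#' to fix the additive constant) reproduces it to solver tolerance at any
#' resolution. Returns the L2 error of the computed against the analytic
#' solution.
#'
#' @param nx,ny mesh resolution.
#' @param a membrane position (must be a grid line).
#' @param alpha diffusion coefficient.
#' @param p membrane permeability.
#' @param J imposed flux (positive from left slab to right slab).
#' @return list with the error and the two solution vectors.
#' @export
twoSlabSteadyState <- function(nx = 8L, ny = 4L, a = 0.5, alpha = 2,
                               p = 0.25, J = 1) {
  mesh <- rectangleMesh(nx, ny, width = 1, height = 0.5, interfaceX = a)
  space <- dgSpace(mesh)
  core <- assembleCore(space)
  sigmaFactor <- 20 * (space@degree + 1)^2
  # exact: u = u0 - (J/alpha) x on the left, minus an extra jump J/p right
  u0 <- 1
  exact <- function(x, y) u0 - (J / alpha) * x - (J / p) * (x > a)
  # DG interpolant is region-aware at the interface (x == a nodes belong to
  # their element's side)
  xy <- dofCoordinates(space)
  reg <- dofRegion(space)
  uex <- u0 - (J / alpha) * xy[, 1L] - (J / p) * (reg == "cytoplasm")
  D <- alpha * (core$Dgrad1 + sigmaFactor * core$Dpen1)
  P <- p * core$P1
  # normal flux on the outer boundary: -alpha du/dn = J on x-faces
  bflux <- boundaryFluxVector(space, function(x, y, nx_, ny_) {
    # alpha grad u . n = -J nx
    -J * nx_
  })
  A <- core$M + D + P
  rhs <- as.numeric(core$M %*% uex) + bflux
  u <- as.numeric(Matrix::solve(A, rhs))
  err <- sqrt(sum((u - uex) * as.numeric(core$M %*% (u - uex))))
  list(error = err, computed = u, exact = uex, space = space)
}
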