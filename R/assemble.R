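# Symmetric interior-penalty DG assembly on a TriMesh.
#
# Degree-1 nodal elements, fully discontinuous: dofs (e-1)*3 + (1,2,3)
# correspond to the three vertices of element e. Interior edges carry the
# symmetric consistency terms and the (sigma/h) penalty; membrane edges carry
# only the permeability coupling p * int [u].[v] ds (the interface condition
# is the physics there and replaces the continuity penalty); outer boundary
# edges carry nothing (zero-flux condition is natural).

#' Discontinuous Galerkin space on a mesh
#'
#' @param mesh a [TriMesh].
#' @param degree polynomial degree; only 1 (linear) is supported.
#' @return a [DGSpace].
#' @export
dgSpace <- function(mesh, degree = 1L) {
  new("DGSpace", mesh = mesh, degree = as.integer(degree),
      ndof = 3L * nrow(mesh@triangles))
}

#' @rdname dgSpace
#' @param space a [DGSpace].
#' @export
nDof <- function(space) space@ndof

#' @rdname dgSpace
#' @export
dofCoordinates <- function(space) {
  tri <- space@mesh@triangles
  v <- space@mesh@vertices
  idx <- as.vector(t(tri))            # e1v1 e1v2 e1v3 e2v1 ...
  v[idx, , drop = FALSE]
}

#' @rdname dgSpace
#' @export
dofRegion <- function(space) rep(space@mesh@elementRegion, each = 3L)

setMethod("show", "DGSpace", function(object) {
  cat(sprintf("DGSpace: degree %d, %d elements, %d dofs (fully discontinuous)\n",
              object@degree, nrow(object@mesh@triangles), object@ndof))
})

# Per-element geometry: areas, gradient matrices, diameters.
elementGeometry <- function(mesh) {
  tri <- mesh@triangles; v <- mesh@vertices
  p1 <- v[tri[, 1L], , drop = FALSE]
  p2 <- v[tri[, 2L], , drop = FALSE]
  p3 <- v[tri[, 3L], , drop = FALSE]
  det2 <- (p2[, 1L] - p1[, 1L]) * (p3[, 2L] - p1[, 2L]) -
    (p3[, 1L] - p1[, 1L]) * (p2[, 2L] - p1[, 2L])
  A <- det2 / 2                        # positive, triangles are CCW
  gx <- cbind(p2[, 2L] - p3[, 2L], p3[, 2L] - p1[, 2L], p1[, 2L] - p2[, 2L]) / det2
  gy <- cbind(p3[, 1L] - p2[, 1L], p1[, 1L] - p3[, 1L], p2[, 1L] - p1[, 1L]) / det2
  diam <- pmax(sqrt(rowSums((p2 - p3)^2)),
               sqrt(rowSums((p1 - p3)^2)),
               sqrt(rowSums((p1 - p2)^2)))
  list(A = A, gx = gx, gy = gy, diam = diam,
       centroid = (p1 + p2 + p3) / 3)
}

#' Mass matrix of a DG space
#'
#' @param space a [DGSpace].
#' @param weight optional nodal weight field w; returns int w phi_i phi_j dx
#'   integrated with the 3-point edge-midpoint rule (exact for quadratics and
#'   consistent with the reaction-equilibrium identity).
#' @return sparse symmetric matrix (ndof x ndof).
#' @export
massMatrix <- function(space, weight = NULL) {
  mesh <- space@mesh
  ne <- nrow(mesh@triangles)
  eg <- elementGeometry(mesh)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  base <- (seq_len(ne) - 1L) * 3L
  if (is.null(weight)) {
    loc <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2) / 12, 3L, 3L)
    for (l in 1:3) for (m in 1:3) {
      ii <- c(ii, base + l); jj <- c(jj, base + m)
      xx <- c(xx, eg$A * loc[l, m])
    }
  } else {
    # 3-point midpoint rule; basis values at the points are the barycentrics
    qp <- triQuadrature(2L)
    wq <- matrix(0, ne, 3L)            # weight field at the 3 quad points
    for (q in 1:3) {
      lam <- qp[q, 1:3]
      wq[, q] <- lam[1L] * weight[base + 1L] + lam[2L] * weight[base + 2L] +
        lam[3L] * weight[base + 3L]
    }
    for (l in 1:3) for (m in 1:3) {
      val <- numeric(ne)
      for (q in 1:3) {
        lam <- qp[q, 1:3]
        val <- val + qp[q, 4L] * wq[, q] * lam[l] * lam[m]
      }
      ii <- c(ii, base + l); jj <- c(jj, base + m)
      xx <- c(xx, eg$A * val)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(space@ndof, space@ndof))
}

# Edge data used by the face integrals: per non-outer edge the plus/minus
# elements, the unit normal pointing out of the plus element, length, the
# average adjacent diameter h, and 2x3 trace matrices mapping local nodal
# values to values at the two edge endpoints.
edgeData <- function(space) {
  mesh <- space@mesh
  eg <- elementGeometry(mesh)
  keep <- which(mesh@edgeClass != "outer_boundary")
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    a <- mesh@edges[i, 1L]; b <- mesh@edges[i, 2L]
    pa <- mesh@vertices[a, ]; pb <- mesh@vertices[b, ]
    L <- sqrt(sum((pb - pa)^2))
    tvec <- (pb - pa) / L
    n <- c(tvec[2L], -tvec[1L])
    ep <- mesh@edgeElements[i, 1L]; em <- mesh@edgeElements[i, 2L]
    mid <- (pa + pb) / 2
    if (sum(n * (mid - eg$centroid[ep, ])) < 0) n <- -n
    Tp <- matrix(0, 2L, 3L); Tm <- matrix(0, 2L, 3L)
    vp <- mesh@triangles[ep, ]; vm <- mesh@triangles[em, ]
    Tp[1L, vp == a] <- 1; Tp[2L, vp == b] <- 1
    Tm[1L, vm == a] <- 1; Tm[2L, vm == b] <- 1
    out[[k]] <- list(edge = i, class = mesh@edgeClass[i], ep = ep, em = em,
                     n = n, L = L, h = (eg$diam[ep] + eg$diam[em]) / 2,
                     Tp = Tp, Tm = Tm)
  }
  out
}

# Assemble the parameter-normalized operator blocks once per mesh.
assembleCore <- function(space) {
  mesh <- space@mesh
  ne <- nrow(mesh@triangles)
  eg <- elementGeometry(mesh)
  base <- (seq_len(ne) - 1L) * 3L

  # volume gradient term, per unit alpha
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (l in 1:3) for (m in 1:3) {
    ii <- c(ii, base + l); jj <- c(jj, base + m)
    xx <- c(xx, eg$A * (eg$gx[, l] * eg$gx[, m] + eg$gy[, l] * eg$gy[, m]))
  }

  ed <- edgeData(space)
  Q <- matrix(c(2, 1, 1, 2), 2L, 2L) / 6       # int trace_l trace_m ds / L
  gi <- integer(0); gj <- integer(0); gx <- numeric(0)   # consistency (unit alpha)
  pi_ <- integer(0); pj <- integer(0); px <- numeric(0)  # penalty (unit sigma)
  mi <- integer(0); mj <- integer(0); mx <- numeric(0)   # membrane (unit p)
  for (e in ed) {
    dp <- (e$ep - 1L) * 3L + 1:3
    dm <- (e$em - 1L) * 3L + 1:3
    dofs <- c(dp, dm)
    TT <- cbind(e$Tp, e$Tm)                    # 2 x 6 traces
    sg <- c(1, 1, 1, -1, -1, -1)               # jump signs
    S <- (t(TT) %*% Q %*% TT) * e$L            # 6x6 edge mass of traces
    J <- outer(sg, sg) * S                     # int [u][v] ds
    if (e$class == "membrane") {
      blk <- J
      mi <- c(mi, rep(dofs, times = 6L)); mj <- c(mj, rep(dofs, each = 6L))
      mx <- c(mx, as.vector(blk))
    } else {
      # penalty int (1/h) [u][v] ds, per unit sigma
      blk <- J / e$h
      pi_ <- c(pi_, rep(dofs, times = 6L)); pj <- c(pj, rep(dofs, each = 6L))
      px <- c(px, as.vector(blk))
      # consistency: -int {grad u}.n+ (v+ - v-) ds and its transpose
      gn <- c(eg$gx[e$ep, ] * e$n[1L] + eg$gy[e$ep, ] * e$n[2L],
              eg$gx[e$em, ] * e$n[1L] + eg$gy[e$em, ] * e$n[2L]) / 2
      tint <- sg * colSums(TT) * e$L / 2       # int (v+ - v-) trace ds
      C <- -outer(tint, gn)                    # rows: test v, cols: trial u
      blk2 <- C + t(C)
      gi <- c(gi, rep(dofs, times = 6L)); gj <- c(gj, rep(dofs, each = 6L))
      gx <- c(gx, as.vector(blk2))
    }
  }
  nd <- space@ndof
  Dgrad1 <- Matrix::sparseMatrix(i = c(ii, gi), j = c(jj, gj), x = c(xx, gx),
                                 dims = c(nd, nd))
  Dpen1 <- if (length(px)) Matrix::sparseMatrix(i = pi_, j = pj, x = px,
                                                dims = c(nd, nd))
  else Matrix::sparseMatrix(i = 1L, j = 1L, x = 0, dims = c(nd, nd))
  P1 <- if (length(mx)) Matrix::sparseMatrix(i = mi, j = mj, x = mx,
                                             dims = c(nd, nd))
  else Matrix::sparseMatrix(i = 1L, j = 1L, x = 0, dims = c(nd, nd))

  # bleach-region mass, per unit beta
  bl <- mesh@elementBleach
  if (any(bl)) {
    bb <- (which(bl) - 1L) * 3L
    bi <- integer(0); bj <- integer(0); bx <- numeric(0)
    loc <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2) / 12, 3L, 3L)
    Abl <- eg$A[bl]
    for (l in 1:3) for (m in 1:3) {
      bi <- c(bi, bb + l); bj <- c(bj, bb + m)
      bx <- c(bx, Abl * loc[l, m])
    }
    B1 <- Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(nd, nd))
  } else {
    B1 <- Matrix::sparseMatrix(i = 1L, j = 1L, x = 0, dims = c(nd, nd))
  }
  list(M = massMatrix(space), Dgrad1 = Dgrad1, Dpen1 = Dpen1, P1 = P1, B1 = B1)
}

#' Assemble the IPDG system for the FLIP model
#'
#' Builds the mass matrix, the interior-penalty diffusion operator, the
#' membrane permeability coupling, the reaction coupling and the bleach sink
#' for a parameter set. The Nitsche penalty defaults to
#' sigma = 20 * alpha * (degree + 1)^2; coercivity of the resulting diffusion
#' operator is verified on a coarse probe mesh at assembly time.
#'
#' @param space a [DGSpace] on a classified mesh.
#' @param params a [ModelParameters] object.
#' @param rates a [RateMaps] object on the same space.
#' @param sigma Nitsche penalty; default `20 * alpha * (degree + 1)^2`.
#' @param checkCoercivity probe the smallest eigenvalue of D on a coarse mesh.
#' @return an [AssembledSystem].
#' @export
assembleSystem <- function(space, params, rates, sigma = NULL,
                           checkCoercivity = TRUE) {
  if (length(rates@kPlus) != space@ndof)
    stop("assembly error: rate map length does not match the space")
  if (!is.null(sigma) && sigma <= 0) stop("assembly error: sigma must be > 0")
  sigmaFactor <- if (is.null(sigma)) 20 * (space@degree + 1)^2
  else sigma / params@alpha
  core <- assembleCore(space)
  gamma <- rates@kMinus / rates@u0
  ub0 <- rates@kPlus / gamma
  Kp1 <- massMatrix(space, weight = ub0)
  if (checkCoercivity) {
    probe <- dgSpace(rectangleMesh(4L, 4L))
    pc <- assembleCore(probe)
    Dp <- as.matrix(pc$Dgrad1 + sigmaFactor * pc$Dpen1)
    ev <- eigen((Dp + t(Dp)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev)))
      stop("assembly error: Nitsche parameter too small, diffusion operator not coercive")
  }
  new("AssembledSystem", space = space, M = core$M, Dgrad1 = core$Dgrad1,
      Dpen1 = core$Dpen1, P1 = core$P1, Kp1 = Kp1, B1 = core$B1,
      params = params, rates = rates, sigmaFactor = sigmaFactor,
      cache = new.env(parent = emptyenv()))
}

#' Rescale an assembled system to new parameter values
#'
#' Re-uses the cached parameter-normalized matrices: no re-assembly is
#' performed, only the scalar factors change (and cached factorizations are
#' dropped). Zero values are permitted here for diagnostic limits (e.g. p = 0
#' for compartment isolation), even though [modelParameters()] requires
#' strictly positive parameters.
#'
#' @param system an [AssembledSystem].
#' @param alpha,beta,gamma,p new values; NULL keeps the current one.
#' @return the rescaled [AssembledSystem].
#' @export
updateSystem <- function(system, alpha = NULL, beta = NULL, gamma = NULL, p = NULL) {
  pr <- system@params
  vals <- c(alpha %||% pr@alpha, beta %||% pr@beta,
            gamma %||% pr@gamma, p %||% pr@p)
  if (vals[1L] <= 0 || any(vals < 0) || any(!is.finite(vals)))
    stop("updateSystem: alpha must be positive; beta, gamma, p nonnegative")
  np <- pr                       # bypass the strict-positivity validity so
  slot(np, "alpha", check = FALSE) <- vals[1L]   # diagnostic zero limits
  slot(np, "beta", check = FALSE) <- vals[2L]    # (p = 0, beta = 0) can be
  slot(np, "gamma", check = FALSE) <- vals[3L]   # expressed on an assembled
  slot(np, "p", check = FALSE) <- vals[4L]       # system

  oldGamma <- system@rates@kMinus / system@rates@u0
  gEff <- max(np@gamma, .Machine$double.xmin)   # keep ub0 recoverable at gamma = 0
  nr <- new("RateMaps",
            kPlus = system@rates@kPlus * (gEff / oldGamma),
            kMinus = gEff * system@rates@u0,
            u0 = system@rates@u0)
  new("AssembledSystem", space = system@space, M = system@M,
      Dgrad1 = system@Dgrad1, Dpen1 = system@Dpen1, P1 = system@P1,
      Kp1 = system@Kp1, B1 = system@B1, params = np, rates = nr,
      sigmaFactor = system@sigmaFactor, cache = new.env(parent = emptyenv()))
}

# Scaled operator blocks of a system.
systemBlocks <- function(system) {
  pr <- system@params
  list(M = system@M,
       D = pr@alpha * (system@Dgrad1 + system@sigmaFactor * system@Dpen1),
       P = pr@p * system@P1,
       Kp = pr@gamma * system@Kp1,
       kMinus = pr@gamma * system@rates@u0,
       B = pr@beta * system@B1)
}

#' Operator blocks of an assembled system
#'
#' Returns the scaled sparse matrices of the semi-discrete system: mass `M`,
#' interior-penalty diffusion `D`, membrane coupling `P`, binding coupling
#' `Kp`, the scalar release rate `kMinus` (the release block is kMinus * M)
#' and the bleach sink `B`.
#'
#' @param system an [AssembledSystem].
#' @return named list of sparse matrices and the scalar `kMinus`.
#' @export
systemMatrices <- function(system) systemBlocks(system)

setMethod("show", "AssembledSystem", function(object) {
  cat(sprintf("AssembledSystem on %d dofs, sigma = %.4g (sigma/alpha = %.4g)\n",
              object@space@ndof, object@sigmaFactor * object@params@alpha,
              object@sigmaFactor))
  show(object@params)
})

#' Verify the jump product identity on an edge
#'
#' Evaluates both sides of the identity
#' \code{[[q u]] = [[q]] \{u\} + \{q\} . [[u]]} for one-sided values of a
#' vector field q and a scalar u on an edge with unit normal `normal`
#' (pointing out of the plus side) and returns the residual.
#'
#' @param qPlus,qMinus numeric length 2, one-sided vector values.
#' @param uPlus,uMinus scalars.
#' @param normal unit normal of the plus side.
#' @return residual (expected 0 to round-off).
#' @export
jumpIdentityCheck <- function(qPlus, qMinus, uPlus, uMinus, normal) {
  nP <- normal; nM <- -normal
  lhs <- sum(qPlus * nP) * uPlus + sum(qMinus * nM) * uMinus
  jq <- sum(qPlus * nP) + sum(qMinus * nM)
  au <- (uPlus + uMinus) / 2
  aq <- (qPlus + qMinus) / 2
  ju <- uPlus * nP + uMinus * nM
  lhs - (jq * au + sum(aq * ju))
}

# Boundary load int_{dOmega} g v ds for a prescribed normal flux
# g(x, y, nx, ny); used by verification harnesses.
boundaryFluxVector <- function(space, fluxFun) {
  mesh <- space@mesh
  eg <- elementGeometry(mesh)
  rhs <- numeric(space@ndof)
  gl <- gauss01(3L)
  bnd <- which(mesh@edgeClass == "outer_boundary")
  for (i in bnd) {
    a <- mesh@edges[i, 1L]; b <- mesh@edges[i, 2L]
    pa <- mesh@vertices[a, ]; pb <- mesh@vertices[b, ]
    L <- sqrt(sum((pb - pa)^2))
    tvec <- (pb - pa) / L
    n <- c(tvec[2L], -tvec[1L])
    e <- mesh@edgeElements[i, 1L]
    mid <- (pa + pb) / 2
    if (sum(n * (mid - eg$centroid[e, ])) < 0) n <- -n
    Te <- matrix(0, 2L, 3L)
    ve <- mesh@triangles[e, ]
    Te[1L, ve == a] <- 1; Te[2L, ve == b] <- 1
    dofs <- (e - 1L) * 3L + 1:3
    for (q in seq_along(gl$x)) {
      s <- gl$x[q]
      x <- pa + s * (pb - pa)
      g <- fluxFun(x[1L], x[2L], n[1L], n[2L])
      trace <- c(1 - s, s)
      rhs[dofs] <- rhs[dofs] + gl$w[q] * L * g * as.vector(trace %*% Te)
    }
  }
  rhs
}

#' L2 norm of a DG field
#'
#' @param space a [DGSpace].
#' @param coefs nodal coefficient vector.
#' @return sqrt of int coefs^2 dx.
#' @export
fieldL2Norm <- function(space, coefs) {
  M <- massMatrix(space)
  sqrt(max(0, sum(coefs * as.numeric(M %*% coefs))))
}
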