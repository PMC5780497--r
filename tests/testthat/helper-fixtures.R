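# Shared fixtures, built in code. Expensive objects are memoized per session.

paperGeometry <- function(pixelSize = 0.05467326) {
  syntheticGeometry(
    cellEllipse    = list(center = c(7.5, 7.5), semiAxes = c(6, 5)),
    nucleusEllipse = list(center = c(7.5, 7.5), semiAxes = c(2.5, 2)),
    bleachCenter   = c(11.5, 7.5),
    pixelSize      = pixelSize)
}

truthParams <- function() modelParameters(16.1, 35.6, 0.319, 0.111)

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) assign(key, force(expr), .fixtureCache)
  .fixtureCache[[key]]
}

# coarse calibration-scale setup (~400 elements)
coarseSetup <- function() memo("coarse", {
  mesh <- triangulateGeometry(paperGeometry(), 0.9)
  space <- dgSpace(mesh)
  c0 <- ifelse(dofRegion(space) == "nucleus", 0.85, 0.35)
  list(mesh = mesh, space = space, c0 = c0)
})

# paper-scale mesh (~1500 elements)
fineSetup <- function() memo("fine", {
  mesh <- triangulateGeometry(paperGeometry(), 0.45)
  space <- dgSpace(mesh)
  c0 <- ifelse(dofRegion(space) == "nucleus", 0.85, 0.35)
  list(mesh = mesh, space = space, c0 = c0)
})

relErr <- function(est, truth) abs(est - truth) / abs(truth)

# Independent symbolic-style assembly of the IPDG diffusion matrix on the
# two-triangle unit-square mesh: explicit affine basis functions, exact
# 3-point Gauss quadrature on the shared edge. Used as the oracle for the
# vectorized assembly path.
handAssembledTwoTriangleD <- function(mesh, alpha, sigma) {
  tri <- meshTriangles(mesh); v <- meshVertices(mesh)
  basisCoef <- function(e) solve(cbind(1, v[tri[e, ], ]))  # cols: phi_1..3
  area <- function(e) {
    p <- v[tri[e, ], ]
    abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
          (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
  }
  grads <- lapply(1:2, function(e) basisCoef(e)[2:3, ])
  oracle <- matrix(0, 6, 6)
  for (e in 1:2) {
    idx <- (e - 1) * 3 + 1:3
    oracle[idx, idx] <- oracle[idx, idx] +
      alpha * area(e) * (t(grads[[e]]) %*% grads[[e]])
  }
  ie <- which(edgeClass(mesh) == "interior")
  a <- mesh@edges[ie, 1]; b <- mesh@edges[ie, 2]
  A <- v[a, ]; B <- v[b, ]
  L <- sqrt(sum((B - A)^2))
  ep <- mesh@edgeElements[ie, 1]; em <- mesh@edgeElements[ie, 2]
  tvec <- (B - A) / L
  n <- c(tvec[2], -tvec[1])
  centEp <- colMeans(v[tri[ep, ], ])
  if (sum(n * ((A + B) / 2 - centEp)) < 0) n <- -n
  hEdge <- mean(c(max(dist(v[tri[ep, ], ])), max(dist(v[tri[em, ], ]))))
  gq <- list(x = 0.5 + c(-sqrt(3 / 5), 0, sqrt(3 / 5)) / 2, w = c(5, 8, 5) / 18)
  phiAt <- function(e, x) as.numeric(c(1, x) %*% basisCoef(e))
  side <- c(rep(ep, 3), rep(em, 3))
  sign_ <- c(rep(1, 3), rep(-1, 3))
  locIdx <- c(1:3, 1:3)
  dofMap <- c((ep - 1) * 3 + 1:3, (em - 1) * 3 + 1:3)
  for (q in seq_along(gq$x)) {
    x <- A + gq$x[q] * (B - A)
    w <- gq$w[q] * L
    tr <- numeric(6); gn <- numeric(6)
    for (k in 1:6) {
      tr[k] <- phiAt(side[k], x)[locIdx[k]]
      gn[k] <- sum(grads[[side[k]]][, locIdx[k]] * n)
    }
    for (i in 1:6) for (j in 1:6) {
      ii <- dofMap[i]; jj <- dofMap[j]
      oracle[ii, jj] <- oracle[ii, jj] +
        w * (sigma / hEdge) * sign_[i] * tr[i] * sign_[j] * tr[j] -
        w * (alpha / 2) * gn[j] * sign_[i] * tr[i] -
        w * (alpha / 2) * gn[i] * sign_[j] * tr[j]
    }
  }
  oracle
}
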