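# Small geometric helpers shared across modules. Polygons are (n x 2)
# matrices of vertices in order, not closed (last row != first row).

polygonArea <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygonPerimeter <- function(poly) {
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  sum(sqrt(rowSums((poly[j, , drop = FALSE] - poly)^2)))
}

polygonCentroid <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Crossing-number point-in-polygon, vectorized over points.
pointsInPolygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  n <- nrow(poly)
  px <- poly[, 1L]; py <- poly[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  inside <- logical(nrow(pts))
  x <- pts[, 1L]; y <- pts[, 2L]
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (qy[i] > y))
    if (any(crosses)) {
      xi <- px[i] + (y[crosses] - py[i]) * (qx[i] - px[i]) / (qy[i] - py[i])
      inside[crosses] <- xor(inside[crosses], x[crosses] < xi)
    }
  }
  inside
}

pointInPolygon1 <- function(pt, poly) pointsInPolygon(matrix(pt, ncol = 2L), poly)[1L]

# Radial function of a star-shaped polygon about `center`: piecewise-linear
# interpolation of vertex radii over vertex angles (periodic). Errors if the
# polygon is not star-shaped about the center (angles not monotone).
radialFunction <- function(poly, center) {
  d <- sweep(poly, 2L, center)
  phi <- atan2(d[, 2L], d[, 1L])
  r <- sqrt(rowSums(d^2))
  o <- order(phi)
  phi <- phi[o]; r <- r[o]
  if (anyDuplicated(phi))
    stop("outline is not star-shaped about its centre (duplicate angles)")
  phiExt <- c(phi[length(phi)] - 2 * pi, phi, phi[1L] + 2 * pi)
  rExt <- c(r[length(r)], r, r[1L])
  function(a) {
    a <- ((a + pi) %% (2 * pi)) - pi
    stats::approx(phiExt, rExt, xout = a)$y
  }
}

# Sample an ellipse outline.
ellipseOutline <- function(center, semiAxes, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + semiAxes[1L] * cos(th),
        center[2L] + semiAxes[2L] * sin(th))
}

# Triangle quadrature rules on the reference element in barycentric
# coordinates; columns L1, L2, L3, weight (weights sum to 1, scale by area).
triQuadrature <- function(order = 2L) {
  if (order <= 2L) {
    # 3-point edge-midpoint rule, exact for quadratics
    cbind(rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5)),
          rep(1 / 3, 3L))
  } else {
    # 6-point order-4 rule (Dunavant)
    a1 <- 0.445948490915965; b1 <- 0.108103018168070
    a2 <- 0.091576213509771; b2 <- 0.816847572980459
    w1 <- 0.223381589678011; w2 <- 0.109951743655322
    cbind(rbind(c(a1, a1, b1), c(a1, b1, a1), c(b1, a1, a1),
                c(a2, a2, b2), c(a2, b2, a2), c(b2, a2, a2)),
          c(w1, w1, w1, w2, w2, w2))
  }
}

# Gauss-Legendre points/weights on [0, 1].
gauss01 <- function(n = 3L) {
  if (n == 2L) {
    x <- 0.5 + c(-1, 1) / (2 * sqrt(3)); w <- c(0.5, 0.5)
  } else {
    x <- 0.5 + c(-sqrt(3 / 5), 0, sqrt(3 / 5)) / 2
    w <- c(5, 8, 5) / 18
  }
  list(x = x, w = w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
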