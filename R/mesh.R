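# Interface-conforming triangulation.
#
# The nucleus is meshed by mapping a structured square grid onto the unit
# disk (elliptical mapping, no centre singularity) and then radially onto the
# nucleus outline; the cytoplasm is meshed as a structured annulus between
# the nucleus and cell outlines along rays from the nucleus centre. Both
# parts share the nucleus-boundary vertices, so the membrane is a union of
# element edges by construction. Outlines must be star-shaped about the
# nucleus centre, which holds for typical segmented cell shapes.

# Triangulate a quad strip between two rings of equal length, splitting each
# quad along its shorter diagonal (keeps corner quads shape-regular).
ringStripTris <- function(inner, outer, verts) {
  n <- length(inner)
  i <- seq_len(n); ip <- c(i[-1L], 1L)
  d1 <- rowSums((verts[inner[i], , drop = FALSE] - verts[outer[ip], , drop = FALSE])^2)
  d2 <- rowSums((verts[outer[i], , drop = FALSE] - verts[inner[ip], , drop = FALSE])^2)
  useD1 <- d1 <= d2
  rbind(
    cbind(inner[i], outer[i], outer[ip])[useD1, , drop = FALSE],
    cbind(inner[i], outer[ip], inner[ip])[useD1, , drop = FALSE],
    cbind(inner[i], outer[i], inner[ip])[!useD1, , drop = FALSE],
    cbind(outer[i], outer[ip], inner[ip])[!useD1, , drop = FALSE])
}

# Build the edge table and classify edges from triangles + region labels.
finalizeMesh <- function(vertices, triangles, region, bleach) {
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL; dimnames(triangles) <- NULL
  ne <- nrow(triangles)
  # orient all triangles counter-clockwise
  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  cc <- vertices[triangles[, 3L], , drop = FALSE]
  det2 <- (b[, 1L] - a[, 1L]) * (cc[, 2L] - a[, 2L]) -
    (cc[, 1L] - a[, 1L]) * (b[, 2L] - a[, 2L])
  flip <- det2 < 0
  if (any(flip)) triangles[flip, 2:3] <- triangles[flip, 3:2]

  eAll <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
                triangles[, c(3L, 1L)])
  eKey <- paste(pmin(eAll[, 1L], eAll[, 2L]), pmax(eAll[, 1L], eAll[, 2L]))
  eElem <- rep(seq_len(ne), times = 3L)
  uk <- !duplicated(eKey)
  edges <- cbind(pmin(eAll[, 1L], eAll[, 2L]), pmax(eAll[, 1L], eAll[, 2L]))[uk, , drop = FALSE]
  keyLevels <- eKey[uk]
  idx <- match(eKey, keyLevels)
  ned <- nrow(edges)
  e1 <- rep(NA_integer_, ned); e2 <- rep(NA_integer_, ned)
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (is.na(e1[i])) e1[i] <- eElem[k] else e2[i] <- eElem[k]
  }
  cls <- ifelse(is.na(e2), "outer_boundary",
                ifelse(region[e1] == region[pmax(e2, 1L)], "interior", "membrane"))
  new("TriMesh", vertices = vertices, triangles = triangles,
      elementRegion = region, elementBleach = bleach,
      edges = edges, edgeClass = cls,
      edgeElements = cbind(e1, e2, deparse.level = 0L))
}

triangleAngles <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1L], , drop = FALSE]
  p2 <- vertices[triangles[, 2L], , drop = FALSE]
  p3 <- vertices[triangles[, 3L], , drop = FALSE]
  l1 <- sqrt(rowSums((p2 - p3)^2)); l2 <- sqrt(rowSums((p1 - p3)^2))
  l3 <- sqrt(rowSums((p1 - p2)^2))
  a1 <- acos(pmin(1, pmax(-1, (l2^2 + l3^2 - l1^2) / (2 * l2 * l3))))
  a2 <- acos(pmin(1, pmax(-1, (l1^2 + l3^2 - l2^2) / (2 * l1 * l3))))
  cbind(a1, a2, pi - a1 - a2) * 180 / pi
}

triangleAreas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  cc <- vertices[triangles[, 3L], , drop = FALSE]
  abs((b[, 1L] - a[, 1L]) * (cc[, 2L] - a[, 2L]) -
        (cc[, 1L] - a[, 1L]) * (b[, 2L] - a[, 2L])) / 2
}

#' Triangulate a cell geometry with a conforming membrane interface
#'
#' Produces a [TriMesh] in which the nucleus outline is a union of element
#' edges (so the membrane interface condition can be imposed edge-wise),
#' elements are labeled nucleus/cytoplasm, and elements whose centroid falls
#' inside the bleach disk are flagged. The bleach region is represented by
#' this flagged-element union; its boundary is not meshed, since bleaching is
#' a volume source and carries no jump condition.
#'
#' @param geometry a [CellGeometry].
#' @param targetEdgeLength requested edge length in um; must be positive and
#'   smaller than the nucleus semi-minor extent.
#' @param minAngle mesh-quality threshold in degrees (default 20); a mesh
#'   with a smaller angle is rejected.
#' @return a [TriMesh].
#' @export
triangulateGeometry <- function(geometry, targetEdgeLength, minAngle = 20) {
  h <- targetEdgeLength
  if (h <= 0) stop("targetEdgeLength must be positive")
  nucCtr <- polygonCentroid(geometry@nucleusOutline)
  rNuc <- radialFunction(geometry@nucleusOutline, nucCtr)
  rCell <- radialFunction(geometry@cellOutline, nucCtr)
  probe <- seq(0, 2 * pi, length.out = 721L)
  rN <- rNuc(probe); rC <- rCell(probe)
  if (any(!is.finite(rN)) || any(!is.finite(rC)) || any(rC <= rN))
    stop("outlines must be star-shaped about the nucleus centre and nested")
  if (h >= min(rN)) stop("targetEdgeLength must be smaller than the nucleus semi-minor axis")

  perimN <- polygonPerimeter(geometry@nucleusOutline)
  perimC <- polygonPerimeter(geometry@cellOutline)
  # angular count balances nucleus-boundary and cell-boundary chord lengths
  nsc <- max(2L, as.integer(ceiling(max(perimN, 0.7 * perimC) / h / 4)))
  ntheta <- 4L * nsc

  # --- nucleus: O-grid on the unit disk (square core + radial transition
  # rings blending to the circle; no centre or corner singularity), then
  # scaled radially onto the outline ---
  w <- 0.5                                   # half-width of the core square
  s <- seq(-w, w, length.out = nsc + 1L)
  coreX <- rep(s, times = nsc + 1L)
  coreY <- rep(s, each = nsc + 1L)
  vid <- matrix(seq_len((nsc + 1L)^2), nsc + 1L, nsc + 1L)
  nucTris <- NULL
  for (j in seq_len(nsc)) {
    i <- seq_len(nsc)
    nucTris <- rbind(nucTris,
                     cbind(vid[i, j], vid[i + 1L, j], vid[i + 1L, j + 1L]),
                     cbind(vid[i, j], vid[i + 1L, j + 1L], vid[i, j + 1L]))
  }
  # core-square boundary, counter-clockwise
  sqIdx <- c(vid[1:nsc, 1L], vid[nsc + 1L, 1:nsc],
             vid[(nsc + 1L):2L, nsc + 1L], vid[1L, (nsc + 1L):2L])
  stopifnot(length(sqIdx) == ntheta)
  sqPts <- cbind(coreX[sqIdx], coreY[sqIdx])
  sqR <- sqrt(rowSums(sqPts^2))
  bPhiUnit <- atan2(sqPts[, 2L], sqPts[, 1L])
  nrr <- max(2L, as.integer(round((1 - mean(sqR)) * ntheta / (2 * pi))))
  # uniform target angles on the circle (same ordering as the square walk),
  # blended with the square-boundary angles across the transition rings so
  # corner wedges relax to uniform spacing
  phiUni <- bPhiUnit[1L] + 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  dphi <- ((bPhiUnit - phiUni + pi) %% (2 * pi)) - pi
  diskVerts <- cbind(coreX, coreY)
  ringIds <- vector("list", nrr + 1L)
  ringIds[[1L]] <- sqIdx
  for (j in seq_len(nrr)) {
    f <- j / nrr
    rj <- (1 - f) * sqR + f                  # radius along each angular ray
    phij <- phiUni + (1 - f) * dphi
    ringIds[[j + 1L]] <- nrow(diskVerts) + seq_len(ntheta)
    diskVerts <- rbind(diskVerts, cbind(rj * cos(phij), rj * sin(phij)))
  }
  bIdx <- ringIds[[nrr + 1L]]                # unit-circle ring = membrane
  bPhi <- phiUni
  # map unit disk radially onto the nucleus outline
  rho <- sqrt(rowSums(diskVerts^2))
  phi <- atan2(diskVerts[, 2L], diskVerts[, 1L])
  rb <- rNuc(phi)
  nucVerts <- cbind(nucCtr[1L] + rho * rb * cos(phi),
                    nucCtr[2L] + rho * rb * sin(phi))

  # --- cytoplasm: structured annulus on rays through the boundary vertices ---
  rIn <- rNuc(bPhi); rOut <- rCell(bPhi)
  m <- max(2L, as.integer(round(mean(rOut - rIn) / h)))
  nv0 <- nrow(nucVerts)
  ringVerts <- NULL
  annRingIds <- vector("list", m + 1L)
  annRingIds[[1L]] <- bIdx
  for (k in seq_len(m)) {
    f <- k / m
    rk <- rIn + f * (rOut - rIn)
    annRingIds[[k + 1L]] <- nv0 + (k - 1L) * ntheta + seq_len(ntheta)
    ringVerts <- rbind(ringVerts,
                       cbind(nucCtr[1L] + rk * cos(bPhi), nucCtr[2L] + rk * sin(bPhi)))
  }
  vertices <- rbind(nucVerts, ringVerts)
  for (j in seq_len(nrr))
    nucTris <- rbind(nucTris, ringStripTris(ringIds[[j]], ringIds[[j + 1L]], vertices))
  annTris <- NULL
  for (k in seq_len(m))
    annTris <- rbind(annTris, ringStripTris(annRingIds[[k]], annRingIds[[k + 1L]], vertices))
  triangles <- rbind(nucTris, annTris)
  region <- c(rep("nucleus", nrow(nucTris)), rep("cytoplasm", nrow(annTris)))

  cent <- (vertices[triangles[, 1L], ] + vertices[triangles[, 2L], ] +
             vertices[triangles[, 3L], ]) / 3
  r2 <- (cent[, 1L] - geometry@bleachCenter[1L])^2 +
    (cent[, 2L] - geometry@bleachCenter[2L])^2
  bleach <- r2 <= (geometry@bleachDiameter / 2)^2 & region == "cytoplasm"

  areas <- triangleAreas(vertices, triangles)
  if (any(areas < 1e-14))
    stop("mesh-quality error: degenerate (near-zero-area) triangle produced")
  ang <- triangleAngles(vertices, triangles)
  if (min(ang) < minAngle)
    stop(sprintf("mesh-quality error: minimum angle %.1f deg below %.1f deg",
                 min(ang), minAngle))
  finalizeMesh(vertices, triangles, region, bleach)
}

#' Structured triangular mesh of a rectangle
#'
#' Utility mesh for verification problems: a uniform nx-by-ny grid of the
#' rectangle [0, width] x [0, height], each cell split into two triangles.
#' If `interfaceX` is given (it must coincide with a grid line), elements
#' left of it are labeled "nucleus", elements right of it "cytoplasm", and
#' the vertical grid line becomes a membrane — a two-slab configuration with
#' a straight internal interface.
#'
#' @param nx,ny number of cells per direction.
#' @param width,height rectangle dimensions (um).
#' @param interfaceX optional x coordinate of an internal membrane.
#' @return a [TriMesh].
#' @export
rectangleMesh <- function(nx, ny, width = 1, height = 1, interfaceX = NULL) {
  xs <- seq(0, width, length.out = nx + 1L)
  ys <- seq(0, height, length.out = ny + 1L)
  if (!is.null(interfaceX)) {
    if (min(abs(xs - interfaceX)) > 1e-12 * max(1, width))
      stop("interfaceX must coincide with a vertical grid line")
  }
  vid <- matrix(seq_len((nx + 1L) * (ny + 1L)), nx + 1L, ny + 1L)
  vertices <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L))
  tris <- NULL
  for (j in seq_len(ny)) {
    i <- seq_len(nx)
    tris <- rbind(tris,
                  cbind(vid[i, j], vid[i + 1L, j], vid[i + 1L, j + 1L]),
                  cbind(vid[i, j], vid[i + 1L, j + 1L], vid[i, j + 1L]))
  }
  cent <- (vertices[tris[, 1L], 1L] + vertices[tris[, 2L], 1L] +
             vertices[tris[, 3L], 1L]) / 3
  region <- if (is.null(interfaceX)) rep("cytoplasm", nrow(tris)) else
    ifelse(cent < interfaceX, "nucleus", "cytoplasm")
  finalizeMesh(vertices, tris, region, rep(FALSE, nrow(tris)))
}

#' Region measures of a mesh
#'
#' @param mesh a [TriMesh].
#' @return list with `areaNucleus`, `areaCytoplasm`, `areaCell`,
#'   `membraneLength` and `bleachArea` (um^2 / um).
#' @export
regionMeasures <- function(mesh) {
  areas <- triangleAreas(mesh@vertices, mesh@triangles)
  memEdges <- mesh@edges[mesh@edgeClass == "membrane", , drop = FALSE]
  memLen <- if (nrow(memEdges)) {
    d <- mesh@vertices[memEdges[, 1L], , drop = FALSE] -
      mesh@vertices[memEdges[, 2L], , drop = FALSE]
    sum(sqrt(rowSums(d^2)))
  } else 0
  list(areaNucleus = sum(areas[mesh@elementRegion == "nucleus"]),
       areaCytoplasm = sum(areas[mesh@elementRegion == "cytoplasm"]),
       areaCell = sum(areas),
       membraneLength = memLen,
       bleachArea = sum(areas[mesh@elementBleach]))
}

#' Mesh accessors
#'
#' Read-only access to the components of a [TriMesh].
#'
#' @param mesh a [TriMesh].
#' @name mesh-accessors
#' @rdname mesh-accessors
NULL

#' @rdname mesh-accessors
#' @export
nElements <- function(mesh) nrow(mesh@triangles)

#' @rdname mesh-accessors
#' @export
meshEdges <- function(mesh) mesh@edges

#' @rdname mesh-accessors
#' @export
edgeClass <- function(mesh) mesh@edgeClass

#' @rdname mesh-accessors
#' @export
elementRegion <- function(mesh) mesh@elementRegion

#' @rdname mesh-accessors
#' @export
elementBleach <- function(mesh) mesh@elementBleach

#' @rdname mesh-accessors
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @rdname mesh-accessors
#' @export
meshTriangles <- function(mesh) mesh@triangles

setMethod("show", "TriMesh", function(object) {
  rm_ <- regionMeasures(object)
  cat(sprintf("TriMesh: %d triangles (%d nucleus, %d cytoplasm, %d bleach-flagged)\n",
              nrow(object@triangles),
              sum(object@elementRegion == "nucleus"),
              sum(object@elementRegion == "cytoplasm"),
              sum(object@elementBleach)))
  cat(sprintf("  %d edges: %d outer, %d interior, %d membrane\n",
              nrow(object@edges), sum(object@edgeClass == "outer_boundary"),
              sum(object@edgeClass == "interior"),
              sum(object@edgeClass == "membrane")))
  cat(sprintf("  areas: cell %.3f, nucleus %.3f um^2; membrane %.3f um\n",
              rm_$areaCell, rm_$areaNucleus, rm_$membraneLength))
})
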