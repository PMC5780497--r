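#' Construct a synthetic cell geometry
#'
#' Builds a [CellGeometry] from elliptical cell and nucleus outlines and a
#' circular bleach region placed in the cytoplasm. This stands in for the
#' segmentation step of an experimental pipeline: label masks produced from a
#' real acquisition can be supplied to [geometryFromMasks()] instead.
#'
#' Defaults mirror a typical confocal FLIP acquisition: a field of about
#' 15 x 15 um at 0.05467326 um per pixel, with a 30-pixel (1.64 um) diameter
#' circular bleach region in the cytoplasm.
#'
#' @param cellEllipse list with `center` (length 2, um) and `semiAxes`
#'   (length 2, um) of the cell outline.
#' @param nucleusEllipse list with `center` and `semiAxes` of the nucleus.
#' @param bleachCenter numeric length 2, centre of the bleach disk (um).
#' @param bleachDiameter bleach disk diameter in um (default 1.64).
#' @param pixelSize pixel edge length in um (default 0.05467326).
#' @param fieldExtent numeric length 2, field width and height in um.
#' @param outlinePoints number of polygon vertices per outline.
#' @return a valid [CellGeometry].
#' @examples
#' geo <- syntheticGeometry(
#'   cellEllipse    = list(center = c(7.5, 7.5), semiAxes = c(6, 5)),
#'   nucleusEllipse = list(center = c(7.5, 7.5), semiAxes = c(2.5, 2)),
#'   bleachCenter   = c(11.5, 7.5))
#' @export
syntheticGeometry <- function(cellEllipse,
                              nucleusEllipse,
                              bleachCenter,
                              bleachDiameter = 1.64,
                              pixelSize = 0.05467326,
                              fieldExtent = c(15, 15),
                              outlinePoints = 256L) {
  cellOut <- ellipseOutline(cellEllipse$center, cellEllipse$semiAxes, outlinePoints)
  nucOut <- ellipseOutline(nucleusEllipse$center, nucleusEllipse$semiAxes, outlinePoints)
  geo <- new("CellGeometry",
             cellOutline = cellOut, nucleusOutline = nucOut,
             bleachCenter = as.numeric(bleachCenter),
             bleachDiameter = bleachDiameter,
             pixelSize = pixelSize, fieldExtent = as.numeric(fieldExtent))
  v <- validObject(geo, test = TRUE)
  if (!isTRUE(v)) stop("invalid geometry: ", paste(v, collapse = "; "))
  geo
}

#' Extract a cell geometry from a label mask
#'
#' Accepts a single-channel integer label image using the codes 0 background,
#' 1 cytoplasm, 2 nucleus, 3 bleach, and recovers the cell and nucleus
#' outlines as closed polygons in physical micrometres (origin at the lower
#' left, y up; the raster y-flip is handled here). Each label must form one
#' connected component; the outlines must be star-shaped about their
#' centroids, which holds for typical convex-ish cell and nucleus shapes.
#'
#' @param labelImage integer matrix (rows x cols), row 1 = top of the image.
#' @param pixelSize um per pixel.
#' @return a [CellGeometry].
#' @export
geometryFromMasks <- function(labelImage, pixelSize) {
  if (pixelSize <= 0) stop("pixelSize must be positive")
  lab <- as.matrix(labelImage)
  if (!all(lab %in% 0:3)) stop("label image must use codes 0..3")
  cellMask <- lab >= 1L
  nucMask <- lab == 2L
  bleachMask <- lab == 3L
  if (!any(cellMask)) stop("mask contains no cell pixels (all background)")
  if (!any(nucMask)) stop("mask contains no nucleus pixels")
  for (nm in c("cell", "nucleus", "bleach")) {
    m <- switch(nm, cell = cellMask, nucleus = nucMask, bleach = bleachMask)
    if (!any(m)) next
    ncomp <- max(EBImage::bwlabel(m * 1))
    if (ncomp != 1L)
      stop("label '", nm, "' must form one connected component, found ", ncomp)
  }
  if (any(nucMask[1L, ]) || any(nucMask[nrow(lab), ]) ||
      any(nucMask[, 1L]) || any(nucMask[, ncol(lab)]))
    stop("nucleus label touches the image border; containment violated")

  cellOut <- traceOutline(cellMask, pixelSize)
  nucOut <- traceOutline(nucMask, pixelSize)
  if (!all(pointsInPolygon(shrinkPolygon(nucOut, 1e-6), cellOut)))
    stop("nucleus outline not inside cell outline; nesting violated")
  if (any(bleachMask)) {
    ctr <- maskCentroidPhysical(bleachMask, pixelSize)
    dia <- 2 * sqrt(sum(bleachMask) * pixelSize^2 / pi)
  } else {
    stop("mask contains no bleach pixels (code 3)")
  }
  geo <- new("CellGeometry",
             cellOutline = cellOut, nucleusOutline = nucOut,
             bleachCenter = ctr, bleachDiameter = dia, pixelSize = pixelSize,
             fieldExtent = c(ncol(lab), nrow(lab)) * pixelSize)
  v <- validObject(geo, test = TRUE)
  if (!isTRUE(v)) stop("invalid geometry from masks: ", paste(v, collapse = "; "))
  geo
}

# Physical (x, y) coordinates of pixel centres of a mask, lower-left origin.
maskPixelCenters <- function(mask, pixelSize) {
  idx <- which(mask, arr.ind = TRUE)
  nr <- nrow(mask)
  cbind(x = (idx[, 2L] - 0.5) * pixelSize,
        y = (nr - idx[, 1L] + 0.5) * pixelSize)
}

maskCentroidPhysical <- function(mask, pixelSize) {
  colMeans(maskPixelCenters(mask, pixelSize))
}

# Outline of a connected mask as a polygon: boundary pixels (mask pixels with
# a 4-neighbour outside) ordered by angle about the mask centroid. Adequate
# for star-shaped regions, which the mesher requires anyway.
traceOutline <- function(mask, pixelSize) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  boundary <- mask & !inner
  pts <- maskPixelCenters(boundary, pixelSize)
  ctr <- maskCentroidPhysical(mask, pixelSize)
  ang <- atan2(pts[, 2L] - ctr[2L], pts[, 1L] - ctr[1L])
  ord <- order(ang)
  pts <- pts[ord, , drop = FALSE]
  # collapse boundary pixels sharing (numerically) one ray
  ang <- ang[ord]
  keep <- c(TRUE, diff(ang) > 1e-9)
  pts <- unname(pts[keep, , drop = FALSE])
  # boundary-pixel centres sit ~half a pixel inside the true outline;
  # push them outward radially to compensate
  d <- sweep(pts, 2L, ctr)
  r <- sqrt(rowSums(d^2))
  pts + d / r * (pixelSize / 2)
}

shrinkPolygon <- function(poly, eps) {
  ctr <- polygonCentroid(poly)
  sweep(sweep(poly, 2L, ctr), 2L, ctr, FUN = function(d, c) c + d * (1 - eps))
}

#' Rasterize a geometry to a label mask
#'
#' Renders a [CellGeometry] as an integer label image (0 background,
#' 1 cytoplasm, 2 nucleus, 3 bleach) at its pixel size; the inverse of
#' [geometryFromMasks()] up to pixelation.
#'
#' @param geometry a [CellGeometry].
#' @return integer matrix, row 1 = top of the image.
#' @export
rasterizeGeometry <- function(geometry) {
  px <- geometry@pixelSize
  nc <- ceiling(geometry@fieldExtent[1L] / px)
  nr <- ceiling(geometry@fieldExtent[2L] / px)
  cx <- (seq_len(nc) - 0.5) * px
  cy <- (nr - seq_len(nr) + 0.5) * px
  pts <- cbind(rep(cx, each = nr), rep(cy, times = nc))
  lab <- integer(nr * nc)
  inCell <- pointsInPolygon(pts, geometry@cellOutline)
  lab[inCell] <- 1L
  inNuc <- pointsInPolygon(pts, geometry@nucleusOutline)
  lab[inNuc & inCell] <- 2L
  r2 <- (pts[, 1L] - geometry@bleachCenter[1L])^2 +
    (pts[, 2L] - geometry@bleachCenter[2L])^2
  lab[inCell & !inNuc & r2 <= (geometry@bleachDiameter / 2)^2] <- 3L
  matrix(lab, nr, nc)
}

setMethod("show", "CellGeometry", function(object) {
  cat("CellGeometry\n")
  cat(sprintf("  cell outline: %d vertices, area %.2f um^2\n",
              nrow(object@cellOutline), polygonArea(object@cellOutline)))
  cat(sprintf("  nucleus outline: %d vertices, area %.2f um^2\n",
              nrow(object@nucleusOutline), polygonArea(object@nucleusOutline)))
  cat(sprintf("  bleach disk: centre (%.2f, %.2f), diameter %.3f um\n",
              object@bleachCenter[1L], object@bleachCenter[2L],
              object@bleachDiameter))
  cat(sprintf("  field %.2f x %.2f um at %.6g um/px\n",
              object@fieldExtent[1L], object@fieldExtent[2L], object@pixelSize))
})
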