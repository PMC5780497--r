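# Image-stack handling: multi-page float TIFF IO, masked Gaussian
# preconditioning, raster <-> DG-mesh conversion, and synthetic FLIP stacks.
#
# Raster convention: frame row 1 is the top of the image; mesh coordinates
# are physical um with the origin at the lower-left pixel corner and y up,
# so y = (nrow - row + 0.5) * pixelSize and x = (col - 0.5) * pixelSize.

#' Construct an image stack
#'
#' @param frames numeric array (rows x cols x nframes) or a list of matrices.
#' @param times frame timestamps (s), strictly increasing.
#' @param pixelSize um per pixel.
#' @param cellMask optional logical matrix.
#' @param meta optional metadata list.
#' @return an [ImageStack].
#' @export
imageStack <- function(frames, times, pixelSize, cellMask = NULL, meta = list()) {
  if (is.list(frames))
    frames <- array(unlist(frames), dim = c(dim(frames[[1L]]), length(frames)))
  obj <- new("ImageStack", frames = frames, times = as.numeric(times),
             pixelSize = pixelSize, cellMask = cellMask, meta = meta)
  v <- validObject(obj, test = TRUE)
  if (!isTRUE(v)) stop("invalid image stack: ", paste(v, collapse = "; "))
  obj
}

#' Stack accessors
#' @param stack an [ImageStack].
#' @name stack-accessors
#' @rdname stack-accessors
NULL

#' @rdname stack-accessors
#' @export
stackFrames <- function(stack) stack@frames

#' @rdname stack-accessors
#' @export
frameTimes <- function(stack) stack@times

#' @rdname stack-accessors
#' @export
nFrames <- function(stack) dim(stack@frames)[3L]

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack: %d frames of %d x %d px (%.4g um/px), t in [%.2f, %.2f] s\n",
              d[3L], d[1L], d[2L], object@pixelSize, min(object@times),
              max(object@times)))
})

#' Read or write an image stack as multi-page TIFF
#'
#' Stacks are written as single-channel 32-bit multi-page TIFF (values on
#' [0, 1], quantization 2^-32, i.e. exact to one part in 4e9), with a JSON
#' sidecar (`<path>.json`) holding times,
#' pixel size, and metadata. 8/16-bit integer input read back from other
#' sources is rescaled to [0, 1] by the dtype maximum (the tiff reader does
#' this natively) and the bit depth is recorded in the metadata.
#'
#' @param path TIFF file path.
#' @param stack an [ImageStack].
#' @return `readStack` returns an [ImageStack].
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1L]])) == 3L)
    stop("format error: stack must be single-channel (got multi-channel data)")
  bits <- attr(pages[[1L]], "bits.per.sample") %||% NA
  frames <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    times <- meta$times
    px <- meta$pixelSize
    cellMask <- if (!is.null(meta$cellMaskPacked))
      matrix(meta$cellMaskPacked != 0L, dim(frames)[1L], dim(frames)[2L])
    meta$times <- NULL; meta$pixelSize <- NULL; meta$cellMaskPacked <- NULL
  } else {
    times <- seq_len(dim(frames)[3L]) - 1
    px <- 1
    cellMask <- NULL
    meta <- list()
  }
  meta$bitsPerSample <- bits
  imageStack(frames, times, px, cellMask, meta)
}

#' @rdname readStack
#' @export
writeStack <- function(stack, path) {
  if (min(stack@frames) < 0 || max(stack@frames) > 1)
    stop("stack intensities must lie in [0, 1] for storage; precondition first")
  d <- dim(stack@frames)
  pages <- lapply(seq_len(d[3L]), function(i) stack@frames[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- stack@meta
  meta$times <- stack@times
  meta$pixelSize <- stack@pixelSize
  if (!is.null(stack@cellMask)) meta$cellMaskPacked <- as.integer(stack@cellMask)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

gaussianKernel <- function(sigmaPx) {
  r <- max(1L, ceiling(4 * sigmaPx))
  x <- (-r):r
  k <- outer(stats::dnorm(x, sd = sigmaPx), stats::dnorm(x, sd = sigmaPx))
  k / sum(k)
}

# Mask-normalized Gaussian blur of one frame: outside-mask pixels do not
# bleed into the cell and are left unchanged themselves.
maskedBlur <- function(frame, mask, sigmaPx) {
  k <- gaussianKernel(sigmaPx)
  num <- EBImage::filter2(frame * mask, k, boundary = 0)
  den <- EBImage::filter2(mask * 1, k, boundary = 0)
  out <- frame
  inm <- mask & den > 0
  out[inm] <- num[inm] / den[inm]
  out
}

#' Precondition a FLIP stack
#'
#' Applies a Gaussian blur (standard deviation `blurRadiusPx` pixels,
#' mask-normalized so that pixels outside the cell do not bleed in) to every
#' frame within the cell domain, then normalizes the whole stack by the
#' maximum of the first blurred frame inside the cell, so the first frame
#' lies in [0, 1]. The normalization factor is recorded in the metadata.
#'
#' @param stack an [ImageStack] with a cell mask.
#' @param blurRadiusPx Gaussian standard deviation in pixels (default 1).
#' @return the preconditioned [ImageStack].
#' @export
precondition <- function(stack, blurRadiusPx = 1) {
  if (is.null(stack@cellMask)) stop("precondition requires a cell mask")
  if (!any(stack@cellMask)) stop("empty cell mask")
  d <- dim(stack@frames)
  out <- stack@frames
  for (i in seq_len(d[3L]))
    out[, , i] <- maskedBlur(stack@frames[, , i], stack@cellMask, blurRadiusPx)
  nrm <- max(out[, , 1L][stack@cellMask])
  if (nrm <= 0) stop("first frame has no positive intensity inside the mask")
  out <- out / nrm
  meta <- stack@meta
  meta$normalization <- nrm
  imageStack(out, stack@times, stack@pixelSize, stack@cellMask, meta)
}

# Fractional (row, col) image position of physical points.
physToPixel <- function(x, y, nrow, pixelSize) {
  list(col = x / pixelSize + 0.5, row = nrow - y / pixelSize + 0.5)
}

#' Interpolate an image frame onto a DG space
#'
#' Every DG node takes the bilinearly interpolated image value at its
#' physical location (with the raster y-flip applied).
#'
#' @param frame numeric matrix, row 1 = top.
#' @param space a [DGSpace] whose mesh lies inside the imaged field.
#' @param pixelSize um per pixel.
#' @return nodal coefficient vector.
#' @export
imageToMeshFunction <- function(frame, space, pixelSize) {
  xy <- dofCoordinates(space)
  nr <- nrow(frame); nc <- ncol(frame)
  pp <- physToPixel(xy[, 1L], xy[, 2L], nr, pixelSize)
  r <- pp$row; cc <- pp$col
  if (any(r < 0.5) || any(r > nr + 0.5) || any(cc < 0.5) || any(cc > nc + 0.5))
    stop("geometry/field mismatch: mesh node outside the image")
  # clamp into the centre grid, then bilinear
  r <- pmin(pmax(r, 1), nr); cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- r - r0; fc <- cc - c0
  v00 <- frame[cbind(r0, c0)]
  v10 <- frame[cbind(r0 + 1L, c0)]
  v01 <- frame[cbind(r0, c0 + 1L)]
  v11 <- frame[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Rasterize a DG field to a pixel image
#'
#' Every pixel centre inside the mesh is evaluated in its containing
#' element (so membrane discontinuities appear as sharp pixel steps);
#' pixels outside get `background`.
#'
#' @param coefs nodal coefficient vector.
#' @param space a [DGSpace].
#' @param nrow,ncol output image size.
#' @param pixelSize um per pixel.
#' @param background value for pixels outside the mesh.
#' @return numeric matrix.
#' @export
rasterizeField <- function(coefs, space, nrow, ncol, pixelSize, background = 0) {
  mesh <- space@mesh
  img <- matrix(background, nrow, ncol)
  cx <- (seq_len(ncol) - 0.5) * pixelSize
  cy <- (nrow - seq_len(nrow) + 0.5) * pixelSize
  tri <- mesh@triangles; v <- mesh@vertices
  for (e in seq_len(nrow(tri))) {
    p1 <- v[tri[e, 1L], ]; p2 <- v[tri[e, 2L], ]; p3 <- v[tri[e, 3L], ]
    xr <- range(p1[1L], p2[1L], p3[1L]); yr <- range(p1[2L], p2[2L], p3[2L])
    ci <- which(cx >= xr[1L] - pixelSize & cx <= xr[2L] + pixelSize)
    ri <- which(cy >= yr[1L] - pixelSize & cy <= yr[2L] + pixelSize)
    if (!length(ci) || !length(ri)) next
    px <- rep(cx[ci], each = length(ri))
    py <- rep(cy[ri], times = length(ci))
    det2 <- (p2[1L] - p1[1L]) * (p3[2L] - p1[2L]) -
      (p3[1L] - p1[1L]) * (p2[2L] - p1[2L])
    l2 <- ((px - p1[1L]) * (p3[2L] - p1[2L]) - (py - p1[2L]) * (p3[1L] - p1[1L])) / det2
    l3 <- ((p2[1L] - p1[1L]) * (py - p1[2L]) - (p2[2L] - p1[2L]) * (px - p1[1L])) / det2
    l1 <- 1 - l2 - l3
    tol <- -1e-12
    inside <- l1 >= tol & l2 >= tol & l3 >= tol
    if (!any(inside)) next
    dofs <- (e - 1L) * 3L
    vals <- l1 * coefs[dofs + 1L] + l2 * coefs[dofs + 2L] + l3 * coefs[dofs + 3L]
    rows <- rep(ri, times = length(ci))[inside]
    cols <- rep(ci, each = length(ri))[inside]
    img[cbind(rows, cols)] <- vals[inside]
  }
  img
}

#' Goal functions from a preconditioned stack
#'
#' Builds the calibration targets: one DG mesh function per frame, by nodal
#' interpolation of the blurred, normalized images.
#'
#' @param stack a preconditioned [ImageStack].
#' @param space a [DGSpace].
#' @param frames which frames to use (default all).
#' @return a [GoalSeries].
#' @export
goalSeriesFromStack <- function(stack, space, frames = NULL) {
  frames <- frames %||% seq_len(nFrames(stack))
  coefs <- vapply(frames, function(i)
    imageToMeshFunction(stack@frames[, , i], space, stack@pixelSize),
    numeric(space@ndof))
  new("GoalSeries", coefs = coefs, times = stack@times[frames])
}

#' @rdname goalSeriesFromStack
#' @param trajectory a [FlipTrajectory]; goals are its total-intensity
#'   snapshots (useful for self-consistency studies).
#' @export
goalSeriesFromTrajectory <- function(trajectory) {
  new("GoalSeries", coefs = trajectory@U + trajectory@Ub,
      times = trajectory@times)
}

#' Synthesize a FLIP image stack
#'
#' Forward-simulates the reaction-diffusion model from a steady initial
#' pattern, rasterizes the snapshots at the frame times, and adds seeded
#' Gaussian noise (clipped at zero). Ground-truth parameters, the seed and
#' the schedule are recorded in the stack metadata; the function also
#' returns the mesh, system and trajectory used, plus the label mask.
#'
#' @param params ground-truth [ModelParameters].
#' @param geometry a [CellGeometry].
#' @param schedule a [BleachSchedule].
#' @param basePattern initial intensity: a function(x, y), or NULL for the
#'   default steady pattern (0.35 in the cytoplasm, 0.85 in the nucleus,
#'   reflecting nuclear accumulation of the fluorophore).
#' @param noiseSd additive Gaussian noise standard deviation (intensity units).
#' @param seed integer seed for the noise.
#' @param targetEdgeLength mesh resolution (um).
#' @param refine iterative-refinement steps for the solver.
#' @return list with `stack`, `labelMask`, `mesh`, `space`, `system`,
#'   `trajectory` and the initial nodal intensity `c0`.
#' @export
synthesizeFlipStack <- function(params, geometry, schedule,
                                basePattern = NULL, noiseSd = 0.01,
                                seed = 1L, targetEdgeLength = 0.4,
                                refine = 1L) {
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  mesh <- triangulateGeometry(geometry, targetEdgeLength)
  space <- dgSpace(mesh)
  c0 <- if (is.null(basePattern)) {
    ifelse(dofRegion(space) == "nucleus", 0.85, 0.35)
  } else {
    xy <- dofCoordinates(space)
    basePattern(xy[, 1L], xy[, 2L])
  }
  if (any(c0 < 0) || any(c0 > 1)) stop("base pattern must lie in [0, 1]")
  rates <- rateMaps(c0, params@gamma)
  state <- initFieldsFromFrame(c0)
  system <- assembleSystem(space, params, rates)
  trajectory <- runFlip(state, system, schedule, bleach = TRUE, refine = refine)
  px <- geometry@pixelSize
  nc <- ceiling(geometry@fieldExtent[1L] / px)
  nr <- ceiling(geometry@fieldExtent[2L] / px)
  labelMask <- rasterizeGeometry(geometry)
  cellMask <- labelMask >= 1L
  set.seed(seed)
  ctot <- snapshotTotals(trajectory)
  frames <- array(0, dim = c(nr, nc, ncol(ctot)))
  for (i in seq_len(ncol(ctot))) {
    f <- rasterizeField(ctot[, i], space, nr, nc, px, background = 0)
    if (noiseSd > 0) f <- pmax(0, f + stats::rnorm(length(f), sd = noiseSd))
    frames[, , i] <- f
  }
  stack <- imageStack(frames, trajectory@times, px, cellMask,
                      meta = list(groundTruth = as.list(paramVector(params)),
                                  seed = seed, noiseSd = noiseSd,
                                  schedule = list(tBleach = schedule@tBleach,
                                                  tRecover = schedule@tRecover,
                                                  nFrames = schedule@nFrames,
                                                  dt = schedule@dt,
                                                  tOffset = schedule@tOffset)))
  list(stack = stack, labelMask = labelMask, mesh = mesh, space = space,
       system = system, trajectory = trajectory, c0 = c0)
}
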