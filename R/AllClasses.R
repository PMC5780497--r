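#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal t crossprod colSums rowSums
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Cell geometry for a FLIP experiment
#'
#' Holds the planar cell and nucleus outlines (closed polygons in micrometres,
#' origin at the lower-left corner of the imaged field, y increasing upward),
#' the circular bleach region placed in the cytoplasm, and the pixel geometry
#' of the imaged field.
#'
#' @slot cellOutline numeric matrix (n x 2), cell boundary polygon, not closed.
#' @slot nucleusOutline numeric matrix (m x 2), nucleus boundary polygon.
#' @slot bleachCenter numeric length 2, centre of the bleach disk (um).
#' @slot bleachDiameter numeric, diameter of the bleach disk (um).
#' @slot pixelSize numeric, pixel edge length (um/px).
#' @slot fieldExtent numeric length 2, width and height of the field (um).
#' @export
setClass("CellGeometry", representation(
  cellOutline    = "matrix",
  nucleusOutline = "matrix",
  bleachCenter   = "numeric",
  bleachDiameter = "numeric",
  pixelSize      = "numeric",
  fieldExtent    = "numeric"
))

setValidity("CellGeometry", function(object) {
  msg <- character()
  if (ncol(object@cellOutline) != 2L || nrow(object@cellOutline) < 3L)
    msg <- c(msg, "cellOutline must be an (n x 2) matrix with n >= 3")
  if (ncol(object@nucleusOutline) != 2L || nrow(object@nucleusOutline) < 3L)
    msg <- c(msg, "nucleusOutline must be an (m x 2) matrix with m >= 3")
  if (length(object@bleachCenter) != 2L)
    msg <- c(msg, "bleachCenter must have length 2")
  if (object@bleachDiameter <= 0) msg <- c(msg, "bleachDiameter must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) return(msg)
  if (!all(pointsInPolygon(object@nucleusOutline, object@cellOutline)))
    msg <- c(msg, "nucleus outline must lie strictly inside the cell outline")
  th <- seq(0, 2 * pi, length.out = 33L)[-33L]
  rim <- cbind(object@bleachCenter[1] + object@bleachDiameter / 2 * cos(th),
               object@bleachCenter[2] + object@bleachDiameter / 2 * sin(th))
  if (!all(pointsInPolygon(rim, object@cellOutline)))
    msg <- c(msg, "bleach disk must lie inside the cell outline")
  if (any(pointsInPolygon(rim, object@nucleusOutline)) ||
      pointInPolygon1(object@bleachCenter, object@nucleusOutline))
    msg <- c(msg, "bleach disk must lie outside the nucleus (in the cytoplasm)")
  if (length(msg)) msg else TRUE
})

#' Interface-conforming triangulation of a cell
#'
#' A triangulation whose edge set contains the nuclear membrane: every element
#' carries a region label (nucleus or cytoplasm) and a bleach flag, and every
#' edge is classified as outer boundary, interior, or membrane. Membrane edges
#' always separate a nucleus element from a cytoplasm element.
#'
#' @slot vertices numeric matrix (nv x 2), coordinates in um.
#' @slot triangles integer matrix (ne x 3), vertex indices, counter-clockwise.
#' @slot elementRegion character vector, "nucleus" or "cytoplasm" per element.
#' @slot elementBleach logical vector, TRUE for elements in the bleach region.
#' @slot edges integer matrix (ned x 2), vertex index pairs.
#' @slot edgeClass character vector: "outer_boundary", "interior", "membrane".
#' @slot edgeElements integer matrix (ned x 2), incident elements (NA if one).
#' @export
setClass("TriMesh", representation(
  vertices      = "matrix",
  triangles     = "matrix",
  elementRegion = "character",
  elementBleach = "logical",
  edges         = "matrix",
  edgeClass     = "character",
  edgeElements  = "matrix"
))

setValidity("TriMesh", function(object) {
  ne <- nrow(object@triangles)
  msg <- character()
  if (length(object@elementRegion) != ne) msg <- c(msg, "elementRegion length mismatch")
  if (length(object@elementBleach) != ne) msg <- c(msg, "elementBleach length mismatch")
  if (!all(object@elementRegion %in% c("nucleus", "cytoplasm")))
    msg <- c(msg, "elementRegion labels must be 'nucleus' or 'cytoplasm'")
  if (nrow(object@edges) != length(object@edgeClass) ||
      nrow(object@edges) != nrow(object@edgeElements))
    msg <- c(msg, "edge table size mismatch")
  if (!all(object@edgeClass %in% c("outer_boundary", "interior", "membrane")))
    msg <- c(msg, "invalid edge class")
  if (length(msg)) return(msg)
  bnd <- object@edgeClass == "outer_boundary"
  if (any(!is.na(object@edgeElements[bnd, 2L])))
    msg <- c(msg, "outer boundary edges must have exactly one incident element")
  two <- !bnd
  if (any(is.na(object@edgeElements[two, 2L])))
    msg <- c(msg, "interior/membrane edges must have two incident elements")
  mem <- object@edgeClass == "membrane"
  if (any(mem)) {
    r1 <- object@elementRegion[object@edgeElements[mem, 1L]]
    r2 <- object@elementRegion[object@edgeElements[mem, 2L]]
    if (any(r1 == r2))
      msg <- c(msg, "membrane edges must separate nucleus from cytoplasm")
  }
  int <- object@edgeClass == "interior"
  if (any(int)) {
    r1 <- object@elementRegion[object@edgeElements[int, 1L]]
    r2 <- object@elementRegion[object@edgeElements[int, 2L]]
    if (any(r1 != r2))
      msg <- c(msg, "interior edges must join elements of the same region")
  }
  if (any(object@elementBleach & object@elementRegion != "cytoplasm"))
    msg <- c(msg, "bleach elements must lie in the cytoplasm")
  if (length(msg)) msg else TRUE
})

#' Discontinuous Galerkin function space
#'
#' Nodal, fully discontinuous piecewise-linear space on a [TriMesh]: three
#' degrees of freedom per triangle, none shared between elements.
#'
#' @slot mesh a [TriMesh].
#' @slot degree integer polynomial degree (only 1 supported).
#' @slot ndof integer, total number of coefficients (3 per element).
#' @export
setClass("DGSpace", representation(
  mesh   = "TriMesh",
  degree = "integer",
  ndof   = "integer"
))

setValidity("DGSpace", function(object) {
  if (object@degree != 1L) return("only degree-1 (linear) elements are supported")
  if (object@ndof != 3L * nrow(object@mesh@triangles))
    return("ndof must equal 3 * number of elements")
  TRUE
})

#' Model parameters of the FLIP reaction-diffusion system
#'
#' @slot alpha diffusion coefficient of the free species (um^2/s).
#' @slot beta effective bleach rate b*q/(1+q) (1/s); the intrinsic bleach rate
#'   and the ground/excited equilibrium constant are not separately
#'   identifiable from FLIP data and are not stored individually.
#' @slot gamma proportionality constant of the binding-rate map (1/(intensity*s)).
#' @slot p membrane permeability (um/s).
#' @export
setClass("ModelParameters", representation(
  alpha = "numeric", beta = "numeric", gamma = "numeric", p = "numeric"
))

setValidity("ModelParameters", function(object) {
  v <- c(object@alpha, object@beta, object@gamma, object@p)
  if (length(v) != 4L || any(!is.finite(v)) || any(v <= 0))
    return("alpha, beta, gamma and p must all be finite and strictly positive")
  TRUE
})

#' Spatially varying binding/release rate maps
#'
#' Binding rate k+ is proportional to the initial hindered intensity
#' (k+ = gamma * ub0), stored in the same DG nodal basis as the fields so the
#' initial reaction equilibrium holds exactly in the discrete system; release
#' rate k- = gamma * u0 is a scalar.
#'
#' @slot kPlus numeric vector of nodal binding rates (1/s).
#' @slot kMinus numeric scalar release rate (1/s).
#' @slot u0 numeric, uniform initial free intensity used to build the maps.
#' @export
setClass("RateMaps", representation(
  kPlus = "numeric", kMinus = "numeric", u0 = "numeric"
))

setValidity("RateMaps", function(object) {
  if (any(object@kPlus < 0)) return("kPlus must be nonnegative everywhere")
  if (object@kMinus <= 0) return("kMinus must be strictly positive")
  TRUE
})

#' State of the two fluorophore pools
#'
#' @slot u numeric, DG coefficients of the free intensity.
#' @slot ub numeric, DG coefficients of the hindered intensity.
#' @slot t numeric, time (s).
#' @export
setClass("FieldState", representation(u = "numeric", ub = "numeric", t = "numeric"))

setValidity("FieldState", function(object) {
  if (length(object@u) != length(object@ub)) return("u and ub must have equal length")
  if (any(!is.finite(object@u)) || any(!is.finite(object@ub)))
    return("field coefficients must be finite")
  TRUE
})

#' Bleach/scan timing of a FLIP acquisition
#'
#' @slot tBleach bleach interval per frame (s).
#' @slot tRecover recovery/scan interval per frame (s).
#' @slot nFrames number of frames.
#' @slot dt solver time step (s); tBleach must be an integer multiple of dt.
#' @slot tOffset snapshot offset within each frame (s).
#' @export
setClass("BleachSchedule", representation(
  tBleach = "numeric", tRecover = "numeric", nFrames = "integer",
  dt = "numeric", tOffset = "numeric"
))

setValidity("BleachSchedule", function(object) {
  if (object@dt <= 0 || object@tBleach <= 0 || object@tRecover < 0)
    return("dt and tBleach must be positive, tRecover nonnegative")
  m <- object@tBleach / object@dt
  if (abs(m - round(m)) > 1e-9)
    return("tBleach must be an integer multiple of dt")
  period <- object@tBleach + object@tRecover
  k <- period / object@dt
  if (abs(k - round(k)) > 1e-9)
    return("frame period must be an integer multiple of dt")
  s <- object@tOffset / object@dt
  if (abs(s - round(s)) > 1e-9 || object@tOffset < 0 || object@tOffset > period)
    return("tOffset must lie on the step grid within one frame period")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  TRUE
})

#' Assembled IPDG system matrices
#'
#' Stores the mass matrix and parameter-normalized building blocks of the
#' semi-discrete system, so that rescaling in (alpha, beta, gamma, p) during
#' calibration does not require re-assembly. The actual operator blocks are
#' D = alpha * Dgrad1 + sigma * Dpen1 (interior-penalty diffusion),
#' P = p * P1 (membrane jump coupling), Kp = gamma * Kp1, Km = gamma * u0 * M,
#' B = beta * B1 (bleach mass on the bleach elements).
#'
#' @slot space the [DGSpace] the system was assembled on.
#' @slot M sparse mass matrix.
#' @slot Dgrad1 volume gradient + interior consistency terms per unit alpha.
#' @slot Dpen1 interior (sigma/h) penalty per unit sigma.
#' @slot P1 membrane jump coupling per unit permeability.
#' @slot Kp1 binding coupling per unit gamma (mass weighted by ub0).
#' @slot B1 bleach-region mass matrix per unit beta.
#' @slot params [ModelParameters] currently applied.
#' @slot rates [RateMaps] currently applied.
#' @slot sigmaFactor Nitsche parameter expressed as sigma/alpha.
#' @slot cache environment holding sparse LU factorizations keyed by (dt, bleach).
#' @export
setClass("AssembledSystem", representation(
  space = "DGSpace", M = "ANY", Dgrad1 = "ANY", Dpen1 = "ANY", P1 = "ANY",
  Kp1 = "ANY", B1 = "ANY", params = "ModelParameters", rates = "RateMaps",
  sigmaFactor = "numeric", cache = "environment"
))

#' Trajectory of a FLIP forward simulation
#'
#' @slot U matrix (ndof x nSnapshots) of free-intensity coefficients.
#' @slot Ub matrix (ndof x nSnapshots) of hindered-intensity coefficients.
#' @slot times numeric snapshot times t_i (s).
#' @slot mass data.frame per solver step: t, total, nucleus, cytoplasm.
#' @export
setClass("FlipTrajectory", representation(
  U = "matrix", Ub = "matrix", times = "numeric", mass = "data.frame"
))

#' Time-lapse fluorescence image stack
#'
#' @slot frames numeric array (nrow x ncol x nframes), row 1 = top of image.
#' @slot times numeric, strictly increasing frame timestamps (s).
#' @slot pixelSize numeric, um per pixel.
#' @slot cellMask logical matrix or NULL.
#' @slot meta list of free-form metadata (normalization, ground truth, seed).
#' @export
setClass("ImageStack", representation(
  frames = "array", times = "numeric", pixelSize = "numeric",
  cellMask = "matrixOrNULL", meta = "list"
))

setValidity("ImageStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3D array (rows x cols x nframes)")
  if (length(object@times) != d[3L]) return("times must have one entry per frame")
  if (d[3L] > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(!is.finite(object@frames))) return("frame intensities must be finite")
  if (!is.null(object@cellMask) && !identical(dim(object@cellMask), d[1:2]))
    return("cellMask must match frame dimensions")
  TRUE
})

#' Goal functions for calibration
#'
#' Per-frame DG mesh functions interpolating the preconditioned images.
#'
#' @slot coefs matrix (ndof x nFrames) of goal coefficients.
#' @slot times numeric snapshot times (s).
#' @export
setClass("GoalSeries", representation(coefs = "matrix", times = "numeric"))

setValidity("GoalSeries", function(object) {
  if (ncol(object@coefs) != length(object@times))
    return("one goal function per time required")
  if (any(object@coefs < -0.1) || any(object@coefs > 1.1))
    return("goal coefficients outside [-0.1, 1.1]; input not preconditioned?")
  TRUE
})

#' Misfit configuration
#'
#' @slot frameIndices integer, snapshots entering the misfit.
#' @slot weights numeric per-frame weights summing to one.
#' @export
setClass("MisfitConfig", representation(frameIndices = "integer", weights = "numeric"))

setValidity("MisfitConfig", function(object) {
  if (length(object@frameIndices) != length(object@weights))
    return("frameIndices and weights must have equal length")
  if (abs(sum(object@weights) - 1) > 1e-12) return("weights must sum to 1")
  TRUE
})

#' Result of a Nelder-Mead calibration
#'
#' @slot bestParams estimated [ModelParameters].
#' @slot bestE misfit value at the estimate.
#' @slot trace data.frame per iteration: best vertex, E1 and simplex spread E5-E1.
#' @slot nIterations integer.
#' @slot nEvaluations integer, forward solves performed.
#' @slot converged logical, TRUE if both tolerances were met.
#' @export
setClass("CalibrationResult", representation(
  bestParams = "ModelParameters", bestE = "numeric", trace = "data.frame",
  nIterations = "integer", nEvaluations = "integer", converged = "logical"
))

#' Pixel-wise stretched-exponential parameter maps
#'
#' @slot I0 amplitude image.
#' @slot tau time-constant image (s).
#' @slot hHet heterogeneity image (dimensionless, (0, 2]).
#' @slot Ib background image.
#' @slot rmse root-mean-square residual image.
#' @slot fitMask logical image of converged fits.
#' @export
setClass("StrExpMaps", representation(
  I0 = "matrix", tau = "matrix", hHet = "matrix", Ib = "matrix",
  rmse = "matrix", fitMask = "matrix"
))

#' Time-dependent rate-coefficient maps
#'
#' @slot kOfT numeric array (nrow x ncol x ntimes) of rate coefficients (1/s).
#' @slot times numeric evaluation times (s).
#' @export
setClass("RateCoefficientMap", representation(kOfT = "array", times = "numeric"))
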