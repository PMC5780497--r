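#' Model parameters
#'
#' Bundle the four parameters of the FLIP reaction-diffusion model: the
#' diffusion coefficient of the free species, the effective bleach rate, the
#' binding-rate proportionality constant and the nuclear-membrane
#' permeability. All must be strictly positive.
#'
#' @param alpha diffusion coefficient (um^2/s).
#' @param beta effective bleach rate (1/s).
#' @param gamma binding-rate proportionality (1/(intensity*s)).
#' @param p membrane permeability (um/s).
#' @return a [ModelParameters] object.
#' @examples
#' modelParameters(16.1, 35.6, 0.319, 0.111)
#' @export
modelParameters <- function(alpha, beta, gamma, p) {
  obj <- new("ModelParameters", alpha = alpha, beta = beta, gamma = gamma, p = p)
  v <- validObject(obj, test = TRUE)
  if (!isTRUE(v)) stop("parameter error: ", paste(v, collapse = "; "))
  obj
}

#' @rdname modelParameters
#' @param params a [ModelParameters] object.
#' @export
paramVector <- function(params) {
  c(alpha = params@alpha, beta = params@beta, gamma = params@gamma, p = params@p)
}

setMethod("show", "ModelParameters", function(object) {
  cat(sprintf(
    "ModelParameters: alpha = %.4g um^2/s, beta = %.4g 1/s, gamma = %.4g, p = %.4g um/s\n",
    object@alpha, object@beta, object@gamma, object@p))
})

#' Bleach/scan schedule
#'
#' Defaults follow a typical confocal FLIP protocol: a 0.8 s bleach pulse
#' followed by 1.8 s of recovery/scanning per frame (2.6 s frame period),
#' 50 frames, solver step 0.2 s, and snapshots taken 2.0 s into each frame
#' (i.e. at t_i = 2.6 (i - 1) + 2.0 s), during late recovery when the image
#' is scanned.
#'
#' @param tBleach bleach interval (s).
#' @param tRecover recovery interval (s).
#' @param nFrames number of frames.
#' @param dt solver time step (s).
#' @param tOffset snapshot time within each frame (s).
#' @return a [BleachSchedule].
#' @export
bleachSchedule <- function(tBleach = 0.8, tRecover = 1.8, nFrames = 50L,
                           dt = 0.2, tOffset = 2.0) {
  obj <- new("BleachSchedule", tBleach = tBleach, tRecover = tRecover,
             nFrames = as.integer(nFrames), dt = dt, tOffset = tOffset)
  v <- validObject(obj, test = TRUE)
  if (!isTRUE(v)) stop("schedule error: ", paste(v, collapse = "; "))
  obj
}

#' @rdname bleachSchedule
#' @param schedule a [BleachSchedule].
#' @export
snapshotTimes <- function(schedule) {
  (schedule@tBleach + schedule@tRecover) * (seq_len(schedule@nFrames) - 1L) +
    schedule@tOffset
}

#' @rdname bleachSchedule
#' @export
stepsPerFrame <- function(schedule) {
  m <- as.integer(round(schedule@tBleach / schedule@dt))
  k <- as.integer(round((schedule@tBleach + schedule@tRecover) / schedule@dt))
  c(bleach = m, recover = k - m)
}

#' Laser indicator function
#'
#' Returns 1 while the bleach laser is on (the first `tBleach` seconds of
#' each frame) and 0 during recovery; periodic with the frame period.
#'
#' @param t time (s), vectorized.
#' @param schedule a [BleachSchedule].
#' @return 0/1 vector.
#' @export
thetaAt <- function(t, schedule) {
  stopifnot(all(t >= 0))
  phase <- t %% (schedule@tBleach + schedule@tRecover)
  as.numeric(phase < schedule@tBleach)
}

#' Initialize free and hindered pools from the first frame
#'
#' Before bleaching the system is at reaction equilibrium with the free
#' molecules uniformly distributed; any excess intensity is carried by the
#' hindered pool. Hence u is set to the spatial minimum of the normalized
#' initial intensity and ub to the remainder.
#'
#' @param c0 numeric vector of nodal intensities of the first preconditioned
#'   frame, in [0, 1].
#' @return a [FieldState] at t = 0.
#' @export
initFieldsFromFrame <- function(c0) {
  if (any(c0 < 0) || any(c0 > 1))
    stop("normalization error: c0 must lie in [0, 1]; run precondition() first")
  u0 <- min(c0)
  new("FieldState", u = rep(u0, length(c0)), ub = c0 - u0, t = 0)
}

#' @rdname initFieldsFromFrame
#' @param u,ub nodal coefficient vectors.
#' @param t time (s).
#' @export
fieldState <- function(u, ub, t = 0) new("FieldState", u = u, ub = ub, t = t)

#' Field accessors
#' @param state a [FieldState].
#' @name field-accessors
#' @rdname field-accessors
NULL

#' @rdname field-accessors
#' @export
freeIntensity <- function(state) state@u

#' @rdname field-accessors
#' @export
hinderedIntensity <- function(state) state@ub

#' @rdname field-accessors
#' @export
totalIntensity <- function(state) state@u + state@ub

#' Build binding/release rate maps from the initial frame
#'
#' The binding rate is proportional to the initial hindered excess,
#' k+(x) = gamma * (c0(x) - min c0), so regions of elevated steady-state
#' intensity are modeled as regions of stronger hindrance; the release rate
#' is the constant k- = gamma * min(c0). By construction the initial state is
#' a nodewise equilibrium: k+ * u0 = k- * ub0.
#'
#' @param c0 nodal intensities of the first preconditioned frame.
#' @param gamma proportionality constant (> 0).
#' @return a [RateMaps] object.
#' @export
rateMaps <- function(c0, gamma) {
  if (!is.finite(gamma) || gamma <= 0) stop("parameter error: gamma must be > 0")
  if (any(c0 < 0) || any(c0 > 1)) stop("c0 must lie in [0, 1]")
  u0 <- min(c0)
  if (u0 <= 0) stop("min(c0) must be positive (nonzero background required)")
  new("RateMaps", kPlus = gamma * (c0 - u0), kMinus = gamma * u0, u0 = u0)
}

#' Membrane permeability from a first-order influx rate
#'
#' Converts a measured first-order nuclear influx rate constant into a
#' membrane permeability via p = k * V / A with nuclear volume V and nuclear
#' surface area A. Defaults are a typical mammalian nucleus (V = 1130 um^3,
#' A = 540 um^2).
#'
#' @param kInflux influx rate constant (1/s).
#' @param V nuclear volume (um^3).
#' @param A nuclear surface area (um^2).
#' @return permeability (um/s).
#' @export
permeabilityFromInflux <- function(kInflux, V = 1130, A = 540) {
  if (any(c(kInflux, V, A) <= 0)) stop("parameter error: inputs must be positive")
  kInflux * V / A
}

#' Stokes-Einstein scaling of a diffusion coefficient
#'
#' Rescales a reference diffusion coefficient to a probe of different Stokes
#' radius using D proportional to 1/R.
#'
#' @param alphaRef reference diffusion coefficient (um^2/s).
#' @param RRef reference Stokes radius (nm).
#' @param RNew new Stokes radius (nm).
#' @return scaled diffusion coefficient (um^2/s).
#' @export
scaleByStokesRadius <- function(alphaRef, RRef, RNew) {
  if (any(c(alphaRef, RRef, RNew) <= 0))
    stop("parameter error: radii and coefficient must be positive")
  alphaRef * RRef / RNew
}

#' Inert probe presets
#'
#' Model parameters for inert permeation probes of different Stokes radius,
#' scaled from a GFP reference (alpha = 16.1 um^2/s at R = 2.42 nm,
#' p = 0.111 um/s) by the Stokes-Einstein relation for diffusion. The
#' permeability is likewise reduced with size (1/R here); true size
#' dependence of nuclear-pore passage is much steeper, but the ordering of
#' probes is preserved, which is what forward comparisons rely on.
#'
#' @param name one of "Fl-Cys" (0.67 nm), "Ubq" (1.69 nm), "MBP" (2.85 nm),
#'   "GFP" (2.42 nm).
#' @param beta,gamma bleach and binding parameters to carry over.
#' @return a [ModelParameters] object with a `stokesRadius` attribute (nm).
#' @export
probePreset <- function(name = c("GFP", "Fl-Cys", "Ubq", "MBP"),
                        beta = 35.6, gamma = 0.319) {
  name <- match.arg(name)
  R <- c("GFP" = 2.42, "Fl-Cys" = 0.67, "Ubq" = 1.69, "MBP" = 2.85)[[name]]
  pp <- modelParameters(
    alpha = scaleByStokesRadius(16.1, 2.42, R),
    beta = beta, gamma = gamma,
    p = 0.111 * 2.42 / R)
  attr(pp, "stokesRadius") <- R
  pp
}

setMethod("show", "BleachSchedule", function(object) {
  spf <- stepsPerFrame(object)
  cat(sprintf(
    "BleachSchedule: %d frames of %.2f s (%.2f s bleach + %.2f s recovery), dt = %.3g s\n",
    object@nFrames, object@tBleach + object@tRecover, object@tBleach,
    object@tRecover, object@dt))
  cat(sprintf("  %d bleach + %d recovery steps per frame; snapshots at offset %.2f s\n",
              spf["bleach"], spf["recover"], object@tOffset))
})
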