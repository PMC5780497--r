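# Pixel-wise stretched/compressed exponential (StrExp) analysis of
# fluorescence-loss stacks:
#   I(x, t) = I0(x) exp[-(t / tau(x))^(1 / h(x))] + Ib(x),
# with heterogeneity h in (0, 2]: h < 1 compressed (delayed, accelerating
# loss), h = 1 mono-exponential, h > 1 stretched (decelerating loss). The
# instantaneous rate coefficient of the normalized decay is
#   k(x, t) = (1 / (h tau)) (t / tau)^(1/h - 1).

#' StrExp model function
#'
#' @param t time (s), vectorized.
#' @param I0 amplitude.
#' @param tau time constant (s).
#' @param h heterogeneity (0 < h <= 2).
#' @param Ib background.
#' @return model intensities.
#' @export
strExpValue <- function(t, I0, tau, h, Ib = 0) {
  I0 * exp(-(t / tau)^(1 / h)) + Ib
}

#' Fit a StrExp decay to one pixel time series
#'
#' Bounded Levenberg-Marquardt least squares with 0 < h <= 2, tau > 0,
#' I0 > 0, Ib >= 0. Initialization: Ib from the mean of the last 10 percent
#' of frames, I0 from the first value, tau from the 1/e crossing, h = 1.
#'
#' @param intensity numeric time series (>= 8 points, overall decreasing).
#' @param times matching time points (s), positive.
#' @return list with I0, tau, h, Ib, rmse, converged, degenerate.
#' @export
fitStrExpPixel <- function(intensity, times) {
  if (length(intensity) < 8L) stop("need at least 8 time points")
  if (length(intensity) != length(times)) stop("length mismatch")
  nTail <- max(1L, round(length(intensity) * 0.1))
  Ib0 <- max(0, mean(utils::tail(intensity, nTail)))
  I00 <- max(intensity[1L] - Ib0, 1e-6)
  if (diff(range(intensity)) < 1e-12) {
    return(list(I0 = 0, tau = NA_real_, h = NA_real_, Ib = mean(intensity),
                rmse = 0, converged = FALSE, degenerate = TRUE))
  }
  target <- Ib0 + I00 / exp(1)
  below <- which(intensity <= target)
  tau0 <- if (length(below)) times[below[1L]] else utils::tail(times, 1L)
  tau0 <- max(tau0, min(times) / 2)
  df <- data.frame(t = times, I = intensity)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ I0 * exp(-(t / tau)^(1 / h)) + Ib, data = df,
      start = list(I0 = I00, tau = tau0, h = 1, Ib = Ib0),
      lower = c(I0 = 1e-9, tau = 1e-9, h = 1e-3, Ib = 0),
      upper = c(I0 = Inf, tau = Inf, h = 2, Ib = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(I0 = NA_real_, tau = NA_real_, h = NA_real_, Ib = NA_real_,
                rmse = NA_real_, converged = FALSE, degenerate = FALSE))
  }
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  list(I0 = unname(cf["I0"]), tau = unname(cf["tau"]), h = unname(cf["h"]),
       Ib = unname(cf["Ib"]), rmse = rmse, converged = TRUE,
       degenerate = FALSE)
}

#' Fit StrExp decays pixel-wise over a stack
#'
#' Runs [fitStrExpPixel()] at every pixel inside the mask (on the
#' preconditioned stack); non-converged or degenerate pixels are excluded
#' from the fit mask, not silently returned.
#'
#' @param stack an [ImageStack] (preconditioned).
#' @param mask logical matrix of pixels to fit.
#' @return a [StrExpMaps] object.
#' @export
fitStrExpStack <- function(stack, mask) {
  if (is.null(mask) || !any(mask)) stop("empty mask")
  d <- dim(stack@frames)
  mk <- function() matrix(NA_real_, d[1L], d[2L])
  I0 <- mk(); tau <- mk(); hh <- mk(); Ib <- mk(); rmse <- mk()
  fitMask <- matrix(FALSE, d[1L], d[2L])
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1L]; cc <- idx[k, 2L]
    f <- fitStrExpPixel(stack@frames[r, cc, ], stack@times)
    if (isTRUE(f$converged)) {
      I0[r, cc] <- f$I0; tau[r, cc] <- f$tau; hh[r, cc] <- f$h
      Ib[r, cc] <- f$Ib; rmse[r, cc] <- f$rmse
      fitMask[r, cc] <- TRUE
    }
  }
  new("StrExpMaps", I0 = I0, tau = tau, hHet = hh, Ib = Ib, rmse = rmse,
      fitMask = fitMask)
}

#' Rate-coefficient maps of fitted StrExp decays
#'
#' Evaluates k(x, t) = (1/(h tau)) (t/tau)^(1/h - 1) per fitted pixel and
#' requested time. For a compressed decay (h < 1) the rate increases in
#' time, for a stretched decay (h > 1) it decreases, and for h = 1 it is the
#' constant 1/tau. At t = 0 the expression is singular for h > 1; zero times
#' are rejected.
#'
#' @param maps a [StrExpMaps].
#' @param times evaluation times (s), strictly positive.
#' @return a [RateCoefficientMap].
#' @export
rateCoefficient <- function(maps, times) {
  if (any(times <= 0)) stop("rate-coefficient times must be strictly positive")
  d <- dim(maps@tau)
  k <- array(NA_real_, dim = c(d, length(times)))
  ok <- maps@fitMask & is.finite(maps@tau) & is.finite(maps@hHet) &
    maps@tau > 0 & maps@hHet > 0
  for (i in seq_along(times)) {
    t <- times[i]
    ki <- matrix(NA_real_, d[1L], d[2L])
    ki[ok] <- (1 / (maps@hHet[ok] * maps@tau[ok])) *
      (t / maps@tau[ok])^(1 / maps@hHet[ok] - 1)
    k[, , i] <- ki
  }
  new("RateCoefficientMap", kOfT = k, times = as.numeric(times))
}

#' Classify pixels by heterogeneity
#'
#' Thresholds the h map at 1 with a tolerance band: h < 1 - tol compressed,
#' |h - 1| <= tol exponential, h > 1 + tol stretched.
#'
#' @param maps a [StrExpMaps].
#' @param tol half-width of the "exponential" band (default 0.05).
#' @return character matrix with NA outside the fit mask.
#' @export
classifyHeterogeneity <- function(maps, tol = 0.05) {
  out <- matrix(NA_character_, nrow(maps@hHet), ncol(maps@hHet))
  ok <- maps@fitMask & is.finite(maps@hHet)
  out[ok & maps@hHet < 1 - tol] <- "compressed"
  out[ok & abs(maps@hHet - 1) <= tol] <- "exponential"
  out[ok & maps@hHet > 1 + tol] <- "stretched"
  out
}

#' Export StrExp maps
#'
#' Writes the maps as a float32 multi-page TIFF in the page order I0, tau,
#' h, Ib, rmse (non-fitted pixels as 0), plus a JSON sidecar documenting the
#' page order.
#'
#' @param maps a [StrExpMaps].
#' @param path output TIFF path.
#' @return invisibly, the path.
#' @export
writeStrExpMaps <- function(maps, path) {
  z <- function(m) { m[!is.finite(m)] <- 0; m }
  writeScaledTIFF(list(I0 = z(maps@I0), tau = z(maps@tau), h = z(maps@hHet),
                       Ib = z(maps@Ib), rmse = z(maps@rmse)), path)
}

# 32-bit TIFF stores values on [0, 1]; pages are affinely rescaled and the
# per-page (offset, scale) recorded in a JSON sidecar so they can be
# recovered (quantization 2^-32).
writeScaledTIFF <- function(pages, path) {
  scales <- lapply(pages, function(m) {
    lo <- min(m); hi <- max(m)
    if (hi <= lo) hi <- lo + 1
    list(offset = lo, scale = hi - lo)
  })
  out <- Map(function(m, s) (m - s$offset) / s$scale, pages, scales)
  tiff::writeTIFF(unname(out), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(pages = names(pages), scaling = scales),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read maps written by [writeStrExpMaps()]
#'
#' @param path TIFF path with its JSON sidecar.
#' @return named list of matrices.
#' @export
readScaledTIFF <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  stats::setNames(Map(function(m, s) m * s$scale + s$offset,
                      pages, meta$scaling), unlist(meta$pages))
}

#' Region summary of StrExp maps
#'
#' @param maps a [StrExpMaps].
#' @param labelMask integer label image (codes 1 cytoplasm, 2 nucleus,
#'   3 bleach).
#' @return data.frame of per-region median/mean parameter statistics.
#' @export
strExpRegionSummary <- function(maps, labelMask) {
  regions <- list(cytoplasm = labelMask == 1L | labelMask == 3L,
                  nucleus = labelMask == 2L,
                  bleach = labelMask == 3L)
  do.call(rbind, lapply(names(regions), function(nm) {
    sel <- regions[[nm]] & maps@fitMask
    if (!any(sel)) return(NULL)
    data.frame(region = nm, nPixels = sum(sel),
               I0_mean = mean(maps@I0[sel]), tau_median = stats::median(maps@tau[sel]),
               tau_mean = mean(maps@tau[sel]), h_median = stats::median(maps@hHet[sel]),
               Ib_mean = mean(maps@Ib[sel]), rmse_mean = mean(maps@rmse[sel]))
  }))
}

setMethod("show", "StrExpMaps", function(object) {
  n <- sum(object@fitMask)
  cat(sprintf("StrExpMaps: %d fitted pixels\n", n))
  if (n) cat(sprintf("  tau median %.3g s, h median %.3g\n",
                     stats::median(object@tau[object@fitMask]),
                     stats::median(object@hHet[object@fitMask])))
})
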