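# Misfit functional and Nelder-Mead parameter estimation.
#
# The misfit is the frame-averaged squared L2 distance between the simulated
# total intensity and the goal functions. The search runs over
# log-parameters, which enforces positivity by construction (the estimation
# problem is an argmin over strictly positive alpha, beta, gamma, p).

#' Misfit configuration
#'
#' @param frameIndices snapshots entering the misfit (default: all goals).
#' @param weights per-frame weights; default uniform 1/N.
#' @param nGoals number of goal frames (used for defaults).
#' @return a [MisfitConfig].
#' @export
misfitConfig <- function(frameIndices = NULL, weights = NULL, nGoals = NULL) {
  if (is.null(frameIndices)) {
    if (is.null(nGoals)) stop("either frameIndices or nGoals required")
    frameIndices <- seq_len(nGoals)
  }
  if (is.null(weights)) weights <- rep(1 / length(frameIndices), length(frameIndices))
  obj <- new("MisfitConfig", frameIndices = as.integer(frameIndices),
             weights = weights)
  v <- validObject(obj, test = TRUE)
  if (!isTRUE(v)) stop("invalid misfit config: ", paste(v, collapse = "; "))
  obj
}

#' Misfit between a simulated trajectory and goal functions
#'
#' E = sum_i w_i * int |u(t_i) + u_b(t_i) - c_g(t_i)|^2 dx, computed by
#' element quadrature (exact for the piecewise-linear fields). With uniform
#' weights over N frames this is the frame-averaged squared L2 distance.
#'
#' @param trajectory a [FlipTrajectory].
#' @param goals a [GoalSeries] on the same mesh and times.
#' @param space the [DGSpace] both live on.
#' @param config optional [MisfitConfig]; default all frames, uniform weights.
#' @return scalar misfit E >= 0.
#' @export
misfit <- function(trajectory, goals, space, config = NULL) {
  if (ncol(goals@coefs) != length(trajectory@times) ||
      any(abs(goals@times - trajectory@times) > 1e-9))
    stop("trajectory and goals must share snapshot times")
  if (is.null(config)) config <- misfitConfig(nGoals = ncol(goals@coefs))
  M <- massMatrix(space)
  E <- 0
  for (k in seq_along(config@frameIndices)) {
    i <- config@frameIndices[k]
    d <- trajectory@U[, i] + trajectory@Ub[, i] - goals@coefs[, i]
    E <- E + config@weights[k] * sum(d * as.numeric(M %*% d))
  }
  E
}

# One forward solve + misfit at natural-scale parameters.
forwardMisfit <- function(theta, baseSystem, state0, schedule, goals, M,
                          config, refine) {
  sys <- updateSystem(baseSystem, alpha = theta[1L], beta = theta[2L],
                      gamma = theta[3L], p = theta[4L])
  traj <- tryCatch(
    runFlip(state0, sys, schedule, bleach = TRUE, refine = refine),
    error = function(e) NULL)
  if (is.null(traj)) return(Inf)
  E <- 0
  for (k in seq_along(config@frameIndices)) {
    i <- config@frameIndices[k]
    d <- traj@U[, i] + traj@Ub[, i] - goals@coefs[, i]
    E <- E + config@weights[k] * sum(d * as.numeric(M %*% d))
  }
  if (!is.finite(E)) Inf else E
}

# Standard downhill-simplex iteration (reflection 1, expansion 2,
# contraction 0.5, shrink 0.5) with the dual stopping rule: simplex
# x-spread <= xTol AND value spread (worst - best) <= fTol.
nelderMead <- function(fn, x0, step = 0.05, xTol = 1e-4, fTol = 1e-4,
                       maxIter = 1000L, traceCb = NULL) {
  n <- length(x0)
  simplex <- matrix(rep(x0, n + 1L), ncol = n, byrow = TRUE)
  for (j in seq_len(n)) simplex[j + 1L, j] <- simplex[j + 1L, j] + step
  nEval <- 0L
  evalF <- function(x) { nEval <<- nEval + 1L; fn(x) }
  fv <- apply(simplex, 1L, evalF)
  if (!is.finite(fv[1L]))
    stop("non-finite misfit at the initial guess; check setup")
  iter <- 0L
  converged <- FALSE
  repeat {
    o <- order(fv)
    simplex <- simplex[o, , drop = FALSE]; fv <- fv[o]
    if (!is.null(traceCb)) traceCb(iter, simplex[1L, ], fv[1L], fv[n + 1L] - fv[1L])
    xSpread <- max(abs(sweep(simplex[-1L, , drop = FALSE], 2L, simplex[1L, ])))
    fSpread <- fv[n + 1L] - fv[1L]
    if (xSpread <= xTol && fSpread <= fTol) { converged <- TRUE; break }
    if (iter >= maxIter) break
    iter <- iter + 1L
    centroid <- colMeans(simplex[seq_len(n), , drop = FALSE])
    xr <- centroid + (centroid - simplex[n + 1L, ])
    fr <- evalF(xr)
    if (fr < fv[1L]) {
      xe <- centroid + 2 * (centroid - simplex[n + 1L, ])
      fe <- evalF(xe)
      if (fe < fr) { simplex[n + 1L, ] <- xe; fv[n + 1L] <- fe }
      else { simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr
    } else {
      if (fr < fv[n + 1L]) {
        xc <- centroid + 0.5 * (xr - centroid)   # outside contraction
        fc <- evalF(xc)
        if (fc <= fr) { simplex[n + 1L, ] <- xc; fv[n + 1L] <- fc }
        else {
          for (j in 2:(n + 1L)) {
            simplex[j, ] <- simplex[1L, ] + 0.5 * (simplex[j, ] - simplex[1L, ])
            fv[j] <- evalF(simplex[j, ])
          }
        }
      } else {
        xc <- centroid - 0.5 * (centroid - simplex[n + 1L, ]) # inside
        fc <- evalF(xc)
        if (fc < fv[n + 1L]) { simplex[n + 1L, ] <- xc; fv[n + 1L] <- fc }
        else {
          for (j in 2:(n + 1L)) {
            simplex[j, ] <- simplex[1L, ] + 0.5 * (simplex[j, ] - simplex[1L, ])
            fv[j] <- evalF(simplex[j, ])
          }
        }
      }
    }
  }
  o <- order(fv)
  list(x = simplex[o[1L], ], f = fv[o[1L]], iterations = iter,
       evaluations = nEval, converged = converged)
}

#' Calibrate the FLIP model against goal functions
#'
#' Estimates (alpha, beta, gamma, p) by downhill-simplex search on the
#' misfit. Each evaluation is a full forward FLIP solve with the candidate
#' parameters (reaction, membrane, bleach and diffusion blocks are rescaled
#' from cached matrices, so no re-assembly occurs) followed by the misfit
#' evaluation. The search runs over log-parameters; the initial simplex
#' perturbs each coordinate by `simplexStep` (5 percent) in log space. The
#' iteration stops when both the simplex parameter spread and the misfit
#' variation across the simplex fall below the tolerances (defaults 1e-4).
#' A failed forward solve scores +Inf and the search continues.
#'
#' @param goals a [GoalSeries].
#' @param space the [DGSpace] the goals live on.
#' @param schedule a [BleachSchedule] with `nFrames == ncol(goals)`.
#' @param c0 nodal initial intensity (first preconditioned frame) used to
#'   initialize the fields and rebuild the rate maps per candidate gamma.
#' @param initialGuess starting [ModelParameters] or named vector; default
#'   (alpha, beta, gamma, p) = (25, 20, 0.5, 0.05).
#' @param xTol,fTol stopping tolerances (default 1e-4).
#' @param maxIter iteration cap.
#' @param config optional [MisfitConfig].
#' @param refine iterative-refinement steps per solve (0 for speed; the
#'   misfit differences dominate the solve error here).
#' @param simplexStep initial per-coordinate log-space step.
#' @return a [CalibrationResult].
#' @export
calibrateFlip <- function(goals, space, schedule, c0,
                          initialGuess = c(alpha = 25, beta = 20,
                                           gamma = 0.5, p = 0.05),
                          xTol = 1e-4, fTol = 1e-4, maxIter = 1000L,
                          config = NULL, refine = 0L, simplexStep = 0.05) {
  if (schedule@nFrames != ncol(goals@coefs))
    stop("schedule frame count must match the goal series")
  if (inherits(initialGuess, "ModelParameters"))
    initialGuess <- paramVector(initialGuess)
  if (any(initialGuess <= 0)) stop("initial guess must be strictly positive")
  if (is.null(config)) config <- misfitConfig(nGoals = ncol(goals@coefs))
  state0 <- initFieldsFromFrame(c0)
  pr0 <- modelParameters(initialGuess[["alpha"]], initialGuess[["beta"]],
                         initialGuess[["gamma"]], initialGuess[["p"]])
  baseSystem <- assembleSystem(space, pr0, rateMaps(c0, pr0@gamma))
  M <- massMatrix(space)
  obj <- function(xi) forwardMisfit(exp(xi), baseSystem, state0, schedule,
                                    goals, M, config, refine)
  rows <- list()
  cb <- function(iter, xi, e1, spread) {
    th <- exp(xi)
    rows[[length(rows) + 1L]] <<- data.frame(
      iteration = iter, alpha = th[1L], beta = th[2L], gamma = th[3L],
      p = th[4L], E_best = e1, E_spread = spread)
  }
  res <- nelderMead(obj, log(unname(initialGuess)), step = simplexStep,
                    xTol = xTol, fTol = fTol, maxIter = maxIter, traceCb = cb)
  th <- exp(res$x)
  new("CalibrationResult",
      bestParams = modelParameters(th[1L], th[2L], th[3L], th[4L]),
      bestE = res$f, trace = do.call(rbind, rows),
      nIterations = as.integer(res$iterations),
      nEvaluations = as.integer(res$evaluations),
      converged = res$converged)
}

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: E = %.6g after %d iterations (%d evaluations)%s\n",
              object@bestE, object@nIterations, object@nEvaluations,
              if (object@converged) ", converged" else ", NOT converged"))
  show(object@bestParams)
})

#' Write a calibration report
#'
#' Writes the iteration trace as CSV and the result (parameters, misfit,
#' counts, convergence flag, configuration echo) as JSON.
#'
#' @param result a [CalibrationResult].
#' @param dir output directory.
#' @param configEcho optional list echoed into the JSON.
#' @return invisibly, the JSON path.
#' @export
writeCalibrationReport <- function(result, dir, configEcho = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result@trace, file.path(dir, "calibration_trace.csv"),
                   row.names = FALSE)
  out <- list(parameters = as.list(paramVector(result@bestParams)),
              misfit = result@bestE,
              iterations = result@nIterations,
              evaluations = result@nEvaluations,
              converged = result@converged,
              config = configEcho)
  jp <- file.path(dir, "calibration_result.json")
  jsonlite::write_json(out, jp, auto_unbox = TRUE, digits = NA)
  invisible(jp)
}
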