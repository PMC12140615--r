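#' @import methods
NULL

#' Virtual parent class for discrete-time dynamics
#'
#' Any object for which \code{\link{deltaState}} is defined: fitted or planted
#' \linkS4class{MindyModel}s, \linkS4class{CombinedDynamics} (convex
#' combinations of two models' vector fields) and the analytic
#' \linkS4class{ToySnic} planar model.
#'
#' @name MindyDynamics-class
#' @aliases MindyDynamics
#' @exportClass MindyDynamics
setClass("MindyDynamics", representation("VIRTUAL"))

#' MINDy neural-mass network model
#'
#' A discrete-time neural-mass network model over \eqn{N} parcels with
#' one-step dynamics
#' \deqn{x_{n+1} = x_n + W \psi_\alpha(x_n) - D \odot x_n,}
#' where the effective connectivity \eqn{W = W_S + W_1 W_2^T} is the sum of a
#' sparse matrix and a rank-\eqn{k} matrix, \eqn{\psi_\alpha} is an odd
#' saturating transfer function with region-specific curvature \eqn{\alpha}
#' (see \code{\link{transferPsi}}) and \eqn{D} is a per-region decay. All
#' stored parameters are the per-TR (discrete-time) quantities; continuous-time
#' rates are recoverable by dividing by \code{tr}. The induced vector field is
#' odd, \eqn{f(-x) = -f(x)}, so the origin is always an equilibrium and
#' non-origin attractors occur in \eqn{\pm} pairs.
#'
#' @slot sparseWeights \eqn{N \times N} sparse connectivity component.
#' @slot lowrankLeft \eqn{N \times k} left low-rank factor.
#' @slot lowrankRight \eqn{N \times k} right low-rank factor.
#' @slot curvature Positive length-\eqn{N} transfer-function curvature
#'   \eqn{\alpha}.
#' @slot decay Length-\eqn{N} per-TR decay \eqn{D} (unconstrained sign).
#' @slot shapeConstant Positive scalar \eqn{b} shaping the transfer function
#'   (default \code{20/3}).
#' @slot tr Sampling interval in seconds (one model step).
#' @slot fitInfo List of fitting metadata (loss trace, rescaling factors,
#'   seed); empty for hand-constructed models.
#'
#' @seealso \code{\link{mindyModel}}, \code{\link{deltaState}},
#'   \code{\link{fitMindy}}, \code{\link{classifyLandscape}}
#' @name MindyModel-class
#' @aliases MindyModel
#' @exportClass MindyModel
setClass("MindyModel",
  contains = "MindyDynamics",
  slots = c(
    sparseWeights = "matrix",
    lowrankLeft   = "matrix",
    lowrankRight  = "matrix",
    curvature     = "numeric",
    decay         = "numeric",
    shapeConstant = "numeric",
    tr            = "numeric",
    fitInfo       = "list"
  )
)

setValidity("MindyModel", function(object) {
  n <- nrow(object@sparseWeights)
  k <- ncol(object@lowrankLeft)
  msg <- character(0)
  if (ncol(object@sparseWeights) != n)
    msg <- c(msg, "sparseWeights must be square")
  if (nrow(object@lowrankLeft) != n || nrow(object@lowrankRight) != n)
    msg <- c(msg, "low-rank factors must have one row per parcel")
  if (ncol(object@lowrankRight) != k)
    msg <- c(msg, "low-rank factors must share rank k")
  if (k >= n)
    msg <- c(msg, "rank k must be < number of parcels N")
  if (length(object@curvature) != n || length(object@decay) != n)
    msg <- c(msg, "curvature and decay must have length N")
  if (!all(is.finite(object@curvature)) || any(object@curvature <= 0))
    msg <- c(msg, "curvature must be finite and > 0")
  if (!all(is.finite(object@decay)))
    msg <- c(msg, "decay must be finite")
  if (!all(is.finite(object@sparseWeights)) ||
      !all(is.finite(object@lowrankLeft)) ||
      !all(is.finite(object@lowrankRight)))
    msg <- c(msg, "weights must be finite")
  if (length(object@shapeConstant) != 1 || object@shapeConstant <= 0)
    msg <- c(msg, "shapeConstant must be a positive scalar")
  if (length(object@tr) != 1 || object@tr <= 0)
    msg <- c(msg, "tr must be a positive scalar (seconds)")
  if (length(msg)) msg else TRUE
})

#' Construct a MindyModel
#'
#' @param sparseWeights \eqn{N \times N} numeric matrix \eqn{W_S}.
#' @param lowrankLeft,lowrankRight \eqn{N \times k} factors of the low-rank
#'   connectivity component (\eqn{k < N}).
#' @param curvature Positive numeric vector \eqn{\alpha} of length \eqn{N} (a
#'   scalar is recycled).
#' @param decay Numeric vector \eqn{D} of length \eqn{N} (a scalar is
#'   recycled).
#' @param shapeConstant Transfer-function shape constant \eqn{b}, default
#'   \code{20/3}.
#' @param tr Sampling interval in seconds, default \code{0.72}.
#' @param fitInfo Optional list of fitting metadata.
#' @return A validated \linkS4class{MindyModel}.
#' @examples
#' m <- mindyModel(sparseWeights = diag(0, 3),
#'                 lowrankLeft = matrix(0, 3, 1),
#'                 lowrankRight = matrix(0, 3, 1),
#'                 curvature = 1, decay = 0.2)
#' deltaState(m, c(1, 1, 1))  # pure decay: -0.2 * x
#' @export
mindyModel <- function(sparseWeights, lowrankLeft, lowrankRight,
                       curvature = 1, decay = 0.2,
                       shapeConstant = 20 / 3, tr = 0.72,
                       fitInfo = list()) {
  n <- nrow(sparseWeights)
  if (length(curvature) == 1) curvature <- rep(curvature, n)
  if (length(decay) == 1) decay <- rep(decay, n)
  new("MindyModel",
      sparseWeights = sparseWeights,
      lowrankLeft = lowrankLeft, lowrankRight = lowrankRight,
      curvature = as.numeric(curvature), decay = as.numeric(decay),
      shapeConstant = shapeConstant, tr = tr, fitInfo = fitInfo)
}

#' Convex combination of two models' dynamics
#'
#' Dynamics object evaluating to \eqn{\gamma f_1(x) + (1-\gamma) f_2(x)} for
#' two \linkS4class{MindyModel}s sharing the same state dimension.
#' \eqn{\gamma = 1} reproduces \code{modelA} exactly, \eqn{\gamma = 0}
#' \code{modelB}. The combination of two MINDy vector fields is generally not
#' itself expressible as one MINDy parameter set (the two curvatures differ),
#' so this is a dynamics object, not a \linkS4class{MindyModel}; contrast
#' \code{\link{mixWeights}}, which mixes the parameter tensors instead.
#'
#' @slot modelA,modelB The two endpoint models.
#' @slot gamma Mixing coefficient in \eqn{[0, 1]} (weight of \code{modelA}).
#' @seealso \code{\link{combineDynamics}}, \code{\link{sampleSpectrum}}
#' @name CombinedDynamics-class
#' @aliases CombinedDynamics
#' @exportClass CombinedDynamics
setClass("CombinedDynamics",
  contains = "MindyDynamics",
  slots = c(modelA = "MindyModel", modelB = "MindyModel", gamma = "numeric")
)

setValidity("CombinedDynamics", function(object) {
  msg <- character(0)
  if (length(object@gamma) != 1 || !is.finite(object@gamma) ||
      object@gamma < 0 || object@gamma > 1)
    msg <- c(msg, "gamma must be a scalar in [0, 1]")
  if (nrow(object@modelA@sparseWeights) != nrow(object@modelB@sparseWeights))
    msg <- c(msg, "the two models must share the number of parcels")
  if (length(msg)) msg else TRUE
})

#' Analytic planar SNIC (infinite-period) toy model
#'
#' The symmetric saddle-node-on-invariant-circle normal form in polar
#' coordinates,
#' \deqn{dr/dt = g\, r (1 - r^2), \qquad d\theta/dt = \mu - \sin(2\theta),}
#' integrated as discrete dynamics with a small fixed step. For
#' \eqn{0 < \mu < 1} it has two pairs of hyperbolic equilibria on the unit
#' circle (one stable pair, one saddle pair, see
#' \code{\link{snicEquilibria}}); for \eqn{\mu > 1} it has a unique attracting
#' limit cycle (the unit circle) whose slowest points (angular speed
#' \eqn{\mu - 1}) are the ghost attractors; the bifurcation occurs at
#' \eqn{\mu = 1} with diverging period. The field is symmetric under state
#' negation (180-degree rotation), mirroring the odd symmetry of MINDy
#' dynamics.
#'
#' @slot mu Bifurcation parameter \eqn{\mu > 0}.
#' @slot radialGain Radial attraction gain \eqn{g > 0} (default 1).
#' @slot stepSize Integration step in model time units (default 0.01).
#' @seealso \code{\link{toySnic}}, \code{\link{snicEquilibria}}
#' @name ToySnic-class
#' @aliases ToySnic
#' @exportClass ToySnic
setClass("ToySnic",
  contains = "MindyDynamics",
  slots = c(mu = "numeric", radialGain = "numeric", stepSize = "numeric")
)

setValidity("ToySnic", function(object) {
  msg <- character(0)
  if (length(object@mu) != 1 || object@mu <= 0)
    msg <- c(msg, "mu must be a positive scalar")
  if (length(object@radialGain) != 1 || object@radialGain <= 0)
    msg <- c(msg, "radialGain must be a positive scalar")
  if (length(object@stepSize) != 1 || object@stepSize <= 0)
    msg <- c(msg, "stepSize must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Parcel-averaged timeseries
#'
#' A time-by-parcel real matrix with its sampling interval, run boundaries and
#' optional parcel/network annotation. Run boundaries are 1-based start
#' indices of each scanning run (first is always 1); operations that pair
#' consecutive frames never cross a run boundary.
#'
#' @slot data \eqn{T \times N} numeric matrix (rows = frames).
#' @slot tr Sampling interval in seconds.
#' @slot runBoundaries Integer vector of 1-based run start indices, strictly
#'   increasing, first element 1.
#' @slot parcelIds Character vector of \eqn{N} parcel identifiers.
#' @slot networkLabels Named character vector mapping parcel id to network
#'   name (may be empty).
#' @slot meta List of provenance metadata (e.g. the centering/scaling applied
#'   by z-scoring, generator seeds).
#' @seealso \code{\link{parcelTimeseries}}, \code{\link{preprocessTimeseries}}
#' @name ParcelTimeseries-class
#' @aliases ParcelTimeseries
#' @exportClass ParcelTimeseries
setClass("ParcelTimeseries",
  slots = c(
    data = "matrix", tr = "numeric", runBoundaries = "integer",
    parcelIds = "character", networkLabels = "character", meta = "list"
  )
)

setValidity("ParcelTimeseries", function(object) {
  msg <- character(0)
  t <- nrow(object@data)
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be numeric")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data must not contain non-finite entries")
  if (length(object@tr) != 1 || object@tr <= 0)
    msg <- c(msg, "tr must be a positive scalar (seconds)")
  rb <- object@runBoundaries
  if (length(rb) < 1 || rb[1] != 1L || any(diff(rb) <= 0) || any(rb > t))
    msg <- c(msg, "runBoundaries must start at 1, be strictly increasing and be <= T")
  if (any(diff(c(rb, t + 1L)) < 2L))
    msg <- c(msg, "each run must have at least 2 frames")
  if (length(object@parcelIds) != ncol(object@data))
    msg <- c(msg, "parcelIds must have one entry per column")
  if (length(msg)) msg else TRUE
})

#' Construct a ParcelTimeseries
#'
#' @param data \eqn{T \times N} numeric matrix of parcel-averaged signal.
#' @param tr Sampling interval in seconds.
#' @param runBoundaries 1-based start index of each run (default: one run).
#' @param parcelIds Optional parcel identifiers (default \code{"P1"...}).
#' @param networkLabels Optional named character vector, parcel id to network.
#' @param meta Optional metadata list.
#' @return A validated \linkS4class{ParcelTimeseries}.
#' @export
parcelTimeseries <- function(data, tr = 0.72, runBoundaries = 1L,
                             parcelIds = NULL, networkLabels = character(0),
                             meta = list()) {
  data <- as.matrix(data)
  if (is.null(parcelIds)) {
    parcelIds <- colnames(data)
    if (is.null(parcelIds)) parcelIds <- paste0("P", seq_len(ncol(data)))
  }
  colnames(data) <- parcelIds
  new("ParcelTimeseries",
      data = data, tr = tr, runBoundaries = as.integer(runBoundaries),
      parcelIds = as.character(parcelIds),
      networkLabels = networkLabels, meta = meta)
}

#' Hidden-state training pairs for model fitting
#'
#' States \eqn{x_n} paired with smoothed forward-difference targets
#' \eqn{\hat\Delta x_n = (x_{n+2} - x_n)/2} (or the plain forward difference
#' \eqn{x_{n+1} - x_n} with smoothing off). Pairs never span a run boundary.
#'
#' @slot states \eqn{M \times N} matrix of states.
#' @slot targets \eqn{M \times N} matrix of derivative targets.
#' @slot sampleIndex Original frame index of each row.
#' @slot smoothed Logical: two-point moving-average smoothing applied.
#' @seealso \code{\link{buildTrainingPairs}}, \code{\link{fitMindy}}
#' @name DerivativeSamples-class
#' @aliases DerivativeSamples
#' @exportClass DerivativeSamples
setClass("DerivativeSamples",
  slots = c(states = "matrix", targets = "matrix",
            sampleIndex = "integer", smoothed = "logical")
)

setValidity("DerivativeSamples", function(object) {
  msg <- character(0)
  if (!identical(dim(object@states), dim(object@targets)))
    msg <- c(msg, "states and targets must have identical dimensions")
  if (length(object@sampleIndex) != nrow(object@states))
    msg <- c(msg, "sampleIndex must have one entry per row")
  if (length(msg)) msg else TRUE
})

#' Attractor landscape of a dynamical system
#'
#' The result of \code{\link{classifyLandscape}}: stable equilibria (clustered
#' terminal states of converged trajectories), stable limit cycles (recurrent
#' trajectories), ghost attractors (slowest cycle points) and the canonical
#' taxonomy label \code{"<a>FP <b>LC"}. Equilibrium counts include an origin
#' equilibrium when present; whether the landscape is origin-only is exposed
#' separately so "single stable equilibrium at the origin" is distinguishable.
#'
#' @slot equilibria List of equilibrium records (fields \code{state},
#'   \code{basinCount}, \code{atOrigin}, \code{residual}).
#' @slot cycles List of limit-cycle records (fields \code{samples},
#'   \code{period}, \code{speeds}, \code{basinCount}).
#' @slot ghosts List of ghost-attractor records (fields \code{state},
#'   \code{cycleIndex}, \code{speed}).
#' @slot nFp,nLc Counts of stable equilibria and stable limit cycles.
#' @slot label Canonical taxonomy string, e.g. \code{"2FP 0LC"}.
#' @slot counts List: \code{nInit}, \code{converged}, \code{cycling},
#'   \code{unresolved}, \code{divergent}.
#' @slot originOnly TRUE when the only attractor is an equilibrium at the
#'   origin.
#' @slot flags Character vector, e.g. \code{"numerical issues"} when more than
#'   half of all trajectories diverged.
#' @name MindyLandscape-class
#' @aliases MindyLandscape
#' @exportClass MindyLandscape
setClass("MindyLandscape",
  slots = c(
    equilibria = "list", cycles = "list", ghosts = "list",
    nFp = "integer", nLc = "integer", label = "character",
    counts = "list", originOnly = "logical", flags = "character"
  )
)

## ---- shared accessors & show methods ------------------------------------

#' @describeIn MindyModel-class Number of parcels.
#' @export
setMethod("nParcels", "MindyModel", function(x) nrow(x@sparseWeights))

#' @describeIn CombinedDynamics-class Number of parcels.
#' @export
setMethod("nParcels", "CombinedDynamics", function(x) nParcels(x@modelA))

#' @describeIn ToySnic-class State dimension (always 2).
#' @export
setMethod("nParcels", "ToySnic", function(x) 2L)

#' @describeIn ParcelTimeseries-class Number of parcels.
#' @export
setMethod("nParcels", "ParcelTimeseries", function(x) ncol(x@data))

#' @describeIn DerivativeSamples-class Number of parcels.
#' @export
setMethod("nParcels", "DerivativeSamples", function(x) ncol(x@states))

#' Effective connectivity of a model
#'
#' Returns \eqn{W = W_S + W_1 W_2^T}.
#'
#' @param model A \linkS4class{MindyModel}.
#' @return \eqn{N \times N} numeric matrix.
#' @export
connWeights <- function(model) {
  stopifnot(is(model, "MindyModel"))
  model@sparseWeights + model@lowrankLeft %*% t(model@lowrankRight)
}

#' @rdname MindyModel-class
#' @param model A \linkS4class{MindyModel}.
#' @export
curvature <- function(model) model@curvature

#' @rdname MindyModel-class
#' @export
decayRates <- function(model) model@decay

#' @rdname ParcelTimeseries-class
#' @param ts A \linkS4class{ParcelTimeseries}.
#' @export
tsMatrix <- function(ts) ts@data

#' @rdname ParcelTimeseries-class
#' @export
runBoundaries <- function(ts) ts@runBoundaries

#' @rdname MindyLandscape-class
#' @param x,landscape A \linkS4class{MindyLandscape}.
#' @export
taxonomyLabel <- function(landscape) landscape@label

#' @rdname MindyLandscape-class
#' @export
equilibria <- function(landscape) landscape@equilibria

#' @rdname MindyLandscape-class
#' @export
limitCycles <- function(landscape) landscape@cycles

#' @rdname MindyLandscape-class
#' @export
ghostAttractors <- function(landscape) landscape@ghosts

setMethod("show", "MindyModel", function(object) {
  n <- nParcels(object)
  cat(sprintf("MindyModel: %d parcels, rank-%d low-rank component, TR %.3g s\n",
              n, ncol(object@lowrankLeft), object@tr))
  cat(sprintf("  curvature alpha in [%.3g, %.3g]; decay D in [%.3g, %.3g]; b = %.4g\n",
              min(object@curvature), max(object@curvature),
              min(object@decay), max(object@decay), object@shapeConstant))
  if (length(object@fitInfo))
    cat("  fitInfo:", paste(names(object@fitInfo), collapse = ", "), "\n")
})

setMethod("show", "CombinedDynamics", function(object) {
  cat(sprintf("CombinedDynamics: gamma = %.3f (A) + %.3f (B), %d parcels\n",
              object@gamma, 1 - object@gamma, nParcels(object)))
})

setMethod("show", "ToySnic", function(object) {
  regime <- if (object@mu < 1) "two stable equilibria + two saddles"
            else if (object@mu > 1) "one stable limit cycle"
            else "at bifurcation"
  cat(sprintf("ToySnic: mu = %.4g (%s), radial gain %.3g, step %.3g\n",
              object@mu, regime, object@radialGain, object@stepSize))
})

setMethod("show", "ParcelTimeseries", function(object) {
  cat(sprintf("ParcelTimeseries: %d frames x %d parcels, TR %.3g s, %d run(s)\n",
              nrow(object@data), ncol(object@data), object@tr,
              length(object@runBoundaries)))
  if (length(object@networkLabels))
    cat(sprintf("  network labels for %d parcels (%d networks)\n",
                length(object@networkLabels),
                length(unique(object@networkLabels))))
})

setMethod("show", "DerivativeSamples", function(object) {
  cat(sprintf("DerivativeSamples: %d pairs x %d parcels (%s targets)\n",
              nrow(object@states), ncol(object@states),
              if (object@smoothed) "smoothed (x[n+2]-x[n])/2"
              else "forward difference"))
})

setMethod("show", "MindyLandscape", function(object) {
  cat(sprintf("MindyLandscape: %s (%d equilibria, %d limit cycles, %d ghosts)\n",
              object@label, object@nFp, object@nLc, length(object@ghosts)))
  cnt <- object@counts
  cat(sprintf("  trajectories: %d total, %d converged, %d cycling, %d unresolved, %d divergent\n",
              cnt$nInit, cnt$converged, cnt$cycling, cnt$unresolved,
              cnt$divergent))
  if (isTRUE(object@originOnly))
    cat("  single stable equilibrium at the origin\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})
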