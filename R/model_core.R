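## Core dynamics: transfer function, one-step vector field, simulation,
## convex combination. All hot paths operate on row-per-state matrices.

#' Saturating transfer function
#'
#' The odd, strictly increasing, (-1, 1)-bounded transfer function
#' \deqn{\psi_\alpha(x) = \sqrt{\alpha^2 + (bx + 0.5)^2} -
#'       \sqrt{\alpha^2 + (bx - 0.5)^2},}
#' applied element-wise with a per-element curvature \eqn{\alpha}. As
#' \eqn{\alpha \to 0} it approaches the piecewise-linear limit
#' \eqn{\mathrm{clip}(2bx, -1, 1)}.
#'
#' @param x Numeric vector, or a matrix with one state per row (in which case
#'   \code{alpha} is per column).
#' @param alpha Positive curvature, scalar or one value per element/column.
#' @param b Positive shape constant, default \code{20/3}.
#' @return Same shape as \code{x}.
#' @examples
#' transferPsi(0, 1)                    # 0: odd at the origin
#' transferPsi(0.0375, 1e-12)           # ~0.5: the alpha -> 0 linear branch
#' @export
transferPsi <- function(x, alpha, b = 20 / 3) {
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x))
    stop("non-finite input to transferPsi at index ", bad[1])
  }
  stopifnot(all(alpha >= 0), b > 0)
  if (is.matrix(x)) {
    a2 <- matrix(alpha^2, nrow(x), ncol(x), byrow = TRUE)
  } else {
    a2 <- alpha^2
  }
  bx <- b * x
  sqrt(a2 + (bx + 0.5)^2) - sqrt(a2 + (bx - 0.5)^2)
}

## d(psi)/dx, same broadcasting as transferPsi
psiPrime <- function(x, alpha, b = 20 / 3) {
  if (is.matrix(x)) {
    a2 <- matrix(alpha^2, nrow(x), ncol(x), byrow = TRUE)
  } else {
    a2 <- alpha^2
  }
  bx <- b * x
  b * ((bx + 0.5) / sqrt(a2 + (bx + 0.5)^2) -
       (bx - 0.5) / sqrt(a2 + (bx - 0.5)^2))
}

## d(psi)/d(alpha), same broadcasting
psiDAlpha <- function(x, alpha, b = 20 / 3) {
  if (is.matrix(x)) {
    a <- matrix(alpha, nrow(x), ncol(x), byrow = TRUE)
  } else {
    a <- alpha
  }
  bx <- b * x
  a / sqrt(a^2 + (bx + 0.5)^2) - a / sqrt(a^2 + (bx - 0.5)^2)
}

## states as matrix [m x N]; returns matrix delta. Internal hot path.
deltaMindyMat <- function(model, X) {
  psi <- transferPsi(X, model@curvature, model@shapeConstant)
  W <- connWeights(model)
  psi %*% t(W) - X * rep(model@decay, each = nrow(X))
}

asStateMatrix <- function(dynamics, x) {
  n <- nParcels(dynamics)
  if (is.matrix(x)) {
    if (ncol(x) != n)
      stop("state has ", ncol(x), " columns but the dynamics have ", n,
           " parcels")
    x
  } else {
    if (length(x) != n)
      stop("state has length ", length(x), " but the dynamics have ", n,
           " parcels")
    matrix(x, nrow = 1)
  }
}

#' @describeIn deltaState MINDy vector field
#'   \eqn{W\psi_\alpha(x) - D \odot x}.
#' @export
setMethod("deltaState", "MindyModel", function(dynamics, x) {
  X <- asStateMatrix(dynamics, x)
  d <- deltaMindyMat(dynamics, X)
  if (is.matrix(x)) d else drop(d)
})

#' @describeIn deltaState Convex combination
#'   \eqn{\gamma f_A(x) + (1-\gamma) f_B(x)}.
#' @export
setMethod("deltaState", "CombinedDynamics", function(dynamics, x) {
  X <- asStateMatrix(dynamics, x)
  g <- dynamics@gamma
  d <- g * deltaMindyMat(dynamics@modelA, X) +
    (1 - g) * deltaMindyMat(dynamics@modelB, X)
  if (is.matrix(x)) d else drop(d)
})

#' @describeIn deltaState Planar SNIC normal form (Euler step of
#'   \eqn{dr/dt = g r (1 - r^2)}, \eqn{d\theta/dt = \mu - \sin 2\theta}).
#' @export
setMethod("deltaState", "ToySnic", function(dynamics, x) {
  X <- asStateMatrix(dynamics, x)
  r2 <- X[, 1]^2 + X[, 2]^2
  theta <- atan2(X[, 2], X[, 1])
  dr <- dynamics@radialGain * (1 - r2)        # dr/dt / r
  dtheta <- dynamics@mu - sin(2 * theta)
  ## cartesian: dx = (dr/r) x - dtheta * y ; dy = (dr/r) y + dtheta * x
  d <- dynamics@stepSize *
    cbind(dr * X[, 1] - dtheta * X[, 2],
          dr * X[, 2] + dtheta * X[, 1])
  if (is.matrix(x)) d else drop(d)
})

#' @rdname stepState
#' @export
setMethod("stepState", "MindyDynamics", function(dynamics, x) {
  x + deltaState(dynamics, x)
})

#' Construct a convex combination of two models' dynamics
#'
#' @param modelA,modelB Two \linkS4class{MindyModel}s over the same parcels.
#' @param gamma Mixing coefficient in \eqn{[0, 1]}; weight of \code{modelA}.
#' @return A \linkS4class{CombinedDynamics}.
#' @seealso \code{\link{sampleSpectrum}}, \code{\link{mixWeights}}
#' @export
combineDynamics <- function(modelA, modelB, gamma) {
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must lie in [0, 1], got ", gamma)
  new("CombinedDynamics", modelA = modelA, modelB = modelB,
      gamma = as.numeric(gamma))
}

#' Simulate a trajectory of a dynamical system
#'
#' Iterates \eqn{x_{n+1} = x_n + f(x_n)} for \code{nSteps} steps from
#' \code{x0}, one step per TR. With \code{noiseSd > 0}, i.i.d. Gaussian
#' increments (sd \code{noiseSd} per parcel per step) are added after each
#' deterministic step (fixed-step Euler--Maruyama). Deterministic given
#' \code{seed}.
#'
#' @param dynamics Any \linkS4class{MindyDynamics} object.
#' @param x0 Initial state vector.
#' @param nSteps Number of steps (\eqn{\ge 1}).
#' @param noiseSd Process-noise standard deviation (default 0: deterministic).
#' @param seed Optional integer seed used when \code{noiseSd > 0}.
#' @param blowup States with any \eqn{|x| >} \code{blowup} abort with an error
#'   naming the step (numerical divergence; such models are flagged and
#'   excluded downstream).
#' @return Numeric matrix with \code{nSteps + 1} rows (the trajectory,
#'   including \code{x0}).
#' @examples
#' m <- mindyModel(diag(0, 2), matrix(0, 2, 1), matrix(0, 2, 1),
#'                 decay = 0.1)
#' traj <- simulateTrajectory(m, c(1, 1), 10)
#' traj[11, ]  # 0.9^10
#' @export
simulateTrajectory <- function(dynamics, x0, nSteps, noiseSd = 0,
                               seed = NULL, blowup = 1e6) {
  stopifnot(nSteps >= 1)
  n <- nParcels(dynamics)
  if (length(x0) != n) stop("x0 must have length ", n)
  out <- matrix(NA_real_, nSteps + 1, n)
  out[1, ] <- x0
  runStep <- function() {
    x <- matrix(x0, nrow = 1)
    for (i in seq_len(nSteps)) {
      x <- x + deltaState(dynamics, x)
      if (noiseSd > 0) x <- x + matrix(stats::rnorm(n, 0, noiseSd), nrow = 1)
      if (!all(is.finite(x)) || any(abs(x) > blowup))
        stop("trajectory diverged at step ", i, call. = FALSE)
      out[i + 1, ] <<- x
    }
  }
  if (!is.null(seed) && noiseSd > 0) withr::with_seed(seed, runStep())
  else runStep()
  out
}

## Vectorized multi-trajectory integrator used by landscape classification.
## X0: [m x N]; returns list(terminal, converged, divergent, runCounter)
## where runCounter[i] = number of consecutive final steps with all
## |delta| < eqTol. If keepStates, also returns states [nSteps+1, m, N].
simulateMany <- function(dynamics, X0, nSteps, eqTol = 1e-6,
                         blowup = 1e6, keepStates = FALSE,
                         earlyStop = TRUE) {
  m <- nrow(X0)
  X <- X0
  counter <- integer(m)
  divergent <- logical(m)
  states <- if (keepStates)
    array(NA_real_, c(nSteps + 1, m, ncol(X0))) else NULL
  if (keepStates) states[1, , ] <- X0
  for (i in seq_len(nSteps)) {
    d <- deltaState(dynamics, X)
    X2 <- X + d
    bad <- !is.finite(rowSums(X2)) |
      rowSums(abs(X2) > blowup, na.rm = TRUE) > 0
    if (any(bad & !divergent)) {
      divergent <- divergent | bad
      X2[divergent, ] <- 0  # park diverged trajectories; flagged in output
      d[divergent, ] <- 0
    }
    small <- rowSums(abs(d) >= eqTol) == 0
    counter <- ifelse(small, counter + 1L, 0L)
    X <- X2
    if (keepStates) states[i + 1, , ] <- X
    if (earlyStop && !keepStates && all(divergent | counter >= 10L) &&
        i >= 10L) {
      ## every live trajectory has been stationary for >= 10 steps; the
      ## remaining steps cannot change the converged/terminal outcome
      break
    }
  }
  list(terminal = X, converged = counter >= 10L & !divergent,
       divergent = divergent, counter = counter, states = states)
}
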