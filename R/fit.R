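## Model fitting: regularized one-step prediction loss, analytic gradients,
## NADAM minibatch optimization, global rescaling, derivative R^2.

#' Fitting configuration
#'
#' Hyperparameters of the MINDy loss and optimizer. The regularization
#' weights are \code{lambda1} (L1 on the sparse component \eqn{W_S}),
#' \code{lambda2} (absolute diagonal of \eqn{W_S}; note the diagonal is
#' penalized by both) and \code{lambda3} (L1 on the low-rank factors).
#' Minibatches of \code{batchSize} samples are drawn with replacement for
#' \code{nBatches} updates. NADAM uses library-standard defaults; curvature
#' is clamped at \code{alphaFloor} after each update and decay is left
#' unconstrained.
#'
#' @param lambda1,lambda2,lambda3 Nonnegative regularization weights
#'   (defaults 0.075, 0.2, 0.05).
#' @param batchSize Minibatch size (default 300).
#' @param nBatches Number of minibatch updates (default 5000).
#' @param rank Rank \eqn{k} of the low-rank component; default
#'   \code{NULL} picks \code{max(1, round(0.36 N))}, the 72/200 ratio used at
#'   full parcellation.
#' @param learningRate,beta1,beta2,epsilon NADAM hyperparameters (defaults
#'   1e-2, 0.9, 0.999, 1e-8).
#' @param alphaFloor Lower clamp for curvature (default 1e-3).
#' @param seed Integer seed for initialization and minibatch sampling.
#' @return A list of class \code{"fitConfig"}.
#' @export
fitConfig <- function(lambda1 = 0.075, lambda2 = 0.2, lambda3 = 0.05,
                      batchSize = 300L, nBatches = 5000L, rank = NULL,
                      learningRate = 1e-2, beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-8, alphaFloor = 1e-3, seed = 1L) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0,
            batchSize >= 1, nBatches >= 1,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 batchSize = as.integer(batchSize),
                 nBatches = as.integer(nBatches), rank = rank,
                 learningRate = learningRate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, alphaFloor = alphaFloor,
                 seed = as.integer(seed)),
            class = "fitConfig")
}

## params: list(Ws [NxN], W1 [Nxk], W2 [Nxk], alpha [N], D [N], b scalar)
paramsPredict <- function(params, X) {
  psi <- transferPsi(X, params$alpha, params$b)
  W <- params$Ws + params$W1 %*% t(params$W2)
  psi %*% t(W) - X * rep(params$D, each = nrow(X))
}

#' Regularized one-step prediction loss
#'
#' \deqn{J = \tfrac12 \|\hat\Delta x - [(W_S + W_1 W_2^T)\psi_\alpha(x)
#'   - D \odot x]\|_2^2 + \lambda_1 \|W_S\|_1 + \lambda_2
#'   \mathrm{Tr}(|W_S|) + \lambda_3 (\|W_1\|_1 + \|W_2\|_1),}
#' with the data term summed over the batch and
#' \eqn{\mathrm{Tr}(|W_S|)} the absolute sum of the diagonal of \eqn{W_S}.
#'
#' @param params Parameter list with elements \code{Ws}, \code{W1},
#'   \code{W2}, \code{alpha}, \code{D} and shape constant \code{b}.
#' @param batch A \linkS4class{DerivativeSamples} object (or a subset).
#' @param cfg A \code{\link{fitConfig}}.
#' @return Nonnegative finite scalar.
#' @export
mindyLoss <- function(params, batch, cfg) {
  if (!all(vapply(params[c("Ws", "W1", "W2", "alpha", "D")],
                  function(p) all(is.finite(p)), logical(1))))
    stop("non-finite parameters")
  R <- paramsPredict(params, batch@states) - batch@targets
  0.5 * sum(R^2) +
    cfg$lambda1 * sum(abs(params$Ws)) +
    cfg$lambda2 * sum(abs(diag(params$Ws))) +
    cfg$lambda3 * (sum(abs(params$W1)) + sum(abs(params$W2)))
}

#' Analytic gradients of the fitting loss
#'
#' Gradients of \code{\link{mindyLoss}} with respect to every parameter
#' tensor; the L1 subgradient at exact zeros is taken as 0.
#'
#' @inheritParams mindyLoss
#' @return List of gradients with the shapes of the parameters.
#' @export
mindyGradients <- function(params, batch, cfg) {
  X <- batch@states
  psi <- transferPsi(X, params$alpha, params$b)
  W <- params$Ws + params$W1 %*% t(params$W2)
  R <- psi %*% t(W) - X * rep(params$D, each = nrow(X)) - batch@targets
  G <- crossprod(R, psi)               # dJ/dW  [N x N]
  dAlpha <- colSums(R %*% W * psiDAlpha(X, params$alpha, params$b))
  list(
    Ws = G + cfg$lambda1 * sign(params$Ws) +
      cfg$lambda2 * diag(sign(diag(params$Ws)), nrow(G)),
    W1 = G %*% params$W2 + cfg$lambda3 * sign(params$W1),
    W2 = t(G) %*% params$W1 + cfg$lambda3 * sign(params$W2),
    alpha = dAlpha,
    D = -colSums(R * X)
  )
}

## One NADAM update. state: list(m, v, t) with m, v mirroring params.
## Returns list(params, state). Deterministic given inputs.
nadamStep <- function(state, params, grads, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2; t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    ## Nesterov momentum: look-ahead combination of mhat and current gradient
    upd <- (b1 * mhat + (1 - b1) * g / (1 - b1^t)) /
      (sqrt(vhat) + cfg$epsilon)
    params[[nm]] <- params[[nm]] - cfg$learningRate * upd
  }
  list(params = params, state = state)
}

## Curvature starts high (near-linear transfer over the data range): the
## saturating regime is a local optimum that fabricates spurious attractors
## on stationary noise, so the optimizer descends into saturation only when
## the data demand it.
initParams <- function(n, k, b) {
  sdw <- 0.01 / sqrt(n)
  list(Ws = matrix(stats::rnorm(n * n, 0, sdw), n, n),
       W1 = matrix(stats::rnorm(n * k, 0, sdw), n, k),
       W2 = matrix(stats::rnorm(n * k, 0, sdw), n, k),
       alpha = rep(30, n), D = rep(0.2, n), b = b)
}

#' Fit a MINDy model to derivative samples
#'
#' Minimizes \code{\link{mindyLoss}} by minibatch NADAM from a small random
#' initialization, then applies \code{\link{globalRescale}}. Minibatches are
#' sampled with replacement; curvature is clamped at \code{cfg$alphaFloor}
#' after each update. Deterministic given \code{cfg$seed}.
#'
#' @param samples A \linkS4class{DerivativeSamples} object with at least
#'   \code{cfg$batchSize} rows.
#' @param cfg A \code{\link{fitConfig}}.
#' @param tr Sampling interval stored on the fitted model (seconds).
#' @param b Transfer-function shape constant (default 20/3).
#' @return A fitted \linkS4class{MindyModel}; \code{fitInfo} carries the loss
#'   trace (every 100 batches), the rescaling factors and the seed.
#' @export
fitMindy <- function(samples, cfg = fitConfig(), tr = 0.72, b = 20 / 3) {
  stopifnot(is(samples, "DerivativeSamples"))
  M <- nrow(samples@states)
  n <- ncol(samples@states)
  if (M < cfg$batchSize)
    stop("need at least batchSize = ", cfg$batchSize, " samples, have ", M)
  k <- if (is.null(cfg$rank)) max(1L, as.integer(round(0.36 * n))) else
    as.integer(cfg$rank)
  if (k >= n) stop("rank must be < number of parcels")
  lossTrace <- numeric(0)
  fitted <- withr::with_seed(cfg$seed, {
    params <- initParams(n, k, b)
    state <- list(m = lapply(params[c("Ws", "W1", "W2", "alpha", "D")],
                             function(p) p * 0),
                  v = lapply(params[c("Ws", "W1", "W2", "alpha", "D")],
                             function(p) p * 0),
                  t = 0L)
    for (it in seq_len(cfg$nBatches)) {
      idx <- sample.int(M, cfg$batchSize, replace = TRUE)
      batch <- new("DerivativeSamples",
                   states = samples@states[idx, , drop = FALSE],
                   targets = samples@targets[idx, , drop = FALSE],
                   sampleIndex = samples@sampleIndex[idx],
                   smoothed = samples@smoothed)
      grads <- mindyGradients(params, batch, cfg)
      if (!all(vapply(grads, function(g) all(is.finite(g)), logical(1))))
        stop("divergent loss (non-finite gradient) at batch ", it)
      res <- nadamStep(state, params, grads, cfg)
      params <- res$params; state <- res$state
      params$alpha <- pmax(params$alpha, cfg$alphaFloor)
      if (it %% 100L == 0L)
        lossTrace <- c(lossTrace, mindyLoss(params, batch, cfg))
    }
    params
  })
  model <- mindyModel(fitted$Ws, fitted$W1, fitted$W2, fitted$alpha,
                      fitted$D, b, tr,
                      fitInfo = list(lossTrace = lossTrace,
                                     seed = cfg$seed, rank = k))
  globalRescale(model, samples)
}

#' Global rescaling of fitted parameters
#'
#' Counteracts regularization shrinkage by solving the two-parameter least
#' squares problem \eqn{\hat\Delta x \approx p_W W \psi_\alpha(x) -
#' p_D D \odot x} over all samples and folding \eqn{p_W, p_D} into the
#' parameters (\eqn{p_W} applied to \eqn{W_S} and split as
#' \eqn{\sqrt{|p_W|}} over each low-rank factor, preserving the
#' sparse-plus-low-rank decomposition; \eqn{p_D} applied to \eqn{D}).
#'
#' @param model A fitted \linkS4class{MindyModel}.
#' @param samples The \linkS4class{DerivativeSamples} used for fitting.
#' @return The rescaled model; \code{fitInfo$rescale} records
#'   \eqn{(p_W, p_D)}. If the 2x2 normal system is singular the scales are
#'   left at 1 with a warning.
#' @export
globalRescale <- function(model, samples) {
  X <- samples@states
  A <- transferPsi(X, model@curvature, model@shapeConstant) %*%
    t(connWeights(model))
  B <- X * rep(model@decay, each = nrow(X))
  Y <- samples@targets
  ## minimize || Y - pW A + pD B ||^2
  M <- matrix(c(sum(A * A), -sum(A * B), -sum(A * B), sum(B * B)), 2, 2)
  rhs <- c(sum(A * Y), -sum(B * Y))
  p <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(p) || !all(is.finite(p))) {
    warning("singular rescaling system; leaving scales at 1")
    p <- c(1, 1)
  }
  pw <- p[1]; pd <- p[2]
  fi <- model@fitInfo
  fi$rescale <- c(pW = pw, pD = pd)
  initialize(model,
             sparseWeights = model@sparseWeights * pw,
             lowrankLeft = model@lowrankLeft * sign(pw) * sqrt(abs(pw)),
             lowrankRight = model@lowrankRight * sqrt(abs(pw)),
             decay = model@decay * pd,
             fitInfo = fi)
}

#' Variance of derivative targets explained by a model
#'
#' \eqn{R^2 = 1 - \mathrm{SSE}/\mathrm{SST}} over all entries of the targets,
#' with SST taken about the grand mean. May be negative for poor models.
#'
#' @param model A \linkS4class{MindyModel}.
#' @param samples A \linkS4class{DerivativeSamples} object (e.g. held-out).
#' @return Scalar \eqn{\le 1}.
#' @export
r2Derivatives <- function(model, samples) {
  Y <- samples@targets
  sst <- sum((Y - mean(Y))^2)
  if (sst == 0) stop("targets have zero total variance")
  pred <- deltaMindyMat(model, samples@states)
  1 - sum((Y - pred)^2) / sst
}
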