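## Bifurcation probing: spectrum of taxonomies under convex combination of
## models, weight-mixing and weight-shuffling controls, and the analytic
## infinite-period (SNIC) toy model.

#' Construct the planar SNIC toy model
#'
#' @param mu Bifurcation parameter (\eqn{\mu > 0}); \eqn{\mu < 1} gives two
#'   pairs of equilibria on the unit circle, \eqn{\mu > 1} one stable limit
#'   cycle.
#' @param radialGain Radial attraction gain (default 1).
#' @param stepSize Euler integration step in time units (default 0.01).
#' @return A \linkS4class{ToySnic} dynamics object.
#' @seealso \code{\link{snicEquilibria}}, \code{\link{classifyLandscape}}
#' @export
toySnic <- function(mu, radialGain = 1, stepSize = 0.01) {
  new("ToySnic", mu = mu, radialGain = radialGain, stepSize = stepSize)
}

#' Analytic equilibria of the SNIC toy model
#'
#' For \eqn{0 < \mu < 1} the angular equation \eqn{\sin(2\theta) = \mu} has
#' four solutions on the unit circle: \eqn{2\theta = \arcsin\mu} and
#' \eqn{\pi - \arcsin\mu}, each plus \eqn{\pi}. Stability follows from the
#' angular Jacobian \eqn{-2\cos(2\theta)}: the \eqn{\arcsin\mu} pair is
#' stable, the \eqn{\pi - \arcsin\mu} pair are saddles. For \eqn{\mu \ge 1}
#' there are no equilibria off the origin.
#'
#' @param mu Bifurcation parameter.
#' @return Data frame with columns \code{x}, \code{y}, \code{theta},
#'   \code{stable}; zero rows when \eqn{\mu \ge 1}.
#' @export
snicEquilibria <- function(mu) {
  stopifnot(mu > 0)
  if (mu >= 1)
    return(data.frame(x = numeric(0), y = numeric(0),
                      theta = numeric(0), stable = logical(0)))
  th <- c(asin(mu) / 2, (pi - asin(mu)) / 2)
  th <- c(th, th + pi)
  stable <- cos(2 * th) > 0
  data.frame(x = cos(th), y = sin(th), theta = th, stable = stable)
}

#' Sample the spectrum of dynamics under convex combination
#'
#' Draws \code{nSamples} (pair, \eqn{\gamma}) combinations — pairs taken
#' within persons (the two session models of one person) or across the whole
#' model set, \eqn{\gamma \sim U[0,1]} — classifies each combined dynamics
#' from standard normal initial conditions, and returns one record per draw.
#'
#' @param models List of \linkS4class{MindyModel}s.
#' @param mode \code{"within"} (requires \code{sessionOf}/\code{personOf})
#'   or \code{"across"}.
#' @param nSamples Number of draws (default 500).
#' @param nInit Initial conditions per classification (default 120).
#' @param nSteps Integration steps (default 1600).
#' @param seed Integer seed.
#' @param personOf,sessionOf For \code{mode = "within"}: vectors giving each
#'   model's person and session; each person must have exactly two session
#'   models.
#' @return Data frame with columns \code{i}, \code{j} (model indices),
#'   \code{gamma}, \code{label}, \code{nFp}, \code{nLc}.
#' @export
sampleSpectrum <- function(models, mode = c("within", "across"),
                           nSamples = 500L, nInit = 120L, nSteps = 1600L,
                           seed = 1L, personOf = NULL, sessionOf = NULL) {
  mode <- match.arg(mode)
  if (length(models) < 2) stop("need at least 2 models")
  draws <- withr::with_seed(seed, {
    g <- stats::runif(nSamples)
    if (mode == "within") {
      if (is.null(personOf))
        stop("within mode requires personOf metadata")
      persons <- unique(personOf)
      pidx <- sample(persons, nSamples, replace = TRUE)
      ij <- t(vapply(pidx, function(p) which(personOf == p)[1:2],
                     integer(2)))
      cbind(ij, g)
    } else {
      ij <- t(replicate(nSamples, sample.int(length(models), 2)))
      cbind(ij, g)
    }
  })
  out <- vector("list", nSamples)
  for (s in seq_len(nSamples)) {
    i <- draws[s, 1]; j <- draws[s, 2]; g <- draws[s, 3]
    dyn <- combineDynamics(models[[i]], models[[j]], g)
    ls <- classifyLandscape(dyn, nInit = nInit, nSteps = nSteps,
                            seed = seed + s)
    out[[s]] <- data.frame(i = i, j = j, gamma = g, label = ls@label,
                           nFp = ls@nFp, nLc = ls@nLc)
  }
  do.call(rbind, out)
}

#' Mix model weights element-wise
#'
#' Returns a \linkS4class{MindyModel} whose every parameter tensor is the
#' convex combination \eqn{\gamma \theta_1 + (1-\gamma)\theta_2} of the two
#' models' tensors. This differs from \code{\link{combineDynamics}}: mixing
#' the parameters does not in general equal mixing the vector fields when
#' the curvatures differ.
#'
#' @param m1,m2 Two \linkS4class{MindyModel}s with identical dimensions,
#'   shape constant and TR.
#' @param gamma Mixing coefficient in \eqn{[0, 1]}.
#' @return A \linkS4class{MindyModel}.
#' @export
mixWeights <- function(m1, m2, gamma) {
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must lie in [0, 1]")
  if (!identical(dim(m1@sparseWeights), dim(m2@sparseWeights)) ||
      !identical(dim(m1@lowrankLeft), dim(m2@lowrankLeft)))
    stop("models must share N and k")
  mix <- function(a, b) gamma * a + (1 - gamma) * b
  mindyModel(mix(m1@sparseWeights, m2@sparseWeights),
             mix(m1@lowrankLeft, m2@lowrankLeft),
             mix(m1@lowrankRight, m2@lowrankRight),
             mix(m1@curvature, m2@curvature),
             mix(m1@decay, m2@decay),
             m1@shapeConstant, m1@tr)
}

#' Shuffle connectivity entries (negative control)
#'
#' Randomly permutes the entries of the effective connectivity
#' \eqn{W = W_S + W_1 W_2^T}, storing the permuted matrix entirely in the
#' sparse component (shuffling destroys the low-rank structure, so the
#' low-rank factors are zeroed). Other parameters are untouched. The entry
#' multiset of \eqn{W} is preserved exactly.
#'
#' @param model A \linkS4class{MindyModel}.
#' @param seed Integer seed for the permutation.
#' @return A \linkS4class{MindyModel} with shuffled connectivity.
#' @export
shuffleWeights <- function(model, seed = 1L) {
  W <- connWeights(model)
  n <- nrow(W)
  Wp <- withr::with_seed(seed,
                         matrix(sample(as.vector(W)), n, n))
  k <- ncol(model@lowrankLeft)
  initialize(model, sparseWeights = Wp,
             lowrankLeft = matrix(0, n, k),
             lowrankRight = matrix(0, n, k))
}

#' Compare two taxonomy tallies
#'
#' Groups labels with relative frequency below \code{othersBelow} (applied to
#' the pooled tally, identically for both) into \code{"others"}, then reports
#' the total-variation distance between the two relative-frequency
#' distributions and a chi-squared statistic on the pooled categories.
#'
#' @param tallyA,tallyB Named integer vectors: counts per taxonomy label.
#' @param othersBelow Pooling threshold on relative frequency (default
#'   0.005).
#' @return List: \code{tv} (total-variation distance in \eqn{[0,1]}),
#'   \code{chisq} (statistic), \code{table} (grouped label-by-sample counts).
#' @export
compareTaxonomyDistributions <- function(tallyA, tallyB,
                                         othersBelow = 0.005) {
  if (!length(tallyA) || !length(tallyB)) stop("empty tally")
  labs <- union(names(tallyA), names(tallyB))
  a <- stats::setNames(rep(0, length(labs)), labs)
  b <- a
  a[names(tallyA)] <- tallyA
  b[names(tallyB)] <- tallyB
  pooled <- (a + b) / sum(a + b)
  rare <- pooled < othersBelow
  if (any(rare)) {
    a <- c(a[!rare], others = sum(a[rare]))
    b <- c(b[!rare], others = sum(b[rare]))
  }
  pa <- a / sum(a)
  pb <- b / sum(b)
  tab <- rbind(A = a, B = b)
  keep <- colSums(tab) > 0
  chisq <- suppressWarnings(stats::chisq.test(tab[, keep, drop = FALSE]))
  list(tv = sum(abs(pa - pb)) / 2, chisq = unname(chisq$statistic),
       table = tab)
}
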