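## Reliability & clustering: anatomical pattern correlation, dominant
## attractor similarity (DAS), cosine K-means, optimal label matching,
## cluster instability index, K selection, cluster-by-network variance
## decomposition.

#' Anatomical similarity of two activation patterns
#'
#' Pearson correlation over parcels between two attractor patterns.
#'
#' @param a,b Numeric vectors of equal length with nonzero variance.
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
patternCorrelation <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance pattern")
  stats::cor(a, b)
}

#' Dominant attractor similarity (DAS)
#'
#' The maximum \code{\link{patternCorrelation}} over all cross pairs of the
#' two models' attractor patterns (stable equilibria and ghost attractors
#' both count).
#'
#' @param attractorsA,attractorsB Matrices with one attractor pattern per
#'   row (see \code{\link{attractorPatterns}}); both non-empty.
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
das <- function(attractorsA, attractorsB) {
  if (is.vector(attractorsA)) attractorsA <- matrix(attractorsA, 1)
  if (is.vector(attractorsB)) attractorsB <- matrix(attractorsB, 1)
  if (!nrow(attractorsA) || !nrow(attractorsB))
    stop("model with no (non-origin) attractors: DAS undefined")
  max(stats::cor(t(attractorsA), t(attractorsB)))
}

#' Pairwise DAS table across sessions
#'
#' Scores every unordered pair of models from different sessions and flags
#' whether the pair comes from the same person and whether the two
#' landscapes have the same taxonomy. Models without non-origin attractors
#' are dropped (the zero pattern carries no anatomical similarity).
#'
#' @param landscapes List of \linkS4class{MindyLandscape}s.
#' @param personOf,sessionOf Vectors giving each model's person and session.
#' @return Data frame with columns \code{modelA}, \code{modelB},
#'   \code{samePerson}, \code{sameType}, \code{das}.
#' @export
dasGroupTable <- function(landscapes, personOf, sessionOf) {
  stopifnot(length(landscapes) == length(personOf),
            length(landscapes) == length(sessionOf))
  pats <- lapply(landscapes, attractorPatterns)
  keep <- vapply(pats, nrow, integer(1)) > 0
  out <- list()
  n <- length(landscapes)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (sessionOf[i] == sessionOf[j]) next
      if (!keep[i] || !keep[j]) next
      out[[length(out) + 1L]] <- data.frame(
        modelA = i, modelB = j,
        samePerson = personOf[i] == personOf[j],
        sameType = landscapes[[i]]@label == landscapes[[j]]@label,
        das = das(pats[[i]], pats[[j]]))
    }
  }
  if (!length(out))
    return(data.frame(modelA = integer(0), modelB = integer(0),
                      samePerson = logical(0), sameType = logical(0),
                      das = numeric(0)))
  do.call(rbind, out)
}

## cosine distance of rows of X to unit-norm centroid rows C: 1 - X C^T
## (X rows must be unit norm)
unitRows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("zero vector cannot be unit-normalized")
  X / nrm
}

#' K-means under cosine distance
#'
#' Lloyd iteration with distance \eqn{d(x, y) = 1 - \cos\angle(x, y)}:
#' rows are scaled to unit norm, assignment is to the nearest centroid by
#' cosine, and each centroid is the unit-normalized mean of its members.
#' Initialization is k-means++-style under cosine distance; the best of
#' \code{nRestarts} runs by total within-cluster distance is returned. An
#' emptied cluster is re-seeded from the point farthest from its centroid.
#' Deterministic given \code{seed}. Assignments are invariant to scaling any
#' input row.
#'
#' @param x Numeric matrix, one observation per row, no zero rows,
#'   \code{nrow(x) >= K}.
#' @param K Number of clusters.
#' @param seed Integer seed.
#' @param nRestarts Number of restarts (default 20).
#' @param maxIter Maximum Lloyd iterations per restart (default 100).
#' @return List of class \code{"cosineKmeans"}: \code{assignments} (integer
#'   per row), \code{centroids} (\eqn{K \times N}, unit-norm rows),
#'   \code{withinDist} (total within-cluster cosine distance), \code{K}.
#' @export
cosineKmeans <- function(x, K, seed = 1L, nRestarts = 20L, maxIter = 100L) {
  stopifnot(is.matrix(x), nrow(x) >= K, K >= 1)
  X <- unitRows(x)
  n <- nrow(X)
  oneRun <- function() {
    ## k-means++ seeding under cosine distance
    centers <- integer(K)
    centers[1] <- sample.int(n, 1)
    if (K > 1) {
      d2 <- pmax(0, 1 - X %*% X[centers[1], ])
      for (kk in 2:K) {
        p <- as.vector(d2)
        centers[kk] <- if (sum(p) == 0) sample.int(n, 1)
          else sample.int(n, 1, prob = p)
        d2 <- pmin(d2, pmax(0, 1 - X %*% X[centers[kk], ]))
      }
    }
    C <- X[centers, , drop = FALSE]
    assign <- integer(n)
    for (it in seq_len(maxIter)) {
      sim <- X %*% t(C)
      newAssign <- max.col(sim, ties.method = "first")
      ## re-seed emptied clusters from the farthest point
      for (kk in seq_len(K)) {
        if (!any(newAssign == kk)) {
          far <- which.min(sim[cbind(seq_len(n), newAssign)])
          C[kk, ] <- X[far, ]
          newAssign[far] <- kk
        }
      }
      if (identical(newAssign, assign)) break
      assign <- newAssign
      for (kk in seq_len(K)) {
        mu <- colMeans(X[assign == kk, , drop = FALSE])
        nrm <- sqrt(sum(mu^2))
        if (nrm > 0) C[kk, ] <- mu / nrm
      }
    }
    within <- sum(1 - rowSums(X * C[assign, , drop = FALSE]))
    list(assignments = assign, centroids = C, withinDist = within, K = K)
  }
  best <- withr::with_seed(seed, {
    runs <- lapply(seq_len(nRestarts), function(r) oneRun())
    runs[[which.min(vapply(runs, `[[`, numeric(1), "withinDist"))]]
  })
  structure(best, class = "cosineKmeans")
}

## classify rows of X (unit-normalized internally) by nearest centroid
classifyByCentroids <- function(x, centroids) {
  X <- unitRows(x)
  max.col(X %*% t(centroids), ties.method = "first")
}

## exact minimum-cost assignment on a K x K cost matrix by bitmask DP
## (optimal assignment, the optimum the Hungarian algorithm attains)
solveAssignment <- function(cost) {
  K <- nrow(cost)
  nMask <- bitwShiftL(1L, K)
  dp <- rep(Inf, nMask)
  dp[1] <- 0
  pop <- integer(nMask)
  for (m in seq_len(nMask - 1))
    pop[m + 1] <- pop[bitwShiftR(m, 1) + 1] + bitwAnd(m, 1L)
  for (m in 0:(nMask - 2)) {
    if (!is.finite(dp[m + 1])) next
    i <- pop[m + 1] + 1L          # next row to assign
    for (j in seq_len(K)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(m, bit) == 0L) {
        nm <- bitwOr(m, bit)
        v <- dp[m + 1] + cost[i, j]
        if (v < dp[nm + 1]) dp[nm + 1] <- v
      }
    }
  }
  dp[nMask]
}

#' Label-matched misclassification cost
#'
#' The minimum over label permutations of the fraction of disagreeing items
#' between two labelings, computed via exact optimal assignment on the
#' \eqn{K \times K} confusion matrix (the optimum the Hungarian algorithm
#' attains).
#'
#' @param labelsA,labelsB Integer labelings in \code{1..K} of the same items.
#' @param K Number of labels.
#' @return Misclassification fraction in \eqn{[0, 1]}.
#' @export
hungarianCost <- function(labelsA, labelsB, K) {
  stopifnot(length(labelsA) == length(labelsB), length(labelsA) >= 1)
  conf <- matrix(0, K, K)
  for (i in seq_along(labelsA))
    conf[labelsA[i], labelsB[i]] <- conf[labelsA[i], labelsB[i]] + 1
  ## cost of mapping label a -> b: items with label a not labelled b
  cost <- rowSums(conf) - conf
  solveAssignment(cost) / length(labelsA)
}

#' Cluster instability index
#'
#' For one candidate \eqn{K}: over \code{nSplits} random halvings of the
#' data, K-means is run on the first half, its centroids classify the second
#' half, and the result is compared (after optimal label matching) with
#' K-means run directly on the second half. The mean matched
#' misclassification cost is normalized by the same quantity computed with
#' uniformly random labels. Lower is more stable. Deterministic given
#' \code{cfg$seed}.
#'
#' @param x Attractor matrix, one pattern per row (\code{nrow >= 2K}).
#' @param K Number of clusters.
#' @param nSplits Number of random halvings (default 30).
#' @param seed Integer seed.
#' @param nRestarts K-means restarts per run (default 20).
#' @return Instability index (about 0 for perfectly stable clusterings,
#'   about 1 for structureless data).
#' @export
instabilityIndex <- function(x, K, nSplits = 30L, seed = 1L,
                             nRestarts = 20L) {
  stopifnot(nrow(x) >= 2 * K)
  n <- nrow(x)
  withr::with_seed(seed, {
    cost <- nullCost <- numeric(nSplits)
    for (s in seq_len(nSplits)) {
      perm <- sample.int(n)
      h1 <- perm[seq_len(floor(n / 2))]
      h2 <- perm[(floor(n / 2) + 1):n]
      km1 <- cosineKmeans(x[h1, , drop = FALSE], K,
                          seed = sample.int(.Machine$integer.max, 1),
                          nRestarts = nRestarts)
      km2 <- cosineKmeans(x[h2, , drop = FALSE], K,
                          seed = sample.int(.Machine$integer.max, 1),
                          nRestarts = nRestarts)
      transferred <- classifyByCentroids(x[h2, , drop = FALSE],
                                         km1$centroids)
      cost[s] <- hungarianCost(transferred, km2$assignments, K)
      nullCost[s] <- hungarianCost(sample.int(K, length(h2), replace = TRUE),
                                   sample.int(K, length(h2), replace = TRUE),
                                   K)
    }
    mean(cost) / mean(nullCost)
  })
}

#' Select the number of clusters by instability
#'
#' Evaluates \code{\link{instabilityIndex}} over candidate \eqn{K} and
#' returns the interior local minima of the curve, choosing the global
#' minimum among them. When no interior local minimum exists the global
#' minimum is returned with a warning. \eqn{K = 2} is reported but flagged:
#' with attractors occurring in \eqn{\pm} pairs it represents only one
#' pattern and its opposite.
#'
#' @param x Attractor matrix, one pattern per row.
#' @param kCandidates Candidate values of \eqn{K} (default \code{2:10}).
#' @param nSplits Halvings per candidate (default 30).
#' @param seed Integer seed.
#' @param nRestarts K-means restarts (default 20).
#' @return List: \code{K} (selected), \code{curve} (named instability
#'   values), \code{localMinima}, \code{k2Antipodal} (TRUE when the selected
#'   K is 2).
#' @export
selectK <- function(x, kCandidates = 2:10, nSplits = 30L, seed = 1L,
                    nRestarts = 20L) {
  curve <- vapply(kCandidates, function(K)
    instabilityIndex(x, K, nSplits, seed + K, nRestarts), numeric(1))
  names(curve) <- kCandidates
  nc <- length(curve)
  isMin <- if (nc >= 3)
    which(curve[2:(nc - 1)] < curve[1:(nc - 2)] &
          curve[2:(nc - 1)] < curve[3:nc]) + 1L
  else integer(0)
  if (length(isMin)) {
    K <- kCandidates[isMin[which.min(curve[isMin])]]
  } else {
    warning("no interior local minimum in the instability curve; ",
            "returning the global minimum")
    K <- kCandidates[which.min(curve)]
  }
  list(K = K, curve = curve, localMinima = kCandidates[isMin],
       k2Antipodal = K == 2)
}

#' Variance explained by cluster-by-network cell means
#'
#' Fraction of the total (grand-mean-centered) sum of squares of the
#' attractor matrix explained by the two-way cell means over attractor
#' cluster (rows) and parcel network (columns).
#'
#' @param x Attractor matrix, one pattern per row.
#' @param assignments Cluster label per row.
#' @param networkLabels Network label per column.
#' @return Fraction in \eqn{[0, 1]}.
#' @export
varianceDecomposition <- function(x, assignments, networkLabels) {
  stopifnot(length(assignments) == nrow(x),
            length(networkLabels) == ncol(x))
  cl <- as.integer(factor(assignments))
  nw <- as.integer(factor(networkLabels))
  fit <- matrix(0, nrow(x), ncol(x))
  for (a in unique(cl)) {
    ri <- cl == a
    for (b in unique(nw)) {
      cj <- nw == b
      fit[ri, cj] <- mean(x[ri, cj])
    }
  }
  1 - sum((x - fit)^2) / sum((x - mean(x))^2)
}
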