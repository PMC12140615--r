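## Attractor landscape extraction: equilibrium detection on trajectories,
## greedy terminal-state clustering, limit-cycle recurrence detection,
## ghost-attractor extraction, taxonomy labelling.

#' Detect equilibrium convergence of a trajectory
#'
#' A trajectory has converged to a stable equilibrium when every one of its
#' last 10 one-step changes is below \code{tol} in every coordinate
#' (strictly; a constant drift of exactly \code{tol} does not converge).
#'
#' @param traj Trajectory matrix (rows = states), at least 11 rows.
#' @param tol Element-wise convergence tolerance (default 1e-6).
#' @return The terminal state if converged, otherwise \code{NULL}.
#' @export
detectEquilibrium <- function(traj, tol = 1e-6) {
  stopifnot(is.matrix(traj), nrow(traj) >= 11)
  tail10 <- traj[(nrow(traj) - 10):nrow(traj), , drop = FALSE]
  d <- abs(diff(tail10))
  if (all(d < tol)) traj[nrow(traj), ] else NULL
}

#' Greedy clustering of converged terminal states
#'
#' First-come assignment in input order: each terminal joins the first
#' already-identified equilibrium whose founder lies within \code{distThresh}
#' Euclidean distance, otherwise it founds a new equilibrium. The cluster
#' representative is the founder terminal state.
#'
#' @param terminals List of terminal state vectors (or a row-matrix).
#' @param distThresh Euclidean distance threshold (default 0.1).
#' @return List of equilibrium records: \code{state} (the founder),
#'   \code{basinCount} (number of members), \code{atOrigin}
#'   (\eqn{\|x\|_2 <} \code{distThresh}).
#' @export
clusterEquilibria <- function(terminals, distThresh = 0.1) {
  if (is.matrix(terminals))
    terminals <- lapply(seq_len(nrow(terminals)), function(i) terminals[i, ])
  eq <- list()
  for (x in terminals) {
    assigned <- FALSE
    for (i in seq_along(eq)) {
      if (sqrt(sum((x - eq[[i]]$state)^2)) < distThresh) {
        eq[[i]]$basinCount <- eq[[i]]$basinCount + 1L
        assigned <- TRUE
        break
      }
    }
    if (!assigned)
      eq[[length(eq) + 1L]] <- list(state = x, basinCount = 1L,
                                    atOrigin = sqrt(sum(x^2)) < distThresh)
  }
  eq
}

## Recurrence bookkeeping on one stored trajectory: distances to the terminal
## state; the trajectory is cycling if it approached the terminal
## neighbourhood (radius-`radius` ball), left it, and re-entered. One full
## period is the segment between the two most recent entry events (with an
## exit in between), so the first and last samples sit at the same phase of
## the orbit. Returns NULL or the cycle record.
extractCycle <- function(traj, radius = 0.5) {
  T <- nrow(traj)
  if (T < 3) return(NULL)
  terminal <- traj[T, ]
  d <- sqrt(rowSums((traj - rep(terminal, each = T))^2))
  inside <- d < radius
  trans <- diff(inside)          # +1 = entry, -1 = exit
  exits <- which(trans == -1L)
  entries <- which(trans == 1L) + 1L
  if (length(entries) < 2 || !length(exits)) return(NULL)
  eLast <- entries[length(entries)]
  ePrev <- entries[length(entries) - 1L]
  if (!any(exits > ePrev & exits < eLast)) return(NULL)
  samples <- traj[ePrev:eLast, , drop = FALSE]
  sp <- sqrt(rowSums(diff(samples)^2))
  list(samples = samples, period = eLast - ePrev,
       speeds = sp, basinCount = 1L)
}

#' Detect a stable limit cycle in a trajectory
#'
#' Scans the trajectory for entries and exits of the Euclidean ball of radius
#' \code{radius} around its final state. If the state approached the terminal
#' neighbourhood, left it, and re-entered at least once, the segment from the
#' last re-entry to the end is returned as one period. If no recurrence is
#' found and \code{dynamics} is supplied, the simulation is prolonged (in
#' blocks) up to \code{maxExtend} additional steps until the state recurs
#' after a full cycle.
#'
#' @param traj Trajectory matrix (typically not equilibrium-converged).
#' @param dynamics Optional dynamics used to extend the simulation.
#' @param radius Neighbourhood radius (default 0.5).
#' @param maxExtend Maximum number of additional steps (default 20x the
#'   trajectory length).
#' @return A limit-cycle record (\code{samples} [one period, first/last
#'   close], \code{period} in steps, \code{speeds} with
#'   \eqn{s_n = \|x_{n+1} - x_n\|_2}) or \code{NULL} when no recurrence was
#'   found within the budget.
#' @export
detectLimitCycle <- function(traj, dynamics = NULL, radius = 0.5,
                             maxExtend = 20L * nrow(traj)) {
  cyc <- extractCycle(traj, radius)
  if (!is.null(cyc) || is.null(dynamics)) return(cyc)
  block <- nrow(traj)
  used <- 0L
  while (used < maxExtend) {
    nExt <- min(block, maxExtend - used)
    ext <- simulateTrajectory(dynamics, traj[nrow(traj), ], nExt)
    traj <- rbind(traj, ext[-1, , drop = FALSE])
    used <- used + nExt
    cyc <- extractCycle(traj, radius)
    if (!is.null(cyc)) return(cyc)
    ## also re-check equilibrium convergence after extension
    if (!is.null(detectEquilibrium(traj))) return(NULL)
  }
  NULL
}

#' Ghost attractors of a limit cycle
#'
#' The slowest point on the cycle, \eqn{\arg\min_n \|x_{n+1} - x_n\|_2}
#' (ties broken by lowest index). When the landscape contains exactly one
#' limit cycle, the odd symmetry \eqn{f(-x) = -f(x)} makes the cycle
#' self-symmetric, and a pair of symmetric slowest points (the argmin and its
#' negation) is returned rather than a single one.
#'
#' @param cycle A limit-cycle record from \code{\link{detectLimitCycle}}.
#' @param singleCycleLandscape TRUE when the landscape has exactly one limit
#'   cycle.
#' @return List of ghost records: \code{state}, \code{speed},
#'   \code{cycleIndex} (position of the slowest sample on the cycle).
#' @export
ghostPoints <- function(cycle, singleCycleLandscape = FALSE) {
  stopifnot(nrow(cycle$samples) >= 2)
  i <- which.min(cycle$speeds)
  g <- list(state = cycle$samples[i, ], speed = cycle$speeds[i],
            cycleIndex = i)
  if (singleCycleLandscape)
    list(g, list(state = -g$state, speed = g$speed, cycleIndex = i))
  else list(g)
}

#' Speed ratio of a limit cycle
#'
#' \code{max(speeds)/min(speeds)} along the cycle; large ratios signal a
#' ghost attractor (the slowing signature of a nearby infinite-period
#' bifurcation). A zero minimum speed reports \code{Inf}.
#'
#' @param cycle A limit-cycle record.
#' @return Scalar \eqn{\ge 1} (possibly \code{Inf}).
#' @export
speedRatio <- function(cycle) {
  if (min(cycle$speeds) == 0) return(Inf)
  max(cycle$speeds) / min(cycle$speeds)
}

## min Euclidean distance from point p to the polyline through rows of S
pointPolylineDist <- function(p, S) {
  A <- S[-nrow(S), , drop = FALSE]
  B <- S[-1, , drop = FALSE]
  AB <- B - A
  AP <- -sweep(A, 2, p)
  t <- rowSums(AP * AB) / pmax(rowSums(AB^2), .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  proj <- A + AB * t
  sqrt(min(rowSums(sweep(proj, 2, p)^2)))
}

## greedy merge of cycle records: b joins a when b's terminal sample lies
## within `radius`/2 of a's closed orbit (point-to-polyline distance, so
## coarsely sampled fast cycles still merge across phases)
sameCycle <- function(a, b, radius) {
  pb <- b$samples[nrow(b$samples), ]
  pointPolylineDist(pb, a$samples) < radius / 2
}

#' Classify the attractor landscape of a dynamical system
#'
#' Simulates the (noise-free) dynamics from many initial conditions, applies
#' equilibrium detection, greedy equilibrium clustering, limit-cycle
#' recurrence detection with prolongation, and ghost extraction, and returns
#' the taxonomy. Initial conditions are either rows sampled from supplied
#' data frames (the model's training data) or standard normal draws.
#' Trajectories neither converged nor recurrent after prolongation are
#' counted as unresolved, not silently dropped. Deterministic given
#' \code{seed}. A model whose trajectories diverge in more than half of the
#' initial conditions is flagged \code{"numerical issues"}.
#'
#' @param dynamics Any \linkS4class{MindyDynamics} object.
#' @param nInit Number of initial conditions (default 1000).
#' @param initData Optional matrix of data frames to sample initial
#'   conditions from; \code{NULL} uses standard normal draws.
#' @param nSteps Integration steps per trajectory (default 1600).
#' @param seed Integer seed for the initial conditions.
#' @param distThresh Equilibrium clustering threshold (default 0.1); an
#'   equilibrium is "at the origin" if its norm is below this.
#' @param eqTol Equilibrium convergence tolerance (default 1e-6).
#' @param cycleRadius Recurrence neighbourhood radius (default 0.5).
#' @param maxExtend Maximum prolongation steps (default \code{20 * nSteps}).
#' @param blowup Divergence threshold on \eqn{|x|} (default 1e6).
#' @return A \linkS4class{MindyLandscape}.
#' @examples
#' decayOnly <- mindyModel(diag(0, 3), matrix(0, 3, 1), matrix(0, 3, 1))
#' taxonomyLabel(classifyLandscape(decayOnly, nInit = 20, nSteps = 200,
#'                                 seed = 1))  # "1FP 0LC"
#' @export
classifyLandscape <- function(dynamics, nInit = 1000L, initData = NULL,
                              nSteps = 1600L, seed = 1L, distThresh = 0.1,
                              eqTol = 1e-6, cycleRadius = 0.5,
                              maxExtend = 20L * nSteps, blowup = 1e6) {
  n <- nParcels(dynamics)
  X0 <- withr::with_seed(seed, {
    if (is.null(initData)) {
      matrix(stats::rnorm(nInit * n), nInit, n)
    } else {
      initData[sample.int(nrow(initData), nInit, replace = TRUE), ,
               drop = FALSE]
    }
  })
  ## phase 1: streaming integration, no storage
  res <- simulateMany(dynamics, X0, nSteps, eqTol, blowup)
  convIdx <- which(res$converged)
  openIdx <- which(!res$converged & !res$divergent)

  equil <- clusterEquilibria(res$terminal[convIdx, , drop = FALSE],
                             distThresh)

  ## phase 2: re-simulate unresolved trajectories with storage, in chunks,
  ## and look for limit-cycle recurrence (extending when needed)
  cycles <- list()
  unresolved <- 0L
  if (length(openIdx)) {
    chunk <- max(1L, floor(2e6 / (nSteps * n)))
    for (from in seq(1, length(openIdx), by = chunk)) {
      ids <- openIdx[from:min(from + chunk - 1L, length(openIdx))]
      sm <- simulateMany(dynamics, X0[ids, , drop = FALSE], nSteps, eqTol,
                         blowup, keepStates = TRUE, earlyStop = FALSE)
      for (j in seq_along(ids)) {
        if (sm$divergent[j]) next
        traj <- sm$states[, j, ]
        cyc <- detectLimitCycle(traj, dynamics, cycleRadius, maxExtend)
        if (is.null(cyc)) {
          ## prolongation may have revealed equilibrium convergence instead
          unresolved <- unresolved + 1L
          next
        }
        merged <- FALSE
        for (ci in seq_along(cycles)) {
          if (sameCycle(cycles[[ci]], cyc, cycleRadius)) {
            cycles[[ci]]$basinCount <- cycles[[ci]]$basinCount + 1L
            merged <- TRUE
            break
          }
        }
        if (!merged) cycles[[length(cycles) + 1L]] <- cyc
      }
    }
  }

  ## a-posteriori verification of equilibria against the vector field
  for (i in seq_along(equil)) {
    equil[[i]]$residual <- max(abs(deltaState(dynamics, equil[[i]]$state)))
    if (equil[[i]]$residual >= 1e-5)
      warning("equilibrium ", i, " failed vector-field verification ",
              "(residual ", signif(equil[[i]]$residual, 3), ")")
  }

  ghosts <- list()
  if (length(cycles)) {
    single <- length(cycles) == 1L
    for (ci in seq_along(cycles)) {
      gs <- ghostPoints(cycles[[ci]], singleCycleLandscape = single)
      for (g in gs) {
        g$cycle <- ci
        ghosts[[length(ghosts) + 1L]] <- g
      }
    }
  }

  nFp <- length(equil)
  nLc <- length(cycles)
  nDiv <- sum(res$divergent)
  flags <- character(0)
  if (nDiv > nInit / 2) flags <- "numerical issues"
  originOnly <- nFp == 1L && nLc == 0L && isTRUE(equil[[1]]$atOrigin)
  new("MindyLandscape",
      equilibria = equil, cycles = cycles, ghosts = ghosts,
      nFp = as.integer(nFp), nLc = as.integer(nLc),
      label = sprintf("%dFP %dLC", nFp, nLc),
      counts = list(nInit = as.integer(nInit),
                    converged = length(convIdx),
                    cycling = if (length(cycles))
                      sum(vapply(cycles, `[[`, integer(1), "basinCount"))
                    else 0L,
                    unresolved = unresolved,
                    divergent = nDiv),
      originOnly = originOnly, flags = flags)
}

#' Attractor patterns of a landscape
#'
#' Stacks the anatomical patterns of a landscape's attractors (stable
#' equilibria and ghost attractors) as rows. Origin equilibria are excluded
#' by default: the zero pattern has no direction, so it carries no anatomical
#' similarity and cannot be unit-normalized for clustering.
#'
#' @param landscape A \linkS4class{MindyLandscape}.
#' @param include One of \code{"both"}, \code{"equilibria"},
#'   \code{"ghosts"}.
#' @param includeOrigin Keep origin equilibria (default FALSE).
#' @return Numeric matrix with one attractor pattern per row (possibly 0
#'   rows).
#' @export
attractorPatterns <- function(landscape,
                              include = c("both", "equilibria", "ghosts"),
                              includeOrigin = FALSE) {
  include <- match.arg(include)
  pats <- list()
  if (include != "ghosts") {
    for (e in landscape@equilibria)
      if (includeOrigin || !isTRUE(e$atOrigin))
        pats[[length(pats) + 1L]] <- e$state
  }
  if (include != "equilibria") {
    for (g in landscape@ghosts)
      pats[[length(pats) + 1L]] <- g$state
  }
  if (!length(pats)) {
    n <- if (length(landscape@equilibria))
      length(landscape@equilibria[[1]]$state) else 0L
    return(matrix(numeric(0), 0, n))
  }
  do.call(rbind, pats)
}
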