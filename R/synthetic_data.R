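## Synthetic ground truth: planted models with prescribed attractor
## landscapes, BOLD-like noisy observations, spectrum/covariance-matched
## stationary surrogates, stable-linear-system data, labelled attractor
## clouds, and a persons-by-sessions cohort.

## amplitude s at which w * psi(s) = d * s gives a nonzero fixed point:
## returns the self-excitation weight solving the 1-D fixed-point equation
selfWeightFor <- function(s, d = 0.2, alpha = 1, b = 20 / 3) {
  d * s / transferPsi(s, alpha, b)
}

## core construction; couplings: list(c = slaved coupling vector) optional
constructPlanted <- function(taxonomy, N, k, seed, attractorScale = 1.5,
                             d = 0.2, couplingSd = 0.15, tr = 0.72,
                             couplings = NULL, cycleGainBoost = 1.3,
                             cycleAngle = 1.2) {
  b <- 20 / 3
  withr::with_seed(seed, {
    W <- matrix(0, N, N)
    w <- selfWeightFor(attractorScale, d)
    R <- matrix(c(cos(cycleAngle), sin(cycleAngle),
                  -sin(cycleAngle), cos(cycleAngle)), 2, 2)
    drive <- integer(0)   # parcels whose psi output drives the slaved ones
    block <- integer(0)   # parcels reserved for normal-form blocks
    if (taxonomy == "1FP") {
      ## pure decay: globally attractive origin
    } else if (taxonomy == "2FP") {
      stopifnot(N >= 3)
      W[1, 1] <- w
      drive <- 1L
      block <- 1:2   # parcel 2 left as pure decay, mirroring the 1LC layout
    } else if (taxonomy == "4FP") {
      stopifnot(N >= 3)
      W[1, 1] <- w
      W[2, 2] <- w
      drive <- 1:2
      block <- 1:2
    } else if (taxonomy == "1LC") {
      stopifnot(N >= 3)
      W[1:2, 1:2] <- w * cycleGainBoost * R
      drive <- 1L
      block <- 1:2
    } else if (taxonomy == "2LC") {
      stopifnot(N >= 4)
      W[1, 1] <- w
      W[2:3, 2:3] <- w * cycleGainBoost * R
      drive <- 1L
      block <- 1:3
    } else {
      stop("unsupported planted taxonomy: ", taxonomy)
    }
    slaved <- setdiff(seq_len(N), block)
    if (length(drive) && length(slaved)) {
      cc <- couplings
      if (is.null(cc))
        cc <- matrix(stats::rnorm(length(slaved) * length(drive), 0,
                                  couplingSd),
                     length(slaved), length(drive))
      W[slaved, drive] <- cc
    }
    ## tiny low-rank component so the sparse+low-rank decomposition is
    ## exercised without disturbing the planted attractors
    kk <- min(k, N - 1L)
    W1 <- matrix(stats::rnorm(N * kk, 0, 1e-3 / sqrt(N)), N, kk)
    W2 <- matrix(stats::rnorm(N * kk, 0, 1e-3 / sqrt(N)), N, kk)
    mindyModel(W, W1, W2, curvature = 1, decay = d, shapeConstant = b,
               tr = tr,
               fitInfo = list(planted = taxonomy, seed = seed,
                              attractorScale = attractorScale))
  })
}

expectedLabel <- function(taxonomy) {
  switch(taxonomy,
         "1FP" = "1FP 0LC", "2FP" = "2FP 0LC", "4FP" = "4FP 0LC",
         "1LC" = "0FP 1LC", "2LC" = "0FP 2LC",
         stop("unsupported planted taxonomy: ", taxonomy))
}

#' Construct a model with a prescribed attractor landscape
#'
#' Embeds low-dimensional normal-form blocks into \eqn{N} dimensions:
#' bistability by strong self-excitation solved against the actual transfer
#' function (numerically inverting \eqn{w\,\psi(s) = d\,s} for the requested
#' attractor amplitude), limit cycles by a rotational 2x2 block whose gain
#' exceeds the decay, and distributed anatomical patterns by random coupling
#' from the block parcels into the remaining ("slaved") parcels. The
#' resulting landscape is verified by \code{\link{classifyLandscape}}; on a
#' verification failure the construction is regenerated with the next seed
#' (up to 10 tries).
#'
#' @param taxonomy One of \code{"1FP"}, \code{"2FP"}, \code{"4FP"},
#'   \code{"1LC"}, \code{"2LC"}.
#' @param N Number of parcels (\eqn{\ge 2}; cycles need \eqn{\ge 3}).
#' @param k Rank of the (tiny) low-rank component; default
#'   \code{max(1, round(0.36 N))}.
#' @param seed Integer seed.
#' @param attractorScale Amplitude of the planted block attractor (default
#'   1.5).
#' @param verify Run the classification check (default TRUE).
#' @return A \linkS4class{MindyModel} whose classified taxonomy equals the
#'   request; \code{fitInfo$planted} records it.
#' @export
makePlantedModel <- function(taxonomy, N, k = max(1L, round(0.36 * N)),
                             seed = 1L, attractorScale = 1.5,
                             verify = TRUE) {
  for (try in 0:9) {
    model <- constructPlanted(taxonomy, N, k, seed + try, attractorScale)
    if (!verify) return(model)
    ls <- classifyLandscape(model, nInit = 48L, nSteps = 1600L,
                            seed = seed + try)
    if (ls@label == expectedLabel(taxonomy)) return(model)
  }
  stop("could not construct a verified '", taxonomy, "' model in 10 tries")
}

#' Simulate a BOLD-like observation of a model
#'
#' Integrates the model with per-parcel white process noise (burn-in
#' discarded), optionally convolves each parcel with the canonical HRF,
#' adds i.i.d. measurement noise, and (optionally) z-scores each run. The
#' per-run mean and sd of the hidden neural series are recorded in
#' \code{meta$neuralScale} so planted ground-truth states can be mapped into
#' the standardized coordinates the fitting pipeline sees.
#'
#' @param model A \linkS4class{MindyModel}.
#' @param T Total number of frames across runs (\eqn{\ge 10}).
#' @param nRuns Number of equal-length runs (default 1).
#' @param processNoiseSd Process-noise sd per parcel per step (default 0.3).
#' @param measurementNoiseSd Measurement-noise sd (default 0.1).
#' @param hrf Convolve with \code{\link{canonicalHrf}} (default TRUE).
#' @param zscore Standardize each run (default TRUE); zero-variance columns
#'   are left unscaled.
#' @param burnIn Discarded initial steps per run (default 100).
#' @param seed Integer seed.
#' @return A \linkS4class{ParcelTimeseries} (runs split by
#'   \code{runBoundaries}).
#' @export
simulateObservation <- function(model, T, nRuns = 1L, processNoiseSd = 0.3,
                                measurementNoiseSd = 0.1, hrf = TRUE,
                                zscore = TRUE, burnIn = 100L, seed = 1L) {
  stopifnot(T >= 10, T %% nRuns == 0)
  n <- nParcels(model)
  perRun <- T %/% nRuns
  h <- canonicalHrf(model@tr)
  withr::with_seed(seed, {
    runs <- vector("list", nRuns)
    neuralScale <- vector("list", nRuns)
    for (r in seq_len(nRuns)) {
      traj <- simulateTrajectory(model, rep(0, n), burnIn + perRun - 1L,
                                 noiseSd = processNoiseSd)
      x <- traj[(burnIn + 1):(burnIn + perRun), , drop = FALSE]
      neuralScale[[r]] <- list(center = colMeans(x),
                               scale = apply(x, 2, stats::sd))
      y <- x
      if (hrf) {
        pad <- length(h) - 1L
        for (j in seq_len(n)) {
          f <- stats::filter(c(rep(0, pad), x[, j]), h, sides = 1)
          y[, j] <- as.numeric(f[(pad + 1):(pad + perRun)])
        }
      }
      if (measurementNoiseSd > 0)
        y <- y + matrix(stats::rnorm(length(y), 0, measurementNoiseSd),
                        nrow(y), ncol(y))
      if (zscore) {
        mu <- colMeans(y)
        sdv <- apply(y, 2, stats::sd)
        sdv[sdv == 0] <- 1
        y <- sweep(sweep(y, 2, mu), 2, sdv, "/")
      }
      runs[[r]] <- y
    }
    parcelTimeseries(do.call(rbind, runs), tr = model@tr,
                     runBoundaries = seq(1L, T, by = perRun),
                     meta = list(neuralScale = neuralScale,
                                 seed = seed,
                                 processNoiseSd = processNoiseSd,
                                 measurementNoiseSd = measurementNoiseSd,
                                 hrf = hrf))
  })
}

#' Map ground-truth states into observation coordinates
#'
#' Applies the per-parcel centering and scaling of the hidden neural series
#' recorded by \code{\link{simulateObservation}} (averaged over runs) to a
#' state vector or pattern matrix, so planted attractors can be compared
#' with attractors of models fitted on the standardized observation.
#'
#' @param x State vector or row-matrix of patterns in model coordinates.
#' @param ts The \linkS4class{ParcelTimeseries} returned by
#'   \code{\link{simulateObservation}}.
#' @return \code{x} mapped into standardized coordinates.
#' @export
mapToObservedScale <- function(x, ts) {
  ns <- ts@meta$neuralScale
  if (is.null(ns)) stop("ts carries no neuralScale metadata")
  ctr <- rowMeans(vapply(ns, `[[`, numeric(length(ns[[1]]$center)),
                         "center"))
  scl <- rowMeans(vapply(ns, `[[`, numeric(length(ns[[1]]$scale)),
                         "scale"))
  if (is.matrix(x))
    sweep(sweep(x, 2, ctr), 2, scl, "/")
  else (x - ctr) / scl
}

#' Stationary surrogate with matched spectrum and cross-covariance
#'
#' Multivariate phase randomization: within each run, a common random phase
#' per frequency is applied to every parcel's Fourier transform (DC and
#' Nyquist untouched). Each series' amplitude spectrum is preserved exactly
#' and, because all parcels share the same phases, so are the cross-spectra
#' and hence the circular cross-covariance structure — a stationary Gaussian
#' null with the covariance and spectral content of the input.
#'
#' @param ts A \linkS4class{ParcelTimeseries}.
#' @param seed Integer seed.
#' @return A surrogate \linkS4class{ParcelTimeseries}.
#' @export
stationarySurrogate <- function(ts, seed = 1L) {
  x <- ts@data
  withr::with_seed(seed, {
    for (r in seq_along(ts@runBoundaries)) {
      rows <- runRows(ts, r)
      T <- length(rows)
      nHalf <- floor((T - 1) / 2)
      phi <- numeric(T)
      if (nHalf >= 1) {
        ph <- stats::runif(nHalf, 0, 2 * pi)
        phi[2:(nHalf + 1)] <- ph
        phi[T:(T - nHalf + 1)] <- -ph
      }
      rot <- exp(1i * phi)
      for (j in seq_len(ncol(x))) {
        X <- stats::fft(x[rows, j])
        x[rows, j] <- Re(stats::fft(X * rot, inverse = TRUE)) / T
      }
    }
  })
  initialize(ts, data = x, meta = c(ts@meta, list(surrogateSeed = seed)))
}

#' Noisy simulation of a stable linear system
#'
#' \eqn{x_{n+1} = x_n + A x_n + \epsilon_n} with
#' \eqn{\epsilon_n \sim N(0, \mathrm{noiseSd}^2 I)}; requires the spectral
#' radius of \eqn{I + A} to be below 1. Output is z-scored per run.
#'
#' @param A Stable \eqn{N \times N} matrix.
#' @param T Total number of frames.
#' @param noiseSd Innovation sd (default 0.3).
#' @param nRuns Number of equal-length runs (default 1).
#' @param tr Sampling interval in seconds (default 0.72).
#' @param burnIn Discarded initial steps (default 100).
#' @param seed Integer seed.
#' @return A \linkS4class{ParcelTimeseries}.
#' @export
linearSystemTimeseries <- function(A, T, noiseSd = 0.3, nRuns = 1L,
                                   tr = 0.72, burnIn = 100L, seed = 1L) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), T %% nRuns == 0)
  rho <- max(Mod(eigen(diag(nrow(A)) + A, only.values = TRUE)$values))
  if (rho >= 1)
    stop("unstable system: spectral radius of I + A is ", signif(rho, 4))
  n <- nrow(A)
  perRun <- T %/% nRuns
  M <- diag(n) + A
  withr::with_seed(seed, {
    runs <- vector("list", nRuns)
    for (r in seq_len(nRuns)) {
      x <- numeric(n)
      out <- matrix(0, perRun, n)
      for (i in seq_len(burnIn + perRun)) {
        x <- drop(M %*% x) + stats::rnorm(n, 0, noiseSd)
        if (i > burnIn) out[i - burnIn, ] <- x
      }
      runs[[r]] <- scale(out)
    }
    parcelTimeseries(do.call(rbind, runs), tr = tr,
                     runBoundaries = seq(1L, T, by = perRun),
                     meta = list(seed = seed, linear = TRUE))
  })
}

#' Labelled cloud of attractor-like patterns
#'
#' Unit-norm cluster directions (random, or \eqn{\pm} pairs when
#' \code{antipodal}), each with \code{nPerCluster} members
#' direction + \eqn{N(0, \mathrm{withinSd}^2)} noise.
#'
#' @param KTrue Number of clusters (even when \code{antipodal}).
#' @param N Pattern dimension.
#' @param nPerCluster Members per cluster.
#' @param withinSd Within-cluster noise sd (default 0.05).
#' @param antipodal Generate directions in \eqn{\pm} pairs (default FALSE).
#' @param seed Integer seed.
#' @return List: \code{x} (pattern matrix), \code{labels} (integer per row),
#'   \code{directions} (\eqn{K \times N} unit rows).
#' @export
attractorCloud <- function(KTrue, N, nPerCluster, withinSd = 0.05,
                           antipodal = FALSE, seed = 1L) {
  stopifnot(KTrue >= 1, !antipodal || KTrue %% 2 == 0)
  withr::with_seed(seed, {
    if (antipodal) {
      half <- KTrue / 2
      dirs <- matrix(stats::rnorm(half * N), half, N)
      dirs <- unitRows(dirs)
      dirs <- rbind(dirs, -dirs)
    } else {
      dirs <- unitRows(matrix(stats::rnorm(KTrue * N), KTrue, N))
    }
    labels <- rep(seq_len(KTrue), each = nPerCluster)
    x <- dirs[labels, , drop = FALSE] +
      matrix(stats::rnorm(length(labels) * N, 0, withinSd),
             length(labels), N)
    list(x = x, labels = labels, directions = dirs)
  })
}

#' Generate a synthetic persons-by-sessions cohort of planted models
#'
#' Each person has a shared attractor geometry (their slaved-parcel coupling
#' pattern) and two session models. A configurable fraction of persons sit
#' near the bistable-to-cycle transition and switch taxonomy between
#' sessions ("2FP" in one, "1LC" in the other) while keeping the shared
#' geometry — the infinite-period mechanism linking sessions. Remaining
#' persons keep one taxonomy with the coupling pattern perturbed by
#' \code{sessionPerturbationSd} between sessions.
#'
#' @param nPersons Number of persons (\eqn{\ge 2}).
#' @param N Parcels per model (default 10).
#' @param sessionPerturbationSd Coupling perturbation between sessions
#'   (default 0.02; 0 makes the two session models identical for
#'   non-switching persons).
#' @param nearBifurcationFraction Fraction of persons switching taxonomy
#'   across sessions (default 0.5).
#' @param attractorScale Planted attractor amplitude (default 1.5).
#' @param seed Integer seed.
#' @param verify Verify each model's taxonomy (default FALSE; constructions
#'   are deterministic and verified in the generator's tests).
#' @return List: \code{models} (list of \linkS4class{MindyModel}s),
#'   \code{info} (data frame: \code{person}, \code{session},
#'   \code{taxonomy}).
#' @export
makeCohort <- function(nPersons, N = 10L, sessionPerturbationSd = 0.02,
                       nearBifurcationFraction = 0.5, attractorScale = 1.5,
                       seed = 1L, verify = FALSE) {
  stopifnot(nPersons >= 2)
  k <- max(1L, round(0.36 * N))
  nSwitch <- round(nearBifurcationFraction * nPersons)
  models <- list()
  person <- session <- taxonomy <- c()
  baseSeeds <- withr::with_seed(seed, sample.int(1e6, nPersons))
  for (p in seq_len(nPersons)) {
    sd0 <- baseSeeds[p]
    cc <- withr::with_seed(sd0, matrix(stats::rnorm(N - 2, 0, 0.15),
                                       N - 2, 1))
    switching <- p <= nSwitch
    baseTax <- if (withr::with_seed(sd0 + 1,
                                    stats::runif(1)) < 0.5) "2FP" else "1LC"
    for (s in 1:2) {
      ccS <- cc
      if (s == 2 && sessionPerturbationSd > 0)
        ccS <- cc + withr::with_seed(sd0 + 2,
                                     matrix(stats::rnorm(length(cc), 0,
                                            sessionPerturbationSd),
                                            nrow(cc), 1))
      tax <- if (switching) c("2FP", "1LC")[s] else baseTax
      m <- constructPlanted(tax, N, k, seed = sd0 + 10L,
                            attractorScale = attractorScale,
                            couplings = ccS)
      if (verify) {
        ls <- classifyLandscape(m, nInit = 48L, nSteps = 1600L,
                                seed = sd0 + s)
        if (ls@label != expectedLabel(tax))
          stop("cohort model (person ", p, ", session ", s,
               ") failed verification")
      }
      models[[length(models) + 1L]] <- m
      person <- c(person, p)
      session <- c(session, s)
      taxonomy <- c(taxonomy, tax)
    }
  }
  list(models = models,
       info = data.frame(person = person, session = session,
                         taxonomy = taxonomy))
}
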