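# Fixtures are built in code; nothing is read from disk.

# pure-decay model: globally attractive origin
decayModel <- function(n = 3, d = 0.2, k = 1) {
  mindyModel(diag(0, n), matrix(0, n, k), matrix(0, n, k),
             curvature = 1, decay = d)
}

# small random model (weights scaled to stay stable)
randomModel <- function(n = 4, k = 2, seed = 1, scale = 0.05) {
  withr::with_seed(seed, {
    mindyModel(matrix(rnorm(n * n, 0, scale), n, n),
               matrix(rnorm(n * k, 0, scale), n, k),
               matrix(rnorm(n * k, 0, scale), n, k),
               curvature = runif(n, 0.5, 2), decay = runif(n, 0.1, 0.3))
  })
}

# derivative samples directly from matrices
makeSamples <- function(X, Y, smoothed = TRUE) {
  new("DerivativeSamples", states = X, targets = Y,
      sampleIndex = seq_len(nrow(X)), smoothed = smoothed)
}

# samples generated by simulating a model with process noise and pairing
# states with the exact smoothed forward difference
modelSamples <- function(model, T = 1000, noiseSd = 0.05, seed = 1) {
  traj <- simulateTrajectory(model, rep(0, nParcels(model)), T,
                             noiseSd = noiseSd, seed = seed)
  ts <- parcelTimeseries(traj, tr = model@tr)
  buildTrainingPairs(ts, smooth = TRUE)
}

# transient-rich samples: many short noisy trajectories from dispersed
# starts, so the deterministic drift dominates the derivative targets
transientSamples <- function(model, nTraj = 120, len = 20, noiseSd = 0.05,
                             seed = 1, spread = 2) {
  n <- nParcels(model)
  states <- targets <- NULL
  withr::with_seed(seed, {
    for (i in seq_len(nTraj)) {
      traj <- simulateTrajectory(model, rnorm(n, 0, spread), len,
                                 noiseSd = noiseSd)
      m <- len - 1L
      states <- rbind(states, traj[seq_len(m), , drop = FALSE])
      targets <- rbind(targets,
                       (traj[seq_len(m) + 2L, , drop = FALSE] -
                          traj[seq_len(m), , drop = FALSE]) / 2)
    }
  })
  makeSamples(states, targets)
}

# random parameter list for loss/gradient tests
randomParams <- function(n = 3, k = 2, seed = 1) {
  withr::with_seed(seed, {
    list(Ws = matrix(rnorm(n * n), n, n), W1 = matrix(rnorm(n * k), n, k),
         W2 = matrix(rnorm(n * k), n, k), alpha = runif(n, 0.5, 2),
         D = rnorm(n), b = 20 / 3)
  })
}

# central finite-difference gradient of mindyLoss
fdGradients <- function(params, samp, cfg, eps = 1e-6) {
  out <- list()
  for (nm in c("Ws", "W1", "W2", "alpha", "D")) {
    fd <- params[[nm]] * 0
    for (i in seq_along(fd)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd[i] <- (mindyLoss(pp, samp, cfg) - mindyLoss(pm, samp, cfg)) /
        (2 * eps)
    }
    out[[nm]] <- fd
  }
  out
}

# all permutations of 1..k (exhaustive oracle for label matching)
allPerms <- function(k) {
  if (k == 1) return(list(1L))
  do.call(c, lapply(seq_len(k), function(i) {
    lapply(allPerms(k - 1L), function(p) {
      v <- seq_len(k)[-i]
      c(i, v[p])
    })
  }))
}

bruteMatchCost <- function(la, lb, K) {
  min(vapply(allPerms(K), function(p) mean(p[la] != lb), numeric(1)))
}
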