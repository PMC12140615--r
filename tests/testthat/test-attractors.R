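# a stored planar rotation trajectory on a circle (oracle for cycle detection)
rotationTrajectory <- function(radius = 2, dTheta = 0.1, n = 1600,
                               theta0 = 0) {
  th <- theta0 + dTheta * (0:n)
  cbind(radius * cos(th), radius * sin(th))
}

test_that("equilibrium detection enforces the strict last-10-steps rule", {
  m <- decayModel(3)
  traj <- simulateTrajectory(m, c(1, -1, 2), 200)
  term <- detectEquilibrium(traj)
  expect_false(is.null(term))
  expect_lt(max(abs(term)), 1e-8)

  # constant drift of exactly the tolerance does not converge (strict <)
  drift <- matrix(1e-6 * (0:30), 31, 1)
  expect_null(detectEquilibrium(drift))
  slower <- matrix(0.99e-6 * (0:30), 31, 1)
  expect_false(is.null(detectEquilibrium(slower)))

  # a fast cycle never converges
  expect_null(detectEquilibrium(rotationTrajectory()))

  expect_error(detectEquilibrium(matrix(0, 5, 2)), "11")
})

test_that("greedy terminal clustering follows the founder-distance rule", {
  same <- clusterEquilibria(matrix(1, 5, 2), distThresh = 0.1)
  expect_length(same, 1)
  expect_equal(same[[1]]$basinCount, 5L)

  two <- clusterEquilibria(rbind(c(0, 0), c(1, 0), c(0.01, 0), c(1.02, 0)))
  expect_length(two, 2)

  # chain 0, 0.09, 0.18: the third is 0.18 from the founder -> new cluster
  chain <- clusterEquilibria(matrix(c(0, 0.09, 0.18), 3, 1))
  expect_length(chain, 2)
  expect_equal(chain[[1]]$basinCount, 2L)
  expect_true(chain[[1]]$atOrigin)
  expect_false(sqrt(sum(chain[[2]]$state^2)) < 0.1)
})

test_that("limit-cycle detection recovers a constructed rotation and its period", {
  traj <- rotationTrajectory(radius = 2, dTheta = 0.1)
  cyc <- detectLimitCycle(traj)
  expect_false(is.null(cyc))
  expect_equal(cyc$period, round(2 * pi / 0.1), tolerance = 0.03)
  # one period: first and last samples at the same phase
  expect_lt(sqrt(sum((cyc$samples[1, ] - cyc$samples[nrow(cyc$samples), ])^2)),
            0.5)
  # constant speed circle
  expect_equal(speedRatio(cyc), 1, tolerance = 1e-6)

  # decaying spiral converges to the origin: no cycle
  m <- decayModel(2)
  expect_null(detectLimitCycle(simulateTrajectory(m, c(2, 0), 200)))

  # still in transit, no dynamics to extend with -> absent
  part <- rotationTrajectory(dTheta = 0.002, n = 500)
  expect_null(detectLimitCycle(part))
})

test_that("ghost extraction picks the slowest point with lowest-index ties", {
  cyc <- list(samples = rotationTrajectory(n = 63)[1:64, ],
              period = 63,
              speeds = rep(0.2, 63))
  g <- ghostPoints(cyc)
  expect_length(g, 1)
  expect_equal(g[[1]]$cycleIndex, 1L)      # tie -> lowest index

  cyc$speeds <- c(1, 1, 0.01, rep(1, 60))
  g2 <- ghostPoints(cyc)
  expect_equal(g2[[1]]$cycleIndex, 3L)
  expect_equal(g2[[1]]$state, cyc$samples[3, ])

  # single-cycle landscape: symmetric pair
  g3 <- ghostPoints(cyc, singleCycleLandscape = TRUE)
  expect_length(g3, 2)
  expect_equal(g3[[2]]$state, -g3[[1]]$state)
})

test_that("speed ratio has its closed-form values", {
  expect_equal(speedRatio(list(speeds = c(2, 0.5))), 4)
  expect_equal(speedRatio(list(speeds = rep(1.3, 10))), 1)
  expect_equal(speedRatio(list(speeds = c(1, 0))), Inf)
})

test_that("landscape classification identifies planted landscapes", {
  # pure decay -> single equilibrium at the origin
  ls <- classifyLandscape(decayModel(4), nInit = 30, nSteps = 400, seed = 1)
  expect_equal(taxonomyLabel(ls), "1FP 0LC")
  expect_true(ls@originOnly)
  expect_true(equilibria(ls)[[1]]$atOrigin)

  # planted bistable -> two equilibria forming a +- pair
  m2 <- makePlantedModel("2FP", N = 8, seed = 3, verify = FALSE)
  ls2 <- classifyLandscape(m2, nInit = 60, nSteps = 1600, seed = 2)
  expect_equal(taxonomyLabel(ls2), "2FP 0LC")
  eq <- equilibria(ls2)
  expect_equal(eq[[1]]$state, -eq[[2]]$state, tolerance = 1e-4)
  # every reported equilibrium verified against the vector field
  for (e in eq) expect_lt(e$residual, 1e-5)

  # toy SNIC above the bifurcation -> one stable limit cycle
  ls3 <- classifyLandscape(toySnic(2), nInit = 60, nSteps = 1600, seed = 3)
  expect_equal(taxonomyLabel(ls3), "0FP 1LC")
  expect_length(ghostAttractors(ls3), 2)   # symmetric pair on a single cycle
})

test_that("cycle period is stable under doubling the integration length", {
  m <- makePlantedModel("1LC", N = 6, seed = 4, verify = FALSE)
  ls1 <- classifyLandscape(m, nInit = 20, nSteps = 1600, seed = 5)
  ls2 <- classifyLandscape(m, nInit = 20, nSteps = 3200, seed = 5)
  expect_equal(taxonomyLabel(ls1), "0FP 1LC")
  expect_equal(taxonomyLabel(ls2), "0FP 1LC")
  expect_lte(abs(limitCycles(ls1)[[1]]$period -
                 limitCycles(ls2)[[1]]$period), 1)
})

test_that("attractor set is closed under negation with sign-balanced starts", {
  m <- makePlantedModel("4FP", N = 7, seed = 6, verify = FALSE)
  withr::with_seed(7, X0 <- matrix(rnorm(40 * 7), 40, 7))
  X0 <- rbind(X0, -X0)
  res <- mindyscapes:::simulateMany(m, X0, 1600)
  eq <- clusterEquilibria(res$terminal[res$converged, , drop = FALSE])
  states <- t(vapply(eq, `[[`, numeric(7), "state"))
  for (i in seq_len(nrow(states))) {
    dists <- sqrt(rowSums((states - rep(-states[i, ],
                                        each = nrow(states)))^2))
    expect_lt(min(dists), 0.1)
  }
})

test_that("equilibrium count is invariant to trajectory order for separated attractors", {
  m <- makePlantedModel("4FP", N = 7, seed = 6, verify = FALSE)
  withr::with_seed(8, X0 <- matrix(rnorm(30 * 7, 0, 2), 30, 7))
  res <- mindyscapes:::simulateMany(m, X0, 1600)
  terms <- res$terminal[res$converged, , drop = FALSE]
  n1 <- length(clusterEquilibria(terms))
  withr::with_seed(9, {
    for (r in 1:5) {
      perm <- sample.int(nrow(terms))
      expect_equal(length(clusterEquilibria(terms[perm, , drop = FALSE])),
                   n1)
    }
  })
})

test_that("divergent models are flagged as numerical issues", {
  unstable <- mindyModel(diag(2, 3), matrix(0, 3, 1), matrix(0, 3, 1),
                         decay = rep(-1, 3))
  ls <- suppressWarnings(
    classifyLandscape(unstable, nInit = 20, nSteps = 300, seed = 10,
                      blowup = 1e3))
  expect_true("numerical issues" %in% ls@flags)
  expect_gt(ls@counts$divergent, 10)
})
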