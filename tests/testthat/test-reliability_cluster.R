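test_that("pattern correlation and DAS follow their definitions", {
  withr::with_seed(1, p <- rnorm(20))
  expect_equal(patternCorrelation(p, p), 1)
  expect_equal(patternCorrelation(p, -p), -1)
  expect_equal(patternCorrelation(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_error(patternCorrelation(rep(1, 5), 1:5), "variance")

  expect_equal(das(p, p), 1)
  expect_equal(das(matrix(p, 1), matrix(-p, 1)), -1)
  # with +- pairs on both sides, the maximum is 1
  expect_equal(das(rbind(p, -p), rbind(p, -p)), 1)

  # brute force over all 6 cross pairs
  withr::with_seed(2, {
    A <- matrix(rnorm(3 * 10), 3, 10)
    B <- matrix(rnorm(2 * 10), 2, 10)
  })
  expect_equal(das(A, B), max(outer(1:3, 1:2, Vectorize(function(i, j)
    cor(A[i, ], B[j, ])))))
  # symmetry
  expect_equal(das(A, B), das(B, A))

  expect_error(das(matrix(numeric(0), 0, 10), B), "no")
})

test_that("the cross-session DAS table counts pairs and separates persons", {
  mkLs <- function(pattern, label = "2FP 0LC") {
    new("MindyLandscape",
        equilibria = list(list(state = pattern, basinCount = 1L,
                               atOrigin = FALSE),
                          list(state = -pattern, basinCount = 1L,
                               atOrigin = FALSE)),
        cycles = list(), ghosts = list(), nFp = 2L, nLc = 0L,
        label = label,
        counts = list(nInit = 1L, converged = 1L, cycling = 0L,
                      unresolved = 0L, divergent = 0L),
        originOnly = FALSE, flags = character(0))
  }
  withr::with_seed(3, {
    pA <- rnorm(15); pB <- rnorm(15)
  })
  # 2 persons x 2 sessions; person A's pattern reproducible across sessions
  lss <- list(mkLs(pA), mkLs(pA + rnorm(15, 0, 0.05)),
              mkLs(pB), mkLs(pB + rnorm(15, 0, 0.05)))
  tab <- dasGroupTable(lss, personOf = c("a", "a", "b", "b"),
                       sessionOf = c(1, 2, 1, 2))
  expect_equal(nrow(tab), 4)            # cross-session pairs only
  expect_equal(sum(tab$samePerson), 2)
  expect_true(all(tab$sameType))
  expect_gt(min(tab$das[tab$samePerson]), 0.99)
  expect_gt(median(tab$das[tab$samePerson]),
            median(tab$das[!tab$samePerson]))
})

test_that("cosine K-means separates antipodal bundles and ignores scale", {
  cl <- attractorCloud(2, 12, 20, withinSd = 0.03, antipodal = TRUE,
                       seed = 4)
  km <- cosineKmeans(cl$x, 2, seed = 5)
  expect_equal(km$K, 2)
  expect_lt(km$withinDist / nrow(cl$x), 0.01)
  expect_equal(length(unique(km$assignments[cl$labels == 1])), 1)
  expect_equal(length(unique(km$assignments[cl$labels == 2])), 1)
  expect_equal(sqrt(rowSums(km$centroids^2)), rep(1, 2))

  # scaling rows never changes assignments
  x2 <- cl$x * withr::with_seed(6, runif(nrow(cl$x), 0.1, 10))
  km2 <- cosineKmeans(x2, 2, seed = 5)
  expect_equal(km2$assignments, km$assignments)

  # K = 1 centroid is the normalized mean direction
  km1 <- cosineKmeans(cl$x[1:20, ], 1, seed = 7)
  mu <- colMeans(cl$x[1:20, ] / sqrt(rowSums(cl$x[1:20, ]^2)))
  expect_equal(as.numeric(km1$centroids), mu / sqrt(sum(mu^2)),
               tolerance = 1e-10)

  # determinism
  expect_equal(cosineKmeans(cl$x, 2, seed = 5)$assignments,
               km$assignments)
})

test_that("label matching cost equals the exhaustive-permutation minimum", {
  expect_equal(hungarianCost(c(1, 2, 1), c(1, 2, 1), 2), 0)
  expect_equal(hungarianCost(c(1, 2, 1), c(2, 1, 2), 2), 0)  # pure relabel

  withr::with_seed(8, {
    for (K in 2:5) {
      for (rep in 1:3) {
        la <- sample.int(K, 12, replace = TRUE)
        lb <- sample.int(K, 12, replace = TRUE)
        expect_equal(hungarianCost(la, lb, K), bruteMatchCost(la, lb, K))
      }
    }
  })
})

test_that("instability selects the planted number of clusters", {
  cl <- attractorCloud(4, 20, 30, withinSd = 0.05, seed = 9)
  sel <- selectK(cl$x, kCandidates = 2:6, nSplits = 15, seed = 10,
                 nRestarts = 10)
  expect_equal(sel$K, 4)
  expect_lt(sel$curve["4"], sel$curve["3"])
  expect_lt(sel$curve["4"], sel$curve["5"])
  expect_lt(sel$curve["4"], 0.1)

  # exact copies: instability essentially zero at K_true
  cl0 <- attractorCloud(3, 10, 15, withinSd = 0, seed = 11)
  expect_lt(instabilityIndex(cl0$x +
                               withr::with_seed(12,
                                 matrix(rnorm(45 * 10, 0, 1e-6), 45, 10)),
                             3, nSplits = 10, seed = 13, nRestarts = 10),
            0.05)

  # structureless noise: near 1 for any K (null normalization)
  withr::with_seed(14, noise <- matrix(rnorm(120 * 10), 120, 10))
  for (K in c(3, 5))
    expect_gt(instabilityIndex(noise, K, nSplits = 10, seed = 15,
                               nRestarts = 5), 0.5)

  # antipodal two-bundle data selects the trivial +- solution and flags it
  cl2 <- attractorCloud(2, 15, 25, withinSd = 0.05, antipodal = TRUE,
                        seed = 16)
  sel2 <- suppressWarnings(selectK(cl2$x, kCandidates = 2:5,
                                   nSplits = 10, seed = 17,
                                   nRestarts = 10))
  expect_equal(sel2$K, 2)
  expect_true(sel2$k2Antipodal)
})

test_that("instability is invariant to attractor scaling", {
  cl <- attractorCloud(3, 12, 20, withinSd = 0.05, seed = 18)
  i1 <- instabilityIndex(cl$x, 3, nSplits = 8, seed = 19, nRestarts = 8)
  i2 <- instabilityIndex(cl$x * 7.3, 3, nSplits = 8, seed = 19,
                         nRestarts = 8)
  expect_equal(i1, i2)
})

test_that("variance decomposition matches its closed-form anchors", {
  cl <- attractorCloud(4, 20, 25, withinSd = 0.08, seed = 20)
  nw <- rep(1:4, each = 5)

  # attractors equal to their cell means -> fraction 1
  fit <- cl$x * 0
  for (a in 1:4) for (b in 1:4)
    fit[cl$labels == a, nw == b] <- mean(cl$x[cl$labels == a, nw == b])
  expect_equal(varianceDecomposition(fit, cl$labels, nw), 1)

  # pure noise -> fraction near #cells / (n N)
  withr::with_seed(21, noise <- matrix(rnorm(400 * 20), 400, 20))
  frac <- varianceDecomposition(noise, sample(4, 400, replace = TRUE), nw)
  expect_lt(frac, 0.01)

  # planted signal with noise: fraction ~ signal / (signal + sigma^2)
  sigma <- 0.3
  base <- matrix(0, 4, 4)
  withr::with_seed(22, base[] <- rnorm(16))
  signal <- base[cl$labels, nw]
  withr::with_seed(23, {
    x <- signal + matrix(rnorm(length(signal), 0, sigma),
                         nrow(signal), ncol(signal))
  })
  expected <- var(as.numeric(signal)) /
    (var(as.numeric(signal)) + sigma^2)
  expect_equal(varianceDecomposition(x, cl$labels, nw), expected,
               tolerance = 0.05)
})
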