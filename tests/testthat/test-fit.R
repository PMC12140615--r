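test_that("loss matches hand-computed penalty sums and zero cases", {
  cfg <- fitConfig()
  zero <- makeSamples(matrix(0, 4, 3), matrix(0, 4, 3))
  pz <- list(Ws = diag(0, 3), W1 = matrix(0, 3, 1), W2 = matrix(0, 3, 1),
             alpha = rep(1, 3), D = rep(0, 3), b = 20 / 3)
  expect_equal(mindyLoss(pz, zero, cfg), 0)

  # zero data term, W_S = identity: J = 3*lambda1 + 3*lambda2 = 0.825
  pid <- pz
  pid$Ws <- diag(1, 3)
  expect_equal(mindyLoss(pid, zero, cfg), 3 * 0.075 + 3 * 0.2)
  expect_equal(mindyLoss(pid, zero, cfg), 0.825)

  bad <- pz
  bad$Ws[1, 1] <- NaN
  expect_error(mindyLoss(bad, zero, cfg), "non-finite")
})

test_that("analytic gradients match central finite differences", {
  cfg <- fitConfig()
  withr::with_seed(12, {
    samp <- makeSamples(matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3))
  })
  params <- randomParams(3, 2, seed = 13)
  g <- mindyGradients(params, samp, cfg)
  fd <- fdGradients(params, samp, cfg)
  for (nm in names(fd)) {
    relerr <- max(abs(fd[[nm]] - g[[nm]])) / max(abs(fd[[nm]]))
    expect_lt(relerr, 1e-5)
  }

  # data-term gradient w.r.t. D on one sample: -(residual * x)
  cfg0 <- fitConfig(lambda1 = 0, lambda2 = 0, lambda3 = 0)
  one <- makeSamples(matrix(c(0.5, -0.2), 1, 2), matrix(c(0.1, 0.3), 1, 2))
  p2 <- randomParams(2, 1, seed = 14)
  pred <- transferPsi(one@states, p2$alpha, p2$b) %*%
    t(p2$Ws + p2$W1 %*% t(p2$W2)) - one@states * rep(p2$D, each = 1)
  resid <- as.numeric(pred - one@targets)
  expect_equal(mindyGradients(p2, one, cfg0)$D,
               -resid * as.numeric(one@states))
})

test_that("NADAM is stationary at zero gradient, descends, and solves a quadratic", {
  cfg <- fitConfig(learningRate = 0.05)
  params <- randomParams(2, 1, seed = 15)
  zeroG <- lapply(params[c("Ws", "W1", "W2", "alpha", "D")],
                  function(p) p * 0)
  st <- list(m = zeroG, v = zeroG, t = 0L)
  res <- mindyscapes:::nadamStep(st, params, zeroG, cfg)
  for (nm in names(zeroG)) expect_equal(res$params[[nm]], params[[nm]])

  # first step moves opposite the gradient sign
  g1 <- lapply(zeroG, function(p) p + 1)
  res1 <- mindyscapes:::nadamStep(st, params, g1, cfg)
  for (nm in names(g1))
    expect_true(all(res1$params[[nm]] < params[[nm]]))

  # 1-D quadratic (theta - 3)^2 / 2 via the D slot
  p1 <- list(D = 0)
  st1 <- list(m = list(D = 0), v = list(D = 0), t = 0L)
  for (i in 1:3000) {
    r <- mindyscapes:::nadamStep(st1, p1, list(D = p1$D - 3), cfg)
    p1 <- r$params; st1 <- r$state
  }
  expect_equal(p1$D, 3, tolerance = 1e-6)
})

test_that("fitting recovers a planted model's derivative structure", {
  m <- makePlantedModel("2FP", N = 10, seed = 21, verify = FALSE)
  samp <- transientSamples(m, nTraj = 120, len = 20, noiseSd = 0.05,
                           seed = 22)
  M <- nrow(samp@states)
  hold <- seq(1, M, by = 5)
  train <- makeSamples(samp@states[-hold, ], samp@targets[-hold, ])
  test <- makeSamples(samp@states[hold, ], samp@targets[hold, ])
  fit <- fitMindy(train, fitConfig(nBatches = 1500, seed = 23))
  expect_gt(r2Derivatives(fit, test), 0.8)

  # fitted connectivity correlates with the planted one
  expect_gt(cor(as.numeric(connWeights(fit)), as.numeric(connWeights(m))),
            0.7)
})

test_that("fitting is bit-deterministic given the seed", {
  m <- decayModel(5)
  samp <- modelSamples(m, T = 600, noiseSd = 0.3, seed = 31)
  f1 <- fitMindy(samp, fitConfig(nBatches = 200, seed = 7))
  f2 <- fitMindy(samp, fitConfig(nBatches = 200, seed = 7))
  expect_identical(connWeights(f1), connWeights(f2))
  expect_identical(curvature(f1), curvature(f2))
  expect_identical(decayRates(f1), decayRates(f2))
  f3 <- fitMindy(samp, fitConfig(nBatches = 200, seed = 8))
  expect_false(identical(connWeights(f1), connWeights(f3)))
})

test_that("global rescaling solves the two-parameter least squares exactly", {
  m <- randomModel(5, 2, seed = 41, scale = 0.2)
  samp <- modelSamples(m, T = 800, noiseSd = 0.1, seed = 42)

  # generic least-squares oracle on the two regressors
  A <- as.numeric(transferPsi(samp@states, curvature(m), m@shapeConstant) %*%
                    t(connWeights(m)))
  B <- as.numeric(samp@states * rep(decayRates(m), each = nrow(samp@states)))
  Y <- as.numeric(samp@targets)
  ora <- coef(lm(Y ~ 0 + A + B))

  r <- globalRescale(m, samp)
  expect_equal(unname(r@fitInfo$rescale["pW"]), unname(ora["A"]),
               tolerance = 1e-8)
  expect_equal(unname(r@fitInfo$rescale["pD"]), unname(-ora["B"]),
               tolerance = 1e-8)

  # rescaled model reproduces pW * W and pD * D
  expect_equal(connWeights(r),
               unname(ora["A"]) * connWeights(m), tolerance = 1e-8)

  # a model with W halved beforehand gets pW ~ 2
  half <- initialize(m, sparseWeights = m@sparseWeights / 2,
                     lowrankLeft = m@lowrankLeft / sqrt(2),
                     lowrankRight = m@lowrankRight / sqrt(2))
  r2 <- globalRescale(half, samp)
  expect_equal(unname(r2@fitInfo$rescale["pW"]), 2 * unname(ora["A"]),
               tolerance = 1e-6)

  # an already optimally scaled model keeps scales at 1
  r3 <- globalRescale(r, samp)
  expect_equal(unname(r3@fitInfo$rescale), c(1, 1), tolerance = 1e-6)
})

test_that("derivative R-squared has its fixed points and rejects empty variance", {
  m <- randomModel(3, 1, seed = 51)
  samp <- modelSamples(m, T = 300, noiseSd = 0.1, seed = 52)
  perfect <- makeSamples(samp@states,
                         deltaState(m, samp@states))
  expect_equal(r2Derivatives(m, perfect), 1)

  zeroModel <- decayModel(3, d = 0)
  centered <- makeSamples(samp@states,
                          scale(samp@targets, scale = FALSE))
  expect_equal(r2Derivatives(zeroModel, centered), 0, tolerance = 1e-12)

  expect_error(r2Derivatives(m, makeSamples(samp@states,
                                            samp@targets * 0)),
               "variance")
})
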