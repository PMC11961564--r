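test_that("Wald ratio handles direct ratios, nulls and sign flips", {
  r <- mrWaldRatio(0.2, 0.01, 0.1, 0.02)
  expect_equal(mrBeta(r), 0.5)
  expect_equal(mrSE(r), 0.1)
  expect_equal(oddsRatio(r), exp(0.5))

  expect_equal(mrPval(mrWaldRatio(0.2, 0.01, 0, 0.02)), 1.0)
  # joint sign flip leaves the ratio unchanged
  expect_equal(mrBeta(mrWaldRatio(-0.2, 0.01, -0.1, 0.02)), 0.5)
  expect_error(mrWaldRatio(0, 0.01, 0.1, 0.02), "null instrument")
  # second-order SE adds the exposure term
  r2 <- mrWaldRatio(0.2, 0.01, 0.1, 0.02, secondOrder = TRUE)
  expect_equal(mrSE(r2), sqrt(0.02^2 / 0.04 + 0.01 * 1e-4 / 0.0016))
})

test_that("IVW reproduces the closed-form oracle and floors the scale", {
  # degenerate consensus: all ratios equal -> beta equals the ratio
  h <- makeHarmonized(c(0.1, 0.2, 0.3), c(0.05, 0.10, 0.15),
                      seo = c(0.01, 0.01, 0.01))
  r <- mrIVW(h)
  expect_equal(mrBeta(r), 0.5)
  # zero residuals: sigma floored at 1 -> fixed-effect SE sqrt(1/1400)
  expect_equal(mrSE(r), sqrt(1 / 1400))
  expect_error(mrIVW(makeHarmonized(0.1, 0.05, 0.01)), "mrWaldRatio")
})

test_that("IVW and Egger agree with a generic weighted-least-squares fit", {
  set.seed(31)
  for (i in 1:200) {
    m <- sample(3:30, 1)
    bx <- rnorm(m, 0, 0.1)
    by <- 0.3 * bx + rnorm(m, 0, 0.05)
    seo <- runif(m, 0.01, 0.1)
    h <- makeHarmonized(bx, by, seo)
    fit <- lm(by ~ 0 + bx, weights = 1 / seo^2)
    expect_equal(mrBeta(mrIVW(h)), unname(coef(fit)), tolerance = 1e-10)

    # Egger on rows oriented to non-negative exposure effects
    sgn <- ifelse(bx < 0, -1, 1)
    efit <- lm(I(sgn * by) ~ I(sgn * bx), weights = 1 / seo^2)
    eg <- mrEgger(h)
    expect_equal(eg@intercept, unname(coef(efit)[1]), tolerance = 1e-10)
    expect_equal(mrBeta(eg), unname(coef(efit)[2]), tolerance = 1e-10)
  }
})

test_that("Egger interpolates noiseless pleiotropic data exactly", {
  bx <- c(0.05, 0.1, 0.2, 0.4)
  h <- makeHarmonized(bx, 0.02 + 0.4 * bx, seo = rep(0.01, 4))
  eg <- mrEgger(h)
  expect_equal(eg@intercept, 0.02, tolerance = 1e-12)
  expect_equal(mrBeta(eg), 0.4, tolerance = 1e-12)
  # homogeneous ratios through the origin: Egger slope equals IVW
  h0 <- makeHarmonized(c(0.1, 0.2, 0.4), 0.5 * c(0.1, 0.2, 0.4),
                       seo = rep(0.01, 3))
  expect_equal(mrBeta(mrEgger(h0)), mrBeta(mrIVW(h0)), tolerance = 1e-10)
  expect_error(mrEgger(makeHarmonized(1:2 / 10, 1:2 / 20, c(0.01, 0.01))),
               ">= 3")
})

test_that("weighted median matches the brute-force interpolation oracle", {
  # symmetric equal-weight case
  h <- makeHarmonized(c(1, 1, 1), c(1, 2, 3), seo = c(1, 1, 1))
  expect_equal(mrBeta(mrWeightedMedian(h, nBoot = 0L)), 2)

  # dominant weight pins the estimate
  h2 <- makeHarmonized(bx = c(1, 3, 1), by = c(0.3, 3 * 0.7, 1.2),
                       seo = c(sqrt(1 / 0.05), sqrt(9 / 0.9),
                               sqrt(1 / 0.05)))
  expect_equal(mrBeta(mrWeightedMedian(h2, nBoot = 0L)), 0.7)

  set.seed(17)
  for (i in 1:100) {
    m <- sample(3:25, 1)
    bx <- rnorm(m, 0, 0.1)
    bx[abs(bx) < 1e-3] <- 0.05
    by <- 0.2 * bx + rnorm(m, 0, 0.03)
    seo <- runif(m, 0.01, 0.1)
    h <- makeHarmonized(bx, by, seo)
    expect_equal(mrBeta(mrWeightedMedian(h, nBoot = 0L)),
                 weightedMedianOracle(by / bx, bx^2 / seo^2),
                 tolerance = 1e-12)
  }
})

test_that("weighted mode finds the modal ratio cluster", {
  h <- makeHarmonized(rep(1, 4), rep(0.4, 4), seo = rep(0.1, 4))
  r <- mrWeightedMode(h, nBoot = 0L)
  expect_equal(mrBeta(r), 0.4)  # degenerate bandwidth: the common ratio

  set.seed(5)
  bx <- rep(1, 10)
  by <- c(0.5 + rnorm(7, 0, 0.01), 5 + rnorm(3, 0, 0.01))
  h2 <- makeHarmonized(bx, by, seo = rep(0.1, 10))
  expect_lt(abs(mrBeta(mrWeightedMode(h2, nBoot = 0L)) - 0.5), 0.05)

  # grid refinement: doubling the grid moves the estimate < half a step
  rw <- list(ratio = by / bx, w = bx^2 / 0.01)
  est1 <- mrmediate:::.weightedModeEst(rw$ratio, rw$w, 1, nGrid = 2001L)
  est2 <- mrmediate:::.weightedModeEst(rw$ratio, rw$w, 1, nGrid = 4001L)
  bw <- mrmediate:::.silvermanBandwidth(rw$ratio, 1)
  step <- (diff(range(rw$ratio)) + 6 * bw) / 2000
  expect_lt(abs(est1 - est2), step / 2 + 1e-12)
})

test_that("bootstrap SEs are reproducible under a fixed seed", {
  sim <- simulatePair(simConfig(mSnps = 20L, theta = 0.2), seed = 4)
  h <- harmonizedFromPair(sim$exposure, sim$outcome)
  a <- mrWeightedMedian(h, nBoot = 200L, seed = 9L)
  b <- mrWeightedMedian(h, nBoot = 200L, seed = 9L)
  expect_identical(mrSE(a), mrSE(b))
  expect_error(mrWeightedMedian(h, nBoot = 200L), "seed")
  expect_gt(mrSE(a), 0)
})

test_that("estimators are scale-equivariant and orientation-invariant", {
  sim <- simulatePair(simConfig(mSnps = 15L, theta = 0.3,
                                pleioFrac = 0.2, pleioMean = 0.03),
                      seed = 21)
  h <- harmonizedFromPair(sim$exposure, sim$outcome)
  c0 <- 2.5
  hs <- h
  hs@rows$beta_out <- h@rows$beta_out * c0
  hs@rows$se_out <- h@rows$se_out * c0
  for (fn in list(mrIVW, mrEgger,
                  function(x) mrWeightedMedian(x, nBoot = 100L, seed = 2L),
                  function(x) mrWeightedMode(x, nBoot = 100L, seed = 2L))) {
    expect_equal(mrBeta(fn(hs)), c0 * mrBeta(fn(h)), tolerance = 1e-9)
    expect_equal(mrSE(fn(hs)), c0 * mrSE(fn(h)), tolerance = 1e-9)
  }
  # flipping the orientation of some rows changes nothing
  hf <- h
  flip <- c(1, 4, 7)
  hf@rows$beta_exp[flip] <- -hf@rows$beta_exp[flip]
  hf@rows$beta_out[flip] <- -hf@rows$beta_out[flip]
  for (fn in list(mrIVW, mrEgger,
                  function(x) mrWeightedMedian(x, nBoot = 0L),
                  function(x) mrWeightedMode(x, nBoot = 0L)))
    expect_equal(mrBeta(fn(hf)), mrBeta(fn(h)), tolerance = 1e-12)
})

test_that("the estimator battery dispatches on instrument count", {
  one <- makeHarmonized(0.2, 0.1, 0.02)
  r1 <- mrAllMethods(one, seed = 1L)
  expect_named(r1, "wald_ratio")

  two <- makeHarmonized(c(0.1, 0.2), c(0.05, 0.1), c(0.01, 0.01))
  expect_named(mrAllMethods(two, seed = 1L), "ivw")

  sim <- simulatePair(simConfig(mSnps = 5L, theta = 0.3), seed = 3)
  r4 <- mrAllMethods(harmonizedFromPair(sim$exposure, sim$outcome),
                     seed = 1L, nBoot = 100L)
  expect_setequal(names(r4),
                  c("ivw", "egger", "weighted_median", "weighted_mode"))
  expect_true(attr(r4, "direction_consistent"))
  tab <- mrResultsTable(r4, "X", "Y")
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$or, exp(tab$beta))
})
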