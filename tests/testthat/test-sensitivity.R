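test_that("Cochran's Q matches hand arithmetic and degenerate cases", {
  # perfectly homogeneous ratios
  h0 <- makeHarmonized(c(0.1, 0.2, 0.4), 0.5 * c(0.1, 0.2, 0.4),
                       seo = c(0.01, 0.02, 0.04))
  q0 <- cochranQ(h0)
  expect_equal(q0@q, 0, tolerance = 1e-20)
  expect_equal(q0@pval, 1)

  # two ratios 0.2 and 0.6 with ratio SE 0.1 each: Q = 8, df = 1
  h1 <- makeHarmonized(c(1, 1), c(0.2, 0.6), seo = c(0.1, 0.1))
  q1 <- cochranQ(h1)
  expect_equal(q1@q, 8)
  expect_equal(q1@df, 1L)
  expect_error(cochranQ(makeHarmonized(1, 1, 1)), ">= 2")
})

test_that("Q equals the fixed-effect meta-analysis heterogeneity statistic", {
  skip_if_not_installed("metafor")
  set.seed(13)
  for (i in 1:40) {
    m <- sample(3:20, 1)
    bx <- rnorm(m, 0.1, 0.05)
    bx[abs(bx) < 1e-3] <- 0.05
    by <- 0.3 * bx + rnorm(m, 0, 0.02)
    seo <- runif(m, 0.01, 0.05)
    h <- makeHarmonized(bx, by, seo)
    oracle <- suppressWarnings(
      metafor::rma(yi = by / bx, sei = seo / abs(bx), method = "FE"))
    expect_equal(cochranQ(h)@q, unname(oracle$QE), tolerance = 1e-10)
  }
})

test_that("Q is invariant to row order and joint sign flips", {
  sim <- simulatePair(simConfig(mSnps = 12L, theta = 0.2), seed = 8)
  h <- harmonizedFromPair(sim$exposure, sim$outcome)
  q <- cochranQ(h)@q
  hp <- h
  hp@rows <- h@rows[sample(nrow(h@rows)), ]
  expect_equal(cochranQ(hp)@q, q, tolerance = 1e-12)
  hf <- h
  hf@rows$beta_exp <- -hf@rows$beta_exp
  hf@rows$beta_out <- -hf@rows$beta_out
  expect_equal(cochranQ(hf)@q, q, tolerance = 1e-12)
})

test_that("the Egger intercept is exact on noiseless lines", {
  bx <- c(0.05, 0.1, 0.2, 0.4)
  h <- makeHarmonized(bx, 0.4 * bx, seo = rep(0.01, 4))
  it <- eggerInterceptTest(h)
  expect_equal(it$intercept, 0, tolerance = 1e-14)
})

test_that("MR-PRESSO flags a planted outlier and is deterministic", {
  set.seed(44)
  m <- 30
  bx <- rnorm(m, 0.1, 0.02)
  bx <- abs(bx)
  by <- 0.2 * bx + rnorm(m, 0, 0.002)
  by[7] <- 2.0 * bx[7]          # ratio 10x the common ratio
  h <- makeHarmonized(bx, by, seo = rep(0.01, m), sex = rep(0.002, m))

  pr <- mrPresso(h, nSim = 1000L, seed = 100L)
  expect_true("rs7" %in% pr@outliers$snp_id)
  expect_lt(pr@globalPval, 0.05)
  expect_equal(nSnp(pr@corrected), m - nrow(pr@outliers))
  # corrected estimate closer to truth than raw
  raw <- mrIVW(h)
  expect_lt(abs(mrBeta(pr@corrected) - 0.2), abs(mrBeta(raw) - 0.2))
  expect_false(is.na(pr@distortionPval))

  pr2 <- mrPresso(h, nSim = 1000L, seed = 100L)
  expect_identical(pr@globalPval, pr2@globalPval)
  expect_identical(pr@outliers, pr2@outliers)
  expect_identical(mrBeta(pr@corrected), mrBeta(pr2@corrected))
  expect_identical(pr@distortionPval, pr2@distortionPval)
})

test_that("MR-PRESSO guards and degenerate significance levels", {
  sim <- simulatePair(simConfig(mSnps = 10L, theta = 0.2), seed = 12)
  h <- harmonizedFromPair(sim$exposure, sim$outcome)
  # sig = 0 flags nothing; corrected equals raw
  pr <- mrPresso(h, nSim = 300L, sig = 0, seed = 5L)
  expect_equal(nrow(pr@outliers), 0L)
  expect_equal(mrBeta(pr@corrected), mrBeta(mrIVW(h)), tolerance = 1e-12)
  expect_true(is.na(pr@distortionPval))
  expect_error(mrPresso(makeHarmonized(1:3 / 10, 1:3 / 20, rep(0.01, 3)),
                        seed = 1L), "insufficient")
  expect_error(mrPresso(h, nSim = 100L), "seed")
})

test_that("removing the flagged outlier does not increase Q", {
  set.seed(2)
  m <- 20
  bx <- abs(rnorm(m, 0.1, 0.02))
  by <- 0.2 * bx + rnorm(m, 0, 0.003)
  by[3] <- 1.5 * bx[3]
  h <- makeHarmonized(bx, by, seo = rep(0.01, m), sex = rep(0.002, m))
  pr <- mrPresso(h, nSim = 500L, seed = 77L)
  if (nrow(pr@outliers)) {
    keep <- !h@rows$snp_id %in% pr@outliers$snp_id
    h2 <- h
    h2@rows <- h@rows[keep, ]
    expect_lte(cochranQ(h2)@q, cochranQ(h)@q)
  } else fail("expected at least one flagged outlier")
})

test_that("leave-one-out flags exactly the dominant outlier", {
  # homogeneous by construction: residuals far below the outcome SE
  bx <- seq(0.05, 0.15, length.out = 10)
  by <- 0.25 * bx + 0.001 * rep(c(-1, 1), 5)
  h <- makeHarmonized(bx, by, seo = rep(0.01, 10))
  loo <- leaveOneOut(h)
  expect_equal(nrow(loo), 10L)
  full <- attr(loo, "full")
  expect_true(all(abs(loo$beta - mrBeta(full)) <= mrSE(full)))
  expect_false(any(loo$flagged))

  # plant one dominant outlier
  h2 <- h
  h2@rows$beta_out[4] <- h2@rows$beta_out[4] + 0.5 * h2@rows$beta_exp[4]
  h2@rows$se_out[4] <- h2@rows$se_out[4] / 4
  loo2 <- leaveOneOut(h2)
  expect_true(loo2$flagged[4])
  expect_equal(sum(loo2$flagged), 1L)
  expect_error(leaveOneOut(makeHarmonized(1:2 / 10, 1:2 / 20,
                                          c(0.01, 0.01))), ">= 3")
})

test_that("the sensitivity summary row collates all diagnostics", {
  sim <- simulatePair(simConfig(mSnps = 12L, theta = 0.2), seed = 14)
  h <- harmonizedFromPair(sim$exposure, sim$outcome)
  row <- sensitivitySummary(h, nSim = 300L, seed = 3L)
  expect_equal(nrow(row), 1L)
  expect_equal(row$n_snp, 12L)
  expect_false(is.na(row$q_pval))
  expect_false(is.na(row$intercept_pval))
  expect_false(is.na(row$presso_global_pval))
})
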