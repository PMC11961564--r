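# Monte-Carlo validation studies. These drive the generator through the
# estimators under known truth and summarise recovery, calibration and
# robustness; the test suite and the acceptance script both consume them.

.simIVW <- function(cfg, seed) {
  s <- simulatePair(cfg, seed = seed)
  mrIVW(harmonizedFromPair(s$exposure, s$outcome))
}

#' Estimator recovery under valid instruments
#'
#' Repeatedly simulates exposure/outcome pairs with a known causal effect
#' and no pleiotropy, runs IVW, and summarises the estimate distribution.
#'
#' @param theta true causal effect (default 0.25).
#' @param mSnps,n instruments and per-GWAS sample size.
#' @param nReps Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return list: \code{meanBeta}, \code{mcse} (Monte-Carlo SE of the
#'   mean), \code{truth}, \code{nReps}.
#' @export
studyEstimatorRecovery <- function(theta = 0.25, mSnps = 50L, n = 1e5,
                                   nReps = 500L, seed) {
  cfg <- simConfig(mSnps = mSnps, nExp = n, nOut = n, theta = theta)
  betas <- vapply(seq_len(nReps),
                  function(r) mrBeta(.simIVW(cfg, seed + r)), numeric(1))
  list(meanBeta = mean(betas), mcse = sd(betas) / sqrt(nReps),
       truth = theta, nReps = nReps)
}

#' Type-I error of IVW under the complete null
#'
#' @inheritParams studyEstimatorRecovery
#' @param alpha nominal level (default 0.05).
#' @return list: \code{rejectionRate}, \code{nReps}.
#' @export
studyTypeIError <- function(mSnps = 50L, n = 1e5, nReps = 2000L,
                            alpha = 0.05, seed) {
  cfg <- simConfig(mSnps = mSnps, nExp = n, nOut = n, theta = 0)
  p <- vapply(seq_len(nReps),
              function(r) mrPval(.simIVW(cfg, seed + r)), numeric(1))
  list(rejectionRate = mean(p < alpha), nReps = nReps)
}

#' Robustness split under directional pleiotropy
#'
#' With a fraction of invalid instruments carrying directional pleiotropy,
#' IVW is biased while the weighted median (majority-valid assumption
#' intact) stays consistent, and the Egger intercept estimates the average
#' pleiotropic effect \code{pleioFrac * pleioMean}. All three are measured
#' on the same replicates.
#'
#' @inheritParams studyEstimatorRecovery
#' @param pleioFrac,pleioMean,pleioSd invalid fraction and pleiotropy
#'   distribution.
#' @return list with per-estimator means and Monte-Carlo SEs, plus the
#'   true effect and true mean pleiotropy.
#' @export
studyRobustnessSplit <- function(theta = 0.25, mSnps = 50L, n = 1e5,
                                 pleioFrac = 0.4, pleioMean = 0.05,
                                 pleioSd = 0.01, nReps = 500L, seed) {
  cfg <- simConfig(mSnps = mSnps, nExp = n, nOut = n, theta = theta,
                   pleioFrac = pleioFrac, pleioMean = pleioMean,
                   pleioSd = pleioSd)
  ivw <- wm <- ic <- numeric(nReps)
  for (r in seq_len(nReps)) {
    s <- simulatePair(cfg, seed = seed + r)
    h <- harmonizedFromPair(s$exposure, s$outcome)
    ivw[r] <- mrBeta(mrIVW(h))
    wm[r] <- mrBeta(mrWeightedMedian(h, nBoot = 0L))
    ic[r] <- mrEgger(h)@intercept
  }
  list(ivwMean = mean(ivw), ivwMcse = sd(ivw) / sqrt(nReps),
       medianMean = mean(wm), medianMcse = sd(wm) / sqrt(nReps),
       interceptMean = mean(ic), interceptMcse = sd(ic) / sqrt(nReps),
       truth = theta, truePleiotropy = pleioFrac * pleioMean,
       nReps = nReps)
}

#' MR-PRESSO calibration and power
#'
#' Power arm: a homogeneous panel gets one variant's outcome effect set to
#' ten times the common ratio; measured are the fraction of replicates in
#' which exactly that variant is flagged and the fraction in which the
#' outlier-corrected estimate lands closer to the truth than the raw one.
#' Calibration arm: homogeneous panels only; measured is the global-test
#' rejection rate at 0.05.
#'
#' @param theta true causal effect.
#' @param mSnps panel size (default 30).
#' @param n per-GWAS sample size.
#' @param nRepsPower,nRepsNull replicates per arm.
#' @param nSim MR-PRESSO simulation count.
#' @param seed RNG seed.
#' @return list: \code{flagRate}, \code{correctedCloserRate},
#'   \code{nullRejectionRate}.
#' @export
studyPressoCalibration <- function(theta = 0.25, mSnps = 30L, n = 1e5,
                                   nRepsPower = 200L, nRepsNull = 500L,
                                   nSim = 1000L, seed) {
  cfg <- simConfig(mSnps = mSnps, nExp = n, nOut = n, theta = theta)
  flagged <- closer <- logical(nRepsPower)
  for (r in seq_len(nRepsPower)) {
    s <- simulatePair(cfg, seed = seed + r)
    h <- harmonizedFromPair(s$exposure, s$outcome)
    # plant on an upper-quartile-strength instrument: a ratio outlier on a
    # near-null instrument is undetectable in principle, while one on the
    # single strongest instrument swamps the fit and flags everything
    j <- order(abs(h@rows$beta_exp))[ceiling(0.75 * mSnps)]
    h@rows$beta_out[j] <- 10 * theta * h@rows$beta_exp[j]
    pr <- mrPresso(h, nSim = nSim, seed = seed + 10000L + r)
    flagged[r] <- h@rows$snp_id[j] %in% pr@outliers$snp_id
    closer[r] <- !is.null(pr@corrected) &&
      abs(mrBeta(pr@corrected) - theta) < abs(mrBeta(mrIVW(h)) - theta)
  }
  rejected <- vapply(seq_len(nRepsNull), function(r) {
    s <- simulatePair(cfg, seed = seed + 20000L + r)
    h <- harmonizedFromPair(s$exposure, s$outcome)
    mrPresso(h, nSim = nSim, seed = seed + 30000L + r)@globalPval < 0.05
  }, logical(1))
  list(flagRate = mean(flagged), correctedCloserRate = mean(closer),
       nullRejectionRate = mean(rejected),
       nRepsPower = nRepsPower, nRepsNull = nRepsNull)
}

#' Family-wise error of the Bonferroni screen verdicts
#'
#' Simulates families of all-null outcomes, takes the IVW p-value per
#' outcome, applies the Bonferroni adjustment at the declared family size
#' and counts families with at least one "strong" verdict.
#'
#' @param nOutcomes outcomes per family (default 13).
#' @param mSnps,n panel size and per-GWAS sample size.
#' @param nReps simulated families.
#' @param seed RNG seed.
#' @return list: \code{familywiseRate}, \code{nReps},
#'   \code{familySize}.
#' @export
studyFamilywiseError <- function(nOutcomes = 13L, mSnps = 50L, n = 1e5,
                                 nReps = 2000L, seed) {
  cfg <- simConfig(mSnps = mSnps, nExp = n, nOut = n, theta = 0)
  anyStrong <- vapply(seq_len(nReps), function(f) {
    p <- vapply(seq_len(nOutcomes), function(i)
      mrPval(.simIVW(cfg, seed + f * 100L + i)), numeric(1))
    any(bonferroni(p, m = nOutcomes) < 0.05)
  }, logical(1))
  list(familywiseRate = mean(anyStrong), nReps = nReps,
       familySize = nOutcomes)
}
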