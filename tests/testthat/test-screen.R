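# small simulated families keep the orchestration tests fast; the
# calibration studies live in the acceptance suite

test_that("Bonferroni adjustment uses the declared family size", {
  expect_equal(bonferroni(0.015, m = 13), 0.195)
  expect_equal(bonferroni(1.0, m = 7), 1.0)
  expect_equal(bonferroni(0.001, m = 13), 0.013)
  expect_error(bonferroni(0.01, m = 0), "family size")
  expect_error(bonferroni(1.5, m = 3), "pvals")
})

makeFamily <- function(nOutcomes, causalIdx = NULL, theta = 0.25,
                       seed = 1, mSnps = 30L) {
  outcomes <- vector("list", nOutcomes)
  exposure <- NULL
  for (i in seq_len(nOutcomes)) {
    cfg <- simConfig(mSnps = mSnps, gammaSd = 0.08,
                     theta = if (identical(i, causalIdx)) theta else 0)
    sim <- simulatePair(cfg, seed = seed * 1000 + i)
    if (i == 1L) exposure <- sim$exposure
    out <- sim$outcome
    out@traitName <- paste0("outcome_", letters[i])
    outcomes[[i]] <- out
  }
  list(exposure = exposure, outcomes = outcomes)
}

test_that("the forward screen ranks the causal outcome first", {
  fam <- makeFamily(4, causalIdx = 1L, seed = 3)
  ld <- identityLDMatrix(fam$exposure)
  scr <- runForwardScreen(fam$exposure, fam$outcomes, ld, seed = 5L,
                          nBoot = 100L, nSim = 300L)
  tab <- scr$table
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$status == "ok"))
  expect_equal(tab$outcome[which.min(tab$pval_raw)], "outcome_a")
  expect_equal(tab$verdict[1], "strong")
  expect_true(all(tab$pval_bonferroni >= tab$pval_raw))
  expect_true(all(tab$verdict %in% c("strong", "potential", "null")))
  # sensitivity rows collated per outcome
  expect_false(is.null(scr$details[["outcome_a"]]$sensitivity))
})

test_that("screen output is invariant to outcome ordering", {
  fam <- makeFamily(3, causalIdx = 2L, seed = 9)
  ld <- identityLDMatrix(fam$exposure)
  s1 <- runForwardScreen(fam$exposure, fam$outcomes, ld, seed = 7L,
                         nBoot = 50L, nSim = 200L)
  s2 <- runForwardScreen(fam$exposure, rev(fam$outcomes), ld, seed = 7L,
                         nBoot = 50L, nSim = 200L)
  t1 <- s1$table[order(s1$table$outcome), ]
  t2 <- s2$table[order(s2$table$outcome), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
})

test_that("an empty outcome list warns and outcome failures are non-fatal", {
  fam <- makeFamily(2, seed = 4)
  ld <- identityLDMatrix(fam$exposure)
  expect_warning(runForwardScreen(fam$exposure, list(), ld, seed = 1L),
                 "empty")
  # an outcome sharing no variants fails alone, the screen completes
  stranger <- summaryDataset(makeRecords(paste0("zz", 1:3),
                                         beta = 0.1, se = 0.01),
                             traitName = "stranger")
  scr <- runForwardScreen(fam$exposure,
                          c(fam$outcomes, list(stranger)), ld,
                          seed = 2L, nBoot = 50L, nSim = 200L)
  expect_equal(sum(scr$table$status == "failed"), 1L)
  expect_equal(scr$table$status[scr$table$outcome == "stranger"],
               "failed")
  expect_equal(sum(scr$table$status == "ok"), 2L)
})

test_that("the reverse screen swaps roles and reselects instruments", {
  # X -> Y with a modest effect: the outcome trait has no genuine
  # instruments of its own, so the reverse direction has nothing to select
  cfg <- simConfig(mSnps = 40L, gammaSd = 0.08, theta = 0.1)
  sim <- simulatePair(cfg, seed = 17)
  ld <- identityLDMatrix(sim$exposure)
  fwd <- runForwardScreen(sim$exposure, list(sim$outcome), ld, seed = 3L,
                          nBoot = 50L, nSim = 200L)
  expect_equal(fwd$table$verdict, "strong")

  rvs <- runReverseScreen(list(sim$outcome), sim$exposure, ld, seed = 3L,
                          nBoot = 50L, nSim = 200L)
  expect_equal(rvs$table$direction, "reverse")
  expect_equal(rvs$table$exposure, "sim_outcome")
  # the reverse exposure lacks genome-wide instruments here: either a
  # failed row (none at all) or a much weaker result than forward
  if (rvs$table$status == "ok") {
    expect_gt(rvs$table$pval_raw, fwd$table$pval_raw)
    # instrument sets differ between directions (role-swap plumbing)
    expect_false(identical(records(fwd$instruments)$snp_id,
                           records(rvs$instruments[[1]])$snp_id))
  } else {
    expect_match(rvs$table$error, "instrument")
  }
})

test_that("the mediator screen finds a planted mediation path", {
  cfg <- simConfig(mSnps = 40L, gammaSd = 0.08, nExp = 5e5, nMed = 5e5,
                   nOut = 5e5, beta1 = -0.15, beta2 = 0.2,
                   thetaDirect = 0.1)
  tr <- simulateTriad(cfg, seed = 23)
  decoy <- simulatePair(simConfig(mSnps = 80L, gammaSd = 0.08),
                        seed = 24)$outcome
  decoy@traitName <- "decoy_mediator"
  med <- tr$mediator
  med@traitName <- "true_mediator"
  ld <- identityLDMatrix(tr$exposure)
  ms <- runMediatorScreen(tr$exposure, list(med, decoy), tr$outcome,
                          ld, seed = 31L, nBoot = 50L, nSim = 200L)
  expect_true("true_mediator" %in% ms$mediation$mediator)
  expect_equal(ms$log[["true_mediator"]], "mediation candidate")
  expect_false(isTRUE(ms$log[["decoy_mediator"]] == "mediation candidate"))
  row <- ms$mediation[ms$mediation$mediator == "true_mediator", ]
  # recovered indirect effect near beta1 * beta2 = -0.03
  expect_lt(abs(row$indirect - (-0.03)), 0.03)
  expect_equal(row$indirect + row$direct, row$beta_total,
               tolerance = 1e-12)
  # empty mediator panel
  ms0 <- runMediatorScreen(tr$exposure, list(), tr$outcome, ld,
                           seed = 1L)
  expect_null(ms0$mediation)
})

test_that("replication requires significance and a concordant sign", {
  cfg <- simConfig(mSnps = 40L, gammaSd = 0.08, theta = 0.3)
  sim <- simulatePair(cfg, seed = 41)
  ld <- identityLDMatrix(sim$exposure)
  instr <- buildInstruments(sim$exposure, ld)
  primary <- mrIVW(harmonize(instr, sim$outcome))

  # replication cohort: fresh outcome noise around the same truth
  set.seed(42)
  rec <- records(sim$outcome)
  rec$beta <- rnorm(nrow(rec), sim$truth$theta * sim$truth$gamma,
                    sim$truth$se_out)
  replication <- summaryDataset(rec, traitName = "replication")
  ans <- replicateFinding(mrBeta(primary), instr, replication)
  expect_equal(ans$verdict, "replicated")
  # sign-discordant significant estimate is not replication
  flipped <- sim$outcome
  flipped@records$beta <- -flipped@records$beta
  ans2 <- replicateFinding(mrBeta(primary), instr, flipped)
  expect_equal(ans2$verdict, "not replicated")
})
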