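test_that("readSummaryStats reads well-formed files and both delimiters", {
  df <- makeRecords(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                    se = c(0.01, 0.02, 0.01))
  for (sep in c("\t", ",")) {
    ds <- readSummaryStats(writeToyTsv(df, sep), traitName = "toy")
    expect_s4_class(ds, "SummaryDataset")
    expect_equal(nrow(records(ds)), 3L)
    v <- validationSummary(ds)
    expect_equal(v$rows_dropped, 0L)
    expect_equal(v$rows_read, 3L)
  }
})

test_that("rows failing validation are dropped with reasons", {
  df <- makeRecords(paste0("rs", 1:5), beta = c(0.1, 0.2, 0.1, 0.1, 0.3),
                    se = c(0.01, 0, 0.01, 0.01, 0.01))
  df$pval[3] <- 2            # invalid p
  df$effect_allele[4] <- "G" # same as other_allele
  ds <- readSummaryStats(writeToyTsv(df))
  v <- validationSummary(ds)
  expect_equal(nrow(records(ds)), 2L)
  expect_equal(v$rows_dropped, 3L)
  expect_setequal(v$dropped$reason[v$dropped$snp_id == "rs2"],
                  "nonpositive se")
  expect_setequal(v$dropped$reason[v$dropped$snp_id == "rs3"],
                  "invalid pval")
  expect_setequal(v$dropped$reason[v$dropped$snp_id == "rs4"],
                  "identical alleles")
})

test_that("duplicate rsIDs keep the smallest p-value", {
  df <- makeRecords(c("rs1", "rs1", "rs2"), beta = c(0.1, 0.2, 0.3),
                    se = c(0.05, 0.01, 0.01))
  ds <- readSummaryStats(writeToyTsv(df))
  rec <- records(ds)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$beta[rec$snp_id == "rs1"], 0.2)  # the smaller-p row
  expect_equal(validationSummary(ds)$dropped$reason, "duplicate snp_id")
})

test_that("missing required columns and empty files are fatal", {
  df <- makeRecords(c("rs1", "rs2"), beta = c(0.1, 0.2), se = 0.01)
  path <- writeToyTsv(df)
  tab <- read.delim(path)
  tab$standard_error <- NULL
  path2 <- tempfile(fileext = ".tsv")
  write.table(tab, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSummaryStats(path2), "se")
  empty <- tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(readSummaryStats(empty), "empty")
  expect_error(readSummaryStats(tempfile()), "not found")
})

test_that("harmonize flips swapped alleles and logs every exclusion", {
  exposure <- summaryDataset(makeRecords(
    c("rs1", "rs2", "rs3", "rs4"), beta = c(0.10, 0.15, 0.2, 0.1),
    se = 0.01,
    effect_allele = c("A", "A", "A", "C"),
    other_allele = c("G", "T", "G", "A")), traitName = "X")
  outcome <- summaryDataset(makeRecords(
    c("rs1", "rs2", "rs4"), beta = c(0.05, 0.02, 0.07), se = 0.02,
    effect_allele = c("G", "A", "C"),
    other_allele = c("A", "T", "T")), traitName = "Y")

  h <- harmonize(exposure, outcome)
  rows <- harmonizedRows(h)
  # rs1: alleles swapped in outcome -> sign flip
  expect_equal(rows$beta_out[rows$snp_id == "rs1"], -0.05)
  excl <- exclusionLog(h)
  expect_equal(excl$reason[excl$snp_id == "rs2"], "palindromic")
  expect_equal(excl$reason[excl$snp_id == "rs3"], "not found in outcome")
  expect_equal(excl$reason[excl$snp_id == "rs4"], "ambiguous alleles")
  # every input variant accounted for
  expect_equal(nrow(rows) + nrow(excl), nrow(records(exposure)))
})

test_that("harmonization is idempotent and orientation-consistent", {
  set.seed(42)
  m <- 12
  rec <- makeRecords(paste0("rs", 1:m), beta = rnorm(m, 0, 0.05),
                     se = 0.01,
                     effect_allele = rep(c("A", "T", "C", "G"), 3),
                     other_allele = rep(c("C", "G", "A", "T"), 3))
  outRec <- rec
  outRec$beta <- rnorm(m, 0, 0.02)
  outRec$se <- 0.02
  exposure <- summaryDataset(rec, traitName = "X")
  outcome <- summaryDataset(outRec, traitName = "Y")
  h1 <- harmonize(exposure, outcome)

  # already aligned: no beta changes
  expect_equal(harmonizedRows(h1)$beta_out,
               outRec$beta[match(harmonizedRows(h1)$snp_id,
                                 outRec$snp_id)])

  # flip every outcome record's allele labels and beta sign: same rows out
  flipped <- outRec
  flipped$effect_allele <- outRec$other_allele
  flipped$other_allele <- outRec$effect_allele
  flipped$beta <- -outRec$beta
  h2 <- harmonize(exposure, summaryDataset(flipped, traitName = "Y"))
  expect_equal(harmonizedRows(h2), harmonizedRows(h1))
})

test_that("harmonize with no survivors is fatal", {
  exposure <- summaryDataset(makeRecords("rs1", beta = 0.1, se = 0.01,
                                         effect_allele = "A",
                                         other_allele = "T"),
                             traitName = "X")
  outcome <- summaryDataset(makeRecords("rs9", beta = 0.1, se = 0.01),
                            traitName = "Y")
  expect_error(harmonize(exposure, outcome), "no usable instruments")
})

test_that("harmonized sets and datasets round-trip through TSV", {
  sim <- simulatePair(simConfig(mSnps = 8L, theta = 0.1), seed = 11)
  h <- harmonizedFromPair(sim$exposure, sim$outcome)
  p <- tempfile(fileext = ".tsv")
  writeHarmonized(h, p)
  h2 <- readHarmonized(p, "sim_exposure", "sim_outcome")
  expect_equal(harmonizedRows(h2), harmonizedRows(h), tolerance = 1e-12)

  p2 <- tempfile(fileext = ".tsv")
  writeSummaryDataset(sim$exposure, p2)
  ds <- readSummaryStats(p2, traitName = traitName(sim$exposure))
  expect_equal(validationSummary(ds)$rows_dropped, 0L)
  expect_equal(records(ds)$beta, records(sim$exposure)$beta,
               tolerance = 1e-12)
})
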