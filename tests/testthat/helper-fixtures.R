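# Shared fixture builders; everything is generated in code.

# canonical records data.frame for quick SummaryDataset construction
makeRecords <- function(snp_id, beta, se, pval = NULL,
                        effect_allele = "A", other_allele = "G",
                        chrom = "1", pos = seq_along(snp_id) * 1e5,
                        eaf = 0.3, n = 1e5) {
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

# HarmonizedSet straight from effect vectors
makeHarmonized <- function(bx, by, seo, sex = seo,
                           ids = paste0("rs", seq_along(bx))) {
  new("HarmonizedSet", exposureName = "X", outcomeName = "Y",
      rows = data.frame(snp_id = ids, beta_exp = bx, se_exp = sex,
                        beta_out = by, se_out = seo, eaf_exp = 0.3,
                        stringsAsFactors = FALSE),
      exclusionLog = data.frame(snp_id = character(),
                                reason = character(),
                                stringsAsFactors = FALSE))
}

# write a canonical summary-stats TSV, returning its path
writeToyTsv <- function(df, sep = "\t") {
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  names(df) <- mrmediate::defaultColumnMap()[names(df)]
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Exhaustive verification oracle for greedy clumping: every retained pair
# must be compatible (r2 <= threshold, or beyond the window, or on
# different chromosomes) and every removed variant must be explained by a
# retained variant that beats it (smaller p, or equal p and earlier in
# genomic order) within the window at r2 above threshold.
clumpOracleCheck <- function(input, output, ld, config) {
  pos <- ld@positions
  at <- function(id, col) pos[[col]][match(id, pos$snp_id)]
  win <- config@clumpWindowKb * 1000
  compat <- function(a, b) {
    at(a, "chrom") != at(b, "chrom") ||
      abs(at(a, "pos") - at(b, "pos")) > win ||
      ld@r2[a, b] <= config@clumpR2
  }
  keep <- output$snp_id
  for (a in keep) for (b in keep) if (a != b && !compat(a, b)) return(FALSE)
  beats <- function(a, b) {  # does retained a dominate removed b
    pa <- input$pval[match(a, input$snp_id)]
    pb <- input$pval[match(b, input$snp_id)]
    pa < pb || (pa == pb &&
      (at(a, "chrom") < at(b, "chrom") ||
       (at(a, "chrom") == at(b, "chrom") && at(a, "pos") < at(b, "pos"))))
  }
  removed <- setdiff(input$snp_id, keep)
  for (b in removed) {
    if (!any(vapply(keep, function(a) !compat(a, b) && beats(a, b),
                    logical(1))))
      return(FALSE)
  }
  TRUE
}

# Brute-force weighted-median oracle: invert the piecewise-linear weighted
# cumulative distribution with stats::approx rather than the package's own
# interpolation code.
weightedMedianOracle <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  approx(s, r, xout = 0.5, ties = "ordered")$y
}
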