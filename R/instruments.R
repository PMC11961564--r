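#' Create an instrument-selection configuration
#'
#' @param pPrimary genome-wide significance threshold (default 5e-8).
#' @param pFallback relaxed threshold used when fewer than
#'   \code{minInstruments} variants pass \code{pPrimary} (default 5e-6).
#' @param pMediator threshold for mediator panels (default 1e-5).
#' @param clumpR2 maximum pairwise r^2 among retained instruments
#'   (default 0.001).
#' @param clumpWindowKb clumping window in kilobases (default 10000).
#' @param fMin minimum per-variant F statistic (default 10).
#' @param minInstruments minimum count at \code{pPrimary} before falling back
#'   (default 3).
#' @return a validated \linkS4class{SelectionConfig}.
#' @export
selectionConfig <- function(pPrimary = 5e-8, pFallback = 5e-6,
                            pMediator = 1e-5, clumpR2 = 0.001,
                            clumpWindowKb = 10000, fMin = 10,
                            minInstruments = 3L) {
  new("SelectionConfig", pPrimary = pPrimary, pFallback = pFallback,
      pMediator = pMediator, clumpR2 = clumpR2,
      clumpWindowKb = as.numeric(clumpWindowKb), fMin = fMin,
      minInstruments = as.integer(minInstruments))
}

#' Select variants by p-value with a fallback threshold
#'
#' Keeps variants with p below the primary threshold; if fewer than
#' \code{config@minInstruments} pass, retries at the relaxed fallback
#' threshold and reports which threshold was applied.
#'
#' @param dataset a \linkS4class{SummaryDataset}.
#' @param config a \linkS4class{SelectionConfig}.
#' @param pOverride use this single threshold instead of the
#'   primary/fallback pair (e.g. the mediator threshold); no fallback then.
#' @return list with \code{records} (data.frame) and \code{thresholdUsed}.
#' @export
selectByPvalue <- function(dataset, config = selectionConfig(),
                           pOverride = NULL) {
  rec <- records(dataset)
  if (!is.null(pOverride)) {
    keep <- rec[rec$pval < pOverride, , drop = FALSE]
    if (!nrow(keep))
      stop("no instruments at threshold ", format(pOverride))
    return(list(records = keep, thresholdUsed = pOverride))
  }
  primary <- rec[rec$pval < config@pPrimary, , drop = FALSE]
  if (nrow(primary) >= config@minInstruments)
    return(list(records = primary, thresholdUsed = config@pPrimary))
  fallback <- rec[rec$pval < config@pFallback, , drop = FALSE]
  # relax only when it actually buys instruments; otherwise report the
  # genome-wide threshold that the surviving variants met
  if (nrow(fallback) > nrow(primary))
    return(list(records = fallback, thresholdUsed = config@pFallback))
  if (!nrow(primary))
    stop("no instruments at either threshold (",
         format(config@pPrimary), ", ", format(config@pFallback), ")")
  list(records = primary, thresholdUsed = config@pPrimary)
}

#' Greedy LD clumping
#'
#' Standard greedy clumping: variants are ranked by ascending p-value (ties
#' broken by chromosome then position); the best remaining variant becomes an
#' index SNP and all remaining variants on the same chromosome within
#' \code{clumpWindowKb} of it with r^2 above \code{clumpR2} are removed.
#' Index SNPs are returned in genomic order. The result is independent of
#' input row order.
#'
#' @param recs data.frame of SummaryDataset-style records.
#' @param ld an \linkS4class{LDMatrix} covering every variant in \code{recs}.
#' @param config a \linkS4class{SelectionConfig}.
#' @return the retained rows of \code{recs}, in genomic order.
#' @export
clumpVariants <- function(recs, ld, config = selectionConfig()) {
  if (!nrow(recs)) return(recs)
  miss <- setdiff(recs$snp_id, ld@snpIds)
  if (length(miss))
    stop("variant(s) missing from LD matrix: ",
         paste(head(miss, 5), collapse = ", "))
  pos <- ld@positions
  pidx <- match(recs$snp_id, pos$snp_id)
  chrom <- as.character(pos$chrom[pidx])
  bp <- as.numeric(pos$pos[pidx])

  ord <- order(recs$pval, chrom, bp)
  window_bp <- config@clumpWindowKb * 1000
  r2 <- ld@r2[recs$snp_id, recs$snp_id, drop = FALSE]

  alive <- rep(TRUE, nrow(recs))
  index <- logical(nrow(recs))
  for (i in ord) {
    if (!alive[i]) next
    index[i] <- TRUE
    alive[i] <- FALSE
    prune <- alive & chrom == chrom[i] & abs(bp - bp[i]) <= window_bp &
      r2[i, ] > config@clumpR2
    alive[prune] <- FALSE
  }
  out <- recs[index, , drop = FALSE]
  out[order(chrom[index], bp[index]), , drop = FALSE]
}

#' Instrument-strength F statistic
#'
#' \code{F = ((N - K - 1) / K) * (R^2 / (1 - R^2))}, with \code{N} the GWAS
#' sample size, \code{K} the number of instruments and \code{R^2} the variance
#' of the exposure they explain. For per-variant strength filtering
#' \code{k = 1}.
#'
#' @param n sample size.
#' @param k number of instruments.
#' @param r2 variance explained, in [0, 1).
#' @return the F value.
#' @export
fStatistic <- function(n, k = 1, r2) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (any(n <= k + 1)) stop("need n > k + 1")
  ((n - k - 1) / k) * (r2 / (1 - r2))
}

#' Per-variant variance explained from summary statistics
#'
#' The standard t-statistic-based approximation
#' \code{r2 = beta^2 / (beta^2 + (n - 2) * se^2)}. Used as the default R^2
#' entering \code{\link{fStatistic}}; supply a precomputed r^2 column to
#' override.
#'
#' @param beta,se per-allele effect and its SE.
#' @param n GWAS sample size (> 2).
#' @return variance explained per variant.
#' @export
r2FromSummary <- function(beta, se, n) {
  if (any(n <= 2)) stop("need n > 2")
  beta^2 / (beta^2 + (n - 2) * se^2)
}

#' Build an instrument set: p-value filter, LD clump, F filter
#'
#' Composes \code{\link{selectByPvalue}}, \code{\link{clumpVariants}} and a
#' per-variant F filter (k = 1, dropping F below \code{config@fMin}), logging
#' the count surviving each stage.
#'
#' @inheritParams selectByPvalue
#' @param ld an \linkS4class{LDMatrix}.
#' @return an \linkS4class{InstrumentSet}.
#' @export
buildInstruments <- function(dataset, ld, config = selectionConfig(),
                             pOverride = NULL) {
  sel <- selectByPvalue(dataset, config, pOverride = pOverride)
  clumped <- clumpVariants(sel$records, ld, config)
  if (any(is.na(clumped$n)))
    stop("sample size (n) required for F-statistic filtering; missing for: ",
         paste(head(clumped$snp_id[is.na(clumped$n)], 5), collapse = ", "))
  f <- fStatistic(clumped$n, k = 1,
                  r2 = r2FromSummary(clumped$beta, clumped$se, clumped$n))
  names(f) <- clumped$snp_id
  keep <- f >= config@fMin
  strong <- clumped[keep, , drop = FALSE]
  if (!nrow(strong))
    stop("no instruments with F >= ", config@fMin, " for ",
         traitName(dataset))
  new("InstrumentSet", exposureName = traitName(dataset), records = strong,
      perSnpF = f[keep], thresholdUsed = sel$thresholdUsed,
      stageCounts = c(input = nrow(records(dataset)),
                      p_filter = nrow(sel$records),
                      clump = nrow(clumped),
                      f_filter = as.integer(sum(keep))))
}

#' Read an LD matrix from TSV
#'
#' Accepts either a square matrix TSV (first column = snp_id, remaining
#' headers = snp_ids) or a long format with columns \code{snp_a},
#' \code{snp_b}, \code{r2}. Positions come from a SummaryDataset or a
#' positions data.frame.
#'
#' @param path TSV path.
#' @param positions data.frame with \code{snp_id}, \code{chrom}, \code{pos},
#'   or a \linkS4class{SummaryDataset} to take them from.
#' @return an \linkS4class{LDMatrix}.
#' @export
readLDMatrix <- function(path, positions) {
  if (is(positions, "SummaryDataset"))
    positions <- records(positions)[, c("snp_id", "chrom", "pos")]
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(df))) {
    ids <- sort(unique(c(df$snp_a, df$snp_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    m[cbind(df$snp_a, df$snp_b)] <- df$r2
    m[cbind(df$snp_b, df$snp_a)] <- df$r2
  } else {
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(ids, colnames(m))
    m <- m[, ids, drop = FALSE]
    storage.mode(m) <- "double"
  }
  new("LDMatrix", snpIds = rownames(m), r2 = m,
      positions = positions[positions$snp_id %in% rownames(m), , drop = FALSE])
}

#' Write an LD matrix as a square TSV
#'
#' @param ld an \linkS4class{LDMatrix}.
#' @param path output path.
#' @export
writeLDMatrix <- function(ld, path) {
  df <- data.frame(snp_id = ld@snpIds, ld@r2, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
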