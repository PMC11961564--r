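#' @import methods
#' @importFrom stats pnorm qnorm pchisq pt qt sd rnorm runif p.adjust IQR
#' @importFrom utils read.delim write.table head packageVersion
NULL

#' SummaryDataset: one trait's GWAS summary statistics
#'
#' Per-variant association records for a single trait, as released by GWAS
#' consortia: one row per SNP with alleles, effect size on the log-odds (binary
#' trait) or standardized (quantitative trait) scale, its standard error,
#' p-value and sample size.
#'
#' @slot traitName trait label.
#' @slot records data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{eaf}
#'   (may be \code{NA}), \code{beta}, \code{se}, \code{pval}, \code{n}.
#' @slot ancestry ancestry label (free text, e.g. "European").
#' @slot sourceId accession or file path the data came from.
#'
#' @export
setClass("SummaryDataset",
  representation(
    traitName = "character",
    records   = "data.frame",
    ancestry  = "character",
    sourceId  = "character"
  ),
  prototype(traitName = NA_character_, ancestry = NA_character_,
            sourceId = NA_character_)
)

.SUMMARY_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

setValidity("SummaryDataset", function(object) {
  rec <- object@records
  missing_cols <- setdiff(.SUMMARY_COLS, names(rec))
  if (length(missing_cols))
    return(paste0("records lacks column(s): ",
                  paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(rec$snp_id))
    return("snp_id must be unique within a dataset")
  if (nrow(rec)) {
    if (any(rec$se <= 0)) return("all se must be > 0")
    if (any(rec$pval <= 0 | rec$pval > 1)) return("pval must lie in (0, 1]")
    eaf_ok <- is.na(rec$eaf) | (rec$eaf >= 0 & rec$eaf <= 1)
    if (!all(eaf_ok)) return("eaf must lie in [0, 1] or be NA")
    if (any(rec$effect_allele == rec$other_allele))
      return("effect_allele must differ from other_allele")
  }
  TRUE
})

#' HarmonizedSet: exposure/outcome effects on a shared allele orientation
#'
#' The result of matching an exposure instrument set against an outcome GWAS:
#' per-SNP (beta_exp, se_exp, beta_out, se_out) pairs expressed relative to the
#' same effect allele, with a log of every variant excluded and why.
#'
#' @slot exposureName,outcomeName trait labels.
#' @slot rows data.frame with columns \code{snp_id}, \code{beta_exp},
#'   \code{se_exp}, \code{beta_out}, \code{se_out}, \code{eaf_exp}.
#' @slot exclusionLog data.frame with columns \code{snp_id}, \code{reason}.
#'
#' @export
setClass("HarmonizedSet",
  representation(
    exposureName = "character",
    outcomeName  = "character",
    rows         = "data.frame",
    exclusionLog = "data.frame"
  )
)

setValidity("HarmonizedSet", function(object) {
  need <- c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out", "eaf_exp")
  if (!all(need %in% names(object@rows)))
    return(paste0("rows needs columns: ", paste(need, collapse = ", ")))
  r <- object@rows
  if (nrow(r)) {
    if (!all(is.finite(r$beta_exp)) || !all(is.finite(r$beta_out)) ||
        !all(is.finite(r$se_exp)) || !all(is.finite(r$se_out)))
      return("beta/se must be finite")
    if (any(r$se_exp <= 0) || any(r$se_out <= 0)) return("se must be > 0")
  }
  if (!all(c("snp_id", "reason") %in% names(object@exclusionLog)))
    return("exclusionLog needs columns snp_id, reason")
  TRUE
})

#' MRResult: one estimator's causal estimate
#'
#' @slot method one of \code{wald_ratio}, \code{ivw}, \code{egger},
#'   \code{weighted_median}, \code{weighted_mode}.
#' @slot beta,se causal estimate (log-odds scale for a binary outcome) and SE.
#' @slot ciLow,ciHigh 95\% interval bounds.
#' @slot pval two-sided p-value.
#' @slot or,orCiLow,orCiHigh exponentiated estimate and bounds.
#' @slot nSnp number of instruments used.
#' @slot intercept,interceptSe,interceptPval Egger intercept triple
#'   (NA for other methods).
#'
#' @export
setClass("MRResult",
  representation(
    method = "character", beta = "numeric", se = "numeric",
    ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
    or = "numeric", orCiLow = "numeric", orCiHigh = "numeric",
    nSnp = "integer",
    intercept = "numeric", interceptSe = "numeric", interceptPval = "numeric"
  ),
  prototype(intercept = NA_real_, interceptSe = NA_real_,
            interceptPval = NA_real_)
)

setClassUnion("MRResultOrNULL", c("MRResult", "NULL"))

setValidity("MRResult", function(object) {
  ok_methods <- c("wald_ratio", "ivw", "egger", "weighted_median",
                  "weighted_mode")
  if (!object@method %in% ok_methods)
    return(paste0("method must be one of: ", paste(ok_methods, collapse = ", ")))
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      (object@ciLow > object@beta || object@beta > object@ciHigh))
    return("need ciLow <= beta <= ciHigh")
  if (is.finite(object@pval) && (object@pval <= 0 || object@pval > 1))
    return("pval must lie in (0, 1]")
  TRUE
})

#' QResult: Cochran's Q heterogeneity statistic
#'
#' @slot q Q statistic (>= 0).
#' @slot df degrees of freedom, \code{nSnp - 1}.
#' @slot pval upper-tail chi-square p-value.
#'
#' @export
setClass("QResult",
  representation(q = "numeric", df = "integer", pval = "numeric"))

setValidity("QResult", function(object) {
  if (object@q < 0) return("q must be >= 0")
  if (object@df < 1L) return("df must be >= 1")
  TRUE
})

#' PressoResult: MR-PRESSO global, outlier and distortion tests
#'
#' @slot globalRss observed residual sum of squares.
#' @slot globalPval empirical global-test p (add-one smoothed).
#' @slot outliers data.frame with columns \code{snp_id}, \code{pval}
#'   (Bonferroni-corrected per-SNP outlier p); zero rows if none flagged.
#' @slot corrected IVW \linkS4class{MRResult} after removing flagged
#'   outliers, or \code{NULL} when nothing was flagged or too few SNPs remain.
#' @slot distortionPval empirical p comparing raw vs outlier-corrected slope.
#' @slot nSim simulation count used for the empirical null.
#' @slot seed seed the simulation ran under.
#'
#' @export
setClass("PressoResult",
  representation(
    globalRss = "numeric", globalPval = "numeric",
    outliers = "data.frame", corrected = "MRResultOrNULL",
    distortionPval = "numeric", nSim = "integer", seed = "integer"
  )
)

#' MediationResult: two-step decomposition of a total causal effect
#'
#' Holds the product-of-coefficients decomposition: total effect (exposure on
#' outcome), step-1 (exposure on mediator), step-2 (mediator on outcome),
#' indirect = beta1 * beta2, direct = beta0 - beta1 * beta2, proportion
#' mediated = indirect / beta0, with first-order delta-method SEs and normal
#' 95\% CIs.
#'
#' @slot betaTotal,betaStep1,betaStep2 the three input estimates (log scale).
#' @slot se0,se1,se2 their standard errors.
#' @slot indirect,indirectSe,indirectCiLow,indirectCiHigh,indirectPval
#'   mediated (indirect) effect and its delta-method uncertainty.
#' @slot direct direct effect, \code{betaTotal - indirect}.
#' @slot proportion,proportionSe,proportionCiLow,proportionCiHigh proportion
#'   mediated and its delta-method uncertainty; all NA with
#'   \code{proportionDefined = FALSE} when \code{betaTotal == 0}.
#' @slot proportionDefined logical flag.
#'
#' @export
setClass("MediationResult",
  representation(
    betaTotal = "numeric", betaStep1 = "numeric", betaStep2 = "numeric",
    se0 = "numeric", se1 = "numeric", se2 = "numeric",
    indirect = "numeric", indirectSe = "numeric",
    indirectCiLow = "numeric", indirectCiHigh = "numeric",
    indirectPval = "numeric",
    direct = "numeric",
    proportion = "numeric", proportionSe = "numeric",
    proportionCiLow = "numeric", proportionCiHigh = "numeric",
    proportionDefined = "logical"
  )
)

#' InstrumentSet: variants surviving instrument selection
#'
#' @slot exposureName trait the instruments are for.
#' @slot records SummaryDataset-style data.frame of surviving variants.
#' @slot perSnpF named numeric, per-variant F statistic (k = 1).
#' @slot thresholdUsed the p-value threshold that was actually applied.
#' @slot stageCounts named integer vector of per-stage counts
#'   (input, p_filter, clump, f_filter).
#'
#' @export
setClass("InstrumentSet",
  representation(
    exposureName = "character", records = "data.frame",
    perSnpF = "numeric", thresholdUsed = "numeric",
    stageCounts = "integer"
  )
)

#' LDMatrix: pairwise squared-correlation matrix with genomic positions
#'
#' @slot snpIds ordered variant identifiers.
#' @slot r2 symmetric matrix of squared correlations in [0, 1], unit diagonal,
#'   dimnames = snpIds.
#' @slot positions data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}.
#'
#' @export
setClass("LDMatrix",
  representation(snpIds = "character", r2 = "matrix", positions = "data.frame"))

setValidity("LDMatrix", function(object) {
  m <- object@r2
  if (nrow(m) != length(object@snpIds) || ncol(m) != length(object@snpIds))
    return("r2 dimensions must match snpIds")
  if (nrow(m)) {
    if (max(abs(m - t(m))) > 1e-8) return("r2 must be symmetric")
    if (any(abs(diag(m) - 1) > 1e-8)) return("r2 diagonal must be 1")
    if (any(m < -1e-12) || any(m > 1 + 1e-12))
      return("r2 values must lie in [0, 1]")
  }
  if (!all(c("snp_id", "chrom", "pos") %in% names(object@positions)))
    return("positions needs columns snp_id, chrom, pos")
  if (!all(object@snpIds %in% object@positions$snp_id))
    return("every snpId needs a position")
  TRUE
})

#' SelectionConfig: instrument-selection thresholds
#'
#' Defaults follow standard two-sample MR practice: genome-wide significance
#' 5e-8 with a 5e-6 fallback when too few variants pass, a relaxed 1e-5
#' threshold for mediator panels, clumping at r^2 = 0.001 within a 10,000 kb
#' window, and a minimum per-variant F statistic of 10.
#'
#' @slot pPrimary,pFallback,pMediator p-value thresholds.
#' @slot clumpR2 maximum pairwise r^2 among retained instruments.
#' @slot clumpWindowKb clumping window, kilobases.
#' @slot fMin minimum F statistic.
#' @slot minInstruments minimum count at pPrimary before falling back.
#'
#' @export
setClass("SelectionConfig",
  representation(
    pPrimary = "numeric", pFallback = "numeric", pMediator = "numeric",
    clumpR2 = "numeric", clumpWindowKb = "numeric", fMin = "numeric",
    minInstruments = "integer"
  )
)

setValidity("SelectionConfig", function(object) {
  if (!(object@pPrimary > 0 && object@pPrimary <= object@pFallback &&
        object@pFallback <= object@pMediator && object@pMediator < 1))
    return("need 0 < pPrimary <= pFallback <= pMediator < 1")
  if (object@clumpR2 < 0 || object@clumpR2 >= 1)
    return("need 0 <= clumpR2 < 1")
  if (object@clumpWindowKb <= 0) return("clumpWindowKb must be > 0")
  if (object@fMin < 0) return("fMin must be >= 0")
  if (object@minInstruments < 1L) return("minInstruments must be >= 1")
  TRUE
})
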