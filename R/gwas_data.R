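#' Default column mapping for GWAS summary-statistics files
#'
#' Canonical field -> column header, following GWAS Catalog harmonized naming.
#' Override any entry via the \code{columnMap} argument of
#' \code{\link{readSummaryStats}}.
#'
#' @export
defaultColumnMap <- function() {
  c(snp_id = "variant_id",
    chrom = "chromosome",
    pos = "base_pair_location",
    effect_allele = "effect_allele",
    other_allele = "other_allele",
    eaf = "effect_allele_frequency",
    beta = "beta",
    se = "standard_error",
    pval = "p_value",
    n = "n")
}

.REQUIRED_FIELDS <- c("snp_id", "effect_allele", "other_allele",
                      "beta", "se", "pval")

# validate canonical-format rows; returns kept rows + per-reason drop log
.validateRows <- function(df) {
  rownames(df) <- NULL
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  valid_allele <- function(a) toupper(a) %in% c("A", "C", "G", "T")
  flag(!valid_allele(df$effect_allele) | !valid_allele(df$other_allele),
       "invalid allele")
  flag(toupper(df$effect_allele) == toupper(df$other_allele),
       "identical alleles")
  flag(!is.finite(df$beta), "nonfinite beta")
  flag(!is.finite(df$se) | df$se <= 0, "nonpositive se")
  flag(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1, "invalid pval")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "invalid eaf")
  flag(!is.na(df$n) & df$n <= 0, "nonpositive n")

  kept <- df[is.na(reason), , drop = FALSE]
  # duplicate rsIDs: keep the smallest p-value, deterministic tie-break on
  # file order
  if (nrow(kept) && anyDuplicated(kept$snp_id)) {
    ord <- order(kept$snp_id, kept$pval)
    dup <- duplicated(kept$snp_id[ord])
    drop_idx <- as.integer(rownames(kept)[ord][dup])
    reason[drop_idx] <- "duplicate snp_id"
    kept <- df[is.na(reason), , drop = FALSE]
  }
  dropped <- data.frame(snp_id = df$snp_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  list(kept = kept, dropped = dropped)
}

#' Construct a SummaryDataset from a canonical data.frame
#'
#' @param records data.frame with the canonical columns (\code{snp_id},
#'   \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele},
#'   \code{eaf}, \code{beta}, \code{se}, \code{pval}, \code{n}); missing
#'   optional columns (\code{chrom}, \code{pos}, \code{eaf}, \code{n}) are
#'   filled with \code{NA}.
#' @param traitName,ancestry,sourceId metadata strings.
#' @return a validated \linkS4class{SummaryDataset}.
#' @export
summaryDataset <- function(records, traitName = NA_character_,
                           ancestry = NA_character_,
                           sourceId = NA_character_) {
  for (opt in c("chrom", "pos", "eaf", "n"))
    if (!opt %in% names(records))
      records[[opt]] <- if (opt == "chrom") NA_character_ else NA_real_
  records$effect_allele <- toupper(records$effect_allele)
  records$other_allele <- toupper(records$other_allele)
  records <- records[, .SUMMARY_COLS, drop = FALSE]
  rownames(records) <- NULL
  new("SummaryDataset", traitName = as.character(traitName),
      records = records, ancestry = as.character(ancestry),
      sourceId = as.character(sourceId))
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a TSV or CSV (delimiter auto-detected from the header line), maps
#' columns to the canonical per-SNP fields, drops rows that fail validation
#' (non-positive SE, p-value outside (0, 1], non-ACGT or identical alleles,
#' out-of-range allele frequency, duplicate rsIDs keeping the smallest
#' p-value) and returns a \linkS4class{SummaryDataset}. The validation
#' summary (rows read, rows dropped, drop reasons) is attached as attribute
#' \code{"validation"} and retrievable with \code{\link{validationSummary}}.
#'
#' @param path file path.
#' @param columnMap named character vector overriding
#'   \code{\link{defaultColumnMap}} entries.
#' @param traitName,ancestry trait metadata (default: file basename).
#' @return a \linkS4class{SummaryDataset} with attribute \code{"validation"}.
#' @export
readSummaryStats <- function(path, columnMap = character(),
                             traitName = NULL, ancestry = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!nrow(df)) stop("empty file (no data rows): ", path)

  cmap <- defaultColumnMap()
  cmap[names(columnMap)] <- columnMap
  for (field in .REQUIRED_FIELDS)
    if (!cmap[[field]] %in% names(df))
      stop("missing required column for field '", field, "': expected '",
           cmap[[field]], "'")

  canon <- data.frame(snp_id = as.character(df[[cmap[["snp_id"]]]]),
                      stringsAsFactors = FALSE)
  grab <- function(field, as_fun, default) {
    col <- cmap[[field]]
    if (col %in% names(df)) as_fun(df[[col]]) else rep(default, nrow(df))
  }
  canon$chrom <- grab("chrom", as.character, NA_character_)
  canon$pos <- grab("pos", function(x) as.integer(round(as.numeric(x))),
                    NA_integer_)
  canon$effect_allele <- toupper(as.character(df[[cmap[["effect_allele"]]]]))
  canon$other_allele <- toupper(as.character(df[[cmap[["other_allele"]]]]))
  canon$eaf <- grab("eaf", as.numeric, NA_real_)
  canon$beta <- as.numeric(df[[cmap[["beta"]]]])
  canon$se <- as.numeric(df[[cmap[["se"]]]])
  canon$pval <- as.numeric(df[[cmap[["pval"]]]])
  canon$n <- grab("n", as.numeric, NA_real_)

  v <- .validateRows(canon)
  ds <- summaryDataset(v$kept,
                       traitName = if (is.null(traitName))
                         sub("\\.[^.]*$", "", basename(path)) else traitName,
                       ancestry = ancestry, sourceId = path)
  attr(ds, "validation") <- list(rows_read = nrow(canon),
                                 rows_kept = nrow(v$kept),
                                 rows_dropped = nrow(v$dropped),
                                 dropped = v$dropped)
  ds
}

#' @rdname readSummaryStats
#' @param dataset a SummaryDataset returned by \code{readSummaryStats}.
#' @export
validationSummary <- function(dataset) attr(dataset, "validation")

.isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure instruments against an outcome GWAS
#'
#' Matches variants by rsID and expresses exposure and outcome effects
#' relative to the same effect allele. Where the outcome's allele labels are
#' swapped relative to the exposure, the outcome beta sign is flipped (and its
#' allele frequency complemented). Palindromic variants (A/T or C/G) are
#' removed unconditionally — the alleles alone cannot resolve strand — as are
#' variants with incompatible allele pairs or absent from the outcome. Every
#' exclusion is logged with a reason.
#'
#' @param exposure an \linkS4class{InstrumentSet} or
#'   \linkS4class{SummaryDataset} (the instruments).
#' @param outcome a \linkS4class{SummaryDataset}.
#' @return a \linkS4class{HarmonizedSet}.
#' @export
harmonize <- function(exposure, outcome) {
  exp_rec <- if (is(exposure, "InstrumentSet")) exposure@records
             else records(exposure)
  exp_name <- if (is(exposure, "InstrumentSet")) exposure@exposureName
              else traitName(exposure)
  out_rec <- records(outcome)

  n <- nrow(exp_rec)
  reason <- rep(NA_character_, n)

  pal <- .isPalindromic(exp_rec$effect_allele, exp_rec$other_allele)
  reason[pal] <- "palindromic"

  idx <- match(exp_rec$snp_id, out_rec$snp_id)
  reason[is.na(reason) & is.na(idx)] <- "not found in outcome"

  ea_o <- out_rec$effect_allele[idx]
  oa_o <- out_rec$other_allele[idx]
  direct <- !is.na(idx) & ea_o == exp_rec$effect_allele &
    oa_o == exp_rec$other_allele
  swapped <- !is.na(idx) & ea_o == exp_rec$other_allele &
    oa_o == exp_rec$effect_allele
  reason[is.na(reason) & !(direct | swapped)] <- "ambiguous alleles"

  keep <- is.na(reason)
  beta_out <- out_rec$beta[idx]
  beta_out[swapped] <- -beta_out[swapped]

  rows <- data.frame(
    snp_id = exp_rec$snp_id[keep],
    beta_exp = exp_rec$beta[keep],
    se_exp = exp_rec$se[keep],
    beta_out = beta_out[keep],
    se_out = out_rec$se[idx][keep],
    eaf_exp = exp_rec$eaf[keep],
    stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  excl <- data.frame(snp_id = exp_rec$snp_id[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  if (!nrow(rows))
    stop("no usable instruments after harmonizing ", exp_name, " against ",
         traitName(outcome))
  new("HarmonizedSet", exposureName = exp_name,
      outcomeName = traitName(outcome), rows = rows, exclusionLog = excl)
}

#' Construct a HarmonizedSet directly from aligned effect tables
#'
#' For inputs already on a shared effect-allele orientation (e.g. simulated
#' exposure/outcome pairs from \code{\link{simulatePair}}, which share alleles
#' by construction). Skips allele matching; \code{\link{harmonize}} is the
#' entry point for real files.
#'
#' @param exposure,outcome \linkS4class{SummaryDataset}s with identical
#'   \code{snp_id} order, or data.frames with canonical columns.
#' @return a \linkS4class{HarmonizedSet} with an empty exclusion log.
#' @export
harmonizedFromPair <- function(exposure, outcome) {
  e <- if (is(exposure, "SummaryDataset")) exposure@records else exposure
  o <- if (is(outcome, "SummaryDataset")) outcome@records else outcome
  stopifnot(identical(e$snp_id, o$snp_id))
  rows <- data.frame(snp_id = e$snp_id, beta_exp = e$beta, se_exp = e$se,
                     beta_out = o$beta, se_out = o$se, eaf_exp = e$eaf,
                     stringsAsFactors = FALSE)
  new("HarmonizedSet",
      exposureName = if (is(exposure, "SummaryDataset"))
        exposure@traitName else "exposure",
      outcomeName = if (is(outcome, "SummaryDataset"))
        outcome@traitName else "outcome",
      rows = rows,
      exclusionLog = data.frame(snp_id = character(), reason = character(),
                                stringsAsFactors = FALSE))
}

#' Write / read a HarmonizedSet as TSV
#'
#' \code{writeHarmonized} writes the harmonized rows to \code{path} and the
#' exclusion log to a \code{<path>.exclusions.tsv} sidecar;
#' \code{readHarmonized} round-trips them.
#'
#' @param h a \linkS4class{HarmonizedSet}.
#' @param path output TSV path.
#' @export
writeHarmonized <- function(h, path) {
  utils::write.table(h@rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(h@exclusionLog, paste0(path, ".exclusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHarmonized
#' @param exposureName,outcomeName labels to restore on read.
#' @export
readHarmonized <- function(path, exposureName = "exposure",
                           outcomeName = "outcome") {
  rows <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".exclusions.tsv")
  excl <- if (file.exists(side))
    utils::read.delim(side, stringsAsFactors = FALSE,
                      colClasses = c("character", "character"))
  else data.frame(snp_id = character(), reason = character())
  if (!"eaf_exp" %in% names(rows)) rows$eaf_exp <- NA_real_
  new("HarmonizedSet", exposureName = exposureName,
      outcomeName = outcomeName, rows = rows, exclusionLog = excl)
}

#' Write a SummaryDataset in the package's canonical TSV dialect
#'
#' Uses GWAS Catalog harmonized column names so the file is re-readable by
#' \code{\link{readSummaryStats}} with the default column map.
#'
#' @param dataset a \linkS4class{SummaryDataset}.
#' @param path output TSV path.
#' @export
writeSummaryDataset <- function(dataset, path) {
  rec <- records(dataset)
  cmap <- defaultColumnMap()
  names(rec) <- cmap[names(rec)]
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
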