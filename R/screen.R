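#' Bonferroni adjustment with an explicit family size
#'
#' \code{min(1, p * m)} per p-value, via \code{stats::p.adjust}. The family
#' size is an explicit argument (and is printed in the screen report)
#' because the screening verdicts depend on it directly.
#'
#' @param pvals p-values in (0, 1].
#' @param m family size (>= 1; default: \code{length(pvals)}).
#' @return adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (m < 1) stop("family size m must be >= 1")
  if (any(pvals <= 0 | pvals > 1)) stop("pvals must lie in (0, 1]")
  p.adjust(pvals, method = "bonferroni", n = max(m, length(pvals)))
}

.verdict <- function(praw, pbonf, alpha = 0.05) {
  ifelse(pbonf < alpha, "strong",
         ifelse(praw < alpha, "potential", "null"))
}

# one exposure-outcome analysis: harmonize, estimate, diagnose; returns the
# per-outcome building block of a screen row
.analysePair <- function(instr, outcome, seed, nBoot = 1000L,
                         nSim = 1000L, sensitivity = TRUE,
                         methods = c("all", "ivw")) {
  methods <- match.arg(methods)
  h <- harmonize(instr, outcome)
  if (methods == "ivw") {
    res <- if (nSnp(h) >= 2) list(ivw = mrIVW(h)) else
      list(wald_ratio = with(h@rows, mrWaldRatio(beta_exp, se_exp,
                                                 beta_out, se_out)))
    attr(res, "direction_consistent") <- TRUE
    sens <- NULL
    corrected <- NULL
  } else {
    res <- mrAllMethods(h, seed = seed, nBoot = nBoot)
    sens <- NULL
    corrected <- NULL
    if (sensitivity) {
      pr <- if (nSnp(h) >= 4) mrPresso(h, nSim = nSim, seed = seed + 7L)
            else NULL
      sens <- sensitivitySummary(h, nSim = nSim, seed = seed + 7L,
                                 presso = pr)
      # when outliers are flagged, re-estimate without them and report both
      if (!is.null(pr) && nrow(pr@outliers)) corrected <- pr@corrected
    }
  }
  primary <- res[[if ("ivw" %in% names(res)) "ivw" else 1L]]
  list(h = h, results = res, primary = primary, sensitivity = sens,
       corrected = corrected,
       direction_consistent = attr(res, "direction_consistent"))
}

# per-outcome seeds derive from the outcome name, not its list position,
# so screen results are invariant to outcome ordering
.outcomeSeed <- function(seed, name)
  as.integer((seed + sum(utf8ToInt(name)) * 131L) %% .Machine$integer.max)

.screenCore <- function(instr, outcomes, config, seed, familySize,
                        nBoot, nSim, sensitivity, methods, direction) {
  details <- vector("list", length(outcomes))
  rows <- vector("list", length(outcomes))
  for (i in seq_along(outcomes)) {
    out <- outcomes[[i]]
    ans <- tryCatch(
      .analysePair(instr, out,
                   seed = .outcomeSeed(seed, traitName(out)),
                   nBoot = nBoot,
                   nSim = nSim, sensitivity = sensitivity,
                   methods = methods),
      error = function(e) e)
    if (inherits(ans, "error")) {
      rows[[i]] <- data.frame(
        exposure = instr@exposureName, outcome = traitName(out),
        direction = direction, status = "failed",
        n_snp = NA_integer_, beta = NA_real_, se = NA_real_,
        or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
        pval_raw = NA_real_, pval_bonferroni = NA_real_,
        verdict = NA_character_, direction_consistent = NA,
        error = conditionMessage(ans), stringsAsFactors = FALSE)
      details[[i]] <- list(error = conditionMessage(ans))
      next
    }
    p <- ans$primary
    rows[[i]] <- data.frame(
      exposure = instr@exposureName, outcome = traitName(out),
      direction = direction, status = "ok",
      n_snp = p@nSnp, beta = p@beta, se = p@se, or = p@or,
      or_ci_low = p@orCiLow, or_ci_high = p@orCiHigh,
      pval_raw = p@pval, pval_bonferroni = NA_real_,
      verdict = NA_character_,
      direction_consistent = ans$direction_consistent,
      error = NA_character_, stringsAsFactors = FALSE)
    details[[i]] <- ans
  }
  tab <- do.call(rbind, rows)
  ok <- tab$status == "ok"
  if (any(ok)) {
    tab$pval_bonferroni[ok] <- bonferroni(tab$pval_raw[ok], m = familySize)
    tab$verdict[ok] <- .verdict(tab$pval_raw[ok], tab$pval_bonferroni[ok])
  }
  names(details) <- tab$outcome
  list(table = tab, details = details, familySize = familySize,
       instruments = instr)
}

#' Forward screen: one exposure against a family of outcomes
#'
#' Builds instruments for the exposure once (p-value threshold with
#' fallback, LD clumping, F filter), then for every outcome: harmonize,
#' run the estimator battery, run the sensitivity suite, and — when
#' MR-PRESSO flags outliers — also report the outlier-corrected IVW
#' estimate. Raw IVW p-values are Bonferroni-adjusted with family size
#' \code{familySize} (default: the number of outcomes) and classed
#' \code{strong} (adjusted p < 0.05), \code{potential} (raw p < 0.05 only)
#' or \code{null}. Outcome-level failures are recorded as
#' \code{status = "failed"} rows, never fatal to the screen.
#'
#' @param exposure a \linkS4class{SummaryDataset}.
#' @param outcomes list of \linkS4class{SummaryDataset}s.
#' @param ld an \linkS4class{LDMatrix} for the exposure's variants.
#' @param config a \linkS4class{SelectionConfig}.
#' @param seed RNG seed.
#' @param familySize Bonferroni family size (default
#'   \code{length(outcomes)}).
#' @param nBoot bootstrap replicates for median/mode SEs.
#' @param nSim MR-PRESSO simulation count.
#' @param sensitivity run the sensitivity suite (default TRUE).
#' @param methods \code{"all"} for the full battery or \code{"ivw"} for the
#'   primary estimator only (used by large calibration studies).
#' @return list with \code{table} (one row per outcome), \code{details}
#'   (per-outcome results and diagnostics), \code{familySize},
#'   \code{instruments}.
#' @export
runForwardScreen <- function(exposure, outcomes, ld,
                             config = selectionConfig(), seed,
                             familySize = length(outcomes),
                             nBoot = 1000L, nSim = 1000L,
                             sensitivity = TRUE, methods = "all") {
  if (missing(seed)) stop("seed is required")
  if (!length(outcomes)) {
    warning("empty outcome list")
    return(list(table = NULL, details = list(),
                familySize = familySize, instruments = NULL))
  }
  instr <- buildInstruments(exposure, ld, config)
  .screenCore(instr, outcomes, config, seed, familySize, nBoot, nSim,
              sensitivity, methods, direction = "forward")
}

#' Reverse screen: each outcome as exposure, the exposure as outcome
#'
#' The same machinery with roles swapped: instruments are selected per
#' reverse-exposure (with the same primary/fallback thresholds and F
#' filter) and tested against the original exposure trait. Reverse
#' exposures whose instruments cannot be built are recorded as failed rows.
#'
#' @param outcomes list of \linkS4class{SummaryDataset}s, each used as an
#'   exposure in turn.
#' @param exposure the original exposure, now the outcome.
#' @param lds an \linkS4class{LDMatrix} shared by all reverse exposures, or
#'   a list of one per outcome.
#' @inheritParams runForwardScreen
#' @return as \code{\link{runForwardScreen}} with
#'   \code{direction = "reverse"}; \code{instruments} is a per-trait list.
#' @export
runReverseScreen <- function(outcomes, exposure, lds,
                             config = selectionConfig(), seed,
                             familySize = length(outcomes),
                             nBoot = 1000L, nSim = 1000L,
                             sensitivity = TRUE, methods = "all") {
  if (missing(seed)) stop("seed is required")
  rows <- list(); details <- list(); instrs <- list()
  for (i in seq_along(outcomes)) {
    revExp <- outcomes[[i]]
    ld_i <- if (is(lds, "LDMatrix")) lds else lds[[i]]
    one <- tryCatch({
      instr <- buildInstruments(revExp, ld_i, config)
      instrs[[traitName(revExp)]] <- instr
      .screenCore(instr, list(exposure), config,
                  .outcomeSeed(seed, traitName(revExp)),
                  familySize, nBoot, nSim, sensitivity, methods,
                  direction = "reverse")
    }, error = function(e) e)
    if (inherits(one, "error")) {
      rows[[i]] <- data.frame(
        exposure = traitName(revExp), outcome = traitName(exposure),
        direction = "reverse", status = "failed", n_snp = NA_integer_,
        beta = NA_real_, se = NA_real_, or = NA_real_,
        or_ci_low = NA_real_, or_ci_high = NA_real_, pval_raw = NA_real_,
        pval_bonferroni = NA_real_, verdict = NA_character_,
        direction_consistent = NA, error = conditionMessage(one),
        stringsAsFactors = FALSE)
      details[[traitName(revExp)]] <- list(error = conditionMessage(one))
    } else {
      rows[[i]] <- one$table
      details[[traitName(revExp)]] <- one$details[[1]]
    }
  }
  tab <- do.call(rbind, rows)
  ok <- tab$status == "ok"
  if (any(ok)) {
    tab$pval_bonferroni[ok] <- bonferroni(tab$pval_raw[ok], m = familySize)
    tab$verdict[ok] <- .verdict(tab$pval_raw[ok], tab$pval_bonferroni[ok])
  }
  list(table = tab, details = details, familySize = familySize,
       instruments = instrs)
}

#' Two-step mediator screen with mediation decomposition
#'
#' Step A: every mediator is tested against the outcome (mediator
#' instruments at the relaxed \code{pMediator} threshold); survivors need
#' IVW p < 0.05 and, by default, direction-consistent secondary estimators.
#' Step B: the exposure is tested against each survivor (exposure
#' instruments at the primary/fallback thresholds); survivors need
#' p < 0.05. Step C: each double survivor enters
#' \code{\link{mrMediate}} together with the exposure-outcome total
#' effect. The full audit trail (per-step tables and per-mediator
#' failure reasons) is returned.
#'
#' @param exposure,outcome \linkS4class{SummaryDataset}s.
#' @param mediators list of \linkS4class{SummaryDataset}s.
#' @param ld an \linkS4class{LDMatrix} covering all traits' variants, or a
#'   list with entries \code{exposure} and per-mediator matrices.
#' @param config a \linkS4class{SelectionConfig}.
#' @param seed RNG seed.
#' @param requireConsistent require all estimators to share the IVW sign in
#'   step A (default TRUE).
#' @param nBoot,nSim as in \code{\link{runForwardScreen}}.
#' @return list: \code{stepA}, \code{stepB} (data.frames),
#'   \code{mediation} (data.frame from \code{\link{mediationTable}}),
#'   \code{total} (the exposure-outcome \linkS4class{MRResult}),
#'   \code{log} (per-mediator dispositions).
#' @export
runMediatorScreen <- function(exposure, mediators, outcome, ld,
                              config = selectionConfig(), seed,
                              requireConsistent = TRUE, nBoot = 1000L,
                              nSim = 1000L) {
  if (missing(seed)) stop("seed is required")
  ldFor <- function(name) {
    if (is(ld, "LDMatrix")) ld
    else if (name %in% names(ld)) ld[[name]]
    else ld[["exposure"]]
  }
  instrExp <- buildInstruments(exposure, ldFor("exposure"), config)
  total <- mrIVW(harmonize(instrExp, outcome))

  log <- list(); stepA <- list(); stepB <- list(); medRes <- list()
  medNames <- vapply(mediators, traitName, character(1))
  step2Fits <- list()
  for (i in seq_along(mediators)) {
    med <- mediators[[i]]
    nm <- medNames[i]
    a <- tryCatch({
      instrMed <- buildInstruments(med, ldFor(nm), config,
                                   pOverride = config@pMediator)
      hA <- harmonize(instrMed, outcome)
      resA <- mrAllMethods(hA, seed = seed + i, nBoot = nBoot)
      list(instr = instrMed, res = resA)
    }, error = function(e) e)
    if (inherits(a, "error")) {
      log[[nm]] <- paste("step A failed:", conditionMessage(a))
      next
    }
    pA <- a$res[[if ("ivw" %in% names(a$res)) "ivw" else 1L]]
    consistent <- attr(a$res, "direction_consistent")
    stepA[[nm]] <- data.frame(mediator = nm, beta = pA@beta, se = pA@se,
                              pval = pA@pval, n_snp = pA@nSnp,
                              direction_consistent = consistent,
                              stringsAsFactors = FALSE)
    if (pA@pval >= 0.05) { log[[nm]] <- "step A: not associated"; next }
    if (requireConsistent && !consistent) {
      log[[nm]] <- "step A: inconsistent direction"; next
    }
    step2Fits[[nm]] <- pA

    b <- tryCatch({
      hB <- harmonize(instrExp, med)
      if (nSnp(hB) >= 2) mrIVW(hB)
      else with(hB@rows, mrWaldRatio(beta_exp, se_exp, beta_out, se_out))
    }, error = function(e) e)
    if (inherits(b, "error")) {
      log[[nm]] <- paste("step B failed:", conditionMessage(b))
      next
    }
    stepB[[nm]] <- data.frame(mediator = nm, beta = b@beta, se = b@se,
                              pval = b@pval, n_snp = b@nSnp,
                              stringsAsFactors = FALSE)
    if (b@pval >= 0.05) { log[[nm]] <- "step B: not associated"; next }

    medRes[[nm]] <- mrMediate(total, step1 = b, step2 = pA)
    log[[nm]] <- "mediation candidate"
  }
  list(stepA = if (length(stepA)) do.call(rbind, stepA) else NULL,
       stepB = if (length(stepB)) do.call(rbind, stepB) else NULL,
       mediation = if (length(medRes))
         mediationTable(medRes, exposure = traitName(exposure),
                        mediators = names(medRes),
                        outcome = traitName(outcome)) else NULL,
       mediationResults = medRes, total = total, log = log)
}

#' Replication of a primary screen finding in an external cohort
#'
#' Re-runs the same exposure instruments against a replication outcome
#' GWAS; the finding replicates when the replication IVW p < 0.05 and the
#' estimate has the same sign as the primary one.
#'
#' @param primaryBeta the primary screen estimate (sign is compared).
#' @param instruments the primary \linkS4class{InstrumentSet}.
#' @param replicationOutcome a \linkS4class{SummaryDataset}.
#' @return list with \code{result} (the replication
#'   \linkS4class{MRResult}) and \code{verdict} ("replicated" /
#'   "not replicated").
#' @export
replicateFinding <- function(primaryBeta, instruments,
                             replicationOutcome) {
  h <- harmonize(instruments, replicationOutcome)
  res <- if (nSnp(h) >= 2) mrIVW(h)
  else with(h@rows, mrWaldRatio(beta_exp, se_exp, beta_out, se_out))
  ok <- res@pval < 0.05 && sign(res@beta) == sign(primaryBeta)
  list(result = res, verdict = if (ok) "replicated" else "not replicated")
}
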