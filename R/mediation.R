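.asBetaSe <- function(x) {
  if (is(x, "MRResult")) return(c(beta = x@beta, se = x@se))
  if (is.numeric(x) && all(c("beta", "se") %in% names(x)))
    return(c(beta = unname(x["beta"]), se = unname(x["se"])))
  stop("expected an MRResult or a named numeric c(beta=, se=)")
}

#' Two-step mediation decomposition with delta-method uncertainty
#'
#' Product-of-coefficients decomposition of a total causal effect beta0
#' (exposure on outcome) through a mediator: indirect = beta1 * beta2
#' (exposure on mediator times mediator on outcome), direct =
#' beta0 - beta1 * beta2, proportion mediated = (beta1 * beta2) / beta0.
#' First-order delta-method SEs assuming zero covariance between the two
#' step estimates (they come from non-overlapping GWAS samples):
#' \code{se_ind = sqrt(beta1^2 se2^2 + beta2^2 se1^2)} (optionally adding
#' the second-order \code{se1^2 se2^2} term), and for the proportion
#' \code{sqrt((se_ind/beta0)^2 + (ind * se0 / beta0^2)^2)}. 95\% CIs are
#' \code{estimate +- 1.96 se}; the indirect p is two-sided normal. A
#' proportion with sign opposite the total effect indicates suppression
#' (the mediated path opposes the total effect).
#'
#' @param total,step1,step2 \linkS4class{MRResult}s (or named numerics
#'   \code{c(beta=, se=)}): exposure-outcome, exposure-mediator and
#'   mediator-outcome estimates on the log scale.
#' @param secondOrder add the \code{se1^2 se2^2} term to the indirect-effect
#'   variance (default FALSE).
#' @return a \linkS4class{MediationResult}. When the total effect is exactly
#'   zero the proportion fields are NA and \code{proportionDefined} is
#'   FALSE; indirect and direct are still returned.
#' @export
mrMediate <- function(total, step1, step2, secondOrder = FALSE) {
  t0 <- .asBetaSe(total); s1 <- .asBetaSe(step1); s2 <- .asBetaSe(step2)
  if (s1["se"] <= 0 || s2["se"] <= 0 || t0["se"] <= 0)
    stop("all standard errors must be positive")
  b0 <- t0["beta"]; b1 <- s1["beta"]; b2 <- s2["beta"]
  se0 <- t0["se"]; se1 <- s1["se"]; se2 <- s2["se"]

  indirect <- b1 * b2
  v <- b1^2 * se2^2 + b2^2 * se1^2
  if (secondOrder) v <- v + se1^2 * se2^2
  indSe <- sqrt(v)
  z <- 1.96
  indP <- if (indSe > 0) .twoSided(indirect / indSe) else
    if (indirect == 0) 1 else .Machine$double.xmin

  defined <- b0 != 0
  if (defined) {
    prop <- indirect / b0
    propSe <- sqrt((indSe / b0)^2 + (indirect * se0 / b0^2)^2)
    propLo <- prop - z * propSe
    propHi <- prop + z * propSe
  } else {
    prop <- propSe <- propLo <- propHi <- NA_real_
  }
  new("MediationResult",
      betaTotal = unname(b0), betaStep1 = unname(b1),
      betaStep2 = unname(b2),
      se0 = unname(se0), se1 = unname(se1), se2 = unname(se2),
      indirect = unname(indirect), indirectSe = unname(indSe),
      indirectCiLow = unname(indirect - z * indSe),
      indirectCiHigh = unname(indirect + z * indSe),
      indirectPval = unname(indP),
      direct = unname(b0 - indirect),
      proportion = unname(prop), proportionSe = unname(propSe),
      proportionCiLow = unname(propLo), proportionCiHigh = unname(propHi),
      proportionDefined = defined)
}

#' Monte-Carlo coverage of the delta-method CI for a product of coefficients
#'
#' Validation harness for the first-order delta interval on
#' \code{beta1 * beta2}: draws step estimates from normals around the true
#' values, forms the delta CI each draw, and reports the fraction covering
#' the true product. Near \code{beta1 = beta2 = 0} the first-order interval
#' is known to over- or under-cover; this makes that measurable.
#'
#' @param beta1,beta2 true step effects.
#' @param se1,se2 their sampling SDs.
#' @param nReps Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return the coverage fraction.
#' @export
mediationCiCoverage <- function(beta1, beta2, se1, se2, nReps = 5000L,
                                seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  b1 <- rnorm(nReps, beta1, se1)
  b2 <- rnorm(nReps, beta2, se2)
  ind <- b1 * b2
  se <- sqrt(b1^2 * se2^2 + b2^2 * se1^2)
  truth <- beta1 * beta2
  mean(ind - 1.96 * se <= truth & truth <= ind + 1.96 * se)
}

#' Flatten MediationResults to the mediation report table
#'
#' @param results list of \linkS4class{MediationResult}.
#' @param exposure,mediators,outcome labels (mediators recycled per row).
#' @return data.frame, one row per (exposure, mediator, outcome) triple.
#' @export
mediationTable <- function(results, exposure = NA_character_,
                           mediators = NA_character_,
                           outcome = NA_character_) {
  do.call(rbind, Map(function(x, med) data.frame(
    exposure = exposure, mediator = med, outcome = outcome,
    beta_total = x@betaTotal, beta_step1 = x@betaStep1,
    beta_step2 = x@betaStep2, se0 = x@se0, se1 = x@se1, se2 = x@se2,
    indirect = x@indirect, indirect_se = x@indirectSe,
    indirect_ci_low = x@indirectCiLow, indirect_ci_high = x@indirectCiHigh,
    indirect_pval = x@indirectPval, direct = x@direct,
    proportion = x@proportion, proportion_se = x@proportionSe,
    proportion_ci_low = x@proportionCiLow,
    proportion_ci_high = x@proportionCiHigh,
    stringsAsFactors = FALSE, row.names = NULL),
    results, mediators))
}
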