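# ---- internal closed-form fits ------------------------------------------
# All estimators consume per-SNP (bx, by, se_out [, se_exp]) vectors from a
# HarmonizedSet. Inverse-variance weights are 1/se_out^2 throughout; the
# multiplicative random-effects scale is floored at 1 (under-dispersion is
# never allowed to shrink SEs).

.twoSided <- function(z) pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
.twoSidedT <- function(t, df) pmax(2 * pt(-abs(t), df), .Machine$double.xmin)

.mkResult <- function(method, beta, se, pval, nSnp, ciLow, ciHigh,
                      intercept = NA_real_, interceptSe = NA_real_,
                      interceptPval = NA_real_) {
  new("MRResult", method = method, beta = beta, se = se,
      ciLow = ciLow, ciHigh = ciHigh, pval = pval,
      or = exp(beta), orCiLow = exp(ciLow), orCiHigh = exp(ciHigh),
      nSnp = as.integer(nSnp), intercept = intercept,
      interceptSe = interceptSe, interceptPval = interceptPval)
}

# IVW through the origin, multiplicative random effects floored at 1
.ivwFit <- function(bx, by, seo) {
  w <- 1 / seo^2
  swxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / swxx
  m <- length(bx)
  resid <- by - beta * bx
  sigma <- if (m > 1) sqrt(sum(w * resid^2) / (m - 1)) else 1
  se <- sqrt(1 / swxx) * max(1, sigma)
  list(beta = beta, se = se, sigma = sigma)
}

# weighted regression with intercept; rows oriented so bx >= 0
.eggerFit <- function(bx, by, seo) {
  flip <- bx < 0
  bx[flip] <- -bx[flip]
  by[flip] <- -by[flip]
  w <- 1 / seo^2
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  denom <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swy * swxx - swx * swxy) / denom
  m <- length(bx)
  resid <- by - intercept - slope * bx
  sigma <- sqrt(sum(w * resid^2) / (m - 2))
  scale <- max(1, sigma)
  list(slope = slope, intercept = intercept,
       slopeSe = sqrt(sw / denom) * scale,
       interceptSe = sqrt(swxx / denom) * scale,
       df = m - 2)
}

.ratioWeights <- function(h) {
  r <- h@rows
  list(ratio = r$beta_out / r$beta_exp,
       w = r$beta_exp^2 / r$se_out^2)
}

.weightedMedianEst <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(ratio[1])
  if (s[length(s)] <= 0.5) return(ratio[length(s)])
  below <- max(which(s < 0.5))
  ratio[below] + (ratio[below + 1] - ratio[below]) *
    (0.5 - s[below]) / (s[below + 1] - s[below])
}

.silvermanBandwidth <- function(ratio, factor = 1) {
  m <- length(ratio)
  cand <- c(sd(ratio), IQR(ratio) / 1.34)
  cand <- cand[is.finite(cand) & cand > 0]
  if (!length(cand)) return(0)
  factor * 0.9 * min(cand) * m^(-1 / 5)
}

.weightedModeEst <- function(ratio, w, bandwidthFactor = 1, nGrid = 2001L) {
  h <- .silvermanBandwidth(ratio, bandwidthFactor)
  if (h == 0) return(ratio[1])
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = nGrid)
  w <- w / sum(w)
  dens <- colSums(w * exp(-0.5 * (outer(ratio, grid, "-") / h)^2))
  grid[which.max(dens)]
}

# parametric bootstrap SE shared by weighted median/mode: resample effect
# estimates from normals centred on the observed values, recompute the
# point estimate each draw
.bootstrapSe <- function(h, estFun, nBoot, seed) {
  r <- h@rows
  m <- nrow(r)
  set.seed(seed)
  est <- vapply(seq_len(nBoot), function(i) {
    bx <- rnorm(m, r$beta_exp, r$se_exp)
    by <- rnorm(m, r$beta_out, r$se_out)
    bx[bx == 0] <- .Machine$double.eps
    estFun(by / bx, bx^2 / r$se_out^2)
  }, numeric(1))
  sd(est)
}

# ---- exported estimators -------------------------------------------------

#' Wald ratio: single-variant causal estimate
#'
#' \code{beta = beta_out / beta_exp}; first-order SE
#' \code{se_out / |beta_exp|} (ignoring exposure uncertainty), or the
#' second-order expansion including it when \code{secondOrder = TRUE}.
#' Normal-approximation CI and two-sided p.
#'
#' @param betaExp,seExp exposure association and SE.
#' @param betaOut,seOut outcome association and SE.
#' @param secondOrder include the exposure-uncertainty term in the SE.
#' @return an \linkS4class{MRResult} with method \code{"wald_ratio"}.
#' @export
mrWaldRatio <- function(betaExp, seExp, betaOut, seOut,
                        secondOrder = FALSE) {
  if (betaExp == 0) stop("null instrument: beta_exp is zero")
  beta <- betaOut / betaExp
  se <- if (secondOrder)
    sqrt(seOut^2 / betaExp^2 + betaOut^2 * seExp^2 / betaExp^4)
  else seOut / abs(betaExp)
  z <- qnorm(0.975)
  .mkResult("wald_ratio", beta, se, .twoSided(beta / se), 1L,
            beta - z * se, beta + z * se)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome on exposure associations through the
#' origin, weights \code{1/se_out^2} — equivalently the inverse-variance
#' meta-analysis of per-variant Wald ratios. The SE uses a multiplicative
#' random-effects scale \code{max(1, sigma)} where \code{sigma^2} is the
#' weighted residual variance on \code{n_snp - 1} df, so heterogeneity
#' inflates but under-dispersion never deflates it. p from the standard
#' normal.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 2 variants.
#' @return an \linkS4class{MRResult} with method \code{"ivw"}.
#' @export
mrIVW <- function(h) {
  r <- h@rows
  if (nrow(r) < 2)
    stop("ivw needs >= 2 instruments; use mrWaldRatio for a single variant")
  fit <- .ivwFit(r$beta_exp, r$beta_out, r$se_out)
  z <- qnorm(0.975)
  .mkResult("ivw", fit$beta, fit$se, .twoSided(fit$beta / fit$se),
            nrow(r), fit$beta - z * fit$se, fit$beta + z * fit$se)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure associations \emph{with} an
#' intercept, after orienting every variant so its exposure effect is
#' non-negative. The slope estimates the causal effect allowing directional
#' pleiotropy; the intercept estimates the average pleiotropic effect (zero
#' under no directional pleiotropy / InSIDE). SEs carry the same
#' \code{max(1, sigma)} multiplicative scale as \code{\link{mrIVW}};
#' slope and intercept p-values use the t distribution on \code{n_snp - 2}
#' df.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 3 variants.
#' @return an \linkS4class{MRResult} with method \code{"egger"} and the
#'   intercept slots populated.
#' @export
mrEgger <- function(h) {
  r <- h@rows
  if (nrow(r) < 3) stop("egger requires >= 3 instruments")
  fit <- .eggerFit(r$beta_exp, r$beta_out, r$se_out)
  tq <- qt(0.975, fit$df)
  .mkResult("egger", fit$slope, fit$slopeSe,
            .twoSidedT(fit$slope / fit$slopeSe, fit$df), nrow(r),
            fit$slope - tq * fit$slopeSe, fit$slope + tq * fit$slopeSe,
            intercept = fit$intercept, interceptSe = fit$interceptSe,
            interceptPval = .twoSidedT(fit$intercept / fit$interceptSe,
                                       fit$df))
}

#' Weighted-median estimator
#'
#' Consistent when at least half the total weight comes from valid
#' instruments. Per-variant Wald ratios are sorted and the estimate
#' interpolates the weighted cumulative distribution (midpoint convention
#' \code{s_j - w_j/2}) at probability one half, with inverse-variance
#' weights \code{beta_exp^2 / se_out^2}. SE by parametric bootstrap:
#' exposure and outcome associations are redrawn from normals centred on
#' the observed values and the estimate recomputed.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 3 variants.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (required).
#' @return an \linkS4class{MRResult} with method \code{"weighted_median"}.
#' @export
mrWeightedMedian <- function(h, nBoot = 1000L, seed) {
  r <- h@rows
  if (nrow(r) < 3) stop("weighted median requires >= 3 instruments")
  if (nBoot > 0L && missing(seed)) stop("seed is required for the bootstrap")
  rw <- .ratioWeights(h)
  beta <- .weightedMedianEst(rw$ratio, rw$w)
  if (nBoot == 0L)   # point estimate only (large calibration studies)
    return(.mkResult("weighted_median", beta, NA_real_, NA_real_, nrow(r),
                     NA_real_, NA_real_))
  se <- .bootstrapSe(h, .weightedMedianEst, nBoot, seed)
  z <- qnorm(0.975)
  .mkResult("weighted_median", beta, se, .twoSided(beta / se), nrow(r),
            beta - z * se, beta + z * se)
}

#' Weighted-mode estimator
#'
#' Assumes the largest group of variants sharing a common ratio are the
#' valid ones (zero modal pleiotropy). A Gaussian kernel density with
#' Silverman bandwidth (\code{0.9 min(sd, IQR/1.34) m^(-1/5)}, scaled by
#' \code{bandwidthFactor}) is placed over the per-variant ratios with
#' inverse-variance kernel masses; the estimate is the density argmax on a
#' 2001-point grid spanning the ratio range plus three bandwidths. SE by
#' the same parametric bootstrap as \code{\link{mrWeightedMedian}}. When
#' all ratios coincide the bandwidth degenerates to zero and the common
#' ratio is returned with zero SE.
#'
#' @inheritParams mrWeightedMedian
#' @param bandwidthFactor multiplier on the Silverman bandwidth (default 1).
#' @return an \linkS4class{MRResult} with method \code{"weighted_mode"}.
#' @export
mrWeightedMode <- function(h, bandwidthFactor = 1, nBoot = 1000L, seed) {
  r <- h@rows
  if (nrow(r) < 3) stop("weighted mode requires >= 3 instruments")
  if (nBoot > 0L && missing(seed)) stop("seed is required for the bootstrap")
  rw <- .ratioWeights(h)
  if (.silvermanBandwidth(rw$ratio, bandwidthFactor) == 0) {
    beta <- rw$ratio[1]
    return(.mkResult("weighted_mode", beta, 0, 1, nrow(r), beta, beta))
  }
  est <- function(ratio, w) .weightedModeEst(ratio, w, bandwidthFactor)
  beta <- est(rw$ratio, rw$w)
  if (nBoot == 0L)
    return(.mkResult("weighted_mode", beta, NA_real_, NA_real_, nrow(r),
                     NA_real_, NA_real_))
  se <- .bootstrapSe(h, est, nBoot, seed)
  z <- qnorm(0.975)
  .mkResult("weighted_mode", beta, se, .twoSided(beta / se), nrow(r),
            beta - z * se, beta + z * se)
}

#' Run the estimator battery appropriate to the instrument count
#'
#' One variant: Wald ratio only. Two: IVW only. Three or more: IVW,
#' MR-Egger, weighted median and weighted mode. Also reports whether all
#' estimates share the sign of the IVW estimate
#' (\code{attr(result, "direction_consistent")}), the usual robustness
#' check on the supplementary estimators.
#'
#' @param h a \linkS4class{HarmonizedSet}.
#' @param seed RNG seed for bootstrap SEs.
#' @param nBoot bootstrap replicates for median/mode SEs.
#' @return named list of \linkS4class{MRResult}s with attribute
#'   \code{direction_consistent}.
#' @export
mrAllMethods <- function(h, seed, nBoot = 1000L) {
  r <- h@rows
  m <- nrow(r)
  if (!m) stop("empty harmonized set")
  if (m == 1L) {
    res <- list(wald_ratio = mrWaldRatio(r$beta_exp, r$se_exp,
                                         r$beta_out, r$se_out))
  } else if (m == 2L) {
    res <- list(ivw = mrIVW(h))
  } else {
    res <- list(ivw = mrIVW(h),
                egger = mrEgger(h),
                weighted_median = mrWeightedMedian(h, nBoot, seed),
                weighted_mode = mrWeightedMode(h, nBoot = nBoot,
                                               seed = seed + 1L))
  }
  ref <- sign(mrBeta(res[[1]]))
  attr(res, "direction_consistent") <-
    all(vapply(res, function(x) sign(mrBeta(x)) == ref, logical(1)))
  res
}

#' Flatten MR results to a one-row-per-method data.frame
#'
#' The serialization used by the master results table: one row per
#' (exposure, outcome, method) with estimate, SE, CI, p, OR and instrument
#' count.
#'
#' @param results list of \linkS4class{MRResult} (e.g. from
#'   \code{\link{mrAllMethods}}).
#' @param exposure,outcome trait labels for the table.
#' @return data.frame.
#' @export
mrResultsTable <- function(results, exposure = NA_character_,
                           outcome = NA_character_) {
  do.call(rbind, lapply(results, function(x) data.frame(
    exposure = exposure, outcome = outcome, method = x@method,
    beta = x@beta, se = x@se, ci_low = x@ciLow, ci_high = x@ciHigh,
    pval = x@pval, or = x@or, or_ci_low = x@orCiLow,
    or_ci_high = x@orCiHigh, n_snp = x@nSnp,
    intercept = x@intercept, intercept_se = x@interceptSe,
    intercept_pval = x@interceptPval,
    stringsAsFactors = FALSE, row.names = NULL)))
}
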