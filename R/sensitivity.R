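#' Cochran's Q heterogeneity test
#'
#' Heterogeneity across per-variant Wald ratios: with first-order ratio SEs
#' \code{se_out/|beta_exp|} and weights their inverse squares, Q is the
#' weighted sum of squared deviations of each ratio from the fixed-effect
#' weighted mean, referred to a chi-square on \code{n_snp - 1} df. Large Q
#' signals that instruments disagree about the causal effect (heterogeneity,
#' often pleiotropy).
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 2 variants.
#' @return a \linkS4class{QResult}.
#' @export
cochranQ <- function(h) {
  r <- h@rows
  if (nrow(r) < 2) stop("Cochran's Q needs >= 2 instruments")
  rw <- .ratioWeights(h)
  bfix <- sum(rw$w * rw$ratio) / sum(rw$w)
  q <- sum(rw$w * (rw$ratio - bfix)^2)
  df <- nrow(r) - 1L
  new("QResult", q = q, df = df,
      pval = pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the Egger regression estimates the average direct
#' (pleiotropic) effect of the instruments on the outcome; an intercept
#' distinguishable from zero (conventionally p < 0.05) indicates directional
#' pleiotropy biasing the IVW estimate.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 3 variants.
#' @return list with \code{intercept}, \code{se}, \code{pval}.
#' @export
eggerInterceptTest <- function(h) {
  fit <- mrEgger(h)
  list(intercept = fit@intercept, se = fit@interceptSe,
       pval = fit@interceptPval)
}

# simulate null datasets and all leave-one-out IVW slopes, vectorized over
# simulations: rows = simulations, columns = variants
.pressoSimRss <- function(bx, by, sex, seo, mu, nSim) {
  m <- length(bx)
  w <- 1 / seo^2
  B <- matrix(rnorm(nSim * m, rep(bx, each = nSim), rep(sex, each = nSim)),
              nSim, m)
  Y <- matrix(rnorm(nSim * m, rep(mu, each = nSim), rep(seo, each = nSim)),
              nSim, m)
  W <- matrix(w, nSim, m, byrow = TRUE)
  s1 <- rowSums(W * B * Y)
  s2 <- rowSums(W * B^2)
  betaLoo <- (s1 - W * B * Y) / (s2 - W * B^2)    # per-sim, per-variant
  res2 <- W * (Y - betaLoo * B)^2
  list(rss = rowSums(res2), perSnp = res2, B = B, Y = Y, W = W)
}

.ivwSlope <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)

#' MR-PRESSO: global heterogeneity, outlier and distortion tests
#'
#' Residual-sum-of-squares based pleiotropy diagnostics. For each variant j
#' the leave-one-out IVW slope is computed; the observed RSS is the weighted
#' sum of squared residuals of each variant from its own leave-one-out fit.
#' A simulated null (exposure and outcome associations redrawn from normals
#' centred on their leave-one-out predictions) gives: the global empirical p
#' (add-one smoothed); per-variant outlier p-values (each variant's observed
#' weighted squared residual against its simulated distribution,
#' Bonferroni-corrected across variants, flagged below \code{sig}); and a
#' distortion p comparing the raw IVW slope with the outlier-corrected one
#' against the simulated null distribution of that difference. The corrected
#' estimate is IVW on the unflagged variants.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 4 variants.
#' @param nSim simulation replicates for the empirical null (default 1000).
#' @param sig significance level for flagging outliers (default 0.05,
#'   applied to Bonferroni-corrected per-variant p-values).
#' @param seed RNG seed (required; results are reproducible given it).
#' @return a \linkS4class{PressoResult}.
#' @export
mrPresso <- function(h, nSim = 1000L, sig = 0.05, seed) {
  r <- h@rows
  m <- nrow(r)
  if (m < 4) stop("insufficient instruments for MR-PRESSO (need >= 4)")
  if (missing(seed)) stop("seed is required for MR-PRESSO")
  bx <- r$beta_exp; by <- r$beta_out
  sex <- r$se_exp; seo <- r$se_out
  w <- 1 / seo^2

  s1 <- sum(w * bx * by); s2 <- sum(w * bx^2)
  betaLoo <- (s1 - w * bx * by) / (s2 - w * bx^2)
  obsRes2 <- w * (by - betaLoo * bx)^2
  rssObs <- sum(obsRes2)

  set.seed(seed)
  sim <- .pressoSimRss(bx, by, sex, seo, mu = betaLoo * bx, nSim = nSim)
  globalPval <- (1 + sum(sim$rss >= rssObs)) / (1 + nSim)

  outlierPRaw <- (1 + colSums(sim$perSnp >=
                                matrix(obsRes2, nSim, m, byrow = TRUE))) /
    (1 + nSim)
  outlierP <- pmin(1, outlierPRaw * m)
  flagged <- which(outlierP < sig)

  outliers <- data.frame(snp_id = r$snp_id[flagged],
                         pval = outlierP[flagged],
                         stringsAsFactors = FALSE)

  keep <- setdiff(seq_len(m), flagged)
  corrected <- NULL
  distortionPval <- NA_real_
  if (length(keep) >= 2) {
    hKeep <- new("HarmonizedSet", exposureName = h@exposureName,
                 outcomeName = h@outcomeName,
                 rows = r[keep, , drop = FALSE],
                 exclusionLog = h@exclusionLog)
    corrected <- mrIVW(hKeep)
    if (length(flagged)) {
      dObs <- .ivwSlope(bx, by, w) - corrected@beta
      dSim <- vapply(seq_len(nSim), function(s) {
        .ivwSlope(sim$B[s, ], sim$Y[s, ], w) -
          .ivwSlope(sim$B[s, keep], sim$Y[s, keep], w[keep])
      }, numeric(1))
      distortionPval <- (1 + sum(abs(dSim) >= abs(dObs))) / (1 + nSim)
    }
  }
  new("PressoResult", globalRss = rssObs, globalPval = globalPval,
      outliers = outliers, corrected = corrected,
      distortionPval = distortionPval, nSim = as.integer(nSim),
      seed = as.integer(seed))
}

#' Leave-one-out IVW analysis
#'
#' Refits IVW with each instrument removed in turn. A variant is flagged as
#' influential when dropping it flips the sign of the estimate or moves it
#' by more than \code{flagMultiple} full-set standard errors.
#'
#' @param h a \linkS4class{HarmonizedSet} with at least 3 variants.
#' @param flagMultiple flag threshold in units of the full-set SE
#'   (default 1).
#' @return data.frame with one row per variant left out: \code{snp_id},
#'   \code{beta}, \code{se}, \code{pval}, \code{flagged}; the full-set
#'   \linkS4class{MRResult} is attached as attribute \code{"full"}.
#' @export
leaveOneOut <- function(h, flagMultiple = 1.0) {
  r <- h@rows
  m <- nrow(r)
  if (m < 3) stop("leave-one-out needs >= 3 instruments")
  full <- mrIVW(h)
  rows <- lapply(seq_len(m), function(j) {
    fit <- .ivwFit(r$beta_exp[-j], r$beta_out[-j], r$se_out[-j])
    data.frame(snp_id = r$snp_id[j], beta = fit$beta, se = fit$se,
               pval = .twoSided(fit$beta / fit$se),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- sign(out$beta) != sign(full@beta) |
    abs(out$beta - full@beta) > flagMultiple * full@se
  attr(out, "full") <- full
  out
}

#' One-row sensitivity summary for the report table
#'
#' @param h a \linkS4class{HarmonizedSet}.
#' @param nSim,sig,seed passed to \code{\link{mrPresso}} (skipped, with NA
#'   fields, when fewer than 4 variants).
#' @param presso optionally a precomputed \linkS4class{PressoResult} to
#'   report instead of rerunning the simulation.
#' @return one-row data.frame with Q, Egger intercept and MR-PRESSO fields.
#' @export
sensitivitySummary <- function(h, nSim = 1000L, sig = 0.05, seed,
                               presso = NULL) {
  m <- nrow(h@rows)
  q <- if (m >= 2) cochranQ(h) else NULL
  eg <- if (m >= 3) eggerInterceptTest(h) else NULL
  pr <- if (!is.null(presso)) presso
        else if (m >= 4) mrPresso(h, nSim = nSim, sig = sig, seed = seed)
        else NULL
  data.frame(
    exposure = h@exposureName, outcome = h@outcomeName, n_snp = m,
    q = if (is.null(q)) NA_real_ else q@q,
    q_pval = if (is.null(q)) NA_real_ else q@pval,
    egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept,
    intercept_pval = if (is.null(eg)) NA_real_ else eg$pval,
    presso_global_pval = if (is.null(pr)) NA_real_ else pr@globalPval,
    presso_outliers = if (is.null(pr)) NA_character_
      else paste(pr@outliers$snp_id, collapse = ","),
    distortion_pval = if (is.null(pr)) NA_real_ else pr@distortionPval,
    stringsAsFactors = FALSE)
}
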