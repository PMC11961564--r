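#' Simulation configuration for summary-level GWAS generation
#'
#' Encodes the data-generating model behind the instrumental-variable
#' assumptions: per-variant true effects on the exposure gamma_j ~
#' N(0, gammaSd^2); a fraction \code{pleioFrac} of instruments carry a
#' direct (pleiotropic) effect alpha_j on the outcome with mean
#' \code{pleioMean} and SD \code{pleioSd}, optionally correlated with
#' instrument strength (\code{insideViolation}, a Gaussian-copula
#' correlation with |gamma_j|; nonzero values violate InSIDE); observed
#' summary statistics are the true effects plus normal noise with
#' per-variant SE \code{1/sqrt(2 eaf (1-eaf) n)}, eaf ~ Uniform(0.1, 0.9).
#' Binary-trait outcomes are emulated directly on the log-odds scale.
#'
#' @param mSnps instrument count (default 50).
#' @param nExp,nMed,nOut GWAS sample sizes (default 100000).
#' @param gammaSd SD of true instrument effects (default 0.3, matching the
#'   large per-allele odds ratios typical of genome-wide-significant hits
#'   for strongly genetic autoimmune exposures).
#' @param theta total causal effect exposure -> outcome (default 0).
#' @param beta1,beta2 exposure -> mediator and mediator -> outcome effects
#'   for triad mode (default 0).
#' @param thetaDirect direct effect in triad mode; the total is then
#'   \code{thetaDirect + beta1 * beta2} (default 0).
#' @param pleioFrac fraction of invalid instruments (default 0).
#' @param pleioMean,pleioSd directional-pleiotropy distribution
#'   (default 0, 0.01).
#' @param insideViolation copula correlation between pleiotropy and
#'   instrument strength (default 0; InSIDE holds).
#' @param ldBlockSize,ldRho AR(1) LD-block structure for
#'   \code{\link{simulateLD}} (defaults 1, 0: independent variants).
#' @param seed default RNG seed for the simulate functions.
#' @return a validated \code{SimConfig} (S4).
#' @export
simConfig <- function(mSnps = 50L, nExp = 100000L, nMed = 100000L,
                      nOut = 100000L, gammaSd = 0.3, theta = 0,
                      beta1 = 0, beta2 = 0, thetaDirect = 0,
                      pleioFrac = 0, pleioMean = 0, pleioSd = 0.01,
                      insideViolation = 0, ldBlockSize = 1L, ldRho = 0,
                      seed = NA_integer_) {
  new("SimConfig", mSnps = as.integer(mSnps), nExp = as.integer(nExp),
      nMed = as.integer(nMed), nOut = as.integer(nOut), gammaSd = gammaSd,
      theta = theta, beta1 = beta1, beta2 = beta2,
      thetaDirect = thetaDirect, pleioFrac = pleioFrac,
      pleioMean = pleioMean, pleioSd = pleioSd,
      insideViolation = insideViolation,
      ldBlockSize = as.integer(ldBlockSize), ldRho = ldRho,
      seed = as.integer(seed))
}

#' @rdname simConfig
#' @export
setClass("SimConfig",
  representation(
    mSnps = "integer", nExp = "integer", nMed = "integer", nOut = "integer",
    gammaSd = "numeric", theta = "numeric", beta1 = "numeric",
    beta2 = "numeric", thetaDirect = "numeric", pleioFrac = "numeric",
    pleioMean = "numeric", pleioSd = "numeric",
    insideViolation = "numeric", ldBlockSize = "integer",
    ldRho = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  if (object@pleioFrac < 0 || object@pleioFrac > 1)
    return("pleioFrac must lie in [0, 1]")
  if (abs(object@insideViolation) > 1)
    return("|insideViolation| must be <= 1")
  if (object@ldRho < 0 || object@ldRho >= 1)
    return("need 0 <= ldRho < 1")
  if (any(c(object@nExp, object@nMed, object@nOut) < 10))
    return("sample sizes must be >= 10")
  if (object@mSnps < 1L) return("mSnps must be >= 1")
  if (object@gammaSd < 0) return("gammaSd must be >= 0")
  TRUE
})

.resolveSeed <- function(config, seed) {
  if (!is.null(seed)) return(as.integer(seed))
  if (!is.na(config@seed)) return(config@seed)
  stop("a seed is required (in the config or as an argument)")
}

# non-palindromic allele pairs cycled across variants
.ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                        ncol = 2, byrow = TRUE)

.mkRecords <- function(ids, pos, beta, se, eaf, n) {
  z <- beta / se
  k <- ((seq_along(ids) - 1L) %% nrow(.ALLELE_PAIRS)) + 1L
  data.frame(snp_id = ids, chrom = "1", pos = pos,
             effect_allele = .ALLELE_PAIRS[k, 1],
             other_allele = .ALLELE_PAIRS[k, 2],
             eaf = eaf, beta = beta, se = se,
             pval = pmax(2 * pnorm(-abs(z)), .Machine$double.xmin),
             n = n, stringsAsFactors = FALSE)
}

# Pleiotropic direct effects, optionally strength-correlated via a
# Gaussian copula on |gamma|. Directional pleiotropy is directional
# relative to the exposure-increasing allele (the convention under which
# an Egger intercept of pleioFrac * pleioMean is recoverable): the drawn
# magnitude is applied with the sign of the variant's instrument effect.
.drawPleiotropy <- function(gamma, invalid, pleioMean, pleioSd, rho) {
  m <- length(gamma)
  alpha <- numeric(m)
  if (!any(invalid)) return(alpha)
  zg <- qnorm((rank(abs(gamma), ties.method = "first") - 0.5) / m)
  eps <- rnorm(m)
  za <- rho * zg + sqrt(1 - rho^2) * eps
  orient <- ifelse(gamma >= 0, 1, -1)
  alpha[invalid] <- orient[invalid] * (pleioMean + pleioSd * za[invalid])
  alpha
}

#' Simulate an exposure/outcome summary-statistics pair with known truth
#'
#' Draws true instrument effects, pleiotropy and observation noise per the
#' \code{\link{simConfig}} model and returns two
#' \linkS4class{SummaryDataset}s sharing variant IDs, positions and allele
#' orientation, plus a truth record with every latent quantity.
#'
#' @param config a \code{SimConfig}.
#' @param seed RNG seed (overrides \code{config@seed}).
#' @param basePosSpacing base-pair spacing between consecutive variants
#'   (default 100000).
#' @return list with \code{exposure}, \code{outcome}
#'   (\linkS4class{SummaryDataset}s) and \code{truth} (list: gamma, alpha,
#'   valid, theta, se_exp, se_out, eaf).
#' @export
simulatePair <- function(config, seed = NULL, basePosSpacing = 100000) {
  set.seed(.resolveSeed(config, seed))
  m <- config@mSnps
  gamma <- rnorm(m, 0, config@gammaSd)
  invalid <- seq_len(m) %in% sample.int(m, round(config@pleioFrac * m))
  alpha <- .drawPleiotropy(gamma, invalid, config@pleioMean,
                           config@pleioSd, config@insideViolation)
  eaf <- runif(m, 0.1, 0.9)
  seX <- 1 / sqrt(2 * eaf * (1 - eaf) * config@nExp)
  seY <- 1 / sqrt(2 * eaf * (1 - eaf) * config@nOut)
  bx <- rnorm(m, gamma, seX)
  by <- rnorm(m, config@theta * gamma + alpha, seY)
  ids <- paste0("rs", seq_len(m))
  pos <- seq_len(m) * basePosSpacing
  list(
    exposure = summaryDataset(.mkRecords(ids, pos, bx, seX, eaf,
                                         config@nExp),
                              traitName = "sim_exposure",
                              sourceId = "synthetic"),
    outcome = summaryDataset(.mkRecords(ids, pos, by, seY, eaf,
                                        config@nOut),
                             traitName = "sim_outcome",
                             sourceId = "synthetic"),
    truth = list(gamma = gamma, alpha = alpha, valid = !invalid,
                 theta = config@theta, se_exp = seX, se_out = seY,
                 eaf = eaf))
}

#' Simulate an exposure/mediator/outcome triad with known mediation truth
#'
#' The variant panel is the union of \code{mSnps} exposure instruments
#' (gamma_j nonzero) and \code{mSnps} disjoint mediator-specific
#' instruments (kappa_j nonzero, gamma_j = 0). True per-variant effects:
#' mediator \code{beta1 gamma_j + kappa_j}; outcome
#' \code{thetaDirect gamma_j + beta2 (beta1 gamma_j + kappa_j) + alpha_j}.
#' The true total effect is \code{thetaDirect + beta1 beta2} and the true
#' proportion mediated \code{beta1 beta2 / (thetaDirect + beta1 beta2)}.
#'
#' @inheritParams simulatePair
#' @return list with \code{exposure}, \code{mediator}, \code{outcome}
#'   \linkS4class{SummaryDataset}s and \code{truth}.
#' @export
simulateTriad <- function(config, seed = NULL, basePosSpacing = 100000) {
  set.seed(.resolveSeed(config, seed))
  m <- config@mSnps
  mm <- 2L * m
  gamma <- c(rnorm(m, 0, config@gammaSd), numeric(m))
  kappa <- c(numeric(m), rnorm(m, 0, config@gammaSd))
  invalid <- seq_len(mm) %in% sample.int(mm, round(config@pleioFrac * mm))
  alpha <- .drawPleiotropy(gamma + kappa, invalid, config@pleioMean,
                           config@pleioSd, config@insideViolation)
  medTrue <- config@beta1 * gamma + kappa
  outTrue <- config@thetaDirect * gamma + config@beta2 * medTrue + alpha
  eaf <- runif(mm, 0.1, 0.9)
  seX <- 1 / sqrt(2 * eaf * (1 - eaf) * config@nExp)
  seM <- 1 / sqrt(2 * eaf * (1 - eaf) * config@nMed)
  seY <- 1 / sqrt(2 * eaf * (1 - eaf) * config@nOut)
  bx <- rnorm(mm, gamma, seX)
  bm <- rnorm(mm, medTrue, seM)
  by <- rnorm(mm, outTrue, seY)
  ids <- paste0("rs", seq_len(mm))
  pos <- seq_len(mm) * basePosSpacing
  totalTrue <- config@thetaDirect + config@beta1 * config@beta2
  list(
    exposure = summaryDataset(.mkRecords(ids, pos, bx, seX, eaf,
                                         config@nExp),
                              traitName = "sim_exposure",
                              sourceId = "synthetic"),
    mediator = summaryDataset(.mkRecords(ids, pos, bm, seM, eaf,
                                         config@nMed),
                              traitName = "sim_mediator",
                              sourceId = "synthetic"),
    outcome = summaryDataset(.mkRecords(ids, pos, by, seY, eaf,
                                        config@nOut),
                             traitName = "sim_outcome",
                             sourceId = "synthetic"),
    truth = list(gamma = gamma, kappa = kappa, alpha = alpha,
                 valid = !invalid, beta1 = config@beta1,
                 beta2 = config@beta2, thetaDirect = config@thetaDirect,
                 totalEffect = totalTrue,
                 proportionMediated = if (totalTrue != 0)
                   config@beta1 * config@beta2 / totalTrue else NA_real_))
}

#' Simulate a block-structured LD matrix
#'
#' Block-diagonal squared correlations with AR(1) decay
#' \code{rho^(2 |i - j|)} within blocks and zero across blocks; variants
#' are placed \code{basePosSpacing} bp apart on one chromosome.
#'
#' @param mSnps variant count.
#' @param blockSize variants per LD block (last block may be shorter).
#' @param rho AR(1) correlation, 0 <= rho < 1.
#' @param basePosSpacing base-pair spacing (default 100000).
#' @param snpIds optional IDs (default \code{rs1..rsm}, matching
#'   \code{\link{simulatePair}}).
#' @return an \linkS4class{LDMatrix}.
#' @export
simulateLD <- function(mSnps, blockSize = 1L, rho = 0,
                       basePosSpacing = 100000, snpIds = NULL) {
  if (rho < 0 || rho >= 1) stop("need 0 <= rho < 1")
  mSnps <- as.integer(mSnps)
  if (is.null(snpIds)) snpIds <- paste0("rs", seq_len(mSnps))
  if (length(snpIds) != mSnps) stop("snpIds length must equal mSnps")
  block <- ((seq_len(mSnps) - 1L) %/% as.integer(blockSize))
  dist <- abs(outer(seq_len(mSnps), seq_len(mSnps), "-"))
  r2 <- rho^(2 * dist) * outer(block, block, "==")
  diag(r2) <- 1
  dimnames(r2) <- list(snpIds, snpIds)
  new("LDMatrix", snpIds = snpIds, r2 = r2,
      positions = data.frame(snp_id = snpIds, chrom = "1",
                             pos = seq_len(mSnps) * basePosSpacing,
                             stringsAsFactors = FALSE))
}

#' Identity LD matrix for a dataset of independent variants
#'
#' @param dataset a \linkS4class{SummaryDataset}.
#' @return an \linkS4class{LDMatrix} with r2 = I and positions taken from
#'   the dataset.
#' @export
identityLDMatrix <- function(dataset) {
  rec <- records(dataset)
  ids <- rec$snp_id
  r2 <- diag(1, length(ids))
  dimnames(r2) <- list(ids, ids)
  new("LDMatrix", snpIds = ids, r2 = r2,
      positions = rec[, c("snp_id", "chrom", "pos")])
}
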