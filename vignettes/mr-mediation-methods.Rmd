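---
title: "Methods: two-sample MR screening and two-step mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening and two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The inferential problem

Two-sample Mendelian randomization estimates the causal effect of an
exposure on an outcome from two independent GWAS: one supplying per-variant
exposure associations, one supplying outcome associations for the same
variants. Because alleles are assorted at conception, a variant that (i) is
robustly associated with the exposure, (ii) shares no confounder with the
outcome, and (iii) affects the outcome only through the exposure is a valid
instrument, and its Wald ratio $\hat\beta_{Y,j}/\hat\beta_{X,j}$ estimates
the causal effect $\theta$ on the scale of the outcome GWAS (log-odds for a
binary outcome, so $e^\theta$ is an odds ratio).

`mrmediate` implements this end to end for a screening design — one
exposure against a family of outcomes, the reverse direction, and a
mediator panel — together with the downstream two-step mediation
decomposition.

## Instrument selection

Variants enter as instruments when they pass, in order:

1. **Association**: $p < 5\times10^{-8}$; when fewer than
   `minInstruments` (default 3) pass, the relaxed $5\times10^{-6}$
   threshold is tried, and is used only if it actually yields more
   variants (so the reported threshold always describes the set that was
   kept). Mediator panels use $1\times10^{-5}$ throughout, the common
   compromise for weakly powered molecular traits.
2. **Independence**: greedy LD clumping at $r^2 \le 0.001$ within
   10,000 kb. Variants are ranked by p-value (ties broken by genomic
   position); the best remaining variant indexes a clump and removes its
   correlated neighbours. The LD matrix is an explicit input (square or
   long TSV) rather than a hidden reference-panel service, which keeps
   runs reproducible and tests hermetic; `simulateLD()` provides
   AR(1)-block matrices with $r^2 = \rho^{2|i-j|}$.
3. **Strength**: per-variant $F = \frac{N-K-1}{K}\cdot\frac{R^2}{1-R^2}$
   with $K = 1$, dropping $F < 10$. When no $R^2$ column is supplied it is
   approximated by $\beta^2/(\beta^2 + (N-2)\,\mathrm{se}^2)$, the
   t-statistic identity; with $K=1$ this makes $F \approx (\beta/\mathrm{se})^2$.

Harmonization then matches variants by rsID, flips the outcome effect where
allele labels are swapped, and removes palindromic (A/T, C/G) variants
unconditionally — allele frequencies are never used to guess strand, the
conservative reading of standard practice. Every exclusion is logged with a
reason, so row counts always reconcile.

## Estimators and their conventions

All estimators consume the harmonized per-variant pairs
$(\hat\beta_{X,j}, \hat\beta_{Y,j})$ with outcome-side inverse-variance
weights $w_j = 1/\mathrm{se}_{Y,j}^2$:

- **IVW** — no-intercept weighted regression,
  $\hat\theta = \sum w b_X b_Y / \sum w b_X^2$. The SE is the fixed-effect
  SE times $\max(1,\hat\sigma)$, where $\hat\sigma^2$ is the weighted
  residual variance on $n-1$ df: heterogeneity inflates uncertainty,
  under-dispersion is never allowed to shrink it. This floored
  multiplicative random-effects convention matches the widely used
  reference implementation, at a cost discussed under *Known limitations*.
- **MR-Egger** — the same regression with an intercept, after orienting
  every variant so $\hat\beta_X \ge 0$. Slope = causal effect robust to
  directional pleiotropy (under InSIDE: pleiotropy independent of
  instrument strength); intercept = average pleiotropic effect, the basis
  of the intercept test (threshold 0.05). Inference uses the t
  distribution on $n-2$ df, SEs floored as above.
- **Weighted median** — ratios sorted, weights
  $w_j = b_{X,j}^2/\mathrm{se}_{Y,j}^2$ normalized, and the estimate
  interpolates the cumulative weight function (midpoint convention
  $s_j - w_j/2$) at one half. Consistent while valid instruments hold
  half the weight.
- **Weighted mode** — Gaussian kernel density over the ratios with
  Silverman bandwidth $0.9\min(\mathrm{sd},\mathrm{IQR}/1.34)\,m^{-1/5}$
  (scaled by `bandwidthFactor`, default 1), weights as kernel masses;
  the estimate is the argmax on a 2001-point grid spanning the ratio range
  ± 3 bandwidths. Doubling the grid moves the estimate by less than half a
  grid step, so the grid is not a practical resolution limit. If all
  ratios coincide the bandwidth degenerates and the common ratio is
  returned with zero SE.

Median and mode SEs come from a parametric bootstrap (associations redrawn
from normals centred on the observed values; default 1000 replicates; a
seed is mandatory — no silently irreproducible results). The Wald ratio SE
is first-order ($\mathrm{se}_Y/|\hat\beta_X|$) by default; the second-order
form including exposure uncertainty is available. With one instrument only
the Wald ratio is reported; with two, IVW; with three or more, all four
estimators plus a direction-consistency flag (all signs agreeing with IVW),
the robustness convention screens rely on.

## Sensitivity analyses

- **Cochran's Q** on the per-variant ratios with first-order ratio SEs;
  upper-tail $\chi^2_{n-1}$ p.
- **Egger intercept test**, as above.
- **MR-PRESSO**: each variant's residual from its own leave-one-out IVW
  fit, summed with weights, gives the observed RSS; a simulated null
  (associations redrawn around the leave-one-out predictions) gives the
  empirical global p with add-one smoothing, $(1 + \#\{RSS^* \ge
  RSS_{obs}\})/(1 + n_{sim})$, so p-values are never zero. Per-variant
  outlier p-values are Bonferroni-corrected across variants and flagged
  below 0.05; the corrected estimate is IVW on the unflagged set; a
  distortion p compares the raw-minus-corrected slope difference against
  its simulated null distribution. Default $n_{sim} = 1000$; note that
  with $m$ variants the smallest attainable corrected outlier p is
  $m/(n_{sim}+1)$, so $n_{sim}$ must comfortably exceed $20m$ for flagging
  at 0.05 to be possible at all.
- **Leave-one-out**: IVW without each variant in turn, flagging variants
  whose removal flips the sign or moves the estimate by more than one
  full-set SE (configurable multiple).

## Screening and verdicts

A forward screen builds the exposure's instruments once, then per outcome:
harmonize, estimate, diagnose; when MR-PRESSO flags outliers the
outlier-corrected estimate is reported alongside the raw one. Raw IVW
p-values are Bonferroni-adjusted ($\min(1, p\cdot m)$) with an *explicit*
family size $m$ (default: the number of outcomes; always printed), and
verdicts are tiered: `strong` (adjusted $p<0.05$), `potential` (raw
$p<0.05$ only), `null`. Outcome-level failures become `failed` rows, never
aborting the family. Per-outcome RNG streams derive from the outcome name,
so results are invariant to outcome ordering. The reverse screen swaps
roles, reselecting instruments per reverse-exposure. Replication re-runs
the primary instruments against an external cohort and requires $p<0.05$
with a concordant sign.

The mediator screen is two-step: (A) every mediator against the outcome
(mediator instruments at $10^{-5}$), keeping IVW $p<0.05$ with
direction-consistent secondary estimators (configurable off); (B) the
exposure against each survivor, keeping $p<0.05$; (C) `mrMediate()` on
each double survivor.

## Mediation decomposition

With independent GWAS samples for the three estimates, the indirect effect
is $\beta_1\beta_2$ with first-order delta SE
$\sqrt{\beta_1^2\mathrm{se}_2^2 + \beta_2^2\mathrm{se}_1^2}$ (zero
covariance; the second-order $\mathrm{se}_1^2\mathrm{se}_2^2$ term is
optional and off by default), the direct effect is $\beta_0 -
\beta_1\beta_2$, and the proportion mediated $(\beta_1\beta_2)/\beta_0$
with delta SE
$\sqrt{(\mathrm{se}_{ind}/\beta_0)^2 + (ind\cdot\mathrm{se}_0/\beta_0^2)^2}$.
Intervals are $\pm 1.96$ SE on the log scale. The identities
$indirect + direct = total$ and $proportion \times total = indirect$ hold
to machine precision by construction. A zero total effect leaves the
proportion undefined (flagged, other fields still returned); a proportion
whose sign opposes the total effect is a suppression effect.

Worked on published step odds ratios 0.9804 (exposure→mediator), 1.0954
(mediator→outcome) and 1.021 (total):

```{r}
mrMediate(c(beta = log(1.021),  se = 0.009),
          c(beta = log(0.9804), se = 0.0087),
          c(beta = log(1.0954), se = 0.029))
```

$\ln(0.9804)\cdot\ln(1.0954) = -0.0018037$ and the proportion against
$\ln(1.021)$ is $-8.68\%$. The source study that reported these step odds
ratios printed a proportion of $-14.3\%$, which is not reproducible from
its printed values — presumably computed from unrounded estimates or a
different total-effect estimator. The package reports what the formula
gives and does not attempt to match the printed figure. The first-order
delta interval is also known to misbehave when the true $\beta_1\beta_2$
is near zero; `mediationCiCoverage()` measures this directly.

## The synthetic-data generator

`simulatePair()` / `simulateTriad()` emulate summary-level GWAS under the
instrumental-variable model itself: true instrument effects
$\gamma_j \sim N(0, \texttt{gammaSd}^2)$; observed associations are truth
plus normal noise with $\mathrm{se} = 1/\sqrt{2\,\mathrm{eaf}(1-\mathrm{eaf})\,n}$,
$\mathrm{eaf} \sim U(0.1, 0.9)$ (bounded away from 0/1 to avoid degenerate
SEs); binary outcomes are emulated directly on the log-odds scale (no
liability model). A fraction `pleioFrac` of instruments receive a direct
outcome effect with mean `pleioMean` and SD `pleioSd`, applied **with the
sign of the variant's instrument effect** — i.e. directional relative to
the exposure-increasing allele. This orientation is what makes
"directional" meaningful for a symmetric $\gamma$: with it, the Egger
intercept converges to $\texttt{pleioFrac}\cdot\texttt{pleioMean}$ and IVW
acquires the expected upward bias; a raw additive constant would cancel
under allele orientation. `insideViolation` correlates pleiotropy with
instrument strength through a Gaussian copula on $|\gamma_j|$, violating
InSIDE. Triads add a disjoint panel of mediator-specific instruments
($\kappa_j$) and compose effects so the true total is
$\theta_{direct} + \beta_1\beta_2$.

Defaults are the package's reference study conditions: 50 instruments,
$n = 100{,}000$ per GWAS, and `gammaSd = 0.3` — per-allele log-odds
effects typical of genome-wide-significant hits for strongly genetic
autoimmune exposures (vitiligo-like, where lead loci reach per-allele odds
ratios of 1.3–2). The strength matters: weaker panels (`gammaSd` ≈ 0.05)
show visible regression-dilution attenuation of IVW, which is a property
of the estimator, not a bug — the recovery studies use instrument
strengths under which it is negligible relative to Monte-Carlo error.

What the generator does **not** emulate: LD between instruments and truth
(LD enters only through the explicit `simulateLD()` matrices used for
clumping tests), selection bias from significance thresholding (winner's
curse), sample overlap between the two GWAS, population stratification,
and case-control liability-scale effects. Passing calibration here
therefore demonstrates correctness of the statistical machinery under the
model's own assumptions, not robustness to everything real data can do.

## Validation studies and their design

The `study*()` functions (driven by `scripts/acceptance.R` and the test
suite) use: recovery, 500 replicates at $\theta = 0.25$; type-I error,
2000 replicates at $\theta = 0$; robustness, 40 % invalid instruments with
directional pleiotropy of mean 0.05; MR-PRESSO, a planted outlier at ten
times the common ratio among 30 variants. The outlier is planted on an
**upper-quartile-strength** instrument: on a near-null instrument a ratio
outlier is undetectable in principle (its absolute effect vanishes), while
on the single strongest instrument it drags the fit so far that every
variant flags and the "corrected" estimate degenerates — the
upper-quartile choice is the regime the test is about, an influential but
non-dominant invalid variant. Family-wise calibration simulates 2000
all-null 13-outcome families through the same IVW + Bonferroni verdict
path the screen uses.

Two honest caveats, measured rather than hidden:

- Under one-sided directional pleiotropy the weighted median is *less
  biased* than IVW by a factor of ~3 at these conditions, but not
  unbiased: it converges to the $0.5/(1-f)$ quantile of the valid-ratio
  distribution ($f$ = invalid weight fraction), a bias of about one
  cross-sectional ratio SD. Since the Monte-Carlo SE of the mean shrinks
  with replicates while this bias does not, a "mean within a few MC SEs
  of truth" reading will fail at any sample size or noise level — the
  meaningful claim, which holds, is the bias ordering.
- The floored random-effects IVW SE is conservative deep in the tail:
  at the Bonferroni-corrected threshold $0.05/13$ the realized per-test
  rate is ~75 % of nominal, so the family-wise "strong" rate under the
  null sits near 0.036 rather than 0.05. Family-wise error is controlled
  *below* nominal; an exactly-nominal rate would require fixed-effect
  p-values, which are computed but are not the reported default.

## Numerical conventions

Two-sided normal p-values are floored at the smallest positive double
(never zero, keeping $p \in (0,1]$); Egger uses t on $n-2$ df; clumping
ties break on genomic order, making results platform-independent; clumping
is idempotent and order-invariant; every stochastic routine takes an
explicit seed and is byte-reproducible under it; all TSV output is
re-readable by the package's own readers.
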