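---
title: "Two-sample MR with mediation: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with mediation: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem this package addresses

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome using SNPs as instrumental variables, with SNP–exposure
and SNP–outcome associations taken from *separate* GWAS. The motivating
application is a screen of many immune-cell phenotypes against a case-control
disease outcome (esophageal cancer), followed by a two-step mediation analysis
asking how much of a phenotype's effect travels through a circulating
inflammatory protein (interleukin-10). `mrmediate` implements the full
workflow: summary-statistic I/O and harmonization, instrument selection,
a battery of MR estimators, sensitivity diagnostics, a Bayesian-weighted
estimator, two-step mediation with delta-method uncertainty, and a synthetic
summary-statistic generator with known ground truth so that every component
can be tested end to end without access to the original GWAS accessions.

The instrumental-variable assumptions are the usual three: each instrument is
associated with the exposure, shares no confounder with the outcome, and
affects the outcome only through the exposure. The sensitivity battery probes
the third (exclusion-restriction) assumption.

## Instrument selection

Instruments are selected by p-value threshold (`1e-5` for forward screens,
where genome-wide significance would leave too few SNPs for these modest-n
immunophenotype GWAS; `5e-8` for reverse analyses), pruned by greedy LD
clumping (r² < 0.001 within 10,000 kb), and screened for strength.

Variance explained and the F statistic use the summary-statistic formulas

$$R^2 = \frac{\beta^2 \,\mathrm{EAF}\,(1-\mathrm{EAF})}{\mathrm{SE}^2\, N},
\qquad
F = \frac{N - K - 1}{K}\cdot\frac{R^2}{1 - R^2},$$

with the screen keeping per-SNP $F > 10$ (computed with $K = 1$, since
screening precedes knowing the retained count $K$). Note a consequence of
this $R^2$ form: per-SNP $F \approx z^2\,\mathrm{EAF}(1-\mathrm{EAF})$, so an
instrument needs $|z| \gtrsim 8$–$9$ to survive — only traits with large
per-locus effects (such as cytometry-derived immunophenotypes) yield usable
instrument sets at $n \approx 3800$.

Because no LD reference panel ships with the package, clumping accepts a
user-supplied pairwise r² lookup (matrix or function; absent pairs are
treated as independent) and falls back to a distance-only rule (one SNP per
window per chromosome). Ties in p-value break lexicographically by variant id
so results are deterministic.

Study power for a binary outcome uses the standard MR power calculator's
normal approximation: with case fraction $v$ and causal odds ratio
$\mathrm{OR}$, $b = v\,(\mathrm{OR}/(1+v(\mathrm{OR}-1)) - 1)$,
$\mathrm{ncp} = N R^2 b^2 / (v(1-v) - b^2)$, and two-sided power
$\Phi(\sqrt{\mathrm{ncp}} - z_{1-\alpha/2}) +
\Phi(-\sqrt{\mathrm{ncp}} - z_{1-\alpha/2})$. The exact
binary-outcome parameterization of the original online calculator is not
printed in most applied papers; this form satisfies the natural boundary
conditions (power equals $\alpha$ at $\mathrm{OR}=1$ or $R^2=0$) and is
monotone in $N$, $R^2$, and $|\log \mathrm{OR}|$.

## Harmonization

`harmonize()` aligns each outcome record onto the exposure's effect allele:
same orientation is kept; a swapped allele pair flips the sign of the outcome
beta and reflects its allele frequency; strand-complement matches are
resolved by complementing the outcome alleles before comparison.
Palindromic SNPs (A/T, C/G) are dropped unconditionally by default — the
conservative convention for cross-consortium data — because their strand
cannot be inferred from the alleles. An optional frequency mode
(`drop_all_palindromic = FALSE`) instead aligns palindromic SNPs by allele
frequency and drops only those inside the ambiguous window (eaf in
[0.42, 0.58]); it exists for interoperability with pipelines that follow
that convention, and is off by default. Matching is by variant id only; the
intended data sources share rsIDs, and positional fallback invites silent
build mismatches.

Harmonization is conservative about information loss: every exposure SNP
appears in the output exactly once with an `action` (`kept`, `flipped`,
`dropped`) and, when dropped, a machine-readable reason.

## The estimators

All estimators consume per-SNP pairs $(\hat\beta_{Xj}, \hat\beta_{Yj})$ with
outcome SEs $\sigma_j$, and report log-odds effects with normal-theory
intervals plus the exponentiated odds-ratio scale.

**IVW.** The zero-intercept weighted regression
$\hat\beta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j \hat\beta_{Xj}^2$
with $w_j = 1/\sigma_j^2$. The fixed-effects SE is
$(\sum w_j \hat\beta_{Xj}^2)^{-1/2}$; the multiplicative random-effects SE
inflates it by $\max(1, \sqrt{Q/(J-1)})$. The pipeline's headline estimate is
fixed-effects unless the Cochran Q p-value falls below 0.05 (the usual
rule: adopt random effects only in the presence of heterogeneity).

**MR-Egger.** The same regression with a free intercept, after orienting all
pairs to non-negative exposure effects. The intercept estimates the average
directional pleiotropic effect; its test uses a two-sided normal p-value,
while the slope uses a t reference on $J-2$ df (the field's convention).

**Weighted median.** The interpolated weighted 50th percentile of the ratio
estimates $\hat\beta_{Yj}/\hat\beta_{Xj}$ with weights
$\hat\beta_{Xj}^2/\sigma_j^2$; consistent when at least half the weight is
valid. SE by parametric bootstrap (default 1000 replicates, explicit seed).

**Mode estimators.** The argmax of a Gaussian-kernel density over the ratio
estimates (simple: equal weights; weighted: inverse-variance weights), with
bandwidth `bandwidth_factor` × the modified Silverman rule
$0.9\min(\mathrm{sd},\mathrm{mad})J^{-1/5}$. A degenerate spread returns the
common ratio directly. SE by bootstrap.

**Wald ratio.** When selection leaves a single instrument the pipeline falls
back to $\hat\beta_{Y}/\hat\beta_{X}$ with first-order SE
$\sigma/|\hat\beta_X|$, labelled distinctly; sensitivity analyses are then
marked not applicable.

## Sensitivity battery

*Cochran Q* sums squared standardized residuals about the IVW (df $J-1$) or
Egger (df $J-2$) fit. *The Egger intercept test* is described above.
*Leave-one-out* refits IVW omitting each SNP in turn.

*MR-PRESSO* follows the residual-sum-and-outlier architecture: for each SNP
the leave-one-out IVW prediction defines a standardized residual; the global
statistic is the residual sum of squares, compared against a parametric
bootstrap null in which exposure betas are redrawn about their observed
values, outcome betas are drawn about the no-pleiotropy predictions *at the
simulated exposure betas*, and the full statistic (including the
leave-one-out slopes) is recomputed on each simulated dataset. Per-SNP
outlier tests compare each observed squared residual with its simulated
distribution, using the $(r+1)/(n+1)$ empirical p-value convention (no zero
p-values) with Bonferroni adjustment; outliers are reported only when the
global test fires at the configured level. When outliers are found, the
corrected estimate is IVW on the remaining SNPs, and the distortion test
references the distortion expected from removing equally many random SNPs.
The default 1000 simulations match the original tool's magnitude; tests and
examples use scaled-down counts (200–500), which only coarsens the empirical
p-value resolution.

## Bayesian-weighted MR

The BWMR estimator addresses polygenic structure and pleiotropic outliers
with a hierarchical Gaussian model: latent instrument effects
$\gamma_j \sim N(0, \sigma_0^2)$, outcome effects
$\Gamma_j = \beta\gamma_j + \alpha_j$ with pleiotropy
$\alpha_j \sim N(0, \tau^2)$, and observed betas Gaussian about the latents
with their reported SEs. Weakly-informative inverse-gamma(1e-3, 1e-3) priors
regularize both variance components (configurable).

Per-SNP Bayesian weights are computed once, from each SNP's evidence under a
preliminary robust fit: residuals about the weighted-median slope are
standardized and scored under a two-component mixture of a clean and a
5-fold-inflated outlier distribution (prior cleanness 0.95); the weight is
the posterior probability of cleanness, rescaled so the best-supported SNP
has weight 1. Holding the weights fixed during the subsequent weighted
variational EM is a deliberate design choice: it makes the weighted evidence
lower bound a single coordinate-ascent objective, so the ELBO trace is
provably non-decreasing — a property lost if weights are re-derived inside
the loop. The E-step posteriors and the $\beta$, $\sigma_0^2$ updates are
closed-form; $\tau^2$ uses a bounded one-dimensional search that is accepted
only when it improves the objective. Convergence is declared at relative
ELBO change below `tol` (default 1e-6, default cap 500 iterations;
non-convergence returns a flagged result rather than an error). The SE comes
from the numeric curvature of the profile objective — the weighted marginal
log-likelihood in $\beta$, which coincides with the ELBO profiled over the
exact conjugate posteriors — at the optimum.

## Two-step mediation

With the total exposure→outcome effect $\hat\tau$, the exposure→mediator
effect $\hat\beta_1$, and the mediator→outcome effect $\hat\beta_2$ (each
from its own two-sample MR with its own instruments), the indirect effect is
$\hat\beta_1\hat\beta_2$, the direct effect is $\hat\tau -
\hat\beta_1\hat\beta_2$, and the mediation proportion is
$100\cdot\hat\beta_1\hat\beta_2/\hat\tau$. The indirect-effect variance uses
the first-order delta method
$\hat\beta_1^2 s_2^2 + \hat\beta_2^2 s_1^2$ (the standard
product-of-coefficients form; an option adds the second-order
$s_1^2 s_2^2$ term). The proportion's interval propagates the total effect's
SE through the ratio, also by the delta method, treating the legs as
independent — an interpretation, since the published tables print a
proportion interval without a formula. The total effect is re-estimated from
its own MR leg, never reconstructed as direct + indirect.

```{r mediation-example}
two_step_mediation(total = -0.0786, total_se = 0.03,
                   beta1 = 0.0274, se1 = 0.012,
                   beta2 = -0.3451, se2 = 0.16)
```

## The synthetic-data generator

`simulate_triplet()` emulates the structure of the study's data: an
exposure GWAS of a strongly genetically determined immunophenotype
(default n = 3757), a mediator protein GWAS (n = 14,824), and a case-control
outcome GWAS (n = 160,589 with 1388 cases), over a shared SNP panel with a
configurable palindromic fraction (default 0.15) so harmonization is always
exercised. The structural model is linear: $M = \theta_1 X + e$,
$Y = \theta_2 M + \theta_{\mathrm{direct}} X + e$, with
$\theta_2, \theta_{\mathrm{direct}}$ defined directly on the log-odds scale
and case-control sampling entering through the effective-sample-size SE
$(2p(1-p)\,n\,v(1-v))^{-1/2}$. This keeps the generative parameters exactly
the MR estimands, so recovery tests have unambiguous truth; a
liability-to-log-odds rescaling would decouple them.

Exposure instruments draw effects scaled to a target total variance
explained (default 0.5; mediator instruments 0.2). These defaults are set so
that roughly 10–25 instruments survive the p<1e-5 + F>10 screen at the
default sample sizes — the instrument counts typical of published
immune-trait MR screens — and reflect the strongly cis-regulated genetics of cell-surface phenotypes
and protein levels. The mediator has its *own* instruments (null for the
exposure, affecting the outcome only through the mediator), which is what a
mediator→outcome MR leg requires. A configurable fraction of exposure
instruments can be made invalid with additive pleiotropic outcome effects
(directional when the mean is nonzero). P-values are computed from the
generated beta/SE pairs, so threshold logic runs end to end. Seeds propagate
hierarchically (panel seed → per-dataset seeds) and identical configurations
reproduce byte-identical datasets.

What the generator does **not** emulate: LD between SNPs (instruments are
generated independent; LD enters only through the optional r² lookup),
sample overlap between cohorts, allele-frequency differences between
populations, winner's-curse selection in the discovery GWAS, and non-Gaussian
effect-size distributions. Passing tests therefore demonstrate correctness of
the estimators and workflow under the stated model, not robustness to those
real-data complications.

One known leakage path is documented rather than hidden: exposure
instruments are associated with the mediator through $\theta_1$, and with a
very strong exposure GWAS they can cross the mediator leg's selection
threshold, contaminating the mediator→outcome leg (their ratio estimates
$\theta_2 + \theta_{\mathrm{direct}}/\theta_1$, not $\theta_2$). At the
default attenuation this leakage is sub-threshold, and the F>10 screen
removes the rare crossers; Steiger-type filtering, which would remove them
in real data, is out of scope.

## Pipeline

`forward_screen()` applies selection → harmonization → all estimators →
sensitivity battery per exposure, flagging those with headline IVW p < .05
and a fully passing battery; failures are logged per exposure and never
fatal. Benjamini–Hochberg q-values are reported for transparency but not
used for flagging (the workflow relies on multi-cohort validation instead). `validate_screen()` requires, in every validation
cohort, a same-sign IVW estimate with p < .05 — one concrete operationalization
of "direction-consistent validation", which the source material does not
pin down. `reverse_mr()` re-runs the stack with the outcome as exposure at
the 5e-8 threshold, reporting "untestable" rather than erroring when no
instrument survives. `run_full()` wires the stages together from an R list
or YAML config, writes TSV artifacts and a timestamped run log recording
every threshold and seed actually applied, and re-runs byte-identically
under the same config.

## Numerical and testing notes

Deterministic estimators are verified to 1e-10 against independent
matrix-algebra, percentile-search, and direct-summation oracles. Stochastic
components take explicit seeds everywhere; all simulation-based tests fix
master seeds. Problem sizes in the test-suite calibration and recovery
studies are 100–500 replicates with 10–50 instruments, and the
parameter-recovery study uses triplets of n = 50,000 with a balanced
case-control outcome and instrument R² of 0.1 per trait — strong instruments
(per-SNP F ≈ 25–60) while keeping exposure-instrument leakage into the
mediator GWAS sub-threshold. Degenerate inputs have defined behavior: empty
selections return empty results or "untestable" statuses, a single
instrument routes to the Wald ratio, zero exposure betas are excluded from
ratio estimators with a warning, exact-proportional data yield Q = 0 with
p = 1, and validation failures are collected row-wise with reasons rather
than discarded.

## Limitations

Multivariable MR, CAUSE/contamination-mixture estimators, radial MR, Steiger
filtering, proxy-SNP lookup, LD computation from genotype panels, and full
posterior sampling for BWMR are intentionally out of scope. The delta-method
proportion interval ignores the covariance between the total effect and the
indirect effect (they share the exposure GWAS); treat it as descriptive.
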