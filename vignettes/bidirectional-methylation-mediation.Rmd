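---
title: "Bidirectional mediation between DNA methylation and allergic sensitization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional mediation between DNA methylation and allergic sensitization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimediate)
```

## The scientific question

Epigenome-wide association studies keep finding CpG sites whose methylation
tracks allergic disease, but association alone cannot say whether
differential methylation *precedes* sensitization (a potential predictor or
cause) or *follows* it (a biomarker of established disease). With
longitudinal cohort data — exposures fixed at or before birth, methylation
and aeroallergen sensitization (specific IgE > 0.35 kU/L) each measured at
two later ages — the question becomes testable as two competing mediation
hypotheses:

* **H1 (methylation as mediator):** exposure → methylation at the earlier
  age → sensitization at the later age;
* **H2 (methylation as consequence):** exposure → sensitization at the
  earlier age → methylation at the later age.

Exposures are the classical determinants of allergy: maternal smoking in
pregnancy, a family history of allergic disease, and a polygenic risk score
(PRS) for any allergic disease. Mediators/outcomes are single CpG beta
values and methylation risk scores (MRS) built from published EWAS weights.

`epimediate` implements the full analysis — risk-score construction,
counterfactual single-mediator causal mediation, three high-dimensional
mediator-nomination strategies, validation with pooled FDR control, and the
accompanying sensitivity analyses — plus a seeded synthetic-cohort
generator with planted effects in either direction, so the whole pipeline
is testable end-to-end with known ground truth.

## The causal mediation model

For one exposure $X$, mediator $M$ and outcome $Y$ with covariates $Z$, two
regressions are fit by maximum likelihood (linear for continuous responses,
logistic for binary ones):

$$M = \alpha_0 + \alpha_1 X + \alpha_Z' Z + \varepsilon, \qquad
g(E[Y]) = \beta_0 + \beta_1 X + \beta_2 M + \beta_Z' Z.$$

Effects are decomposed by the standard quasi-Bayesian simulation: parameter
vectors are drawn from each fit's asymptotic normal distribution; per draw,
potential mediator values $M(x)$ and potential outcomes $Y(x, M(x'))$ are
simulated over the observed covariate distribution; then

$$\mathrm{ACME}(x) = E[Y(x, M(1)) - Y(x, M(0))], \qquad
\mathrm{ADE}(x) = E[Y(1, M(x)) - Y(0, M(x))],$$

reported as averages over $x \in \{0, 1\}$, with the total effect per draw
equal to $\mathrm{ACME}(x) + \mathrm{ADE}(1-x)$. Because that identity
holds within every draw, the reported decomposition satisfies
$\mathrm{TE} = \mathrm{ACME} + \mathrm{ADE}$ to machine precision, for both
linear and logistic outcome models — the same additivity visible in the
result tables of mediation studies. Binary-outcome effects are reported on
the risk-difference scale via simulated potential outcome probabilities.
Confidence intervals are percentile intervals over draws (1000 by default),
p-values are two-sided simulation p-values, and the proportion mediated is
the mean of per-draw ACME/TE ratios; draws with $|TE| < 10^{-12}$ are
excluded from that ratio and counted (`n_excluded_draws`), because the
ratio is unstable when the total effect crosses zero — which is why
proportion-mediated intervals can be wildly wide in published tables. The
ratio-of-point-estimates convention is available via
`prop_med = "ratio_of_means"`; the choice matters only in weak-total-effect
regimes. No treatment–mediator interaction is included by default
(`interaction = TRUE` adds one).

With no interaction and linear models on both stages, the ACME converges to
the product of coefficients $\hat\alpha_1 \hat\beta_2$ as the number of
draws grows; the test suite checks this against the two separate fits.

## Risk scores

An MRS is the weighted sum of CpG beta values using EWAS effect sizes,
z-scored across the cohort (sample SD). Construction follows
clumping-and-thresholding: markers passing a p-value threshold are visited
in ascending p-value order and dropped if their squared correlation with
any retained marker exceeds $r^2 = 0.7$; the score is computed per
threshold over the grid $\{5\times 10^{-8}, 10^{-5}, 10^{-3}, 0.01, 0.05,
1\}$ and the threshold with the best cross-sectional AUC against baseline
sensitization wins, ties broken towards fewer markers. Markers absent from
the matrix are skipped and counted, never imputed — mirroring how published
weight lists only partially overlap a given array. The PRS applies the
conventional dosage filters first: multiallelic SNPs, imputation quality
below 0.4, minor allele frequency below 1%, and zero-effect markers are
excluded before pruning at $r^2 > 0.7$.

Scoring an empty marker set is an explicit error (never a silent zero
score), and within-cohort z-scoring is used for both MRS and PRS for
consistency, since raw weighted sums have no absolute scale.

## High-dimensional mediator nomination

Three complementary strategies nominate single-CpG mediators for H1; H2
uses only the first (the others require a high-dimensional *mediator*, not
a high-dimensional outcome).

**Composite-null test (DACT) over prior-knowledge candidates.** Candidate
CpGs come from published allergy EWAS (here: the union of the weight
tables), intersected with the measured matrix and filtered to those
associated with baseline sensitization (cell-type-adjusted logistic
regression, BH-FDR ≤ 0.05). For each candidate, `marginal_scan()` produces
the two path p-values, and `dact()` aggregates them under the composite
null ($\alpha = 0$, $\beta = 0$, or both): null proportions $\pi_0$ for
each path are estimated (threshold estimator at $\lambda = 0.5$ by
default; a characteristic-function estimator as an option), the three null
cases are weighted by the normalized products $w_1 = \pi_{0a}(1-\pi_{0b})$,
$w_2 = (1-\pi_{0a})\pi_{0b}$, $w_3 = \pi_{0a}\pi_{0b}$, and the combined
p-value is $w_1 p_a + w_2 p_b + w_3 \max(p_a, p_b)^2$. The combined
p-values are then recalibrated against an empirical null: they are mapped
to z-scores, a truncated-normal maximum-likelihood fit to the central peak
($z \in [-2, 2]$, median/MAD fallback) estimates the null mean and SD, and
calibrated p-values follow. Calibration needs on the order of 100+ markers;
below that the uncalibrated values are returned with a warning. Under a
complete null the weights collapse towards $(0,0,1)$ and
$\max(p_a,p_b)^2$ is itself uniform, so the test holds its size; the
suite verifies a rejection rate within [0.03, 0.07] at $\alpha = 0.05$ and
that calibration moves the null distribution closer to uniform.

**Screen–penalize–joint-test (HIMA-style) epigenome-wide.** Sure
independence screening ranks CpGs by the absolute standardized coefficient
against the outcome (adjusted for exposure and covariates) and keeps the
top $\lfloor 2n/\ln n \rfloor$ — at this study's per-model sample sizes
(154–215) that is 61–80 markers, and the multiplier is exposed because
small cohorts may loosen it. The outcome is then regressed on all screened
CpGs (penalized) plus exposure and covariates (unpenalized) under the
minimax concave penalty ($\gamma = 3$, 50 log-spaced penalties, warm
starts). The solver is coordinate descent in compiled code; binomial
outcomes use the majorize–minimize quadratic bound with weight 1/4 and the
adaptive rescaling of the penalty concavity to the coordinate curvature —
without it the firm-threshold update is undefined at $\gamma = 3$ for
logistic loss. The penalty is chosen by BIC computed on *unpenalized
refits* of each active set: near the activation threshold the penalized
estimates are still shrunk, and a plugged-in deviance systematically
favours the null model (we observed a mediator with a Wald $z \approx 3.9$
being rejected by plugged-in BIC). Deep-path penalties whose active set
exceeds `dfmax` or whose fit does not converge head into quasi-separation;
they are flagged and excluded from selection, and an error (carrying the
penalty value) is raised only if no grid point converges. Selected CpGs
get a joint-significance p-value $\max(p_a, p_b)$, BH-adjusted over the
selected set.

**Gene-based kernel test (gHMA).** CpGs are assigned to their nearest gene
within 20 kb (BED 0-based annotation; 1-based CpG positions; distance ties
break towards the smaller gene start, then the lexicographically smaller
id). Member CpGs are centred and scaled and summarized by the fewest
kernel principal components reaching an explained-variance threshold
(0.7/0.8/0.9 ladder; 0.8 default) — a linear kernel for the linear test, a
Gaussian kernel with median-pairwise-distance bandwidth for the nonlinear
test. Each stage is tested jointly (multivariate test of exposure → PCs;
likelihood-ratio test of the PC block in the outcome model), the gene
p-value is the maximum of the two, the omnibus test combines linear and
nonlinear p-values by the Cauchy combination rule, and omnibus p-values
are BH-corrected across genes. The upstream method is summarized at
contract level from a one-paragraph description; the internal statistics
here (Pillai trace for the multivariate stage, LRT for the outcome stage,
Cauchy omnibus) are this package's reconstruction and are validated by
size and reduction properties — a single-CpG gene reproduces the
single-mediator joint-significance test exactly — not against the original
implementation.

## The pipeline and its multiplicity structure

`run_h1()` evaluates, per exposure: each MRS as mediator (causal mediation
directly), then single-CpG nomination by the enabled methods, then
validation of every nominated CpG with `estimate_effects()`. `run_h2()`
swaps the roles: baseline sensitization is the (binary, logistic-model)
mediator and the follow-up MRS / CpGs are continuous outcomes, nominated
by the composite-null test only. Direction integrity is structural: H1
consumes baseline methylation and follow-up sensitization, H2 baseline
sensitization and follow-up methylation.

Multiple-testing families mirror the study design: one BH correction
pooled over all H1 validations (across exposures), one over all H2
validations, and the MRS mediations corrected within each direction.
Exposure–mediator adjustment sets default to the minimal sufficient sets
from the study's causal diagrams (smoking: SES; family history: SES and
NO2; PRS: sex); mediator–outcome models default to the full covariate list
(sex, baseline age, season, BMI, SES, NO2, cell proportions with one
simplex-redundant column dropped). The exact mediator–outcome sets in the
original analysis live in supplementary material not restated here, so
they are configuration (`covariates_mo`), not constants. Complete cases
are taken per model, and each model's effective n is recorded in the run
manifest.

The sensitivity suite re-estimates every validated mediation under
cell-type-augmented exposure–mediator adjustment, after excluding children
already sensitized at baseline (H1 only), and within sex strata; strata
below `min_stratum` (30 by default) are skipped with a warning, matching
how underpowered strata are reported rather than force-fit.

## The synthetic cohort

The generator emulates the marginal structure of the cohort the design is
drawn from: maternal smoking ≈ 7.5%, family history ≈ 64.5%, male sex
≈ 57.7%, PRS ~ N(0.2, 1), sensitization rising from ≈ 31.6% at baseline to
≈ 44.9% at follow-up (via a persistence log-odds term, 2 by default),
covariates with the published means and SDs, and 6-part cell proportions
from a Dirichlet calibrated to typical child blood composition.
Methylation is simulated on the M-value (logit) scale, where Gaussian
residual noise (`noise_sd`, default 0.5 — chosen as a typical EPIC-array
CpG M-value SD before any test was run) is natural, and mapped through the
inverse logit, which guarantees beta values strictly in (0, 1). Planted H1
paths write $a \cdot X$ into the baseline M-values of chosen CpGs and
$b \cdot M$ into the follow-up sensitization log-odds; planted H2 paths
write $c \cdot X$ into baseline sensitization and a $d$ shift into
follow-up M-values of sensitized children. All other CpGs are null given
any configured confounders. One global seed expands into named substreams
(cohort, planted signal, each methylation time point, genotypes, weights,
positions), so enlarging the methylome never perturbs the phenotype draws
— a property the suite asserts.

What the generator does *not* emulate: probe-level array noise, genomic
correlation structure among CpGs (they are independent given confounders),
linkage disequilibrium among SNPs, or any real joint distribution of
covariates (independent by default; the exposure/mediator/outcome effects
of any covariate are configurable). Passing tests therefore demonstrate
the statistical machinery under clean, known-truth conditions, not
robustness to array artefacts or correlated nulls.

## Numerical choices and limitations

* Logistic fits guard against separation (error when coefficients
  diverge); scan-level logistic fits that fail IRLS return the marker as
  dropped-with-warning rather than poisoning downstream p-values.
* The MCP solver's convergence tolerance is $10^{-4}$ on standardized
  coefficients for binomial loss (the penalized-regression standard) and
  $10^{-8}$ for Gaussian loss, where the unpenalized-limit identity with
  OLS is asserted at $10^{-6}$.
* Kernel PCA eigenvalues below $10^{-10}$ are treated as numerically zero
  when counting explained variance.
* Proportion-mediated summaries exclude near-zero-total-effect draws, as
  above.
* Power at realistic single-CpG effect sizes is modest: with
  `noise_sd = 0.5`, a planted mediator→outcome log-odds of 0.5 yields a
  path Wald $z \approx 2$–2.5 at $n = 500$, so a single weakly planted CpG
  among 1000 nulls is recovered by the screen–penalize–joint pipeline in a
  minority of replicates — the oracle power of the mediator–outcome test
  alone (perfect selection) is ≈ 0.5 at $\alpha = 0.05$ under those
  conditions, which upper-bounds any selection procedure. The end-to-end
  recovery tests therefore plant stronger paths (e.g. $b = 1.2$–1.5),
  where recovery is reliable, and the weak-signal condition is reported as
  measured.

## Problem sizes used by the test suite

The suite regenerates all data in code. The statistical acceptance checks
use: 5 replicated decomposition fits per family (additivity identity);
complete-null composite-null calibration over 200 replicates of 5000
markers at $n = 150$; ACME recovery and CI coverage over 200 linear–linear
cohorts of $n = 2000$; planted-mediator recovery over 60 seeds at
$n = 500$ with 1001 CpGs; direction-specificity over 24 seeds of paired
forward/reverse runs at $n = 400$ with 150 CpGs; and exact-oracle
comparisons (BH over 1000 random vectors, firm-threshold closed form,
exhaustive greedy pruning, rank-sum AUC). `scripts/acceptance.R` recomputes
the same quantities from scratch at comparable sizes under a caller-chosen
seed.

## A worked example

```{r example, eval = FALSE}
library(epimediate)

cfg <- sim_config(
  n_samples = 400, n_cpgs = 250, seed = 11,
  planted_h1 = plant_h1(3, a = 0.6, b = 1.2, exposure = "prs"),
  planted_h2 = plant_h2(7, c = 1.0, d = 0.6, exposure = "family_history"))
study <- simulate_study(cfg)

rc <- run_config(methods = c(dact = TRUE, hima = TRUE, ghma = FALSE),
                 n_draws = 300, seed = 5)
h1 <- run_h1(study, rc)
h2 <- run_h2(study, rc)
tidy(h1)
autoplot(h1)
write_report(h1, "results/")
```

The forward run nominates and validates the CpG carrying the planted
exposure→methylation→sensitization path; the reverse run recovers the CpG
shifted by prior sensitization, and the follow-up MRS built from weight
tables loaded on that CpG shows a significant indirect effect through
sensitization — the qualitative pattern that separates "methylation as
cause" from "methylation as consequence".
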