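---
title: "Mixture-model normalization of non-targeted GC/MS data: model, assumptions, and benchmark"
author: "mixnormr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model normalization of non-targeted GC/MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixnormr)
```

## The problem

Non-targeted GC/MS metabolomics quantifies relative abundances (log2 MS
peak areas) of hundreds of metabolites without analyte-specific
calibration. Large studies must batch samples over weeks or months, and
instrument state shifts between batches produce additive, per-metabolite
batch effects on the log2 scale, plus drift with injection position
("run order") within a batch. A second, less obvious problem compounds
the first: each batch has its own *detection threshold*, an abundance
floor below which a metabolite's peak is simply not reported. Low-abundance
metabolites are therefore missing not at random — they vanish
preferentially in batches with high thresholds or unlucky (negative) batch
effects. Normalizers that drop or impute the missing cells misestimate
both location and variability exactly where correction matters most.

`mixnormr` estimates batch and run-order effects per metabolite from
pooled quality-control (QC) samples — aliquots of a common pool injected
in every batch, so that all between-QC variation is technical — under a
likelihood that models the missingness mechanism explicitly, and then
removes the estimated effects from every sample as location shifts.

## The model

For QC sample $i$ and one metabolite, let $\delta_i$ indicate detection,
$y_i$ the observed log2 abundance when detected, and $T_i$ the detection
threshold of the sample's batch. The likelihood contribution is

$$\left[(1-p_i) + p_i\,\Phi\!\left(\tfrac{T_i-\mu_i}{\sigma}\right)\right]^{1-\delta_i}
  \left[p_i\,\tfrac{1}{\sigma}\phi\!\left(\tfrac{y_i-\mu_i}{\sigma}\right)\right]^{\delta_i},$$

with a logistic model for presence, $\mathrm{logit}(p_i) = x_i'\beta$, and
a linear model for the mean, $\mu_i = z_i'\alpha$. A non-detection arises
either from true absence (probability $1-p_i$, allowing for compound
degradation) or from presence below the threshold (the normal mass below
$T_i$). The residual variance $\sigma^2$ is assumed constant across
batches conditional on the technical covariates — plausible for QC
aliquots from a single pool, and the assumption that keeps the
per-metabolite parameter count manageable with 3 QCs per batch.

Covariates are technical only: batch indicators (both components), a QC
pool type indicator when several pools are used, and optionally a
run-order term in the mean model (log run order by default, the form that
fits typical within-batch drift; linear and quadratic forms are
selectable). The presence model may use fewer covariates than the mean
model; detect/non-detect data carry less information.

Estimation is by BFGS on $(\beta, \alpha, \log\sigma)$ with the analytic
gradient; optimizing $\log\sigma$ keeps the domain open. Starting values
are least squares on the detected values for $\alpha$, the logit of the
observed detection fraction (clipped to $[0.01, 0.99]$) for the logistic
intercept, and the complete-case residual SD for $\sigma$; one seeded
jittered restart is attempted on non-convergence (gradient sup-norm
$\le 10^{-6}$ or relative function change $\le 10^{-10}$, at most 500
iterations). The censored-component log term is evaluated with log-space
addition of $\log(1-p_i)$ and $\log p_i + \log\Phi(\cdot)$, so extreme
linear predictors underflow gracefully.

## Numerical and design choices

**Thresholds.** $T_i$ is the minimum *detected* value of the metabolite in
the batch containing sample $i$, computed over all samples in the batch
(QC and analytical — detectability is a property of the instrument run,
not of the sample class). This per-metabolite reading of the batch
threshold is a deliberate choice: a single batch-wide threshold across
metabolites would ignore that peak detection operates per compound. When a
batch has no detection at all for a metabolite, the metabolite's global
minimum detected value is substituted so the truncation probability
remains computable.

**Degenerate configurations.** With every value detected the logistic
component carries no information; it is bypassed ($p \equiv 1$) and the
fit reduces to Gaussian least squares, to which the full optimization also
converges (the package tests both routes). With no detected value the MLE
does not exist and the metabolite is reported unfittable. In between sits
the practically important case of a *batch* with no detected QC: its batch
coefficient is unidentifiable — the likelihood is flat once the batch mean
is far enough below the threshold, and the batch's logistic indicator
separates — and a quasi-Newton iterate simply drifts along the flat
direction to an arbitrary stopping point. Applying such a drifted
coefficient as a correction can be catastrophic (corrections of tens of
log2 units). `fit_mixnorm()` therefore drops those QC rows and indicator
columns from the maximization, then estimates the batch's level from the
information non-detection does carry: with all $q$ of the batch's QCs
below the threshold $T$, the batch QC level $m_k$ satisfies a one-sided
constraint, and its coefficient is set to the posterior mean of $m_k$
under a Gaussian prior centered at the cross-batch mean QC level with
spread equal to the standard deviation of the fitted batch coefficients,
conditioned on $\Pr(\text{all } q \text{ QCs} < T) =
\Phi((T-m_k)/\hat\sigma)^q$ (one-dimensional quadrature). This uses the
censored observations the way the likelihood intends — as evidence the
batch runs low — while staying bounded. When fewer than three batch
coefficients are available to set the prior, the batch falls back to the
average estimated correction (no shift relative to the cross-batch
anchor).

**Referent and anchor.** The referent batch (indicator coefficient 0) is
the batch whose QC median abundance is the median across batch medians,
with ties broken toward the lower batch label. After subtracting each
sample's fitted batch and run-order terms, the unweighted mean of the
batch coefficients is added back, so normalized values sit at the
cross-batch average location; this makes the output invariant to the
referent choice. The raw-referent behavior is available via
`anchor = "referent"` for comparison, since the anchoring convention is
genuinely open — it changes only the per-metabolite location, not
variability or associations.

**QC-type shifts.** With multiple QC pools, the pool-type coefficient is
always estimated (batch and run-order effects are estimated jointly from
all QCs) and always removed from QC samples, aligning the pools. It is
applied to analytical samples only on request (`apply_qc_type_shift`),
with a user-supplied mapping from analytical class to pool type.

**Outlying QCs.** An optional pre-fit filter drops QC observations beyond
`qc_outlier_k` SDs of the metabolite's QC mean (off by default; in
well-controlled data QCs rarely exceed 3 SD, but the filter is there for
messier runs).

**Never imputation.** No step writes a value into an undetected cell; the
detection mask is preserved cell-for-cell by every normalizer in the
package.

## Comparator normalizers

Three standard methods are included for benchmarking, all operating on
detected values only: per-metabolite batch **mean centering** (subtract
batch mean minus grand mean), batch **median scaling** (divide by the
ratio of batch median to overall median), and **quantile normalization**
across samples (delegated to `limma::normalizeQuantiles`, which
interpolates when detected counts differ and averages target quantiles
for ties). Published batch-correction methods beyond these can be attached
via `register_normalizer()` and then participate in `run_benchmark()`
without being reimplemented here.

## What the simulator emulates

`simulate_experiment()` generates the study design used throughout
validation: 150 metabolites; 20 batches of 24 analytical + 3 QC samples
(480 + 60). Per-metabolite mean abundances $\alpha_m \sim N(18, 2^2)$
(log2 scale, matching typical GC/MS peak areas of 13.5–23.5); analytical
phenotypes $v_i \sim N(0,1)$ with per-metabolite effects
$\beta_m \sim N(0,1)$; measurement noise $N(0, (0.03\,\alpha_m)^2)$; batch
effects $b_{mk} \sim N(0, 2^2)$ added identically to QC and analytical
samples of a batch; and batch detection thresholds spanning 12.5–15 in 20
equal increments, permuted onto batches anew each round. Everything below
a batch's threshold is marked undetected. $\alpha_m$, $\beta_m$ and $v_i$
are drawn once and held constant across rounds (two separate seed
streams), so round-to-round variation isolates noise, batch effects and
truncation. QCs sit at run-order positions 1, 14 and 27 of each 27-sample
batch — placement is informational only, as no run-order effect is
simulated.

These settings put true QC RSD near 3% and true analytical RSD near 5.8%,
and produce per-metabolite undetected fractions from 0 to above 80%
depending on $\alpha_m$ — the regime in which the truncation model
matters.

What the simulator deliberately does *not* emulate: correlated
metabolites, retention-time drift, peak-shape artifacts, run-order
effects, or heteroscedastic batch noise. Passing benchmarks here
demonstrates correct recovery of additive batch structure under
batch-specific truncation; it does not certify behavior under those
additional real-data phenomena.

## Evaluation metrics and benchmark scale

`run_benchmark()` pools per-metabolite RSDs (100·SD/mean over detected
values, sample SD) across all (metabolite, round) pairs — pooling all
pairs, rather than summarizing within round first, is the adopted
convention. Metabolites above 80% undetected in a round are omitted from
that round's metrics; recovery of true RSD is summarized by no-intercept
regression slopes of estimated on true RSD within 5%-wide missingness bins
(exact zero its own bin, bins left-open/right-closed). Phenotype
association scans run per metabolite as ordinary least squares on detected
values and as the downstream mixture model (phenotype in both components,
Wald test on the linear coefficient); true-positive probability at
threshold $t$ is the rejection fraction at $p < 0.05$ among tests with
true $|\beta_m| \ge t$, and the false-positive set is operationalized as
$|\beta_m| < 0.05$, the smallest grid point, since "effectively null"
needs a concrete cut. No multiplicity correction is applied — the metric
is the per-test error rate. QC-sample comparability uses pairwise Spearman
correlations (average ranks for ties, pairwise-complete cells, metabolites
at ≥20% detection), and agreement with calibrated targeted assays uses
per-analyte Spearman correlations by sample class.

The package's acceptance tests and `scripts/acceptance.R` run this
benchmark at 100 rounds — the scale at which the pooled summaries are
stable to well within the tolerances checked, chosen as the package's
standard validation size. Example at toy scale:

```{r benchmark, eval = FALSE}
cfg <- sim_config(n_metabolites = 30, n_rounds = 5)
report <- run_benchmark(cfg, n_rounds = 5,
                        methods = c("none", "mixnorm", "mean_center"))
report$rsd_summary
```

## Known limitations

- Batch effects are modeled as pure location shifts; batch-specific
  variance changes are not corrected (the constant-$\sigma$ assumption).
- Per-metabolite fitting ignores correlation between metabolites; no
  information is shared across compounds.
- A batch whose QCs are all undetected for a metabolite receives a
  prior-shrunk posterior-mean correction rather than a maximum-likelihood
  one; its accuracy depends on the batch-effect spread being well
  estimated from the other batches, and the substituted threshold (the
  metabolite's global minimum detected value) can understate the batch's
  true detection limit.
- The logistic component is plain maximum likelihood; with few QCs and
  many batches its coefficients for sparsely detected batches are noisy
  (harmless for normalization, which uses only the linear component, but
  visible in `wald_test()` on logistic coefficients).
- Estimation uses QC samples only; phenotype balance across batches is an
  experimental-design matter the software cannot repair.
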