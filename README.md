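# mixnormr

Mixture-model normalization for non-targeted GC/MS metabolomics.

Large metabolomics studies run samples in batches over weeks; instrument
state shifts between batches add per-metabolite effects to log2 peak
areas, sensitivity drifts with injection position, and — the part most
normalizers ignore — each batch has its own detection threshold, so
low-abundance metabolites go missing *not at random*. `mixnormr` is for
analysts of batched GC/MS experiments that include pooled quality-control
(QC) samples in every batch: it estimates batch and run-order effects per
metabolite from the QCs under a likelihood that models the missingness
mechanism, and removes them from all samples as location shifts, without
dropping or imputing undetected values.

## The model

For QC sample *i* and one metabolite, with detection indicator δᵢ,
observed log2 abundance yᵢ, and batch detection threshold Tᵢ, the
likelihood contribution is

    [(1 − pᵢ) + pᵢ Φ((Tᵢ − μᵢ)/σ)]^(1−δᵢ) · [pᵢ · φ((yᵢ − μᵢ)/σ)/σ]^δᵢ

where logit(pᵢ) = xᵢ′β governs presence (true absence has probability
1 − pᵢ; presence below the threshold contributes the normal mass below
Tᵢ) and μᵢ = zᵢ′α is the mean model. Covariates are technical: batch
indicators in both components, optionally a QC pool-type indicator and a
log run-order term in the mean model. Fitting is maximum likelihood by
BFGS with analytic gradients, per metabolite; the fitted batch and
run-order terms are then subtracted from every sample (QC and
analytical), anchored at the cross-batch average. Batch mean centering,
batch median scaling, and quantile normalization are included as
comparators, and a full simulation benchmark with ground truth measures
what each method recovers.

## Worked example

Simulate one round of a batched experiment (150 metabolites, 20 batches
of 24 analytical + 3 QC samples, batch effects and batch-specific
truncation), normalize it, and compare QC variability:

```r
library(mixnormr)

cfg <- sim_config()                       # the benchmark study design
sim <- simulate_experiment(cfg, round_index = 1)
sim$matrix
#> abundance_matrix: 150 metabolites x 540 samples (91.5% detected)

qc <- is_qc(sim$annotation)
model <- fit_mixnorm(sim$matrix, sim$annotation, min_detection = 0)
model
#> mixnorm_model: 150/150 metabolites normalizable; covariates x = {batch}, z = {batch}
normalized <- apply_mixnorm(model, sim$matrix, sim$annotation)

round(c(truth     = mean(sim$truth$true_rsd_qc),
        raw       = mean(rsd_per_metabolite(sim$matrix, qc), na.rm = TRUE),
        mixnorm   = mean(rsd_per_metabolite(normalized, qc), na.rm = TRUE)), 2)
#>   truth     raw mixnorm
#>    2.99   10.07    2.44
```

The mean per-metabolite QC RSD (100·SD/mean over detected values) is ~3%
by construction before batch effects, is inflated above 10% by them, and
returns to ~2.4% after normalization — slightly below truth because the
batch fit absorbs some within-batch noise. The same corrections applied
to analytical samples preserve their biological variability (phenotype
effects), which is the point: technical noise out, signal intact.

Real data come in as tab-delimited files via
`read_dataset(matrix_path, annotation_path)` (metabolites × samples
matrix with `NA` for undetected; annotation with `sample_id`, `batch`,
`run_order`, `sample_class`). A thin CLI with `simulate`, `normalize`,
`evaluate` and `benchmark` subcommands is installed at
`inst/cli/mixnormr`.

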