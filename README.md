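# masldstage

Transcriptomic staging of MASLD (metabolic dysfunction-associated steatotic
liver disease) from severity-associated gene signatures.

Histology grades MASLD on two ordinal axes — the activity score NAS (0–8)
and fibrosis stage (F0–F4) — but histology is unavailable for most archived
expression data, and mouse-model severity is hard to place on the human
scale at all. `masldstage` derives a severity signature from graded human
liver RNA-seq cohorts and uses it to stage any liver transcriptome, human
or mouse:

1. **Severity regression.** Per gene, a negative-binomial GLM
   `log μ = batch + sex + β_nas·NAS + β_fib·fibrosis + log(size factor)`
   fit by IRLS with per-gene ML dispersion. Severity DEGs are genes with
   `|log2FC| > 0.1` per NAS unit or `> 0.2` per fibrosis unit at
   BH-adjusted `p < 0.05`, hierarchically clustered into the three
   recurrent progression patterns (down, up, up-then-down).
2. **Signature selection.** Boruta shadow-feature selection over the DEGs
   (random-forest importance vs. permuted shadow copies, binomial hit test),
   then curation to Boruta-confirmed, positively associated genes with a
   mouse ortholog — a unified human–mouse signature.
3. **Scoring.** Single-sample GSEA: with rank weights `r_i = n − i + 1`,
   `ES = Σ_i [ P_in(i) − P_out(i) ]` where `P_in` is the `r^α`-weighted
   in-set ECDF (α = 0.25) and `P_out` the unweighted out-of-set ECDF.
   Scores depend only on within-sample ranking.
4. **Staging.** Spearman validation of scores against NAS/fibrosis; query
   (mouse) samples are pooled with annotated human references on the
   ortholog-shared gene universe and mapped to the severity of their k = 5
   nearest reference neighbors in enrichment score; concordant
   human–mouse DEGs are counted per timepoint.

A synthetic multi-cohort generator (NB counts, planted per-NAS/per-fibrosis
effects in three pattern clusters, batch and sex nuisance effects,
correlated NAS/fibrosis, an ortholog-linked mouse time-course) makes every
stage verifiable without downloads; all planted values are returned as
ground truth.

## Worked example

```r
library(masldstage)
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "masldstage_out")
writeLines(res$run_log)
```

```
masldstage 0.1.0 | R 4.3.3
seed=1 boruta_n_iter=100 boruta_alpha=0.05 ssgsea_alpha=0.25 k=5
thresholds: lfc_nas=0.1 lfc_fib=0.2 alpha=0.05 mouse_lfc=1
severity DEGs: 266 (up 139, down 127, ambiguous 5)
Boruta confirmed: 198 of 266 candidates
unified signature: 104 genes
held-out Spearman rho: NAS 0.9676 (p=2.33e-36), fibrosis 0.9638 (p=5.52e-35)
```

Reading: from two simulated training cohorts (150 samples, 2000 genes,
300 planted severity genes) the pipeline calls 266 severity DEGs, Boruta
confirms 198, and curation (positive association + mouse ortholog) leaves a
104-gene unified signature. On a held-out simulated cohort of 60 samples
the signature's ssGSEA scores correlate with the planted NAS at Spearman
ρ = 0.97. `res$staging` places each mouse sample on the human NAS scale
(the planted week 0→16 ramp maps to monotonically increasing NAS), and
`res$overlap` counts concordant human–mouse DEGs per timepoint.

Individual stages are available as plain functions — `generate_human_cohorts()`,
`median_of_ratios_size_factors()`, `vst_transform()`, `de_severity()`,
`call_severity_degs()`, `boruta_select()`, `curate_signature()`,
`ssgsea_matrix()`, `spearman_validate()`, `rank_map_to_human()` — and as a
thin CLI (`inst/scripts/masldstage-cli.R`) with subcommands
`simulate | normalize | de | signature | score | stage | validate | run`.

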