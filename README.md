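# tcelldyn

Translational and outcome analytics for biomarker-directed immunotherapy
trials in checkpoint-refractory cancer, built around three data classes
that such trials collect:

1. **Longitudinal blood TCR-β repertoires** (immunoSEQ or AIRR
   Rearrangement clonotype tables at scheduled visits) — parsing,
   productive filtering, diversity/clonality summaries, repertoire
   overlap, and per-clonotype expansion calling between visits.
2. **Tumor gene expression** (TPM matrices or hybridization panel
   counts) — single-sample GSEA scoring of inflammation signatures such
   as the 18-gene tumor inflammation signature (TIS), subgroup rank-sum
   comparisons, panel normalization, and longitudinal mixed-effect
   modeling of signature scores.
3. **Clinical records** (RECIST assessments, survival, biomarker
   covariates) — response-rate arithmetic, resistance/TMB/PD-L1
   classification, progression-free survival with protocol missed-visit
   censoring, and Kaplan–Meier estimation with 80% confidence intervals.

A seeded simulator generates all three input classes with ground-truth
labels, so every stage is testable without patient data.

## The statistics at the core

**Clone expansion calling.** For each clonotype in the union of a
patient's two visits, with counts $a, b$ and template totals $n_A, n_B$,
the two-sided Fisher exact test on
$\begin{pmatrix} a & n_A-a \\ b & n_B-b \end{pmatrix}$
tests the null that the clone's population abundance is identical at the
two visits. P-values are Benjamini–Hochberg adjusted across all tested
clones of the pair; clones with $q < 0.01$ are called expanded or
contracted by the sign of the frequency change. A significantly expanded
clone absent at the first visit and detected above 5 reads at the second
is a **newly detected expanded clone**.

**Repertoire summaries.** For productive clone frequencies $f_i$ with
richness $R$: Shannon entropy $H=-\sum_i f_i \ln f_i$, Pielou evenness
$J=H/\ln R$, and clonality $C = 1 - J \in [0,1]$ (0 = perfectly even,
1 = monoclonal). Between-sample overlap is the Morisita–Horn index
$MH = 2\sum_i p_i q_i \,/\, (\sum_i p_i^2 + \sum_i q_i^2)$, which is
dominated by the abundant clones.

**ssGSEA.** Within each sample, genes are ranked by expression; in-set
genes are weighted by $\mathrm{rank}^{0.25}$ and the enrichment score is
the sum over the ordered gene list of the difference between the
weighted in-set ECDF and the uniform out-of-set ECDF, optionally
normalized by the score range across samples. Scores depend on ranks
only.

**Endpoints.** ORR counts confirmed CR/PR over all treated patients;
DCR requires holding CR/PR/SD through the 12- or 24-week landmark. PFS
events (first progression or death) occurring after two or more missed
scheduled assessments are censored back at the last evaluable
assessment; imaging is scheduled every 6 weeks (±1) to week 24 and every
8 weeks (±1) thereafter. Kaplan–Meier medians use the smallest event
time with $S(t) \le 0.5$, with Brookmeyer–Crowley median CIs from
Greenwood log(−log) bands at the 80% level.

## Worked example

Simulate two patients' repertoires with one clone injected to expand
10-fold at cycle 1 day 1, then call dynamics:

```r
library(tcelldyn)

sim <- simulate_longitudinal_repertoires(
  n_patients = 2, n_clones = 500, depth = 5000,
  expansion_events = data.frame(clone = 25L, visit = "C1D1",
                                fold = 10, target_freq = NA),
  seed = 7)
s <- sim$repertoires$PT001$samples
clonality(s$C0D1)
#> # A tibble: 1 × 4
#>   richness entropy evenness clonality
#>      <int>   <dbl>    <dbl>     <dbl>
#> 1      459    4.70    0.767     0.233

res <- classify_dynamics(s$C0D1, s$C1D1, alpha = 0.01, read_threshold = 5)
subset(res$tests, direction != "unchanged")[
  , c("count_a", "count_b", "q_value", "direction")]
#> # A tibble: 1 × 4
#>   count_a count_b  q_value direction
#>     <int>   <int>    <dbl> <chr>
#> 1      30     262 6.53e-46 expanded
```

The injected clone (rank 25, ~30 of 5,000 templates at baseline) is the
single significant call: its count rises to 262 with $q \approx
10^{-46}$, while all 494 null clones stay unchanged — the calibrated
behavior of BH at $q < 0.01$.

Simulate a four-arm clinical cohort at the trial's arm sizes and
estimate the ATR-combination arm's outcomes:

```r
cohort <- simulate_clinical_cohort(seed = 7)
cer <- cohort$patients[cohort$patients$module == "durvalumab_ceralasertib", ]
compute_orr(cer, cohort$assessments)
#> 12.7% (10/79)
surv <- derive_survival(cer, cohort$assessments)
km_estimate(surv$pfs_time, surv$pfs_event)
#> <survival_curve> n = 79, events = 76; median = 32 (80% CI 24-39.1)
```

The arm was simulated with a 13.9% responder probability and a latent
median PFS of 25.1 weeks; the estimated ORR is 12.7% (binomial noise at
n = 79) and the KM median lands on the week-32 scan because progression
is only observed at scheduled imaging.

The full pipeline (`simulate_study_inputs()` → `run_pipeline()`, or the
thin CLI at `inst/scripts/pipeline.R` with subcommands `simulate` and
`run-all`) writes per-stage TSV tables, a `summary.json` and a parameter
log, and reproduces byte-identically on re-run.

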