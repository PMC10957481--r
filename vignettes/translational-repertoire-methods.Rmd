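---
title: "Methods: repertoire dynamics, signature scoring and trial endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire dynamics, signature scoring and trial endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcelldyn)
```

This vignette documents the statistical procedures tcelldyn implements,
the conventions chosen where the methods literature leaves room, and
what the in-package simulators do and do not establish about behavior on
real data.

## Clonotype tables and productivity

A clonotype is a unique TCR-β rearrangement; by default its identity key
is the CDR3 nucleotide sequence plus V and J calls (`id_key = "nt_vj"`),
matching rearrangement-level vendor reporting. A nucleotide-only key
(`id_key = "nt"`) is available because public datasets differ in how
they deduplicate; the choice is recorded in the parsed object so results
are reproducible. Rows sharing a key are merged by summing template
counts. Counts must be non-negative integers — the downstream Fisher
test is defined on integer templates, so fractional counts are rejected
rather than rounded.

Productivity is taken from the table's own `productive`/`frame_type`
column when present, on the view that the vendor's frame call is
authoritative; otherwise it is derived (non-empty amino-acid junction,
no stop symbol, nucleotide length divisible by three). Only productive
clonotypes enter any statistic. A sample whose clones are all
unproductive is flagged empty, and every statistic refuses it
explicitly rather than returning NaN.

## Diversity and overlap

For productive frequencies $f_i$ with richness $R$: entropy
$H = -\sum f_i \ln f_i$, evenness $J = H/\ln R$, clonality $C = 1 - J$.
Natural logarithms are used; the base cancels in $J$, so this is purely
cosmetic. Conventions for degenerate inputs:

* $R = 1$: $J$ is 0/0. The limit of increasing concentration gives
  $C \to 1$, so a monoclonal repertoire is defined as $C = 1$ (with a
  warning, since a richness-1 blood repertoire usually signals an
  upstream filtering problem).
* Zero-count clones (possible after merging) are dropped before the
  entropy sum, i.e. $0 \ln 0 := 0$.
* $C$ is clamped to $[0, 1]$ against floating-point drift.

The label "Simpson's clonality" is sometimes attached to
$\sqrt{\sum f_i^2}$ in the repertoire literature; this package
implements the evenness-complement form $1 - H/\ln R$ throughout, which
is the operational definition used in the trial analyses it follows.
The formula, not the name, is what is computed.

Morisita–Horn overlap is computed on template frequencies over the union
of clonotype keys. An alternative is presence-weighted overlap; template
frequencies were chosen because the index is meant to track the
distribution of clonotype sizes, and this is exposed nowhere as an
option to keep reported overlap values comparable across runs.

## Clone expansion testing

Each clonotype in the union of a visit pair contributes a 2×2 table
(clone templates vs all other templates, at each visit). The two-sided
Fisher exact p-value sums, over the conditional hypergeometric support,
all table probabilities not exceeding the observed one (with the
conventional $1 + 10^{-7}$ relative tolerance, matching
`stats::fisher.test`). The implementation is a vectorized `dhyper`
computation — clone counts are small relative to depth, so each support
is short — and is verified in the test suite against both
`stats::fisher.test` and an independent `lchoose`-based enumeration over
every table with totals ≤ 30. P-values are floored at the smallest
positive double so that BH adjustment, defined on $(0, 1]$, is always
applicable.

Conventions, each configurable:

* BH family = the tested clones of that visit pair (the union of
  clonotypes observed at either visit); significance is strict,
  $q < \alpha$ with $\alpha = 0.01$.
* Direction comes from the frequency comparison, not the test; the test
  is two-sided, so a significant clone with $f_B > f_A$ is expanded and
  with $f_B < f_A$ contracted. No minimum fold-change is applied.
* Newly detected expanded clones: absent at the first visit
  (`count_a == 0`) and strictly above 5 reads at the second. By default
  this is restricted to Fisher-significant expanded clones — the rule is
  read as selecting among expanded clones — with
  `newly_requires_significance = FALSE` giving the looser
  absence-plus-count reading for sensitivity analysis.

Cohort-level comparisons of per-patient values between visits use the
two-sided Wilcoxon paired signed-rank test on complete pairs, zero
differences dropped, exact null distribution up to 25 non-zero pairs and
the continuity-corrected normal approximation above, BH-adjusted across
the comparison set. All-zero-difference comparisons are skipped with a
warning rather than reported as $p = 1$, since the statistic is
undefined there.

## ssGSEA

The enrichment score follows the weighted-ECDF single-sample form: genes
ranked by expression within the sample (average ranks for ties), in-set
genes weighted by $\mathrm{rank}^\alpha$ with $\alpha = 0.25$, and the
score equal to the sum over the ordered list of (weighted in-set ECDF −
uniform out-of-set ECDF). Normalization by the score range across
samples is on by default, emulating the behavior of the widely used
implementation; both modes are tested against an independently written
naive reference to $10^{-10}$.

One detail the usual descriptions leave open: when two genes tie on
expression, their weights are equal (average ranks) but their *order* in
the running sum still matters. Tied positions are ordered
deterministically by gene id, in both the implementation and the
reference, so scores are reproducible across platforms. Constant
expression within a sample triggers a warning (every gene ties).

Signatures are data, not code: the 18-gene TIS ships as an editable GMT
file under `inst/extdata/signatures/` populated from the published
signature, and any signature can be supplied via `read_gene_sets()`.
Symbol matching is case-insensitive exact matching after whitespace
stripping, with no alias resolution — deterministic, at the cost of
missing renamed symbols; at least 50% of a signature must match or the
scorer errors listing the missing genes. Subgroup comparisons of scores
use the two-sided Wilcoxon rank-sum test with deliberately *no*
multiplicity adjustment, mirroring exploratory subgroup reporting;
treat these p-values accordingly.

Gene-wise z-scoring (for heat-map display) uses the population
(divide-by-$n$) standard deviation; zero-variance rows become all zeros
with a warning.

Panel counts are normalized per sample by background subtraction (mean
of negative controls plus $k$ SDs, default $k = 0$, floored at zero)
followed by housekeeping scaling to the cohort geometric mean, which
makes housekeeping sums equal across retained samples by construction;
samples with zero housekeeping signal are excluded with a warning.

The longitudinal model for signature scores is
`score ~ visit + (1 | patient)` fitted by maximum likelihood, with a
likelihood-ratio test against the intercept-only model for the global
visit effect and Wald contrasts per visit versus baseline. A random
intercept was chosen over random slopes because the design has at most
three visits per patient, which cannot identify a slope covariance; on
non-convergence the model falls back to paired signed-rank tests with a
warning.

## Clinical endpoints

Classification boundaries: primary resistance is progression on prior
checkpoint blockade within ≤ 24 weeks of starting it (the boundary is
primary), acquired after > 24 weeks; TMB-high is ≥ 10 mutations/Mb;
PD-L1-positive is ≥ 1% tumor cells. The resistance rule based on
progression timing is used rather than the alternative best-response
definition (progression or stable disease lasting under six months)
that appears in some framings of the same concept; the two disagree for
patients with short stable disease, and the timing rule is the one the
enrollment procedure operationalizes.

Best overall response requires confirmation for CR/PR; stable disease
must be held at or after week 6 (the first scheduled assessment,
configurable) to count. ORR uses all treated patients as denominator
and reports to 0.1%. Disease control at a landmark requires no
progression and no death by the landmark (within the ±1-week visit
window) plus an evaluable CR/PR/SD assessment at or beyond the landmark
minus the window.

PFS follows the protocol censoring rule: events (first progression or
death) are kept if at most one scheduled visit was missed since the last
evaluable assessment; with two or more missed visits the patient is
censored back at that last evaluable assessment. A visit is "missed"
when no evaluable assessment falls within ±1 week of its scheduled week
— the protocol gives the schedule (every 6 weeks to week 24, every 8
weeks after) but not a detection rule, so this window-based
operationalization is the package's choice and both the window and the
schedule are arguments.

Kaplan–Meier estimation is delegated to `survival::survfit` (Greenwood
variance, log(−log) confidence bands). The median is extracted as the
smallest event time with $S(t) \le 0.5$ — the pure step-function
convention — rather than `survfit`'s default, which averages the
boundary times when the curve sits exactly at 0.5. The median CI is the
Brookmeyer–Crowley construction read off the bands: the first times the
lower and upper band drop to 0.5. CIs default to 80%, the level used in
signal-finding cohort reporting; pass `ci_level = 0.95` for
conventional intervals.

## What the simulators emulate, and what they do not

The repertoire generator draws latent clone frequencies per patient
(rank$^{-1}$ power law by default, or log-normal) and observes each
visit as an independent multinomial of fixed depth; expansions perturb
the *latent* frequencies before sampling, so called expansions compete
against genuine sampling noise. Defaults — 10³ clones, depth 10⁴ —
were set so that full error-control simulations (200 replicate pairs)
complete in minutes on one CPU while keeping clone frequencies in the
range where the Fisher test is actually exercised. The generator does
not model: shared clones between patients, V/J usage bias, sequencing
error or PCR amplification noise, or correlation of repertoires across
visits beyond the shared latent distribution (each visit is an
independent draw, which is exactly the null the expansion test assumes
— convenient for calibration, optimistic about overdispersion on real
longitudinal blood draws).

The expression generator is log-normal TPM with a mean shift on
signature genes in one group; it has no gene-gene correlation, batch
structure or biopsy-site effects, so rejection-rate results speak to
the test's calibration and power under clean separation, not to
confounded real cohorts.

The clinical generator calibrates exponential progression and death
hazards so the *minimum* of the two has the stated median PFS and death
alone the stated median OS (requiring median PFS < median OS), assigns
responders a confirmed-PR assessment sequence, and records progression
at the first scheduled scan on or after the latent progression time.
That last point matters when interpreting recovery tests: estimated
PFS medians are medians of scan-grid detection times, upward of the
latent median by up to one assessment interval, which is equally true
of real RECIST data. Arm defaults use the reported module sizes and
response counts (79 patients at 11/79 responders; 87, 45 and 57 at
4/87, 0/45 and 1/57) with medians converted from months at 52/12 weeks
per month.

All generators take a mandatory seed, thread it through a
state-restoring wrapper, and never touch global RNG state.

## Problem sizes used in the test suite

Unit and property tests run at reduced scale (tens of patients,
hundreds of clones); the calibration and recovery checks run at the
generators' default study conditions: 200 replicate visit pairs at 10³
clones and depth 10⁴ for false-discovery calibration and for the
50-fold/0.1%-clone recovery check, n = 2000 for the exponential KM
median, and the full study-scale pipeline smoke run (62 repertoire
patients, 48 expression samples, 268 clinical patients). The whole
suite completes in a few minutes on one CPU.

## Known limitations

* The expansion test treats templates as independent draws; true
  template counts are overdispersed (PCR, cell clustering), so nominal
  FDR on real data will be somewhat anti-conservative. The simulators
  quantify calibration only under multinomial sampling.
* ssGSEA normalization by score range couples samples: adding a sample
  can change every normalized score. Use `normalize = FALSE` when
  scores must be stable under cohort growth.
* The mixed model assumes exchangeable patients and homoscedastic
  visits; with only ~3 visits, violations are hard to detect.
* Response categories enter as adjudicated RECIST calls; no
  lesion-level arithmetic is performed.
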