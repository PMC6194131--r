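---
title: "Methods: the copy-number-driven onco-miRNA screen"
author: "oncomiRscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the copy-number-driven onco-miRNA screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncomiRscreen)
```

# The scientific question and the model

Focal copy-number gains can drive oncogene expression even at low
amplitude.  This package screens for mature microRNAs in squamous cell
lung carcinoma (Sq) whose expression (i) tracks the copy ratio of a
precursor locus, (ii) is specifically elevated in Sq relative to
adenocarcinoma (Ad) and normal lung, and (iii) predicts shorter overall
survival.  The three filters are deliberately orthogonal in mechanism —
genomic dosage, histology specificity, clinical outcome — so that a miRNA
surviving all three is a strong onco-miRNA candidate.

The implied generative model is simple and is exactly what the synthetic
cohort generator draws from: for miRNA $m$ in sample $s$,

$$\log_2 \mathrm{CPM}_{ms} \;=\; \mu_m \;+\; \beta_m\, r_{ms}
  \;+\; \delta_m\, \mathbf{1}[s \in \mathrm{Sq}] \;+\; \varepsilon_{ms},$$

where $r_{ms}$ is the segment-mean copy ratio $\log_2(\mathrm{CN}/2)$ at
the precursor locus, $\beta_m$ the dosage slope, $\delta_m$ the
Sq-specific offset, and $\varepsilon$ residual noise.  Survival follows a
proportional-hazards law,
$h_s(t) = h_0 \exp\!\big(\sum_m \gamma_m z_{ms}\big)$, with $z_{ms}$ the
z-scored expression of the prognostic miRNAs.  The screen never fits this
model directly; each stage uses a rank- or counting-process statistic that
is robust to the model's distributional details.

# Stage-by-stage procedure

## Locus assignment and aggregation

Segment means are assigned to precursor loci as the *length-weighted mean*
of all overlapping segments (1-based inclusive overlap in bases).  The
weighted mean is continuous in the breakpoints, deterministic, lies within
the range of the overlapping segment means, and reduces to the segment's
own value when the locus is fully contained — the behaviour one wants when
a hairpin of ~80 bp straddles a segmentation breakpoint.

Mature expression is the sum of all isoform read counts annotated
`mature` for one MIMAT accession, across isoforms and precursor loci.
Fragments annotated `precursor`, `stemloop`, or `unannotated` are
excluded, as are mature miRNAs with miRBase status `dead`/`disputed` or
whose every locus lies on chromosome X/Y (sex-linked dosage would
confound the copy-number signal in a mixed-sex cohort).  Per-sample CPM
totals are taken over **all** mature fragments *before* these exclusions:
the total represents the sample's sequenced mature miRNome, and making it
independent of downstream filter choices keeps CPM values stable under
reconfiguration.  Both choices are configurable at the reader level.

## CNV correlation

Pearson correlation with the $t$-based two-sided p-value, computed on
pairwise-complete samples (a sample missing segmentation at one locus
should not be dropped from unrelated loci).  Thresholds are strict
inequalities: $r > 0.2$, $p < 0.05$.  A mature miRNA produced from
several precursor loci is called CNV-correlated when **any** locus passes;
per-locus results are all reported, so the stricter all-loci rule can be
applied post hoc.  The any-locus rule is the only one consistent with a
screen in which more mature miRNAs pass than distinct loci.

## Differential filter (DEMI)

Wilcoxon rank-sum (normal approximation, midrank ties, continuity
correction) per comparison, BH-adjusted *within* each comparison across
the CNV-correlated candidate set; pass requires $\log_2\mathrm{FC} > 0$
and $q < 10^{-10}$ in both Sq-vs-Ad and Sq-vs-Normal.  The rank test is
the natural choice for heavy-tailed CPM data and is the package default
(configurable).  Fold changes use arithmetic means of CPM with a
pseudocount of 1 CPM to keep zero-mean candidates finite; the pseudocount
is a reported configuration value.  Adjusting within the candidate set
(rather than the full miRNome) matches the cascade logic — only
CNV-correlated miRNAs are hypotheses at this stage; the family is
configurable.

Note the practical meaning of $q < 10^{-10}$: with the normal
approximation the attainable minimum p-value is bounded by the group
sizes, so the filter is only meaningful for cohorts of hundreds of
samples — at the package's default study conditions (240/239/91) a planted
offset of 1.5 log2 units clears it comfortably, while a 40-sample group
never could.  The test suite's reduced cohorts are sized with this in
mind (120/100/50).

## Survival screen

Expression is dichotomized at the **median** over survival-eligible Sq
samples; values strictly greater than the cut-off are `high` (ties fall
`low`).  Median is the default because it is the operational rule of this
screen design; the mean is available by configuration (the run log records
the rule).  Samples lacking survival time or event indicator are dropped
from this stage only.  Per candidate, the log-rank test (ties pooled,
hypergeometric variance) is BH-adjusted across candidates; selection
requires $p < 0.05$, $q < 0.2$, and *worse survival in the high group*
(observed > expected deaths).  The direction check makes the screen
onco-specific: a protective miRNA with an equally small p-value is not an
onco-miRNA candidate.  It can be disabled.

The combination group is `high` when **all** member miRNAs are high, with
everyone else — including all-low samples — as the comparator; the
complement choice is configurable.  All non-empty subsets of the selected
set are reported.

## Bootstrap stability

Patients are resampled with replacement jointly (labels travel with the
patients; resampling is not stratified by expression group, so group-size
variability is part of the assessed instability).  Replicates whose
resample contains a single group or no events are redrawn and counted.
The statistic is the fraction of $B$ replicates with log-rank $p <
\alpha$; defaults $B = 10{,}000$, $\alpha = 0.05$.  `plantNullMirnas()`
provides null comparators, optionally matched on baseline expression — the
matched option exists because an unmatched "random other miRNA" may
differ in expression level, which affects dichotomization granularity.

## Cox models and the proportional-hazards check

The Cox partial likelihood is maximized by Newton–Raphson with the
*Efron* tie correction (the standard default of the field's reference
implementation), convergence when the relative log-likelihood change is
below $10^{-9}$ or 50 iterations, with step-halving.  Monotone
likelihoods (perfect separation) are flagged non-converged and no
estimates are reported.  Per covariate the package reports the hazard
ratio, 95% Wald CI, and Wald p-value — matching the
variable/HR/CI/p layout of a clinical Cox table.  The score test at the
null is also computed; for a single binary covariate without tied event
times it equals the log-rank chi-square, which the test suite exploits as
an oracle identity.

Covariates are categorized deterministically: age high iff strictly above
the cohort median; male = 1 (female reference); smoker iff the recorded
status is exactly "current smoker" (any other or missing status is
non-smoker — the conservative reading of an "otherwise" rule); stage high
for Roman-numeral prefix III or IV ("Stage IIIA" is high); missing or
unknown stage is `NA` and the affected rows are dropped model-wise.

The proportional-hazards diagnostic is the scaled-Schoenfeld slope test
(Grambsch–Therneau approximation): per covariate, a 1-df chi-square for
zero slope of $d\,V^{-1}s_k$ against the **rank** of event time.  The
rank transform is the package default because it is insensitive to the
time scale; the transform is configurable in principle.  Schoenfeld
residuals use the risk-set mean at each event time, identical to the
Efron-weighted residuals when event times are untied (the generator draws
continuous times, so ties are confined to hand-made fixtures).

## ROC diagnostics

AUC is computed as $U/(n_1 n_2)$ with midranks (ties count ½), positive
class Sq; the returned curve groups tied scores into single sweep steps,
so its trapezoidal area equals the U-based AUC to machine precision — the
test suite verifies both routes agree to $10^{-12}$.

# The synthetic cohort generator

`generatorConfig()` fixes the emulated study conditions.  Defaults:

| parameter | default | rationale |
|---|---|---|
| `n_sq`, `n_ad`, `n_normal` | 240 / 239 / 91 | TCGA-scale lung cohort with survival-eligible Sq samples |
| classes | 3 onco, 20 cnv_only, 20 sq_up_only, 257 null | a sparse-signal screen: 300 miRNAs, 3 true targets |
| `gain_fraction` | 0.5 | focal gains present in half the tumours |
| `gain_mean`, `gain_sd` | 0.32, 0.1 | $\log_2(2.5/2)$: a low-level gain, ~0.5 extra copies |
| `cnv_slope` | 1.0 log2-CPM per copy-ratio unit | exact dosage response: expression proportional to copy number |
| `sq_log2fc` | 1.5 | a strong but realistic histology effect (~2.8-fold) |
| `log_hr` | ln 2.6 per z-unit | a clinically meaningful prognostic effect |
| `noise_sd` | 0.4 log2 units | residual biological variability |
| `dispersion` | 0.05 | negative-binomial overdispersion typical of deeply sequenced miRNA-seq |
| `library_meanlog`, `sdlog` | ln 5e6, 0.3 | miRNA-seq library sizes |
| `baseline_hazard` | 4e-4 / day | median survival of a few years |
| `censoring_rate` | 0.5 | ~50% events at end of follow-up |
| covariate frequencies | male 76% / smoker 93% / stage-I 48% (Sq); 45% / 83% / 56% (Ad) | clinical table of a lung Sq/Ad cohort |

Design choices worth calling out:

* **Hazard couples to continuous expression**, not to the median split the
  screen will later apply — dichotomization stays an honest downstream
  inference step rather than a planted feature.
* **Negative-binomial counts** (not Poisson): the Wilcoxon stage must
  survive realistic overdispersion.
* **Counts are emitted as isoform records** — two mature isoforms at
  distinct loci plus a stemloop fragment per (miRNA, sample) — so the
  aggregation and exclusion rules are exercised by every end-to-end run,
  not only by unit fixtures.
* **Same seed ⇒ byte-identical files**; the master seed fans out to
  per-stage child seeds through a fixed affine map, so individual stages
  are reproducible in isolation.

What the generator does **not** emulate: subclonal copy-number mixtures,
arm-level events co-varying across loci, batch effects, sequencing-depth
artefacts correlated with histology, competing risks, or informative
censoring.  Passing the recovery tests therefore shows the cascade is
implemented correctly and is well-calibrated under its own model — it
does not certify performance on real TCGA data, where those nuisances
exist.  One real phenomenon the generator *does* expose is CPM
compositionality: strongly upregulated miRNAs inflate the Sq totals and
shrink every miRNA's measured fold change, which is why validation
configurations keep the planted fraction of the miRNome small, as it is
in real data.

# Numerical choices and degenerate inputs

* Strict inequalities at every threshold, as printed in the cascade
  definition; a pair at exactly $r = 0.2$ fails.
* Correlation p-values that underflow at $r = \pm 1$ are reported as the
  smallest positive double rather than zero.
* Constant vectors, single-class inputs, all-censored outcomes,
  degenerate median splits, and single-group bootstrap resamples are
  explicit error or redraw paths, never silent `NA`s.
* Ties: midranks in Wilcoxon and ROC; pooled deaths in the log-rank;
  Efron correction in Cox; ties at a dichotomization cut-off go `low`.
* Percentages in the cohort summary round half away from zero (so
  185/245 prints as 76), matching clinical-table convention.

# Problem sizes used in validation

The shipped validation suite runs the full cascade on 20 cohorts at the
default study conditions; calibration checks use 2000 null replicates for
the log-rank and Wilcoxon type-I error; Cox recovery uses 200 simulations
at $n = 240$ with a planted HR of 2.6; bootstrap stability uses
$B = 1000$ replicates per effect size.  These sizes give binomial
standard errors comfortably inside the asserted bands while keeping a
full validation run to a few minutes on one core.

# Known limitations

* The screen treats precursor loci independently; recurrent arm-level
  gains that co-amplify many miRNAs are not modelled (no GISTIC-style
  recurrence calling).
* The DEMI stage's $q < 10^{-10}$ is tied to large cohorts; the package
  reports raw p-values so users of smaller cohorts can choose a
  defensible threshold.
* Cox models support fixed binary/continuous covariates only — no
  time-varying covariates, stratification, or competing risks.
* The proportional-hazards test uses the classic scaled-residual
  approximation; its p-values can differ modestly from exact score-test
  implementations, and its calibration is verified by simulation in the
  test suite.
* Multi-build genomes are out of scope: coordinates are taken as given
  (1-based inclusive) with no liftover.
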