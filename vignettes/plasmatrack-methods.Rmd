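---
title: "Tumor-informed ctDNA monitoring: models and design choices"
author: "plasmatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-informed ctDNA monitoring: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmatrack)
```

## The problem

Esophageal squamous cell carcinoma recurs frequently after curative-intent
treatment, and conventional serum biomarkers (SCC antigen, p53 antibody)
track tumor burden poorly. Tumor-informed liquid biopsy addresses this in
two stages. First, somatic single-nucleotide variants are called from a
targeted gene panel sequenced in the tumor biopsy against matched normal
tissue. Second, plasma cell-free DNA (cfDNA) from serial blood draws is
interrogated *only at those tumor-identified positions*. Because the plasma
stage tests a handful of pre-specified sites rather than the whole panel,
the multiple-testing burden collapses and the allele-frequency (AF)
detection threshold can drop to 0.0005 — deep into the range where
circulating tumor DNA from residual or recurrent disease lives.

`plasmatrack` implements this analysis end to end, driven by a synthetic
cohort generator so every result in the package is reproducible from a
seed.

## Calling criteria

Both calling stages share per-read filters and differ in the site-level
criteria. A read contributes to a pileup only if its mapping quality is at
least 25, its base quality at least 15, its per-read mismatch count at most
5, and its allele is not N. VAFs are computed on this filtered depth: the
criteria are a single conjunction, so the denominator of the AF criteria is
the same filtered count that the depth criterion tests.

A tumor-vs-normal candidate passes when, in addition: both filtered depths
are at least 100; the tumor VAF is at least 0.05; the normal VAF is at most
0.05; and the Fisher exact p-value is below 0.05. A plasma observation at a
tracked site is *detected* when: filtered cfDNA depth is at least 100; the
cfDNA AF is at least 0.0005 (inclusive — 2 reads out of 4000 passes); at
least 2 reads support the mutation; and the Fisher exact p-value against
the matched normal-tissue pileup is below 0.05. Thresholds written with
`>=`/`<=` are inclusive and the p-value cut is strict, exactly as the
criteria are stated; all are config switches in `tumor_thresholds()` and
`cfdna_thresholds()`.

Design points that were genuinely open:

* **Fisher sidedness.** The test's role is to confirm tumor-specific (or
  plasma-specific) excess of the variant allele, so the default is the
  one-sided upper hypergeometric tail, `P(X >= alt_a)` with the observed
  margins, computed by `stats::phyper`. A `two.sided` switch delegates to
  `stats::fisher.test`.
* **Table orientation.** Rows are alt/ref read counts, columns the two
  samples; other non-reference alleles are excluded from the table rather
  than folded into the reference.
* **Plasma comparator.** The plasma Fisher test runs against the matched
  normal-tissue pileup — the only germline control in the design. This has
  a practical consequence: with a clean normal at depth around 3810, about
  5 supporting reads are needed before the Fisher criterion can clear 0.05,
  so Fisher (not the 2-read rule) is usually the binding plasma criterion.
  A much shallower normal would push that to 25-30 reads and make the
  0.0005 AF threshold unreachable, which is why the generator sequences
  normals to full panel depth.
* **Per-read mismatch counts** are taken as supplied and not decremented
  for the candidate variant itself.
* **Multi-allelic sites** are evaluated one alt allele at a time; a site
  can contribute at most one passing call per alt.
* **No multiple-testing correction** is applied across sites: the criteria
  are per-site p < 0.05.

## Monitoring model

Every passing tumor call is tracked through every plasma draw
(`track_patient()`), giving one AF trajectory per mutation. Calendar months
(integer offsets) are the time unit, since recurrence lead is reported in
months.

* A mutation is **concordant** when it is detected in the designated
  pre-treatment (diagnosis) draw. Post-treatment detections do not create
  new concordant mutations, and tumor-only mutations are retained as
  all-negative trajectories rather than dropped.
* **Molecular recurrence** is the earliest post-treatment month at which at
  least one concordant mutation is detected. The published descriptions of
  AF increases are qualitative, so this is the simplest operational rule; a
  stricter `"consecutive"` option requires detection at two consecutive
  draws.
* **Lead time** is the imaging-recurrence month minus the
  molecular-recurrence month. A negative value (molecular after imaging) is
  returned with a warning, not an error.

`detection_power()` is the analytic companion: the probability that the
supporting-read count reaches
`max(min_supporting_reads, ceiling(min_cfdna_vaf * depth))` under
`Binomial(depth, f*v + e/3)`, ignoring Fisher. It is therefore an upper
bound on full detection power. One numerical caveat worth knowing: power is
monotone in tumor fraction, but only piecewise monotone in depth — the
required read count jumps by one at every `ceiling` boundary (depth 4000,
6000, ... at the default AF threshold), and power drops at each jump before
resuming its climb. The tests assert monotonicity within constant-threshold
strata and the reality of the sawtooth.

## What the synthetic cohort emulates

The generator (`simulate_cohort()`) encodes the study conditions the
analysis assumes:

* **13 patients**, truncal mutation count per patient Poisson with mean
  4.3; clonal VAFs uniform on (0.2, 0.5]; gene assignment weights TP53 at
  0.4 of the mass (the remainder uniform over the other 52 genes), so the
  expected TP53-mutant prevalence in a 13-patient cohort is roughly 90%,
  matching the dominance of TP53 in this tumor type.
* **A 53-gene panel** with one 500-bp region per gene. Coordinates are
  synthetic panel geometry, not genome-build positions; nothing downstream
  depends on real coordinates.
* **Mean depth 3810** for tumor, normal and plasma samples alike, with
  per-site depths Poisson around the mean so AF-threshold boundaries are
  exercised at varying depths. Tumor purity defaults to 0.5 (the observed
  tumor VAF is clonal VAF times purity); purity is a free parameter, not an
  estimate from data.
* **Sequencing error 1e-4 per base**, spread uniformly over the three
  alternate bases (e/3 each) — the simplest null that exercises the 2-read
  and Fisher criteria.
* **Read qualities**: mapping quality 60 with 2% mass at 20; base quality
  30 with 5% mass at 10; mismatch count Poisson(1) truncated at 10. The
  low-quality masses sit below the filters, so each per-read criterion
  rejects a nonzero, testable fraction (about 6.9% of reads overall).
* **Trajectory presets** mirror the monitored clinical courses: a
  *responder* (fraction 0.1 at diagnosis, 0.02 at surgery after neoadjuvant
  chemotherapy, 0 afterwards), a *recurrence* course (0 post-operatively,
  then monthly draws with the fraction ramping linearly from half of
  `recurrence_fraction` at onset — the imaging month minus the lead — to
  `recurrence_fraction` at the imaging month), and a *non-shedding* tumor
  (0 at every draw despite tumor mutations). The default cohort assigns
  patient 1 non-shedding, patients 4 and 6 recurrence with 9- and 6-month
  leads, and the rest responder.

What the generator does **not** emulate: read sequences, alignment, cfDNA
fragment-length structure, strand artifacts, copy number, subclonal
evolution beyond the fixed per-mutation shedding fractions, or germline
variation beyond the heterozygous-site tests. Passing tests therefore
demonstrate that the statistical machinery is correct under the stated
binomial read-sampling model — not that the pipeline is robust to the full
error structure of real sequencing data.

## Numerical choices and degenerate inputs

* Percent metrics are **truncated** (floored) at one decimal, the
  convention that reproduces printed cells such as 66.6 for 2/3 and 89.1
  for 33/37; a `round` mode is available. The floor uses a 1e-9 guard
  against doubles representing an integer from just below. One published
  per-gene frequency (23.0% for 3/13 = 23.07...) is consistent with
  neither truncation nor rounding and is not reproduced.
* A zero denominator in any diagnostic metric yields `NA`, never an error;
  a depth-0 pileup has VAF 0.
* The pooled "Total" contingency row sums raw per-gene counts (15 = 9+2+2+2)
  rather than averaging per-gene metrics; the unit of the accuracy table is
  the patient.
* Fisher p-values are exact tail sums, in (0, 1] by construction; ties at
  the threshold follow the printed inequalities (inclusive AF bounds,
  strict p bound).
* Problem sizes in the shipped tests: the exhaustive Fisher cross-check
  enumerates all 923,520 2x2 tables with entries up to 30; Monte-Carlo
  checks use 5,000-100,000 replicates; cohort-level properties run on the
  full 13-patient default cohort at 3810x. The whole suite completes in
  about half a minute on one core.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 101)
cohort <- simulate_cohort(cfg)

s <- cohort$samples$patient_4           # a recurrence-course patient
calls <- call_patient(s$tumor, s$normal, cohort$panel)
traj <- track_patient(calls, s$plasma, s$normal,
                      cohort$scenarios$patient_4$timepoints,
                      patient = "patient_4")
conc <- concordance_status(traj)
mol <- detect_molecular_recurrence(traj, conc,
  cohort$scenarios$patient_4$treatment_end_month)
lead_time(mol, cohort$scenarios$patient_4$imaging_recurrence_month)

plot_trajectories(traj,
  treatment_end_month = cohort$scenarios$patient_4$treatment_end_month,
  imaging_month = cohort$scenarios$patient_4$imaging_recurrence_month)
```

`run_pipeline()` chains the same steps for the whole cohort and writes
plain-text artifacts (VCF per patient, trajectory and monitoring tables,
the accuracy table, a cohort summary, and a run log holding the seed and
thresholds — no timestamps, so a rerun of the same config is byte-identical).

## Known limitations

* The AF trajectories summarize detection per draw; no smoothing or
  longitudinal model links draws, so single-draw dropouts at very low
  tumor fractions translate directly into later molecular-recurrence
  calls under the default rule (the `consecutive` rule trades lead time
  for robustness in the other direction).
* The analytic power calculation ignores the Fisher criterion; near the
  detection floor it overstates power by design.
* Indels are out of scope; the calling model is substitutions only.
* With the plasma Fisher test anchored to a finite normal pileup, plasma
  sensitivity depends on normal depth; the generator keeps normals at full
  panel depth for that reason.
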