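---
title: "Methods: emulating and comparing tumor-only and tumor-normal panel assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating and comparing tumor-only and tumor-normal panel assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelconcord)
```

## Scope and model

`panelconcord` quantifies the agreement between the short-variant output of
a tumor-only (TO) and a paired tumor-normal (TN) NGS gene panel run on the
same DNA, and attributes every discordant call to a cause. "Short variant"
means a base substitution of at most 5 bases or an indel; fusions and
amplifications pass through the I/O layer but are excluded from
concordance. Comparison is restricted to the genes both panels cover
(92 genes in the emulated design, out of 215 TO and 114 TN genes), because
a call in a panel-private gene can never be concordant.

Variant identity is the normalized `(chrom, pos, ref, alt)` key: shared
leading/trailing bases are trimmed (keeping the VCF anchor base for
indels, advancing `pos` for each leading base removed), which makes
normalization idempotent and gives reports from different pipelines a
common key. Gene symbols are annotation, not identity. With per-sample
partition counts, concordance is `n_both / (n_both + n_onlyA + n_onlyB)`
and rates are pooled over samples by **summing counts**, not averaging
per-sample rates — pooled counts are additive over strata, and per-sample
rates on small call sets are noisy or undefined (zero-variant samples are
flagged, not silently treated as 0/0).

## The synthetic cohort: what it states

The simulator's defaults are a fixed stated world mirroring a 30-patient
dual-assay design, and are not tuned to test outcomes:

* **Cohort shape** — 10 fresh-frozen (FF), 10 high-quality FFPE
  (`FFPE_H`, library concentration ≥ 5 nM), 10 low-quality FFPE
  (`FFPE_L`, < 5 nM); tumor cellularity uniform on [0.20, 0.90] (FFPE
  inclusion requires ≥ 20% tumor content); library concentration and
  Q-value drawn per group from the observed ranges of such cohorts.
* **Germline heterozygotes** — true AF exactly 0.5, Poisson mean 2.5 per
  sample over the 237-gene mock model (≈ 0.97 expected on the 92 shared
  genes). This deliberately represents only the *rare* germline variants
  that survive a TO pipeline's upstream polymorphism filtering — common
  SNPs are assumed filtered before reporting — matching the observed
  scale of ≈ 1 germline leak per sample in published TO-vs-TN data.
  Population-database filtering itself is out of scope.
* **Somatic variants** — Poisson mean 5 per sample; true AF
  `0.5 × cellularity × clonal_fraction` with clonal fraction Beta(5, 2)
  (mostly clonal). This is a diploid heterozygous model with no
  copy-number alteration; AFs above 0.5 therefore only arise from
  sampling noise.
* **FFPE deamination artifacts** — Poisson rates 0 / 3 / 12 per sample in
  FF / FFPE_H / FFPE_L. No quantitative per-group artifact rate is
  published; these values are calibrated only to reproduce qualitative
  orderings (more artifacts with worse DNA quality), never exact counts.
  80% of artifacts are C>T or G>A single-base substitutions; artifact AF
  is Beta(1, 40) truncated below 0.10 (≈ 87% under 5% AF).
* **Observation model** — alt reads are Binomial(depth, AF) at a
  per-variant lognormal depth (CV 0.3) around the assay mean (TO 3000×,
  TN 600×, matched normal 500×). The matched normal shows binomial AF 0.5
  evidence for germline variants and a 0.001 cross-contamination rate
  otherwise.
* **Reproducibility** — every sample is simulated on an RNG substream
  derived from the master seed and the sample/stage label, so cohorts are
  byte-identical for a fixed seed and independent of evaluation order.

### Assay-specific artifact sampling

One structural choice deserves emphasis. If artifacts lived in the shared
truth with a stable AF and each assay simply re-sampled reads binomially,
any artifact above the AF floor would be detected by *both* assays and
would **increase** concordance in FFPE_L — the opposite of what is
observed in real dual-assay data, where low-AF FFPE calls are
overwhelmingly one-sided (each laboratory's library prep amplifies a
different subset of deaminated molecules, and the TN caller does not
reproduce the TO panel's low-AF calls). We verified this inversion by
Monte Carlo before fixing it. The emulator therefore applies a
mean-preserving, heavily right-skewed gamma multiplier
(`artifact_dispersion_shape = 0.3`, CV ≈ 1.8) to the *effective* AF of
artifact-origin variants, independently per assay, before binomial read
sampling. Germline and somatic AFs, which are biologically stable, get no
such dispersion. With this single change the expected qualitative
patterns hold: discordance strictly increases from FF to FFPE_L, and the
C>T/G>A share of TO-only discordant calls is highest in FFPE_L. The shape
parameter was chosen once as "strong jackpot dispersion" and exposed as
an argument; it was not iterated against test thresholds.

## Assay emulation rules

Each panel is a `panel_spec`: gene set, matched-normal flag, AF floor,
minimum supporting reads, depth rule, reporting cap, mean depth. The
packaged fixtures declare (vendor values are not disclosed; these are
package defaults, not claims): AF floor 0.02 and minimum 4 supporting
reads for both panels; TO with a per-sample reporting cap of 14 and no
depth rule; TN with no cap and a cellularity-tiered mean-depth
requirement — 200× above 50% cellularity, 250× between 20% and 50%, 500×
below 20%. Both stated endpoints (20%, 50%) fall in the middle tier; the
published tier wording leaves the endpoints ambiguous and we fixed them
once.

Every truth variant presented to an assay ends up either reported or in a
suppression ledger with one reason: `gene_not_on_panel`,
`below_depth_rule`, `below_af_floor` (which also covers the supporting-
read minimum), `germline_subtracted` (TN only: normal evidence with ≥ 3
alt reads at normal AF ≥ 0.25), or `reporting_cap`. The cap is applied
strictly after detection, ranking candidates by actionability tier
(ascending, VUS last), then observed AF (descending), then coordinate —
the published description says only "based on actionability", so the
within-tier tie-break is our fixed convention. Whether the cap of 14
applies per category or overall is unstated; we apply it overall per
sample. Actionability itself is carried as an ordinal label
(tiers 1–5 or `none` = VUS), assigned by origin-specific probabilities
in the simulator (somatic 0.6, germline 0.2, artifact 0.05); no
knowledge base is modeled.

## Attribution

Discordant calls get exactly one of five categories in fixed priority:
germline → reporting_cap → caller_filtered → below_af_threshold →
unexplained. Published five-category breakdowns do not state a priority
for overlapping causes (e.g. a germline call that would also have been
capped); the fixed order resolves ties deterministically and favors the
positively evidenced cause (normal reads) over bookkeeping causes. The
`below_af_threshold` category (reported AF < 5% with no suppression
record in the other assay) only arises for data without emulation
ledgers — on simulated cohorts the absent assay always has a record, so
artifact-origin calls land in `caller_filtered`. An advisory
`germline_af_flag` (observed AF in [0.40, 0.60]) is attached for data
without matched-normal evidence but never drives the primary label.

## Statistical tests

All tests are in-package implementations; `stats::fisher.test`,
`wilcox.test` and `cor.test` are used in the test suite only as
independent oracles.

* **Fisher exact 2×k** (k = 2, 3): full enumeration of tables with fixed
  margins (Freeman–Halton for 2×3); two-sided p is the sum of
  probabilities ≤ the observed table's, with the conventional
  `1 + 1e-7` relative tolerance. Conventions for two-sided exact p
  differ across software; this is the most common one and the one we
  document.
* **Wilcoxon rank test**: the published methods name the signed-rank
  test for comparing two *unpaired* variant groups, which is internally
  inconsistent; the default here is the unpaired rank-sum (Mann–Whitney)
  form, with the signed-rank form behind `paired = TRUE`. Exact p by
  dynamic programming over the null distribution for ≤ 25 untied
  observations per sample, otherwise the normal approximation with
  continuity and tie corrections.
* **Spearman correlation**: average ranks for ties, Pearson on ranks,
  two-sided p from the t approximation (the exact permutation p is not
  implemented; for n ≈ 30, as in per-sample quality correlations, the
  approximation is standard).
* No multiple-testing adjustment is applied anywhere, matching standard
  practice for this design.

Display rounding is one decimal for percentages and three for rates;
all arithmetic is done at full precision first.

## Worked examples and a documented inconsistency

`paper_worked_examples()` recomputes a published case study's headline
rates from its printed partition counts: overall discordance 71.8% from
(51, 99, 31); VUS concordance 6.6% from (7, 82, 17); replicate-TN
concordance 44.7% from (38, 24, 23), with the shared count cross-checked
as 62 − 24 = 61 − 23 = 38; FFPE-H/FFPE-L replicate rates 44.8% / 44.6%;
germline share 32.3% = 32/99. One printed figure — 56.7% concordance for
actionable variants — is inconsistent with its own printed counts, which
give 44 / (44 + 17 + 14) = 58.7%. The package reports the count-derived
value and documents the discrepancy; 56.7 is asserted nowhere.

## What a green test does and does not establish

The simulator reproduces the *statistical structure* the analysis
assumes: set relations between panels, AF regimes (germline ≈ 0.5,
somatic scaled by purity, artifacts < 10%), group-ordered artifact
burden, matched-normal evidence, and the detection/reporting rules above.
It does not model real genomes (coordinates are synthetic intervals, no
trinucleotide context beyond the C>T/G>A label), read-level errors,
copy-number or fusion events, tumor heterogeneity between replicate
sections, panel-specific capture bias, or vendor caller behavior. Green
property tests therefore establish that the pipeline's logic is correct
and that the stated world reproduces the published qualitative orderings
— not that any particular laboratory's panels would show these exact
rates. Published cohort-level figures (per-group rates, AF medians,
quality correlations) depend on non-public per-variant data and are
deliberately not asserted.

## Degenerate inputs and numerical conventions

Zero-variant comparisons have undefined rates and are flagged rather than
reported as 0; degenerate contingency tables (a zero margin) and constant
correlation inputs are errors; `ref == alt` is rejected as "not a
variant"; artifact AFs are truncated (inverse-CDF) rather than resampled
so determinism is preserved; TSV serialization prints doubles with 17
significant digits so write-then-read is the identity.
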