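# panelconcord

Concordance analysis of tumor-only vs tumor–normal NGS gene panels.

## The problem

Clinical cancer sequencing is routinely performed with commercial gene
panels whose analytical pipelines are proprietary. When the same tumor DNA
is run on two different panels — a **tumor-only (TO)** assay that sequences
tumor DNA alone, and a paired **tumor–normal (TN)** assay that also
sequences blood DNA and subtracts germline variants — the reported variant
lists can disagree substantially, even in CLIA-certified laboratories. The
disagreement has reproducible causes: germline heterozygotes leak into the
TO report (a TO assay cannot tell germline from somatic), low-allele-frequency
C>T/G>A artifacts from formalin fixation (FFPE deamination) are called by
one library prep but not the other, callers apply different AF floors and
depth rules, and some panels cap the number of reportable variants.

`panelconcord` implements that comparison as a reusable, tested R pipeline
for analysts who need to benchmark two panels or audit discordant reports,
plus a synthetic dual-assay cohort simulator so every stage is exercisable
without patient data.

## The statistics at its core

Two call sets for one sample are matched on the exact normalized variant
key (chrom, pos, ref, alt), restricted to the genes both panels cover.
With counts of variants found by both assays (*n_both*) or by only one
(*n_onlyA*, *n_onlyB*):

    concordance = n_both / (n_both + n_onlyA + n_onlyB)
    discordance = 1 − concordance

Rates are pooled over samples by summing counts. Each discordant call is
then assigned one of five causes, in fixed priority: **germline** (the
matched normal shows ≥ 3 alt reads at AF ≥ 0.25), **reporting_cap** (the
absent assay detected it but ranked it below its per-sample cap),
**caller_filtered** (suppressed by an AF floor or depth rule),
**below_af_threshold** (reported below 5% AF with no record in the other
assay), or **unexplained**. Group differences use an in-package
Freeman–Halton exact test on 2×k tables, AF differences a Wilcoxon
rank-sum test (exact by enumeration for small untied samples), and
quality correlations Spearman's rank correlation.

The simulator draws germline heterozygotes at true AF 0.5, somatic variants
at `0.5 × cellularity × clonal_fraction`, and FFPE artifacts at
Beta(1, 40)-distributed AFs with Poisson rates ordered
FF ≤ FFPE-H ≤ FFPE-L; reads are binomial at lognormal per-variant depths.

## Worked example

```r
library(panelconcord)
res <- run_pipeline(seed = 1)   # 30 samples: 10 FF, 10 FFPE-H, 10 FFPE-L
print(res$report)
```

```
<concordance_report>
  shared-gene partition: both=70 only_a=38 only_b=7
  pooled concordance: 60.9%
  strata:
  stratum n_both n_only_a n_only_b n_total concordance_rate discordance_rate
1      FF     19       10        0      29        0.6551724        0.3448276
2  FFPE_H     23       12        2      37        0.6216216        0.3783784
3  FFPE_L     28       16        5      49        0.5714286        0.4285714
```

Of 115 shared-gene variants, 70 were reported by both emulated assays and
45 by only one; discordance rises from fresh-frozen (34%) to low-quality
FFPE (43%) samples. The discordant calls decompose by cause as

```r
table(res$attribution$category)
#> caller_filtered  germline  reporting_cap
#>              13        30              2
```

— germline leakage into the tumor-only report dominates, with
caller-filtered low-AF artifacts concentrated in FFPE-L (the C>T/G>A share
of TO-only calls is 0.00 / 0.08 / 0.19 across FF / FFPE-H / FFPE-L in this
run, `res$spectra`). The published case study's headline numbers are
reproduced from their printed partition counts:

```r
paper_worked_examples()[1:2, c("id", "value")]
#>                    id value
#> 1 overall_discordance  71.8
#> 2     vus_concordance   6.6
```

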