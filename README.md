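# fsgsprio

Diagnostic exome analysis for focal segmental glomerulosclerosis (FSGS)
cohorts, in tidyverse-style R. FSGS is a kidney-biopsy pattern of segmental
glomerular scarring; in roughly one patient in ten it has a monogenic cause,
and finding that cause spares the patient ineffective immunosuppression.
`fsgsprio` is for nephrology/genetics groups who have per-patient annotated
exome VCFs and want a reproducible, auditable path from raw variant lists to
a cohort-level diagnostic-yield report.

## What it computes

**Five-criteria prioritization cascade.** Per patient, exome variants are
reduced to candidates by keeping only variants that are (I) coding in
consequence, (II) covered at read depth > 20, (III) in a screening panel of
FSGS-associated and phenocopy genes (87 genes in the bundled default, fully
replaceable), (IV) rare in an inheritance-mode-aware way — population allele
frequency < 1/1,000 for autosomal-recessive (AR) genes and < 1/10,000 for
autosomal-dominant (AD) or X-linked (XL) genes — and (V) consistent with the
gene's inheritance: one variant suffices in AD/XL genes (hemizygous calls in
males satisfy this), while AR genes require two distinct hits or one
homozygote. Every stage's survivor count is traced.

**ACMG/AMP evidence combining.** Candidate variants carry evidence codes
(PVS1, PS1–4, PM1–6, PP1–5, BA1, BS1–4, BP1–7), each at a default or
overridden strength; `acmg_classify()` is a pure function combining them
into Pathogenic / Likely pathogenic / VUS / Likely benign / Benign, with an
explicit conflict state, e.g. Pathogenic ⇐ PVS1 ∧ ≥2 Moderate, Likely
pathogenic ⇐ PVS1 ∧ 1 Moderate, etc. Truncating variants in
loss-of-function genes and absent-from-database frequencies earn PVS1/PM2
automatically; all other codes come from a curated assertion table.

**Cohort statistics.** Detection rate (fraction of patients with a
pathogenic/likely-pathogenic finding) overall and by subgroup (adult,
pediatric, familial, sporadic, by syndrome), causal-gene breakdown, and
median onset/kidney-failure ages.

**Synthetic cohorts.** A seeded generator writes a full cohort (annotated
VCFs + clinical metadata + truth table) with planted causal variants and
background variants each constructed to fail exactly one criterion, so the
whole pipeline is testable end to end without patient data.

## Worked example

The bundled reference cohort (53 patients, six of them carrying the
catalogued causal variants in *CLCN5*, *LMX1B*, *COL4A4* ×3 and *MAFB*):

```r
library(fsgsprio)
report <- cohort_report(fsgs_reference_cohort())
report
#> <fsgs_report> 53 patients; diagnostic yield 6/53 (11.3%)
#>   overall           6/53  11.3%
#>   adult             4/35  11.4%
#>   pediatric         2/18  11.1%
#>   familial          2/ 2  100%
#>   sporadic          4/51  7.8%
#>   SRNS              3/31  9.7%
#>   SSNS              0/ 5  0%
#>   proteinuric_CKD   2/16  12.5%
#>   causal genes: COL4A4 (3), CLCN5 (1), LMX1B (1), MAFB (1)
#>   median onset 33y (solved 42.5y); median ESRD age 47y (solved 48y)
```

Reading: 6 of 53 patients (11.3%) have a reportable (P/LP) finding; yield is
almost identical in adults (11.4%) and children (11.1%); both familial cases
are solved; half the solved patients carry *COL4A4* variants; solved
patients had a median biopsy age of 42.5 years.

A fully synthetic cohort, simulated and pushed through the whole pipeline:

```r
dir <- tempfile()
generate_cohort(cohort_params(), out_dir = dir, seed = 1)
run <- run_pipeline(list(vcf_dir = dir,
                         metadata = file.path(dir, "metadata.csv"),
                         knowledge = fsgs_knowledge_table()))
glance(run)
#> # A tibble: 1 × 8
#>   n_patients n_solved detection_rate detection_rate_pct n_vus_carriers
#>        <int>    <int>          <dbl>              <dbl>          <int>
#> 1         53        6          0.113               11.3             15
#> # ℹ 3 more variables: median_onset_all <dbl>, median_onset_solved <dbl>,
#> #   median_esrd_solved <dbl>
```

All six planted variants survive the cascade and classify P/LP; the 15
planted VUS carriers are flagged but never counted as solved. `tidy(run)`
gives per-patient verdicts, `autoplot(run$report)` the yield-by-subgroup
figure, and single classifications are one call away:

```r
acmg_classify("PVS1 + PM2 + PM4")
#> # A tibble: 1 × 2
#>   class      rule_fired
#>   <chr>      <chr>
#> 1 PATHOGENIC P.Ib
```

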