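---
title: "Variant prioritization and diagnostic yield in FSGS exomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant prioritization and diagnostic yield in FSGS exomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsgsprio)
```

## The problem

Focal segmental glomerulosclerosis (FSGS) is a histologic pattern, not a
single disease. A minority of biopsy-proven FSGS cases are monogenic —
podocyte cytoskeleton and slit-diaphragm genes, glomerular basement
membrane (collagen IV) genes, and phenocopy diseases such as Alport, Dent,
Lowe and Fabry whose renal histology mimics FSGS. Identifying these
patients changes management: genetic FSGS rarely responds to
immunosuppression and rarely recurs after transplantation. `fsgsprio`
implements the analysis layer of a diagnostic exome workflow for such
cohorts: panel-based variant prioritization, ACMG/AMP classification, and
cohort-level yield statistics, plus a simulator that makes the whole chain
testable without patient data.

Upstream computation (alignment, variant calling) and downstream histology
scoring are out of scope; the package starts from annotated VCFs.

## The prioritization cascade

Per patient, all exome variants are reduced to candidates by five filters
applied in order, each a pure subset operation:

1. **Coding consequence.** Default vocabulary: missense, stop gained/lost,
   start lost, frameshift, in-frame indels, and the canonical splice
   acceptor/donor terms. Synonymous and non-coding terms are dropped.
   Unrecognised terms are dropped by default (`keep_unknown_consequences`
   flips this) and reported via a message, so annotation-dialect drift is
   visible rather than silent.
2. **Read depth > 20.** Strict inequality ("more than 20"): depth 21
   passes, 20 fails. Depth comes from FORMAT/DP of the proband sample,
   falling back to INFO/DP, falling back to 0 — a variant of unknown depth
   fails the filter rather than passing silently (fail-closed, the right
   default for a diagnostic tool).
3. **Panel membership.** Gene symbol (case-insensitive) must be on the
   screening panel. The bundled FSGS-87 v1.0 panel holds 87 established
   FSGS/SRNS genes and phenocopy genes, one declared inheritance mode per
   row; it is data, not code, and fully replaceable via `load_panel()`.
4. **Inheritance-mode-aware rarity.** Population allele frequency must be
   < 1/1,000 in autosomal-recessive genes and < 1/10,000 in dominant or
   X-linked genes (both strict; a frequency exactly at the ceiling fails).
   An *absent* frequency is distinct from zero at the I/O layer; the filter
   treats it as zero by default (`treat_absent_af_as_zero`) because a
   variant never catalogued in population databases is precisely the novel
   variant the workflow must not discard.
5. **Zygosity rule.** Dominant and X-linked genes: every surviving variant
   is a candidate (a hemizygous call in a male satisfies the one-variant
   rule). Recessive genes: candidates only if the patient carries two or
   more distinct surviving variants in the gene, or one homozygous-ALT
   variant (counted as two alleles). Phase is not modelled: two
   heterozygous hits are *assumed* in trans, a documented limitation of
   singleton exomes — with parental data a phasing step would slot in
   after this rule.

Stages 1–4 are independent per-variant predicates (the test suite asserts
they commute); stage 5 is the only group-level operation, keyed on
(patient, gene). Every stage's input/output counts are traced per patient,
so the funnel is auditable (`tidy()` on the cascade, `autoplot()` for the
figure).

Genes listed twice with distinct modes get both retention rules evaluated
over the variants frequency-qualified for each mode, keeping the union —
the least surprising extension for dual-inheritance genes such as the
collagen IV family.

## Evidence combining

`acmg_classify()` implements the standard ACMG/AMP combining rules as a
pure function of an evidence set. Codes carry a default strength derived
from their prefix (PVS very strong, PS/BS strong, PM moderate, PP/BP
supporting, BA stand-alone) and may be individually re-weighted with a
`:STRENGTH` suffix; a downgraded `PVS1:STRONG` no longer triggers the
very-strong clauses and counts as an ordinary strong criterion. This
strength modulation is the hook through which gene-specific refinements
(for example the expert-consensus collagen-IV adjustments, whose details
are site policy rather than package code) are expressed via the curated
assertion table.

Decisions worth stating explicitly:

* When both a Pathogenic and a Likely-pathogenic clause are satisfied, the
  stronger class wins (one strong plus three moderate is Pathogenic).
* When rules from both directions fire, the result is VUS with
  `rule_fired = "conflict"` — conflicting evidence is an explicit state,
  not an arbitrary tie-break.
* PP5/BP6 (reputable source) are accepted because published criterion sets
  use them; `use_reputable_source = FALSE` removes them before combining,
  matching later field guidance that deprecates them.
* Only two codes are ever automated: PVS1 for truncating consequences in
  genes with an established loss-of-function mechanism (an explicit,
  user-editable gene list), and PM2 when the population frequency is
  absent or below `pm2_af_max` (default 1e-4). Everything else — hotspots,
  functional data, in-silico consensus — must come from the curated table.
  No predictor is computed in-package.

The test suite checks the combiner against an independently written
clause-by-clause evaluator over all 1,024 subsets of a ten-code universe,
and property-tests that adding pathogenic-direction evidence never moves a
classification toward benign except into the explicit conflict state.

## Cohort statistics

A patient is **solved** when at least one candidate classifies Pathogenic
or Likely pathogenic; VUS-only carriers are counted separately and never
contribute to the yield. Detection rates are computed from counts with
tidy-eval predicates (`detection_rate(cohort, age_at_biopsy > 18)`);
adult means biopsy age strictly over 18 years. Disease onset is
operationalized as age at kidney biopsy — the only per-patient onset proxy
routinely available in biopsy-ascertained cohorts — and medians use the
midpoint convention. Reported percentages are rounded half-up to one
decimal, matching clinical-report formatting.

### The bundled reference cohort

`fsgs_reference_cohort()` reconstructs a 53-patient reference cohort: six
solved patients carry their published per-patient covariates and causal
variants verbatim (`fsgs_causal_catalog()`); the 47 unsolved rows are
synthetic fills fixed once so the cohort marginals reproduce the published
summary table (28 males; age bands 6/12/19/13/3; 2 familial cases, both
solved; 40 on immunosuppression; 12 reaching kidney failure; cohort-wide
median onset 33 y and median ESRD age 47 y). Those published marginals are
treated as inputs; they were not adjusted afterwards.

Two internal inconsistencies of the source tables cannot be reconciled and
are resolved in favour of the per-patient data:

* the per-patient table lists **three** solved SRNS patients while the
  subgroup text reports 2/31 (6.5%); computed from the per-patient data
  the SRNS yield is 3/31 (9.7%), and the package reports the computed
  value;
* the three syndrome categories of the summary table total 53, leaving no
  slot for the solved asymptomatic-proteinuria patient; the reconstruction
  keeps that patient and fills one fewer proteinuric-CKD row (16 rather
  than 17).

Similarly, the sporadic yield is computed from counts (6 solved − 2
familial = 4/51 = 7.8%), which matches one of the two printed versions.
The Dent-disease gene *CLCN5* is encoded X-linked (the carrier is male and
hemizygous) even though cohort-style tables conventionally print a single
"AD" inheritance column.

## The simulator

`generate_cohort()` writes, deterministically from a seed, one annotated
VCF per patient plus metadata and a truth table. Defaults are the
reference study conditions: 53 patients, 6/53 solved, the published
syndrome/sex/age mixes, 15/53 VUS carriers. Solved patients receive a
catalog variant with matching zygosity (carriers of X-linked entries are
forced male and hemizygous); planted "novel" variants carry an *absent*
population frequency so the absent-AF pathway is exercised.

Background variants (Poisson, mean 50 per patient — a plausible
panel-region load after upstream triage) are each **constructed to fail
exactly one criterion**, in proportions 35% off-panel gene, 30% common
(AF drawn from 0.005–0.05, above every ceiling), 15% shallow (depth ≤ 20),
15% non-coding, 5% a lone heterozygous hit in a recessive gene. At most
one lone-het variant is planted per recessive gene per patient, so no
spurious compound heterozygote can arise. Background positions come from a
synthetic per-gene coordinate map (disjoint 100 kb windows spaced 3 Mb
within each chromosome) rather than a downloaded annotation.

What passing end-to-end tests on these cohorts shows: the cascade keeps
exactly what it is specified to keep, the classifier reproduces the
intended classes, and the aggregation arithmetic is right. What it does
*not* show: robustness to real-world annotation noise — multiple
transcripts per gene, conflicting population frequencies, caller-specific
genotype quirks, pseudo-autosomal X regions, structural variants — none of
which the generator emulates. The simulator validates the pipeline's
logic, not the annotation ecosystem upstream of it.

## Numerical and I/O choices

* Coordinates are 1-based point positions; contig names are normalized to
  the `chr`-prefixed spelling; catalog REF/ALT letters mirror the cDNA
  change (coding-strand convention), since only cDNA-level changes and
  genomic positions are published.
* Annotation is a single configurable INFO key (default `ANN`, Number=A)
  with the fixed five-subfield schema `gene|consequence|hgvs_c|hgvs_p|af`;
  full VEP/SnpEff CSQ parsing is out of scope. Multi-allelic records are
  split per carried ALT; genotypes are canonicalized to `1`, `0/1` or
  `1/1`, which makes read→write→read a fixed point.
* Malformed annotation blocks skip the record/block with a warning and are
  counted in a parse report; a missing annotation key in the header is a
  hard error naming the key.
* A diploid-coded homozygous ALT on chrX in a male is treated as
  hemizygous (callers commonly emit `1/1` there); a heterozygous-coded X
  call in a male is left heterozygous, since demotion is unsafe in
  pseudo-autosomal regions.
* Percentages round half away from zero at one decimal
  (`round_half_up()`), not banker's rounding.

## Problem sizes

The shipped checks run at: all 1,024 evidence subsets for the
combiner–oracle sweep; 1,000-variant random cohorts for cascade–oracle
equivalence; 20 seeds × 53 patients (~2,800 variants each) for end-to-end
recovery. These sizes were chosen as the smallest that exercise every code
path and group-level interaction several times over.

## Known limitations

* Phase is assumed, not inferred; trio data would be needed to confirm
  compound heterozygosity.
* The bundled 87-gene panel is a curated default, not a clinical
  authority; sites should load their own validated panel.
* PP3-style predictor evidence is an input assertion; the package never
  runs predictors.
* The reference cohort's unsolved covariates are synthetic fills
  constrained by published marginals — per-patient analyses beyond those
  marginals are not meaningful on it.
* No CNV/SV detection, no consanguinity/ROH inference, no joint-genotype
  trio modelling.
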