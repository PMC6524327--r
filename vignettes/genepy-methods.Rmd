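---
title: "Gene-level pathogenicity burden scores: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level pathogenicity burden scores: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genepyr)
```

## The model

For each individual $h$ and gene $g$, the burden score is the sum over the
$k$ variants observed in that individual within the gene's coding region:

$$S_{gh} = -\sum_{i=1}^{k} D_i \, \log_{10}(f_{i1} \cdot f_{i2})$$

Each variant contributes the product of two ingredients:

* **Deleteriousness** $D_i \in [0, 1]$ — an in-silico pathogenicity
  estimate for the mutated allele, with 0 benign and 1 maximally damaging.
* **Rarity and zygosity** — the two observed alleles' population
  frequencies $f_{i1}, f_{i2}$. A homozygote contributes its allele
  frequency squared; a heterozygote the product of the two observed
  alleles' frequencies, which extends naturally to multi-allelic sites; a
  hemizygous male-X genotype (and single-copy chrY/MT genotypes) is
  treated as homozygous. The $\log_{10}$ upweights rare variation.

The model's assumptions are worth stating plainly: variant effects within
a gene combine additively; alleles at one locus combine multiplicatively
on the frequency scale (a Hardy-Weinberg-flavoured diploid model); the
deleteriousness metric is a meaningful, monotone proxy for functional
impact; and the annotated population frequency is appropriate for the
cohort's ancestry (the frequency column is configurable at ingest
precisely because this is an assumption, not logic).

## Parameters that matter

* **Frequency floor** (`floor`, default `1e-5`, a fraction): imposed on
  novel or unannotated alleles, and as the minimum for the reference-
  allele complement. It bounds a single variant's contribution at
  $-\log_{10}(10^{-10}) = 10$ (homozygous) and ~5 (rare heterozygote vs
  common reference). The default conservatively reflects the smallest
  frequency observable in ExAC-scale repositories; with a different
  floor, these bounds move accordingly.
* **Deleteriousness metric** (`metric`): one of sixteen supported. Bounded
  metrics are used natively on (0, 1); the five unbounded ones (CADD,
  FATHMM, GERP++_RS, MetaSVM, phyloP) are rescaled linearly using the
  extreme values observed in dbNSFP v3.3a (e.g. CADD $-7.53$ to $35.79$);
  reverse-directed metrics (FATHMM, PROVEAN, SIFT) take the complement
  after rescaling; MutationTaster is complemented only for its N/P
  prediction classes. The bounds ship in `inst/extdata/metrics.tsv` and a
  user file can override them.
* **Median-length constant** (`median_length`, default 1461 bp): the
  length correction is `score / targeted_bp * median_length`. The default
  is the median targeted gene length observed in the cohort this constant
  was originally derived from; because the constant is cohort-specific by
  construction, passing `median_length = NULL` recomputes it as the
  median of the supplied per-gene targeted lengths.

## Numerical and design choices

Several points are genuinely open in the model's published description;
the package resolves them as follows, and documents rather than hides
them:

* **PROVEAN** has a native $-14..14$ range, reverse-directed, and no
  imposed transformation range. We rescale from $(-14, 14)$ and then
  complement, so raw $-14$ (most deleterious) maps to $D = 1$. This keeps
  directionality uniform across all sixteen metrics.
* **Raw values outside a metric's bounds** (possible with newer
  annotation database builds) are clamped to the bounds, not rejected,
  keeping $D \in [0, 1]$.
* **Missing metric annotation** for a variant skips the variant for that
  metric's score (it contributes 0). Different metrics genuinely annotate
  different variant sets; no imputation rule is defensible, so none is
  applied. MutationTaster values without a prediction class are likewise
  treated as missing, since the class-conditional rule cannot be
  evaluated.
* **Protein-truncating classes** (stopgain, stoploss, frameshift
  insertions/deletions) receive $D = 1$ regardless of metric annotation:
  most metrics do not score truncating variation at all. Synonymous and
  splicing classes are excluded entirely. Non-truncating indels are
  scored only when a metric value exists for them.
* **Multi-allelic heterozygotes** (genotype 1/2) carry two mutated
  alleles but the equation has a single $D_i$ per locus. We use the
  maximum $D$ over the observed, non-excluded alt alleles and the product
  of the two observed alleles' frequencies, and credit the contribution
  to the union of the alleles' gene assignments. Averaging the two $D$s
  was the alternative; the maximum was chosen because the locus's
  functional impact is at least that of its worst allele.
* **Diploid-coded male-X heterozygotes** (a 0/1 call for a male on chrX,
  which upstream callers do emit) are scored hemizygously for the alt
  allele, consistent with treating male X as homozygous.
* **Missing genotypes** (./.) contribute nothing: the model scores
  variants *observed* in a sample, and an uncalled genotype is not an
  observation.
* **Multi-gene annotations** ("GENE1;GENE2") contribute to each listed
  gene independently.
* **Frequencies at multi-allelic sites** are resolved jointly: each alt
  allele is floored, and the reference frequency is $1 - \sum$ alt
  frequencies (floored itself, with a warning when annotations are
  malformed and the alts alone exceed 1).
* **Accumulation** is in double precision; matrices are written with six
  significant digits so anchors like 0.60206 survive a TSV round trip.
* **Corrected matrices** drop genes absent from the target regions (with
  a warning naming them): such genes have no targeted length, and
  erroring the whole run for a handful of untargetable genes would be
  unhelpful. The scalar `length_correct()` still errors on a nonpositive
  length, naming the gene.
* **Histogram convention**: left-closed bins of width 0.01, with the
  overrepresented sub-0.01 bulk droppable; the coefficient of variation
  and gene-wise Z-scores use the population (divide-by-$n$) standard
  deviation.

## Cohort comparison statistics

Per-gene case/control comparisons use the Mann-Whitney U test for
unpaired data (`stats::wilcox.test` supplies the p-value; the U statistic
is also recomputed from midranks and the two are kept consistent). Score
matrices are strongly zero-inflated, so the tie-corrected normal
approximation with continuity correction is the default; the exact null
distribution is used only for untied groups of at most eight. When every
observation across both groups ties (an invariant gene), the test is
defined to return $p = 1$.

The extreme-tail comparison selects the top $\lceil q \cdot n \rceil$
scores *within each group independently* — the published design compares
the top 5% of cases with the top 5% of controls — including all values
tied with the cut, then applies the one-tailed (case > control) test. At
$q = 1$ it reduces exactly to the one-tailed full-distribution test. No
multiple-testing correction is applied by default, but `run_validation()`
emits a Bonferroni column scaled by the number of genes tested.

## The synthetic-cohort generator

`simulate_cohort()` writes a complete, self-contained input bundle — VCF,
sidecar annotation TSV, two deliberately offset capture-kit BEDs whose
intersection covers every gene, a gene model, phenotype and sex TSVs —
plus a ground-truth score matrix computed directly from the score
equation by a separate code path, so the full ingest/transform/score
pipeline can be verified end to end against known answers.

What it emulates: diploid genotypes drawn at Hardy-Weinberg proportions
from each variant's MAF (hemizygous draws for males at chrX genes); an
exome-like functional-class mix including truncating and excluded
classes; raw metric values generated by *inverting* each metric's
transform, so normalisation is exercised rather than bypassed; and causal
genes in which cases are enriched for a rare deleterious variant at
configurable carrier fractions.

Default conditions (chosen once, as a realistic desk-scale study): 170
cases and 170 controls; twenty genes with targeted lengths 300–6000 bp
and on average ~7 variants each; MAFs log-uniform between the floor and
0.5; deleteriousness Beta(0.5, 0.5); one causal gene carried
heterozygously (MAF $10^{-4}$, $D = 0.9$) by 30% of cases and 5% of
controls. The null-calibration check draws both groups of 100 from the
same 70%-zero-inflated score distribution — matching the observed
fraction of invariant genes per individual in real exome cohorts — over
2500 genes; the power check uses 200 replicates of the causal-gene
design. `archetype_cohort()` (200 genes, 40 samples) generates the
two-spike profile: every odd gene carries a common homozygous-prone
D = 1, MAF 0.5 variant (any carrier scores 0.60206) and every even gene a
very rare D = 1 heterozygote (carriers score ~5.000004, sampled at an
enriched 25% carrier rate so the spike is populated at desk scale).

What it does **not** emulate — and hence what passing tests do not show
about real data: linkage disequilibrium and realistic site-frequency
spectra; annotation error (by default the annotated MAF *is* the sampling
MAF; an `af_noise` knob perturbs it); ancestry structure and relatedness;
capture and coverage artefacts; genotype missingness. End-to-end
agreement with the generator's ground truth validates the arithmetic and
plumbing, not robustness to those real-world failure modes, which
upstream QC must handle.

## Known limitations

* Gene assignment is symbol-level, not transcript-level; overlapping
  genes each receive the full contribution of shared variants.
* Compound heterozygosity, phasing and dominance beyond the
  frequency-product model are out of scope.
* The score depends on the annotation database versions used upstream;
  scores are comparable only across samples annotated identically and
  restricted to a common capture intersection.
* Rank-sum p-values rely on the normal approximation under heavy ties;
  for very small groups with ties, permutation is the safer reference
  (the test suite cross-checks against one).
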