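---
title: "SNP-aware differential methylation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-aware differential methylation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dmlscreen` implements a whole-genome bisulfite sequencing (WGBS)
differential-methylation workflow for a two-treatment design with an
ordinal developmental covariate, of the kind used to ask whether ocean
acidification reshapes the gonad methylome of the Pacific oyster: eight
animals, four per pH treatment, each with a gonad maturation stage scored
0 (indeterminate) to 3 (spawn-ready mature female). The pipeline starts
at strand-resolved CpG counts (the post-alignment abstraction: read
trimming, bisulfite alignment and deduplication are upstream tools' jobs)
and ends at differentially methylated loci (DML) characterized against
genome features and GO terms. This vignette explains the statistical
model, the numerical choices, and what the synthetic data generator does
and does not emulate.

## Why a SNP screen comes first

Bisulfite chemistry converts unmethylated cytosine to thymine (via
uracil) while 5-methyl-cytosine is protected. A genomic C→T SNP is
therefore indistinguishable from a permanently unmethylated cytosine on
the read strand — both read as T. The opposite strand breaks the tie: the
base paired with the read-strand T is an **A** when the T is a genuine
SNP allele, and a **G** when it is a bisulfite-converted reference C.
`call_site()` uses only this opposite-strand evidence: with
f = A/(A+G) on the opposite strand, a site with informative coverage
A+G ≥ 5 is called homozygous C→T at f ≥ 0.85, heterozygous at
0.1 ≤ f < 0.85, and reference otherwise. The 5× floor matches the
coverage floor used everywhere else in the pipeline; the allele-fraction
cuts mirror the documented defaults of the standard bisulfite SNP caller
whose full Bayesian genotyper we deliberately do not reproduce — what
matters downstream is the exclusion set, not genotype likelihoods.

Screening runs twice: once on counts **merged** across all samples
(maximum power for shared variants) and once **per sample** (a variant
private to one animal contributes, e.g., f = 10/160 ≈ 0.06 to the merged
pool and vanishes, but is obvious in its own sample). The union of the
two call sets is the exclusion set — the most conservative choice, since
the source study does not state how its merged and individual call sets
were combined. Both strand positions of a CpG are screened, and an
exclusion at either position removes the destranded locus.

## From coverage files to a methylation matrix

The canonical order is fixed and tested: **destrand → filter →
normalize → unite → SNP-exclude**.

* *Destrand.* The plus-strand C at position p and the minus-strand C at
  p+1 of one CpG are summed and reported at p. An orphan minus-strand
  record is kept at its CpG's start.
* *Filter* (per sample): drop loci below 5× coverage, and loci above the
  sample's 99.9th coverage percentile (linear interpolation between order
  statistics), a guard against PCR duplicates.
* *Normalize*: each sample's counts are scaled by
  (median of sample median coverages) / (sample median coverage), so no
  sample dominates the regression by depth. Scaled counts are rounded
  half away from zero; a locus whose scaled coverage would reach zero is
  floored at coverage 1.
* *Unite*: keep loci covered ≥ 5× in **all** samples. This united set is
  both the background for testing and the gene universe for enrichment.

Global characterization uses the SNP-excluded united matrix: per-locus
percent methylation is the coverage-weighted pooled mean across samples
(total methylated reads over total reads). The pooled mean, rather than
the mean of per-sample percentages, matches the count-level pooling used
everywhere else; the unweighted alternative sits behind
`classify_loci(weighted = FALSE)`. Class bounds follow the conventional
invertebrate landscape: **high** ⟺ percent ≥ 50, **low** ⟺ percent ≤ 10,
moderate in between, boundaries inclusive on the high/low side.

## The per-locus test

At each united locus the methylated count M_i out of n_i reads in sample
i is modeled as binomial with

  logit(p_i) = β₀ + β₁·treatment_i + β₂·stage_i

fitted by maximum likelihood (IRLS via `stats::glm.fit`). The maturation
stage enters as a single ordinal numeric term: with eight samples there
is no room for three dummy columns plus a treatment effect, and the
stages are ordered by construction (a categorical encoding is available
behind `covariate_factor = TRUE`). The treatment effect is tested by the
likelihood-ratio statistic G = 2(ℓ_full − ℓ_reduced) against χ²(1).

Counts from pooled cell populations are overdispersed relative to the
binomial. The correction scales the statistic by the Pearson dispersion
of the full model, φ = Σ r²_Pearson / (n − k), and refers G/max(φ, 1) to
χ²(1) — the correction never deflates. Non-convergent fits (possible
under complete separation at low coverage) are flagged and reported with
p = 1 rather than dropped.

A calibration caveat that users should know: with eight samples φ is
estimated on five degrees of freedom, so under strong overdispersion
G/φ̂ behaves approximately like F(1,5) rather than χ²(1), and the
χ²-referenced test is anti-conservative — at ρ = 0.05 and 30× coverage
the empirical p < 0.05 rate on null data is ≈ 0.13 (≈ 0.33 without the
correction; and at ρ = 0 the corrected test is well calibrated,
≈ 0.05). An F(1, n−k) reference would restore calibration, but the
χ² reference is retained as the method under study. In practice the DML
definition is protected by the 50-point effect-size threshold: null loci
essentially never show a pooled difference that large, which is why
recovery runs show empirical FDR ≈ 0 despite the inflated per-locus
rates.

The reported effect size is the **pooled difference**: 100 × (treatment
methylated/total − control methylated/total), pooling counts within each
group. Group-mean differences are available via `pooled_diff = FALSE`;
the two differ when coverages are unequal.

## SLIM q-values

False-discovery control sharpens Benjamini–Hochberg with an estimate of
the true-null proportion π₀: q = π₀ · BH(p). π₀ comes from a
sliding-linear-model estimator: the empirical p-value CDF is evaluated on
100 bins of [0, 1]; ordinary least-squares slopes are computed on sliding
windows of 20 bins; under the two-group mixture the CDF slope decreases
toward π₀ as λ → 1, so the estimate is the slope of the first window
after which successive slopes stabilize (change below half the median
absolute slope change), clipped to (0, 1]. The exact windowing constants
of the original sliding-linear-model publication are not restated in our
sources; these values were fixed once, before any calibration runs, and
the estimator is validated by its contracts: with π₀ forced to 1 the
q-values equal BH exactly, and on uniform p-values the estimate lands in
[0.9, 1.0]. Below 100 p-values the estimator is unreliable and the code
falls back to π₀ = 1 (plain BH) with a warning.

A **DML** is a locus with q < 0.01 (strict), |pooled difference| ≥ 50
percentage points (inclusive), not overlapping the C→T exclusion set.
Hypermethylated means higher in the treatment (low pH) group.

## Feature tracks and characterization

Annotation algebra runs on `GRanges` (1-based closed internally; BED I/O
converts): intron = gene ∖ exon, exon UTR = exon ∖ CDS, flanks = 1000-bp
strand-aware windows beside genes minus any gene bases (upstream flanks
double as putative promoters), intergenic = complement of genes minus
flanks. CDS ⊆ exon ⊆ gene nesting is verified before deriving, and every
derived identity (intron/exon partition gene bases; UTR/CDS partition
exon bases; intergenic excludes genes and flanks) is tested against a
brute-force per-base boolean-mask oracle.

Overlap counting uses the ≥1-base rule on width-2 CpG intervals, so one
locus can sit in several classes (genic and TE, say) and overlap
percentages may sum past 100. Contingency tests need a partition, which
the sources do not define; we assign each locus its first match in the
precedence order CDS > exon UTR > intron > upstream flank > downstream
flank > intergenic (genic classes first, mirroring the genic emphasis of
the results being reproduced), and test background-vs-query tables with
`chisq.test(correct = FALSE)` — no continuity correction for any table
size, to keep one rule.

GO enrichment is gene-level: a gene is "of interest" if it contains ≥ 1
retained DML (SNP-overlapping candidates are already gone); the universe
is every gene containing a united (5×-in-all-samples) CpG. Each term gets
a one-sided Fisher's exact test on the 2×2 in-term × in-interest table,
checked in tests against a direct hypergeometric tail sum to 1e-10.
P-values are deliberately **not** corrected for multiple comparisons,
matching the term-by-term convention of the tooling being emulated;
significance is flagged at p < 0.01.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 2 × 4 samples,
stages 0–3, mean per-strand coverage 30 (negative binomial, size 10),
beta-binomial methylation counts with intra-site correlation ρ = 0.05
(one beta draw per locus-sample shared by both strands, so destranded
counts keep the configured ρ), a low/mid/high baseline mixture of
0.82/0.09/0.09 echoing the heavily low-methylated landscape of a mollusc
genome, planted DML at a 60-point difference (the smallest callable
effect is 50), planted C→T SNPs at 5% of CpGs (30% heterozygous), and a
maturation effect of 0.3 logits per stage. Planted effects are applied on
the probability scale so the truth table's effect sizes are exactly the
expected pooled differences; baselines for planted loci are drawn so both
group probabilities stay inside [0.02, 0.98]. Coverage draws of zero are
simply absent from coverage files, matching Bismark coverage semantics.

Deliberate simplifications, hence limits on what passing tests show
about real data:

* **Genotypes are population-fixed.** A planted SNP has the same
  genotype in every animal, as the truth-set contract specifies, so SNP
  loci read as uniformly unmethylated rather than as spurious
  between-group differences; the candidate-exclusion path is exercised by
  constructed cases in the unit tests rather than by the simulator.
* No read-level artifacts: no quality scores, adapters, mapping errors,
  or conversion-efficiency failures; sequencing error is a uniform
  per-base flip.
* CpGs are planted at controlled density on a scrubbed random background
  (the emitted CpG count is exact, keeping truth tables unambiguous);
  there is no CpG-island structure.
* Annotation is a regular tiling of 1–3-exon genes with UTR margins —
  enough to exercise every derived track, with none of the pathology of
  real annotations (trans-splicing, nested genes, pseudogenes).

## Problem sizes and reproducibility

Everything is seeded through `sim_config(seed=)`; identical configs give
byte-identical outputs. The bundled analysis scripts and the acceptance
script use desk-scale problems chosen to make every estimate stable but
cheap: 5,000 CpG loci for null calibration, 2,000 CpGs with 100 planted
DML and 100 planted SNPs for recovery (sensitivity ≈ 0.85–0.91 and FDR 0
across seeds), and 10,000 uniform p-values for the π₀ check. Scaling the
generator up changes runtimes linearly and none of the conclusions.
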