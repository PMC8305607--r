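---
title: "Methods: rare-variant profiling and genomic subtyping of ovarian failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant profiling and genomic subtyping of ovarian failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

ofprofiler implements a case/control analysis of annotated exome variants
built on an *accumulation* premise: no single variant explains ovarian
failure in a heterogeneous idiopathic cohort, but a recurring set of rare,
protein-affecting variants — each individually of uncertain significance —
can jointly mark affected women and partition them into genomic subtypes.
The analysis therefore treats the variant *profile* (which variants a
patient carries, and with which genotype) as the unit of inference, not the
individual variant.

The assumptions are explicit:

* **Purifying selection.** Variants contributing to reduced fertility are
  kept rare by selection, so candidate variants are required to be absent
  from the reference panel or to have panel MAF < 0.05.
* **Effect on protein.** Only annotation terms with a moderate (missense,
  5'/3' UTR, splice acceptor/donor) or deleterious (frameshift, stop
  gain/loss, protein-contact and structural-interaction modifiers,
  disruptive inframe indels) predicted effect are considered.
* **Recurrence over privacy.** A variant seen in one patient reflects
  individual variation; one carried by at least 10% of cases and absent
  from every control is a candidate disease marker. Both thresholds are
  configurable (`profile_config()`); the carrier floor is the ceiling of
  the exact product (0.10 × 118 → 12), with a 1e-9 guard so that exact
  products such as 0.2 × 10 are not rounded upward by floating-point
  representation.
* **Genotype-aware similarity.** Two patients share a profile element only
  when variant *and* zygosity agree, so the Jaccard coefficient is computed
  over (variant, zygosity) pair sets.

## Filtering

Quality gating is **per call**, not per variant: a call with DP < 100,
GQ < 20, or an alternate-read fraction below 0.2 (non-reference calls only)
is demoted to missing, and a variant is removed only when no informative
carrier call survives. This is the least destructive reading of a
coverage-based criterion — one bad sample should not delete a cohort-wide
variant. The coverage boundary is inclusive (DP = 100 passes) while the MAF
boundary is strict (panel MAF = 0.05 is removed); both sit in
`filter_config()` alongside the GQ and alt-fraction cut-offs, which are
conventional values rather than study-fixed ones and are therefore exposed.
Missing quality fields fail the gate rather than erroring, so VCFs without
GQ/DP/AD degrade predictably; matrices built without any quality fields
pass the stage untouched.

The cascade order is effect class → reference frequency → call quality,
with a telescoping report (`apply_filters()`). The effect and frequency
filters commute on the retained variant set; the report is defined by the
stage order.

## Association

The per-variant contrast is a two-sided Fisher exact test on the carrier
table (carrier = any non-reference zygosity; missing calls leave both the
numerator and the denominator of their group). The p-value is the sum of
hypergeometric probabilities not exceeding that of the observed table (with
the customary 1 + 1e-7 relative guard against ties lost to rounding). The
odds ratio is the **conditional maximum-likelihood estimate**: the ψ whose
noncentral hypergeometric mean equals the observed cell, solved by
`uniroot` on log ψ to a tolerance well below 1e-8. This is the convention
of standard exact-test software; it shrinks relative to the sample
cross-product ratio in small or unbalanced tables, and it is exactly
inverted under table transposition. Boundary cells give 0 or ∞; a zero
margin leaves the estimate undefined (`NA`) with p = 1. FDR control is
Benjamini–Hochberg (`stats::p.adjust`), the default step-up procedure in
this setting; the choice is isolated behind `bh_fdr()`.

Under a null cohort with equal carrier probability in both groups the scan
must not exceed its nominal level; because exact tests are conservative on
discrete tables the realised fraction flagged at p < 0.01 typically falls
well below 1% (the suite checks a 2,000-variant null at n = 150).

## Stratification

Similarity is J(X, Y) = |X ∩ Y| / |X ∪ Y| over (variant, zygosity) pairs.
Two conventions are fixed deliberately:

* **Empty versus empty is 1.** Controls carrying no profile variants are
  identically absent and must cluster together; empty versus non-empty
  is 0. Without this convention the control cluster would be undefined.
* **Linkage is average (UPGMA)** on 1 − J, the common default for
  binary/Jaccard data; single, complete and Ward (on the encoded features)
  are available.

The number of clusters is chosen by scanning dendrogram cuts with two
within-cluster dispersion indexes computed on the 0/1/2 genotype encoding
(the indexes are sum-of-squares constructs, so they need a numeric feature
space): Ball's W_k / k with the maximum-successive-difference rule, and
Hartigan's (W_k / W_{k+1} − 1)(n − k − 1) with a threshold of 10. For the
Hartigan rule we take k as **one past the last index value above 10**
rather than the first value at or below 10: dendrogram cuts on Jaccard
distances do not decrease the sum of squares monotonically in k, and the
first-crossing form can stop at k = 1 when the 2-cut happens to be poor in
sum-of-squares terms even though a later cut is clearly demanded. When no
value exceeds 10 the data are treated as one cluster. On disagreement the
Hartigan choice is returned with a warning — Ball's rule has a known bias
toward k = 2 because the first difference dominates whenever the 1-cluster
dispersion is large.

Cluster naming is content-based and deterministic: the cluster holding the
most controls is C; the remaining clusters are A, B, … by increasing size,
matching a taxonomy in which A is the small, genomically distinct case
subtype. Ties in merge heights are resolved by `hclust`'s deterministic
order, so identical inputs give identical trees.

## Classification

One three-class (A/B/C) random forest (500 trees, √p features per split,
unlimited depth) is fitted; case-versus-control metrics are obtained by
collapsing the non-control classes of the *same* fit, rather than training
a separate binary model. This reproduces both reported views of the
classifier from a single model; a two-stage alternative would differ only
in calibration. Evaluation is stratified 10-fold cross-validation repeated
100 times (10 repeats in the packaged checks; see *Problem sizes*), with
fold assignment by per-class round-robin so every fold's class proportions
are within one sample of the cohort's. Metrics are computed per repeat and
reported as mean with min–max range; the pooled confusion matrix sums
repeats, and Cohen's κ and the one-vs-rest, class-size-weighted AUROC
accompany per-class sensitivity/specificity/precision. Importance is mean
decrease in impurity, normalised to sum 1 per fit and averaged across
fits.

Profile selection on the full cohort leaks the control-absence criterion
into evaluation: every fold's controls were already consulted when the
features were chosen. The default (`mode = "naive"`) reproduces that
design; `mode = "honest"` re-selects the profile inside every training
fold, and on noisy cohorts honest accuracy is bounded above by naive
accuracy (the suite asserts this direction). The naive default is kept
because the profile itself — not only the classifier — is the analysis
product being evaluated.

Screening assigns an external individual to the argmax class only when its
score reaches 0.9 (`screen_population()`); variants absent from the
external data encode as homozygous reference, so schema mismatch is
impossible by construction.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture. Its
defaults define the emulated study conditions: 118 cases and 32 controls; a
66-variant planted profile with per-variant case prevalence in
[0.10, 0.27]; subtypes of 17 (A) and 101 (B) cases; three
subtype-characteristic variants per subtype (near-fixed within A at rate
0.95; drawn from the prevalence range within B); per-patient accumulation
constrained to [1, 15] with histogram mode 9 ± 1; one control-enriched
variant planted at exactly 14/32 controls vs 4/118 cases (confined to
subtype B); and a rare background with panel MAF below 0.05, a
panel-absent fraction (0.3), a synonymous fraction (0.4) and a
panel-common fraction (0.1) so that every filter stage has work to do.
Carriers are heterozygous with probability 0.9 — rare variants are
overwhelmingly heterozygous — and per-call DP/GQ/AD come from a depth
model (mean 250, sd 80, floor 120) matching a clinical-exome coverage
profile that passes the quality gates by design.

Two generator choices deserve emphasis:

* **Subtype-aligned carrier pools.** The common profile pool is carried
  mainly by subtype B (with a small cross-subtype rate), and subtype A is
  defined by its characteristic and enriched variants (four additional
  A-enriched variants remain in the shared pool at low B carriage). A
  cleanly separable two-subtype taxonomy under genotype-aware Jaccard
  distance *requires* this: if both subtypes drew uniformly from one pool,
  the between-subtype similarity would approach the within-subtype
  similarity of the larger subtype and no dendrogram cut could recover the
  partition — so a planted, recoverable taxonomy is taken as part of the
  study conditions being emulated.
* **Accumulation shaping.** Prevalences are drawn per variant, genotypes
  assigned by independent Bernoulli draws under the subtype masks, and the
  cohort is then repaired (carriers added from a variant's home subtype,
  preferring low-accumulation cases; excess carriers removed only from
  variants comfortably above the 12-carrier floor) and re-drawn — bounded
  at 200 attempts — until every case's accumulation lies in the envelope
  and the histogram mode lands within 1 of the target. Infeasible
  configurations error with an explanation rather than looping.

The generator writes a complete VCF 4.2 with SnpEff-style `ANN` fields and
GT:GQ:DP:AD calls, so tests exercise the real parser path; identical seeds
give byte-identical files. What it does **not** emulate: linkage
disequilibrium, mutation-rate heterogeneity along the genome, population
structure or relatedness, sex chromosomes, strand or mapping artefacts,
and multi-allelic sites (those are covered by hand-built parser fixtures).
Passing recovery tests on generated cohorts therefore demonstrates that
the pipeline's inference machinery is correct under its own model — not
that real exomes satisfy that model.

Genotype noise is a per-call flip (0 → 1, 1 → 0, 2 → 1) at rate 0.02 by
default, plus 1% missing calls. Noise interacts with the hard
control-absence rule exactly as it would in practice: flipped-on control
carriers remove profile variants from the selection, which is why the
exact-recovery checks run at zero noise while classification robustness is
checked at the default rates.

## Numerical choices and degenerate inputs

* CMLE solver: `uniroot` on log ψ ∈ [−50, 50], tolerance 1e-10; weights
  computed with a max-subtraction guard against overflow.
* `required_case_carriers()` subtracts 1e-9 before the ceiling.
* Jaccard: exact symmetry is enforced by averaging the similarity matrix
  with its transpose (guards against float asymmetry in the cross
  products); the diagonal is set to 1.
* Empty profiles: `select_profile()` warns and returns an empty profile
  (the accumulation histogram is then all-zero); `encode_genotypes()` on
  an empty profile errors, since a feature space of width zero is
  meaningless.
* Cross-validation with a class smaller than the fold count reduces the
  fold count with a warning; single-class input errors.
* All randomness flows from explicit seeds: `cross_validate()` and
  `train_final()` seed once and run sequentially, so identical
  configurations give bit-identical reports; the pipeline derives
  per-stage seeds from the global seed by stage-name hashing, keeping
  every stage independently reproducible.

## Problem sizes

The packaged checks run the evaluation at reduced but structurally
identical sizes: cross-validation at 10 repeats (the protocol's 100
repeats change only the width of the min–max band), taxonomy recovery and
external screening over 20 generator seeds, the null calibration at 2,000
variants × 150 samples, and prevalence-tracking at 600 cases. These sizes
were chosen so the full suite exercises every code path in well under a
minute of simulation time per property while keeping Monte-Carlo error far
smaller than the tolerances asserted.

## Known limitations

* The hard zero-control rule makes profile membership brittle under
  genotype noise; `control_carrier_max` can relax it, but the default
  reproduces the analysis design.
* Ball and Hartigan indexes are evaluated on the 0/1/2 encoding while the
  tree is built on Jaccard distance; the two geometries agree on planted
  structure but need not in general — the index trace is returned so the
  scan can be audited.
* The odds-ratio estimator is the conditional MLE; analysts comparing
  against cross-product ("sample") odds ratios will see systematically
  larger values in small tables.
* Multi-allelic records are split with mixed heterozygotes (e.g. 1/2)
  treated as heterozygous for each involved alternate allele; allele-level
  dosage beyond 0/1/2 is not modelled.
* X-chromosome genotypes receive no special treatment; all contigs are
  handled identically.
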