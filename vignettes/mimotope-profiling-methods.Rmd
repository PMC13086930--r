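---
title: "Methods: mimotope immunoprofiling with mimoprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mimotope immunoprofiling with mimoprofile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the analysis problem

Mimotope variation analysis profiles the serum antibody repertoire by
panning a random 12-mer peptide phage library against IgG, deep-sequencing
the captured phage, and counting reads per displayed peptide. One sample
therefore becomes a sparse map from 12-mer peptides (20-letter amino-acid
alphabet) to read counts — its *immunoprofile*. `mimoprofile` implements the
downstream analysis of such immunoprofiles for a two-group,
two-timepoint cohort design:

1. **Similarity QC.** Immunoprofiles are highly individual but stable
   within a subject over years. The cosine similarity index (CSI) of the
   top-k (default 5000) peptide count vectors quantifies this: paired
   (same-subject, two-timepoint) CSI is expected to be high, unpaired CSI
   near zero. Subjects whose paired CSI falls below 0.70 are excluded —
   the package operationalizes the published display floor of 0.70 as the
   exclusion rule, since removals were reported without an explicit
   criterion; the threshold is a config field (`csi_pair_min`).
2. **Motif discovery.** Group-discriminative "epitopes" are gapped
   patterns spanning 5–11 positions with exactly five fixed residues
   (wildcards elsewhere, fixed flanks). Candidates are instantiated
   exhaustively from observed peptides — every admissible (span, gap
   layout, offset) window of every discovery peptide — which enumerates
   exactly the scorable pattern space: a pattern matching no observed
   peptide has undefined presence counts and cannot be scored. Each
   candidate is scored by the upper-tail hypergeometric probability of its
   per-sample presence (a sample "has" a motif when any peptide with count
   ≥ `min_count` matches it), in both the case-enriched and
   control-enriched directions. Patterns with identical sample-match sets
   collapse to the shortest representative.
3. **Feature selection.** Per motif and timepoint, the case/control
   contrast of log seroreactivity is tested with the classical
   pooled-variance Student t-test (a Welch switch exists) and the
   Youden-optimal cutpoint (J = sensitivity + specificity − 1, maximized
   over midpoints of adjacent sorted values). A motif is selected when
   p < 0.05 and J > 0.25 at either timepoint; the per-timepoint
   combination is a union because the source protocol states "either
   timepoint" without a combination rule, and union is the inclusive
   reconstruction. No multiplicity correction is applied at this stage,
   mirroring the source analysis (FDR enters at annotation and group
   comparison).
4. **Reference annotation.** Selected motifs are exactly aligned
   (wildcards free, overlaps counted, 1-based offsets) against a reference
   database of linear epitopes with antigen/organism/category annotations.
   Significance of each aligned motif–sequence pair comes from a
   composition-preserving permutation null: the fixed residues are
   re-ordered uniformly at random among the fixed positions (the wildcard
   layout is part of the motif's identity and is preserved),
   `n_permutations` = 10,000 times, and the empirical p-value is
   (matches + 1)/(permutations + 1), where a "match" is a permutation
   whose motif aligns at least once. Benjamini–Hochberg FDR is applied
   jointly across all tested pairs of a run. Motifs hitting both a
   pathogen and an autoantigen record become mimicry records carrying the
   autoantigen's cellular location.
5. **Quantification.** Repertoires are scaled to a common total
   (3 × 10⁶ reads), the normalized counts of all distinct peptides
   matching a motif are summed, and the sum is log-transformed. Group
   comparisons use Wilcoxon rank-sum tests with BH adjustment; timepoint
   persistence uses Spearman correlation of per-subject summarized values.
   Epitope-level structure is visualized by embedding the motif × sample
   matrix with t-SNE (dims 2, perplexity 15, 500 iterations) and
   clustering the coordinates with DBSCAN (ε 2, minPts 10).
6. **Classification.** A logistic regression on the selected epitope
   panel is evaluated by apparent AUC, the Youden operating point
   (sensitivity, specificity, balanced accuracy), stratified 5-fold
   cross-validated AUC over pooled out-of-fold predictions, and a
   label-permutation test: labels are shuffled 10,000 times, the
   cross-validated AUC recomputed, and p reported as the plain proportion
   of permuted AUCs ≥ the observed one.

## Deliberate numerical and design choices

* **Two permutation p-value conventions coexist.** The alignment null uses
  (k+1)/(N+1) — bounded away from zero, appropriate for FDR input — while
  the classifier permutation test uses the plain proportion, so zero is
  attainable. Both conventions follow the respective published
  definitions; they are not harmonized on purpose.
* **Permuted orderings are sampled with replacement.** Sampling N = 10,000
  orderings uniformly (duplicates allowed) matches the "shuffled N times"
  procedure literally and keeps cost independent of residue degeneracy.
  Internally only the distinct sampled orderings (at most 5! = 120) are
  aligned and weighted by multiplicity, so the test is cheap at any N. A
  motif whose five fixed residues are identical is permutation-invariant
  and yields p = 1 by construction.
* **Tie-breaks are deterministic everywhere.** Top-k profiles break count
  ties lexicographically; Youden ties resolve to the smallest cutpoint;
  match-set duplicates keep the shortest, then lexicographically smallest
  pattern. This makes every deterministic stage byte-reproducible.
* **t-test degeneracies.** Zero pooled variance with equal means returns
  t = 0, p = 1 (no evidence); zero variance with unequal means is an error
  surfaced to the caller; constant features yield p = 1, J = 0, never
  selected.
* **Log transform.** Base 10 with pseudocount 1 (`log10(1 + x)`), so
  zero-match samples map to 0 and values stay non-negative. The base does
  not affect rank-based or t inference; both are config fields.
* **Separation in the logistic fit.** Near-perfect panels (specificity 1
  is plausible in this assay) make the ML fit diverge; the package detects
  non-convergence, diverging coefficients or saturated fitted
  probabilities and refits with a small L2 ridge (default 10⁻⁶) by damped
  Newton iterations, warning the caller. Reported coefficients are then
  finite and the ranking (hence AUC) is essentially unchanged.
* **Discovery restricted to immunodominant peptides.** Pattern
  instantiation runs on the top `discover_top` (default 500) peptides per
  sample. This mirrors the assay's top-abundance focus (5000 of ~3M reads
  in the source protocol) and bounds the enumeration; presence counting
  and scoring remain exact over the instantiated space.
* **Seeds.** Every stochastic stage (permutation nulls, fold assignment,
  embedding initialization, cohort generation) takes a seed derived
  deterministically from the master `rng_seed` and the stage name, so
  adding a stage never perturbs another stage's stream.
* **t-SNE and DBSCAN are implemented in-package** as plain exact versions
  of the published algorithms (perplexity-calibrated Gaussian affinities
  by per-point binary search, early exaggeration 12, momentum 0.5→0.8,
  learning rate n/12 bounded to [50, 200]; DBSCAN by breadth-first
  expansion of core points). The embedding is cluster support, not the
  inferential core, so tests assert contracts — determinism given a seed,
  label partitioning, recovery of well-separated planted blocks — rather
  than coordinates.

## What the synthetic cohort emulates — and what it does not

`cohort_design()` / `generate_cohort()` produce a complete, seeded cohort:

* **Subject-stable repertoires.** Each subject has a private peptide core
  (fraction `subject_core_fraction`, default 0.8) whose counts persist to
  the second timepoint under multiplicative log-normal noise
  (`timepoint_noise_sd`, default 0.2), plus freshly drawn background. At
  these defaults the generated mean paired CSI is ~0.84 against an
  unpaired mean of ~0.03 — the stability regime the assay exhibits on real
  sera — and an occasional subject still falls below the 0.70 QC floor,
  exercising the exclusion rule.
* **A public peptide pool** (`shared_peptides`, default 100) present in
  every sample with independent subject-level counts — the analog of
  shared library clones that give real cohorts their small positive
  unpaired similarity, and the source of genuinely continuous,
  exchangeable features for null calibration.
* **Heavy-tailed counts.** Background counts are log-normal
  (meanlog 3, sdlog 1.5), rounded and truncated at 1 — a desk-scale
  stand-in for the rank-abundance shape of phage display without modelling
  panning chemistry. The default 1000 peptides per sample keep a full
  pipeline run in minutes; the per-sample read totals are therefore ~10⁵
  rather than 3 × 10⁶, which is immaterial because all quantification is
  normalization-invariant.
* **Planted motifs.** Each planted gapped motif (five distinct fixed
  residues) is carried by subjects with probability 0.9 in its enriched
  group and 0.1 otherwise; carriers receive `planted_peptides_per_motif`
  distinct matching peptides with counts scaled by `planted_effect`
  (default 8×). A configurable fraction of motifs is enriched in controls
  instead (the direction-reversed case the real data also contains). Every
  planted motif is embedded in a distinct mock pathogen epitope of the
  reference database; the first is additionally embedded in a mock human
  autoantigen so the mimicry cross-mapping has a positive instance.
  Serostatus (POS/NEG/B) links to carriage with probability
  `sero_link_strength` (default 0.8) against a background rate of 0.15.
* **Ground truth is emitted, never consumed.** The pipeline sees only
  repertoires, metadata and reference; recovery is judged against the
  emitted truth.

Not emulated: sequencing error, phage amplification and library synthesis
bias, epitope conformational effects, linkage between motifs on one
antigen, and realistic clinical covariate structure (age/BMI are
uninformative noise). Passing tests on this generator therefore
demonstrate algorithmic correctness and statistical calibration under the
stated model, not performance on real sera.

## Problem sizes used in the shipped checks

The test-suite and acceptance benchmarks run at desk scale, chosen so the
complete suite executes in minutes on one CPU: the planted-recovery cohort
uses 20 case and 20 control subjects (plus 4 technical controls), 1000
peptides per sample, discovery on the top 300 peptides per sample with up
to 300 ranked candidates, and 2000 alignment permutations; null
calibration uses 16 + 16 subjects, 120 peptides per sample and 40 public
peptides across 10–20 seeds. Exhaustive oracle comparisons (hypergeometric,
Fisher, Wilcoxon, Spearman, AUC, Youden) cover every instance or a random
census of instances at n ≤ 12, where enumeration is exact.

## Known limitations

* The exact t-SNE is O(n²) per iteration; beyond a few thousand epitopes a
  tree-based implementation would be preferable.
* k×2 Fisher tests use the exact network algorithm, which is feasible at
  cohort scale but not for large counts; a simulated p-value would be the
  escape hatch.
* The discovery search space, while exact over instantiated patterns, is
  restricted to the top peptides per sample; motifs carried exclusively by
  low-abundance peptides are invisible by design.
* The selection stage deliberately reports raw p-values; its output is a
  candidate set for annotation, not a multiplicity-controlled discovery
  list.
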