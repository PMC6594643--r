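---
title: "Methods: scoring non-frameshifting indels and their functional impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring non-frameshifting indels and their functional impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(indelrisk)
```

This vignette documents the models and statistics implemented in
`indelrisk`, the assumptions behind them, the parameters that matter, and
the choices made where the design was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## 1. The problem and the data model

A non-frameshifting indel removes a contiguous run of residues, inserts a
run, or both at one locus (a complex indel, delins). Variants are
represented with 1-based inclusive coordinates; a pure insertion is
anchored "after residue p" with p in [0, L] (p = 0 being an N-terminal
insertion), the convention presumed by phrases like "the first residue
prior to the insertion site". Each protein carries per-residue property
tracks — scores in [0, 1] from upstream residue-level predictors of
mechanisms such as intrinsic disorder, binding, PTM sites — each with a
*confident threshold*, the cutoff at which the upstream predictor runs at
10% false-positive rate. These tracks are consumed, never computed, by
this package.

Two windows recur and are deliberately distinct:

* **impact window** (per-variant statistics): the deleted span plus three
  flanking residues on each side. For insertions the span degenerates to
  the insertion boundary and the window is the three residues on each side
  of it (p−2..p+3). The insertion case is not forced by any external
  convention; the symmetric reading was chosen and is frozen here.
* **enrichment window** (cohort statistics): only the residues the variant
  directly modifies — the deleted span, or for insertions the two residues
  on each side of the insertion point. Complex indels use their deleted
  span, grouped with deletions.

Both clip silently at the termini. Clipping can empty the conservation
window of a single-residue N-terminal insertion; the implementation then
falls back to residue 1 rather than emitting a missing value.

## 2. Features

Per variant: general (relative position start/L, inserted and deleted
counts); composition (frequencies of the 20 amino acids over the ten
wildtype residues on each side of the span, deleted residues excluded,
normalised by the residues actually present so terminal windows remain
proper distributions; plus the single-amino-acid repeat run length at the
site, 1 outside repeats — for insertions the longer run containing either
flanking residue); conservation (maximum of each attached index over the
deleted span, or over the k positions starting at the residue before an
insertion of k residues); homologs (counts of human and mouse homologs at
identity thresholds 50, 55, ..., 95 — cumulative counts, ten per organism;
eleven inclusive thresholds would contradict the stated count of ten, so
100% identity lands in the ≥ 95 bin); and functional counts (confident
residues within 4 and 20 residues of the span and over the whole protein,
per mechanism). A PSSM-derived per-position vector can be attached as an
additional conservation-style track and is aggregated by the same
max-over-span rule; no further encoding is assumed. Gene-level function
scores pass through unchanged with a presence flag (0-imputed when a
protein lacks them). Feature order is fixed by `feature_layout()` and each
feature carries its group label for ablation studies.

## 3. The classifier

`indel_ensemble()` fits, in order:

1. **Feature filter** — per-feature two-sample Welch t-test between
   classes; features with P < 0.5 are retained (a deliberately minimal
   filter; the t-test flavour is a free choice, Welch's was taken).
   Constant features are dropped first.
2. **Normalisation and projection** — z-scoring with training means/SDs,
   then PCA keeping the smallest number of components with cumulative
   variance ≥ 0.99.
3. **Bagged balanced networks** — 100 members by default. Each bag holds
   every minority-class example plus an equally sized uniform undersample
   (without replacement, fresh per member) of the majority class. A
   stratified 25% of the bag is held out; the member (one hidden layer of
   10 tanh units, sigmoid output, cross-entropy loss) is trained by
   resilient propagation (iRprop−, step sizes in [1e−6, 50], grow 1.2,
   shrink 0.5, initial 0.07) and the weights with the best validation loss
   are kept. Early stopping: patience 10 epochs, budget 100 epochs. The
   epoch budget and patience are tunable; the published training setup
   names the optimiser family and the validation fraction but not the
   stopping details, so the contract here is "any gradient method with
   early stopping on the 25% split", and iRprop− was implemented because
   no installed package offers resilient propagation with a validation
   split.

The ensemble score is the member mean. Everything is reproducible from
(data, config, seed): one seeded RNG stream drives preprocessing, bagging,
splits and initialisation, and the caller's RNG state is restored
afterwards.

Score cutoffs anchored at 10/5/1% FPR on the training neutral scores are
stored on the model; `threshold_at_fpr()` returns the *least* cutoff whose
neutral exceedance is within the target (so the empirical FPR is ≤ nominal
by construction), and a percentile mode supports the "at or above the 95th
percentile of the neutral distribution" flag used in cohort analyses. The
constants 0.546 / 0.672 / 0.85 are kept (`published_thresholds()`) purely
for compatibility reporting; retrained models derive their own.

## 4. Evaluation protocols

Grouped cross-validation prevents homology leakage: per-protein folds keep
all variants of a protein together; per-cluster folds do the same for
single-linkage clusters of proteins at ≥ 50% global-alignment identity.
Identity is matches / alignment-length under match +1, mismatch 0, zero
gap penalties — no tool or formula is externally fixed, so this simplest
exact choice is frozen and tested; single-linkage (transitive closure) is
likewise a choice, made because it is the conservative one for leakage
(anything connected by a chain of similarity ends up co-partitioned). An
exact shortcut links equal-length pairs whose ungapped identity already
meets the threshold (a lower bound on the gapped value) before running
dynamic programming on the rest. Groups are dealt largest-first onto the
lightest fold to balance fold sizes, with seeded tie-shuffling.

AUC is the rank-based (Mann–Whitney) form with half-credit for ties,
tested against exhaustive pairwise concordance. The preprocessor is
refitted inside every training fold; a leakage test asserts that refitting
a fold from scratch reproduces its out-of-fold scores bit for bit.

## 5. Functional-impact statistics

The impact score of variant v for mechanism m counts confident residues in
the impact window. The empirical P-value against a neutral cohort's null
is the literal exceedance fraction k/n — it can be exactly 0, matching the
defining phrase "fraction of neutral variants with scores at least as
high"; an optional (k+1)/(n+1) mode exists for users who need positive
P-values and is off by default.

The neutral cohort is positive-unlabeled: a fraction α of it genuinely
carries mechanism m. The prior-corrected P-value P′ = (1 − α)·P downweights
common mechanisms so P′ ranks comparably across mechanisms; it is the
numerator of FDR = (1−α)FPR / (αTPR + (1−α)FPR) with P read as the FPR
(`fdr_from_rates()` exposes the full identity for documentation and
tests). α comes from configuration when available; otherwise a
conservative stand-in estimator is provided: the median over upper-tail
thresholds (50th–90th percentiles of the positive scores) of the
exceedance ratio Pr(unlabeled ≥ t)/Pr(positive ≥ t), capped into
[0, 0.99]. The ratio converges to α where negatives are rare above t, and
is biased upward (conservative) where they are not; the median over
moderately deep thresholds trades a little of that bias for much lower
variance than a deep-tail minimum. When neither source provides α it
defaults to 0, i.e. P′ = P — failing conservative toward the uncorrected
definition. Reports keep mechanisms with P′ < 0.05, sorted by P′; ties
break by larger impact score then mechanism name (a frozen convention, not
an external one), so output is invariant to input order. A separate
percentile rule (impact score ≥ 95th percentile of the neutral scores) and
a single-residue filter are provided as explicit modes for cohort
analyses, not conflated with the P < 0.05 call.

## 6. Enrichment statistics

E = (F_path − F_neut)/(F_path + F_neut) over impacted fractions computed
on the enrichment window; E is antisymmetric in its arguments, lies in
[−1, 1], hits ±1 exactly when one fraction is 0, and is reported missing
when both are. Significance uses `stats::fisher.test` (two-sided,
point-probability criterion) on the 2×2 impacted-by-cohort table with
Bonferroni correction over the mechanisms tested. Whether the original
analyses were one- or two-sided is not stated anywhere; the two-sided
convention was chosen and reproduces the published worked examples to
three significant figures, so no discrepancy handling was needed. An
exhaustive hypergeometric enumeration serves as the oracle in tests.
Recurrence stratification takes the maximum externally supplied hit count
over a variant's enrichment-window residues: ≥ 2 recurrent, ≥ 25 highly
recurrent. Deduplication for functional analyses keys on (protein, span,
deleted, inserted) after restricting to canonical isoforms.

## 7. The synthetic generator

`simulate_indel_config()` freezes the study conditions the package is
exercised under; they are chosen to emulate the operating regime of
curated germline training cohorts, not to make tests easy, and are not
revisited:

* 300 proteins of 120–400 residues; 15% carry a single-amino-acid repeat
  segment (4–10 residues), exercising the repeat features.
* 4 mechanism tracks; planted contiguous sites (blocks of 3–8 residues)
  cover ~8% of residues per mechanism. Background scores ~ Beta(2, 8),
  site scores ~ Beta(8, 2); the confident threshold is the background's
  90th percentile, mirroring 10%-FPR track cutoffs (an explicit threshold
  override exists for noise-free-limit tests).
* Conservation mixes the site indicator with uniform noise at weight 0.7 —
  functional sites are strongly conserved, so conservation features carry
  real signal.
* 760 pathogenic / 1240 neutral variants (the ~38/62 split of curated
  cohorts); 70% deletions, 20% insertions, 10% complex; 54% single-residue
  events with a capped geometric tail — the documented predominance of
  short events.
* Pathogenic variants sit on a planted site of a random mechanism with
  probability 0.9; neutral variants are steered away from all sites (with
  a 9-residue margin) with probability 0.7, reflecting the observed
  segregation of tolerated indels into disordered, low-constraint regions;
  5% of the neutral set is generated like pathogenic variants but labeled
  neutral — the hidden positives of the positive-unlabeled setting.
* Optionally, proteins are duplicated as isoform-like family members
  (sequence mutated to a requested identity, tracks jittered copies, site
  masks shared), and events on one isoform are re-emitted on the twin with
  probability 0.8. This reproduces the cross-isoform duplication that
  inflates per-protein cross-validation relative to per-cluster.

What the generator does *not* emulate: realistic amino-acid composition or
evolutionary substitution processes, length/gene distributions of real
cohorts, genuinely correlated mechanisms, or track errors structured like
real upstream predictors. Passing tests therefore demonstrate that the
machinery recovers planted signal under honest protocols — not that any
particular real-data AUC would be attained. The published cross-validation
figures depend on licensed variant databases and ~50 upstream predictors
and are deliberately out of reach here; the evaluation presets exist so a
holder of those data could rerun them.

## 8. Problem sizes and numerical choices

Test and acceptance runs use: the default dataset (300 proteins, 2000
variants, 4 mechanisms) for signal recovery across 5 seeds and for the
affinity dose–response (0.5/0.7/0.9); 25-protein, 320-variant,
isoform-duplicated datasets with 5 folds and 25 networks across 10
replicates for the per-protein vs per-cluster comparison; and n = 2000
fresh null draws for P-value calibration. These sizes are the package's
own benchmark choices, small enough to run anywhere while keeping the
statistical assertions comfortably powered.

Numerical details worth knowing: tanh hidden / sigmoid output with
probabilities clamped to [1e−12, 1 − 1e−12] inside the loss; iRprop−
skips the weight update after a gradient sign flip; PCA components are
taken in variance order with at least one always kept; t-test P-values of
exactly-constant-per-class features are treated as 1 (dropped); the
FPR-anchored cutoff for a constant score vector is placed just above the
constant so that no neutral variant is called; `sample2()` guards R's
length-one `sample()` surprise in site placement; all seeds below 2^31.

## 9. Known limitations

* The MLP trainer is full-batch; cohorts of millions of variants would
  need mini-batching (out of scope for the intended data sizes).
* The α estimator is a documented stand-in, reliable only under clear
  positive/negative score separation; configured α always wins.
* Pairwise identity clustering is O(n²) alignments; beyond a few hundred
  proteins a dedicated clustering tool should replace it upstream.
* Impact scores are integers, so empirical P-values move in steps of 1/n;
  calibration statements are meaningful only for nulls large enough that
  the step size is small relative to the level of interest.
* Published score thresholds are reporting constants; they do not transfer
  to retrained models, which must derive their own via
  `threshold_at_fpr()`.
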