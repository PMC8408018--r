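---
title: "Multi-model motif discovery and peak classification: methods"
author: "multimotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-model motif discovery and peak classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimotif)
```

## The problem

Transcription factor binding sites (TFBS) recovered from a single ChIP-seq
experiment are structurally heterogeneous: some sites are well described by
independent per-position letter preferences, others show nearest-neighbour
or longer-range dependencies between positions. A single scoring model
therefore recognises only part of the binding signal. `multimotif` trains
four model families of increasing dependence structure on the *same* peak
set, puts them on a common footing by calibrating each to the same
empirical false positive rate (FPR) on a promoter background, scans the
peaks, and classifies every peak by which models find sites in it and
whether those sites overlap positionally. The per-category fractions
quantify how much of the binding signal each family explains alone and
jointly.

## Model families

All four families score an `L`-bp window `w` with a log2 likelihood ratio
against a background model; the minus strand is scored as the reverse
complement of the window. Higher scores mean a window is more likely to be
a functional site.

* **PWM.** Per-position letter frequencies with a background-distributed
  pseudocount, `freq[j,b] = (n_j(b) + c·bg_b) / (N + c)`; the score matrix
  is `log2(freq/bg)`. A window whose column frequencies equal the
  background scores 0.
* **Dinucleotide PWM.** Frequencies of the 16 adjacent letter pairs at the
  `L−1` junctions, pseudocounted the same way against a 16-category
  dinucleotide background. This captures nearest-neighbour dependence.
* **Inhomogeneous Markov model of order `k`.** Position `j` carries
  conditional letter probabilities given the preceding `min(j−1, k)`
  letters, estimated recursively with interpolation toward the
  next-lower-order estimate:
  `p_j^m(b|ctx) = (n_j(ctx,b) + α_m · p_j^{m−1}(b|ctx′)) / (n_j(ctx) + α_m)`,
  where `ctx′` drops the most distant context letter and the order-0 base
  case is the pseudocounted column frequency. Consequently an order-0
  Markov model scores *identically* to the PWM — a property the test suite
  asserts to 1e-9.
* **Order-pruned Markov model.** For each position independently, the
  effective order is chosen among `0..k` by the Bayesian information
  criterion on that position's conditional likelihood
  (`−2·loglik + 3·4^m·log N`; ties go to the lower order). Positions
  without genuine upstream dependence fall back to order 0. This is a
  deliberate, documented approximation of parsimonious context-tree
  models: it prunes depth per position, not per context.

Defaults: pseudocount `c = 1` distributed by background composition (keeps
every cell finite without distorting well-observed columns); Markov order
`k = 2` (exercisable with hundreds of sites; orders beyond 5 are refused);
interpolation strengths follow the geometric schedule `α_m = 7·3^(m−1)`.
Backgrounds are estimated from the full peak-sequence set (mononucleotide
for PWM/Markov, dinucleotide for the diPWM) so a run is self-contained.
All scores are in bits (log base 2).

## De novo discovery

Discovery initialises from data rather than from a known motif:

1. **Seeding.** Every `k`-mer (default 7) is counted strand-collapsed (a
   word and its reverse complement share one count) in the peaks and in
   per-sequence mononucleotide-shuffled copies; words are ranked by the
   z-score of the observed count against the shuffled replicates.
2. **ZOOPS EM.** Each of the top seeds (default 5) initialises a PWM which
   is refined by expectation–maximisation under the
   zero-or-one-occurrence-per-sequence model: the E-step computes a
   posterior over all window positions and strands plus a no-occurrence
   option (fixed occupancy prior 0.8), the M-step re-estimates the PWM
   from posterior-weighted letter counts. The observed-data log-likelihood
   is non-decreasing and iteration stops when it improves by less than
   `em_tol` (default 1e-4). The run with the best final likelihood wins,
   and the maximum-posterior site of every sequence with occurrence
   posterior ≥ 0.5 forms the site alignment.
3. **Length selection.** Candidate lengths (default grid 8–20 bp) are
   compared by cross-validated partial AUC of the PWM discovered at each
   length; the best (ties to the smaller length, for parsimony) is used
   for *all* model families, which are then trained from one shared
   alignment. Sharing one alignment is a simplification — independent
   tools would each optimise their own — and is stated here deliberately:
   it isolates the effect of the scoring family from the effect of the
   optimiser.

A known limitation: ZOOPS EM with a fixed occupancy prior overfits a weak
pattern on motif-free sequences rather than failing, as any unregularised
EM does. The pipeline does not rely on the EM itself to reject empty
datasets; rejection happens downstream, where it is measurable — seed
z-scores stay near chance level, the cross-validated pAUC of a
noise-trained model is at its finite-sample chance value, and the
reference-matrix filter flags the dataset as not enriched.

## Evaluation

Accuracy is estimated by repeated 90/10 splits: train on 90 % of peaks,
score the held-out peaks (positives) and one mononucleotide-shuffled copy
of each (negatives) by their best window score over positions and strands,
sweep all thresholds into a ROC curve, and integrate the partial AUC on
FPR ∈ [0, 0.001] (trapezoidal, with a point interpolated exactly at the
bound; reported raw, so a perfect classifier attains 0.001 and a random
one 5e-7). The default is 10 repeats. With `n` held-out controls the
smallest nonzero FPR step is `1/n`, so at small `n` the chance level of
the pAUC is `~0.001/(n+1)`, not 5e-7 — the test suite asserts the
finite-sample value.

Cross-dataset transfer uses the same machinery: diagonal cells of the
transfer matrix run the 90/10 protocol within a dataset; off-diagonal
cells train on the full dataset `i` and evaluate on the full dataset `j`
(no split is needed because no peak is shared). Distributions of
per-dataset fractions are compared with the two-sided Mann–Whitney U test
(exact for small tie-free groups, normal approximation with tie
correction otherwise) and Bonferroni correction over the number of pairs.

## Threshold calibration and scanning

Score thresholds are not comparable across model families, so each model
is calibrated to the same empirical FPR on a background set — in real use,
regions 2000 bp upstream of transcription starts; in self-contained runs,
the synthetic motif-free background. Every window position on both strands
is scored (windows containing N are skipped and do not count as available
positions); `FPR(t)` is the fraction of positions scoring `≥ t`; the
selected threshold is the *smallest* observed score whose FPR does not
exceed the target (sensitivity-maximising subject to the bound), so the
achieved FPR re-measured on the same background equals the reported value
exactly. The default target FPR is 1.9e-4, exposed as a configuration
parameter. Scanning then emits every window scoring `≥` its model's
threshold (the same inequality as the FPR definition), overlapping hits
included.

## Peak classification

Two complementary schemes:

* **Pairwise, position-aware** (all 6 unordered model pairs): a peak is
  `intersection` if at least one hit pair shares at least one base
  (half-open intervals, so adjacent hits do not intersect; the rule is
  strand-agnostic — the sources describe it in terms of positions only),
  `no_intersection` if both models hit but no pair overlaps, `only_A` /
  `only_B` / `no_sites` otherwise. The five categories partition the peak
  set.
* **Combinatorial, position-blind**: each peak is labelled by the subset
  of models with ≥ 1 hit; all 2^4 subsets are tabulated (Venn counts),
  from which the recognised fraction, the all-models overlap and the
  single-model-only contributions derive.

Fractions are reported exactly (`100·count/total`); report files format
them to at most three decimals because published per-category values
include three-decimal percentages such as 0.975 %, which two-decimal
rounding would destroy.

## Reference-matrix similarity filter

To check that a discovered motif corresponds to a known one, the raw
frequency matrix of the discovered alignment is compared to a reference
matrix over all column offsets with ≥ 4 overlapping columns and both
orientations. A placement is scored by the sum of per-column Pearson
correlations divided by `min(L, M)`; normalising by the shorter matrix
length rather than the overlap size means a short perfect partial overlap
can never tie a full-length match, which keeps the permutation null
resolvable. The p-value is the add-one permutation estimate over
column-order permutations of the query (default 9999; at least 999 are
required to resolve the strict `p < 0.001` enrichment cut, which a
dataset must pass to enter aggregate statistics). Two caveats are
inherent to this stand-in: per-column Pearson is affine-invariant, so
matrices of different sharpness but the same consensus compare as
identical; and for short consensi with repeated letters the high-IC
columns of the same letter are nearly interchangeable, so type-preserving
permutations produce near-ties and the attainable p floors near the
fraction of such permutations (about 1e-3 for a 7-bp word with four
identical letters). Longer or more letter-diverse motifs do not have this
floor.

## Synthetic data

The generator emulates one ChIP-seq dataset for a FOXA2-like factor: `n`
peaks of fixed length over an i.i.d. background of configurable GC
content (default 0.41, a human-like value), an `occupancy` fraction of
which (default 0.9) receive one copy of the consensus `GTAAACA` with
independent per-letter substitutions (default rate 0.1) at a
Gaussian-jittered position around the peak centre (sd 30 bp, clipped to
stay inside the peak) on a random strand. Peak quality scores decrease
with rank so top-peak selection is exercised, and a truth table records
every planted site. Defaults are `n = 200` peaks of 301 bp. What the
generator does *not* emulate: multiple sites per peak, positional
read-density profiles, sequence composition heterogeneity
(CpG islands, repeats), or cooperative/composite motifs — so green tests
demonstrate correctness of the machinery under the stated generative
model, not performance on real chromatin.

One consequence of these study conditions deserves emphasis. A 7-bp
consensus carries at most 14 bits of information; at the default scanning
FPR of 1.9e-4 the calibrated threshold lands above the score of any
single-mismatch copy (an exact 7-bp word already occurs at ~1e-4 per
background position, and admitting all 1-mismatch words would push the FPR
to ~2e-3). Since ~52 % of planted copies carry at least one substitution
at mutation rate 0.1, per-site scan sensitivity is capped near 48 % for
*any* scoring model — scoring the sites with the true generative model
reproduces exactly this ceiling. The pipeline's measured ~50–55 % union
sensitivity on the default synthetic dataset is therefore at the
information-theoretic bound, not a deficiency of the implementation;
longer planted words (10–12 bp) remove the ceiling, and the test suite
uses them where score separation is the property under test.

## Numerical and design choices

* Coordinates are BED-convention 0-based half-open everywhere.
* Sequence shuffles are mononucleotide (seeded Fisher–Yates), preserving
  letter multisets exactly.
* Peaks are sorted by quality score with a stable sort; ties keep input
  order (the published procedure does not state a tie rule).
* N letters are kept at ingestion and handled at scan time: any window
  containing N is unscorable (`NA`) and excluded from both hit emission
  and FPR denominators. Soft-masked (lowercase) genome letters are
  uppercased and treated as ordinary sequence.
* EM restarts from the top 5 seed words; discovery is deterministic given
  the configuration seed, and the whole pipeline is byte-reproducible
  from one master seed (all derived seeds stay within 32-bit range).
* The 1:1 shuffled-negative ratio in cross-validation is a choice, not a
  law; pAUC values at small control counts should be read against the
  finite-sample chance level above.
* Problem sizes used by the test-suite and the acceptance script —
  200-peak datasets, 1000 × 2000 bp calibration backgrounds, 2–3
  cross-validation repeats, grids of 2–3 candidate lengths — were chosen
  as the smallest sizes at which every asserted property is stable under
  the fixed seeds.

## A small worked run

```{r example, eval = FALSE}
spec <- synthetic_spec(n_peaks = 200, seed = 1)
sim <- generate_peaks(spec)
cfg <- discovery_config(length_grid = 12, seed = 1)
bundle <- train_all_models(sim$sequences, 12, cfg)
background <- generate_background(1000, 2000, gc = 0.41, seed = 2)
bundle <- calibrate_bundle(bundle, background, target_fpr = 1.9e-4)
hits <- scan_peaks(bundle, sim$sequences)
comb <- classify_combinatorial(hits, names(sim$sequences))
venn_aggregates(comb$venn, length(sim$sequences))
```

The same flow, driven from files with a run manifest, is
`run_full_pipeline(pipeline_config(...))`; individual stages can be
re-run from cached artifacts with `run_stage()` (for example,
re-calibrating at a new FPR re-uses the trained models untouched).
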