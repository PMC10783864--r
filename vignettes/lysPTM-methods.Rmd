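---
title: "Methods: multi-label lysine PTM site recognition in lysPTM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-label lysine PTM site recognition in lysPTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysPTM)
```

## The problem and the model

Lysine side chains accept several chemically distinct modifications, and a
single site may be annotated with more than one of acetylation,
crotonylation, methylation and succinylation — or with none ("other").
`lysPTM` models this as multi-label classification of the peptide segment
`R_-L ... R_-1 K R_1 ... R_L` centered on the lysine. The method has two
parts, both deliberately simple and fully deterministic given the training
set.

**Distribution features.** For each adjacent residue pair at a fixed signed
window position (a *di-residue key*; the two pairs touching the center
lysine are excluded, leaving `2(L-1)` keys per segment), the training set
gives a total carrier count `N` and four per-type carrier counts `N_type`.
A key is encoded by the proportions `rho_type = N_type / N`, and a segment
by the concatenation of its keys' `rho` vectors in ascending position
order: `8(L-1)` features, each in `[0, 1]`. The representation therefore
carries *label* information from the training set, which is why
cross-validation must refit it per fold (below).

**Per-label masked kernel regression.** Because feature slot `v` of every
block refers to label `v` alone, the score for label `v` is computed by
Gaussian kernel regression over the ±1 training labels using only those
slots: `S_v = sum_i l_i^v w_i / sum_i w_i`, with
`w_i = exp(-d_i(v) / (2 theta^2))` and `d_i(v)` the squared difference over
columns `4j + v`. The unmasked variant (`engine = "gkr"`), which uses the
full squared distance for every label, is retained as a baseline. A label
is called present when `S_v >= 0`; the tie at exactly zero is resolved
toward the positive call, matching the defining inequality.

### Assumptions

- The association between a residue pair and a PTM type is *location
  fixed*: the same pair at a different offset from the lysine is a
  different feature. Nothing is shared across positions.
- Scores are convex combinations of ±1 labels, so `|S_v| <= 1` always; the
  model has no calibration step and the decision threshold is fixed at 0.
- No correction for class imbalance is applied; rare types are carried by
  the masking, not by resampling.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `half_width` (`L`) | 13 | window half width; features number `8(L-1)` (96 at the default, 184 at the `L = 24` setting used with the larger CPLM-style corpora) |
| `theta` | 1/6 | Gaussian kernel width; supported grid `1/2, 1/4, 1/6, 1/8, 1/16, 1/32` (`sweep_grid()` evaluates it) |
| `engine` | `"gkpr"` | per-label masked distances; `"gkr"` = full distance baseline (its customary width is 1/4) |
| `folds`, `mode` | 5, `"general"` | cross-validation design; `"strict"` partitions proteins |
| `exclude_unlabeled` | `FALSE` | drop all-negative sites before splitting |

With `theta = 1/6` the exponent is `-18 d`; beyond `d ≈ 40` the raw weight
underflows double precision. `score_labels()` therefore subtracts the
per-query minimal distance inside the exponent. The subtraction cancels in
the ratio exactly (it is not an approximation), and it guarantees the
nearest training record has weight 1, so the denominator is at least 1 and
no epsilon guard is needed. Scores are finally clamped to `[-1, 1]` to
absorb summation round-off at the boundary.

## Conventions the definitions leave open

Several corner cases are not fixed by the defining formulas; the package's
choices are:

- **Terminal padding.** When the window overruns a protein terminus, the
  missing slots repeat the single nearest terminal residue (`"AKV"` at
  `L = 2` becomes `"AAKVV"`). Copying longer terminal runs would be an
  alternative reading of "nearest"; single-residue repetition is the
  simplest and is applied uniformly.
- **Non-standard residues.** Letters outside the 20-residue alphabet
  (B, Z, U, O, J, X, ...) map to one unknown symbol `X` that is counted
  like any other letter, so no site is discarded and every ratio stays
  defined.
- **Unseen keys.** A key with `N = 0` in training encodes as
  `(0, 0, 0, 0)`: no evidence is read as zero support for every type,
  consistent with the interpretation that uniformly small entries indicate
  an unmodified site.
- **Denominator population.** `N` counts *all* training segments,
  including the unlabeled class — the totals are sums over the whole
  training set, not over labeled segments only.
- **Feature order.** Blocks ascend by start position (`-L` first); within
  a block the order is acetylation, crotonylation, methylation,
  succinylation. The masked distance's column set `4j + v` presumes
  exactly this layout, so it is part of the model contract and of the
  serialized model format.
- **Empty label sets in the overall metrics.** A ratio with an empty
  denominator set contributes 1 when both sets are empty and 0 when only
  the denominator set is empty; the exact-match indicator counts two empty
  sets as agreement. These conventions are *certified*, not guessed: they
  are the unique combination that reproduces all five published overall
  metrics for the 20 evaluation sites of protein Q16778 bundled as
  `table6_fixture()` (0.8250, 0.8250, 0.8167, 0.8000, 0.0625), and the
  test suite pins them there.
- **Per-label precision and F1** are 0 when their denominators are 0;
  sensitivity/specificity are `NA` when a label has no positives or no
  negatives in the evaluation set.

## Cross-validation design

Because the features embed training-set label information, an honest
evaluation must re-derive them inside each fold: `run_cv()` fits the count
table and model on the training folds only and encodes the held-out fold
with that table. Two designs are provided. *General* mode partitions
records uniformly at random into folds as equal as possible (remainder on
the first folds). *Strict* mode partitions proteins (balancing protein
counts, since the design randomly and equally divides the sequences) and
assigns every site of a protein to its protein's fold, which removes
within-protein information sharing between training and test.

The five overall metrics are reported as the mean of the per-fold values;
per-label confusion metrics and ROC/PR areas are computed on the pooled
held-out predictions. Pooling keeps the curves well defined when a fold
happens to contain very few positives of a rare type; averaging the
overall metrics matches the convention of selecting the average
performance over the parts. The two choices coexist in one report and are
labeled accordingly.

AUROC is computed by the rank (Mann–Whitney) formula with midrank tie
handling; AUPR by step integration of precision over recall with tied
scores entering as one block. The test suite cross-checks AUROC against an
independent implementation (`pROC`) and AUPR against a brute-force
threshold sweep.

## The synthetic data generator

`generate_synthetic_dataset()` exists so that every stage — extraction,
encoding, scoring, both CV modes, the CLI — can be exercised end to end
with no external data. Its generative model mirrors the feature model's
core assumption (a location-fixed association between residue pairs and
types), so parameter-recovery tests are meaningful:

1. **Labels first.** Each site's four indicators are drawn from an
   exchangeable Gaussian copula with the requested marginal prevalences;
   `multilabel_rate` is the latent correlation. Marginals are therefore
   exact at any co-annotation level. Defaults
   (0.45, 0.10, 0.08, 0.30, rate 0.15) emulate the published benchmark's
   imbalance: acetylation most prevalent, succinylation second,
   crotonylation and methylation rare, about a third of sites unlabeled.
2. **Residues second.** Segment residues are drawn i.i.d. from a
   background frequency table; the center is forced to `K`. For each
   active label, each of its enrichment motifs (a position, a residue
   pair, an odds multiplier `m`) is placed with probability
   `m q / (1 - q + m q)`, where `q` is the background probability of the
   pair — i.e. the background odds boosted `m`-fold.
3. **Proteins.** Sites are grouped into synthetic proteins (default 100
   proteins × 6–14 sites, ~1000 sites) whose sequences are the
   concatenation of their segments, so `fasta_plus_sites` round trips
   exactly and strict CV is exercisable.

The default background is a reduced eight-letter alphabet (A, L, E, G, S,
V, K, T at Swiss-Prot proportions, renormalized). This is a deliberate
distortion of real composition: with 20 letters a ~1000-site dataset
leaves most di-residue keys with only one or two carriers, and the
proportion estimates `rho` degenerate into near-binary noise, which is an
artifact of small synthetic corpora rather than a property of the method
(the real benchmark has 6394 sites). The reduced alphabet (~60 effective
pairs per position) restores the many-carriers-per-key regime at n ≈ 1000.
The `"strong"` enrichment preset plants four motifs per type (fewer for
very narrow windows) at distinct positions with multiplier 1000, giving
placement probabilities around 0.95 — near-deterministic motifs, as the
recovery tests require.

What the generator does **not** emulate: real amino-acid composition,
homology and shared motifs *between* proteins (synthetic proteins are
independent, so strict CV is structurally easy here), soft or degenerate
motifs, position correlations, and annotation noise. Passing the recovery
tests therefore shows that the pipeline recovers the kind of signal the
model assumes when it is present — it is not evidence about performance on
real proteomes, which is why the published-benchmark reproduction path
(`load_qiu_dataset()`, README) is kept separate.

## Problem sizes and runtime choices

The test suite works at deliberately small scales chosen as the smallest
that still separate signal from noise: oracle comparisons use ≤ 50
training segments and 20 queries at `L = 3` (double-loop references are
quadratic); property tests use 100–1000 random cases under fixed seeds;
the end-to-end recovery runs use the generator's default ~1000 sites at
`L = 13`, where a full 5-fold CV takes well under a second. Scoring is
vectorized as a queries × training distance matrix per label; memory is
`O(n_test × n_train)` per fold, which is comfortable up to tens of
thousands of sites.

## Known limitations

- Class imbalance is not corrected; under strict CV rare-type precision
  degrades first, as expected for a nearest-evidence method.
- The feature space is exactly the per-type proportion profile: segments
  sharing no training keys encode identically to the zero vector and are
  scored by global label priors alone.
- `predict()` on a FASTA scores *every* lysine, including lysines whose
  modification status is unknowable from sequence context alone; scores
  are not calibrated probabilities.
- Only the four types above are modeled; extending the label set changes
  the feature layout (`8(L-1)` → `2m(L-1)`) and the masked column map.
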