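---
title: "Predicting and optimizing cell-penetrating peptides with cpprop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and optimizing cell-penetrating peptides with cpprop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpprop)
```

## The problem

Cell-penetrating peptides (CPPs) are short sequences (roughly 4–40
residues) that cross cell membranes and can ferry molecular cargo into
cells. Sequence-based CPP predictors trained on the few thousand known
CPPs tend to produce many false positives when scanned across arbitrary
protein sequence, because almost everything they saw during training that
*wasn't* a CPP was still a curated peptide, not ordinary protein
background. `cpprop` implements a window-based prediction pipeline built
around two ideas:

1. **Learn on 9-mers, not whole peptides.** Every training peptide is
   sliced into overlapping 9-residue windows (peptides shorter than 9 are
   right-padded with `-`). This multiplies the effective training set
   roughly ten-fold and lets the model localize *which part* of a longer
   sequence carries penetration propensity.
2. **Use proteome background as negatives.** In addition to curated
   non-CPPs, all 9-mers of a reference proteome (minus any window
   identical to a positive window) can be added as negatives, pulling the
   score of ordinary protein sequence down and improving specificity.

On top of the classifier the package provides per-residue propensity
profiles (for scanning whole proteins such as the 770-residue amyloid
precursor protein, whose N-terminal 17-mer signal peptide
`MLPGLALLLLAAWTARA` is the running example in this vignette), and an
exhaustive substitution-space optimizer for improving a wild-type CPP.

## The model

Each 9-mer window is scored by an ensemble of five small neural
classifiers. All five share the same skeleton — a learned embedding of
the 21-symbol vocabulary (20 amino acids + the pad symbol), an optional
1-D convolution, a stack of LSTM layers, a stack of additive
self-attention layers, global average pooling, and a sigmoid output — and
differ in their layer counts:

| member | embedding dim | conv filters | LSTM layers | attention layers |
|--------|--------------:|-------------:|------------:|-----------------:|
| Model1 | 10 | 15 | 2 | 3 |
| Model2 | 10 | 15 | 0 | 2 |
| Model3 | 10 | 15 | 3 | 6 |
| Model4 | 3  | 0  | 0 | 1 |
| Model5 | 6  | 0  | 0 | 1 |

The ensemble score of a window is the arithmetic mean of the five member
scores; the score of a peptide is the mean of its window scores; the
propensity of a *residue* is the mean of the scores of every window that
covers it (exactly nine windows for interior residues, fewer near the
termini).

Details the layer-count table does not fix were chosen once, for
smallness and trainability on a single CPU, and are constants of the
package: convolution kernel 3 (ReLU), LSTM hidden width 8, single-head
additive attention with attention width 8, global average pooling before
the sigmoid head. An attention layer maps the position sequence to a
position sequence so the stacks compose: scores
$e_t = v^\top \tanh(W_a h_t + b_a)$ give weights
$\alpha = \mathrm{softmax}(e)$ and a context $c = \sum_t \alpha_t h_t$,
and the output at position $t$ is
$\tanh(U_h h_t + U_c c + b_o)$. The pad symbol receives an ordinary
embedding row and is never masked: a padded window is a legitimate model
input, and the pad position carries the information that the peptide
ends there.

Training minimizes binary cross-entropy with Adam (default learning rate
0.005, batch size 256). The nominal training length is 1000 epochs; all
desk-scale examples and tests in this package use far fewer (50 or less),
which is already enough to saturate the synthetic benchmark below.
The forward and backward passes are implemented directly in vectorized
R, with no external deep-learning dependency; every analytic gradient is
checked against central finite differences in the test suite, so the
optimizer is exactly the one described here.

### Class imbalance

A realistic proteome contributes millions of negative windows versus a
few thousand positives. Rather than training on that imbalance, each
epoch uses all curated fragments plus a fresh random subsample of
proteome negatives at `negative_subsample_ratio` (default 2) per
positive. The model therefore sees a changing sample of the background
over epochs without the loss being dominated by it. Setting the ratio to
0 disables proteome negatives entirely.

## Dataset construction rules

* Curated training peptides must be 5–38 residues long (the length range
  of the curated CPP collections); scan targets and proteome proteins are
  exempt.
* Duplicate windows are removed globally. A window observed under both
  labels is dropped from both classes — silently preferring one label
  would bias training, and the conflict count is reported instead.
* Proteome windows identical to a positive window are excluded from the
  negative set (exact 9-mer identity; `exclude_hamming = 1` additionally
  excludes single-mismatch neighbours for a stricter notion of "low
  similarity to known CPPs").
* Sequences containing non-standard symbols (`B J O U X Z *`) are dropped
  at parse time and counted.
* Offsets are 0-based internally; every user-facing coordinate (profile
  positions, region bounds, substitution positions) is 1-based inclusive.

## The synthetic data generator

Real curated CPP collections cannot be redistributed with the package,
so `generator_config()` defines a fully seeded synthetic study condition
that preserves the one property the method needs: a compositional
difference between classes. Positives are drawn with probability mass
0.35 on the cationic residues K/R/H and 0.40 on hydrophobic residues
(L/A/I/V/F/W/M) — mimicking the cationic/amphipathic character of known
CPPs — while negatives and the mock proteome use a uniform background
(each residue 0.05, hence K/R/H mass 0.15). Peptide lengths are uniform
on 5–38; the default set is 1000 positives + 1000 negatives, and the
default mock proteome is 100 proteins of 80–300 residues. A planted-motif
mode (`motif = TRUE`) additionally inserts a fixed cationic patch for
context-sensitivity experiments.

What the generator does *not* emulate: amphipathic helical periodicity,
secondary structure, position-within-peptide effects, or the redundancy
structure of real databases. A high held-out AUC on synthetic data
therefore demonstrates that the training machinery can recover a
compositional signal, not that the package reproduces published
benchmark numbers on curated data — those depend on the original
training corpus and weights and are out of scope here.

## A worked desk-scale run

Generate data, train a reduced ensemble, and evaluate on held-out
peptides (the test suite runs the full five-member, 50-epoch version of
this; here we keep the chunk light):

```{r train, eval = FALSE}
peps <- generate_labelled_peptides(generator_config(seed = 7))
idx <- sample(nrow(peps))
test <- peps[idx[1:400], ]
train <- peps[idx[-(1:400)], ]

frags <- fragment_peptides(train)
ens <- train_ensemble(frags, config = train_config(epochs = 50, seed = 7))

evaluate_peptides(test, ens)
tidy(ens)      # per-member architecture and final loss
```

Scan a protein and call candidate regions:

```{r scan, eval = FALSE}
proteins <- read_fasta("my_proteins.fasta")
profile <- scan_protein(ens, proteins[1, ])
autoplot(profile)
call_regions(profile, threshold = 0.8, min_length = 5)
```

Optimize a wild-type CPP by scoring its substitution space:

```{r optimize, eval = FALSE}
wt <- "MLPGLALLLLAAWTARA"
count_mutants(nchar(wt), 3)          # 4,713,539 sequences
scan <- score_space(ens, wt, max_subs = 3, threshold = 0.8)
autoplot(scan)                        # histogram of mutant scores
pfm <- position_frequency_matrix(scan$survivors$sequence)
autoplot(pfm)                         # logo-style summary
select_candidates(scan)               # rule-filtered, ranked candidates
```

## Numerical and design choices

* **Aggregation rules are distinct.** A peptide score is the mean of
  *window* scores; a residue score is the mean of the windows covering
  that residue. The mean of residue scores is *not* the peptide score,
  and the test suite asserts the two are not conflated.
* **Terminal residues** average only the windows that exist. Padding a
  full-length protein to give terminal residues nine windows would
  fabricate sequence context, so it is not done.
* **Classification threshold** for confusion-based metrics is 0.5, with
  ties (score exactly at threshold) predicted positive. AUC is computed
  in the rank-statistic form (ties counted ½), which equals the
  trapezoidal ROC area. MCC uses the standard four-factor formula with
  the value defined as 0 when any denominator factor vanishes.
* **Region calling** uses maximal runs of residues at or above a
  threshold (default 0.8, the optimization cut-off) of at least 5
  residues (the minimum curated CPP length). There is no canonical
  region-calling rule for propensity profiles, so this one is
  deliberately simple and exposed as parameters.
* **Mutant enumeration order** is fully deterministic: by substitution
  count, then position combination (lexicographic), then replacement
  residues (alphabet order, last position fastest). The wild type is
  excluded — the count 4,713,539 for a 17-mer at up to three
  substitutions is $\sum_{k=1}^{3} \binom{17}{k} 19^k$, and streaming
  enumeration visits each sequence exactly once in constant memory.
* **Survivor summaries** use raw position frequencies (columns sum to
  1), not information-content scaling, and the default candidate
  selection rule (positions 3/4/14, replacements K/R/H) encodes the
  position preferences seen in the signal-peptide optimization logo; both
  are overridable.
* **Determinism.** One global seed is fanned out per stage through a
  stable string-hash derivation, so identical seeds give byte-identical
  output files (scores are written at fixed 6-decimal precision), and
  stages can be re-run independently without disturbing each other's
  streams.
* **Model bundles are plain text**: a JSON manifest plus one JSON weight
  file per member, written at full precision, so a save/load round trip
  changes probe scores by less than $10^{-6}$.

## Problem sizes used in the shipped checks

The package's own acceptance checks train the five-member ensemble for
50 epochs on the generator defaults (1000 + 1000 peptides, ~22,000
unique fragments after an 80/20 peptide-level split) and require held-out
peptide-level AUC ≥ 0.90 with the ensemble no worse than its best member
by more than 0.02. The full 4.71-million-sequence space of the 17-mer
wild type is enumerated (not scored) in full; scored space scans in the
tests use a single-substitution space or an explicit `limit`. These sizes
were chosen as the smallest that still exercise every code path at
realistic scale.

## Known limitations

* The five member architectures are specified by their layer counts; the
  hidden-width constants (kernel 3, LSTM width 8, attention width 8) are
  the package's own choice, so member *shapes*, not exact weight counts,
  are the contract.
* Synthetic-data performance does not transfer to curated CPP corpora;
  the pipeline accepts real labelled tables and proteome FASTA through
  the same entry points when such data are available.
* No insertion/deletion variants in the optimizer, no clustering-based
  redundancy reduction of positives (exact-duplicate removal only), no
  modeling of chemical modifications (fluorophores, amidation),
  D-amino acids, or oligomerization.
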