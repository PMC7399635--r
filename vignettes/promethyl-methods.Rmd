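---
title: "Methods: the promethyl 5mC ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the promethyl 5mC ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promethyl)
```

## The prediction problem

Promoter 5-methylcytosine (5mC) calling is a per-base binary
classification: given the local sequence context of a cytosine in a
promoter, is it methylated? The assay-derived label sets this package is
designed for are heavily imbalanced — roughly one methylated site per
eleven unmethylated — and the signal is local: 5mC in somatic cells occurs
almost exclusively at CpG dinucleotides, and promoter methylation
concentrates in CpG-dense islands. Both facts shape the design below.

## Windows and strand handling

A candidate site is the window of `2δ + 1` nucleotides centred on the
candidate base. The default `δ = 20` (41 nt) reflects the common
observation that flanks shorter than ~15 nt carry too little context while
very long flanks add noise; `δ` is a free parameter of every function that
touches windows. On the plus strand candidates are `C`; on the minus
strand they are `G` and the extracted window is reverse-complemented, so
downstream code sees a C-centred window regardless of strand. Reported
coordinates always refer to the original, un-complemented input (0-based
in the API, 1-based in the human-readable `pos_1based` column, half-open
0-based in BED output).

Edge candidates whose window would overhang the sequence are skipped —
the model is only defined on full-length windows, and padding would feed
it contexts it never saw in training. Windows containing `N` are excluded
from training (assay-derived benchmarks are N-free) but are scored at
prediction time — `N` encodes as all-zero features, a graceful
degradation — and flagged in the `has_n` column so users can filter.

## Encodings

Three encodings are provided; all produce values in `[0, 1]` and none is
standardised afterwards (the inputs are already bounded and comparable).

* **One-hot** (default): 4 indicator values per base, `4L` per window.
  `N` is all zeros, so each 4-block sums to 1 for a real base and 0 for
  `N`.
* **DPF**: per position `k`, the three chemical-property bits
  (ring structure = purine {A,G}; functional group = amino {A,C};
  hydrogen bond = weak pairing {A,T}) followed by the cumulative
  frequency `λ_k` = (occurrences of the base at `k` among positions
  `1..k`) / `k`. The denominator is the position index `k`, not the full
  window length: `λ` is then the running density of that base up to `k`,
  so `λ_1 = 1` always and `λ_k·k` is an exact integer count (asserted in
  the tests). Feature order within a position is (ring, functional,
  hydrogen, λ).
* **Fused**: one-hot followed by DPF, `8L` values. The concatenation
  order is fixed (one-hot first) purely for reproducibility.

At `δ = 20` the widths are 164, 164 and 328.

## The down-sampling ensemble and unanimous fusion

With a 1:11 class ratio, a single classifier trained on all data can reach
high accuracy by ignoring positives. Instead the negatives of the training
set are partitioned at random (seeded) into `k = 11` groups whose sizes
differ by at most one; each group is paired with the positive set, the
larger side down-sampled (seeded) to the smaller so every subset is
exactly balanced; and one sub-network is trained per subset. Every
negative thus trains exactly one sub-model and the positives train all of
them. `k = 11` mirrors the 1:11 imbalance so that group size ≈ positive
count and down-sampling is minimal; `k` is configurable.

Each sub-network is a fully connected multilayer perceptron: hidden layers
of 64, 128, 256, 128 and 64 ReLU units and a 2-unit sigmoid output (one
unit per class; the positive unit's activation is the score). A 2-unit
sigmoid output is unconventional for a binary problem — a single unit
would do — but it is retained as the reference architecture of this
ensemble design; the loss is binary cross-entropy summed over both units.
Dropout 0.3 is applied to the last hidden layer (inverted dropout, so
inference needs no rescaling). The network is implemented in base R matrix
code and trained with Adam (learning rate 1e-3, `β₁ = 0.9`, `β₂ = 0.999`),
minibatches of 256, at most 50 epochs with early stopping on a 10%
validation split (patience 5, best weights restored). Optimiser, batch
size and epoch budget are this package's choices; they are exposed in
`submodel_config()` and all seeded — initialisation, shuffling, dropout
masks and the validation split derive deterministically from one master
seed, so a fit is bit-reproducible on one CPU.

Decision fusion is **strict unanimity**: a query is positive only if all
`k` sub-model scores exceed the threshold (default 0.5 on the
positive-unit probability). The fused positive set is therefore a subset
of every sub-model's positive set, which guarantees fused specificity ≥
each sub-model's specificity on any fixed test set — the property the
ensemble exists for. A majority rule is available as an alternative. For
ROC curves a binary vote is useless, so a continuous fused score is
needed; the default is the **minimum** sub-model score, chosen because
thresholding the minimum at `t` reproduces the unanimous decision at `t`
exactly (an identity the tests verify exhaustively). The mean is offered
as an alternative but is not decision-consistent.

## Metrics

`Sn = 1 − FN/N⁺`, `Sp = 1 − FP/N⁻`, `Acc = 1 − (FN+FP)/(N⁺+N⁻)`. MCC uses
the standard TP/TN/FP/FN correlation formula, which equals the Pearson
correlation of the two binary vectors (asserted to 1e-12 in the tests);
a zero denominator returns 0 with a warning. AUC is computed from average
ranks — the Mann–Whitney statistic with ties counted ½ — and the ROC
curve by a full threshold sweep whose trapezoidal area equals the rank
AUC to numerical precision. Cross-validation metrics are macro-averaged:
over folds, then over repeats.

## The synthetic generator

`generate_dataset()` emulates the *shape* of an RRBS-derived promoter
benchmark: C-centred windows of length `2δ+1`, an arbitrary class ratio
(1:11 in all shipped defaults), and a tunable class signal. Negatives are
i.i.d. draws from a background with a chosen GC fraction (default 0.5;
promoter-like GC richness can be dialled in). Positives plant a motif of
width 8 around the centre: at each motif position the base is a
CpG-flavoured consensus (alternating C/G, with G immediately downstream of
the central C) with probability `effect`, otherwise a background draw. At
`effect = 0` the classes are exchangeable by construction — the null
model — and at `effect = 0.9` the classes are strongly separable. The
dinucleotide-level CpG flavour was chosen because CpG density is the
biologically plausible signal for promoter methylation; any separable
signal would do for testing the machinery.

What the generator does **not** emulate: real positional dependence
beyond the motif, sequence redundancy and homology structure, methylation
levels (labels are binary), genomic coordinates, or assay noise. Passing
tests on synthetic data therefore demonstrate that the pipeline learns a
planted local signal under realistic imbalance and that the fusion logic
behaves as designed — not that the headline numbers would transfer to any
particular cell line's benchmark.

## Problem sizes and numerical choices in the shipped checks

The test suite and `scripts/acceptance.R` cross-validate the full
11-sub-model ensemble on 500 positives / 5,500 negatives at `δ = 20`
(5-fold, one repeat), sizes chosen so the whole check runs in about a
minute per condition on one CPU while keeping the 1:11 ratio and full
window length; unit tests use smaller windows and a 16-unit single hidden
layer where only the plumbing is under test. Observed behaviour at these
sizes: fused CV AUC ≈ 0.99 at `effect = 0.9`, fused AUC ≈ 0.48 (chance)
at `effect = 0`, and fused specificity above every sub-model in every
fold. Degenerate inputs are errors, not silent fixes: single-class
training data, mixed window lengths in a batch, non-C centres, window
overhang, and AUC with one class absent all raise informative errors;
the only warning-convention is MCC = 0 on a degenerate confusion table.

## Known limitations

* Sub-networks are trained sequentially on one CPU; there is no GPU path.
  At benchmark scale (hundreds of thousands of windows) training is
  feasible but slow; the architecture is small enough that this is an
  engineering, not statistical, limit.
* The unanimous rule's specificity guarantee has a price: one poorly
  calibrated sub-model caps the ensemble's sensitivity.
* No redundancy filtering is built in; if training windows share high
  sequence identity, cross-validation estimates will be optimistic.
  Users should pre-filter (e.g. with an external clustering tool).
* The model learns local sequence only; trans factors, chromatin state
  and cell-type effects are out of scope.
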