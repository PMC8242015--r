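---
title: "rmnet: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rmnet: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Post-transcriptional RNA modifications — N6-methyladenosine (m6A),
N1-methyladenosine (m1A), 5-methylcytidine (m5C), 5-methyluridine (m5U),
N6,2'-O-dimethyladenosine (m6Am), 7-methylguanosine (m7G), pseudouridine
(Psi), inosine (I) and the four 2'-O-methylations (Am, Cm, Gm, Um) — each
occur on one specific nucleotide and leave a statistical footprint in the
surrounding primary sequence. `rmnet` learns one integrated model that maps
a fixed-length sequence window centered on a candidate base to twelve
per-modification probabilities, then explains every positive call at
nucleotide resolution and quantifies how strongly the twelve tasks share
sequence preferences.

Because the twelve tasks are modeled jointly, rare modifications borrow
statistical strength from abundant ones through the shared encoder, and the
learned per-task attention parameters become a window into cross-modification
association.

# The model

A window $x$ of odd length $L$ over $\{A,C,G,U,N\}$ is embedded in one of
two ways:

* **word2vec** (default): overlapping 3-mers (a window of length $L$ yields
  $L-2$ tokens) are looked up in an embedding table trained in-package by
  skip-gram (or CBOW) with negative sampling on the study corpus. Tokens
  never seen in pre-training (e.g. N-containing 3-mers from boundary
  padding) map to the zero vector; this out-of-vocabulary policy is a
  deliberate choice and is reported with a warning.
* **one-hot + CNN**: the window is one-hot encoded ($A, C, G, U$ unit rows,
  $N$ the zero row) and passed through a 1-D convolution (width 8, 32
  filters by default) with ReLU and max-pooling (width 4), which densifies
  the sparse input before the recurrent layer.

The embedded sequence feeds an LSTM encoder. By default the encoder is
bidirectional: the forward and backward passes are concatenated, so each
position's state carries a signature of its distance from both window ends.
This matters at desk scale — additive attention was designed over a
bidirectional encoder, and with a single direction the attention heads have
almost no positional information at initialization and fail to localize the
centered candidate site within a practical training budget (in our
single-direction control runs the per-label AUC plateaus near 0.6 under
conditions where the bidirectional encoder exceeds 0.95).

On top of the encoder sit twelve additive (Bahdanau) attention heads, one
per modification. With hidden states $c_i$ and learned features $y_i$ (the
LSTM cell and hidden states), head $j$ scores position $i$ as

$$e_{j,i} = v_j^\top \tanh(W c_i + U y_i + b_j),$$

with $W, U$ shared across heads and $v_j, b_j$ head-specific. Softmax over
positions yields attention weights $\alpha_{j,i}$ and the context vector
$\mathrm{ctx}_j = \sum_i \alpha_{j,i} \, y_i$. Each context passes through a
per-label two-layer fully connected branch (ReLU, dropout 0.2 by default)
ending in a sigmoid; the twelve probabilities are independent binary
decisions with no sum-to-one constraint. The twelve score vectors $v_j$ are
exposed for the association analysis.

All forward and backward passes are implemented in compiled code
(RcppArmadillo) with hand-derived gradients; the test suite verifies every
parameter gradient against central finite differences.

## Supervision masking

Each base supports only some labels (A: m6A, m1A, m6Am, Am, I; C: m5C, Cm;
G: Gm, m7G; U: Psi, Um, m5U). A training window supervises:

* its own positive label(s), and
* if it is a sampled negative, **all** tasks on its center base.

A positive window of one modification is deliberately *not* used as a
negative for sibling modifications on the same base. Real site corpora
assert presence, not absence: a position reported as m5C has simply never
been assayed for Cm, and forcing the Cm head to score it zero manufactures
training conflicts whenever two same-base modifications prefer similar
contexts (which is exactly the regime the association analysis cares
about). Sampled negatives, by contrast, are drawn from unmodified
occurrences of the base and are genuine negatives for every task on that
base. Tasks not supervised by a window are excluded from the loss through a
mask.

## Training objectives

All modes act on masked per-label binary cross-entropy (BCE). The
normalization conventions are chosen so the modes collapse into each other
exactly in their degenerate corners (these identities are tested):

* `bce` — mean over samples of the per-sample mean over supervised tasks.
* `focal` — per-entry BCE scaled by $(1-p_t)^\gamma$ ($\gamma = 2$ default);
  $\gamma = 0$ is exactly `bce`.
* `bce+ohem` — online hard example mining: only the top-$q$ fraction of
  samples by per-sample loss is kept in the batch objective ($q = 0.7$
  default); $q = 1$ is exactly `bce`.
* `bce+uw` — uncertainty weighting: $\sum_j e^{-s_j} L_j + s_j$ with
  task-mean losses $L_j$ and learnable $s_j$ (initialized 0, trained by the
  same Adam optimizer); frozen $s = 0$ is exactly the unweighted task sum.
* `bce+ohem+uw` — OHEM sample selection under the UW task weighting.
* `effective_number` — fixed class weights proportional to
  $(1-\beta)/(1-\beta^{n_j})$, normalized to mean one ($\beta = 0.999$
  default); equal weights as $\beta \to 0$, inverse frequency as
  $\beta \to 1$.

Training uses Adam (default learning rate $2 \times 10^{-3}$; the bundled
studies use $4 \times 10^{-3}$), mini-batches of 128, exponential or
cosine-annealing learning-rate decay, at most 100 epochs, and early stopping
when the validation loss rises for five successive epochs; the parameters of
the best validation epoch are restored (optionally, a Polyak average of the
final epochs can be kept instead). All randomness — initialization,
shuffling, dropout masks, word2vec negative sampling — flows through R's
RNG, so a fixed seed reproduces a training run exactly on the same
numerical platform.

# Data assembly

Site tables are TSVs (`sequence_id, position, strand, label`) in a declared
0- or 1-based convention, normalized internally to 0-based; display output
is 1-based. T and U are interchangeable on input. Windows are centered on
the site, N-filled where they overrun the sequence, and reverse-complemented
for minus-strand sites so the center base reads 5'→3'. Negatives are drawn
uniformly from unmodified occurrences of the label's original base on the
same transcripts (1:1 by default), excluding all positive positions and any
exclusion list (e.g. lower-confidence reported sites). The DRACH (m6A) and
BCA (m6Am) consensus restrictions are available for curated real-data
tables (`apply_motif_filter`; `--motif-filter` in the CLI); they are applied
after negative sampling, and an N anywhere in the motif context fails the
match. Validation and test sets take exactly 150 and 50 windows per class
(every modification plus one negative pool per base); the remaining,
imbalanced windows form the training set.

# Interpretation

**Integrated gradients.** Attribution for one (window, label) pair is the
midpoint Riemann approximation (50 steps by default) of the path integral of
the probability gradient from a baseline to the input. The baseline is the
all-zero embedding (word2vec) or the all-N one-hot — the model's natural
"no sequence" input. Token-level attributions are projected to nucleotides
by splitting each token's score equally over the k nucleotides it covers,
which preserves the completeness identity: attributions sum to the
probability difference between input and baseline, up to a quadrature
residual that is reported and shrinks as steps grow (the ReLU kinks make the
decrease monotone only on average).

**Motif mining.** True positives with predicted probability in the top
decile are attributed; per sample, up to 3 non-overlapping windows of width
6 with the highest mean attribution are extracted greedily, masking each
selected window and its (w−1)-nt neighborhood. Candidates need not contain
the modified site itself. Equal-length candidates are one-hot flattened
(already aligned, so no multiple alignment is needed), embedded to two
dimensions by principal components (coordinates scaled to unit variance),
and clustered with DBSCAN (eps 0.5, min_samples 5); noise points are
dropped and each cluster becomes a column-stochastic PWM with pseudocount
0.01, exportable in MEME minimal format.

**Association.** The twelve attention score vectors $v_j$ are correlated
pairwise (Pearson); p-values come from the exact distribution of the sample
correlation coefficient under the bivariate-normal null (`stats::cor.test`).
A zero-variance vector yields NA rather than a fabricated value. Note the
correlation is estimated over `attention_dim` coordinates, so small
attention spaces give noisy associations; the bundled association study
uses 64 dimensions for this reason.

**Site-distance aggregation.** For two site sets, the observed median
nearest-neighbor distance on shared sequences is compared to a null built by
uniformly repositioning the second set on the same sequences; the one-sided
empirical p-value uses the add-one correction.

# Statistical significance of predictions

A predicted probability is converted to a p-value upper bound by ranking it
against a background of scores from unmodified occurrences of the same base:
bound = (#background scores above + 1) / (N + 1). The add-one (permutation
style) correction keeps the bound strictly positive for finite backgrounds;
for a large background where 1% of scores are higher, the bound is 0.01.
Backgrounds are per-(base, label), built from held-out negative windows and
persisted inside the checkpoint so server-style prediction is reproducible.

# The synthetic corpus generator

`synth_generate` emulates the structure of real base-resolution corpora:
random transcripts from a configurable base composition; per-label planted
PWMs (width 4–8, default 5) whose center column is degenerate at the
label's original base; non-overlapping implantation (overlap beyond capacity
is an error, not silent clipping); same-transcript negatives; configurable
abundance skew and forced PWM sharing between same-base labels. Auto
generated PWMs place probability 0.9 on a random consensus base per
flanking column — a sharp, information-rich motif; with four informative
columns this puts the Bayes-optimal binary AUC near 0.98, which is the
right ceiling to exercise a discriminative model without making the task
trivial.

What the generator does *not* emulate: transcript-level covariates
(expression, secondary structure), technology-specific noise and batch
effects, clustered or strand-asymmetric site placement, and motif-free
modifications. Passing the bundled recovery suites therefore demonstrates
that the estimator works — not that real epitranscriptomes are this easy.

The bundled studies use deliberately scaled problem sizes: the 12-label
recovery study plants 500 positives per label in a 2-Mb corpus (planted
motifs occupy ~1.7% of sequence, matching the sparsity of real corpora
where a few hundred thousand sites spread over hundreds of megabases — a
denser corpus puts planted motifs inside many negative windows and measures
an artifact of the generator rather than the method), trains a small
configuration (L = 51, hidden 32, embedding 32) for 40 epochs with training
hyper-parameters selected on the validation set (dropout 0.1 rather than the
0.2 package default: at this scale the model is noise- rather than
overfit-limited), and checks per-label validation AUC and PWM recovery. The association study plants one
shared PWM across two same-base labels plus an independent label; the
imbalance study uses a 50:1 skew (5000 vs 100 positives). With 150
validation positives per label the AUC estimate carries a standard error of
roughly 0.013, which bounds how sharply any per-label claim at these sizes
should be read.

# Numerical choices and edge cases

* Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ inside losses.
* ROC-derived quantities use the finite set of observed scores, so the AUC
  equals the Mann–Whitney statistic exactly; the G-mean threshold breaks
  ties toward higher specificity, and a degenerate ROC (all scores equal)
  returns the better of the two trivial calls.
* MCC with a zero denominator is reported as 0 with a `degenerate` flag.
* Glorot-uniform initialization; LSTM forget-gate bias 1.
* Word2vec uses a fixed context radius (no random window shrinking) and a
  single thread so results are exactly seed-reproducible.
* Checkpoints store an embedding-table fingerprint and refuse to load
  against a mismatched table.

# Limitations

* Training is CPU-bound and single-threaded; the implementation targets
  desk-scale studies (thousands to tens of thousands of windows), not the
  hundreds of thousands of sites of a full transcriptome compilation.
* The association analysis reads sequence-preference similarity off jointly
  learned attention parameters; it does not establish co-occurrence of
  modifications in any biological condition.
* P-value bounds control only the type-I error against the sequence
  background; with strongly different class abundances the false-discovery
  proportion at a fixed cutoff differs between modifications.
* Per-label AUC under the bundled study sizes is intrinsically noisy (SE
  ~0.013); claims about single labels at these sizes deserve wide error
  bars.
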