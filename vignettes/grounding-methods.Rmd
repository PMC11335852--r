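---
title: "Methods: the grounding model, its bridges, and the evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the grounding model, its bridges, and the evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groundlex)
```

## The model and its assumptions

`groundlex` grounds a frozen textual embedding space in vision through a
single linear map. Given caption–image pairs $(S_j, I_j)$, with
$S_j = [w_1, \dots, w_n]$ and $I_j \in \mathbb{R}^{D}$ a precomputed image
feature vector, each word's textual vector $t_i \in \mathbb{R}^{d}$ is
mapped into the grounded space by the alignment $M$ ($d \times c$, no
bias):

$$g_i = t_i \cdot M.$$

A sequence encoder (*bridge*) turns the grounded sequence into a predicted
image vector, and the joint parameters $\Theta = (M, \theta)$ are trained
by stochastic gradient descent on the mean squared error between
prediction and image vector. The central modeling assumptions are:

* **The textual space is frozen.** Only $M$, the bridge and any projection
  head learn; the embedding table is read-only throughout. This is what
  lets the model *adjust* rather than replace distributional structure.
* **The alignment is linear by default.** A linear $M$ restricts how far
  vision can deform the textual space; the nonlinear ablations
  (`activation = "relu"` / `"leaky_relu"`, `activation_layers = 2`) exist
  precisely to study what happens when that restriction is lifted.
* **Grounding is zero-shot.** After training, $M$ is applied to the whole
  vocabulary. Nothing in the mapping depends on whether a word occurred in
  a caption, so abstract and otherwise unseen words are grounded
  indirectly through the structure they share with caption words.

## Bridges

| bridge | encoder | prediction |
|---|---|---|
| `word_level` | none (stop words removed) | each token's $g$ regressed on the PCA-reduced image vector |
| `bow` | mean of grounded vectors | tanh hidden layer, then linear |
| `gru`, `lstm` | recurrent, final hidden state | identity, or linear head when `encoder_units != D_img` |
| `transformer` | stacked self-attention encoders | mean-pooled states, linear head |

All forward and backward passes are implemented in the package (base R
matrix algebra) and are verified in the test suite against
finite-difference gradients at small dimensions; there is no external
deep-learning dependency.

Bridge-specific choices worth knowing:

* **LSTM/GRU initial states** default to zeros at every sequence for
  determinism, with `init_state = "learned"` providing trainable
  $h_0$/$c_0$ for setups that want the initial state to be part of the
  model. Zeros-by-default is a deliberate deviation from describing the
  initial state as "random": a per-run random state is not reproducible
  and adds nothing at these problem sizes.
* **The LSTM hidden size defaults to `D_img`** so the final hidden state
  *is* the prediction; a linear projection head is inserted automatically
  whenever `encoder_units != D_img` (always for the transformer and BoW
  bridges, which have their own output layers).
* **Transformer details** the architecture leaves open: sinusoidal
  position encoding, feed-forward inner width $2m$, post-norm residual
  blocks, mean pooling over positions. Defaults are hidden size 1024 with
  16 heads and learning rate $10^{-4}$; all are configurable.
* **Word-level PCA** (`D_img -> c`) is fit with centered, unscaled
  principal components on the *training split only* and applied unchanged
  to validation data.

## Training loop

Defaults in `grounding_config()`: grounded dimension $c = 1024$, image
dimension $D = 2048$, batch size 256, at most 20 epochs, NAdam with
learning rate $10^{-3}$ ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$), early stopping with patience 5 on the validation
loss, caption vocabulary truncated to the 10,000 most frequent tokens.
The loss is the plain element-wise MSE, averaged over batch ×
image-dimension entries; where the summation convention of an MSE can be
read in more than one way, per-element averaging is the interpretation
used, since it only rescales the gradient. Weight initialization is
Glorot-uniform from the run's seed; a single `seed` drives
initialization, the train/validation carve-out, epoch shuffling and
(in the MLP) dropout masks, so identical configurations reproduce
bit-identical parameters and traces.

Early stopping counts *consecutive non-improving validation epochs*; when
the count reaches `patience` the run halts and the best-epoch parameters
are restored, so the number of epochs after the best epoch never exceeds
the patience.

Preprocessing: captions are lowercased, ASCII punctuation is deleted
in place (so `co-pilot's` becomes `copilots`), tokens are split on
whitespace. The caption vocabulary keeps the `top_k` most frequent tokens
with frequency ties broken lexicographically (determinism; the choice is
otherwise arbitrary), and is intersected with the embedding table's words
*before* training so lookups cannot fail mid-epoch. Captions that become
empty after filtering are excluded from training batches. Duplicate words
keep the first occurrence in embedding files and the last in rating
files, both logged — the common loader conventions for each format.

## Evaluation protocol

* Benchmarks are scored by per-pair cosine similarity and Spearman
  $\rho \times 100$; pairs with an out-of-vocabulary word are skipped and
  counted, never zero-filled, because imputing a similarity for a missing
  vector would contaminate the correlation.
* Min–max normalization uses each dataset's observed bounds; it cannot
  change any Spearman score (rank-preserving) and exists purely so
  datasets on different scales can be pooled.
* Pair concreteness is the arithmetic mean of the two words' ratings, and
  only pairs with both words rated survive the merge.
* Standardization divides by the **population** standard deviation
  (switchable), so standardized scores have unit SD exactly.
* The σ-bins partition the standardized scores at $-\sigma$, the mean and
  $+\sigma$ with the extreme bins closed: $x \le -1$ is highly abstract
  and $x \ge 1$ highly concrete. Where prose and figure conventions for
  the boundary inclusivity conflict, the closed extreme bins are used
  consistently here.
* The paired model test compares per-pair absolute errors of the cosine
  against the normalized human score — "model predictions" admit several
  readings, and absolute error is the most conservative per-pair quantity
  that is defined for every scorable pair; squared error is available via
  a flag.
* Concreteness prediction uses tenfold CV: words are shuffled under the
  seed into folds whose sizes differ by at most one; the Spearman
  correlation is computed per fold and the folds' correlations averaged
  (not pooled). The MLP's unstated details are fixed defaults: ReLU,
  dropout 0.2, 50 epochs, batch 64, NAdam $10^{-3}$, batch normalization
  after each hidden layer using batch statistics in training and running
  statistics (momentum 0.9) at prediction.

## The synthetic worlds

`make_world()` plants the complete generative story: Gaussian textual
embeddings ($V \times d$, iid $N(0,1)$), a full-rank alignment $M^*$ with
$N(0, 1/d)$ entries, and a projection $P$ to image space. Captions are
uniform random token sequences; an image vector is
$\mathrm{mean}_i(t_i M^*)\,P + \varepsilon$. Benchmark "human" scores are
cosines of planted grounded vectors plus noise; concreteness ratings are
a fixed linear functional of the textual vector plus noise, shifted to a
1–5-like scale.

Fixed generator choices: composition is the *mean* of grounded token
vectors — encoder-agnostic, and it makes the linear-plus-BoW model
well-specified so a closed-form oracle exists, while recurrent bridges
merely have to match it. $P$ is the identity whenever $c = D$, which
makes single-token noiseless captions carry exactly $t M^*$ (the setting
in which the word-level bridge must recover the least-squares solution);
otherwise $P$ is Gaussian. Where a desk-scale image dimension is needed
and nothing pins it down, $D = 32$ is used. These worlds emulate the
*shape* of the real inputs, not their statistics: no Zipfian token
frequencies, no caption syntax, no CNN feature correlations. Passing the
planted-recovery tests therefore demonstrates correctness of the
machinery — estimation, zero-shot application, evaluation — not that any
particular real corpus will show a grounding benefit of a particular
size.

Problem sizes used by the test suite and the acceptance script (chosen as
the smallest worlds at which the planted effects are comfortably
identifiable): recovery worlds of $V = 500$, $d = 16$, $c = 8$ with 2,000
single-token captions; benefit worlds of $V = 300$ with 2,000 captions of
3–8 tokens, benchmark of 500 pairs, noise 0.05, five seeds; concreteness
at $V = 500$ with tenfold CV. The grounding-benefit runs train the BoW
bridge for up to 150 epochs — on these small worlds the default
20-epoch budget stops well short of convergence, and the benefit is a
property of the converged alignment.

## Numerical choices and degenerate inputs

* NAdam uses bias-corrected first/second moments with the Nesterov
  correction $\beta_1 \hat m + (1-\beta_1) g / (1-\beta_1^t)$; no
  gradient clipping by default.
* Nearest-neighbour ties and vocabulary-frequency ties break
  lexicographically.
* Zero vectors make cosine similarity undefined and raise errors, as do
  constant inputs to Spearman or standardization, degenerate score
  ranges in min–max normalization, and fewer than two scorable pairs in
  any correlation.
* Embedding files are written with 9 significant digits; a write/read
  round trip reproduces a table to better than $10^{-6}$ per entry.
* Checkpoints are JSON (full-precision numbers) holding config, every
  parameter array, the PCA projection and the training vocabulary with an
  md5 fingerprint.

## Limitations

* Training is plain R matrix algebra: fine for desk-scale studies and the
  packaged synthetic worlds, not for 100k-caption corpora at
  2048-dimensional image vectors on a deadline.
* The word-level bridge with `activation != "linear"` regresses through
  the activation stack; the published word-level protocol is linear, and
  the nonlinear combination is unvalidated territory.
* Image feature extraction is out of scope; the package consumes image
  vectors as opaque numeric inputs.
* The transformer bridge implements the standard encoder faithfully but
  at small scale; conclusions about transformer bridges on real corpora
  require real corpora.
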