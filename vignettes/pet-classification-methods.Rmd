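---
title: "Identifying personal health experience tweets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying personal health experience tweets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petminer)
```

## The problem

Public-health surveillance from social media — pharmacovigilance in
particular — depends on telling apart tweets that report the author's *own*
health experience ("Thank you aspirin, no more headache") from the far more
numerous news items, advertisements and chatter that merely mention a
medicine. `petminer` implements a pipeline that learns its own features from
unlabeled text instead of relying on hand-engineered ones: word embeddings
trained on a large unlabeled corpus feed a class-weighted LSTM classifier,
and a bag-of-words logistic regression plus a cross-validated comparison
harness provide the reference points.

This vignette documents the models, the tunable parameters and their
defaults, the synthetic-data design, the numerical choices, and the
limitations — the things a user needs to interpret results and a maintainer
needs to change them safely.

## Preprocessing and phrase learning

`filter_corpus()` applies the conventional cleaning rules for tweet corpora:
retweets (metadata flag *or* a leading `"RT "`), tweets with URLs
(`http(s)://` or `t.co` patterns, or the metadata flag), tweets whose
language flag is present and not English, and exact duplicate texts (first
occurrence kept) are removed; record order is preserved. The removed
punctuation set is `. , ! ? ; : " ( )`, replaced by token boundaries;
apostrophes are kept so contractions survive as single tokens. Tokenisation
lowercases and splits on whitespace. Both choices — the exact punctuation
set and the case policy — are conventions rather than derived facts:
lowercasing shrinks the vocabulary, which matters most for embedding
quality on modest corpora, and keeping apostrophes avoids splitting
"don't". When the language flag is absent the tweet is kept: language
identification models are out of scope, and the generators emit all-English
corpora.

`learn_phrases()` scores every adjacent token pair with the discounted
point-wise association
$$\mathrm{score}(a,b) = \frac{(\mathrm{count}(ab) - \delta)\,N}
{\mathrm{count}(a)\,\mathrm{count}(b)},$$
where $N$ is the corpus token count. The discount $\delta$ (default 5)
suppresses rare accidental pairs; pairs scoring above the threshold
(default 10) are merged left-to-right, greedily and without overlap, into
underscore-joined tokens. One pass handles bigrams only — re-running the
procedure on merged output builds longer phrases if needed. The defaults are
the customary ones for this scoring rule; both are exposed.

## Vocabulary and embeddings

`build_vocabulary()` reserves index 0 for `pad` and 1 for `unk`; real terms
get indices from 2 upward, ordered by descending corpus frequency with
lexicographic tie-breaks, so a vocabulary is reproducible from its corpus.
Downstream, every tweet is a fixed-length sequence of these indices. Corpus
tokens literally spelled `pad`/`unk` would collide with the reserved entries
and are excluded (encoding as `unk`) with a warning.

`train_embeddings()` implements skip-gram with negative sampling: each
(center, context) pair within the window is a positive example contrasted
against `negatives` samples from the unigram distribution raised to 3/4.
Defaults: dimension 128, window 5, 5 negatives, initial learning rate 0.025
decaying linearly to 1/100 of itself. The trainer is single-threaded C++
driven by R's RNG, so a fixed seed reproduces the matrix exactly — a
deliberate trade of speed for auditability at the corpus sizes this package
targets. The `pad` row is frozen at zero (padding must contribute nothing
to the classifier); `unk` is trained like any token. `pet_pipeline()`
defaults to 50 passes over the corpus: a handful of epochs is the norm on
web-scale corpora, but on the 10^3–10^4-tweet corpora this wrapper is built
for, the vector space needs many more visits per term to stabilise.

## Encoding

`encode_corpus()` produces sequences of exactly `max_len` indices (default
48, the anticipated maximum tweet length in tokens): shorter tweets are
right-padded with 0, longer ones tail-truncated (truncation, not error, is
the default because overlong inputs should degrade gracefully at prediction
time; `on_long = "error"` is available). Phrase-merged tokens count as
single tokens toward the limit, since merging happens before encoding. The
pre-padding length is carried as `true_length`, so pads always form a
contiguous suffix and masking information is never lost.

## The class-weighted LSTM

The classifier is embedding layer → LSTM layer → single sigmoid unit. Per
step $t$ with embedded input $x_t$:
$$i_t = \sigma(x_t W_i + h_{t-1} U_i + b_i),\quad
  f_t = \sigma(x_t W_f + h_{t-1} U_f + b_f),$$
$$\tilde c_t = \tanh(x_t W_c + h_{t-1} U_c + b_c),\quad
  o_t = \sigma(x_t W_o + h_{t-1} U_o + b_o),$$
$$c_t = f_t \odot c_{t-1} + i_t \odot \tilde c_t,\qquad
  h_t = o_t \odot \tanh(c_t),$$
with $h_0 = c_0 = 0$ and output $p = \sigma(h_T \cdot w + b)$ read at the
final step $T = \texttt{max\_len}$. Reading at the padded final step mirrors
feeding full fixed-length sequences to the network; because the pad
embedding row is frozen at zero, pad steps only propagate the recurrence on
zero inputs. A masked readout at `true_length` is available
(`masked_readout = TRUE`) and makes the output provably invariant to the
amount of padding, but it is off by default to match the fixed-length
formulation.

Training minimises the class-weighted cross-entropy
$$L = -\left[w_+\, y \log p + w_-\, (1-y) \log(1-p)\right]
      + \lambda\left(\lVert W \rVert^2 + \lVert U \rVert^2\right)$$
averaged over the batch. The minority (PET) weight is the majority/minority
count ratio, $w_+ = n_-/n_+$, and conversely $w_- = n_+/n_-$; by default the
counts come from the training portion actually optimised (after the
validation split), since those are the instances whose imbalance the weights
must counter. L2 ($\lambda = 0.01$ by default) applies to the LSTM gate and
recurrent weights only — not biases, not the embedding — because the
regulariser belongs to the recurrent layer.

Optimisation is Adam (learning rate 0.001, batch 32 — the framework-era
defaults), for exactly 5 epochs by default; the last 30 % of a seeded
shuffle is held out and its loss and accuracy logged per epoch
(`tidy()`/`autoplot()` expose the history). The embedding layer is
initialised from the pretrained vectors and fine-tuned jointly; freezing it
(`finetune_embedding = FALSE`) is exposed because either reading of the
architecture is defensible, and fine-tuning from the pretrained space
honours both. Gate weights use uniform Glorot initialisation, the forget
bias starts at 1 (the standard aid to gradient flow early in training), and
everything — shuffle, initialisation, batch order — derives from one seed,
so runs are bit-reproducible single-threaded. Backpropagation through time
is implemented in R with BLAS-batched matrix products; the analytic
gradients are validated against central finite differences in the test
suite (relative error under $10^{-4}$), and probabilities are clipped to
$[10^{-7}, 1-10^{-7}]$ inside the loss to keep logs finite.

## Baselines and evaluation

The bag-of-words baseline counts word occurrences (not tf-idf, not binary —
though binary indicators are a flag) over a vocabulary rebuilt from each
training fold, and fits an L2 logistic regression with inverse
regularisation $C = 1000$ via the ridge path of `glmnet` (penalty weight
$1/(Cn)$); the problem is convex, so the fit is deterministic.
`external_feature_harness()` runs conventional classifiers — logistic
regression ($C=1$), a greedy entropy decision tree (depth ≤ 30, minimum
split 2, minimum leaf 1), 1-nearest-neighbour, and an RBF SVM
($\mathrm{cost}=1$, $\gamma=0.001$) — on caller-supplied feature tables;
engineered features themselves are deliberately not computed here. The
decision tree is implemented in the package: it takes the best midpoint
split even at zero information gain, so a fully grown tree memorises any
consistent training set, which is the behaviour the depth-30/leaf-1
configuration implies; off-the-shelf recursive partitioning in R refuses
zero-gain splits and cannot reproduce it.

Evaluation: stratified 10-fold cross-validation by default (stratification
prevents positive-free folds in imbalanced data; plain splitting is
available), with accuracy, PET-class precision/recall/F1, and ROC-AUC
computed by the rank (Mann–Whitney) formulation with half-credit ties —
chosen because it equals exhaustive pair counting exactly, which the test
suite verifies by brute force. Undefined precision or recall is reported as
0 with a warning rather than dropped, keeping fold vectors aligned for the
paired test. Method comparison uses one-tail paired t-tests on per-fold
scores, $t = \bar d / (s_d/\sqrt{k})$ with $k-1$ degrees of freedom; all
methods must share one fold assignment (enforced), which is what makes the
pairing valid. Zero-variance differences are degenerate for a t statistic
and are flagged, with p reported as 0 (mean favours the hypothesis), 1
(against), or 0.5 (identical scores). Raw p-values are reported; multiple
testing correction is out of scope.

## The synthetic corpus generator

Real annotated PET corpora are not freely redistributable, so the package
ships generators that emulate the two corpora the pipeline needs. The token
model: tweet length is Poisson (mean 12) truncated to $[1, 48]$; each token
position carries class signal with probability 0.3, drawing from the
tweet's own-class indicator set with odds `signal_odds` : 1 against the
opposite set; remaining positions draw from a shared Zipf-weighted
background vocabulary (500 types by default, seeded with a small
English-like lexicon so examples read naturally). Labels are PET with
probability 0.25 by default — the class imbalance regime the class weights
exist for — either i.i.d. or with exact counts for fixture tables, and
`noise_rate` flips labels for robustness studies.

The defaults were fixed by a design calculation, not by tuning against any
test: with signal odds 4:1 and signal rate 0.3, the Bayes-optimal
classifier's AUC is about 0.95, which leaves a learnable but non-trivial
gap for a five-epoch model. `signal_odds = 1` makes the classes identically
distributed (a null corpus on which any classifier's expected AUC is 0.5).

Two structural options make specific claims falsifiable. First,
`order_sensitive = TRUE` plants one first-person token and one symptom
token in every tweet — at equal rates in both classes — with their *order*
determined by the class: a bag-of-words representation is blind to this
component of the signal by construction, while a sequence model is not, so
"the LSTM exploits word order" becomes a measurable AUC gap. Second, the
unlabeled generator can plant an always-adjacent token pair and a lone
token that never shares a tweet with it; planted tweets are topical (the
pair's tweets draw background from one half of the vocabulary, the lone
token's from the other), because distributional similarity comes from
shared contexts — with a topic-free background, direct adjacency alone is
expressed in the input–output geometry of skip-gram rather than in the
input-space cosine that the inspection tools report.

What the generator does **not** emulate: real orthographic noise
(misspellings, elongations, emoji), topic drift, annotation disagreement,
or the scale of web corpora. Passing tests on synthetic corpora demonstrate
that the machinery is correct and that the architecture can exploit the
kinds of structure it claims to exploit — not that any particular accuracy
will transfer to live data.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the full pipeline at
2,000-tweet scale (with 128-dimensional embeddings and a 128-unit hidden
state, the default architecture), the embedding-geometry checks on
200-tweet corpora, and the gradient checks on toy instances — sizes chosen
so the whole suite documents the method's behaviour in minutes on a single
CPU while still exercising every component at its default configuration.
All randomness flows from explicit seeds; training and generation are
deterministic given a seed and single-threaded execution.

## Known limitations

- Single-layer, unidirectional LSTM only; no dropout, no early stopping
  (the epoch count is fixed by design), no GPU path.
- The skip-gram trainer is deliberately single-threaded for
  reproducibility; web-scale corpora are out of scope.
- Language identification is trusted from metadata, never inferred.
- The 0.5 decision threshold is a convention; with heavy class imbalance,
  threshold tuning on validation data would be the first practical
  improvement.
- Class weights computed on the optimised training portion can differ
  slightly from weights computed on a full dataset; both are one function
  call (`compute_class_weights()`) if an explicit choice is needed.
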