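---
title: "Contextual subspace geometry for graded metaphor judgements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual subspace geometry for graded metaphor judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaphorspace)
```

## The model

`metaphorspace` implements a dynamically contextual distributional
semantic model. The working hypothesis is that the metaphoricity of a
verb–object phrase is visible in the *geometry* of a low-dimensional
co-occurrence subspace selected jointly by the two words: literal
combinations project into tight, convergent configurations, while novel
metaphors pull the word vectors apart relative to the subspace's own
reference points.

### Base space

The corpus is lowercased, split into sentences at `.`, `!`, `?` followed
by whitespace (configurable), stripped of punctuation other than
apostrophes and hyphens (each removed character becomes a space, so
punctuation-glued tokens split), and tokenized on whitespace. The
vocabulary is the `size_limit` most frequent types; co-occurrence is
observation within a symmetric window of ±`window` tokens (default 2)
inside a sentence. Context columns cover *all* corpus types, not only the
vocabulary, and a word does co-occur with other occurrences of itself.

Counts are weighted by a smoothed non-negative PMI,

$$\mathrm{PMI}(w,c) = \log_2\!\left(\frac{f(w,c)\,W}{f(w)\,(f(c)+a)} + 1\right),$$

with $W$ the summed vocabulary token count. Two deliberate departures
from textbook PMI matter here. The smoothing constant $a$ (default
10 000) suppresses the explosive weights that standard PMI assigns to
very rare context words, which would otherwise dominate dimension
selection; 10 000 is of the order of the mean context-word frequency at
the corpus scale the default targets, and desk-scale helpers use the mean
context frequency of the corpus at hand for the same reason. The $+1$
inside the logarithm forces every weight to be non-negative, zero exactly
for unobserved pairs — giving the space a meaningful origin, extent,
centre and periphery, which the geometric features below rely on.

### Subspace selection

For a dyad $(w_1, w_2)$, `select_dimensions()` picks $k$ context types
(default 200) by one of three techniques:

* **mean** — highest arithmetic mean $(\mathrm{PMI}(w_1,c) + \mathrm{PMI}(w_2,c))/2$;
* **geom** — highest geometric mean $\sqrt{\mathrm{PMI}(w_1,c)\cdot\mathrm{PMI}(w_2,c)}$,
  which is non-zero only where *both* words co-occur with $c$ and favours
  dimensions valued highly by both (it combines (5, 5) to 5 but (9, 1) to
  only 3);
* **indy** — strict alternation over each word's own PMI-ranked context
  list, starting with the verb, skipping types already taken, so the
  subspace concatenates dimensions independently salient to either word.

All top-$k$ selections break score ties lexicographically on the context
type, so builds are reproducible. Projection is trivial by design: the
coordinate of any word on a selected dimension is its value in the full
base space.

Each subspace also carries three generic vectors: the mean-vector $M$
(per-dimension mean over vocabulary words with non-zero values there, 0
if none), the maximum-vector $X$ (per-dimension maximum) and the
central-vector $C$ (uniform, at the mean of $M$'s elements). Generic
vectors are computed over the entire vocabulary's projections. Normalized
counterparts (denoted by a prime, `p` in feature names) are the
intersections with the unit sphere.

### The 48 features

`extract_features()` returns exactly 48 named measures in a fixed
canonical order: 7 distances (the norms of $V, N, M, X, C$, the distance
$\overline{VN}$ and its normalized counterpart $\overline{V'N'}$), 6
means of distance pairs (word-to-$M$/$X$/$C$, full and normalized), 6
min/max ratios of the same pairs, 13 directed fractions, 10 angles (at
the origin and at generic-vector vertices, in radians) and 6 triangle
areas. Ratios take the lower of a pair over the higher so that neither
word is presumed as numerator; fractions keep their stated orientation,
so they and the two word norms are the only features that are not
symmetric in $(V, N)$ — a swap inverts the fractions and exchanges the
norms, and maps the $V$-anchored areas ($\triangle VXM$, $\triangle VCM$
and normalized counterparts) to $N$-anchored triangles outside the set.

Numerical choices: cosines are clamped to $[-1, 1]$ before `acos`;
coincident rays give an exact 0 angle; areas use the Gram-determinant
form $\tfrac12\sqrt{\|a\|^2\|b\|^2 - (a\cdot b)^2}$, valid in any
dimension, with the radicand floored at 0; a ratio of two zero distances
is 1 (coincident geometry) and of one zero distance is 0. Degenerate
inputs — a word with no mass on the selected dimensions, a zero-length
angle ray, a zero denominator — raise errors in strict mode and produce
`NaN` flags in permissive mode; `standardize_features()` later imputes
flagged cells to the column mean (0 after z-scoring) with a logged count.

### Regression protocol

Features are z-scored once on the full dataset before cross-validation —
the protocol deliberately mirrors a pre-processing-then-LOO design,
accepting the mild leakage that implies; constant columns become zeros
with a warning. Graded ratings are evaluated by leave-one-out OLS (with
intercept), summarized as the Pearson correlation between held-out
predictions and observed ratings; rank-deficient folds fall back to the
minimum-norm pseudoinverse solution with a warning. Class labels are
evaluated by leave-one-out one-vs-rest logistic regression: three binary
models per fold, predicted class the one with the highest predicted
probability (probabilities and linear scores order identically for a
shared design; we use probabilities), ties broken lexicographically. On
separation or non-convergence the fit falls back to a fixed small ridge
penalty ($\lambda = 10^{-2}$, intercept unpenalized) with a warning.

Single features are ranked by $|r|$ (zero-variance features get $r = 0$
with a warning; ties break lexicographically). The VIF walk seeds with
the top-ranked feature and descends the ranking, regressing each
candidate on the selected set and accepting only while
$1/(1-R^2) < \mathit{fac}$ (default 2, a stringent collinearity bound),
stopping at 5 features.

Significance machinery: `fisher_r_to_z_test()` implements the
independent-samples form $z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)
/ \sqrt{1/(n_1-3) + 1/(n_2-3)}$ — note that comparing correlations
computed on the *same* items technically calls for an overlapping-samples
correction, which this function does not apply; treat such p-values as
approximate. `permutation_test()` uses the add-one estimator
$p = (1 + \#\{\text{permuted} \ge \text{observed}\})/(n_\text{perm}+1)$
with a mandatory seed, supports label-shuffling nulls and paired
prediction swaps, and has an exhaustive mode (all $n!$ orders or $2^n$
swap patterns) for small $n$.

An LOO one-vs-rest subtlety worth knowing: with a completely
uninformative feature the held-out item's true class has one fewer
training positive than the alternatives, so its predicted probability is
strictly lowest and LOO accuracy lands *below* the 1/3 chance level, not
at it. The meaningful chance reference is the single-class predictor
(call every phrase literal), which scores exactly 76/228 on a balanced
228-item design.

### Cosine baseline

`load_embeddings()` reads the word2vec text format (training such models
is out of scope; the vectors are external input). `dyad_cosines()` plus
`baseline_evaluate()` run the identical protocol with the cosine as the
sole predictor — a strict $p = 1$ special case of the machinery above,
and tested as such. Dyads with out-of-vocabulary words are dropped with a
logged count (or raise an error in strict mode).

## Synthetic data: what it does and does not show

Because neither a corpus of Wikipedia's scale nor the human rating
dataset is distributable, the package ships generators.

* `micro_corpus()` is a frozen 12-sentence corpus whose counts and PMI
  values are verified against brute-force scans in the tests.
* `generate_corpus()` samples sentences from topic-specific word pools
  with a configurable number of bridge words shared between topic pairs.
  This reproduces the one property the subspace techniques are sensitive
  to — controllable overlap between two words' co-occurrence profiles
  (within-topic pairs share many non-zero dimensions; with zero bridges,
  cross-topic pairs share none) — while making no attempt to imitate
  natural-language lexical statistics (no Zipfian tail, no syntax, no
  polysemy).
* `generate_dyad_dataset()` builds ratings as a linear combination of
  named geometric features plus Gaussian noise, clipped to $[1, 7]$, with
  meaningfulness and familiarity driven by the same latent signal with
  negative slopes, and balanced classes assigned by latent tertiles. The
  intercepts and slopes are calibrated once to the published per-class
  rating means of the judgement study this emulates (metaphoricity
  2.74/3.98/5.00, meaningfulness 5.99/5.17/4.09, familiarity
  3.85/2.97/2.15); the default noise SD of 0.5 is about the published
  per-class standard error scaled back to item level.

The ratings are therefore functions of the model's own feature space — a
circularity by design. Passing tests demonstrate that the pipeline
*recovers* planted feature–rating relationships (machinery correctness);
they say nothing about whether real human judgements follow subspace
geometry, which is an empirical question requiring the original corpus
and ratings.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `window` | 2 | co-occurrence half-window (tokens, within sentence) |
| `size_limit` | 200 000 | vocabulary size (desk-scale runs use far less) |
| `smoothing_a` | 10 000 | PMI smoothing; ≈ mean context frequency at target scale |
| `k` | 200 | subspace dimensionality |
| `fac` | 2 | VIF acceptance threshold $1/(1-R^2)$ |
| `max_features` | 5 | cap on VIF-selected features |
| `n_perm` | 10 000 | sampled permutations for significance tests |

Desk-scale defaults used by the test suite and examples: corpora of
120–400 generated sentences, vocabularies under 200 types, $k$ of 8–20,
24–120 dyads. These sizes keep a full three-technique experiment under a
minute while leaving every code path (including the geom shortfall
fallback and degenerate-geometry flags) exercised.

## Design decisions in brief

* Sentence splitting and tokenization rules are package choices
  (documented above), since only "remove punctuation except apostrophes
  and hyphens, lowercase, detect sentence boundaries" is fixed by the
  method; both are configurable where reasonable.
* $W$ counts vocabulary tokens, not all corpus tokens.
* The geometric mean takes the square root of the PMI product; the
  (5, 5) → 5 and (9, 1) → 3 arithmetic fixes this form.
* `indy` starts with the verb and strictly alternates; exhausted lists
  hand the remaining slots to the other word.
* `geom` with fewer than $k$ positive-product candidates takes all of
  them and fills the remainder by arithmetic-mean ranking with a warning;
  any technique short of $k$ total candidates returns a shorter subspace
  with a warning.
* Reports (`run_experiment()`) contain no timestamps and exclude the
  output path from the manifest hash, so identical configurations yield
  byte-identical bundles.

## Known limitations

* No lemmatization, stop-word handling or subword modelling — raw
  surface forms only, by design.
* Performance targets desk-scale corpora; the implementation is sparse
  throughout but makes no attempt at full-Wikipedia-scale engineering.
* The Fisher test ignores sample overlap (above).
* Composition operators between the verb and noun vectors, nonlinear
  regressors, and distance-preserving 3-D visualisation of subspaces are
  out of scope.
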