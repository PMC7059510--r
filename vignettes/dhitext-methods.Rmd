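---
title: "Methods: text analytics for digital health interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: text analytics for digital health interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Guided digital health interventions (DHIs) leave a rich free-text trace:
diary entries and exercise answers written inside the program, and the
message thread between each user and their coach. Alongside these, the
platform records structured touchpoints, notably symptom reports — binary
events such as a binge eating episode, and severity scales such as an
EDE-Q global score. `dhitext` turns a user's journey (the time-ordered
sequence of text snippets and reports) into fixed-length numeric feature
vectors and supports two model families:

* **Snippet-level symptom inference** — pair each snippet with a
  temporally adjacent symptom report and learn to infer the symptom state
  from the text, evaluated either *within users* (random row split, users
  shared across train and test) or *across users* (entire users held
  out).
* **User-level outcome prediction** — aggregate snippet features to one
  row per user and select predictors of a follow-up severity score with
  L1-penalized (LASSO) regression.

## Feature engineering

Each snippet is represented by the concatenation, in fixed order, of six
families. Under the reference *message* configuration (document-frequency
bounds MINOCC = 0.05 / MAXOCC = 0.5 giving a 79-term vocabulary,
50-dimensional embeddings, 44 POS tags, 8 topics) the vector has
2 + 79 + 50 + 44 + 10 + 15 = 200 entries; the *intervention-text*
configuration (MINOCC = 0.005, 189 terms) has 310.

| family | size | content |
|---|---|---|
| metadata | 2 | raw word count (whitespace-delimited) and character count |
| word usage | vocabulary | counts of document-frequency filtered stems |
| embedding | `embedding_dim` | elementwise mean of token vectors (GloVe text dialect) |
| POS | 44 | Penn Treebank tag counts from a pluggable tagger |
| topic | `n_topics` + 2 | LDA proportions, their SD, document log-likelihood |
| sentiment | 15 | NRC (11), AFINN (1), Bing (3) lexicon scores |

Preprocessing tokenizes to lowercase alphabetic tokens, removes stop
words, applies a synonym map, and stems with an in-package implementation
of the Porter algorithm. Tokens matched by the synonym map keep their
mapped base form verbatim (they are not stemmed afterwards), so a
curated clinical mapping like `bingeing → binge` survives intact.
Raw word/character counts are always taken on the original text, before
any removal. Document frequency is computed on the preprocessed tokens —
the same token space in which counting happens — and both MINOCC and
MAXOCC are inclusive bounds.

**Normalization.** Word-usage, embedding, POS and sentiment blocks are
divided by the snippet's raw word count; metadata and topic blocks are
not. Dividing the embedding block — already an average — by length again
is unusual, but it is the reference behaviour of the framework this
package implements; `feature_config(normalize_embedding = FALSE)`
disables it. A zero word count sets the divided blocks to zero.

**Sentiment block conventions.** The NRC lexicon's 11 dimensions are the
8 emotion categories plus positive, negative, and the number of tokens
matched by any NRC category; AFINN contributes the sum of integer scores
(−5..+5); Bing contributes positive count, negative count and their
difference. These compositions are package conventions: the reference
configuration fixes only the dimension counts (11, 1, 3).

**POS tagging.** The inventory is fixed at 44 slots: the 36 word-level
Penn Treebank tags plus 8 punctuation/symbol tags (shipped in
`inst/extdata/ptb_tags.txt`). The tagging backend is pluggable — any
function from text to a tag vector. The shipped
`dictionary_tagger()` is a deterministic lookup, which is what the tests
and synthetic corpora use so that results are reproducible without a
statistical tagger; a wrapper around an external tagger can be dropped
in unchanged.

**Topic model.** LDA is fitted by collapsed Gibbs sampling (Rcpp), 200
sweeps by default, using R's RNG so a fixed seed reproduces the fit
exactly. Priors are symmetric Dirichlet with `alpha = 0.1` and
`beta = 0.1`: snippets are short, and a flat document prior (e.g. the
classic `50/K`) would shrink every document mixture toward uniform,
defeating the topic features. Per-snippet proportions are computed by a
deterministic fixed-point fold-in with the topic–word matrix held fixed,
so featurization involves no sampling; empty or fully out-of-vocabulary
snippets get uniform proportions, zero SD and zero log-likelihood, with
a warning. The topic-proportion SD uses the population formula
`sqrt(mean((p - 1/K)^2))`.

**Out-of-vocabulary embedding.** A snippet with no embedding-table hit
is represented by the zero vector; the featurizer counts such snippets
(`n_oov_snippets` attribute) so the OOV rate is visible.

**Dimensionality rule of thumb.** When `5 × features > snippets` the
featurizer logs a recommendation to apply generic dimensionality
reduction; it deliberately performs none.

## Communication metrics

The coach–user thread is reduced to its sender sequence; content is
ignored by design. The response rate is the fraction of coach messages
whose immediate successor is a user message (for `CCUCUCUCCCUU`: 7 coach
messages, 4 followed directly by a user message, rate 4/7); the mean
response time averages the time gaps over exactly those pairs, in
hours. Only the immediate successor counts — later user messages after
the same coach message are not timing pairs, mirroring the rate
definition. Users with no coach message have undefined metrics; at
aggregation time these are imputed with the across-user median
(configurable: zero, or dropping the user).

## Temporal alignment

In `nearest` mode each snippet takes the value of the same-user report
minimizing the absolute time gap, before or after authoring; equidistant
reports tie-break to the earlier one. The default relevance bound drops
snippets whose nearest report is more than 24 h away, reflecting a
binary binge-episode label defined on a 24-hour window; the bound is
configurable and `Inf` disables it. In `window` mode the label is the
mean report value inside a symmetric ±halfwidth window (boundary
inclusive), and a window wide enough converges to the user's mean label.
Alignment is invariant to shifting a whole journey in time.

## User-level aggregation

Every non-metadata snippet feature is averaged per user; each of the 15
sentiment features also contributes its sample SD (n−1 denominator; a
single-snippet user gets zero SDs with a warning). Metadata is replaced
by five aggregates — total word count, total character count, number of
messages, mean message length, messages per day — plus the two
communication metrics: 5 + 2 + 79 + 50 + 44 + 10 + 30 = 220 for the
message configuration. "Messages per day" divides by the span between
the user's first and last snippet, floored at one day. Time-trend slopes
(`trend_feature()`, OLS per day) are available but off by default, since
the reference aggregation uses only means and sentiment SDs. The
inclusion filter retains users with both baseline and follow-up scores
who sent strictly more than 2 messages (exactly 2 is excluded).

## Modeling

**Splits.** Within-user: a uniform random sample of
`round(fraction × n)` rows (0.70 × 37,228 → 26,060). Across-user: a
uniform random sample of users, all their rows on one side. Both are
deterministic under a seed.

**Classifiers.** Logistic regression is fitted on standardized features
with a small fixed ridge penalty (`1e-3`) for numerical stability on
wide, collinear feature blocks. The random forest uses 200 trees with at
most 20 candidate features per split (`mtry = 20`), unstandardized, on a
single thread for reproducibility. "A maximum of 20 selected features"
is read as the per-split candidate count — the standard random-forest
meaning — rather than a per-tree total cap.

**ROC/AUC.** The ROC sweeps distinct score values as thresholds, tied
scores forming one operating point; the trapezoidal area then equals the
Mann–Whitney concordance with ties counted one half. The test suite
checks this identity against an O(n²) pairwise oracle and against an
independent ROC implementation.

**LASSO.** `fit_lasso_cv()` delegates the coordinate-descent fit to
glmnet over a 100-point log-spaced lambda grid spanning four decades
below the smallest all-zero lambda, with K-fold cross-validation
(default 50 folds — the reference analysis reports 50-fold CV, a figure
caption mentions 100; the fold count is a parameter) and fold assignment
stratified by outcome quartile. Features are standardized internally;
the baseline score is an ordinary candidate column. At `lambda = 0` the
solution matches ordinary least squares to 1e-6 on well-conditioned
problems, and at large lambda only the intercept survives.

## The synthetic journey generator

No clinical dataset ships with the package, so validation uses
`generate_corpus()`: journeys whose lexical content is statistically
coupled to a latent symptom process with known strength.

* A per-user, day-resolution two-state Markov chain (activation 0.10,
  deactivation 0.15 per day — episodes lasting about a week) drives
  symptom state; binary reports are the state sampled at report times
  (one report per day on average).
* Each token is a designated *signal term* with probability 0.03,
  multiplied by `signal_effect` while the state is active;
  `signal_effect = 1` is the null model. Other tokens come from
  per-document topic blocks (half) or background vocabulary (half),
  giving LDA real structure.
* Synthetic words are five-letter consonant–vowel strings chosen to be
  invariant under the whole preprocessing pipeline (no stop-word or
  stemming interference), so generator-side bookkeeping (e.g. signal
  token counts) is an exact oracle for lexicon and count features.
* Threads draw a user reply after each coach message with probability
  0.7 and exponential 6 h delays, the reply always landing before the
  next coach message, so the empirical response rate converges to the
  configured probability.
* The user outcome is `0.6 × baseline + 5 × mean signal exposure +
  N(0, 0.5)`, with baseline ~ N(3, 1) on an EDE-Q-like scale.

Defaults describe a mid-sized pilot: 50 users × Poisson(40) snippets of
~30 words over 84 days, about 2,000 snippets. At these conditions the
planted coupling (`signal_effect = 5`) yields within-user AUCs well
above 0.7 while the null stays at chance; this is a power-based design
choice made once, not a tuned quantity. The validation studies run by
the test suite and the acceptance script use: 5 (tests) or 3 (script)
null corpora and one strong-coupling corpus at the default ~2,000
snippets; a 3 × 3 (effect × seed) monotonicity grid at reduced size
(20 users × 25 snippets); LASSO recovery at n = 100 users, p = 220
features, 5 planted coefficients of 1 against noise SD 0.5, 20 seeds;
and outcome-coefficient recovery at 500 users.

What the generator does *not* emulate: natural-language syntax and
semantics (texts are bags of synthetic words with no grammar), coach
message content, missingness patterns, or drift in vocabulary over a
journey. Passing the validation studies therefore demonstrates that the
pipeline's statistics behave as designed under known coupling — not that
any particular clinical corpus is predictable.

## Numerical and degenerate-input conventions

* Timestamps are ISO-8601 at second resolution, UTC assumed; ties in
  time keep stable input order.
* Empty texts are retained and flagged; they featurize to zero counts,
  uniform topics, and zero normalized blocks.
* Zero-variance feature columns get unit scale during standardization
  rather than dividing by zero.
* Equidistant report ties go to the earlier report; the within-user
  train size rounds to the nearest integer.

## Limitations

The Porter stemmer and Gibbs LDA are in-package implementations; they
are tested against hand-traced cases and planted-structure recovery
respectively, but are intentionally plain (single chain, point estimate
from the final sweep). The logistic model's small fixed ridge penalty is
a stability device, not a tuned hyperparameter. The dictionary POS
tagger is deterministic but knows only what its dictionary contains;
real corpora need an external statistical tagger behind the same
interface. Readability, lexical diversity, spell-check, named-entity and
n-gram-mining features beyond bigrams are out of scope, as are
hierarchical models and any causal interpretation of the fitted
associations.
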