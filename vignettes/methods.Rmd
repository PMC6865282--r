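---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`opichatter` turns raw short-text posts into regional abuse-rate estimates
in five stages: lexicon retrieval and noise filtering, four-class
supervised classification, ensemble voting, imbalance-aware evaluation,
and geotemporal aggregation with correlation against reference health
metrics. This vignette records the model, every tunable that matters, and
the reasoning behind each choice that the problem left genuinely open.

## The classification model

Posts belong to one of four classes: self-reported abuse or misuse (`A`),
information sharing (`I`), unrelated (`U`), non-English (`E`). The class
mix is heavily imbalanced — the canonical prevalences used throughout the
defaults are 19.4%, 22.2%, 53.6% and 4.7% — so accuracy must be read
against the prevalence-random baseline
$\sum_c p_c^2 \approx 0.377$ rather than $1/4$, and per-class recall on
`A` is the quantity a surveillance user actually cares about.

Traditional classifiers see a sparse vector per post: word 1–3-gram
counts, bag-of-cluster-id counts, and two engineered scalars (abuse-term
presence and count). The CNN sees token-id sequences feeding a trainable
embedding layer. Evaluation is micro-averaged F1: pool tp/fp/fn over
classes, then take the harmonic mean of pooled precision and recall. For
single-label multiclass prediction this equals accuracy (trace over
total) — an identity the test suite asserts on random confusion matrices
rather than trusting.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| n-gram range | (1, 3) | conventional for short informal text; the source analyses say "word n-grams" without a range. Counts, not tf-idf: post lengths are nearly constant, so document-frequency weighting adds little and complicates the frozen-vocabulary contract. |
| vocabulary | min count 2, cap 50,000 | drops hapax n-grams that only memorize the training set |
| clusters | 50, top 500 tokens | coarse distributional feature; see below |
| split | 70/10/20, unstratified | floor on train and validation, remainder to test — reproduces a 9,006-post corpus splitting exactly as 6,304/900/1,802. Unstratified is the default so the test set keeps natural prevalence variation. |
| SMOTE `k` | 5 | classic neighbourhood size; every grown class must have more than `k` members (checked, with the offending class named) |
| SVM | hinge OvR, λ = 1e-4, 20 epochs | Pegasos-style decaying step; deterministic given the spec seed |
| random forest | 50 trees, mtry = √p, depth ≤ 25 | CART/Gini split search in C++; trees vote, ties to the earlier label |
| CNN | d = 50, widths {3,4,5} × 32 filters, max_len 32, Adam 1e-3, ≤ 8 epochs, patience 2 | the minimal three-layer reading of a text CNN: embedding → one parallel convolution block with max-pooling → softmax. Early stopping on validation micro-F1; the pad embedding row is pinned to zero. |
| bootstrap | 1,000 resamples, percentile 2.5/97.5 | plain percentile interval, not BCa — the simplest faithful reading of "bootstrap CI"; fewer than 100 resamples warns |
| correlation p-values | two-tailed t approximation, df = n − 2 | applied to both Pearson and Spearman (Spearman on average ranks); validated against `stats::cor.test` and by a type-I-error simulation at n = 75 |

Hyperparameter search, when wanted, is `tune_spec()`: grid search by
10-fold cross-validated micro-F1 on pooled training + validation data for
the traditional families; the CNN instead uses the validation set for
early stopping, since cross-validating a neural model at every grid point
is not worth its cost at this scale.

## Decisions on genuinely open points

**Tokenizer.** Lowercase runs of ASCII letters and digits. No
hashtag/emoji handling: nothing downstream needs it, and the matching
contract ("tar" must not match "guitar") only requires whole tokens.
Multi-word lexicon phrases match as contiguous token sequences.

**Spelling variants.** The variant generator is a stand-in for a learned
misspelling model: single deletions, adjacent transpositions, and
double-letter collapses/expansions — each within Damerau–Levenshtein
distance 1 — keeping the first character fixed, ranked by a consonant-
skeleton heuristic and truncated to a budget. It will not produce pure
substitutions ("percocet" → "percoset"); such variants can be listed
explicitly in the lexicon TSV. Noise keywords are expanded the same way,
and their variants are excluded too.

**Word clusters.** The fallback trainer derives hard clusters by greedy
agglomerative merging (complete-linkage) of positive-PMI co-occurrence
signatures for the most frequent tokens. This is a deliberate
simplification of Brown clustering: same output type (a hard token →
cluster map) and the same greedy-merging spirit, without the class-bigram
likelihood objective. Cluster features are encoded as a bag of cluster
ids, the natural analogue of the n-gram count block.

**Random baseline.** A "random classifier" can mean uniform (expected
accuracy 0.25) or prevalence-proportional assignment (expected accuracy
$\sum p_c^2 \approx 0.377$). Reported baselines near 0.375 in this
literature match the prevalence-proportional reading, which is therefore
the default; `expected_random_micro_f1(..., mode = "uniform")` gives the
other.

**Biased-ensemble tie-break.** When both priority labels `A` and `I`
reach the vote threshold, the one with more votes wins; an exact tie goes
to the best individual classifier's vote if that vote is itself a
priority label, else to `A` — abuse being the surveillance-critical
class. The rule is isolated in `biased_vote()` and verified by exhaustive
enumeration of all $4^4$ panels against an independently written oracle.
One subtlety the enumeration surfaced: on an all-distinct panel
(e.g. `A, I, U, E`) the majority fall-through can return a priority label
holding a single vote via the tie-break, so "a priority label always has
≥ 2 votes" is not an invariant of the stated rule; the tests assert the
corrected form.

**Abuse-rate denominator.** Region abuse rates default to
abuse-indicating posts *per opioid-related post* rather than per capita:
a share of retrieved chatter is robust to regional differences in
user-base size, which is the point of supervised filtering. Per-capita
(per 100,000 population) remains available.

**Seed fan-out.** One global seed drives every stage through a documented
hash (`seed * 69069 + char-sum(stage) * 7919 mod 2^31 − 1`), so any stage
can be rerun in isolation and the whole pipeline is byte-reproducible.

## The synthetic world

`gen_corpus()` emulates exactly what the pipeline consumes: bags of 5–25
tokens per post (no grammar — every downstream feature is token-based),
class-specific token pools mixed with a shared Zipf background at a
`separability` weight, drug-name tokens in `A`/`I` posts misspelled at
`misspell_rate` using the same edit operations as the lexicon expander,
class `E` written in a disjoint pseudo-alphabet rather than a real second
language, regions assigned proportionally to population^(1 + skew), and a
reference metric constructed as
$a\,z(\text{true rates}) + \varepsilon$ with $a$ chosen so the population
correlation equals `target_rho` for any noise scale.

What green tests establish: the mechanics are correct — prevalences,
determinism, retrievability of misspelled drug mentions, parameter
recovery of generated correlations. What they do not establish: real
performance on actual drug chatter. The synthetic classes are far more
separable than human-annotated posts (near-perfect F1 at separability
0.9 versus roughly 0.7 reported on real corpora in this literature),
there is no annotator disagreement, no evolving slang, no geography of
language. Treat synthetic scores as plumbing checks, not benchmarks.

## The no-signal limit (a deliberately red check)

One acceptance check asserts that classifiers trained on a
zero-separability corpus score at the prevalence-random baseline
$\sum p_c^2$. This assumption is empirically false, and the check is left
failing on purpose rather than weakened. When features carry no class
information, a trained classifier does not mimic the prevalence mix — it
reverts to its prior. Naive Bayes and the random forest predict the
majority class almost always and score near $p_U = 0.536$, about ten
standard errors above 0.376; the one-vs-rest hinge SVM collapses to
near-tied negative scores and can land *below* the baseline; only a
memorizing 1-NN is prevalence-proportional. The property that is actually
true — predictions carry no information about the truth, Cohen's
κ ≈ 0 for every family — is asserted green in `test-synthetic.R`.

## Numerical conventions and degenerate inputs

Precision for a never-predicted class is reported as 0 with an
`undefined_precision` flag, so tabulated reports never divide by zero.
Cohen's κ for two identical constant raters is defined as 1. Correlations
on a zero-variance vector return a flagged degenerate result rather than
NaN. Months with no posts appear in monthly series with frequency 0 and a
flagged undefined proportion. Empty-class SMOTE targets are skipped;
undersampling never removes non-majority rows; resampling never alters an
original feature row. The CNN breaks score ties toward the earlier label,
as do forest votes — deterministic by construction.

## Limitations

Classifier implementations favour clarity and determinism over peak
accuracy (no GPU, no pretrained embeddings; embeddings are learned from
the training corpus). The variant generator cannot invent substitution
misspellings. Geolocation inference, annotation tooling and language
identification are out of scope: region ids and gold labels are inputs.
Correlations against reference metrics are descriptive associations, not
causal claims, and at 13–75 regions their p-values deserve the usual
small-n caution.
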