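---
title: "Methods: disclosure classification and egocentric network indexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disclosure classification and egocentric network indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acenet)
```

## The problem

Adverse childhood experiences (ACEs) — abuse, neglect, and household
challenges such as incarceration or substance use in the home — are common
and associated with lifelong health consequences. One mitigation channel is
social connectedness, which makes the *structure* of the social networks
around people who disclose ACEs a public-health question. acenet packages
the analysis chain needed to study this on web platforms: detect disclosure
in short texts, aggregate text-level signals into a per-user index, and
compare bespoke structural indexes of sampled egocentric follow networks
across user groups. Since live platform collection is out of scope (and the
original collection channels are defunct), a synthetic-data generator with
planted structure stands in for every input, making the whole chain testable
offline.

## The pipeline

### Text cleaning and eligibility

`clean_text()` lowercases, expands abbreviations, removes characters outside
`[a-z0-9 ]`, collapses whitespace and splits on it. A "word" is a
whitespace-delimited token of the cleaned string. The cleaning order is
fixed and documented because upstream descriptions of such pipelines rarely
pin it down; the shipped abbreviation map is a small default (common
contractions plus "od" for overdose) and fully replaceable. Stop-word
removal is deliberately **off**: length statistics of short titles and posts
suggest near-raw text, and eligibility thresholds below are calibrated to
that. Texts with five or fewer words after cleaning are dropped everywhere
(`filter_short()`); only longer texts are *eligible* for scoring.

Keyword queries (`keyword_match()`) implement OR-groups combined by AND /
AND NOT, evaluated on raw lowercased text with word-boundary matching, so
"prison" does not fire inside "imprisonment". Boundary-free substring
matching is available but off by default; boundary matching avoids false
positives that manual screening would otherwise have to remove.

### The mention scorer

The classifier is the canonical text-convolution design: a trainable word
embedding (16 dimensions by default), parallel convolution filters of widths
3/4/5 (16 filters each), global max-pooling, and a dense softmax layer whose
positive-class output in [0, 1] is the **ACE mention score**. Inputs are
padded with a reserved index 0 (or truncated) to 45 tokens; unknown words
map to a dedicated out-of-vocabulary index distinct from padding. Training
is minibatch Adam (step size 1e-3, batch 64) on cross-entropy with early
stopping on validation loss (patience 3); the best-validation weights are
kept. No deep-learning framework is required: forward and backward passes
are written directly in vectorized R, which keeps the whole package
dependency-free and makes seeded runs bit-reproducible in single-threaded
linear algebra. The exact architecture is a documented default, not a claim:
every acceptance property holds for any competent classifier on the
separable synthetic corpus.

Before training, the majority class is downsampled uniformly at random to
the minority count (`balance_classes()`), and the corpus is split 72/8/20
into train/validation/test, stratified per class (`split_corpus()`). A text
is *classified* as ACE-associated only when its score strictly exceeds 0.5;
a score of exactly 0.5 is negative. Evaluation reports accuracy, precision,
recall, F1 and AUC; the AUC is computed as the rank statistic with half
credit for ties, which equals the area under the threshold-sweep ROC curve.
Measures with zero denominators are reported as `NA`, never silently 0.

### From texts to users

For a user with at least 30 eligible texts, the **ACE alignment index**
(alpha) is the "top 10% value" of their mention scores. We implement this as
the `ceiling(0.1 n)`-th largest score. The two nearest-rank readings of a
90th percentile differ by one order statistic when `0.1 n` is an integer;
we chose the larger one because it preserves the motivating guarantee: a
user at least 10% of whose texts score at or above 0.5 always receives an
index of at least 0.5. The `ceiling(0.9 n)`-th-smallest alternative is one
argument away (`convention = "smallest_rank"`). Categories: **ACE** when
alpha is at least 0.5 (inclusive); **non-ACE** when every eligible score is
below 0.3; **insufficient data** below 30 eligible texts — we apply the
same evidence floor to the non-ACE label, a choice the upstream definitions
leave open, to avoid labeling near-empty accounts; **indeterminate**
otherwise.

### Sentiment

Sentiment scores arrive from a pluggable scorer in [-1, 1]; the package
classifies `s <= -0.05` as negative, `s >= 0.05` as positive, the open
interval as neutral, and summarizes per-user percentages over eligible
texts (the same eligibility filter as scoring — the upstream description
ties sentiment to the ">5 words after cleaning" set). A deterministic
lexicon stub (`lexicon_sentiment_scorer()`) is shipped for tests; the
production rule-based scorer is intentionally out of scope.

### Egocentric network indexes

An `ego_network()` holds a root, up to 100 sampled followers and followees,
and the observed directed edges among them (edges point follower to
followee). Absent edges are treated as absent relationships; partial
observation is the caller's concern. The indexes:

* **Reciprocity** `r1` = (followers the root follows back) / m1 and
  `r2` = (followees who follow back) / m2. Undefined below 5 sampled
  neighbors on the relevant side, where the ratio is unreliable.
* **Clustering** over unordered pairs of same-side reciprocal neighbors:
  the strict variants C1/C2 require both directed edges between the pair,
  the weak variants C1'/C2' at least one, so strict ≤ weak ≤ 1 always.
  Undefined below 5 sampled neighbors on the source side, and also with
  fewer than 2 reciprocal neighbors — a case the upstream guard does not
  reach but which would otherwise be 0/0.
* **Homophily**: the mean alignment index over the side's neighbors that
  have one (at least 30 eligible texts); undefined when none does. The
  root's own index is never included. `reciprocal_split_avg()` contrasts
  reciprocated and non-reciprocated followers.
* **Degree survival**: `survival_probability()` returns the step function
  `k -> fraction of roots with degree >= k`.

Undefined values propagate as `NA` into group comparison and are excluded
pairwise there, mirroring the "avoided calculating" convention.

### Group comparison

`rank_sum_test()` is the two-sided Mann-Whitney-Wilcoxon test: exact (via
the U distribution) for combined samples of at most 25 without ties,
otherwise the normal approximation with tie and continuity corrections.
`compare_groups()` runs the three pairwise tests between the ACE,
non-ACE-1 and non-ACE-2 groups and multiplies each p-value by 3, capped at
1 (Bonferroni with family size fixed at the three pairs, per metric — not
across metrics).

## The synthetic world

The generator plants exactly the structure the indexes measure, with
defaults fixed once:

* **Corpus** (`generate_corpus()`): two classes, lengths uniform on 6–45
  words, tokens drawn from class-specific vocabularies with cross-class
  mixing `epsilon = 0.1` — separable but not trivial; 1000 documents per
  class.
* **Score streams** (`generate_user_streams()`): 40 eligible scores per
  user; ACE users get a deterministic 15% block of scores in [0.55, 0.95]
  (at least 10%, so the alignment index must reach 0.5), non-ACE users
  only scores below 0.3, with the non-ACE-1 group's distribution centred
  above non-ACE-2's, mirroring the observed ordering between users sampled
  by parent-related vs unrelated keywords.
* **Ego networks** (`generate_ego_network()`): heavy-tailed total degrees
  (discrete log-normal, meanlog 5.3, sdlog 1.4, truncated at 7089 — the
  observed ceiling; the parameters give a mean near the observed several
  hundred), follow-backs i.i.d. with `p_back = 0.4`, triangle closure of
  reciprocal-neighbor pairs with `p_tri = 0.1` (reciprocal with
  probability 1/2, so expected strict clustering is `p_tri/2` and weak
  `p_tri`), neighbor groups copied from the root with homophily `h = 0.6`
  (or drawn group-blind when `h = NULL`), and neighbor alignment indexes
  drawn per group from truncated normals with the observed group means/SDs
  (0.81/0.12, 0.44/0.09, 0.36/0.13); half the neighbors have a computable
  index. The sampled followee set is kept disjoint from the follower set,
  so each side's sample size is `min(degree, 100)`; reciprocated followers
  are still followees of the root via their edges.

What a green test establishes: that the implementations compute the stated
statistics correctly (oracle equivalence), that planted parameters are
recovered at the stated precision, and that the pipeline's thresholds sit
exactly where specified. What it does not establish: anything about real
platform data — real text is not token soup, real degrees and follow-backs
are correlated, and real alignment indexes are classifier outputs, not
draws from a group distribution.

## Numerical choices and edge cases

* Ties at the classification threshold go negative (strict `> 0.5`); the
  alignment threshold is inclusive (`>= 0.5`); sentiment boundaries are
  inclusive outward.
* The AUC rank formula gives ties half credit and matches a brute-force
  pairwise-concordance oracle exactly.
* The exact rank-sum path doubles the smaller tail and caps at 1; the
  asymptotic path subtracts 0.5 for continuity and applies the standard
  tie correction to the variance.
* `split_corpus()` errors when any partition would be empty for some class
  under the requested fractions (at the default 72/8/20 this needs about
  7 documents per class).
* Training determinism holds for fixed seed under single-threaded BLAS;
  multi-threaded linear algebra may not be bit-reproducible.
* An empty text cleans to a zero-word document, not an error; documents of
  only out-of-vocabulary tokens are scored like any other identical index
  sequence.

## Known limitations

The scorer is small by design and not tuned for natural language; pretrained
embeddings can be passed in but are not bundled. The generator does not
emulate tweet semantics, posting dynamics, or realistic degree-reciprocity
correlations. Published platform-scale results (classifier metrics near
83% accuracy, group medians, p-values) depend on data that can no longer be
collected and are deliberately not acceptance targets; the exactly
reproducible worked examples and the property suites above are.
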