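---
title: "Detecting drug discontinuation events with zero-shot entailment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting drug discontinuation events with zero-shot entailment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddetect)
```

## The problem

People describe stopping their medications on health forums long before any
signal reaches a prescriber. A *drug discontinuation event* (DDE) is a
statement from which a specific person's discontinuation of a recurring
medication or treatment can be inferred — medication changes count, one-time
treatments do not. `ddetect` frames DDE detection as zero-shot
natural-language inference (NLI): a forum comment (or a piece of it) is the
*premise*, a fixed sentence such as "Person stopped taking medication." is
the *hypothesis*, and an entailment model returns the probability that the
premise entails the hypothesis. No task-specific training is involved; the
hypothesis is the classifier.

A second, multilabel task assigns each DDE one or more *root causes* from a
closed eight-category taxonomy: treatment success, treatment inefficacy,
adverse reactions, accessibility issues, personal choices, alternative
medical reasons, indeterminate, and non-discontinuation. The last two are
ordinary scored classes, not fallbacks: an empty predicted set is reported
as empty, never coerced to indeterminate.

## Classification strategies

All three strategies reduce a comment to a single decision by
max-aggregation over scored text units:

* **CS1 (individual sentences).** Every sentence is scored separately; the
  comment's *model prediction* is the maximum sentence score, and the
  comment is labeled DDE when that maximum strictly exceeds a user-chosen
  cutoff. Because `max(s) > c` iff some `s_i > c`, CS1 is exactly the OR of
  per-sentence classifiers — a property the test suite checks against a
  brute-force per-sentence implementation.
* **CS2 (groups of sentences).** Consecutive sentences are concatenated
  into the longest chunks that fit the scorer's token budget; chunks are
  scored as single premises and the maximum is thresholded as in CS1. This
  preserves context that spans sentence boundaries.
* **CS3 (entire comment, chat model).** The whole comment goes to a chat
  model at once with a prompt demanding a bare `1`/`0` answer (detection)
  or a summary followed by a `Categories:` line naming taxonomy entries
  verbatim (root causes). Chat backends produce hard decisions, not graded
  probabilities, so threshold sweeps and AUCs are defined only for
  score-producing backends.

For root causes under CS1/CS2 the same construction runs once per category:
the comment-level score for category *c* is the max over units of the
entailment of that category's hypothesis, and *c* is assigned when its score
exceeds its cutoff. Max-aggregation makes the CS1 category set exactly the
union of per-sentence category hits.

The tie rule is strict everywhere: a prediction exactly equal to the cutoff
classifies negative. Empty comments have no units; their prediction is
defined as 0, so any positive cutoff yields non-DDE — the safe default for
empty text.

## Segmentation and chunking

Informal forum text defeats elaborate sentence-boundary detection, so the
splitter is deliberately simple and deterministic: a boundary occurs after a
run of `.`, `!`, `?` followed by whitespace or end of text, except that a
period followed (after whitespace) by a lowercase letter does not split,
which keeps fragments like "e.g. this" together. Text with no terminal
punctuation is one span. Spans carry character offsets, and the material
between consecutive spans is whitespace only, so the input is recoverable
byte-for-byte — an invariant the tests exercise on adversarial inputs
(missing spaces, stray punctuation, leading/trailing whitespace).

Token counting defaults to a transparent scheme — each maximal alphanumeric
run and each punctuation mark is one token ("can't" is three) — and a
backend can substitute its own tokenizer's length function through the same
`tokenizer_spec()` contract. Chunking is greedy left-to-right: extend the
current chunk while the running total stays within the budget, else start a
new one. Greedy packing is optimal for this objective (fewest chunks with
contiguity preserved) and is verified against a brute-force oracle on
10,000 random length profiles. A single sentence that alone exceeds the
budget is hard-windowed at token boundaries into windows of at most the
budget, each flagged `overflow`; this guarantees every text is scoreable.
Sentences within a chunk are joined with a single space.

## Scorers

The scoring contract is one function: premise + hypothesis + scorer →
probability in [0, 1]. Three backends implement it:

* **mock** — fully offline and deterministic. A cue table maps lowercase
  phrases (scoped to a hypothesis label) to scores; a premise containing a
  cue scores the cue's value (default 0.99), otherwise the baseline
  (default 0.01). An optional flip probability ε inverts the cue decision;
  the flip is decided by an FNV-1a hash of (premise, hypothesis, seed), so
  the scorer remains a pure function reproducible across processes, and the
  empirical flip rate over distinct premises concentrates at ε.
* **nli** — a plug point wrapping any user-supplied entailment function
  (e.g. a served zero-shot NLI model). Out-of-range returns are reported as
  transport failures, distinct from configuration errors.
* **chat** — a plug point wrapping a completion function. Unparseable
  responses are retried (default twice) and then recorded as *missing*;
  missing predictions are excluded from metrics with an explicit count,
  never imputed or silently defaulted.

Hypotheses are configuration, never hard-coded: zero-shot results are
sensitive to the hypothesis wording, so `default_hypothesis()` and the
per-category defaults in `category_hypotheses()` are starting points meant
to be overridden.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` (detection) | 0.9 | decision threshold on the max score; sweep with `cutoff_grid()` (0.05–0.95 by 0.05, built from integer numerators to avoid float drift) |
| `cutoff` (root cause) | 0.5 | one global per-category threshold unless overridden per category |
| `max_tokens` | 256 | token budget of the target scorer, drives CS2 chunking |
| `noise` (mock) | 0 | per-unit flip probability ε |
| `retries` (chat) | 2 | re-asks before a missing prediction is recorded |

## Evaluation

Binary metrics come from explicit confusion matrices; zero-denominator
rates are reported as 0 with a `degenerate` flag rather than `NaN` so
reports stay machine-readable. ROC curves step through all distinct scores
with ties grouped; the trapezoidal AUC then equals the pairwise concordance
probability P(score⁺ > score⁻) + ½P(tie), and the suite requires agreement
with a brute-force pairwise oracle to 1e-12. PR curves place a point at
each distinct threshold, end at recall 1, and are extended horizontally to
recall 0 before trapezoidal integration over recall; with labels
independent of scores the PR AUC concentrates at the prevalence, which the
suite checks by simulation.

The multilabel report pools cells across categories (micro), averages
per-category values unweighted (macro), and weights by gold support
(weighted). Hamming loss is the fraction of item-by-category cells
predicted incorrectly; the sample Jaccard defines empty/empty as a perfect
match; subset accuracy demands exact set equality and therefore never
exceeds the sample Jaccard. Per-category AUCs are undefined when a
category's gold column is single-class; such categories are excluded from
the macro/weighted AUC means and their number is reported. Score-free
predictions (CS3) leave all AUC fields flagged undefined. Reported
percentages round half away from zero (1 decimal for rates, 2 for
confidence percentages), matching how such rates are conventionally
printed; base R's banker's rounding would disagree at exact halves.

## The synthetic corpus generator

Real labeled forum corpora cannot ship with a package, so the generator
builds corpora that reproduce the *statistical* structure the pipeline must
survive, paired with a mock scorer that knows the planted cues:

* **Prevalence.** Exactly `round(n × prevalence)` DDE comments
  (default 10.7%) — deterministic planting rather than Bernoulli sampling,
  so small test corpora have exact class counts.
* **Root causes.** Each DDE comment includes each category independently
  with probability equal to the category's observed frequency (personal
  choices 0.670, adverse reactions 0.627, alternative medical reasons
  0.418, treatment inefficacy 0.250, accessibility issues 0.119,
  indeterminate 0.103, non-discontinuation 0.100, treatment success 0.096),
  with at least one forced by a weighted draw. Only the marginals are
  emulated; no co-occurrence structure is imposed, because none is known —
  the independence approximation is a declared choice, not an inference.
* **Text.** One cue sentence per sampled category plus background
  sentences, 2–6 sentences per comment; every template draws a drug name
  and a number so sentences are near-unique, which keeps the seeded mock's
  flip decisions effectively independent across sentences. A DDE comment
  whose only sampled category is non-discontinuation gets an extra generic
  discontinuation sentence so the binary gold invariant (every DDE comment
  carries a cue) holds; the generic sentence carries no category cue, so
  root-cause recovery stays exact.
* **Hard negatives.** A configurable fraction (default 10%) of non-DDE
  comments contain negated-medication phrasing ("I am not on any
  medication …") — the documented failure mode of real detectors. The
  matched cue table does not fire on them; a deliberately naive cue table
  (e.g. the bare substring "medication") does, and a test demonstrates the
  resulting false positive rate.
* **Annotators.** Three simulated labelers disagree on 8.9% of comments
  (one random flip, so the majority vote always recovers the planted
  label) and report confidence levels at rates 96.33 / 3.4 / 0.27%.

With the matched scorer at ε = 0, CS1 at any cutoff strictly between
baseline and cue score recovers the planted gold exactly — detection F1 1.0
and exact root-cause sets. At ε > 0 the comment-level false negative rate
has the closed form mean over DDE comments of ε^k (1−ε)^(m−k), where k of
the m sentences carry cues (all k cue decisions must flip off and none of
the others on); `expected_cs1_fnr()` computes it and the suite requires the
empirical rate to sit within 3 binomial standard errors on a
2000-comment corpus.

What passing these tests shows — and what it does not: they validate the
plumbing, the aggregation semantics, the metric implementations, and the
noise calibration of the pipeline. They say nothing about how well any
real entailment model reads real forum language; template text has none of
the typos, ambiguity, or register of actual posts, and realism is
explicitly a non-goal of the generator.

## Problem sizes and numerical choices

The default test suite runs corpora of 40–2000 comments, oracle-equivalence
batches of up to 200 items, 10,000-trial flip-rate and chunking checks, and
a 20,000-item PR-prevalence simulation — sizes at which every stochastic
tolerance (3σ bands) is comfortably resolvable in well under a minute per
suite file. Cutoff grids are generated from integers (5..95)/100 so
equality comparisons at grid points are exact. The FNV-1a hash is
implemented in 16-bit halves so all intermediate products stay inside the
exactly-representable integer range of doubles.

## Known limitations

* The sentence splitter is intentionally crude; it will merge sentences
  after a period that precedes a lowercase letter and split inside unusual
  abbreviation patterns. Reproducing any specific third-party sentencizer
  is not a contract.
* Keyword prefiltering is whole-word and case-insensitive; corpora
  filtered under different matching rules will differ in size.
* Chat backends are binary-only by design; converting chat output into
  graded entailment probabilities is out of scope, so AUC-based comparisons
  across backends are restricted to score-producing ones.
* Root-cause cutoffs for CS1/CS2 default to a single global 0.5; no claim
  is made that this is optimal for any particular model.
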