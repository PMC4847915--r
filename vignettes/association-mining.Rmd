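---
title: "Mining adverse-drug-reaction associations from spontaneous reports"
author: "adrmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining adverse-drug-reaction associations from spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrmine)
```

## The problem

Spontaneous-reporting databases such as Japan's JADER collect post-marketing
adverse drug reaction (ADR) reports as relational CSV tables: DEMO (one row
per case: gender, age category, weight), DRUG (drug name and causality role
per case) and REAC (one row per reported reaction). Classical signal
detection screens one drug–one event pairs; this package instead asks which
*combinations* co-occur — which ADRs predict other ADRs within a drug class,
and which ADR/age profiles predict the patient's gender. The case (patient
report) is the unit of analysis: each case becomes a market-basket
transaction whose items are its deduplicated ADR preferred terms, optionally
plus one age-decade item and one gender item.

## The model

Association rules X → Y over t transactions are scored from the 2×2
presence/absence table (a: X and Y; b: X only; c: Y only; d: neither):

* support = a/t — how common the combination is;
* confidence = a/(a+b) — the conditional rate of Y given X;
* lift = confidence / ((a+c)/t) — enrichment over Y's marginal; 1 under
  independence;
* conviction = (1 − supp(Y)) / (1 − confidence), equivalently
  ((b+d)/t)/(b/(a+b)) — like lift but directional; undefined when
  confidence = 1 (zero denominator), reported as the literal token `NA`.

A variant conviction with numerator (c+d)/t circulates in some published
method descriptions. The two disagree whenever a ≠ b; on reconstructed
integer tables from published antidepressant rule tables only the standard
form reproduces the printed conviction values (4.92 → "4.9" vs 4.96 →
"5.0" on the anxiety → irritability row at t = 686), so `standard` is the
default and `as_printed` is available in `rule_stats()` and
`miner_config()` for comparison.

Rules are found with a from-scratch level-wise apriori: frequent k-itemsets
are generated by joining (k−1)-itemsets sharing a (k−2)-prefix under a
canonical byte-wise (kind, label) item order, pruned by downward closure,
and counted by intersecting per-itemset transaction-id lists. Every
partition of a frequent itemset into non-empty antecedent and consequent is
scored; the demographic analysis constrains consequents to exactly one
gender item with gender-free antecedents.

## Parameters that matter

* `min_support` (default 0.001): with cohorts of 700–4400 cases this keeps
  rules backed by at least a handful of reports; raising it prunes the
  search aggressively.
* `min_confidence` (default 0.8): only near-deterministic co-reporting
  survives; at 0.8 a rule's consequent follows in four of five matching
  cases.
* `max_len` (default 10): a practical cap; published tables rarely show
  rules beyond two antecedent items.
* `causality_filter` (default `"suspected"`): which DRUG causality roles
  qualify a case for a drug-class cohort. Suspected-only is the
  conservative pharmacovigilance convention; pass
  `c("suspected", "concomitant")` to widen.
* `match_mode` (default `"substring"`): JADER drug names carry salt and
  brand suffixes ("パロキセチン塩酸塩水和物"), so substring matching
  against generic stems is the default.

Two denominator decisions are easy to get wrong and are fixed here by
design: cases with no REAC rows remain in the cohort (they fill the d cell),
and gender- or age-unknown cases remain in the demographic transaction set
with the item simply absent. The second is forced by arithmetic:
reconstructed gender-rule tables only reproduce published lift values when
supp(female) is taken over the full cohort including gender-unknown cases.

## Ranking and reporting

Reports rank rules by descending support; ties break by descending
confidence, then descending lift, then lexicographic antecedent and
consequent keys — the chain makes top-k selection reproducible (the
tie-break order beyond support is a package choice; any deterministic chain
would do). The ADR analysis reports the top 5 single-consequent rules; the
demographic analysis the top 3 per gender. Written CSVs round support to 4
decimals, confidence to 2, and lift/conviction to 1 (ADR reports) or 2
(demographic reports), and a full-precision companion file always carries
the unrounded statistics and the contingency cells, because every rounded
table should be recomputable from its own integers.

## The synthetic population

`default_generator_spec()` emulates an antidepressant cohort: 58% female /
39% male / 3% gender-unknown (spontaneous antidepressant reports skew
female at roughly 3:2); an adult-heavy decade distribution with 2%
age-unknown; a 0.73/0.16/0.11 SSRI/SNRI/NaSSA mixture matching the relative
cohort sizes such databases show; a 22-term ADR vocabulary with background
rates 0.02–0.08 sampled independently per term; two planted ADR pairs
(aspartate→alanine aminotransferase increased with P(X)=0.02,
P(Y|X)=0.95; INR increased→drug interaction with P(X)=0.008, P(Y|X)=1) and
two gender-skewed terms (suicidal ideation 0.06 F / 0.01 M; rhabdomyolysis
0.002 F / 0.035 M). Planted conditional draws *replace* the background draw
for the consequent term, so the planted conditional probability is exactly
the rule's conditional rate: P(Y|X)=1 forces mined confidence 1 for any
seed (its antecedent has background 0), and background(Y)=P(Y|X) yields
exact independence (lift 1). `analytic_rule_statistics()` returns the
closed-form support/confidence/lift/conviction of every planted rule,
accounting for background contamination of both marginals; tests verify the
closed forms against a separate 10^6-draw Monte-Carlo simulation and verify
that mining a 20,000-case sample recovers them within three standard
errors.

What the generator deliberately does not emulate: dependent background
noise (real ADR co-reporting is correlated through indications and
polypharmacy), MedDRA term hierarchies, duplicate and follow-up reports,
and temporal reporting waves. Passing tests therefore demonstrate that the
pipeline recovers known structure from data of this relational shape — not
that any mined rule from real data is causal or unconfounded.

## Numerical and degenerate-input choices

Support and confidence thresholds are compared with a 1e-9/1e-12 tolerance
so that exact-fraction boundary cases (support exactly min_support) are
kept regardless of floating-point representation. Mining an empty
transaction set is an error; an empty *transaction* is not (it counts in
t). Confidence is an error when the antecedent never occurs, lift when the
consequent never occurs; conviction alone is `NA`, and only at
confidence 1. Statistics are kept at full precision throughout and rounded
only at report time. All item ordering uses byte-wise radix sorting, so
output is locale-independent.

## Scale of the shipped validation

The test suite mines cohorts of up to 20,000 synthetic cases (the size at
which three-standard-error recovery checks are sharp enough to be
meaningful) and compares the miner against exhaustive power-set
enumeration on 500 random transaction sets of up to 12 items — sizes chosen
so the whole suite runs in well under a minute on one core while still
exercising candidate generation several levels deep.

## Limitations

Spontaneous reports carry reporting bias and no exposure denominators;
support, confidence, lift and conviction are descriptive co-reporting
measures, not risk estimates, and no multiple-testing control is applied.
ADR terms are used verbatim (no MedDRA normalisation), so synonymous terms
mine as distinct items. Cohorts built on substring matching can collide on
shared name stems; use `match_mode = "exact"` with a full name list when
that matters.
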