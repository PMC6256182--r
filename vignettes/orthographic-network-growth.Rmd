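---
title: "Simulating the growth of orthographic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the growth of orthographic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexnetgrow)
```

## The model

The package models orthographic vocabulary development as frequency-driven
accretion.  A *learning environment* is a frequency lexicon: distinct word
types with token frequencies, standing for the print a child encounters.
A *virtual participant* is a learner whose lexicon grows along a fixed
grade schedule of type counts; at each checkpoint the required number of
new types is drawn from the types not yet known, with inclusion
probability proportional to corpus frequency.  The acquired lexicons are
then treated as networks: types are nodes, and two types are connected iff
their Levenshtein distance is exactly 1.  Development is read off the
trajectory of the network measures across checkpoints.

Three modelling assumptions are built in deliberately, mirroring the
simulation design the package implements: all participants share the same
lexicon sizes (no between-child variation in vocabulary size or growth
rate), word frequency is the sole driver of acquisition, and the learning
environment is the same corpus at every age.  These are simplifications —
real acquisition also reflects semantics, phonology, instruction and
individual print exposure — so results are claims about the mechanism,
not about any individual child.

## Sampling law

"More frequent types are more likely to be drawn" is made precise as
*successive sampling* (probability proportional to size, without
replacement): draw one type with probability proportional to its frequency
among those remaining, remove it, repeat.  This is the simplest law
consistent with frequency sensitivity and with eventual exhaustion of the
environment.  `weighted_sample_without_replacement()` implements it with
per-item exponential keys (`rexp(n)/w`, keep the `m` smallest), which
induces exactly the successive-sampling distribution over ordered draws in
`O(n log n)` — the naive sequential algorithm is quadratic at
corpus scale.  The test suite checks the equivalence against exact
enumeration of all draw paths on small cases, and checks that equal
weights reduce the sampler to simple random sampling.

Reproducibility is seed-derived: every (participant, stage) pair gets its
own 32-bit seed from a documented arithmetic mix of the cohort seed, so
cohorts are reproducible end to end while participants stay independent.
Ties between sampler keys — a measure-zero event with continuous keys —
would resolve by input order, which is why frequency-lexicon entry order
is part of the data contract.

## The synthetic learning environment

The real corpus the design was built around is not redistributable, so
`generate_corpus()` supplies a synthetic stand-in with the three
properties the analysis leans on:

* **Zipfian frequencies.** Rank *r* gets frequency proportional to
  `r^-zipf_exponent` (default exponent 1) — exact, hence strictly
  decreasing and tie-free.
* **Short high-frequency words.** Each rank draws a length from a
  discretised normal whose centre moves from `length_min` to `length_max`
  as rank grows, with strength `length_frequency_link` in [0, 1]; letters
  are then i.i.d. uniform over the alphabet.  At the defaults (lengths
  2–7 over 26 lowercase letters, link 0.7) the correlation between log
  frequency and length is about −0.54 at 5,000 types; at link 0 it
  vanishes.
* **Many neighbourless types.** Long random strings rarely have
  edit-distance-1 neighbours, so the length distribution doubles as a
  hermit dial.  The defaults give a neighbourless fraction near 0.66 of a
  5,000-type corpus, chosen once to sit near the ~63 % reported for
  German children's print corpora, and frozen.

What the generator does **not** emulate: German morphology (inflectional
families create correlated neighbourhoods), capitalisation structure,
compound words, or any semantic/phonological organisation.  Consequently
the pipeline's outputs on synthetic corpora support *directional* claims —
mean degree rises with lexicon size, clustering falls, high-frequency words
are acquired first — but not the numerical values a real corpus would
give.  Passing tests show the machinery is correct and the qualitative
developmental signature is robust across seeds; they do not calibrate any
quantity to real German.

## Neighbour graphs

`levenshtein_distance()` is the standard unit-cost edit distance
(substitution, insertion, deletion; no transpositions) over Unicode code
points after NFC normalisation, so `ä` is one symbol however it was
encoded, and comparison is case-sensitive (types are distinct orthographic
sequences).  `build_neighbor_graph()` finds the distance-1 edge set by
index rather than all-pairs computation: words sharing a single-position
wildcard key are substitution neighbours, and a word whose single-deletion
variant is itself a type yields an insertion/deletion edge.  The tempting
shortcut of matching words through *shared* deletion variants is rejected:
it admits transpositions ("ab"/"ba" share the variant "a"/"b" pattern but
are distance 2).  The tests hold the index to exact agreement with
brute-force all-pairs edit distance across alphabets and length ranges.

Hermits — types with no neighbour — are excluded from the graph before
any measure is computed, and reported as a count and as a proportion of
the *whole* lexicon (hermits / all types).

## Network measures: conventions and numerical choices

* **Average path length `L`** is the mean shortest-path length over
  ordered pairs of distinct, mutually *reachable* nodes.  Hermit removal
  does not make the graph connected, so unreachable pairs are excluded
  rather than counted as infinite; this matches common graph-software
  defaults and keeps `L` finite.  **Diameter `D`** is the largest finite
  distance.
* **Exact vs sampled paths.**  Exact BFS from every node is used up to
  5,000 nodes (configurable); above that, BFS from a seeded random sample
  of sources estimates `L` (a ratio estimator; exactly unbiased when all
  nodes reach equally many others) and bounds `D` from below, flagged as
  such.  The tests show 50-source estimates on 200-node random graphs sit
  within a few percent of exact values.
* **Clustering `C`.**  `C_i = 2 T_i / (k_i (k_i − 1))` is undefined for
  degree-0/1 nodes.  The default averages over nodes with `k_i ≥ 2`;
  an explicit `count_undefined_as_zero` flag switches to counting them as
  0, since either convention appears in the networks literature and the
  choice matters for sparse graphs.
* **Degree distribution `P(k)`** is computed over non-hermit nodes only,
  so `k = 0` never appears and the frequencies sum to 1; mean degree
  satisfies ⟨k⟩ = Σ k·P(k) on every record (tested).

## Trend statistics

Each measure is analysed over grade with a one-way between-groups ANOVA.
With *k* grades and *N* total lexicons the dfs are (k − 1, N − k) — for
the full design, (6, 343) — which is the layout behind the reported
statistics of this kind of simulation; a true within-participant
(repeated-measures) variant is available behind `repeated = TRUE` for
comparison.  Consecutive-grade comparisons use Tukey HSD p-values from
the studentized-range distribution, adjusted over *all* pairs as standard
HSD practice dictates even when only consecutive pairs are reported.

Polynomial trends regress the measure on orthogonal polynomial contrasts
of the *numeric* grade variable, so the gap in a 1–6, 8 schedule is
respected rather than treated as equally spaced; orthogonal rather than
raw parameterisation keeps the per-order t-tests independent on balanced
designs.  With noise-free polynomial data the model fit is exact
(R² = 1) but the higher-order t-values are 0/0 and not meaningful — the
tests therefore assert vanishing *coefficients* there, and t-values only
under noise.

The degree distribution's power-law shape is summarised by OLS of
log₁₀ P(k) on log₁₀ k over observed degrees.  This is the descriptive
convention of the lexical-networks literature, kept deliberately; it is
*not* a maximum-likelihood tail fit and is biased in the heavy tail, so
the slope and R² should be read as a linearity summary, not an exponent
estimate.  On the small demonstration lexicons (hundreds of connected
nodes) the observed-degree scatter keeps this R² low; it rises with
network size.

`correlation_power()` uses the Fisher-z approximation for the two-sided
zero-correlation test; at n = 50, r = 0.4, α = 0.05 it gives 0.83,
consistent with choosing 50 participants to detect medium-to-large
effects with power 0.80.

## Degenerate inputs

Empty type sets give an empty graph; all-hermit lexicons give `n = 0`
records with NA measures rather than errors; single-node graphs have no
path length; groups with fewer than two observations, zero-variance ANOVA
layouts, over-large polynomial orders and sampling beyond the environment
all raise informative errors.  Duplicate types after NFC normalisation are
merged (summing frequencies) with a warning on read, and are an error in
graph construction.

## Problem sizes

The demonstration configuration uses a 5,000-type synthetic corpus, 10
participants and a four-stage schedule whose sizes scale the published
grade-1/3/5/8 lexicon sizes from a 180,000-type corpus down to 5,000
(877, 1299, 1982, 3630).  These sizes keep exact path computation
feasible everywhere while preserving the design's proportions; the growth
arithmetic itself is exercised at full scale (180,000 types, 50
participants, seven grades), where only sampling — not graph analysis —
is required.

## Known limitations

* Synthetic corpora support directional conclusions only (see above).
* The OLS power-law fit is descriptive, not inferential.
* Sampled-mode `L` is a ratio estimator and sampled `D` only a lower
  bound; both are flagged but should not feed fine-grained comparisons.
* No modelling of forgetting, age-varying subcorpora, inter-individual
  size variation, or frequency-weighted edges; these are extensions the
  simulation framework could host but does not implement.
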