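---
title: "Modeling BGC temporal dynamics and FMT engraftment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling BGC temporal dynamics and FMT engraftment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgctempo)
library(dplyr)
```

## The problem

Gut bacteria carry biosynthetic gene clusters (BGCs) — co-located genes
encoding the synthesis of secondary metabolites such as bacteriocins,
siderophores and pigments. In longitudinal stool metagenomes, a given BGC is
sometimes detectable and sometimes not, and the pattern of gains and losses
over repeated visits is informative: some clusters persist for a year in
nearly every carrier, others flicker in and out. bgctempo models that
turnover, classifies clusters as *persistent* or *transient*, and asks
whether the two groups behave differently when a whole community is
transplanted into a new host during fecal microbiota transplantation (FMT).

The package operates downstream of assembly, BGC prediction and read
alignment. Its inputs are plain tables: a BGC catalog (sequences plus gene
intervals), per-sample per-gene coverage summaries, sample metadata, and
functional annotation tables (ARG, VF, MGE labels). Everything upstream —
assemblers, BGC predictors, aligners, annotation databases — is out of
scope and consumed as files.

## The two-state Markov turnover model

For each BGC we observe a presence/absence state at consecutive visits
within each subject. The model is a time-homogeneous two-state Markov
chain with

* inflow probability $p_{\mathrm{in}} = P(\text{present at } v{+}1 \mid
  \text{absent at } v)$,
* outflow probability $p_{\mathrm{out}} = P(\text{absent at } v{+}1 \mid
  \text{present at } v)$.

`fit_markov()` pools all consecutive-visit transitions of a BGC across
subjects into one chain and estimates both probabilities by maximum
likelihood (row-normalized transition frequencies). Pooling is a deliberate
choice: with four visits a subject contributes at most three transitions,
far too few for per-subject fits, and the cohort-level estimate is the
quantity the classification needs. Only *consecutively indexed* visits
form transition pairs; a gap (visits 1, 3, 4 observed) contributes only the
(3, 4) pair and is never imputed.

A from-state never observed leaves the corresponding probability `NA` — we
deliberately use no pseudocount smoothing, so a BGC present in every sample
of every subject has $p_{\mathrm{out}} = 0$ and an *undefined* inflow, and
its classification is `NA` rather than a guess.

Classification uses a threshold of 0.3 on both probabilities, with strict
inequalities:

* **persistent**: $p_{\mathrm{in}} > 0.3$ and $p_{\mathrm{out}} < 0.3$ —
  quickly regained, rarely lost;
* **transient**: $p_{\mathrm{in}} < 0.3$ and $p_{\mathrm{out}} > 0.3$;
* anything else (including a probability exactly at 0.3) is
  **unclassified**.

Two cohort-level summaries accompany the fit: *prevalence* (the fraction of
subjects carrying the BGC in at least one visit) and the consecutive-visit
shared fraction. For the latter the package defaults to the Jaccard overlap
$|A_v \cap A_{v+1}| / |A_v \cup A_{v+1}|$ between the BGC sets of adjacent
visits; the forward-retention variant $|A_v \cap A_{v+1}| / |A_v|$ is
available via `method = "retention"` because both readings of
"consistently shared between consecutive visits" are defensible and the
choice matters for the reported number.

```{r markov-demo}
mk <- gen_markov_cohort(n_bgcs = 120, n_subjects = 30, n_visits = 4, seed = 1)
fit <- fit_markov(mk$presence, mk$meta)
glance(fit)
```

## Presence calling from coverage breadth

A gene is called present when the covered fraction of its length is at
least the *gene cutoff*; a BGC is called present when the fraction of its
genes called present is at least the *BGC cutoff*. Both comparisons are
inclusive (`>=`): the cutoffs are minimum requirements. The defaults,
`gene_cov = 0.3` and `bgc_cov = 0.5`, are the operating point selected by
benchmarking against a mock community with known composition.

`evaluate_cutoffs()` reruns that benchmark: presence calls over every
(sample, BGC) pair are scored against ground truth at each point of a
9 × 9 grid (0.1–0.9 in steps of 0.1 on both axes), yielding TP/FP/FN/TN,
recall, precision and F1. The selected pair maximizes F1 — chosen as the
symmetric scalarization of recall and precision since neither is privileged
here — with ties broken toward higher precision, then lower gene cutoff,
then lower BGC cutoff. The full grid is always returned so any other
selection rule can be applied afterwards.

Abundance is RPKM with the per-sample denominator equal to reads mapped to
the catalog (the only read universe the coverage tables know about).
Masking abundance to zero where presence is false is available but off by
default; the two tables answer different questions and coupling them is a
downstream decision.

## The synthetic-data generators

Every pipeline input can be generated with planted ground truth, which is
what all tests and the acceptance script run on.

* `gen_mock_community()` — presence of each of 100 genomes in each of 100
  samples is Bernoulli(0.7); abundances of present genomes are log-normal
  (μ = 0, σ = 1), renormalized per sample. These defaults are the
  benchmark community design the detection cutoffs are calibrated on.
* `gen_coverage()` — rather than simulating reads, coverage breadth is
  derived from the Lander–Waterman relation: a gene at expected per-base
  depth $c$ has breadth $1 - e^{-c}$, plus Gaussian noise (sd 0.05),
  clamped to [0, 1]; read counts are Poisson with a fixed 150 nt read
  length. `depth_factor = 50` is the "moderate depth" condition: a genome
  at 1% relative abundance gets breadth ≈ 0.39, so detection is good but
  imperfect — the regime where cutoff choice actually matters.
* `gen_markov_cohort()` — per-BGC chains with parameters drawn uniformly
  on (0.05, 0.95)². The visit-1 state is drawn from the chain's
  stationary distribution $\pi = p_{\mathrm{in}} / (p_{\mathrm{in}} +
  p_{\mathrm{out}})$, which makes the short cohort a steady-state sample
  rather than one with a startup transient.
* `gen_fmt_triads()` — donor and pre-FMT BGC sets are sampled
  independently; each donor-only BGC engrafts with its class-specific
  probability, and pre-FMT BGCs are retained with a stated retention
  probability. Every engraftment opportunity is recorded as truth.
* `gen_annotations()` — background BGCs carry a feature with a base rate,
  a target group at `min(1, fold × base_rate)`.

What these generators do *not* emulate: read-level sequencing error,
multi-mapping between near-identical catalog entries, compositional
coupling between genomes, strain-level variation within a species, or any
correlation between a BGC's turnover class and its abundance. Passing
tests therefore demonstrate that the estimators recover what they claim to
estimate under the stated model — not that the model captures every
property of real stool metagenomes. One consequence is visible in the
cutoff benchmark: without mismapping noise, lower cutoffs than the
real-data operating point (0.3, 0.5) win the grid search, which is why the
grid and the F1 at the default pair are both reported.

## Dereplication: MinHash, similarity network, MCL

Redundant catalog entries are collapsed in three steps:

1. **Sketching.** Bottom-1000 MinHash over canonical 21-mers (each k-mer
   identified with its reverse complement), hashed with SplitMix64 — a
   published 64-bit mixing function that is identical across platforms and
   versioned in the sketch object. Hash values are truncated to their top
   53 bits so they are exact R doubles.
2. **Network.** The Mash distance $d = -\tfrac{1}{k}\ln\frac{2j}{1+j}$ is
   estimated from the merged bottom sketch; an edge connects two sequences
   when similarity $1 - d$ is *strictly* above 0.95.
3. **Clustering.** Markov clustering (MCL) with inflation 2.0 (the
   conventional default; no value is prescribed by the source workflow),
   expansion 2, self-loops of weight 1, pruning at $10^{-5}$ and a
   convergence tolerance of $10^{-6}$. Clusters are read from the
   attractor structure of the limit matrix; in the rare overlap case a
   node attracted by two systems goes to the smaller cluster id, so the
   partition always covers every node exactly once.

The longest member of each cluster becomes the representative, with length
ties broken to the lexicographically smallest id — a deterministic rule a
rerun can reproduce.

## FMT colonization statistics

A triad is one donor sample, one pre-FMT and one designated post-FMT
recipient sample. Cohorts with several post-FMT timepoints must designate
one in the metadata; the package refuses to guess. The triad colonization
rate is

$$\frac{|D \cap \mathrm{Post} \setminus \mathrm{Pre}|}
       {|D \setminus \mathrm{Pre}|},$$

`NA` when the denominator is empty, and restricting to a BGC class
(persistent/transient) intersects all three sets with the class first.
Shared fractions use the triad's own post-FMT set as the denominator (the
fraction of the post-FMT clusters, within the class, also seen in the
donor or pre-FMT sample); this per-triad universe was chosen over the
whole catalog because it keeps triads with different richness comparable.
Per-BGC rates count eligible triads (donor-carried, pre-absent) in the
denominator. `NA` triads are excluded from group means with the exclusion
count reported alongside.

## Statistical tests

* **Hypergeometric** enrichment/depletion: exact tail sums, one-tailed in
  the stated direction by default since enrichment and depletion claims
  are directional; a two-sided option doubles the smaller tail. Depletion
  folds are printed as expected/observed so that "2-fold depletion" means
  half the expected rate. No multiple-testing correction by default (raw
  p-values are the primary output; Benjamini–Hochberg is one flag away).
* **Mann–Whitney U** with average ranks on ties: exact when both samples
  have at most 20 observations — the permutation distribution of U is
  computed by a subset-sum dynamic program over the tied rank vector,
  which equals explicit enumeration — and the tie-corrected normal
  approximation otherwise.
* **Pearson chi-square** without continuity correction by default (Yates
  available).

## Numerical choices and degenerate inputs

* All cutoff comparisons are inclusive; all classification thresholds are
  strict. Both choices are stated on the functions and tested at the
  boundary.
* Ratios with empty denominators are `NA`, never 0, never an exception —
  except RPKM with zero total mapped reads, which is an error because it
  indicates a broken upstream sample.
* Readers validate loudly: coverage fractions outside [0, 1], duplicate
  keys, unknown ids, ragged matrices and out-of-bounds gene coordinates
  are all hard errors, never silently repaired.
* Every generator takes a seed and pins the RNG kind, so identical seeds
  give byte-identical outputs across machines.

## Problem sizes

The reference checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use the package's standard study conditions: 300
BGCs × 86 subjects × 4 visits for Markov recovery, a 10,000-step single
chain for stationarity, the 100 × 100 mock community for cutoff
optimization, 50 triads for engraftment recovery, 2,000 replicates for
null calibration of the hypergeometric test, and 20 × 3 planted sequence
groups for dereplication.

## Known limitations

* The Markov model is time-homogeneous and first-order; seasonal or
  abundance-dependent turnover is not modeled.
* Pooling transitions across subjects assumes exchangeability; strong
  subject-level heterogeneity would bias both probabilities toward their
  cohort means.
* Presence calling treats genes as independent; tandem duplications or
  shared genes between catalog entries (mitigated, not eliminated, by
  dereplication) can couple calls.
* The synthetic coverage model has no mismapping, so benchmark-optimal
  cutoffs are lower than what noisy real alignments warrant; on real data
  the shipped defaults (0.3, 0.5) are the sensible operating point.
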