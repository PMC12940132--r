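# bgctempo

Temporal dynamics and transplant engraftment of biosynthetic gene clusters
(BGCs) in the gut microbiome.

Gut bacteria encode secondary metabolites — bacteriocins, siderophores,
pigments — in co-located groups of genes called biosynthetic gene clusters.
In longitudinal stool metagenomes a BGC appears and disappears over repeated
visits, and that turnover is structured: some clusters are *persistent*
(quickly regained, rarely lost), others *transient*. bgctempo is a tidy R
toolkit for the full analysis downstream of assembly and alignment:

- **Catalog dereplication** — bottom-sketch MinHash over canonical 21-mers,
  a similarity network at Mash similarity > 0.95, Markov clustering (MCL),
  and longest-sequence representatives.
- **Presence calling** — a gene is present when ≥ 30% of its length is
  covered, a BGC when ≥ 50% of its genes are present; both cutoffs are
  re-optimizable by grid search (recall/precision/F1) against a mock
  community with known composition.
- **Abundance** — RPKM against per-sample catalog-mapped reads; Shannon,
  richness, Bray–Curtis and Jaccard diversity via vegan.
- **Turnover modeling** — a two-state Markov chain per BGC, pooled across
  subjects. Inflow $p_{in} = P(\mathrm{absent} \to \mathrm{present})$ and
  outflow $p_{out} = P(\mathrm{present} \to \mathrm{absent})$ are estimated
  by maximum likelihood; *persistent* means $p_{in} > 0.3$ and
  $p_{out} < 0.3$, *transient* the reverse, both strict.
- **FMT colonization** — for donor / pre-FMT / post-FMT triads, the
  colonization rate $|D \cap Post \setminus Pre| / |D \setminus Pre|$,
  shared fractions, per-BGC rates, and class- and response-stratified
  summaries.
- **Enrichment** — exact one-tailed hypergeometric tests of ARG / VF / MGE
  annotation classes in the persistent and transient groups, plus
  Mann–Whitney U (exact for small samples) and Pearson chi-square.
- **Synthetic data** — generators for every input with planted ground
  truth (mock communities, coverage with a Lander–Waterman depth-to-breadth
  model, Markov cohorts, FMT triads, annotations), so the whole pipeline is
  testable end to end.

Functions take data frames first and return tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a longitudinal cohort with known turnover parameters, fit the
Markov model, and push the classification through FMT triads with planted
engraftment probabilities (0.8 for persistent, 0.2 for transient):

```r
library(bgctempo)
library(dplyr)

mk <- gen_markov_cohort(n_bgcs = 120, n_subjects = 30, n_visits = 4, seed = 1)
fit <- fit_markov(mk$presence, mk$meta)
fit
#> Two-state Markov turnover fit
#>   BGCs: 120; subjects: 30; transition pairs: 90
#>   persistent: 22  transient: 16  unclassified: 82  (threshold 0.3, strict)

tidy(fit) |>
  select(bgc_id, p_inflow, p_outflow, prevalence, classification) |>
  head(4)
#> # A tibble: 4 × 5
#>   bgc_id  p_inflow p_outflow prevalence classification
#>   <chr>      <dbl>     <dbl>      <dbl> <chr>
#> 1 bgc0001    0.189     0.875      0.567 transient
#> 2 bgc0002    0.481     0.583      0.933 unclassified
#> 3 bgc0003    0.44      0.5        0.9   unclassified
#> 4 bgc0004    0.778     0.278      1     persistent

ft <- gen_fmt_triads(mk$truth$bgc_id, n_triads = 20, donor_richness = 60,
                     pre_richness = 40,
                     class_map = select(mk$truth, bgc_id,
                                        classification = true_class),
                     seed = 2)
group_summary(ft$triads, ft$class_map)
#> # A tibble: 3 × 6
#>   classification cohort     n n_excluded mean_rate sd_rate
#>   <chr>          <chr>  <int>      <int>     <dbl>   <dbl>
#> 1 persistent     sim       20          0     0.799   0.161
#> 2 transient      sim       20          0     0.182   0.176
#> 3 unclassified   sim       20          0     0       0
```

Each `p_inflow` / `p_outflow` pair is the pooled transition-frequency MLE
for one BGC; `prevalence` is the fraction of subjects carrying it at least
once. The triad summary recovers the planted ordering: persistent clusters
engraft at ~0.8, transient at ~0.2.

Enrichment of an annotation class in a group is an exact hypergeometric
tail:

```r
hypergeom_test(N = 1000, K = 200, n = 300, k = 85)
#> # A tibble: 1 × 7
#>       N     K     n     k  fold direction    p_value
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <chr>          <dbl>
#> 1  1000   200   300    85  1.42 enrichment 0.0000175
```

## Command-line pipeline

A thin CLI over the same functions lives at `inst/cli/bgctempo.R`
(subcommands `simulate`, `dereplicate`, `call-presence`,
`optimize-cutoffs`, `abundance`, `diversity`, `dynamics`, `fmt`, `enrich`;
every subcommand takes `--config`, `--seed`, `--log-level`). A full run:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "bgctempo.R", package = "bgctempo"))')
Rscript $cli simulate --seed 17 --out-dir sim
Rscript $cli call-presence --fasta sim/catalog.fasta --genes sim/genes.tsv \
        --coverage sim/coverage.tsv --out-dir out
Rscript $cli dynamics --presence out/presence_matrix.tsv \
        --metadata sim/metadata.tsv --out-dir out
Rscript $cli fmt --presence out/presence_matrix.tsv --metadata sim/metadata.tsv \
        --markov out/markov_estimates.tsv --out-dir out
Rscript $cli enrich --markov out/markov_estimates.tsv \
        --annotations sim/annotations.tsv --out-dir out
```

Reruns with the same seed are byte-identical.

## Further reading

The methods vignette (`vignettes/bgc-temporal-dynamics.Rmd`) documents the
model assumptions, the synthetic-data generators and what they do and do
not emulate, the numerical choices, and known limitations.
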