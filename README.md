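# rabsim

Transposable elements (TEs) seed new regulatory DNA: a TE family can carry
imperfect *proto-motifs* — near-matches to transcription-factor binding
motifs — that mature into functional sites through point mutations after
insertion. `rabsim` implements the computational machinery for studying
this process in the context of the mammalian circadian clock, where a
murine-specific SINE family distributes proto-E-Box and proto-RORE motifs
that mature, preferentially at CpG sites, into binding sites for circadian
regulators (CLOCK:BMAL1, PERs/CRYs) and nuclear receptors.

It is written for computational genomicists who want a tested, scriptable
version of the full analysis chain:

- **RABS classification** — split ChIP-seq peaks into repeat-associated
  binding sites (RABS) vs Non-RABS by the fraction of the peak covered by
  a single RepeatMasker element (`classify_rabs()`, default threshold
  50%).
- **Family enrichment** — observed vs expected bound copies per TE family
  under a constrained-shuffle bootstrap null that preserves each element's
  chromosome and its signed distance to the nearest TSS
  (`constrained_shuffle()`, `bootstrap_expected()`), tested with an exact
  two-sided binomial test (`binomial_enrichment_test()`):
  for family *f* with observed count `O_f` among `n` peaks and bootstrap
  mean `E_f`, the null is `O_f ~ Binomial(n, E_f / n)` and the ratio
  `O_f / E_f` is the enrichment.
- **Motif analysis** — IUPAC scanning (`scan_iupac()`), exact-p-value
  log-odds scanning (`threshold_scan()`), hit merging with score
  averaging, score-weighted density profiles, start-to-start spacing to
  the nearest non-overlapping motif, discriminative k-mer enrichment and
  the bound/unbound motif-gain fold change.
- **Maturation** — proto-motif discovery by bounded Hamming distance,
  minimal substitution paths with strand-aware CpG-deamination
  classification (C→T with a following G, or G→A with a preceding C),
  in-silico "evolved" consensus construction, per-copy maturation calls
  through alignments, and Kimura 2-parameter divergence
  `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))`.
- **Synthetic data** — a generator (`simulation_config()`,
  `simulate_dataset()`) for a SINE amplification burst from a single
  consensus (star phylogeny) with CpG-hypermutable sites (default 10x),
  proximity-biased insertion near ancestral binding sites,
  maturation-dependent peak calls, and a mouse/rat sister-lineage split —
  all with a complete ground-truth table, so every stage of the pipeline
  is testable without external data.

Everything takes and returns tibbles, chains with the pipe, and the main
result types have `autoplot()`, `tidy()` and `glance()` methods.

## Worked example

Simulate a dataset under the default burst model, classify peaks, and test
family enrichment:

```r
library(rabsim)

cfg <- simulation_config(seed = 7)
sim <- simulate_dataset(cfg)

calls <- classify_rabs(sim$peaks, sim$te_annotations)
table(calls$label)
#> Non-RABS     RABS
#>      101       53

enr <- enrichment_report(sim$peaks, sim$te_annotations, sim$tss,
                         sim$chrom_sizes, n_replicates = 30, seed = 3)
head(tidy(enr), 3)
#>   family      observed expected_mean expected_sd ratio p_value
#> 1 RSINE1_like       34         27.2         4.54 1.25    0.169
#> 2 ID_like            6          5.17        1.66 1.16    0.651
#> 3 B1_like            4          4.20        2.09 0.952   1.000
```

Here 53 of 154 peaks are repeat-associated; the focal family's 34 bound
copies against a bootstrap expectation of 27.2 give a mild ratio of 1.25
(the default configuration plants no enrichment; with
`target_enrichment = 4` the report recovers a ~4-fold ratio at
astronomically small p).

The maturation worked example reproduces the canonical proto-motif
arithmetic — perfecting all annotated motifs of the synthetic consensus
changes exactly 7 nt, and each 3' proto-E-Box is a single CpG deamination
from canonical:

```r
model <- rsine_like_consensus()
evolve_consensus(model, perfecting_substitutions())$n_substitutions
#> [1] 7
substitution_path("CACGCG", "CACGTG")
#> # A tibble: 1 x 4
#>   position from_base to_base deamination_consistent
#> 1        5 C         T       TRUE
```

## Vignette

`vignettes/rabsim-methods.Rmd` describes the statistical model behind each
stage, the generator's assumptions and defaults, and the package's design
choices and limitations.
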