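---
title: "Models and methods behind rabsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rabsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rabsim)
```

`rabsim` studies how a transposable-element (TE) family seeds and matures
transcription-factor binding sites, with the circadian regulators of the
mouse liver as the motivating system. This vignette explains the models
and conventions each stage implements, why the defaults are what they
are, and what the synthetic-data generator does and does not emulate.

## Interval model and RABS classification

All intervals are 0-based, half-open (BED convention) in every exposed
tibble; conversion to the 1-based closed convention used by
GenomicRanges happens only internally. RepeatMasker tables in the UCSC
track dialect are read natively (their coordinates are already 0-based)
and rows of class `Low_complexity` or `Simple_repeat` are dropped, since
non-TE repeats are conventionally excluded before peak–repeat analyses.

A peak is a **repeat-associated binding site (RABS)** when a *single*
repeat covers at least `min_fraction` (default 0.5) of the peak's length.
Three conventions deserve note:

- The threshold is `>=`, matching the operational semantics of the
  standard interval-intersection tools (`-f 0.5` reports an overlap at
  exactly 50%).
- The fraction is computed against the single best-covering repeat, not
  the union of repeats; when several repeats qualify, maximal overlap
  wins and ties go to the leftmost repeat start. Union coverage would
  relabel edge cases that have no established definition, and best-single
  attribution is also what makes per-family counting unambiguous. This
  choice matters only for peaks straddling several repeats, which is why
  the attribution rule is exposed in the output for sensitivity checks.
- Distances (`nearest_distance()`) are edge gaps; book-ended intervals
  have distance 0, keeping distance continuous with overlap. Strand is
  carried but ignored by overlap and distance operations.

## The constrained-shuffle enrichment null

To ask whether a TE family is overrepresented among peaks, observed
per-family counts of RABS-attributed peaks are compared to a null in
which repeats are re-placed while preserving two properties of the
repeat complement: the number of elements on each chromosome, and each
element's distance to the nearest transcription start site (TSS). The
implementation records each element's signed start offset to its nearest
TSS, draws a uniformly random TSS on the same chromosome, and re-places
the element at the same signed offset from the drawn anchor. This scheme
provably preserves both constraints per element. Placements that would
exceed a chromosome end are redrawn up to 100 times and then clamped to
the boundary; pure clamping would distort the null near telomeres and
pure rejection can livelock on tiny genomes, so the hybrid keeps the
null usable at all scales (clamping is flagged in the output and is rare
on the recommended genome sizes).

The shuffle is bootstrapped (study-scale default 1000 replicates; the
package's own tests and acceptance runs use 100, which leaves the Monte
Carlo error of the expected mean an order of magnitude below the
binomial sampling noise). Replicate `k` is seeded by a deterministic
function of the master seed and `k`, so replicates are independent and
bit-reproducible.

Significance uses an exact two-sided binomial test: with `n` peaks,
observed count `O` and bootstrap mean `E`, the null is
`O ~ Binomial(n, E/n)`. Two-sided p-values use the minimal-likelihood
convention (the sum of all point probabilities not exceeding that of the
observed count — the construction `stats::binom.test()` implements); the
tail-doubling convention is available as an option. `n` is the number of
peaks because a "success" is a peak attributed to the family, and `E` is
on the same scale. Families are additionally flagged by the conventional
`> 50` observed-copy filter, but never censored: a family can fail the
filter and still be significantly enriched, and the report keeps its
p-value.

When one repeat spans two peaks, *peaks* are counted (each peak is
attributed at most once); this matches the unit in which the enrichment
is interpreted — bound sites, not element copies.

### Calibration

`null_calibration()` checks the whole chain under a no-enrichment null:
peaks, TSS and 20 exchangeable repeat families are placed uniformly at
random and the bootstrap + binomial machinery is run per dataset. The
default sizes (3,000 peaks of 200 bp, 400 copies per family of 150 bp on
a 6-Mb genome) put the per-family expected count near 30 — large enough
that the exact binomial's discreteness does not make it visibly
conservative, while total attribution stays far from saturating the peak
set (attribution competition between families would otherwise induce
negative correlation). Under these conditions the family-level
false-positive rate at p < 0.05 is close to 5%, which the acceptance
suite verifies over 200 datasets.

## Motif model

IUPAC motifs convert to probability columns uniform over the allowed
bases against a flat 0.25 background, so a column with `k` allowed bases
scores `log2(4/k)` bits for any allowed base and `-Inf` otherwise. Two
consequences are intentional: all exact degenerate matches share the
motif's maximum attainable score, and the exact score null used by
`threshold_scan()` is computable by dynamic programming over per-column
score distributions. The package applies no pseudocounts and no
higher-order background — the motifs of interest are short and fully
specified, and a uniform background keeps every p-value exact.

Conventions:

- Windows containing `N` never match and are skipped.
- Palindromic motifs (e.g. CACGTG) collapse their redundant minus-strand
  self-hits to a single plus-strand hit; non-palindromic motifs report
  both strands. A degenerate non-palindromic motif (e.g. CACRTG) can
  legitimately hit the same window on both strands when the window's
  realization is palindromic.
- Overlapping hits merge to their union with the arithmetic mean score,
  mirroring the usual merge-and-average treatment of motif tracks.
- Motif spacing is **start-to-start** to the nearest non-overlapping
  retained hit, pooled across sequences, with only maximum-score hits
  retained by default. Start-to-start is the one convention under which
  a motif pair "separated by 6 nt" (gap) reads as the 12-bp spacing mode
  that tandem E-Box analyses report; the choice is fixed here and
  documented rather than configurable.
- Discriminative motif discovery is implemented as exact k-mer
  presence/absence enrichment (reverse-complement collapsed, one-sided
  hypergeometric p). The functional contract — recovering the canonical
  E-Box and the discriminative RORE from sequence sets that differ by
  maturation — is what the tests assert.

## Proto-motifs, deamination and divergence

A proto-motif is a window within a bounded Hamming distance (default 2)
of a canonical motif, on either strand; exact matches are legitimate
proto-motifs at distance 0 (a copy's window "matured" means it equals
the canonical string, so a distance-0 motif is trivially matured and
contributes no events). Substitution paths between equal-length strings
are minimal by construction (one event per mismatch); gapped paths are
out of scope because the maturation model is purely substitutional.

Each event is classified **deamination-consistent** when, evaluated on
the *source* sequence with up to 1 nt of flanking context, it is C→T
with the C immediately followed by G, or G→A with the G immediately
preceded by C (the minus-strand image of the same CpG deamination).
Unknown neighbours (window at a sequence boundary, no flank supplied)
classify as non-consistent, deliberately conservative.

Kimura 2-parameter divergence is computed by direct counting of
transition and transversion proportions over ungapped columns and the
closed form `d = -1/2 ln((1-2P-Q) sqrt(1-2Q))`. Saturated inputs (where
the logarithm's argument is non-positive) return a flagged undefined
result instead of an error. Unaligned pairs are first aligned globally
with fixed scores (match +1, mismatch −1, gap −2) via Biostrings, so
alignment-dependent results are reproducible; Jukes–Cantor is not
offered because the two-parameter correction is the one this analysis
standardizes on. The tests cross-check the implementation against
`ape::dist.dna(model = "K80")`.

## The synthetic consensus

The package ships a **synthetic** 160-nt consensus
(`rsine_like_consensus()`) reproducing the proto-motif architecture that
makes the studied SINE family distinctive: a perfect antisense RORE
closely followed by a sense RORE two substitutions from optimal, a second
imperfect sense RORE, a central E-Box one non-CpG substitution from
optimal, and a 3' pair of E-Boxes separated by 6 nt, each a single CpG
C→T from canonical. The filler sequence was screened so that no other
window lies within one substitution of the optimal E-Box or RORE on
either strand — the annotated windows are exactly the near-motif content.
It is a constructed stand-in, not a curated database consensus;
perfecting all its annotated motifs changes exactly 7 nt, reproducing
the canonical in-silico-evolution arithmetic.

## The generator: what it emulates

`simulation_config()` defaults describe a desk-scale model of a
murine-specific SINE burst:

| parameter | default | meaning |
|---|---|---|
| `chrom_lengths` | 2 × 750 kb | genome large enough for ~43% repeat content without forced overlap |
| `n_tss` | 100 | shuffle anchors, ≥1 per chromosome |
| `n_ancestral_sites` | 150 | pre-existing bound sites (always emit peaks; the Non-RABS population) |
| `n_te_copies` | 2000 | burst size (scaled down from genome scale) |
| `mu` | 0.05/site | per-copy substitution probability; puts the K2P divergence histogram in the range typical of an old SINE burst |
| `kappa` | 10 | CpG rate multiplier, the literature-scale deamination excess |
| `proximity_bias` | 0.3 | fraction of insertions placed within `proximity_window` (10 kb) of an ancestral site |
| `bind_prob` / `maturation_coupling` | 0.3 / 0.5 | binding probability of a pair-matured copy, plus the proximity boost |
| `post_split_mu` | mouse 0.02, rat 0.02 | independent post-split evolution |
| `loss_fraction` | 0.4 | per-lineage ortholog loss, chosen so ~60% of copies map to the sister lineage |

Key modelling commitments:

- **Star phylogeny**: every copy derives independently from the
  consensus in one step; there is no subfamily structure within the
  burst. This is an explicit property of the emulated system, not a
  simplification to revisit.
- **CpG hypermutation is the deamination channel**: a CpG hit is
  realized as C→T (or G→A on the minus strand), with CpG status read
  from each copy's source sequence. A uniform-channel alternative is a
  configuration toggle for null comparisons. To first order the
  designated proto-E-Box matures at rate `kappa * mu`, which the tests
  verify at 10^4 copies.
- **Placement**: a `proximity_bias` fraction of focal copies is placed
  near — but never on — an ancestral site; all other placements
  (including control families) are truly uniform with no avoidance, so
  their chance overlap with peaks matches what the shuffle null assumes.
  This is what lets control families calibrate at ratio ≈ 1 while
  ancestral peaks remain identifiable as the Non-RABS population.
- **Binding**: a copy can be bound only if its designated E-Box pair has
  matured; binding then succeeds with `bind_prob`, boosted additively by
  `maturation_coupling` for proximity-placed copies. The coupling between
  proximity and binding is a free knob — the emulated observation is an
  association, not a mechanism — so recovery tests assert direction
  only. Bound copies emit a fixed-width (200 bp) peak centered on the
  copy; widths are generator conventions, nothing downstream depends on
  them beyond the overlap arithmetic.
- **Planting**: `target_enrichment = r` places the analytically required
  number of extra focal copies directly onto distinct ancestral sites so
  the observed/expected ratio targets `r`. The arithmetic accounts for
  the per-copy chance of qualifying overlap; the planted fraction of
  peaks should be kept small (large `n_ancestral_sites`) or attribution
  competition visibly depresses the control families.
- **Lineage split**: descendants evolve independently under the same
  mutation scheme; loss is uniform random, not sequence-dependent —
  the simplest model sufficient to exercise the ortholog-map plumbing.

What the generator does **not** emulate: read-level noise, peak-calling
artifacts, GC or mappability biases, methylation state (CpG
hypermutability is unconditional), selection, within-family subfamily
expansion, and real genomic context (gene structure, chromatin). Passing
recovery tests therefore demonstrates that the *analysis* is correct and
calibrated under the stated generative model — not that real data meet
that model's assumptions.

## Problem sizes and numerical choices

The acceptance runs use deliberately scaled problem sizes chosen as the
package's own study conditions: 200 simulated datasets × 20 families for
calibration; a 12-Mb genome with 2,000 ancestral sites and 5,000 copies
for planted-enrichment recovery (planted peaks ≈ 15% of the peak set);
10,000 copies for proximity recovery; 5,000 copies for spacing and
lineage comparisons; 100 bootstrap replicates throughout. Scores are
compared with a 1e-9 rounding guard when distinct per-column sums are
aggregated; random draws all flow from a single master seed through a
deterministic child-seed function, and no package function perturbs the
caller's RNG state.

## Known limitations

- Enrichment p-values are raw binomial probabilities; no multiple-testing
  correction is applied (by design — the convention in this analysis is
  to report raw p with a copy-count filter).
- The binomial treats the bootstrap mean as known; with very few
  replicates the estimated null probability is noisy and the test runs
  slightly anticonservative.
- Attribution competition between families is real but unmodelled by the
  binomial null; keep total attribution well below the number of peaks.
- The exact motif-score null assumes i.i.d. uniform background;
  GC-skewed sequence shifts the realized hit density.
- `threshold_scan()` is exact but limited to motifs ≤ 16 nt.
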