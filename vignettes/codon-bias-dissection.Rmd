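---
title: "Dissecting codon usage bias into mutational and selective components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting codon usage bias into mutational and selective components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonscope)
library(dplyr)
```

## The problem

Synonymous codons are not used at equal frequencies, and in compact
eukaryotic genomes such as budding yeast the departure from equal usage
tracks gene expression. Two classes of forces produce this bias: mutational
pressure, which acts uniformly on the whole genome and is summarised by its
GC content, and natural selection, which acts gene by gene with a strength
that grows with transcript level. `codonscope` implements a set of
statistics and null models for separating the two, with particular
attention to sequence properties connected to mRNA secondary structure:
per-nucleotide double-strandedness scores (PARS), the folding free energy
of introns, codon complementarity and three-base periodicity.

Every user-facing function takes a data frame first (`gene_id` + `cds` for
genomes, `gene_id` + `mrna_per_cell` for expression) and returns a tibble
or a tidy-able fitted object, so analyses compose with the pipe.

## The statistics

**Codon complementarity.** The fraction of a gene's codons participating
in reverse-complement couples: each unordered pair \{c, revcomp(c)\}
contributes min(n(c), n(revcomp(c))) couples, and the index divides the
couple count by the total codon count. A gene of 10 AAT, 20 ATT and 100
CGA scores 10/130 ≈ 0.077, because exactly 10 AAT/ATT couples can form.
No trinucleotide is its own reverse complement, so there is no self-pair
case. High complementarity means many potential intramolecular pairings.

```{r complementarity}
complementarity_index(c(AAT = 10, ATT = 20, CGA = 100))
```

**Three-base periodicity (Pi).** With f(b, p) the frequency of base b at
codon position p implied by the codon frequencies, and f&#772;(b) its mean
over the three positions,

Pi = (1/3) · Σ<sub>b</sub> Σ<sub>p</sub> (f(b, p) − f&#772;(b))².

Pi is zero iff positional base composition is identical across positions
and depends only on codon counts, never on codon order. The original
formulation of this index is cited but not printed in the literature this
package follows; the positional-deviation form above is this package's
documented definition, deliberately isolated in `periodicity_index()` so
it can be swapped if a different operationalisation is preferred.

**CAI, Fop, CBI, Nc.** The four standard bias indices are computed from
their literature definitions: CAI as the geometric mean of relative
adaptiveness w = f/f<sub>max</sub> against a reference pool of highly
expressed genes (w floored at 0.01 when the reference count is zero, the
standard guard against log 0); Fop as the fraction of codons that are the
reference pool's major codons; CBI as the excess of major codons over the
uniform-usage expectation; and Wright's Nc from family homozygosities with
the 2-3-4-6 fold grouping (61 under uniform usage — 2 + 9·2 + 3 + 5·4 +
3·6 — and 20 when one codon serves per amino acid). Met, Trp and stop
codons never enter CAI/Fop/CBI. Terminal stop codons are counted in their
own 3-codon family and excluded from all sense statistics; the stop family
is analysed separately (`stop_codon_usage()`) because it shows the same
expression-linked shift as sense families despite not being decoded by a
tRNA.

**The mutational-contribution estimator.** Treating each 2-fold family's
genome-wide usage as a linear combination of a mutational force (the usage
of lowly transcribed genes) and a selective force (major-codon fraction
of 1), the mutational share of family i is

x<sub>i</sub> = (1 − fw<sub>i</sub>) / (1 − fl<sub>i</sub>),

where fw<sub>i</sub> and fl<sub>i</sub> are the major codon's fraction in
the whole genome and in lowly transcribed genes. This is the unique linear
form with x = 1 when genome usage equals the lowly transcribed usage and
x = 0 when the major codon saturates. Only the two printed boundary
conditions pin the form down, so it is implemented exactly as above, with
values outside [0, 1] (selection opposing mutation) clamped and flagged.
The overall estimate averages the nine 2-fold families. Major codons are
defined once, from the highly expressed pool, so fw and fl always refer to
the same codon.

**Expression classes.** Lowly transcribed: ≤ 0.5 mRNA/cell; moderately:
(0.5, 32]; highly: > 32. The boundary reading is low-inclusive at 0.5 and
moderate-inclusive at 32. These breakpoints delimit the regime where usage
follows the mutational background, the regime of near-linear response, and
the saturated selective regime.

**PARS codon scores.** Each codon occurrence receives two structural
scores: the mean PARS of its whole host transcript (PARS-gene) and the
mean of its own three nucleotides (PARS-nucleotide). Per-codon averages of
the former necessarily have a small spread (gene-mean assignment collapses
within-transcript variation); the spread of the latter, compared with a
codon-shuffle null that keeps every score attached to its position
(`pars_spread_null()`), measures how non-randomly codons sit in locally
structured regions. Spread is the population s.d. over observed codons,
unweighted by occurrence count (the weighting convention is not fixed by
the source literature; unweighted-over-codons is this package's choice).
Profiles must align exactly to CDS length — UTR-trimmed data are rejected,
not padded, because silent misalignment is worse than an explicit error.

## Null models

All four randomizers preserve the amino-acid sequence of every gene
(the codon-order shuffle preserves each gene's codon — hence amino-acid —
multiset) and are bit-reproducible given (input, seed):

* `simulate_neutral_genome()` — every synonymous site redrawn from global
  fractions; the neutral, expression-blind model. The stop family is
  resampled like any degenerate family.
* `shuffle_codons_within_cds()` — uniform permutation of codon order,
  preserving all count statistics; the null for local-structure questions.
* `equalize_synonymous_frequencies()` — within-gene family counts levelled
  to within one (remainders assigned to a seeded random choice of family
  members and flagged); deletes codon bias, keeps composition.
* `exchange_synonymous_identities()` — one random permutation per family
  applied identically to all genes, preserving per-gene fraction multisets
  (hence Nc) while scrambling which identity carries which frequency;
  averaged over 20 draws by default. The stop family is exchanged only on
  request, since the identity-exchange analysis targets sense codons.

`random_major_codon_null()` asks whether an observed number of mutually
complementary major codons is surprising: one codon per degenerate sense
family is chosen uniformly, and chosen codons whose reverse complement is
also chosen are counted (codons, not pairs, so the count is always even).

Randomness runs through a single seeded stream with genes processed in
input row order, restoring the RNG state afterwards. A design with
per-gene streams keyed on gene ids would make results invariant to row
reordering; R offers no splittable generator keyed on strings without
hand-rolling a hash, so the simpler single-stream design was chosen and
row order documented as part of the reproducibility contract.

## Binning and coherence

Trajectories of synonymous fractions along a gene property are built by
trimming the 0.25% most extreme values per tail (floor(0.0025·n) items per
tail; the trim convention is per-tail, the stricter of the two readings of
"0.25% of data with the highest and lowest values"), splitting the
retained range into 20 equal-width bins (right edge of the last bin
inclusive), and pooling codon counts within each bin before normalising
per family. Pooled (not per-gene-averaged) fractions match the
"frequencies in the bins" reading and weight genes by codon count.

Two properties are *coherent* when, codon by codon, the fraction
trajectory along one correlates with the trajectory along the other
(Pearson, paired by bin index, bins without data dropped pairwise;
at least 3 shared bins required). The overall call is positive (negative)
when all significant per-codon correlations share a positive (negative)
sign. The significance rule is not fixed by the source literature; this
package uses a per-codon two-sided t-test at α = 0.05 and excludes codons
with fewer than 50 occurrences under either property, both exposed as
arguments.

`windowed_codon_bias()` splits each gene's codons into contiguous
near-equal blocks (remainders to the earliest windows) and scores each
block; the windowing scheme is this package's documented stand-in for
intragene-bias protocols whose exact form varies.

## The synthetic-genome generator

`generate_genome()` draws a genome in which every analysis has a known
answer. Defaults (all in `synthetic_genome_config()`):

* **6,400 genes** with log-normal mRNA levels (log2 level ~ N(−0.5, 2)),
  giving roughly 40% lowly, 59% moderately and under 1% highly
  transcribed genes — the skew a compact eukaryotic transcriptome shows.
* **Gene lengths** of 60 + Gamma(3, scale 130) ≈ 450 sense codons on
  average, the yeast-scale CDS length. Length realism matters: in very
  short genes the single terminal stop codon mechanically couples the
  complementarity index to the three sense codons whose reverse
  complements are stops.
* **Mutational GC = 0.35** (intergenic-like); with selection off, every
  synonymous site follows `expected_fractions_from_gc(0.35)`.
* **Selection weight** s = 0 up to 0.5 mRNA/cell, rising linearly in
  log2 level to s_max = 0.9 at 32 mRNA/cell — the simplest form matching
  the three-regime description. Each synonymous site draws from
  (1 − s)·GC-fractions + s·major-spike.
* **Major codons**: a yeast-like set in which 10 of the 18 majors form 5
  reverse-complement pairs (TTC/GAA, CAA/TTG, GGT/ACC, GTC/GAC, AGA/TCT),
  so the complementarity-related behaviours are exercisable. The stop
  "major" is TAA. A design-time calculation with these defaults shows the
  expected complementarity index *decreases* with s (≈0.35 at s = 0 to
  ≈0.29 at s = 0.9): concentrating usage onto majors removes more
  cross-family couples than the 5 complementary pairs add.
* **Amino-acid composition**: uniform over the 18 degenerate families with
  Met/Trp at weight 0.01 — the analyses condition on synonymous choice,
  not on composition, so a neutral composition is the cleanest default.
* **PARS profiles** for half the genes (mirroring the roughly-half
  coverage of real structural data): score = base mean (A 0.034, C 0.844,
  G 0.026, T 0.540 — published genome-wide base means) + 0.15·log2 level
  + N(0, 0.5) noise, so gene-average structure rises with expression and
  codon scores carry composition signal.
* **Introns** in 5% of genes: length = 120 + 25·log2 level + N(0, 40) nt
  (min 30), ΔG = −0.3·length + N(0, 5) kcal/mol — folding energy is
  consumed as a precomputed input everywhere in the package, and the
  generator fabricates it from this stated linear-in-length model rather
  than folding sequences.
* **Stops**: the same s-mixture with a TAA spike, so the TAA fraction
  rises toward 1 with expression.
* **Protein** = level^1.3 × log-normal noise: protein per mRNA rises with
  transcript level.
* **tRNA table**: one anticodon per family decoding its major codon —
  Watson-Crick (the reverse complement) unless that anticodon is in the
  excluded set \{ACA, ACC\}, in which case the G:U/U:G wobble decoder is
  used (Cys TGT → GCA, Gly GGT → GCC). Only codons ending T or G can be
  wobble-decoded under this rule; real genomes also lack Watson-Crick
  anticodons for some C-ending majors, which are inosine-decoded in vivo —
  inosine is deliberately not modelled, so those cases are outside the
  generator's scope.

What the generator does *not* emulate: amino-acid composition variation
between genes, sequence homology and gene families, UTRs, alternative
splicing, real PARS noise structure (heteroscedastic, position-dependent),
and any evolutionary dynamics — codon choice is drawn i.i.d. per site
given s. Passing recovery tests on these genomes therefore demonstrates
the correctness of the estimators under the stated generative model, not
their robustness to every property of real data.

```{r generator, eval = FALSE}
gen <- generate_genome(synthetic_genome_config(), seed = 11)
estimate_mutational_contribution(gen$genes, gen$expression)
#> Mutational contribution to codon usage: 84 % (mean over 9 2-fold families)
```

The hidden per-gene selection weights are exposed via `truth_report()`;
the generator's codon-weighted mutational share (1 minus the
degenerate-site-weighted mean of s) is the quantity
`estimate_mutational_contribution()` recovers.

## Numerical choices

* Codons containing non-ACGT letters are skipped and tallied, never
  silently counted; a CDS whose length is not a multiple of 3 is a frame
  error naming the gene. Internal stop codons are counted as-is with a
  warning, since annotated CDSs are taken as given.
* Major-codon ties break alphabetically and are flagged.
* `equal_width_bins()` closes the right edge of the last bin, so the
  maximum never creates a phantom bin.
* Equalization remainders go to a seeded random choice of family members
  (the source protocol does not specify a rule) and are counted.
* Correlation of constant vectors is reported as undefined (flagged NA),
  never as 0.
* Back-calculated expression of a gene is a convex combination of the
  per-codon profile means, so predictions can never leave the profile
  range.

## Validation scale

The test suite validates the full chain on default-scale genomes (6,400
genes, ≈450 codons each, three seeds), including the 1000-replicate
codon-shuffle null for the PARS spread and a 200-replicate neutral-genome
null for the per-codon expression-profile Z-scores; unit tests run on
small genomes (≈250 genes) built by the same generator. The Monte-Carlo
major-codon test uses 100,000 replicates and is cross-checked against
exact enumeration on a reduced three-family code.

## Limitations

* The Pi definition is this package's operationalisation; comparisons with
  other software should verify the formula first.
* CAI/Fop/CBI depend on the reference pool; two analyses are only
  comparable under the same reference.
* The coherence call is a sign-consistency summary, not an effect size;
  use the per-codon table (`tidy()`) for anything quantitative.
* Identity-exchange statistics are computed from count matrices;
  returning full exchanged genomes (`keep_genomes = TRUE`) is memory-heavy
  at genome scale.
* PARS profiles must cover the CDS exactly; aligning UTR-inclusive
  profiles is the caller's responsibility.
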