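---
title: "Alignment-free SNV detection and super-population ancestry inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free SNV detection and super-population ancestry inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rootstock)
```

## The method

rootstock infers continental ("super-population") ancestry labels from a
whole-genome sample — sequencing reads or an assembly — without aligning a
single read. The pipeline has three stages.

**1. A Bloom filter of the sample's k-mers.** All canonical k-mers of the
sample (the lexicographic minimum of each k-mer and its reverse complement,
so queries are strand-agnostic) are stored in a Bloom filter: a bit array of
length $m$ with $h$ hash functions whose theoretical false-positive rate is
$(1 - e^{-hn/m})^h$ for $n$ inserted keys. The filter is sized for a target
false-positive rate (default $10^{-3}$, with $h = 3$); membership has no
false negatives. From sequencing reads, k-mers are first counted exactly and
only *solid* k-mers — those at or above a multiplicity threshold — are
inserted, which removes most sequencing-error k-mers. From an assembly (or
any other 1&times; representation) every k-mer is inserted, since single-copy
input offers no redundancy to filter on.

**2. Per-base scanning against a reference.** Every position of the
reference genome is interrogated 5'&rarr;3'. For a candidate base at a
position, the caller takes the k-mer whose 3'-most base is that position,
then slides the window start forward in steps of $j$ bases until the window
starts at the position, substituting the candidate base each time, and
queries each window in the Bloom filter. Windows running past contig ends or
containing non-ACGT characters are dropped. With $k_{ct}$ hits among
$n_q \le \lceil k/j \rceil$ queried windows, the *support fraction* is
$k_{ct}/n_q$; an alternate base is reported as an SNV when its support
fraction is at least the threshold $Y$. The same statistic for the reference
base is recorded for information only — no genotype is called. Because the
caller substitutes one base at a time, two true variants closer than $k$
bases depress each other's support and may be missed; under a Poisson model
at the human SNP density of roughly 1 per 1000 bases the probability of two
or more SNPs in one window is small (`prob_multi_snp(1/1000, 30)` &asymp;
4&times;10^-4^ through &asymp; 2&times;10^-3^ at 70 bp), so the loss has
little effect on ancestry estimates.

**3. Panel cross-referencing and label scores.** Calls are matched — on
chromosome, position, reference allele *and* alternate allele — against a
panel of known SNVs carrying an allele frequency (AF) for each of the five
super-population labels (EAS, AFR, EUR, SAS, AMR), admitted to the panel
only when AF &ge; 1% in at least one label. For each label, in a scope (the
whole genome, or one fixed-size tile):

$$S = \overline{AF} \times R_{nz}, \qquad
  \overline{AF} = \frac{1}{n}\sum_{i=1}^{n} AF_i, \qquad
  R_{nz} = \frac{\#\{\text{SNVs with } AF > 0 \text{ for the label}\}}
                {\#\{\text{SNVs with } AF > 0 \text{ in any label}\}}$$

All three quantities lie in $[0, 1]$. The global ranking of $S$ gives the
global ancestry call (GAI); per-tile, the top-scoring label is assigned to
the tile (local ancestry, LAI), and the per-label ancestry fraction is the
summed length of tiles assigned that label divided by the total length of
assigned tiles — actual tile lengths, not tile counts, so remainder tiles at
contig ends carry their true weight.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 55 | k-mer length (bases), 2–64; 16+ recommended. Larger `k` favours precision, smaller favours recall. |
| `j` | 3 | window stride (bases); `ceiling(k/j)` windows per position in contig interiors. |
| `Y` | 0.55 | minimum support fraction to report an SNV. |
| `tile_size` | 5,000,000 | LAI tile width (bases). |
| `min_count` | automatic | reads-mode solidity threshold (see below). |
| `target_fpr` | 0.001 | Bloom filter false-positive rate the bit array is sized for. |
| `min_queried` | `max(3, floor(k/(2j)))` | positions with fewer queryable windows are skipped. |

The window stride has no published default in the tools this method builds
on; `j = 3` probes about a third of the overlapping windows, balancing cost
against redundancy, and is exposed as a flag. The support-fraction
denominator is the number of windows actually queried, which keeps the
statistic in $[0, 1]$ at contig ends where the window set is truncated.

**The automatic solidity threshold.** The k-mer multiplicity histogram of
error-bearing reads is bimodal: a decaying error cluster at counts 1, 2, …
and a solid cluster around the k-mer coverage. `bloom_from_reads()` picks
the threshold one count above the histogram's first upturn. The valley-floor
bin itself is left on the error side deliberately: the error cluster decays
by a factor of roughly $\lambda/c$ per bin (Poisson), and at typical depths
that tail still accounts for essentially the whole valley bin, while the
solid cluster loses only a vanishing fraction of its mass there. A fixed
threshold can be supplied instead; at 30&times; coverage with 0.5% errors,
`min_count = 2` demonstrably admits recurrent error k-mers (two reads
sharing the same miscall at the same position are common at that depth) and
produces orders of magnitude more spurious calls than the automatic rule.

## Design choices where the design was open

* **Non-zero-rate denominator.** $R_{nz}$ divides by the number of
  cross-referenced SNVs with non-zero AF in *at least one* label (per
  scope), not by the sum of per-label non-zero counts. Both keep
  $R_{nz} \le 1$; this choice makes $R_{nz} = 1$ attainable for a single
  dominant label, so $S$ reaches its "highest-confidence" endpoint of 1.
* **Mean-AF numerator.** $\overline{AF}$ averages over *all*
  cross-referenced SNVs in scope, including those with $AF = 0$ for the
  label in question.
* **Panel matching.** A call matches a panel variant only when both alleles
  agree, not on position alone — the stricter reading of "concordant
  positions", which prevents a coincidental different substitution at a
  known site from importing that site's frequencies.
* **Ties and empty tiles.** Per-tile argmax ties are broken by higher
  $R_{nz}$, then by the fixed label order EAS, AFR, EUR, SAS, AMR, and the
  tile is flagged ambiguous. Tiles with no cross-referenced SNVs (or all
  scores zero) are left unassigned and excluded from both the numerator and
  the denominator of the ancestry fractions, and counted separately.
* **No reference pre-check.** Alternates are tested at every position
  regardless of reference-base support (the SNV mode bypasses the
  error-checking used in polishing); the reference support fraction is
  reported in the VCF as `RSF` for information.
* **Multiple alternates.** If several alternates pass `Y` at one position,
  each becomes its own VCF record.
* **Sex chromosomes and organelles** are tiled and scored like any other
  contig; no ploidy adjustment is attempted.

## The synthetic-data generator

Because the method's natural inputs (a human reference, a 1000-Genomes-style
panel, donor genomes) are large external resources, the package generates
its own, at any scale, with planted truth:

* `simulate_reference()` — uniform-random ACGT contigs.
* `simulate_panel()` — variant positions arise per base at `snv_density`
  (default 1/1000, the approximate human SNP density); each variant draws an
  ancestral frequency $p \sim U(0.05, 0.95)$ and per-label frequencies from
  the Balding–Nichols model,
  $AF \sim \mathrm{Beta}\!\big(p\tfrac{1-F}{F}, (1-p)\tfrac{1-F}{F}\big)$,
  i.e. mean $p$ and variance $p(1-p)F$ — the standard population-genetics
  model for differentiated allele frequencies, with $F$ (`fst`) a single
  knob for how hard label recovery is.
* `tile_mosaic()` + `simulate_individual()` — an admixed diploid donor:
  each tile has a source label, and each panel variant in the tile is
  genotyped as two Bernoulli($AF_{label}$) draws, one per haplotype.
* `simulate_reads()` — fixed-length reads, uniform starts over both
  haplotypes, independent per-base substitution errors.

What the generator does **not** emulate: linkage disequilibrium and
recombination-scale haplotype structure, indels and structural variants,
GC/coverage bias, long-read error profiles, and real 1kGP frequency spectra
(in particular, Balding–Nichols frequencies are continuous, so a label's AF
is almost never exactly zero and the $R_{nz}$ term is uninformative on
synthetic panels — on real panels, where rare alleles are absent from most
labels, it carries signal). Passing recovery tests on this generator
therefore demonstrates the correctness of the machinery — k-mer indexing,
scanning, cross-referencing, scoring — not performance on real cohorts.

## Numerical and degenerate-input behaviour

Bloom filter sizing uses the closed form
$m = \lceil hn / (-\ln(1 - f^{1/h})) \rceil$ rounded up to a whole byte,
with a one-byte floor. K-mers containing non-ACGT characters are skipped at
build and query time (lowercase is accepted). Positions whose reference base
is not A/C/G/T, or with fewer than `min_queried` queryable windows, are
skipped and tallied. Empty inputs, reads all shorter than `k`, panels
missing an AF key, and cross-referenced SNVs falling outside every tile are
errors. An empty scoring scope yields all-zero scores rather than an error;
an entirely unassigned tiling is an error for the ancestry fractions, whose
assigned-tile fractions otherwise sum to 1 within $10^{-9}$.

## A worked example

```{r example, eval = FALSE}
lens <- c(chr1 = 300000)
ref <- simulate_reference(lens, seed = 1)
panel <- simulate_panel(ref, fst = 0.2, seed = 2)
mosaic <- tile_mosaic(lens, 50000, c(AFR = 2 / 3, EAS = 1 / 3))
donor <- simulate_individual(ref, panel, mosaic, seed = 3)

bf <- bloom_from_assembly(donor$haplotypes, k = 31, target_fpr = 1e-4)
calls <- call_snvs(ref, bf, j = 3, Y = 0.55)
records <- cross_reference(calls, panel)
report <- infer_ancestry(records, lens, tile_size = 50000)
glance(report)    # global label, score, fractions
tidy(report)      # one row per tile
autoplot(report)  # tile track coloured by assigned label
```

The same flow runs end-to-end, with files, via `run_ancestry_pipeline()`
or the command-line driver in `inst/cli/rootstock.R`.

## Problem sizes used by the test suite

The package validates itself on genomes it simulates: unit tests use 1–100
kb contigs with exact brute-force oracles (hash-map k-mer counting, window
enumeration, per-record re-summation); the end-to-end recovery check uses a
5 Mb genome with 500 kb tiles, `fst = 0.15`, a 70/30 two-label mosaic,
assembly input and 30&times; reads with 0.5% errors — sizes chosen so the
per-tile signal (a few hundred cross-referenced SNVs per tile) comfortably
separates the planted label while the whole suite stays desk-scale. Defaults
(`k = 55`, `Y = 0.55`, 5 Mb tiles) are untouched by the tests, which pass
smaller `k` explicitly.

## Known limitations

* Labels are geographic cohort labels, not genetic ancestry; the method
  ranks label evidence, it does not model admixture explicitly.
* No indel detection, no genotype likelihoods, no base qualities, and no
  use of paired-end structure.
* Variants closer than about $Y \cdot k$ bases to each other can be missed
  (see the Poisson bound above).
* `k` is capped at 64 by the two-bit packed k-mer representation.
* Single-threaded; the per-base scan is linear in genome length with about
  $4\lceil k/j \rceil$ membership queries per position.
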