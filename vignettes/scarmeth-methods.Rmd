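---
title: "Restriction-scar single-cell methylation calling: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restriction-scar single-cell methylation calling: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarmeth)
```

## The assay in brief

scarmeth analyses single-cell DNA methylation data produced without
bisulfite conversion. A methylation-sensitive restriction enzyme (HhaI,
recognition sequence GCGC) digests a cell's genomic DNA: cleavage of a
site is completely blocked when the internal CpG is methylated on one
(hemimethylation) or both strands, while unmethylated sites are cleaved
between the third and fourth base (GCG^C), leaving 2-nt 3' "CG"
overhangs. Terminal transferase then tags every fresh 3' end with a
poly(dA) tail, and adapter-mediated quasilinear amplification carries
the tagged ends into a sequencing library. A scarred, tailed site end
therefore testifies that the site was *unmethylated* in that cell; a
site whose surroundings are read through intact testifies that it was
*methylated*; seeing both at one site implies the two alleles disagree
(heterozygous methylation, state 0.5).

Per cell and site the caller emits one of three states:

| evidence at the site | state | interpretation |
|---|---|---|
| only cleaved (scar) reads | 0 | unmethylated |
| only intact coverage | 1 | methylated |
| both | 0.5 | allele-discordant |

## Coordinate and geometry conventions

All coordinates are 0-based half-open internally; BED/bedGraph
conventions are used on disk. A recognition site starting at `p`
occupies `[p, p+4)` and its CpG `[p+1, p+3)`. Double-stranded digestion
products are represented in top-strand space: a cut at `p` yields an
upstream fragment ending at `p+3` (right end a 3' scar, terminating
`...GCG`) and a downstream fragment starting at `p+1` (left end a 5'
scar, starting `CGC...`); the shared `[p+1, p+3)` renders the 2-nt
overhang as a 2-bp overlap. This representation reproduces the anchor
coordinates of both scar flavours without modelling the two strands
explicitly.

In read space the scars appear as the 9-mers `GCGAAAAAA` (3' scar:
genomic GCG followed by the tail) and `TTTTTTCGC` (5' scar), which are
reverse complements of each other — a read sequenced from the opposite
strand of a scarred end simply swaps motif class. The calling rules are
therefore orientation-aware: a 3'-scar anchor on the `+` strand or a
5'-scar anchor on the `-` strand must equal `[p, p+3)`, and the
mirrored combinations must equal `[p+1, p+4)`. On the `+` strand this
reduces to the classical statement of the rule; the mirrored cases are
the only completion consistent with the cleavage chemistry.

## Read classification

Classification (in `classify_reads()`) searches both 9-mer motifs at
Hamming distance at most 1, with three guards:

* the 3-nt genomic core (GCG/CGC) must match exactly — it is the
  nucleotide-precise anchor that downstream matching depends on, so the
  single tolerated mismatch must fall in the homopolymer part;
* a mismatch that recreates the full GCGC recognition sequence adjacent
  to the core (e.g. genomic `GCGC` followed by an A-run) is rejected:
  such a match is an *intact* site followed by a genomic homopolymer,
  not a scar, and accepting it would convert methylated sites into
  false heterozygous calls;
* the tail side of the motif must remain at least 80% A (respectively
  T) up to the read end, emulating a k-mer filter followed by tail
  trimming.

Matches overhanging the read boundary (which approximate matchers
permit when mismatches are allowed) are discarded: all nine motif
positions must be read. A read matching both motifs is routed to the
class whose motif lies closer to its corresponding read end; exact ties
are dropped from the scar streams but, like every read, remain in the
all-read stream used for intact-site evidence. The constant adapter is
trimmed in both orientations before classification, including partial
terminal occurrences of at least 8 bp.

## Calling rules

Alignments are filtered to primary, mapped records with MAPQ >= 10.
Scar alignments are reduced to their outermost three nucleotides on the
scar side and must coincide exactly with the scar geometry above; the
reduction is computed on the *retained* (trimmed) read interval so that
motif hits inside genomic sequence cannot inherit an anchor from
unrelated read ends. Intact evidence requires an all-read alignment to
completely cover the site expanded by 1 bp on each side, `[p-1, p+5)`.
An intact candidate is discarded when a *different*, genomically
overlapping site carries cut evidence in the same cell (the
`GCGCG(A)n` configuration): complete digestion immediately next to a
fresh DNA end cannot be guaranteed, so the conservative move is to
abstain. Intact and cut evidence at the *same* site is the heterozygous
signal and is kept.

`min_evidence` defaults to 1 read per site: single-cell libraries are
sparse and the three-state call is already categorical; raising the
threshold trades coverage for robustness against alignment artefacts.
Heterozygosity requires at least one cut and one intact read at the
same site, with no binomial test — mirroring the set-overlap definition
of the assay.

## The simulator

The simulator is first-class, tested code: it generates the inputs the
caller assumes, plus ground truth, so that the full chain is verifiable
without external sequencing data.

* **Methylome truth** — each site carries one methylation bit per
  allele; the truth state is the mean of the two bits. In the default
  mode the allele-discordant fraction is set directly
  (`p_allelic_discord`); in `independent` mode both alleles draw
  i.i.d. from a per-site probability, the natural companion of
  `group_profile()`, which gives a cell *group* a shared, bimodal
  (Beta-distributed, concentration 0.6) site profile. Shared site
  profiles are what make cells of one line correlate: with independent
  per-cell methylomes, window-level Pearson correlation within a group
  would be near zero and no clustering method could separate groups.
* **Digestion** — an allele's site is cuttable only if unblocked
  (either-strand methylation blocks; optional hemimethylation blocks
  without changing the truth state) and is cut with probability
  `efficiency`. Cuts are applied left to right; a site overlapping a
  previous cut (GCGCGC runs) has no intact duplex left and cannot be
  cut. The default efficiency is 1, matching the complete digestion the
  spike-in controls of the assay support.
* **Library** — scar ends receive poly(dA) tails of 8–16 nt (at least
  6 nt are required for the 9-mer motifs to be observable), both
  molecule ends receive a constant 16-mer adapter, and each molecule
  carries a log-normal amplification factor (`amp_sigma`)
  approximating quasilinear preamplification; `amp_sigma = 0` gives
  uniform representation.
* **Reads** — merged single-end reads: each read is one sampled
  molecule (probability proportional to the amplification factor),
  whole if shorter than the read length, else a uniform window, in
  random orientation, with uniform substitution errors. The truth SAM
  records the genomic span of each read's genomic portion with tails
  and adapters as soft clips. Because reads are drawn per molecule
  rather than per base, long (methylation-rich, rarely cut) molecules
  receive lower per-base coverage — a coverage bias the real assay
  shares, and the reason intact evidence saturates more slowly than
  scar evidence.
* **SNVs and dropout** — heterozygous loci are placed outside all site
  margins with alternate bases that cannot create new GCGC
  occurrences; allelic dropout withholds one entire allele's fragments
  over the locus. The pileup shortcut (`simulate_pileup()`) models
  per-allele Poisson depth, so dropout loci run at half the expected
  depth; apparent dropout consequently decreases as the depth cutoff
  rises, for the mechanistic reason the assay observes.
* **Spike-ins** — 100 bp amplicons with exactly one recognition site
  and no tail-like homopolymer runs. The length is matched to the read
  length so that every read reports the control site; each cleavage
  event exposes two scarred ends while an intact molecule is a single
  locus, so scar coverage is halved before forming
  `efficiency = scar / (scar + intact)`, making the read-level
  estimator unbiased for the molecule-level cut fraction.

What the simulator does **not** model: PCR chimeras, adapter dimers,
per-cycle error profiles, paired-end reads (reads are post-merge
singletons), indels, context-dependent digestion at GCGCGC runs beyond
the duplex-destruction rule, and the non-blocking of overlapping
(GCGC-context) methylation, for which no quantitative model is
available. Tests passing on simulated data therefore demonstrate the
correctness of the calling logic under the assay's idealised
biochemistry, not robustness to every artefact of real libraries.

## Aggregation

Pseudo-bulk averages states per site over covering cells, keeping
sites covered in at least `min_cells` (default 5, as used with 20-cell
groups to damp coverage bias). Concordance between two cells is the
fraction of jointly called sites with *exactly* equal state, 0.5
included, with no tolerance. Metaprofiles place sites by CpG midpoint
(`p+2` — unambiguous at window edges) into fixed windows around an
anchor point, with an optional scaled-body mode that bins variable
feature interiors into a fixed number of bins. Window matrices (default
200 kb windows; 5 kb in the desk-scale studies, which use a 100 kb
reference) feed correlation clustering: average linkage on
`1 - Pearson`, the most common convention for correlation-based
clustering; pairs with degenerate variance get maximal distance. UMAP
or other embeddings are deliberately out of scope — the window matrix
is their documented input.

## Genotyping

The naive genotyper calls hom/het/hom from the alt-allele fraction
(band 0.1–0.9 exclusive) at loci with depth >= 10, the coverage floor
used for dropout estimation; a production variant caller is explicitly
out of scope. Heterozygous truth sets come either from simulator truth
or from bulk VAF tables filtered to 0.45–0.55 inclusive. The ADO
denominator is truth-het loci *genotyped at sufficient depth* — not all
truth loci — since the comparison is only meaningful where the
single-cell library was actually read.

## Numerical and design choices

* Every stochastic operation takes an explicit seed and restores the
  global RNG state (`withr::with_seed`); composite operations derive
  fixed offsets from their seed.
* Window counts must divide flanks exactly; profile anchors are feature
  starts (ends for `-` strand features, with flipped window order).
* The Gini coefficient uses the sorted-weights identity of the
  mean-absolute-difference formula, cross-checked against the explicit
  double sum.
* Degenerate inputs error early and loudly: empty genomes, all-zero
  depth vectors, fewer than 3 correlation pairs, zero-variance vectors,
  zero-overlap concordance (reported missing, never 0).
* Desk-scale study sizes — a 100 kb uniform random reference
  (~400 sites), 20 000 error-free reads per cell, 20 cells in two
  groups with mean methylation 0.8 vs 0.6, 200 spike-in replicates of
  30 molecules, and 1000 heterozygous loci at 40x — were chosen so
  every end-to-end property is exercised in minutes on one CPU while
  keeping per-criterion counting statistics (binomial confidence
  intervals) meaningful.

## Known limitations

* Recovery is scored at sites with full evidence coverage; sparse
  libraries leave sites uncalled rather than miscalled, so coverage —
  not accuracy — is the binding constraint at low depth.
* Pseudo-bulk means inherit a small negative bias (about one point of
  methylation at 10x per-allele coverage) from the molecule-level read
  sampling described above; it shrinks with depth.
* The classifier loses scar reads whose window ends 1–7 bp inside the
  adapter (partial occurrences shorter than the 8 bp minimum are not
  trimmed and break the tail-purity rule); this costs a small fraction
  of evidence, never correctness.
* Genome-scale site censuses report both overlap conventions
  (`count_sites()`), because published totals rarely state whether
  overlapping GCGC occurrences are counted separately.
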