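---
title: "Methods: plastid transcriptome profiling and C-to-U editing detection"
author: "plastoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastid transcriptome profiling and C-to-U editing detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastoscope)
```

# Scope and model

Angiosperm chloroplast genomes (plastomes) are circular molecules of
120–200 kb with a characteristic quadripartite organization: two identical
inverted repeats (IRa/IRb) separate a large (LSC) and a small (SSC)
single-copy region.  Their genes are transcribed largely as polycistronic
primary mRNAs that are then matured by cleavage, intron splicing and C-to-U
RNA editing.  `plastoscope` implements the computational side of a
transcriptome-mapping study of such a genome: given the genome, its
annotation and RNA-seq alignments, it quantifies transcription coverage,
delineates transcription units, detects editing sites with their codon
consequences, scores annotated introns as spliced or not, detects the
quadripartite structure from sequence alone, and catalogues indels between
aligned plastomes.

Every stage is paired with a simulator that generates plastome-like genomes,
transcription units, planted edits, partially spliced introns and reads with
a machine-readable truth set, so the whole pipeline is testable without any
external data.

# Editing-site calling

RNA editing in flowering-plant plastids converts selected cytidines to
uridines, mostly in mRNA coding regions.  On the plus strand of the genome
an edit on a plus-strand transcript appears as C→T read evidence; an edit on
a minus-strand transcript appears as G→A.  `call_editing_sites()` therefore
considers pileup columns whose reference base is `C` (plus-strand
candidates) or `G` (minus-strand candidates) and accepts a column as an
editing site when all of the following hold:

* read depth ≥ `min_depth` (default 10) and ≤ `max_depth` (default 2000);
* edited-base support ≥ `min_support` (default 5);
* editing frequency `support/depth` ≥ `min_frequency` (default 0.5).

Depth counts all four bases after base-quality filtering (Phred ≥ 20 by
default, applied when the pileup is built).  A site is *complete* when every
read carries the edited base and *partial* otherwise.  Only C-to-U (and its
plus-strand mirror G-to-A) is considered; U-to-C editing is out of scope.

**Orientation modes.**  For minus-strand features the edited base should
appear as plus-strand `A` (`strict` mode).  Unstranded cDNA libraries,
however, can report edited-base evidence in transcript orientation — in
published per-site count tables one intron site on a minus-strand gene
carries its support in the `U` column while others carry it in `A`.  The
default `lenient` mode therefore counts `max(A, U)` for minus-strand
candidates, which reproduces all published sites from an unstranded library;
`strict` is available for stranded data and is by construction a subset of
`lenient`.

**Codon annotation.**  For sites inside CDS exons the codon is read in
transcript orientation — exons spliced together and reverse-complemented for
minus-strand genes — the edited base is replaced by `T`, and both codons are
translated under the standard genetic code.  Pseudogenes carry no reading
frame and are reported without codon fields.

# Coverage, transcription units and splicing

`profile_coverage()` reports the consensus covered fraction (positions with
depth ≥ `cover_min`, default 1, i.e. any mapped read) and per-feature mean
depth and covered fraction; `untranscribed_features()` lists genes whose
exons are essentially uncovered (covered fraction < 5% by default).
`percent_coding()` reports the exon-union length as a percentage of the
genome.  Because conventions differ on whether "coding" includes tRNA/rRNA
genes and duplicated IR copies, both choices are exposed as flags; the
defaults (all gene kinds except pseudogenes, both IR copies) match the usual
plastome summary-table convention.

No published rule defines transcription-unit boundaries, so
`delineate_units()` uses the most conservative reading of
contiguous-transcript evidence: maximal runs of positions with depth ≥
`d_min` (default 1), optionally merging gaps ≤ `max_gap` (default 0), with
runs meeting across the origin joined — the genome is circular.  A unit's
presumed strand is the majority strand of its protein-coding members, and
each member gene is flagged *sense* or *antisense* relative to it.  This is
annotation-relative because typical libraries are unstranded; it is exactly
the inference that lets a unit spanning two minus-strand genes and a
plus-strand tRNA report the tRNA as an antisense passenger of the
polycistronic transcript.

`extract_junctions()` converts every `N` (reference-skip) CIGAR operation
into a donor/acceptor pair (the exon-adjacent bases) with pooled read
support; `score_introns()` marks an annotated intron *spliced* when a
junction matches its boundaries within `tolerance` (default 0 bp, exact),
*unspliced* otherwise, and *no data* when the intron has no read coverage at
all (when a depth vector is supplied).  Trans-spliced genes whose exons lie
on opposite strands are not representable as a single reference skip and are
out of scope.

# Quadripartite structure detection

`detect_quadripartite()` searches for the maximal pair of disjoint *exact*
inverted repeats of at least `min_ir_len` bp (default 1000).  The search
seeds on k-mer matches between the sequence and its reverse complement,
de-duplicates seeds by their anti-diagonal (a maximal inverted-repeat pair
occupies a single anti-diagonal of the comparison matrix), and extends each
candidate outward in both directions on the circle until mismatch or
collision.  Ties in length are broken by leftmost start.  Real IR pairs are
near-identical, so exactness gives a sharp, testable contract; the detected
IRb is verified byte-exact against the reverse complement of IRa before
returning.  The larger single-copy region is labelled LSC and the repeat
clockwise of it IRb, matching the conventional LSC–IRb–SSC–IRa order.
Intervals may span the origin and are then reported with `end < start`.

# Indel cataloguing

`catalog_indels()` consumes a precomputed gapped alignment (computing
whole-genome alignments is out of scope) and records each maximal gap run as
one indel relative to the chosen reference: position is the ungapped
reference coordinate of the base before the run, gap runs separated by at
least one match column are separate events, and regions are classified
through the annotation.  `indel_summary()` reports count, size range, total
and mean length — the mean both at one decimal and integer-rounded, because
published summaries sometimes round a 6.6 bp mean to "6 bp" and the package
does not force agreement either way.

# The simulator and what it does (not) emulate

`generate_plastome()` builds the genome the analysis expects at reduced
scale: default 20 kb with two exact 2 kb inverted repeats separating an
82:18 split of single-copy sequence (the LSC:SSC ratio of real plastomes),
18 genes of realistic kind mix (roughly 20% tRNA, one rRNA inside the IR and
therefore duplicated, two intron-containing genes, two pseudogenes with
planted internal stops), polycistronic transcription units covering 95% of
the circle by default, three genes left untranscribed (one protein-coding
gene and two tRNAs, mirroring the handful of silent genes seen in real
plastid transcriptomes), editing sites planted in transcribed coding exons
with fractions drawn from [0.6, 1] (plastid editing is mostly but not
always complete), and introns spliced at fraction 0.8 by default.
`simulate_reads()` samples 100 bp reads (the usual short-read chemistry)
uniformly within each unit at a mean depth of 40× scaled by mild
per-unit expression multipliers (rRNA units doubled), emits each read on a
random strand with probability 0.5 (unstranded library), plants the edited
base per read with the site's fraction, skips introns per read with the
intron's splicing fraction (producing `N` CIGAR gaps), and corrupts bases at
an error rate of 0.002.  Placements are ground truth — no aligner runs — so
every read is uniquely placed and the truth tables are exact.

Two flanking bases of each planted IR are forced to break the repeat, so
the planted coordinates are also the *maximal* exact repeat and the detector
can be held to exact recovery.

Deliberate simplifications, which bound what passing tests demonstrate about
real data: reads are single-end (paired-end adds nothing to pileup or
junction truth), base qualities are uniformly high, errors are uniform and
strand-independent, expression is piecewise-constant within a unit, spliced
and unspliced molecules are approximated per read rather than per molecule
(reads starting inside an intron are always treated as unspliced), IR flip
isomers, heteroplasmy and nuclear plastid-like insertions are not modelled,
and alignment ambiguity inside the IRs does not exist because placements
are simulated.  Results on real data additionally depend on aligner
behaviour and library artefacts that the simulator does not reproduce.

# Numerical and design choices

* Coordinates are 1-based inclusive on the plus strand everywhere
  user-facing; positions are normalized modulo the genome length because
  the molecule is circular.
* Read-level filters follow common organellar RNA-seq practice: length ≥ 30
  bp, uniquely mapped (mapping quality > 0 as the available proxy for a
  unique placement), alignment identity ≥ 90% computed as
  `1 − NM/alignment columns` from the CIGAR and `NM` tag; reads without an
  `NM` tag cannot be identity-checked and are kept with a warning, since
  SAM dialects vary.  Per-base Phred ≥ 20 is applied at pileup time; the
  boundary is inclusive (≥ 20) where sources state "quality scores > 20",
  a one-unit strictness choice recorded here and in `ingest_params()`.
* Overlapping features are resolved by the fixed priority CDS > tRNA >
  rRNA > pseudogene; no published convention exists, so the rule is simply
  deterministic.
* The editing caller's thresholds sit exactly at the published operating
  point (depth ≥ 10, support ≥ 5, frequency ≥ 0.5) and boundary cases are
  accepted, not rejected: a 10-deep column with 5 edited reads is a call.
* Problem sizes in the test-suite simulations (9–26 kb genomes, depths
  1–60×, up to 25 replicate genomes for the structure detector) were chosen
  as the smallest scales at which every recovery property is
  non-degenerate: depths ≥ 30 keep binomial sampling noise at edited sites
  well inside the caller's frequency threshold for fractions ≥ 0.6, and
  20 kb genomes leave room for ~18 genes plus a duplicated IR gene.
* Where an acceptance check needs the deposited genome and transcriptome
  accessions, the package validates against them only when the files are
  present locally; they are not bundled.

# Known limitations

The GenBank reader is a minimal flat-file parser (LOCUS/FEATURES/ORIGIN,
`join`/`complement` locations, `/gene`, `/pseudo`, `/codon_start`): enough
for plastome records, not a general GenBank implementation.  The unit
delineator is coverage-driven and cannot separate adjacent units that are
genuinely co-covered at the chosen `d_min`; with unstranded data this is a
fundamental ambiguity, not an implementation limit.  Editing detection at
sites with frequency near the 0.5 threshold is sensitive to binomial
sampling noise at low depth — at depth 10 a site edited at 60% is missed
with appreciable probability; the published thresholds inherit this
behaviour by design.
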