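---
title: "Quantifying stress-induced loss of 5' mRNA binding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stress-induced loss of 5' mRNA binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stress5p)
```

# The scientific problem

When budding yeast is starved of glucose or heat-shocked, bulk translation
shuts down within minutes, without eIF2&alpha; phosphorylation and without
loss of initiation-factor protein. The mechanism is a loss of *RNA binding*
by the scanning initiation factors eIF4A, eIF4B and Ded1: in unstressed
cells these factors sit on the 5' ends of mRNAs (the 5'UTR and the start
of the coding sequence); under stress that 5' occupancy collapses --
essentially instantaneously after glucose withdrawal, progressively over
about 16 minutes of heat shock. Three assays probe this system:

* **CRAC** (UV crosslinking and analysis of cDNA): sequencing reads whose
  crosslink-proximal end reports where on the transcript a tagged factor
  sat.
* **Spike-in RNA-seq**: mRNA abundance measured against an exogenous
  second-species spike so that *global* changes in mRNA content are
  visible, not just compositional ones.
* **SILAC TRAPP**: protein-level heavy/light ratios quantifying how much
  each RNA-binding protein remains RNA-associated over a stress time
  course.

`stress5p` implements the complete quantitative pipeline for all three,
*plus* a synthetic-data module that generates reads and ratio tables from
a known ground truth. Every statistic the pipeline produces can therefore
be validated by parameter recovery, which is what the test suite and
`scripts/acceptance.R` do.

# The binding model

Each study transcript carries two occupancy components:

* a **5' component** confined to the 5' region, operationally the 5'UTR
  plus the first 150 nt of CDS (clipped to the CDS when shorter);
* a **pervasive component** spread uniformly over the rest of the body
  (the Ded1-like pattern).

`make_binding_truth()` plants two archetypes: eIF4B-like transcripts give
the 5' component a share `fivep_share` (default 0.9) of their occupancy,
and a configurable fraction of transcripts (`pervasive_transcript_fraction`)
have the shares swapped. Per condition, each component keeps a retention
factor in [0, 1]; control and mock conditions are pinned at 1. Expected
read probabilities are the renormalized products
`abundance x (fivep_weight x fivep_retention + pervasive_weight x
pervasive_retention)`.

## Why the generator includes an rRNA-like background

Real initiation-factor CRAC libraries are dominated by ribosomal RNA
(eIF4B has a single major 18S crosslinking site; Ded1 several), with mRNA
reads a modest minority. This background matters quantitatively, not just
cosmetically. Reads-per-million normalization only measures *relative*
binding; after a stress removes most 5' occupancy, per-condition
renormalization re-inflates whatever remains. Writing the total surviving
occupancy mass as $T_s$ (control mass $T_c$), the recovered 5' ratio for a
planted retention $L$ is $L \cdot T_c / T_s$. With an mRNA-only library,
$T_s$ shrinks almost in proportion to $L$ and the recovered fold change is
badly compressed (for $L = 0.1$ the log2 error would be 0.4-2.4 depending
on the transcript mix). With a stress-stable rRNA background holding 90%
of the control library -- the realistic regime -- $T_c/T_s \le 1.09$ and
recovery is accurate to about 0.12 log2 units. The generator therefore
simulates that background (`background_share`, default 0.9) from a
dedicated rRNA-like locus, and the default RPM library size is **total
mapped reads** (tracks are "normalized to total library size"), with
transcript-assigned reads available via `normalize_binding(...,
library = "assigned")` for mRNA-restricted statistics.

A corollary worth stating plainly: on real data this pipeline, like any
RPM-based CRAC quantification, measures relative binding; absolute loss is
inferred only because the rRNA anchor is stress-stable. If that assumption
fails, fold changes are biased by exactly $T_c/T_s$.

# Read processing

Reads have layout `[3-nt random tag][6-nt barcode][insert][adapter
TGGAATTCTCGGGTGCCAAGGC][filler]` at 75 nt. Processing applies, in order:

1. **Demultiplexing** on an exact barcode match at the fixed offset; the
   random tag (UMI) is recorded and the prefix removed.
2. **Trimming**: reads with more than 2 uncalled bases are discarded; the
   maximal 3' suffix of bases below Phred 20 is removed; the adapter is
   removed at the right end -- the leftmost position where the full
   adapter matches internally or where an adapter prefix of at least 4 nt
   exactly matches the read suffix; survivors shorter than 11 nt are
   discarded. Adapter matching allows zero mismatches (a free choice; it
   keeps the rule exactly testable).
3. **Duplicate collapsing** keeps the first read of every distinct
   (UMI, sequence) pair, so PCR copies collapse while independent
   molecules with identical inserts survive via their random tags.
4. **Entropy filtering** removes low-complexity reads. For every window of
   10 consecutive bases, the Shannon entropy of the window's 6-mer
   frequency distribution is computed and normalized by
   `log(min(window - k + 1, 4^k))`; a read's score is the *maximum* over
   windows, and reads scoring below 0.5 are discarded. Reads shorter than
   the window are scored on the full read; shorter than k, they are kept;
   a window admitting a single k-mer scores 0. Max-over-windows and the
   log-normalization are this package's normative definition (the
   upstream tool's exact semantics are not published); an independent
   brute-force implementation of the same definition is the test oracle.
   Whether quality trimming preceded adapter removal in the original runs
   is equally unrecoverable; this package fixes quality-then-adapter.

With the defaults, a window passes iff it contains at least three
distinct 6-mers, which removes homopolymer and dinucleotide-repeat
contaminants at >99% while leaving error-free reads from non-repetitive
transcripts untouched (a tested invariant).

# Alignment and counting

The simulator emits error-free reads, so alignment is exact matching:
reads are seeded on their first 11 bases against a genome k-mer index and
verified over the full length, on both strands. A read matching several
loci gets exactly one, chosen uniformly at random from a seeded generator,
and is flagged (the random-assignment multi-mapper policy). BED/bedGraph
output is provided so real aligner output can be substituted for real
data; note the engine itself allows no mismatches or gaps.

Counting assigns each read to the transcript containing its
**crosslink-proximal base** (alignment start on `+`, end on `-`), sense
strand only. That base increments `total_count` and, iff it lies in the 5'
region, `fivep_count`. Single-base assignment makes every boundary case
deterministic: a read whose 5' base sits at CDS offset 150 (the 151st
coding nucleotide) is total-only. Three pseudocounts are added to both
metrics before RPM scaling; ranked target selection uses the mean
reference-condition total RPM (the top-2,000-transcripts analog), and per-
transcript fold changes are ratios of pseudocounted RPMs. The
stress-versus-mock comparison is an unpaired Welch t test on the two log2
fold-change samples.

# Metagene and pervasive-binding statistics

Start-codon profiles tally crosslink-proximal bases at offsets relative to
the first CDS base (offset 0 = A of AUG; window default -200..+499, a free
choice). The default averages per-transcript normalized vectors with equal
weight -- metagene convention, preventing dominance by strongly bound
transcripts -- and is therefore invariant to duplicating reads. Because
per-transcript normalization erases absolute loss, between-condition
comparisons of 5' signal use `scale = "rpm"`, which pools counts and
scales by library size.

A transcript is **pervasive** iff its downstream read count (total minus
5') is at least its 5' count -- an inclusive, raw-count comparison ("at
least as much binding downstream"), deliberately not length-normalized.
The pervasive fraction is taken over transcripts with at least one read.
Whether the original statistic was computed on counts or densities, and
over which transcript set, is not recoverable; counts over read-bearing
transcripts is this package's labeled choice, and the count-pair
definition makes the fraction invariant to library scale. Heatmaps bin
each transcript into 50 equal-length bins, row-normalize, and sort rows by
descending 5'/pervasive ratio.

# Spike-in RNA-seq

The spike species is fixed at 2% of the *control* study molar input and
identical in every condition, so study-wide decay raises the spike's read
share. Scale factors are share-based,

$$\mathrm{sf}(s) = \frac{\mathrm{spike}(ref)/\mathrm{study}(ref)}
{\mathrm{spike}(s)/\mathrm{study}(s)},$$

which is invariant to sequencing depth and composes exactly under
rebasing (the published analysis states only that spike counts were "used
as a normalization standard"; the share-based form is this package's
normative choice). Per-transcript RPKM times the sample's factor gives
spike-adjusted abundance; log fold changes add a pseudo-RPKM of 0.1 to
both sides to guard lowly expressed transcripts. Regulon decay defaults
emulate the study conditions: glucose starvation multiplies RP/RiBi
abundances by 0.4 (~2.5-fold loss) and other mRNAs by 0.97, totalling a
~17% drop in mRNA content; heat shock multiplies RP/RiBi by 1/16 with
other mRNAs stable, a ~23% total drop; the cycloheximide co-treatment
condition sets all multipliers to 1. Read counts are sampled
proportionally to molar abundance with uniform start positions;
per-transcript RPKM ratios equal abundance ratios under any
length-weighting, so no recovered statistic depends on that convention.

# SILAC TRAPP

Input is a long table of protein-level log2(stress/control) ratios --
MaxQuant-style output is out of scope, so a TSV contract stands in for it
-- with peptide counts and a (condition, time, replicate) grid; the
default time course is 2, 4, 8, 12, 16 min with glucose starvation in
quadruplicate. Processing: drop measurements from proteins identified
with fewer than 2 peptides; keep proteins present in at least 2
replicates at every scoped time point; aggregate replicates by the
median (the median is also what the published PCA used; whether the
2-fold classification used mean or median is unstated, and the median is
chosen for consistency). Classification at 16 min uses a strict
inequality at the 2-fold boundary ("greater than 2-fold"), so a median of
exactly 1.0 log2 units is unclassified. PCA takes the complete-case
protein set, mean-centres columns without scaling (raw log2 ratios are
already on a common scale), decomposes by SVD, and fixes signs so each
component's largest-magnitude loading is positive.

The simulator draws measurement noise as Gaussian with sd 0.1 log2 units
and missingness independently per measurement; peptide counts are
1 + Poisson(4), so ~1.8% of proteins fall below the confidence filter.
This has a visible consequence: when 22 proteins are planted with >2-fold
effects, a run occasionally reports 21 because one of them was never
quantified -- a property of the confidence filter, not a classification
error, and the recovery tests assess misclassification over the
quantified set.

# Numerical and testing choices

* All randomness flows through explicit integer seeds; every generator
  and every pipeline stage is byte-reproducible, which the suite checks
  by hashing twice-written outputs.
* Coordinates are 1-based inclusive internally (the Bioconductor
  convention of the IRanges stack this package is built on); GFF3 (1-based
  inclusive) and BED/bedGraph (0-based half-open) conversions happen at
  the rtracklayer boundary.
* Tie-breaks are fixed everywhere: transcript ranking ties resolve
  lexicographically; summit ties resolve to the smaller coordinate;
  transcript-overlap ambiguity in counting resolves by a seeded uniform
  draw.
* Degenerate inputs have defined behaviour rather than errors where a
  convention exists: zero-variance Welch input with equal means returns
  p = 1; a zero-count transcript floors at the pseudocount; an
  unscoreable (too-short) read passes the entropy filter.
* Problem sizes in the tests and acceptance script are chosen so every
  recovery has a pre-computed error budget with at least 3-sigma margin:
  CRAC recovery runs use ~50,000 transcript-assigned reads per condition
  (500,000 total at the default 90% rRNA background) over 10 transcripts;
  the pervasive-fraction run uses 100 transcripts at 50,000 reads; RNA-seq
  recovery uses 100-200 transcripts at 100,000-300,000 reads per sample;
  TRAPP misclassification is assessed over 10,000 proteins.

# What the synthetic data does and does not show

The generator reproduces the *statistical* structure the pipeline
measures: mixture binding with condition-specific retention, PCR
duplication, low-complexity contamination, a two-species read pool with
molar spike-in, regulon-specific decay, and a replicated, partially
missing SILAC grid. It deliberately omits sequencing errors, antisense
reads, introns, paired ends, isoforms, overlapping genes and
peptide-level quantification. Passing recovery tests therefore
demonstrates that the *computations* are correct and unbiased under the
stated model -- not that the pipeline is robust to alignment artifacts,
splice isoforms or search-engine quirks in real libraries. For real data,
the alignment stage should be replaced by a production aligner (BED import
is provided), and the mismatch allowance of that aligner is the user's
responsibility.

# Session info

```{r}
sessionInfo()
```
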