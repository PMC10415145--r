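---
title: "Somatic structural variant calling from paired long reads: methods and design"
author: "svlr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic structural variant calling from paired long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Somatic structural variations (SVs) in a tumor must be separated from the
far more numerous germline SVs the patient carries and from alignment
artifacts. Calling SVs separately in tumor and matched control and
subtracting the call sets is fragile: a germline SV that passes the
detection threshold in the tumor but narrowly misses it in the control
(for instance because of lower control coverage) surfaces as a false
somatic call. `svlr` therefore genotypes tumor and control jointly: the
control is examined for *raw read evidence* at each tumor candidate, at
thresholds far more permissive than the tumor-side detection thresholds,
and every surviving candidate is re-genotyped read-by-read in both samples
before it is reported.

Two rearrangement shapes are handled by two modules:

* **Canonical SVs** - two locatable breakpoints plus any inserted sequence
  between them (deletions, duplications, insertions, inversions,
  translocations).
* **Single-breakend SVs** - only one breakpoint is locatable; the partner
  sequence (centromeric satellite, telomere, mobile element, virus) cannot
  be placed uniquely on the reference. These are detected from long soft
  clips and characterized by classifying the polished beyond-breakpoint
  contig.

## Canonical SV module

**Parsing.** Per-read junction signals come from two sources: deletion and
insertion CIGAR operations, and adjacent pairs of split-alignment segments
of the same read (primary + supplementary records, ordered by their query
intervals in the read's own orientation). Each signal is an oriented
breakpoint pair. The direction convention used everywhere in the package:
at `(chrom, pos, dir)`, `+` means the adjacency retains the reference up
to and including `pos` and leaves rightward; `-` means `pos` is the first
retained base. Indel signals are parsed down to 50 bp - half of the 100 bp
reporting threshold - so that candidates whose noisy per-read size
estimates straddle the boundary still reach the refinement stage, which
recovers the true size.

**Clustering and control subtraction.** Signals sharing the chromosome and
direction pair cluster by single linkage with a 200 bp margin; clusters
with fewer than 3 distinct reads are dropped. Control (and optional
panel-of-normals) signals are parsed at 25 bp / 1 read and any match
within 200 bp of both breakpoint ranges removes the cluster. The
asymmetric stringency is deliberate: sensitivity for germline evidence in
the control costs nothing, whereas a missed germline match becomes a false
somatic call.

**Refinement.** The junction-spanning portions of the supporting reads
(300 bp each side of the junction, clipped at read ends, oriented to a
common frame) are polished into a consensus: the centroid segment (highest
summed pairwise alignment score over a deterministic subset) is chosen,
all segments are aligned to it with a banded ends-free alignment, and a
per-column majority vote - gap votes included, insertion slots voted as
strings with votes pooled over adjacent slots, since alignment ambiguity
can place the same inserted base one column left or right - produces the
polished sequence. Two rounds are run, the second against the first
round's output. This replaces an external polisher with a self-contained
procedure whose contract (error-corrected junction sequence) is what the
pipeline actually needs; it is not a reimplementation of any particular
tool.

The consensus is then aligned to the two candidate reference windows with
a Smith-Waterman variant that permits a *one-time jump*: layer 1 is a
local alignment against window 1; at any query position the dynamic
program may carry the best layer-1 prefix into layer 2 (window 2), paying
`jump_penalty + per_inserted_base * k` for `k` skipped query bases, which
become the inserted sequence at the junction. The jump cell recurrences
only enter and leave in match states - under negative gap costs an optimal
alignment never ends in a gap, so this loses nothing and keeps the
endpoint semantics exact. The reported score also covers the two no-jump
alternatives, so it is never below a plain local alignment against either
window alone; the refinement itself requires an actual jump with at least
50 aligned bases on each side. Junction micro-homology makes the optimal
split non-unique; ties resolve to the *latest* layer-1 end (maximal
attribution to breakpoint 1) and the homology length is reported.

Scoring defaults are `match 2, mismatch -4, gap open -4, gap extend -2`
(a gap of length k costs `open + k * extend`), with a free jump and free
inserted bases. These mirror common long-read local-alignment practice and
are configuration-exposed, as the optimum is not sensitive to them at the
error rates involved. Two deliberate choices differ from a naive setup:

* Reference windows are padded by the *extraction flank plus* the 200 bp
  refinement pad. The consensus carries 300 bp of flank by construction;
  a window padded by less would truncate alignable flank and bias the
  breakpoint inward.
* The minimum acceptable jump score is a fraction (0.6 of the maximal
  match score) of the *aligned* query length, not of the whole query.
  For insertion candidates most of the consensus is inserted sequence
  that by construction aligns to neither window; a whole-query threshold
  would reject every long insertion.

**Validation.** From the refined breakpoints the putative SV segment is
rebuilt: 300 bp of reference approaching breakpoint 1 (per its
direction), the inserted sequence, and 300 bp leaving breakpoint 2
(reverse-complemented when the direction demands). Every read overlapping
either breakpoint in tumor and control is aligned against the SV segment
and against contiguous reference segments spanning each breakpoint;
scores are normalized by twice the shorter sequence length. A read is a
*variant read* iff its normalized SV-segment score exceeds the best
reference score by 0.05 *and* the alignment spans 50 bp on both sides of
the junction; the reverse condition gives a *reference read*; anything in
between is *ambiguous* and counts for neither allele. The ambiguous class
is an addition over a binary rule: reads barely overlapping the junction
otherwise contaminate both counts. Candidates with at least 3 tumor
variant reads and 0 control variant reads survive. Finally, deletions and
insertions under 100 bp are removed, as are deletions and insertions with
both breakpoints inside one simple-repeat interval (padded by 10 bp) -
the operationalization of "confined within a simple repeat".

## Single-breakend module

Soft clips of at least 500 bp whose clipped sequence is not explained by a
split alignment start breakend signals; the clip is normalized
junction-outward. Clustering uses a tighter 50 bp margin (soft-clip
positions are much less dispersed than indel evidence). Consensus inputs
are the clips prefixed by 100 bp of aligned sequence inside the
breakpoint; polishing reuses the canonical consensus machinery with two
rounds. A plain local alignment of the contig against the reference
window fixes the breakpoint at single-base resolution, and validation
reuses the read re-genotyping with the same 3/0 rule, the putative
segment being reference flank + contig.

Classification follows a fixed priority: (1) breakends within 200 bp of
an already-called canonical breakpoint are duplicates and are dropped;
(2) a contig aligning uniquely to the reference over at least 80% of its
length is *rescued* into a canonical record - the implied partner
breakpoint is derived from the placement and the record must pass the
full canonical validation; (3) contigs at least 60% covered by satellite,
simple-repeat, or telomeric `(TTAGGG)n` annotation take those classes;
(4) a LINE1 (or Alu) match of at least 200 bp at the contig start,
followed by a remainder aligning uniquely at least 10 kb away, gives
`L1Mediated` / `AluMediated`; (5) a virus match of at least 200 bp gives
`VirusMediated`; (6) otherwise `Unclassified`. The numeric cutoffs
operationalize a qualitative decision chart and are all
configuration-exposed. Annotation is a provider interface: the built-in
local-alignment annotator runs against any `name#class` consensus
library, and a RepeatMasker `.out` reader can substitute for it.

Uniqueness of a genome placement is decided by seed-and-extend: sampled
k-mers (k = 17, every 29 bp) are located exactly on both strands,
clustered by alignment diagonal, and the placement is unique when the
runner-up diagonal cluster at a genuinely different locus collects fewer
than half the seed hits of the best.

## Insertion classification

Full-length inserted sequences of at least 100 bp are classified in fixed
order: transcript match covering 80% of the insert and spanning at least
2 exon junctions (to exclude retained-intron fragments) gives
`ProcessedPseudogene`; a single mobile-element family covering 80% (polyA
tail excluded from the denominator) gives a solo class; otherwise the
largest unannotated block is placed on the reference - adjacent to the
insertion site (within 1 kb) it is a `TandemDup`, downstream of a LINE1
source element (strand-aware, within 10 kb; "downstream" has no stated
bound in the field, 10 kb covers reported transduction tract lengths) it
is a `PartneredTransduction` when LINE1 sequence is also present in the
insert and an `OrphanTransduction` otherwise.

Structural features:

* **5' inversion (twin priming)**: the insert decomposes into a 5'
  antisense segment and a 3' sense segment against the element consensus,
  query-adjacent, with the antisense consensus interval upstream-adjacent
  to or overlapping the sense start; the internal consensus loss between
  the segments is reported. A fully antisense insert is a strand
  orientation, not an inversion.
* **polyA tail**: longest run in the 30 bp terminal window with A-fraction
  at least 0.8 and length at least 10, enumerated over all substrings that
  begin and end with the base (so `AAAAAGAAAAA` qualifies while a 9-base
  pure run cannot borrow a flanking base to reach the threshold).
* **Target-site duplication**: at an insertion the two refined breakpoints
  overlap on the reference; the TSD is the span between them, length
  `pos1 - pos2 + 1`, reported between 5 and 50 bp. A blunt junction has
  `pos2 == pos1 + 1`. (The length convention is fixed by the breakpoint
  convention above - `pos2` is the first retained base - and is applied
  consistently in the generator and the detector.)

Transduction events group by source element; events whose source is
itself a somatic LINE1 insertion call are flagged as nested
transductions.

## Higher-order repeat score

Satellite-classified contigs are decomposed into monomer blocks: the
contig is tiled left to right, each boundary fitted with every monomer by
an end-free global alignment (so a trailing monomer may be truncated),
the best-scoring monomer claiming the block; stretches under 50% identity
become gap blocks. Both orientations are tried and the better tiling is
kept. The decomposition is a greedy boundary-chained tiling rather than a
full automaton; on arrays whose monomers are as divergent as
alpha-satellite monomers (tens of percent apart) the greedy and exact
tilings coincide, which the exactness tests exercise.

For each block whose predecessor relationship is consistent with the
chromosome's canonical cyclic monomer order, `(end - start) * identity /
100` is added, and the sum divided by the contig length is the HOR match
score. The first block is always consistent (it has no predecessor -
declared, since the alternative of skipping it makes a perfect array
score below 1); gap blocks contribute nothing and break adjacency. The
profile over all chromosomes' catalogs yields a best chromosome and an
interchromosomal flag when it differs from the breakend's chromosome; no
call is made when the best score is under 0.3.

## The synthetic data generator

The generator exists so that the entire pipeline is testable with exact
truth and no external aligner or download. A haplotype is an ordered list
of blocks over the reference (forward slice, reverse slice, or novel
insertion); injected SVs - deletions, insertions (with TSD), tandem
duplications, inversions, translocations, single-breakends with foreign
sequence, and MEI classes built from the packaged synthetic consensus
library - edit this block structure, so every read's true alignment is
known by construction. Reads are drawn per haplotype, mutated at the
requested error rate (40:30:30 substitution:insertion:deletion, each
event 1 bp), and emitted directly as alignment records: contained
deletions/insertions become D/I CIGAR operations, strand flips and
back-jumps split the read into primary + supplementary records with
mutually consistent SA tags, foreign single-breakend sequence becomes a
soft clip, and target-site duplications are absorbed into the insertion
operation exactly as a real aligner represents them. Translocations are
modelled as an extra derived fusion segment (25 kb each side of the
junction) so that coverage elsewhere stays balanced under chained events.

The default study conditions - two 1 Mb chromosomes, 40 somatic SVs (10
each of deletion, insertion, inversion, translocation; 150-5000 bp), 10
germline SVs shared by both samples, 30x coverage per sample at 10%
read error, gamma-distributed read lengths with 8 kb mean - are the
conditions the acceptance checks run at. They scale the published
evaluation design (whole-genome simulation with hundreds of events at
30-50x) down to desk size while keeping the quantities that drive caller
behaviour: per-junction support ~15 reads per haplotype, error rate at
the high end of Nanopore-like data, and event sizes straddling every
filter boundary.

What the generator does **not** emulate - and hence what passing tests do
not show about real data: basecaller-specific error profiles
(homopolymer-biased deletions are off by default), mapping ambiguity in
genomic repeats (the random background is unrealistically mappable),
chimeric library artifacts, coverage waviness, and subclonal tumor
heterogeneity (somatic events sit on one haplotype at ~50% VAF). The
repeat/virus consensus library and the centromere monomer catalog are
synthetic sequences generated under fixed internal seeds - they make
classification tests self-consistent but carry no biological sequence;
real analyses must supply real libraries.

## Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; 1-based appears only at
  the SAM/VCF boundary. Breakpoint convention as above; this pins down
  which base a TSD includes and what "blunt" means.
* Alignment scores are integers internally; endpoint coordinates come
  from lean score-only passes, with starts recovered by an anchored
  extension pass over reversed prefixes.
* Clusters with a single usable segment pass through unpolished; a
  consensus whose inputs disagree with the centroid below 80% mean
  identity marks the candidate as a discordant mixture and drops it.
* Candidates whose breakpoint falls within a flank of a chromosome end
  keep a truncated segment and are flagged.
* Ties: cluster order is genomic; consensus base votes break toward the
  centroid's base; insertion-slot votes take the modal string; jump
  splits resolve to maximal breakpoint-1 attribution.

## Problem sizes used by the test suite

The acceptance checks run the full study conditions above (about 120 Mb
of simulated read bases through the complete caller), 1000 random
jump-alignment instances against an exhaustive enumeration oracle, 100
consensus replicates, and the constructed classification panels. Module
tests use smaller genomes (50-200 kb) chosen so each property is
exercised with the smallest input that makes it non-trivial.

## Known limitations

* The caller assumes split alignments carry full read sequence in
  supplementary records (minimap2's `-Y` behaviour); hard-clipped
  supplementaries contribute signals but not junction segments.
* Insertions longer than the read length cannot be spanned and are not
  recovered; there is no local assembly across the unalignable side of a
  single breakend.
* VAF is a point estimate; no confidence intervals, no subclone model.
* The greedy monomer tiling can differ from an exact maximum-weight
  tiling on monomer sets with near-identical members.
* Phasing, multi-sample joint calling beyond tumor/control/panel, CRAM
  input, and repeat-expansion genotyping are out of scope.
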