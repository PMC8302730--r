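---
title: "Separating conspecific strains from long-read metagenome assemblies"
author: "strainsep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating conspecific strains from long-read metagenome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

strainsep treats strain separation as iterated diploid haplotype phasing.
A *strain* is operationally a bacterial haplotype: a contiguous sequence
of nucleotides jointly supported by reads at sufficient abundance.  The
input is a *strain-oblivious* assembly — contigs in which an upstream
assembler collapsed conspecific strains into consensus — and long reads
aligned to it.  Three assumptions drive everything downstream:

* **Collapse is conservative.**  Strains of the same species land on one
  backbone contig; the strain signal survives as dense columns of
  single-nucleotide variants (SNVs) in the read pileup.
* **Reads span many SNVs.**  At ~1% divergence a 6 kbp read covers ~60
  SNV sites; even at a 10% sequencing error rate the read is orders of
  magnitude closer to its own strain's allele vector than to the other
  strain's, so assignment by Hamming distance is nearly error-free.
* **Two haplotypes at a time.**  Phasing is strictly diploid; a mixture
  of `n` strains is peeled apart over at most `n − 1` rounds, each round
  splitting the most divergent signal from the rest.

## SNV detection

For each backbone contig, aligned bases of primary records are piled up
per column.  A column becomes a biallelic SNV when total depth
≥ `min_depth` (10), the backbone base and the most frequent non-backbone
base each have ≥ `min_per_allele` (5) reads, and the alternate fraction
is ≥ `min_alt_frac` (0.2).  The per-allele floor is the guard that
matters at long-read error rates: with ~6% substitution errors spread
over three alternate bases, a spurious allele rarely reaches 5 reads and
a 20% fraction simultaneously, while a real strain at ≥ 10× does.  Only
substitutions are used; indel variants are ignored (they are the
dominant long-read error mode, and the separation signal in SNVs is
sufficient).

## Phasing and phasesets

The read × SNV allele matrix is sparse: an entry exists only where a
read's alignment spans a site and shows the ref or alt base (third bases
and deletions are *missing*).  Phase blocks break wherever no single
read holds alleles at two consecutive sites.  Within a block the
bipartition is found greedily:

1. seed haplotype 1 with the read covering the most sites;
2. extend outward from the seed — remaining reads are processed by
   decreasing overlap with the already-phased region (an outward sweep
   by start/end position), each assigned to the nearer haplotype and
   immediately voting on its sites;
3. two refinement sweeps reassign every read against the fixed majority
   haplotypes, then rebuild the votes.

The extension order is load-bearing.  Scoring reads against a static
order (e.g. by coverage alone) lets ties — which are systematic when
three or more strains are collapsed, because a read of strain B is
equidistant from "strain A's pattern" and its complement — cascade into
locally incoherent bipartitions.  Sweeping from the seed keeps a locally
consistent pattern that reads of the matching strain continually
re-anchor.  All ties are deterministic: equidistant reads stay untagged
and cast no vote, tied site votes default to the reference allele, and
read order ties break lexicographically, so the phasing is reproducible
without randomness (the `seed` argument is accepted for interface
stability).

Haplotype 2 is the complement of haplotype 1 at every site, as in
diploid genotypes: both alleles were observed at every retained site, so
a het call `0|1` is implied.  The objective reported per block is the
MEC — the number of allele entries that must be flipped for every read
to be consistent with one haplotype — and on instances small enough for
exhaustive search the greedy result is checked against the true minimum
in the test suite.

A block becomes a *phaseset* `PS = (i, s, e)`: the interval of backbone
contig `i` from the first to the last phased SNV, with density
`dens(PS) = 100 · #SNV / (e − s + 1)` percent.  Phasesets with
`dens < min_dens` (0.1%, strict `<`, so exactly 0.1% is retained) are
discarded.  This single filter is the divergence floor: strains more
than ~99.9% identical are deliberately not separated, and a handful of
false-positive SNVs cannot fragment a contig.

## Haplotype assembly

Reads overlapping a retained phaseset are split into h1 / h2 / untagged
by minimum Hamming distance (ties untagged).  Each tagged set is
assembled by a coordinate-anchored column consensus over its existing
alignments: per backbone column, the majority base; a deletion when
> 50% of covering reads delete; the most frequent insertion when > 50%
insert after the column.  Contigs split where coverage drops below
`min_cov` (3) — below three reads a majority vote is meaningless.
Because every consensus base carries its backbone anchor, trimming to
`[s, e]` is exact; contigs from an external assembler (hook:
`external_assembler`, a command template; the published pipeline used
wtdbg2 with `-e 5 -l 1000 -L 3000 -S 1 -R`) lack anchors and are trimmed
through a local alignment against the backbone window `[s − 10 kbp,
e + 10 kbp]`, dropped with a warning when fewer than half their bases
align.  Trimming exists because separated-read coverage decays outside
the phaseset, making the consensus unreliable exactly where reads were
no longer constrained by phased SNVs.

Unphased backbone stretches strictly longer than `min_unphased_len`
(500 bp) are retained as shared contigs; together with the haplotype
contigs they form the strain-aware contig set, every contig stamped with
its origin contig, interval and haplotype.

## Scaffolding

The original reads are re-aligned to the strain-aware contigs
(minimap2, preset `map-pb`/`map-ont`).  Primary records with mapping
quality strictly greater than `min_mapq` (40) whose shape joins a contig
end to a read end — allowing an unaligned overhang of at most
`min(max_overhang = 50 bp, overhang_frac = 10% of the match length)` on
both sides of the junction — are dovetails.  A read with one prefix- and
one suffix-dovetail to two different contigs supports a bi-directed edge
(arrow away from a vertex when the contig suffix is involved, toward it
for the prefix).  Edges are admitted only between (i) consecutive
contigs on one backbone, (ii) adjacent haplotype contigs (no phaseset
between them), (iii) an unphased piece and a haplotype contig linked by
the read, or (iv) two contigs on backbone extremities (within
`end_window` = 1 kbp of an end, a window the published description
leaves unstated).  Parallel haplotype contigs of the *same* phaseset
share an identical origin interval and are never treated as consecutive
— an edge between them would join the two alternative haplotypes into
one molecule.

Simplification removes transitive edges (a two-edge path with matching
outer arrows and a traversable pass-through at the middle vertex,
evaluated against the original edge set so the result is independent of
edge order) and weak edges (< `weak_edge_min_reads` = 10 supporting
reads, or < `weak_edge_frac` = 90% of the total support of a vertex
side).  Two readings of the 90% rule are possible; strainsep compares an
edge against the side total *including itself*, and treats the two sides
of a vertex as independent pools, which is what the bi-directed arrows
imply.  Note this removes both edges of an even split — conservative, and
consistent with such forks being untraversable anyway.

Scaffolds are maximal unambiguous paths: only edges that are unique at
both their endpoint sides are traversable, cycles are broken at their
lowest-weight edge with a warning, and path walks start preferentially
through suffix sides so that flipping every contig's orientation yields
reverse-complement scaffolds.  Gaps take the lower median (gaps are
integer base counts; no interpolation) of the per-read distance samples
— read bases strictly between the two dovetail alignments, negative when
they overlap — and non-positive medians give a direct join.  Outputs:
FASTA, AGP 2.1, and a GFA 1.0 dump of the simplified graph.

## Iteration

After a round, reads are re-aligned to the scaffolds and a tentative
re-phasing is scored by the Hamming rate: per read and phaseset, the
mismatching fraction of shared SNV positions against the closer
haplotype, computed only for reads overlapping the phased region by at
least `hamming_min_overlap` (3000 bp — shorter overlaps share too few
sites for a stable rate).  Another round runs only while the global mean
rate improves by at least `improvement_frac` (1%) *relative* to the
previous round ("1% of the previous value", i.e. `current ≤ 0.99 ·
previous`), and re-separation is applied only to sequences whose local
mean rate satisfies the same rule; sequences absent from the previous
round are eligible by convention.  The baseline rate comes from the
tentative phasing of the input assembly, before any separation.  At most
`max_strains − 1` rounds run (default `max_strains` = 5, the largest
strain count the method is intended for).  Unsplit whole contigs keep
their names across rounds so the local rule can compare them; re-split
scaffolds are new sequences.

# The synthetic community generator

The generator emulates the conditions under which strain separation is
studied: 2–5 conspecific strains derived from a common ancestor by
uniform random substitutions at a chosen divergence (0.1–3% is the
regime of interest), per-strain fold-coverages of 5–80×, and PacBio-like
reads — gamma-distributed lengths with mean 6100 bp and SD 3700 bp
truncated at 500 bp, per-read identity drawn from a beta distribution
with mean 0.90, SD 0.03, capped at 0.97, and errors split 60/20/20
between substitutions, single-base insertions and deletions.  Strain 1's
genome doubles as the backbone, standing in for the collapsed consensus;
with substitution-only divergence all strains share its coordinate
system, so the generator can emit *exact* truth alignments (position,
strand, and the CIGAR implied by the injected errors) and every pipeline
stage is testable without an aligner in the loop.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data:

* a fragmented or erroneous backbone.  Real strain-oblivious assemblies
  degrade sharply below ~20× pooled coverage; here the backbone is
  perfect at every coverage, so low-coverage behaviour reflects the
  separation stages only.  This is why the 10× rung of the coverage
  ladder separates far better here than degraded-input studies report;
  the 5× rung, where SNV calling itself runs out of depth, is the first
  point of failure under these conditions.
* structured error profiles (homopolymer indels, chimeras, junk reads),
  uneven coverage, inter-strain structural variation or recombination
  tracts, and indel divergence between strains.  Nanopore-skewed indel
  profiles can be approximated by lowering `mean_identity` and are
  exposed as parameters rather than guessed.

# Numerical and design choices

* Coordinates are 0-based half-open internally; VCF output is 1-based
  with phased `GT` and `PS` = phaseset start.
* Degenerate inputs: an empty separated read set assembles to nothing
  with a warning; a contig absent from the backbone errors; a zero-depth
  contig yields no SNVs; an assembly with no retained phaseset passes
  through unchanged, byte-identical.
* Determinism: the pipeline core is deterministic (all ties broken
  lexicographically); simulation randomness is fully driven by `seed`
  through R's RNG, and the RNG state of the caller is restored.
* minimap2 is the default aligner hook for read-to-contig, re-alignment,
  and contig-to-reference alignment (`-x asm20`, one run per reference
  so each contig/reference pair is chained independently); any aligner
  producing PAF/SAM, or MUMmer `show-coords` tab output via
  `read_coords()`, can be substituted, since every operation consumes
  alignment tables.
* The evaluation assignment rule — a contig belongs to the reference
  maximising alignedBases × averageIdentity among references covering
  ≥ 50% of it — counts the union of *all* alignment blocks to a
  reference, not just the best chain; ties break to the
  lexicographically smaller reference id.

# Problem sizes in the test suite

Unit tests run on hand-built alignments and 20–150 kbp communities; the
acceptance suite uses the full study conditions (1 Mbp genomes, 50× per
strain, with a 5–30× ladder and 0.05%/0.5% divergence floors).  A
three-strain 150 kbp community exercises the iterative loop end to end
(two rounds).  These sizes were chosen so the whole suite, including the
end-to-end runs, completes in minutes on a single CPU while keeping
every rate (coverage, divergence, read length, identity) at its
full-scale value.

# Known limitations

* Diploid-only per round: `n` equally abundant strains need `n − 1`
  rounds, and intermediate consensus of still-mixed groups can be a
  hybrid until a later round separates it.  Very uneven strain ratios
  push the minority strain below the allele-count floor.
* The divergence floor (~0.1% SNV density) is a feature, not a bug —
  near-identical strains are left collapsed by design.
* No plasmid-aware handling, no polishing, and no misassembly
  classification; the evaluation module reports coverage/ANI/NG50/
  duplication and delegates misassembly calling to external evaluators
  whose output can be ingested.
* Scaffolding resolves unambiguous adjacencies only; repeat-induced
  forks are left unjoined rather than guessed.
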