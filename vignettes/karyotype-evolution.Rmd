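---
title: "Tracing chromosome-number evolution in budding yeasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing chromosome-number evolution in budding yeasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyevol)
```

## The problem

Saccharomycetaceae yeasts carry *point centromeres*: short,
sequence-defined elements of three parts — an 8 bp CDEI motif, an
AT-rich CDEII spacer of species-characteristic length, and a 26 bp
CDEIII motif containing an invariant CCGAA core. Because every
chromosome needs exactly one centromere and two telomeres, any change
in chromosome number must leave a footprint at these loci. A
whole-genome duplication (WGD) in this family doubled the ancestral
set of 8 chromosomes to 16; extant post-WGD species carry 10–16
chromosomes and non-WGD species 6–8, so chromosomes have been lost
repeatedly and independently.

karyevol implements the comparative machinery needed to reconstruct
how: detecting point centromeres in DNA, mapping extant centromeres
and telomere locations back to an ancestral gene order by shared
synteny, tracing rearrangement breakpoints into reuse cycles, and
classifying the mechanisms that changed chromosome number —
telomere-to-telomere fusion with the death of one centromere,
centromere fission with arm capture by other telomeres, and WGD.
A seeded karyotype-evolution simulator generates ancestors, event
histories along a species tree and extant genomes with ground-truth
logs; it is the test bed against which every inference stage is
validated.

## Data model

A `Genome` holds one species' gene order (one row per gene: id,
ancestral *pillar* id or `NA`, chromosome, 1-based index, orientation,
subtelomeric flag), its point-centromere annotations (an intergenic
position `pos` in `0..n` meaning "between gene `pos` and `pos+1`",
strand, and the CDEI/CDEII/CDEIII sequences when known), and
optionally chromosome DNA as a `DNAStringSet`. Pillars are
ortholog/paralog columns tying genes across species to the ancestral
gene order; they are the unit of all synteny comparison. Telomere
locations are treated as *locations, not sequences*: the telomere of a
chromosome end is the location beside its outermost pillar-bearing
gene, and the pillar-less genes beyond it form the subtelomeric zone.

Gene indices are 1-based and DNA spans 1-based closed, following R and
Bioconductor convention; the intergenic coordinate keeps its natural
"0 = before the first gene" anchor so that centromere positions and
breakpoints live between genes without off-by-one arithmetic.

## The simulator

`makeAncestor()` builds an 8-chromosome ancestor with 50 genes per
chromosome, 4 pillar-less subtelomeric genes at each end, and one
centromere per chromosome at the mid-chromosome intergenic. These
defaults emulate the scale of the reconstructed pre-WGD yeast genome
at roughly one tenth of its gene count, which keeps every simulation
and test fast while leaving dozens of pillars per chromosome arm for
synteny evidence.

Centromere elements are sampled from an IUPAC-degenerate profile:
CDEI is `NNCAVBTG` (four invariant positions, 3/4/7/8), CDEIII is a
26 bp T-rich/A-rich profile with the invariant `CCGAA` core planted at
positions 13–17, and every degenerate position is uniform within its
allowed base set. Within-set uniformity has a useful consequence:
every sampled element scores exactly the model maximum under log-odds
scoring, so the scanner's recall on unmutated planted centromeres is
structural, not statistical. CDEII lengths are drawn per species
(mean uniform in 40–90 bp, the stated twofold cross-species range)
with a within-species standard deviation of 2 bp, truncated at three
standard deviations; the AT fraction is drawn per centromere in
0.76–0.98. Background DNA is 60% AT. None of these per-position
frequencies beyond the invariants are taken from any published
profile; they are the generator's own study conditions.

The event engine (`applyEvent()`) is pure and operates on gene order
plus centromere annotations: WGD, reciprocal translocation, inversion,
telomeric translocation, telomere-to-telomere fusion with centromere
loss, centromere fission (the split chromosome's two arms immediately
fuse to telomeres of two other chromosomes — a single logged event,
since the order of breakage and centromere loss is not observable
afterwards), gene loss, and bare centromere loss. Chromosome DNA is
generated for ancestor-stage genomes and standalone intergenic
fixtures; rearranged genomes drop their sequences, because every
sequence-level analysis the package performs (scanning, consensus
building) operates on ancestor or intergenic sequences.

Random event placement runs in *no-reuse mode*: breakpoints fall only
on ancestrally intact adjacencies flanked by two further intact
adjacencies per side, and never on a centromeric intergenic. This
guarantees that scheduled event counts are exactly recoverable.
Breakpoint reuse is constructed deliberately by
`makeReuseFixture()`: a nine-translocation pathway chained around one
centromere (each event re-breaks the previous event's novel junction,
so eight breakpoints are reused), and a four-translocation closed
cycle with three breakpoints at ancestral centromeric intergenics.

What the simulator does *not* emulate: nucleotide substitution outside
the centromere elements, gene family expansion in subtelomeres,
scaffold-level assembly noise, and within-population dynamics. Tests
passing on simulated data therefore demonstrate algorithmic
correctness under clean annotation, not robustness to annotation
error in real genomes.

## Centromere detection

`buildConsensus()` tallies position frequency matrices for CDEI and
CDEIII from fixed-width annotations (widths 8 and 26 are enforced
throughout; published boundary choices differ slightly between
genome projects, and a fixed delineation keeps positions comparable).
A position is called invariant only when a single base carries 100%
of the pre-pseudocount counts. IUPAC letters cover at least 95% of
the count mass with the smallest sufficient base set.

`scanCentromeres()` scores both strands with log-odds matrices
(pseudocount 1 per base per position, uniform background by default —
training sets of 8–16 centromeres per species are too small to
estimate much more) and requires the full collinear structure: CDEI
and CDEIII windows each at ≥ 60% of their maximum achievable bits, a
spacer inside the model's CDEII length window with AT above the model
floor, all on one strand. The 0.6 threshold was fixed by a
false-positive calibration on unplanted background windows (0
candidates in ≥ 99% of seeded trials) while leaving unmutated planted
elements (which score at the maximum) untouched. The reported score
adds a spacer term — each CDEII base scored under an AT-rich
composition against the background — so that a chance CDEI octamer
just outside a real centromere, which would otherwise tie the true
parse, loses to the compact true structure on sequence evidence.

One ambiguity cannot be resolved within a single sequence: a chance
CDEI match *inside* a GC-streaked CDEII produces an alternative parse
with a shorter spacer that can legitimately outscore the planted one.
`scanCentromereSet()` resolves it with the biology: CDEII length
varies little within a species, so a first pass fixes the species'
median CDEII length and a second pass penalises candidates by 1 bit
per bp of deviation before overlap resolution. Overlap resolution
keeps the best-scoring candidate per overlapping set, breaking ties
leftmost, then most compact.

## Mapping to the ancestor

`mapCentromeres()` assigns extant centromeres to ancestral centromere
loci by flank evidence: with a window of `w = 5` pillars per side, a
full match needs at least one flank pillar on each side in a
consistent layout. The window and the ≥1-per-side minimum are this
package's calibration of "full or partially conserved syntenic gene
content"; no number is inherited from elsewhere. Reversed layouts set
`orientation_change`; half matches are classified by where the
disrupted side's genes now come from (same ancestral chromosome →
`inversion_at_locus`, otherwise `translocation_at_locus`); loci with
no matching centromere are `lost`. Post-WGD genomes owe two tracks
per locus, and every unassigned track is a loss — mirroring how
published fate tables book-keep post-WGD species in two sub-columns.

`mapTelomereEnds()` calls an ancestral end conserved when an extant
chromosome end shares at least two of its five outermost pillars.
Otherwise the flank is internal and the junction beyond its outermost
surviving pillar is classified: abutting another ancestral end's
flank facing the junction with its telomere side → `fused` (the face
condition separates fusion junctions from inversions at the locus and
from translocated segments that merely carry end-proximal content,
and resolves post-WGD fusions between the two sister tracks of one
ancestral end); abutting an ancestral centromere flank of another
chromosome → `fission_fusion`; otherwise lost by inversion (same
ancestral chromosome) or translocation. Junction classification uses
flanks of `2w + 2` pillars, wider than conserved-end matching:
post-WGD gene loss occasionally deletes an entire `w`-pillar flank on
one track, and the junction must still be recognizable from the
surviving context. Post-WGD genomes classify each missing track from
a distinct flank copy. Extant ends matching no ancestral end are
reported as novel telomere sites.

`inferAncestralPresence()` applies the parsimony rule for the WGD
node — present if found in at least one non-WGD and one post-WGD
species, or in both paralogous sister regions of one post-WGD
species — and extends to the older node B (common ancestor of non-WGD
and post-WGD lineages) only with non-WGD support: at least one
non-WGD carrier plus either WGD-node presence or a second independent
non-WGD genus. Node-B calls carry an evidence count because this
extension rests on fewer genomes. `assignEventsToBranches()` places
each derived event above the smallest clade containing exactly its
carriers (Dollo-style single origin) and flags non-monophyletic
carrier sets instead of forcing them.

## Breakpoints and reuse cycles

All rearrangement logic runs on signed gene extremities: a gene's
tail/head pair, joined into adjacencies; two genomes share an
adjacency exactly when the same extremity pair is joined in both,
which absorbs every orientation case. Synteny blocks are maximal runs
of ancestrally consecutive pillars, tolerating up to `max_gap = 1`
missing pillar (post-WGD single-copy losses would otherwise fragment
every block; with two-copy pillars the surviving copy may sit on the
sister track, so post-WGD genomes may skip present pillars too) and
keeping isolated single-gene strand flips inside the block as
within-block inversions, excluded from event counts. The defaults
`min_block_len = 2`, `max_gap = 1` are this package's choices.

A breakpoint edge is a novel extant adjacency; chromosome ends whose
terminal block stops short of an ancestral chromosome end contribute
end edges capped by an extant-telomere pseudo extremity.
`traceCycle()` walks alternately along broken ancestral adjacencies
and breakpoint edges until it returns to the start (a closed cycle)
or reaches telomere caps on both sides (a telomeric path); a dangling
neighbour deleted beyond the gap budget leaves an open chain, flagged
and never silently closed. Ties when a dangling neighbour matches
several edges (true reuse ambiguity, or duplicated pillars after WGD)
prefer unvisited edges and then the lexicographically first junction,
and are recorded in the cycle's ambiguity list.

Event counting is a documented heuristic, exact on the histories used
for validation: a closed cycle of `k` edges represents `k − 1` chained
reciprocal events (a plain translocation or inversion gives a 2-edge
cycle and 1 event; `k − 2` breakpoints were reused), and a telomeric
path counts its internal edges (a fusion: one edge, one event; a
telomeric translocation: one internal edge plus an end edge, one
event). A centromere fission counts as 2 here — its two junctions are
indistinguishable from two telomeric translocations at the breakpoint
level, which is exactly the ambiguity the mechanism classifier
resolves with centromere-fate evidence. No attempt is made at a
general minimal-rearrangement (DCJ-style) solver; the cycle walk is
the method.

## Mechanism classification

`classifyMechanisms()` combines the two mappers: a fusion call needs a
mutual pair of `fused` telomere fates on one extant chromosome plus a
dead centromere associated with that junction — by the ancestral
chromosomes whose ends met, or, when earlier translocations have
shuffled the distal segments, by where the dead centromere's flank
content now lives. Fusion calls always carry `order_unknown`: fusion
followed by centromere loss and centromere loss followed by rescue
fusion leave identical footprints. A fission call needs the two
`fission_fusion` fates naming the same lost centromere. WGD is called
from double conserved synteny — the fraction of ancestral centromere
loci with two mapped extant tracks (default threshold 0.5) — rather
than from retained duplicate genes, which post-WGD gene loss erodes
to ~15%. Centromere losses explained by neither pattern surface as
`unexplained_loss` calls; the published fate tables contain exactly
such bookkeeping ambiguity, so the category is first-class output.

`predictChromosomeNumber()` folds calls along a lineage: ×2 per WGD,
−1 per fusion, −1 per fission. On simulated histories without
breakpoint reuse this equals the leaf's actual chromosome count
whenever recovery is exact, and the test suite holds it to that over
50 seeds.

## Packaged fate-table transcriptions

`table1Fates()` and `table2Fates()` load machine-readable
transcriptions of the published mapping between the eight ancestral
centromeres (ten species, two tracks for post-WGD columns) and the
sixteen ancestral telomere locations (seven finished genomes). The
original table glyphs are preserved alongside parsed status columns.
`countFates()` reproduces the headline counts from them: nine
centromere losses (3/2/2/1/1 by species), 14 of 112 telomere
locations lost to fusion, and 33 turned over by translocation,
inversion and fission-fusion (the 33 includes one loss whose
mechanism flag is not printed in the source table; it is preserved as
`lost_unknown`).

## Problem sizes and runtime

Every simulation in the tests and the acceptance script uses the
default 8 × 50-gene ancestor (400 genes); sweeps run 10–50 seeds;
scanner calibrations use 100–500 windows of 600 bp. The full test
suite and the acceptance script each complete in a few minutes on one
CPU.

## Known limitations

* Mechanism classification is local-synteny based; histories with
  deliberate breakpoint reuse (the supplementary-style fixtures) are
  resolved by the cycle tracer, not the classifier.
* Rearrangement counting after a WGD treats duplicated pillars by
  tie-break rather than by full two-track phasing; counts on post-WGD
  genomes are a flagged lower bound when ambiguities arise.
* The telomere mapper assumes finished chromosome ends; scaffold
  assemblies are out of scope by design.
* Species without a detectable point-centromere consensus cannot be
  scanned; the package makes no attempt to find epigenetic
  centromeres.
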