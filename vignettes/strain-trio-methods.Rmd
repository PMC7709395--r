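---
title: "Methods: fine-scale comparative genomics of near-identical strain trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale comparative genomics of near-identical strain trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`straintrio` analyzes two or three complete bacterial genomes that are so
similar (average nucleotide identity above 99%) that most comparative
tools lose resolution. At that scale the informative signals are not
substitution-model branch lengths but *countable events*: which strain
carries a private nucleotide at an otherwise conserved column, which
CRISPR spacers were acquired after which split, how many segment
inversions separate two chromosome arrangements, and whether a highly
expressed surface gene is a recombinant patchwork of two parents. The
package implements each of those analyses, plus the bookkeeping around
them (origin-anchored reorientation, CDS-overlap refinement, homolog
accounting), and a simulator that generates strain trios with a complete
event log so that every stage can be verified against planted truth.

# Models and procedures

## Replication origin and canonical frame

The cumulative GC skew (running sum of +1 per G, −1 per C) of a circular
bacterial chromosome is minimal near the replication origin and maximal
near the terminus, because the leading strand is G-enriched. `find_ori()`
collects dnaA candidates (product text, or at least 40% amino-acid
identity to a user-supplied DnaA) and chooses the candidate nearest the
cumulative minimum that also has *dnaN* and *gyrB* within a configurable
number of CDS features (default 5, our reading of "immediate proximity";
the choice only matters when several dnaA copies sit near the minimum).
If no candidate passes both filters, the skew-nearest one is returned
with `confidence = "low"`. `reorient()` then reverse-complements if
needed and rotates so the first base of that dnaA is position 1 — the
convention that makes two circular genomes directly comparable.
Window/step defaults for the windowed skew profile (10 kb / 1 kb) are a
display choice; the ori call itself uses the per-base cumulative curve.

## Genome signatures

`tetra_signature()` computes, over the sequence plus its reverse
complement, the z-score of each tetranucleotide against the maximal-order
Markov expectation `E[n(abcd)] = n(abc) n(bcd) / n(bc)` with variance
`E (n(bc) − n(abc)) (n(bc) − n(bcd)) / n(bc)^2`; words containing N are
skipped, and zero-variance words get z = 0. Correlating two such
256-vectors (Pearson) is the usual compositional-relatedness measure.
Note that signatures of *simulated* genomes carry much less
species-specific signal than real chromosomes — an i.i.d. background has
no codon or restriction bias — so correlations between simulated strains
sit near 0.9 rather than the 0.999 typical of real conspecific genomes.
The z-score computation itself is validated against a direct-enumeration
oracle to 1e-9.

`ani()` follows the orthologous-fragment recipe: both genomes are cut
into consecutive 1020-bp fragments (trailing remainder discarded),
fragments are matched across genomes, per-fragment best hits with at
least 35% aligned coverage are kept, and ANI is the mean identity over
reciprocal best-hit pairs averaged over both directions (hence exactly
symmetric). Matching is seeded with 15-mers; each candidate is first
verified *gaplessly* at the seed-voted diagonal — exact whenever the
fragment pair is indel-free, which dominates between near-identical
strains — and falls back to a local alignment (match 2, mismatch −3, gap
open 5, extend 2) otherwise. Ties break by identity, then aligned span,
then lower fragment index. On mutated-copy calibrations the estimator
recovers 1 − rate within binomial error at rates 0 to 0.01.

## Collinear blocks and exact reversal distance

`find_blocks()` is a light stand-in for a whole-genome aligner, adequate
for strains of very high identity: anchors are 21-mers unique in each
genome (both strands counted), excluding k-mers that overlap a
high-copy core (any constituent 15-mer seen four or more times — CRISPR
repeats and IS elements breed spurious junction matches otherwise) and
anchors without diagonal support (a genuine diagonal extends over at
least 100 bp). Anchors chain into blocks when consecutive (same strand,
consistent order, gaps at most 5 kb in both genomes); blocks under 5 kb
are dropped, and residual micro-overlaps (anchors spanning a breakpoint,
or a duplicated segment claimed twice) are trimmed off the downstream
block. Mauve backbone files can be read directly as an alternative
source of blocks.

Block order and orientation along genome B give a signed permutation,
whose exact reversal distance is computed from the capped breakpoint
graph as `d = (n+1) − c + h + f` (cycles, hurdles, fortress), with the
full hurdle/super-hurdle analysis rather than the common
oriented-components shortcut. For circular chromosomes the permutation
is first brought into the canonical frame (rotate, reflecting if needed,
so block 1 leads with positive sign) and the linear formula is applied
to the remainder — the standard circular reduction. The implementation
is validated exhaustively against a breadth-first-search oracle over the
reversal graph for all signed permutations up to n = 6 (46,080 states at
n = 6) and against a circular BFS for n up to 5. `reversal_scenario()`
returns one optimal scenario by repeatedly applying any reversal that
lowers the exact distance (one always exists); scenario length always
equals the distance, which the tests check on 1,000 random permutations
up to n = 10. `flank_transposases()` then asks, for every true
rearrangement breakpoint (collinear splits across indel scars are
excluded), whether a transposase CDS lies within 5 kb on either genome —
an inversion carries its flanking element to the other end of the
segment, so both genomes must be inspected.

## CRISPR spacer genealogy

The large CRISPR array is extracted by approximate matching of the known
30-bp direct repeat (up to 3 mismatches, both strands); tandem hits
whose gaps fall in the 20–50 bp spacer range form an array. De novo
repeat discovery is deliberately out of scope — the repeat of the locus
under study is conserved and known. Orientation (leader end = index 1)
comes from matching the 138-bp leader against the array flanks, or, when
no leader is available, from the conservation gradient across arrays
(shared spacers are old and sit trailerward). Spacers are clustered by
exact sequence identity considering both strands — spacers are short and
the biology of interest is presence/absence, not divergence — and the
arrays, rewritten as cluster-ID strings, are aligned progressively with
match +1, gap −1 and mismatches forbidden: arrays evolve by leader-end
insertion and internal deletion, not substitution, so a "substitution
column" would be a modeling error. Columns classify as shared-by-all,
shared-by-a-pair, or unique; the trailer anchor is the maximal run of
all-shared columns containing the trailer-most such column, and the pair
with strictly the most pair-shared columns leaderward of that anchor is
called sister (the third strain diverged first). With no supporting
columns the call is `undetermined` rather than forced.

## Concatenated-marker apomorphies

Fifty conserved marker genes (the manifest is user-replaceable; the
simulator provides its own) are located per genome by best protein hit
at ≥ 40% identity with a full-length requirement, aligned per marker by
center-star over pairwise global alignments (match 1, mismatch −1, gap
open 5, extend 1 — for inputs above 99% identity the heuristic choice is
immaterial, but it is pinned for determinism), concatenated in fixed
order, and translated codon-wise into a matched amino-acid alignment.
An apomorphy is a column where exactly one strain differs while the
other two agree; columns containing any gap or ambiguity are excluded,
because indels are handled separately by `frameshift_screen()`, which
classifies per-marker differences between two assemblies of the same
strain as substitutions, in-frame indels, or frame-shifting indels
(length not divisible by 3) — the signature of sequencing error rather
than evolution.

## Hybrid surface genes

`sliding_identity()` profiles pairwise identity along a protein
alignment in 20-aa windows at 1-aa steps (identity = matched columns /
columns where not both rows are gaps). `call_chimera()` aligns a query
against two candidate parents and assigns each window to the parent with
the higher identity, but only when the winner is at or above 0.9 and the
loser at or below 0.7 — hysteresis that prevents segment flicker in
mid-identity regions. Runs of same-parent windows merge into segments
tiling the alignment; a query is a hybrid when each parent owns at least
one segment of 30 aa or more. Breakpoints localize to within one window
of the planted position across a sweep of simulated chimeras.

## CDS refinement and homolog accounting

`overlap_refine()` implements the 60-bp overlap rule: when two CDS
overlap by at least 60 bp and the overlap is not attributable to a
mispredicted start codon, the shorter is removed unless its function is
predicted or it appears in the proteome. "Mispredicted start" is
operationalized as: either gene has an in-frame ATG/GTG/TTG downstream
of the overlap that would retain at least half of its length. Equal
lengths break lexicographically by locus tag (the rule's source is
silent; determinism wins). Processing is coordinate-sorted and iterated
to a fixed point, so the result is order-independent and no ≥60-bp
overlap survives among kept genes. `homolog_map()` reports, per query
CDS, the best protein hit in a target genome at ≥ 40% identity with
≥ 50% query coverage (the coverage bound is our pinned choice; identity
alone is not well defined without one), rescuing annotation gaps by
searching the target's six-frame translation with 8-mer seeded windows.

# The simulator and what it does (not) show

`simulate_trio()` builds a 200-kb circular ancestor at GC 0.41 with a
two-replichore skew bias (4% leading-strand G excess in intergenic
sequence; the real magnitude is unknown, this one makes the cumulative
curve unambiguous at 200 kb), an ori cassette (dnaA/dnaN/gyrB), 50
embedded 636-bp marker ORFs, eight identical transposase cassettes, a
leader-bearing CRISPR array, and an 800-aa surface gene. Three strains
derive from it on the tree (sister pair MBR1-like + CSTR1-like, outgroup
KUST-like) by logged events: branch-private marker substitutions
(defaults 2/31/4, with 0/8/0 of them non-synonymous, planted in distinct
codons so recovery is exact), intergenic background substitutions
(200/600/300), two inversions per sister branch with breakpoints at
transposase cassettes, leader-end spacer insertions (45 ancestral
all-shared, 12 on the sister stem, 19/35/85 strain-unique; internal
losses default to zero), a heavily diverged surface variant in one
sister (45% of amino acids — the scale of the real divergence), a mildly
diverged one in the other (1%), and one chimeric surface-gene copy in
the outgroup (breakpoint at aa 400). Spurious 300-bp ORF annotations
overlapping marker genes by 220 bp exercise the refinement rule; the
overlap is deliberately too deep for the start-codon rescue.

The genome is 20× smaller than a real anammox chromosome, so per-gene
features (the diverged surface gene, the CRISPR locus) weigh ~20× more
in genome-wide averages like ANI, and the tetranucleotide background is
i.i.d. rather than organismal. Passing the recovery suite therefore
shows that the *procedures* are correct and calibrated, not that real
data would reproduce any particular published value; real-data
reproduction requires the deposited genomes and is outside the default
test run. The event log (`trio_truth`) replays on the ancestor to the
exact strain sequences, is serialized as checksummed JSON, and a
tampered log is refused on read.

# Numerical and design choices

* Coordinates are 1-based inclusive everywhere, matching GenBank, GFF3
  and the Bioconductor range convention; junction-spanning features of
  circular genomes are stored as two parts sharing a locus tag.
* Ambiguity codes beyond N are normalized to N with a warning and are
  excluded from GC, tetranucleotide and anchor statistics.
* All alignment scoring is pinned (see above) so outputs are
  deterministic; every tie-break (fragment pairing, equal-length CDS,
  candidate markers) has a stated deterministic rule.
* The simulator is deterministic under its single seed; all test and
  acceptance randomness derives from fixed or caller-supplied seeds.
* Problem sizes in the test suite (200-kb genomes, 20 recovery trios,
  exhaustive reversal-distance validation to n = 6, 1,000 random
  scenarios to n = 10) were chosen to exercise every code path at full
  strength on a single CPU.

# Known limitations

* `find_blocks()` assumes dense unique anchors; it is not a replacement
  for a whole-genome aligner on diverged or repeat-rich genomes. Mauve
  backbone input is the supported route for such data.
* Reversal distance is the classical inversion-only model; no
  translocations, duplications or DCJ.
* Spacer clustering at identity 1 treats a single-base spacer variant
  as a different spacer (the fuzzy option exists but is not the
  default).
* The GenBank reader covers the flat-file subset the package writes
  (LOCUS/FEATURES/ORIGIN, locus_tag and product qualifiers,
  complement() and two-part join() locations), not full INSDC syntax.
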