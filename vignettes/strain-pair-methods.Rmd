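---
title: "Methods: profiling and comparing nested endosymbiont strain pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling and comparing nested endosymbiont strain pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiodiff)
```

## The problem this package addresses

Obligate intracellular symbionts of insects carry some of the smallest
bacterial genomes known. The citrus mealybug hosts a nested consortium — a
gamma-proteobacterium living *inside* a beta-proteobacterium — whose two
genomes (roughly 139 kb and 538 kb) show the classic signatures of reductive
evolution: AT enrichment, low coding density, eroding pseudogenes,
slippage-prone homopolymer tracts, partial duplications under concerted
evolution, and a tRNA repertoire decoupled from translational demand.
Comparing two sequenced strains of each partner gives a near-identical
genome pair in which every polymorphism can be enumerated and classified.

`symbiodiff` implements that comparison as a reusable, fully tested
pipeline: genome profiling, strain-pair alignment and variant
classification, indel sequence-context analysis, Nei–Gojobori dN/dS,
exact-repeat detection, and the tRNA-inventory-versus-codon-demand
regression — plus a seeded simulator that generates annotated genome pairs
with planted, labelled mutations, so that every stage is validated against
ground truth without downloading anything.

## Genome representation and partition

Genomes are parsed from GenBank flat files into a `genome_record`:
an uppercase sequence over `{A,C,G,T,N}` (other ambiguity codes are
rejected at parse time; `N` is allowed but excluded from GC numerators and
denominators), circular topology, and typed features (CDS, rRNA, tRNA,
smallRNA, pseudogene). Coordinates are 0-based half-open internally and
1-based inclusive in all reports, the GenBank convention. Features flagged
`/pseudo` are classed pseudogenes regardless of their original key, because
strain comparisons treat the pseudogene fraction as its own partition
class. Features wrapping the origin of a circular molecule are split into
two intervals at parse time.

`build_partition()` assigns every position to exactly one of
coding / rna / pseudogene / igr with the fixed precedence
coding > rna > pseudogene, making the partition independent of annotation
order; gene density is the coding+rna fraction. GC statistics,
per-partition variant counts, and the mean IGR length all derive from this
single positional partition, so the bookkeeping identity
(class lengths sum to genome length; length-weighted class GC equals
overall GC) is tested as an invariant.

## Strain-pair alignment

Near-identical genome pairs do not need a general-purpose aligner: the
package chains maximal shared unique *k*-mer matches (default `k = 31`),
longest first with leftmost tie-break, permitting overlapping co-linear
anchors (overlaps arise around indels inside repeated context and are
trimmed at assembly), and closes every inter-anchor gap with full
affine-gap dynamic programming in compiled code. The scoring scheme is
fixed — match +1, mismatch −2, gap open −4, gap extend −1, so a gap of
length L costs 4 + L — and anchor ends adjacent to a gap are trimmed by
5 bp so that event boundaries are placed by the aligner, not the seed
heuristic. If co-linear chaining discards more than 25% of anchored bases
the aligner refuses with a "not collinear" error rather than returning a
silent partial alignment; rearrangement detection is out of scope.

At the identity levels this design targets (≳99%), the chained alignment
attains the full dynamic-programming optimum; the test suite verifies score
equality against an independent full-DP implementation
(`Biostrings::pairwiseAlignment`) on hundreds of random pairs. Identity is
reported as matched columns with equal, non-`N` bases over all alignment
columns.

Variant calling walks the alignment columns: substitutions per mismatch
column (columns containing `N` are excluded), maximal gap runs merged into
single indel events, mixed runs split into separate insertion and deletion
events at the run boundary. Indels are left-normalized — shifted to the
lowest position yielding the same alternate sequence — the standard variant
convention; it also makes homopolymer-context calls placement-invariant.
Two invariants guard the caller: applying the called variants to genome A
reproduces genome B byte-for-byte, and swapping the inputs maps insertions
to deletions while preserving substitution classes.

## Variant classification

Substitutions are labelled transition/transversion and assigned a direction
class: GC→AT (the derived strain gains A/T), AT→GC, or the content-neutral
A↔T and G↔C classes. For GC↔AT-changing sites the strain carrying the A/T
allele is recorded, giving the per-strain A/T balance that distinguishes a
neutral mutational bias (≈50/50) from directional divergence. Partition
classes are taken from genome A's partition.

## Indel sequence context

Homopolymers are maximal single-base runs of at least 6 nt (the
slippage-prone threshold used throughout); microsatellites are maximal
tandem tracts of 2–8 nt motifs with at least 2 copies and 6 bp, reported
once under their smallest motif. An indel *affects a homopolymer* iff its
allele consists solely of the run base and its left-normalized position
lies inside or immediately adjacent to a qualifying run — the operational
definition adopted here, since "affects" has no standard one. Failing that
it is a microsatellite indel iff the allele is an integer number of motif
copies (up to rotation) inside or adjacent to a tract; otherwise `other`.
Homopolymer takes precedence over microsatellite. Runs are counted on the
deposited strand only; A-runs and T-runs are tallied separately and summed
for A/T figures.

## Selection: Nei–Gojobori dS/dN

Orthologs are paired by locus name; length-mismatched pairs are aligned and
only codon columns where both sequences contribute a full in-frame codon
are kept, so frame-preserving indels drop the affected columns. Sites
follow the NG86 convention with stop-excluded denominators: at each codon
position the synonymous fraction is the number of non-stop single-base
changes that preserve the amino acid, over the number of non-stop changes;
sites are averaged over the two sequences. Codons differing at more than
one position are scored by averaging over all minimal mutational pathways
that avoid stop codons; codon pairs with no stop-free pathway are dropped
and counted. Proportions are corrected with Jukes–Cantor,
d = −(3/4)·ln(1 − 4p/3), which is undefined at p ≥ 0.75 and refused
explicitly. Standard errors come from a seeded 1000-replicate codon-column
bootstrap; ω = dN/dS is reported undefined when dS = 0. The default is
concatenation across orthologs; per-gene estimates are available by
passing a single alignment. The whole counting core is tested against a
brute-force pathway enumerator on hundreds of random codon pairs.

Exact reproduction of published dS/dN values from other studies is
method-sensitive — the site-counting scheme (NG86 versus
transition-weighted variants) changes S/N by tens of percent, and ω with
it — which is why the pipeline treats such comparisons as soft,
reporting computed values alongside published ones.

## Repeats

`find_exact_repeats()` reports all maximal exact repeat pairs at or above a
length threshold (default 1000 bp), in direct and inverted orientation, by
k-mer seeding followed by full scanning of every seeded diagonal
(anti-diagonal for inverted); its contract is output equality with a
quadratic brute-force scan, which the tests enforce. Maximal pairs
contained in another reported pair are suppressed. For inverted repeats the
arms of a spacered pair appear as mirrored runs on one anti-diagonal; a
contiguous palindrome yields one self-mirrored run reported as two
non-overlapping half-arms. `find_ir_flanked_regions()` filters inverted
pairs by minimum arm length and maximum enclosed region, resolving overlaps
longest arm first — this is how the invertible region bounded by 71-bp arms
in the smaller genome is detected. Coordinates are reported 1-based
inclusive.

## tRNA inventory versus codon demand

The tRNA inventory counts functional genes per anticodon (read from the
`anticodon` qualifier or the product string); pseudo-tRNAs are tallied
separately and never enter totals. Translational demand is defined as the
total sense-codon count over all functional CDS — the published correlation
does not define its x-axis operationally, and this is the natural reading.
The cross-genome regression is ordinary least squares of tRNA gene count on
demand with R² the squared Pearson correlation; the overload score is the
leave-one-out change in R². Note that removing a point that lies exactly on
the remaining points' fitted line changes R² unless those points are
collinear, so the "delta = 0 for an on-line focal genome" property is exact
only in the noise-free case, which is how it is tested. Cognate matching is
exact Watson–Crick anticodon reverse-complement by default; wobble rules
vary by lineage and are therefore supplied as a data table, not code.

## The synthetic strain-pair generator

The generator is first-class, tested code, and its defaults are the study
conditions of the system it emulates. `genome_spec()` builds an annotated
ancestor: CDS starting with ATG, ending with a stop (TAA favoured 60/20/20,
as in AT-biased genomes), free of internal stops; non-overlapping features;
intergenic blocks carrying planted maximal A/T homopolymer runs of 6–12 nt
(1.5 runs per kb of IGR) whose flanks are forced to differ from the run
base, so context tests have guaranteed targets; and an optional exactly
duplicated rRNA-like block. The base-level GC used for codon sampling is
solved numerically so that the realized genome GC hits the target despite
stop-codon rejection (which would otherwise inflate GC by about one point
in an 80%-coding genome); realized GC stays within one percentage point of
the target for genomes of 100 kb and larger.

`mutation_model()` plants substitutions by drawing the direction class
explicitly — GC→AT with probability 0.45, AT→GC with 0.45, the neutral
classes taking the remainder split by base composition at the sampled
sites — and transitions within the content-changing classes at a rate that
keeps the marginal transition fraction exactly at its parameter (default
0.435). These defaults mirror the observed strain-pair class structure:
~90% GC↔AT changes evenly split between strains, 43.5% transitions.
Defaults for event counts are the smaller pair's 23 substitutions and 5
indels; the larger pair's 262/60 scale, with its 1–75 nt indel size
mixture (mean ≈ 5.4 nt) and 58.3% homopolymer targeting, is used by the
analysis scripts and acceptance script. Homopolymer-targeted indels insert
or delete whole copies of the run base at the run start (already
left-normalized); deletions are capped below the run length so the run
survives. Events are placed without replacement with a minimum spacing
(default 10 bp) and bounded retries; every event's expected labels (ti/tv,
direction, partition, context, synonymous status) are recorded in the truth
table, and ancestor + truth table reconstructs the derived strain
byte-exactly. With the default spacing the pipeline recovers every planted
event with exact position and class; the acceptance tests assert 100%
agreement rather than a threshold.

When `coding_synonymous_fraction` is set, substitutions are restricted to
CDS interiors and made synonymous with exactly that Bernoulli probability,
using the same genetic-code machinery as the NG86 module (shared code, so
the definitions cannot drift); stop-creating changes are never planted.

`generate_panel()` draws demand uniformly on a configurable range, puts
counts on a line (slope 4 × 10⁻⁵, intercept 25 — endosymbiont-like
magnitudes) plus Gaussian noise, and optionally multiplies one genome's
count by an overload factor. Counts are left unrounded so the noise model
is exactly as stated.

What the simulator does *not* emulate: real annotation noise (partial or
mis-called gene models), sequencing error, rearrangements and inversions,
selection-driven sequence evolution, and phylogenetic structure across a
panel. Passing tests therefore demonstrate the correctness of the
measurement machinery on clean, truth-labelled data, not robustness to
annotation artifacts in real records.

## Numerical and design choices

- **Codon bias test.** Pearson chi-square against the uniform distribution
  within each synonymous family, with an exact multinomial test whenever an
  expected count falls below 5; families with zero counts are untestable.
  The uniform null is the conventional reading of "significantly biased"
  codon usage; the test's type-I rate is calibrated against its nominal
  alpha over 1000 simulated uniform families.
- **GC-rank of amino acids.** Mean G+C fraction over the synonymous codons
  of the standard code, decreasing, alphabetical tie-break.
- **Stop codons** are excluded from amino-acid profiles and from
  translational demand; the final codon of a CDS is tallied among stops,
  never among amino-acid codons; CDS with internal stops are excluded from
  codon statistics and reported.
- **Problem sizes.** The test suite and acceptance script run the
  end-to-end recovery at 150 kb, the statistical-recovery checks at
  10,000 planted substitutions on a 500 kb genome, oracle equivalence on
  200 alignment pairs / 200 codon-pair sets / 1000 scanned sequences, and
  the published-scale comparison at 538 kb — sizes chosen so the full
  suite completes in minutes on one CPU while every estimate's sampling
  error stays far below the tolerances being checked.
- **Reference reproduction.** The deposited strain genomes are not
  redistributable inside the package; `analysis/08_reference_genomes.R`
  (and the corresponding acceptance test) reproduce the published
  per-genome statistics when the four GenBank files are placed under
  `inst/extdata/genomes/`.

## Known limitations

Circular topology is recorded but alignment assumes both strains are
deposited in the same linearization; rearranged pairs are refused, not
resolved. Exact repeats only — a single mismatch truncates a repeat pair.
NG86 with equal pathway weighting has no transition/transversion weighting
and no site-specific ω. The GenBank writer emits a minimal round-trippable
subset of the format, not every qualifier convention in the wild.
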