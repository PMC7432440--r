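---
title: "Methods: comparative mitogenomics with mitocompare"
author: "mitocompare authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics with mitocompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocompare)
```

# Scope and data model

`mitocompare` analyses annotated fungal mitochondrial genomes: circular,
AT-rich molecules (~25–30% GC) carrying a conserved complement of 15 core
protein-coding genes, two rRNA genes, a variable set of tRNAs, and a
highly dynamic load of group I introns, intergenic sequence and repeats.
The central container is the S4 class `Mitogenome`: one genome sequence
plus typed features (genes with exon intervals, introns, RNAs) in a
single 1-based inclusive coordinate frame. Features spanning the origin
of the circle are held in linearized virtual coordinates
(`end = end + L`) and re-wrapped by the GenBank writer; this keeps all
interval arithmetic on ordinary integer ranges.

Records are consumed from GenBank flat files. The parser understands
`join()`, `complement()` and origin-spanning joins, normalizes gene
symbols through a synonym table (`cytb` → `cob`, `rrnL` → `rnl`, …), and
assigns feature classes from the core-PCG name set, with CDS features
contained in an annotated intron classed as intronic ORFs. That
containment rule is the only signal available when a source record does
not label intron-hosted ORFs explicitly, and it is what makes the
region accounting below self-consistent.

Translation uses the mold mitochondrial genetic code (NCBI table 4), in
which TGA encodes tryptophan. A terminal stop codon is stripped; internal
stops are retained as `*` with a warning rather than silently dropped, so
annotation problems stay visible.

# Composition statistics

Strand skews follow the standard definitions AT skew = (A−T)/(A+T) and
GC skew = (G−C)/(G+C), computed on the direct strand as deposited; a zero
denominator is reported as undefined rather than zero. GC percent is
computed over unambiguous bases only.

The region partition assigns every genomic position exactly one of four
classes with the precedence **non-intronic coding exon > RNA gene >
intron > intergenic**. Two consequences are deliberate:

- intron-hosted ORFs count as *intronic*, not coding — the published
  coding/intronic splits for intron-rich mitogenomes are only consistent
  under this convention;
- tRNA and rRNA genes together form a single RNA class.

The precedence is configurable but defaulted; overlaps between
non-intronic coding exons (annotation artifacts) are resolved by union
with a warning. The four class totals sum to the genome length exactly —
this conservation is property-tested on hundreds of random synthetic
annotations.

Codon usage is tallied over extracted coding sequences. By default only
non-intronic PCGs are included; intron-hosted ORFs can be added with
`include = "all_pcgs"`. Published codon tallies rarely state whether
intronic ORFs were included; excluding them is the conservative default
since their codon usage reflects homing-endonuclease sequence, not host
gene expression.

# Repeat detection

Three detectors cover the repeat evidence classes used in mitogenome
surveys. None attempts to reproduce an external tool bit-for-bit; each
implements the underlying definition with explicit, stated parameters.

**Maximal exact repeats** (`findExactRepeats`) finds all maximal exact
matches of length ≥ `minLen` (default 8 bp) between the genome and a
transform of itself: identity (forward), `reverse()`, `complement()` and
reverse-complement (palindromic). Maximality means inextensible in either
direction. Seeds are exact k-mers located through an integer k-mer index;
each symmetric pair is reported once with the lexicographically smaller
interval first. The implementation is checked for exact equality against
a brute-force diagonal-scan oracle on every random sequence up to 300 bp
across 50 seeds.

**Interspersed repeats** (`findInterspersedRepeats`) run the package's
seed-and-extend local aligner on the genome against itself and against
its reverse complement: 11-mer seeds, gapless X-drop extension (X = 20)
under match +1 / mismatch −2, main diagonal masked, mirror duplicates
collapsed. Significance is a Karlin–Altschul E-value
E = K·m·n·exp(−λS) with λ solved from the scoring scheme
(λ ≈ 1.3327 for +1/−2 on uniform composition) and K = 0.621, the standard
ungapped value for this scheme; both are exposed by
`repeatScoringConfig()`. The default threshold is E < 1e-10. Extension is
gapless by design: the planted-truth regime this detector addresses
(duplications diverged by point substitutions) does not require gapped
extension, and the E-value theory used is the ungapped one. Gap penalties
(open 5, extend 2) are carried in the configuration for a future gapped
refinement but unused. On AT-rich genomes homopolymer seeds would
dominate, so a composition-entropy filter (≥ 1 bit) is applied to seed
words by default for this detector — off by default for exact repeats,
where completeness is the contract. On circular genomes the sequence is
extended by word − 1 wrap characters so origin-spanning repeats seed
once.

**Tandem repeats** (`findTandemRepeats`) compare the genome against
itself shifted by each candidate period p ≤ 500 bp. Maximal match runs
are merged across mismatch gaps only when the weaker flanking run
outweighs the gap under the usual tandem-finder weighting (match +2,
mismatch −7) *and* overall motif identity stays ≥ 80%; an array is a run
plus one period, reported when longer than 10 bp with at least two
copies, copy number to 0.1 resolution, consensus by per-position
majority. Overlapping calls at different periods are reduced to the
highest-scoring period (ties prefer the shorter period, then the earlier
start) — without this, every period-2 array would also be reported at
periods 4, 6, ….

**Transfer fragments** (`findTransferFragments`) apply the same
seed-and-extend engine across the mitochondrial and nuclear sequences
(both nuclear strands) and annotate each fragment with the mitochondrial
genes and introns its interval overlaps.

Repeat *coverage* is the union of covered positions over both members of
every hit pair, never the sum of hit lengths: sums double-count
overlapping families, while the union yields a well-defined percentage of
the genome.

# Intron position classes

The comparative unit for intron dynamics is the position class (Pcl): the
insertion site of a *cox1* intron expressed as a nucleotide coordinate of
a reference *cox1* coding sequence. The pipeline computes, for each
intron, the number of coding nucleotides preceding it in the
strand-corrected, exon-concatenated query CDS; translates query and
reference under code 4; aligns the proteins globally (BLOSUM62, affine
gaps: opening 10, extension 1 — `Biostrings::pairwiseAlignment`, whose
tie-breaking is deterministic); and reads off the reference residue
aligned to the query codon containing the insertion. The reference
nucleotide position is `3*(ref_aa − 1) + phase` for phases +1/+2 and
`3*ref_aa` at codon boundaries, rendered `P383` with an optional phase
suffix (`P383+2`). Both the bare and the phase-suffixed label are
emitted, since published matrices use the bare form while per-site
figures mark phases separately.

Alignment is at the protein level with positions back-converted to
nucleotides: across phyla, nucleotide alignments of *cox1* are unreliable
while the protein is strongly conserved, and the phase survives the
round-trip arithmetically. When an insertion site falls in a
reference-gap column the nearest reference residue to the *left* is
taken and the call flagged `exact = FALSE`; left-anchoring is
deterministic and stable under small alignment perturbations. Only
*cox1* is classified: rRNA exon–intron borders are too unreliable across
records to anchor a coordinate system (introns in other hosts are still
counted).

Identical labels across species are merged as homologous introns. A Pcl
is *common* when its prevalence strictly exceeds n/5 of the n species
surveyed, else *rare*. The published phrasing ("more than 1/5") does not
disambiguate the boundary; the strict inequality is the literal reading
and is exposed as a parameter (`commonFraction`). The identity
projection (query = reference recovers the raw offset for every
position), phase consistency (suffix ≡ position mod 3), and robustness
under simulated divergence (100% label recovery under ≤ 30%
substitutions without indels; ≥ 95% with 1–3 indels kept > 5 codons from
the insertion site, 200 simulated introns) are all property-tested.

`pearsonSizeIntron` is the standard Pearson correlation
(`stats::cor`) between mitogenome size and intron count across species,
with degenerate (zero-variance) input flagged as undefined.

# Gene order and rearrangement

The comparison set is the 17 genes shared by essentially all
Basidiomycota mitogenomes: the 15 core PCGs plus *rnl* and *rns*; tRNAs
are excluded because their numbers and positions are too volatile to
compare. A `GeneOrder` is the signed circular sequence of these symbols
ordered by first exon start, canonicalized by rotating *cox1* to the
front and, when *cox1* lies on the minus strand, reflecting the whole
circle and flipping all signs first. Canonicalization is idempotent and
invariant under rotation and whole-genome reflection of the input record
(property-tested), so records deposited in different orientations and
origins compare equal.

Rearrangement between two canonical orders is quantified by breakpoints
on the intersection of their gene sets (missing genes are dropped
pairwise rather than refusing the comparison — real records occasionally
lack *rps3*). An adjacency is an unordered signed pair, `(x, y)`
equivalent to `(−y, −x)`; the breakpoint count is the number of
adjacencies of one order absent from the other, which is symmetric on
equal gene sets and bounded by the number of adjacencies. Orders are
signed by default (inversions count) with an unsigned mode. The
implementation is checked against a brute-force adjacency oracle on 100
random signed circular 17-permutations, and a single block inversion is
verified to change at most two adjacencies.

# Supermatrix preparation

`extractGeneSet` exports the 17 collections (PCGs as code-4
translations, rRNAs as nucleotide). Amino-acid characters are the
default for PCGs — at these divergences protein alignment is the robust
choice, and a nucleotide flag is unnecessary for preparing partitioned
inference inputs that downstream tools re-model anyway.

Per-gene alignment goes through `alignGenes`. The default, used by all
tests, is the package's deterministic progressive aligner: every
sequence is globally aligned to the first sequence in input order and
the per-position insertion profiles merged by maximum. This is a
reference-anchored approximation — adequate for the moderate divergences
of core mitochondrial proteins and fully reproducible offline — not a
replacement for a dedicated aligner; an adapter to an external `mafft`
executable is provided (`method = "mafft"`) for production alignments.

`concatenateAlignments` joins genes in fixed alphabetical order,
gap-fills taxa missing a gene, and emits a contiguous, non-overlapping
partition table covering every column (tiling is asserted on every
build). Writers produce relaxed PHYLIP (round-trip tested), a minimal
NEXUS DATA block, and RAxML-style partition lines
(`WAG, gene = start-end`; model tokens configurable). The sanity tree is
standard neighbor joining (`ape::nj`) on p-distances over shared
non-gap columns, with taxa sorted by label so the result is invariant to
input order; it recovers the generating topology on additive matrices
(20 random 8-taxon trees, property-tested). Outgroup choice and actual
ML/BI inference belong to the external tools that consume these files.

# The synthetic-data generator

Every detector in the package is validated against planted truth, so the
generator is first-class code. `generateMitogenome` lays out the 17-gene
complement in a specified signed circular order with intergenic spacers
and scattered tRNAs over an i.i.d. background at the target GC (default
0.27, the Basidiomycota regime); plants introns at stated host-CDS
offsets — for *cox1*, offsets are reference coordinates, so the planted
Pcl label is known; optionally embeds a LAGLIDADG-like ORF inside an
intron; and plants repeat families and tandem arrays in intergenic
space. Planted tandem motifs are constrained to be primitive (no
internal period) and their flanks period-broken, so "recover the planted
array" is well-posed. Coding sequences are built codon-wise at the
target GC with internal stops resampled; the whole genome is a
deterministic function of the spec's seed, and generation leaves the
caller's RNG stream untouched.

`generateClade` evolves species along a random tree (`ape::rtree`):
protein-level substitutions on CDSs (back-translated under code 4),
per-branch intron gain/loss against the base intron pool, and gene-order
perturbation by random block inversions; divergence is
substitutions-only by design, which keeps reference-projection tests
meaningful (indel robustness is exercised separately with hand-built
indel cases). An `intronMembership` override plants exact per-Pcl
species sets for planted-truth experiments.
`generateNuclearWithTransfer` inserts diverged copies of random
mitogenome segments into a random nuclear background at recorded
positions and identities.

`basidioCohort` assembles a full 75-species survey-scale cohort
emulating the published summary regime of Basidiomycota mitogenomes:
sizes spanning 24,874–235,849 bp with mean 77,184 bp on a lognormal
profile (extremes planted exactly, interior rescaled to the mean);
intron counts 0–46 rising linearly with size, with noise calibrated once
(including a 1.2 inflation factor compensating the variance removed by
the per-genome intron-capacity clamp) so the realized size–intron
Pearson correlation sits near the surveyed 0.81; and a 43-class *cox1*
Pcl census with P383 in 40 species, P1107 in 35, eleven singleton
classes at the published singleton positions, and a 13-common / 30-rare
split under the strict rule. Membership is drawn weighted by remaining
intron capacity, so large genomes accumulate more classes — the
mechanism, not just the statistics, mirrors the biology.

What the generator does **not** emulate: real sequence (the reference
*cox1* shipped by the package, `referenceCox1CDS()`, is itself synthetic
— only its coordinate frame matters); intron secondary structure or
splicing signals; codon-usage selection; tRNA cloverleaves; realistic
repeat family structure. Passing the planted-truth suite therefore
demonstrates the *computations* are correct on data with known answers,
not that annotation of real records is correct — annotation is consumed,
never produced.

# Numerical and engineering choices

- Coordinates are 1-based inclusive throughout (GenBank convention);
  exported TSVs say so in a header comment.
- Karlin–Altschul λ is solved by `uniroot` to 1e-12; E-values use m·n of
  the compared sequences.
- Tandem copy number is rounded to 0.1; consensus is per-position
  majority over complete copies.
- Alignment tie-breaking is delegated to `pairwiseAlignment` and is
  deterministic; the test suite pins scores against an independent Gotoh
  DP oracle rather than alignment strings.
- Degenerate inputs fail loudly: empty sequences, frame violations,
  all-unparseable input directories, non-finite distances, < 3 shared
  genes in an order comparison, < 4 taxa for NJ.
- `runAll` manifests every output file with md5 checksums; identical
  inputs yield identical manifests (tested).

Problem sizes in the shipped tests were chosen to exercise each property
at the smallest scale at which it is meaningful: oracle equivalences on
sequences ≤ 300 bp over 50 seeds, conservation properties on 200 random
~9 kb annotations, recovery suites on 100 planted fixtures, the cohort
at its natural n = 75. The acceptance script regenerates the full cohort
(≈ 5.8 Mb of sequence) and measures everything from the emitted
annotations at run time.

# Known limitations

- The GenBank writer emits the subset of the format the parser consumes;
  exotic qualifiers of third-party records survive parsing (skipped with
  a message) but are not round-tripped.
- The interspersed-repeat engine is gapless; indel-diverged repeat
  copies longer than the X-drop horizon may be reported as split hits.
- The builtin progressive aligner anchors on the first sequence; for
  deep divergences or many indels an external aligner should be used via
  the adapter.
- Counts of repeats/tandems on real accessions depend on merge
  conventions that published totals do not specify; coverage percentages
  (union-based) are the comparable quantity.
- Pcl classification is restricted to *cox1* by design; introns in other
  hosts are counted but not classified.
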