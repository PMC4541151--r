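---
title: "copAminer: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{copAminer: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

copAminer recovers full-length metal-resistance genes — the copper pump /
oxidase gene *copA* is the worked example throughout — from assembled
metagenomic contigs, and screens the encoded proteins for the conserved
motifs that separate the two unrelated protein families that share the
"copA" annotation: Cu(I)-translocating P-type ATPases and multicopper
oxidases. This vignette documents the models and algorithms, every tunable
parameter with its default and rationale, what the synthetic benchmark does
and does not emulate, and the design decisions taken where the problem was
genuinely open.

# The homology search

## Model

The search is a classic seeded local aligner over nucleotides. Each contig
is scanned on both strands; every exact word of length `wordSize` shared
with the reference database seeds a two-way ungapped extension with an
X-drop, and the chained seed segments of each locus are then aligned by a
full affine-gap Smith–Waterman restricted to an adaptively expanded window
around the segments (the window grows whenever the optimal alignment
touches its border, so the reported raw score equals the unrestricted
Smith–Waterman optimum whenever a seed exists — a property the test suite
checks against an independent aligner on hundreds of pairs). Overlapping
alignments to the same reference on the same strand are merged keeping the
highest raw score, so one locus yields one hit while tandem copies stay
separate.

## Statistics

Hit significance uses ungapped Karlin–Altschul theory under uniform base
frequencies: λ is the unique positive root of
¼·e^{λ·match} + ¾·e^{λ·mismatch} = 1, solved by `uniroot` to machine
precision (the validity check requires the identity to hold to 1e−9), and
K comes from a fixed lookup of published calibrations for the canonical
score pairs (keys are reduced by their gcd; K is invariant under score
scaling while λ scales inversely). Scoring schemes with non-negative
expected pair score have no positive root and are rejected; schemes without
a calibrated K require an explicit `kappa`. Bit scores and E-values are

    bit = (λ·S − ln K) / ln 2,    E = m · n · 2^(−bit)

with m the contig length and n the summed database length (no edge-effect
correction — at these search-space sizes the cutoff decision is
insensitive to it). Applying the *ungapped* (λ, K) pair to *gapped* scores
is a deliberate approximation: only the 1e−4 cutoff decision matters
downstream, and gapped hits score at most equal to their ungapped subpaths'
optimum plus positive extensions, so the ranking is unaffected.

## Parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `wordSize` | 11 | legacy blastn seed length; smallest exact match that seeds a hit |
| `match`, `mismatch` | +1, −2 | legacy blastn nucleotide scoring |
| `gapOpen`, `gapExtend` | 5, 2 | a gap of length L costs 5 + 2L |
| `xDrop` | 20 | stop ungapped extension when the running score drops 20 below its maximum |
| `minAlignLen` | 40 bp | screening cutoff on alignment columns (gaps included); **threshold-inclusive**: exactly-40 alignments are kept. The boundary convention is configurable because "length above 40 bp" can be read either way; the inclusive reading treats 40 as a screening threshold |
| `maxEvalue` | 1e−4 | screening cutoff on the E-value |
| `minIdentityPct` | 0 | off at the search stage; identity screening belongs to curation |

# Full-length gene recovery

Gene calling is an exhaustive six-frame ORF scan rather than a trained gene
finder: every maximal start-to-in-frame-stop interval of at least
`minLenNt = 300` nt (100 codons, a conservative floor for real resistance
genes) on either strand is reported, with the most upstream start taken when
several starts share a stop. The scan is deterministic and training-free,
which matters because recovery is *hit-anchored*: ORFs only become gene
calls when a screened homology hit overlaps them (≥ 50% of the hit interval
by default, strand-matched), so the gene finder needs completeness, not
discrimination. Translation uses the bacterial/archaeal code (table 11)
with alternative starts ATG/GTG/TTG rendered as Met and N-containing codons
as X. Internal coordinates are 0-based half-open; GFF3 output is 1-based
inclusive per the standard.

Curation is operationalized as a nearest-reference identity cutoff
(`minIdentityPct = 70`): a recovered gene survives when its best hit
identity is at least 70%, and inherits the family label of that reference.
A manual inspect-against-GenBank step is inherently irreproducible; the
identity cutoff is the quantitative criterion that stands in for it, and it
is configurable.

# Protein alignment and trees

Pairwise protein alignment is global Needleman–Wunsch/Gotoh under BLOSUM62
with affine gaps (open 10, extend 1), deterministic traceback (diagonal
preferred, then up, then left). The multiple aligner is single-pass
progressive: pairwise identity distances (d = 1 − pid/100, uncorrected —
adequate for guide trees at within-family divergences), an NJ guide tree
midpoint-rooted, and profile–profile merges up the tree scored by expected
sum-of-pairs BLOSUM62 score between column frequency profiles (gaps
contribute zero). Iterative refinement is deliberately omitted: the
consumers of these alignments here are motif-column bookkeeping and
distance trees, for which a deterministic single pass is sufficient and
reproducible. Two sequences reduce exactly to the pairwise aligner; row
order is preserved; ungapping any output row reproduces its input — all
invariants the test suite enforces.

Trees are neighbor-joining (via ape) with two post-passes for
well-definedness: taxa are sorted lexicographically before agglomeration so
ties resolve identically across sessions, and negative branch lengths are
clamped to zero with the deficit moved to the sister branch, preserving
path lengths through the parent. Maximum-likelihood estimation is out of
scope: the phylogenetic claims this package supports are topological
(congruence), and NJ on identity distances recovers additive trees exactly
(tested on random 8-leaf additive matrices). Congruence between trees is
quantified by the Robinson–Foulds distance — the symmetric difference of
non-trivial bipartition sets, counting only resolved splits for
multifurcating trees — with the usual normalization rf / (2(n−3)).

## Conserved-block trimming

Block trimming condenses an alignment to its well-aligned regions before
tree building. A column is *conserved* when its most frequent non-gap
residue reaches `consFrac = 0.5` of the rows (*strict* at
`strictFrac = 0.85`) and its gap fraction is at most `maxGapFrac = 0.5`.
Gap-heavy columns, and maximal runs of more than `maxNonconsRun = 8`
non-conserved columns, break blocks; blocks are shrunk to start and end on
strict columns and dropped below `minBlockLen = 10`. The defaults mirror
the spirit of the widely used conserved-block selection tools; the exact
settings such tools were run with in any given study are rarely printed, so
all five parameters are exposed.

# Evolutionary trace

The trace ranks alignment columns by how early in the tree's divergence
order they become conserved. The reference tree is midpoint-rooted (the
trace needs a root; midpoint is the standard choice when the true root is
unknown) and its internal nodes are ordered by topological depth from the
root — earliest-diverging first — with ties broken by the
lexicographically smallest leaf under the node, so partitions are
deterministic. Cutting the top k−1 nodes yields the k-group partition; a
column's rank is the smallest k at which every group is internally
invariant, up to `maxRank` (default: the leaf count, at which every
gap-free column is trivially ranked). Gaps count as a distinct symbol that
breaks invariance — the conservative choice for motif calling, since a
column cannot be called conserved for a group in which some members do not
even align there.

Class-specific columns (k = 2) are those invariant within each family but
with *differing, non-gap* consensus residues; requiring non-gap consensus
on both sides excludes columns that are "invariant" only because one family
is entirely gapped there. Motif windows are then read off the group
consensus at columns with rank ≤ `rankCutoff` (default 3), gaps skipped.
The cutoff of 3 reflects that family-diagnostic motifs should be conserved
at or very near the family partition itself; it is configurable because no
universal rank threshold exists.

# The motif screen

The screening alphabet is the family-diagnostic motif set: CXXC (HXXH
variant) and CPC (YPC variant) for the ATPase family's metal binding,
GDGIN for its ATP binding, HXH for the multicopper-oxidase family. Pattern
X matches any residue; a query X (from ambiguous codons) never satisfies
any pattern position — conservative under assembly ambiguity. Matching
runs on the ungapped candidate protein; all overlapping occurrences are
reported.

The default decision rule is an explicit reconstruction, since no printed
boolean formula exists for this kind of screen: an ATPase-family candidate
is HIGH_POTENTIAL iff it carries (CPC or YPC) *and* GDGIN — CXXC/HXXH are
recorded but not required, because roughly half of the known ATPase-family
members lack the N-terminal CXXC and mutagenesis studies show it is not
essential for resistance, while the transmembrane CPC is; YPC is accepted
wherever CPC is on the strength of an experimentally verified
YPC-carrying pump. A multicopper-oxidase candidate needs at least two
distinct HXH sites (these enzymes bind multiple Cu atoms at His-rich
centers; a single HXH is common by chance). Unclassified candidates are
never called. Every rule's status is enumerated in a rationale string, and
the whole rule set is a pure function of (matches, group), so the screen is
monotone: adding matches can never demote a call.

# The synthetic benchmark

## What it emulates

The generator builds the study conditions the recovery method is meant for:

* a reference database of two gene families (10 + 10 by default, 900–1800
  nt), each family descending from a random ancestor protein carrying its
  diagnostic motifs (CXXC+CPC+GDGIN; two HXH sites), members diverged by
  15% random residue substitution with motif residues protected, and the
  optional CXXC ablated in about half of the ATPase members;
* independent back-translation per member (uniform synonymous codons, ATG
  start, random stop), so nucleotide-level identity between family members
  is realistically far below protein identity;
* planted genes mutated to a target nucleotide identity (±1 point;
  substitution-only) with motif codons protected, embedded at uniform
  random offsets and strands in i.i.d. background contigs at 62% GC — the
  GC content of the thermophile/halophile-dominated tailings libraries this
  benchmark emulates — among decoy contigs (50 by default, 2–5 kb);
* an exact truth table, and scoring in which a recovered gene is a true
  positive when it overlaps a planted interval on the same contig and
  strand with Jaccard ≥ 0.5 (the standard interval-matching convention).

Substitutions that would create an in-frame stop codon are re-drawn: the
planted genes model *functional* full-length coding sequences, and a real
diverged-but-functional gene family is under purifying selection against
premature stops. Without this the benchmark premise ("a full-length gene is
present") would be silently violated at lower identities.

## What it does not emulate

No indels (an indel mode would break motif-coordinate bookkeeping and is
out of scope), no repeat structure or low-complexity sequence in the
background, no chimeric or misassembled contigs, no sequencing error, no
strain mixtures. Passing the benchmark therefore demonstrates the
*algorithmic* correctness of search, recovery and screening under
controlled divergence — not robustness to assembly artifacts, which real
metagenomes add on top.

## Benchmark results the suite reproduces

With the default conditions (20 planted genes, 50 decoys, fixed seed) the
pipeline attains 100% sensitivity and 100% specificity at 85% planted
identity, degrading monotonically over 95/85/75/65%; planting database
members unmutated reproduces perfect self-identification (the
`scripts/acceptance.R` benchmark: 4 members among 20 decoys, scored against
truth). Problem sizes throughout the suite — 200 alignment-oracle pairs,
50 ten-kb ORF-oracle contigs, 100 trace-oracle alignments, 100 additive
8-leaf trees, 1000 random strings per motif pattern — were chosen as the
smallest sets that exercise each property across its edge cases while
keeping the default test run fast on a single CPU.

# Numerical and degenerate-input choices

* Alignment tie-breaks are fixed (diagonal > up > left; M > X > Y among
  affine states), so all alignments are deterministic.
* The seeded search skips seed words containing N; N scores as a mismatch
  against everything during extension; query X residues satisfy no motif
  pattern position.
* Contigs shorter than the word size produce a warning and an empty result,
  not an error; an empty contig file runs the pipeline to completion with
  zero counts.
* An empty truth table makes sensitivity *undefined* (NA with a warning),
  never 0 — the distinction matters when aggregating benchmark runs.
* `njTree` rejects matrices with NA/NaN, asymmetry beyond 1e−8, or fewer
  than 3 taxa; 3-taxon trees use the closed-form branch lengths.
* All generator randomness derives from a single integer seed; generation,
  planting and mutation draw from separated seed streams so changing one
  stage's parameters does not reshuffle another's output.

# Configuration and interfaces

Stages communicate via on-disk artifacts (FASTA, BLAST-style 12-column
TSV, GFF3, newick, JSON report), so any stage can be rerun in isolation;
`runPipeline()` orchestrates them from a single configuration. The
configuration file format is YAML (`readPipelineConfig`), the natural
choice in the R ecosystem. The command-line front end
(`inst/scripts/copaminer`) is a thin wrapper over the exported functions.

# Limitations

* Frameshifted or pseudogenized genes spanning assembly errors are not
  recovered (no frameshift-aware alignment).
* The E-value calibration is ungapped-theory-on-gapped-scores; absolute
  E-values near the cutoff may differ from other engines by small factors,
  so hit *counts* at a fixed cutoff are engine-dependent even when the
  recovered gene set is stable.
* The motif rule set is a declared reconstruction; real screening studies
  involve judgment calls near motif boundaries that no fixed rule set
  reproduces exactly. The rules are configurable and every decision is
  logged in the rationale string.
* Exact conserved-block boundaries and evolutionary-trace rank cutoffs
  depend on alignment quality; highly divergent families (the
  multicopper-oxidase outliers especially) can defeat automatic alignment,
  which is why the screen anchors on ungapped-candidate motif content
  rather than on alignment-mapped positions by default.
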