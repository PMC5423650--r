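---
title: "Methods: comparative analysis of annotated mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of annotated mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocompare)
```

This vignette documents the models, algorithms and design decisions behind
`mitocompare`. The package targets the standard desk analysis of annotated
insect mitochondrial genomes — feature accounting, composition and codon
statistics, control-region structure, pairwise divergence and barcoding-gap
analysis, saturation profiling, and phylogenetic supermatrix construction —
with a synthetic-genome generator providing ground truth for every stage.

## Genome model and coordinates

An `annotated_genome` is a circular (or linear) nucleotide string plus an
ordered table of typed, stranded features. Coordinates are externally always
1-based inclusive, the GenBank convention; `complement(...)` locations parse
to the minority strand label `N`, and two-segment `join(x..L, 1..y)`
locations mark features wrapping the replication origin. A wrapping
feature's length is `end − start + 1 + L`. Extraction returns the stored
subsequence for `J`-strand features and its reverse complement for `N`.

Adjacent features (circularly closed: the last feature pairs with the first)
define one record each: a *spacer* of `next.start − prev.end − 1` bp, an
*overlap* of `prev.end − next.start + 1` bp, or an exact *abutment*. The
A+T-rich control region is treated as an annotated feature, never as a
spacer, so on a fully annotated circle

`sum(feature lengths) + sum(spacers) − sum(overlaps) = genome length`,

an identity the test suite asserts on generated genomes. Ambiguous bases (N)
are allowed in sequence; they never pair in hairpins, never match motifs,
and are excluded from composition denominators (the ACGT-only convention is
primary, since real submissions of this kind contain none).

## Composition and codon usage

AT skew is `(A − T)/(A + T)` and GC skew `(G − C)/(G + C)`, both undefined
(flagged `NA`) when the denominator is zero. Codon usage is counted in frame
0 over supplied CDSs; the 1-2 trailing nucleotides of incomplete stop codons
are dropped, and codons containing non-ACGT characters are skipped with a
warning. RSCU is `count × family_size / family_total` within synonymous
families derived from the invertebrate mitochondrial code (translation
table 5, where AGN is serine and ATA is methionine), with leucine split into
CUN/UUR and serine into UCN/AGN sub-families — the `L/L*/S/S*` convention of
published mitogenome codon tables. Complete stop codons (TAA, TAG) form
their own two-member family and are counted by default, matching the usual
"including the stop codons" reporting. Within every observed family the RSCU
values sum to the family size by construction; this is property-tested on
random codon streams.

Incomplete stop codons are diagnosed from CDS length mod 3: remainder 1 is
`T-`, remainder 2 is `TA-`, remainder 0 requires a literal terminal TAA/TAG
(anything else is a classification error). The annotated stop nucleotides
are assumed to lie inside the printed CDS interval; this assumption is
validated by the length-mod-3 consistency of all 26 CDS rows in the shipped
annotation tables. The start-codon vocabulary is the set observed in
blattarian mitogenomes (ATG, ATA, ATT, ATC, TTG) plus GTG; anything else is
reported verbatim with a warning rather than rejected.

## Control-region structure

**Motif scanning.** IUPAC patterns are expanded to ACGT character classes;
all, possibly overlapping, occurrences are reported, optionally on both
strands (reverse-complement hits are mapped back to stored-strand
coordinates). Composite elements with variable spacers — such as the
`A…TAATTTA…TT…ATA…ACATTT` core of the TA(A)-type conserved block — are
handled by a small gapped-pattern language: whitespace-separated IUPAC words
and `N{n,m}` wildcard runs, rather than a dedicated algorithm.

**Tandem repeats.** The detector is deliberately simple and fully
deterministic, *not* a re-implementation of Tandem Repeat Finder's
probabilistic alignment scoring: for each candidate period `p` (default
3-200) it seeds on maximal runs of exact lag-`p` self-matches, extends
greedily in both directions while the running identity of the extension
stays at or above `min_identity` (default 0.85), and reports maximal,
non-redundant calls with fractional final copies (`copies = span / p`,
minimum 2.0). For any region the minimal-period call wins: calls whose
consensus unit is tiled by a smaller period are suppressed, and a call is
dropped if more than half of its span is already covered by an
earlier (smaller-period) call. Reported identity is the fraction of span
positions matching the rotated consensus unit.

**Conserved blocks.** In an equal-length alignment a column is conserved
when it contains no gaps and all sequences agree (a `column_threshold`
below 1 relaxes this to the modal-state fraction). Runs of conserved columns
are merged across at most `max_interruptions` (default 1) variable columns;
blocks narrower than `min_width` (default 10) are dropped, and similarity is
`100 × conserved columns / width` — so one variable column in twenty scores
95%, the conservation level typical of the subfamily-diagnostic block 1.
The published record gives no numeric widths or boundaries for the three
control-region blocks, so these thresholds are package defaults, exercised
on synthetic alignments.

**Hairpins.** Stem-loop prediction is base-pair maximization, not
thermodynamic folding: an exhaustive search over loop placements within
`[loop_min, loop_max]` (defaults 3-20 nt) extends the stem outwards counting
A:T, G:C and optionally G:T wobble pairs, tolerating up to
`max_stem_mismatch` unpaired rungs (default 0). The call with the most
paired bases wins; ties break to the shorter loop, then leftmost. One
consequence of wobble pairing worth knowing: a perfect `G…/T…/C…` inverted
repeat can reach its maximal stem count with several loop placements
(G pairs the loop Ts), and the tie-break then selects the shortest loop;
disabling `allow_gu` restores the canonical Watson-Crick call. The longest
run of T in the winning loop is reported as the T-stretch; standalone poly-T
detection uses a 5-T floor.

## Divergence, barcoding gap, saturation, NJ

Substitution counts use pairwise deletion: only sites with unambiguous
A/C/G/T in both sequences enter `n`; A↔G and C↔T are transitions (`P`),
every other difference a transversion (`Q`). The Kimura two-parameter
distance is

`d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)`

with the analytic delta-method standard error
`SE² = [c₁²P + c₃²Q − (c₁P + c₃Q)²]/n`, `c₁ = 1/(1−2P−Q)`,
`c₂ = 1/(1−2Q)`, `c₃ = (c₁+c₂)/2`. Outside the logarithm domain the pair is
flagged saturated (`NA`). The implementation is cross-checked in the tests
against `ape::dist.dna(model = "K80", variance = TRUE, pairwise.deletion =
TRUE)` to 12 decimals, and against simulation: at 10⁴ sites the estimator
recovers d ∈ {0.05, 0.15, 0.3} with mean error below 1% over 200 replicates
and an empirical spread matching the analytic SE within 20%. Distances are
kept at full precision internally and rounded to 3 decimals only in the
triangular report (distances below the diagonal, standard errors above).
Whether published tables of this form carry analytic or bootstrap SEs is
generally unstated, so SEs are reported but never asserted against
transcribed tables.

Barcoding-gap analysis partitions all pairs into intraspecific,
interspecific-within-genus (intraspecific pairs excluded — the printed
minimum of 0.076 in the shipped table confirms this convention, since
conspecific pairs go as low as 0.002), and intergeneric; a gap is present
when the smallest intergeneric distance exceeds the largest within-genus
interspecific distance. Optional `focal_genus`/`outside_taxon` arguments
restrict the two non-intraspecific categories.

Saturation profiles compute per-pair transition/transversion proportions and
K2P distances separately for codon positions 1, 2, 3. The summary statistic
is the least-squares slope of transitions against distance among the most
divergent quartile of pairs divided by the slope among the least divergent
quartile; a position is flagged saturated when this ratio falls below 0.5.
The threshold is a package heuristic (published analyses of this kind
present plots only); it cleanly separates a 10× third position from
positions 1-2 in simulation.

Neighbor joining is delegated to `ape::nj` (the standard Saitou-Nei
implementation); negative branch lengths are clamped to zero with a warning,
and Newick serialization goes through `ape::write.tree`. The tests verify
exact topology recovery on additive matrices from every unrooted topology
with 4-6 leaves, the three-point solution on 3 taxa, and agreement with
UPGMA on ultrametric input.

## Supermatrix construction

Per-gene alignments carry a class (PCG/rRNA/tRNA) and, for PCGs, a frame
offset: the number of leading columns before the first complete codon.
Third-position removal drops every column at codon position 3 for the given
frame and then *clears* the frame, so a second application is refused —
removing "third positions" of a two-position alignment is meaningless.

The manual removal of unaligned and unmatched alignment regions practised in
the literature is not reproducible; the package substitutes an explicit
rule, documented as a divergence: columns whose gap fraction exceeds
`max_gap_fraction` (default 0.5) are removed, codon-wise for PCGs (a whole
codon goes when any of its three columns fails) so the frame is preserved.

The four datasets are `ALL-123` (all genes, all positions), `ALL-12` (third
positions of PCGs excluded), `PCG-123` and `PCG-12`. Published descriptions
do not fix the order in which RNA genes are appended, so the package fixes
its own deterministic order: PCGs first, then rRNAs, then tRNAs, each in the
canonical ancestral-insect gene order. Taxa missing a gene receive a
`?`-filled block and are flagged. Widths obey
`PCG-12 = ⅔ × PCG-123` whenever all PCG widths are divisible by 3, and
partitions are contiguous, non-overlapping and cover the matrix — both
property-tested. Output formats are relaxed PHYLIP, NEXUS with a `charset`
per partition, and FASTA ('-' gap, '?' missing); the writers pair with
readers that round-trip sequences and partition boundaries exactly.

## The synthetic-genome generator

The generator emulates the study conditions of a blattid mitogenome: a
circular genome of ~15.6 kb at a target A+T fraction of 0.749, the canonical
37-gene + control-region layout with realistic lengths, start codons as
observed (TTG for COX1, ATT for ATP8/ND6/ND3, ATG elsewhere; stop classes —
complete, `TA-`, `T-` — implied by each CDS length), short intergenic
spacers including a 25 bp spacer carrying the `TACTTAA` realization of the
conserved motif, and a ~900 bp control region containing three planted
tandem arrays (defaults: periods 12/20/28 with 2, 2 and 2.5 copies,
mirroring the two-full-A, two-full-B, two-and-partial-C organization of a
repeat-bearing blattid control region), one planted hairpin (30-pair stem,
15 nt loop, 8 nt loop T-stretch — inside the 30-77-pair / 11-15 nt envelope
of real blattarian stem-loops), and three 20-mer conserved-block seeds.

Design points that make recovery well-defined rather than merely likely:

- **Determinism.** A single integer seed drives all randomness; the caller's
  RNG state is saved and restored, and the emitted truth ledger embeds a
  hash of the generating spec.
- **Composition calibration.** Excluding the AT-rich stop codons from the
  sense-codon draw would depress coding A+T below target, so the CDS base
  probabilities are solved (by root-finding) so that the sense-codon
  expectation hits the target; the emitted genome's AT fraction then sits
  within two binomial standard deviations of 0.749, which the tests assert.
- **Irreducible repeat units.** Planted units are resampled until they have
  no smaller tiling period and no circular lag-q self-match run long enough
  to seed a competing period-q call; flanking guard bases break the
  periodicity at both array ends. The ledger records *realized* copy
  numbers (`round(copies × period) / period`), since the planted span is an
  integer number of bases.
- **Hairpin guards.** The 3' arm is the exact reverse complement of the 5'
  arm; the two bases flanking the stem are chosen non-pairing (the rung just
  outside the stem compares them with each other), and the loop's terminal
  bases are chosen non-pairing and non-T so that neither an extended stem
  nor a longer T-stretch than planted can appear.

K2P pair simulation draws one sequence uniformly over ACGT and mutates it
per site with the K2P transition-probability matrix at total divergence `d`
(rates normalized so `α + 2β = 1`, `κ = α/β`), the same branch-length
convention as the estimator — so the estimate is directly comparable to the
simulation parameter. Codon alignments use a star design: each taxon
descends independently from a common ancestor with per-codon-position rate
multipliers, sufficient for saturation profiling without modelling a full
tree.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: there are no indels (real control regions differ
in length across taxa), no phylogenetic correlation structure (a star, not a
tree), no repeat-unit divergence (planted arrays are perfect copies;
real arrays drift), no AT/GC or strand skew beyond the global target, and no
homology between the conserved-block seeds of independently drawn genomes.
Conserved-block detection is accordingly tested on constructed alignments,
and results on real control regions depend on alignment quality upstream of
this package.

## Problem sizes and numerical conventions

The test suite runs at desk scale by choice: the K2P sweep uses 10⁴ random
(P, Q, n) cases; estimator recovery uses 200 replicates of 10⁴ sites at
three divergences; NJ recovery enumerates all 123 unrooted topologies with
4-6 leaves; planted-structure recovery uses 100 seeded genomes with
randomized array periods (3-30), copy numbers (2-6) and hairpin geometry
(20-40 pairs, 7-18 nt loops); the acceptance script simulates 20 genomes and
50 estimator replicates per divergence. All fixed seeds are arbitrary and
set once. Comparisons against transcribed tables use the printed precision
(3 decimals for distances, ±0.005 on 2-decimal means plus propagated entry
rounding); internal floating-point comparisons use `testthat`'s defaults
except where exact identity is the contract (coordinates, spans, counts).

## Known limitations

- The GenBank reader handles the subset of the format used by mitogenome
  records (single-span, `complement`, two-segment origin-spanning `join`);
  it is not a general GenBank parser.
- The tandem detector's greedy extension can report a slightly different
  span than an alignment-based tool for imperfect arrays near the identity
  threshold; period and unit calls remain stable.
- Saturation flagging is a heuristic summary of plot-based practice; treat
  the per-pair tables as the primary output.
- `barcoding_gap_summary` assumes one genus label per taxon; chimeric or
  unresolved assignments must be cleaned upstream.
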