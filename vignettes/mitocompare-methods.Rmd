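---
title: "Methods: comparative mitogenomics with mitocompare"
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

This vignette is the package's account of its models and procedures: what
each statistic assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and where genuinely open design choices were resolved.

## The data model

An `annotated_genome` is a circular (or linear) DNA sequence plus typed
features: protein-coding genes (`PCG`), `rRNA`, `tRNA`, `intron`,
`intronic_ORF` and free-standing `free_ORF`s. Coordinates are 1-based
inclusive, the GenBank convention, and an interval with start > end wraps
the origin of a circular molecule — the same representation GenBank uses
for origin-spanning features. Multi-exon features list their intervals in
5′→3′ order on the coding strand, so `coding_sequence()` is a simple
concatenate-then-reverse-complement. Two invariants are enforced
throughout and tested as properties: extraction is unchanged when the
genome is rotated, and a wrapped interval extracts the same sequence as
the equivalent non-wrapped interval after rotation.

Features are serialized to a tab-separated feature table
(`write_feature_table()` / `read_feature_table()`) that round-trips
losslessly; GenBank flat files and FASTA are read directly. The GenBank
reader is deliberately minimal — LOCUS, the feature table with
`join()`/`complement()` locations, and ORIGIN — which covers organellar
records; it is not a general-purpose GenBank parser.

## Composition, partition and contribution rates

Strand asymmetry uses AT skew = (A − T)/(A + T) and GC skew =
(G − C)/(G + C). `N` bases are excluded from every composition
denominator but still count toward region lengths: composition describes
the known bases, lengths are physical. A skew whose denominator is zero
is reported as 0 with a degeneracy flag rather than NaN.

`partition_regions()` assigns every nucleotide exactly one of four
classes with priority **rRNA/tRNA exon > PCG exon > intron >
intergenic**. The priority rule is what makes the partition a true
partition (classes always sum to the genome length, a property tested on
random synthetic genomes) and resolves gene overlaps deterministically —
the single base shared by nad4L and nad5 is counted once. Three
classifications were genuinely open and are resolved as follows:

* intronic ORFs count as *intronic*, not protein-coding — intron load is
  what they report;
* introns of rRNA hosts count as *intronic* for the same reason;
* tRNAs count as *RNA* alongside rRNA exons, and free-standing ORFs as
  *protein-coding*.

The contribution of a class to the size difference of two genomes is
`100 · (len_B − len_A) / (len(B) − len(A))`. Rates are signed — a class
can shrink while the genome grows — and sum to 100% whenever the total
difference is non-zero. With equal genome sizes the rates are undefined
and only the per-class differences are reported.

## Codon usage under translation table 4

All translation uses the mold mitochondrial code (table 4): TGA codes
tryptophan, the only stops are TAA and TAG, and ATG/GTG/TTG are accepted
start codons. Start/stop tabulation flags, rather than rejects,
non-canonical codons: real fungal annotations contain TTG and GTG starts
and the flag is the interesting observation. Genes whose CDS length is
not divisible by 3 are excluded from codon counts with a warning instead
of being silently truncated — a frame error is an annotation problem the
user should see. Stop codons are excluded from usage frequencies by
default (the usage plot of interest is over amino-acid-bearing codons);
RSCU of a codon is its count divided by the mean count of its synonymous
family, so each family sums to its size.

## Pairwise alignment

The aligner is global Needleman–Wunsch/Gotoh with affine gaps, compiled
in C++. Default scores: match +1, mismatch −1, gap open −2, gap extend
−0.5, with a gap run of length L costing `open + extend·(L − 1)`.
Tie-breaking in the traceback is fixed (diagonal, then gap in the second
sequence), making every alignment deterministic — important because Pcl
classification keys on exact mapped positions. Pairwise global alignment
(not multiple alignment) is sufficient here because the aligned units are
conserved mitochondrial coding sequences of near-equal length; that is a
deliberate desk-scale simplification.

## K2P and NG86

`k2p()` excludes gap and N columns, then applies
`d = −½ ln((1 − 2P − Q)·√(1 − 2Q))` with P and Q the transition and
transversion proportions. When the log argument is non-positive
(saturation) the distance is flagged undefined rather than clamped.

`nei_gojobori()` implements NG86 counting. Site counts come from the
three single-nucleotide neighbors of each codon; mutations *to* stop
codons are treated as inadmissible and excluded from the per-position
denominator (the most common NG86 convention; the tool it replaces does
not document its exact choice, so this one is stated here and frozen).
Codon pairs differing at k positions are averaged over all k! minimal
pathways, excluding pathways that pass through a stop codon; in the
degenerate case where every pathway is blocked, all pathways are used so
the difference is still counted. pN and pS are Jukes–Cantor corrected
(`K = −¾ ln(1 − 4p/3)`), flagged undefined at saturation, and Ka/Ks is
flagged when Ks = 0. The implementation is validated against an
independent exhaustive-pathway oracle on hundreds of random codon pairs.

Per-gene summaries are unweighted means over all genome pairs — the
source reports per-gene means across species without stating a
weighting, and the unweighted mean over pairs is the simplest
reproducible choice.

## Neighbor joining

`nj_tree()` is classic neighbor joining with two determinism rules: ties
in the Q criterion are broken by taxon order, and negative branch
lengths are clamped to zero with a flag. It is a desk-scale stand-in for
full Bayesian/ML phylogenetics, which is out of scope; on additive
distances it recovers the generating topology exactly (tested against
random trees and against an independent NJ implementation).

## Intron position classes

An intron's insertion position is the number of coding nucleotides 5′ of
it (an intron between nt p and p+1 is at position p, giving names like
P612). Positions are mapped onto a user-supplied reference CDS through a
global alignment: the mapped position is the count of reference bases in
columns up to the insertion point, and an insertion point inside a
reference gap maps to the nearest reference position 5′ of the gap, with
a flag. Mapping is monotone in the query position, and classifying a
genome against its own intron-free CDS returns the raw positions — both
tested as properties.

Class membership is by **exact** mapped position: position classes are
site classes, and no fuzz window is applied by default. Because
orthologous introns also tend to be similar in sequence, an optional
confirmation (`confirm_identity =` a percent threshold) aligns the
introns within each multi-member Pcl and reports the minimum pairwise
identity; position remains authoritative since no universal similarity
threshold exists. The reference CDS is an input (supplied as
FASTA/string), not shipped: reference choice is a scientific decision.

## Repeats

Interspersed repeats: exact k-mer seeds (default k = 16, both strands)
are extended without gaps. At `min_identity = 100` extension is exact and
the finder provably reports maximal exact repeats (it is tested for set
equality against an exhaustive diagonal-scan oracle); below 100 an
X-drop extension keeps the best-scoring endpoints (match +1, mismatch
−1, drop 20). The default thresholds — minimum length 50 bp, minimum
identity 75% — bracket the hit lengths and identities reported for real
fungal mitogenome self-comparisons; both are configurable because the
BLAST parameters they approximate are not standardized. Ungapped
extension is a stated simplification: a 50–400 bp mitochondrial repeat
with an internal indel will be reported as two hits.

The tandem detector compares the sequence with itself at every offset
p ≤ 200 and chains runs of matching positions into arrays. A mismatch
gap is bridged only when it is shorter than the period, the run beyond
it is at least four times the gap (the break-even of Tandem Repeats
Finder's default +2/−7 weights), and the array's overall match fraction
stays ≥ 0.8. Arrays need ≥ 2 copies and a span ≥ 12 bp; overlapping
reports at different periods keep the highest match fraction, then the
longest span, then the smallest period (so a homopolymer is reported at
period 1, not 2). This is an explicit simplification of Tandem Repeats
Finder: spans can exceed the planted array by a base or two when the
flank happens to continue the periodicity, and TRF's probabilistic
scores are not reproduced.

Shared-fragment (NUMT-like) search applies the same engine across
genomes with a 100-bp default minimum, reporting per-fragment identity
and the total aligned length.

## Gene order

Orders are circular lists of (gene, strand) sorted by genomic start;
duplicates are retained with copy ordinals. The conserved backbone of
two genomes is the longest common circular subsequence of their shared
single-copy genes, computed exactly by linearizing one order at every
rotation (and its reflection with strands flipped) and running an LCS —
quadratic per rotation, entirely adequate at ≤ 60 genes. Displaced genes
are shared single-copy genes outside the backbone; doubling events are
genes with a higher copy count in one genome. Displacement is defined
relative to the computed backbone, not an inferred ancestor —
ancestral-state reconstruction is out of scope.

For more than two genomes, a gene is `identical-in-all` only when no
genome in the set shows any displacement; once some genome is
rearranged, genes still in every backbone are `identical-in-majority`
(present in the backbone for more than half of the comparisons), and
genes missing from a backbone are `displaced`. The majority convention
formalizes the usual "identical in k of n species" reading of gene-order
figures.

## tRNA variation

tRNA structures are **inputs**: a per-tRNA region string over the codes
A (acceptor stem), D (D arm), C (anticodon arm), V (variable/extra arm),
T (T arm), L (linker), aligned to the sequence. Structure prediction is
out of scope, so the package never guesses a cloverleaf. Pairs are
matched by name + anticodon with multi-copy tRNAs matched by genome
order; a variable site is an aligned column with differing residues.
Indel columns count as variable by default (configurable) and are
attributed to the region of the structured partner, using the nearest 5′
residue for columns gapped in that partner. Total counts are symmetric
under swapping the genomes when the alignment is gapless; with indels
the attribution (not the count) can differ, which is why the default is
stated rather than silent.

## The synthetic-data generator

`generate_genome()` emulates a mid-sized fungal mitogenome: the 15 core
PCGs (atp6/8/9, cob, cox1–3, nad1–6, nad4L, nad5, rps3) with realistic
per-gene lengths, rns (1,673 bp) and rnl (3,720 bp), the 25-tRNA
complement (three trnM copies; two isoacceptors each for Arg/Ser/Leu;
large extra arms for trnS(tga) and trnL(tag), matching the observation
that tRNA size variation lives in the extra arm), ten group I/II introns
at named coding positions in cox1, cob, rnl, nad5, cox2 and nad1 (six
with embedded intronic ORFs), two planted interspersed repeats, a 1-bp
overlap between nad4L and nad5, AT-rich composition (GC 0.29, the
measured value for the smaller *Ramaria* mitogenome), and a default
molecule size of 52 kb — within the 50–153 kb range observed in the
relevant fungal subclass while keeping every test run fast. All
stochastic choices derive from one seeded RNG stream in documented
order, so output is byte-identical across runs and platforms.

`diverge()` derives a sister genome: per-site substitutions at stated
transition/transversion rates (default 0.02/0.01, a plausible
sister-species divergence), with protein-coding sites constrained to
keep the start codon valid, the stop codon a stop, and no internal stop
under code 4 — a blocked change is resampled among the remaining bases,
and the one base shared by the nad4L/nad5 overlap is left untouched.
Intergenic indels (geometric-ish lengths 1–12), intron gains/losses at
named positions, and gene move/duplication edits are applied with full
coordinate bookkeeping, and every event is recorded as ground truth:
per-gene transition/transversion and synonymous/nonsynonymous counts,
indel positions, and the edit list.

What the generator does **not** emulate — and therefore what passing
tests cannot show about real data: no indels inside genes, no rate
heterogeneity among sites or genes, i.i.d. intergenic composition (no
isochores or skew gradients), no fold-consistent tRNA secondary
structure (region strings are assigned, not derived from base pairing),
and no homology between intronic ORFs and real homing endonucleases.
Planted-truth recovery shows the *bookkeeping and algorithms* are
correct; it does not validate biological realism.

## Problem sizes and numerical choices

The test-suite and acceptance checks run at sizes chosen to exercise
every code path while completing in minutes on one CPU: 52-kb genomes
for full-architecture checks, 9-kb three-gene genomes for replicated
statistics (50 K2P replicates, 100 random partition specs, 200 NG86
oracle pairs, 2-kb sequences for exhaustive repeat oracles, 6-genome Pcl
sets with 49 introns in 27 classes). Floating-point report output is
fixed to 4 decimals so re-runs are byte-identical; percentages print to
2 decimals with raw values retained in JSON. Tolerances: exact
arithmetic is asserted to machine precision or to the printed precision
of the published value it reproduces; stochastic recoveries use 3
standard errors over their replicates.

## Known limitations

* The GenBank reader handles organellar-style records only (no
  multi-record files, no `order()` semantics beyond interval lists).
* Ungapped repeat extension splits indel-containing repeats.
* The NG86 stop-codon convention, while standard, is one of several in
  circulation; comparisons against tools using another convention can
  differ in the third decimal.
* Gene-order comparison assumes gene names are comparable across
  genomes; it does not attempt orthology inference.
* `diverge()` requires non-wrapping feature coordinates (as produced by
  `generate_genome()`); rotate a genome so no feature spans the origin
  before editing it.
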