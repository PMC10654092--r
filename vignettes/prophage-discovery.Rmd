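---
title: "Finding prophages, satellites and toxin cassettes in draft assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding prophages, satellites and toxin cassettes in draft assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Temperate phages integrate into bacterial chromosomes by site-specific
recombination between a phage attachment site (*attP*) and a bacterial one
(*attB*). The two sites share a common core sequence, so an integrated
prophage is flanked by two direct repeats of that core (*attL* and *attR*).
In well-assembled genomes a prophage is a contiguous island of phage-like
genes; in draft assemblies it is frequently interrupted by an assembly break,
leaving one phage fragment at the end of one contig and the rest at the end
of another. Mycobacterial genomes — the motivating system for this package —
additionally carry phage satellites (PICI-like elements with an integrase and
a capsid gene but no complete virion module), decayed prophage remnants, and
phage-encoded ESX-secreted toxin (PEST) cassettes combining a WXG100
effector, a polymorphic toxin (PT) and an immunity protein (Imm).

`prophagr` implements the full discovery chain as composable, data-frame
first functions: prophage calling against a reference phage database,
contig-end fragment splicing, a 15-gene sliding-window scanner with a
four-way classification of phage-like regions, attB/attP reconstruction from
core direct repeats, protein phamily ("pham") clustering with shared-gene-content
genome clusters, and PEST cassette mining via an iterative gene-neighborhood
network. A deterministic synthetic-genome generator with machine-readable
truth provides the benchmark the test suite and the acceptance script run
against.

## Models and procedures

### Nucleotide similarity search

The built-in aligner is a deterministic seed-and-extend search: exact 15-mer
seeds, chaining of seeds on a common diagonal (gaps up to 500 bp), and
ungapped X-drop extension (match +1, mismatch −2, drop-off 20). Identity is
the fraction of matching bases over the ungapped span; `N` never matches.
This is deliberately an *ungapped* stand-in for a BLAST search: the package's
primary use cases involve exact or substitution-mutated copies of reference
sequences, where indel handling buys nothing and determinism and exact
coordinate arithmetic matter. The `LocalAlignment` record contract is
pluggable, so a gapped external aligner can be swapped in for real data.

### Profile hits

Gene categories (archetypal phage genes, integrases, transposases, major
capsid proteins, and the PEST roles) are recognized with ungapped
position-specific score matrices: per-column log2-odds of residue frequency
with +1 pseudocounts over a uniform background. A hit score is the best
ungapped placement sum. Because the maximum over many placements of a
mean-negative random walk is biased upward, unrelated proteins frequently
score slightly above zero (we measured a null maximum near 13 bits over 900
trials), while genuine category members score in the hundreds of bits even at
25% mutation. The significance threshold therefore defaults to 30 bits —
far above the null, far below the signal — and is exposed as
`profile_score_threshold`. A real profile-HMM engine can stand behind the
same hit contract.

### Prophage calling and boundary refinement

`call_prophages()` chains alignments to each reference genome along a contig
(same strand, gaps ≤ 30 kb) and emits a call when the chain covers at least
40% of the reference. Calls are then snapped to the att core when
`find_core_repeats()` finds a qualifying direct repeat near the alignment
edges (at most `core_max_shift_bp` = 1 kb away); the core positions, not the
alignment edges, define the biological boundaries. Quality control then
omits calls that are truncated by a contig end (a boundary within 100 bp of
the end with no att core) or that carry excess bacterial sequence (fewer
than 33% of their genes with significant phage-archetype hits). The
truncation and contamination cutoffs are explicit defaults — the filter
itself is principled, its constants are tunable.

### Attachment-site machinery

The att core is recovered as the *longest exact direct repeat* with one copy
in a ±2 kb window around each prophage boundary. A pure length floor of
10 bp is kept for compatibility with short serine-integrase cores, but with
4 kb windows the longest *chance* shared substring is ~12 bp, so a naive
floor would return a spurious "core" for essentially every boundary pair.
The finder therefore additionally requires the repeat length to satisfy an
expected-occurrence bound: the expected number of chance repeats of that
length across the two windows must stay below `core_alpha` (default 0.001,
a union bound over the dozens of boundary searches a corpus run performs;
set `core_alpha = NULL` for the literal floor). Occurrences from many
strains are mapped onto one reference chromosome by aligning core + 200 bp
of upstream host flank and projecting along the alignment diagonal, so the
mapped interval is exact even when SNPs shave the alignment edges; ties
between equally good loci are flagged ambiguous rather than placed.
Consensus attB sites are the interval *intersections* of overlap-connected
occurrence groups — the most literal reading of "conserved coordinate
positions" — numbered attB-1, attB-2, … by reference position. attP is
rebuilt by circularizing the prophage at the core; `integrate_at_attB()` is
the inverse operation and the two are verified to round-trip exactly.

### Region scanning and classification

A window of 15 consecutive genes qualifies when it contains at least one
significant profile hit; the union of qualifying windows is merged into
maximal runs, so a lone hit yields a region of up to 29 genes, clipped at
contig ends (a hit-bounded extent is available via `region_extent`).
Windows slide one gene at a time and never span contigs. Classification:
regions with an integrase or transposase are *integrated elements* (excluding
regions overlapping an accepted prophage call); regions with archetypal
phage genes (including capsids) are *phage-related*; regions with both an
integrase and a major capsid gene are *candidate PICIs*; and phage-like
regions with significant nucleotide alignment to an intact phage are
*likely defective prophages*. Integrase/transposase-only regions are not
counted phage-related. Classes may co-occur.

### Phams, clusters and the proteome network

Two proteins share a pham iff they are connected in the transitive closure
of: global-alignment identity ≥ 50% over aligned columns with the shorter
sequence ≥ 50% of the longer. Alignment is Needleman-Wunsch
(`Biostrings::pairwiseAlignment`, identity matrix, gap open 10 / extend 4);
identical sequences are collapsed first and only pairs sharing an exact
amino-acid 5-mer are aligned (a pair at the 50% threshold shares one with
high probability; the test oracle runs the exhaustive version). Shared gene
content between genomes is the symmetric mean of the two directional
shared-pham fractions, counting distinct phams (paralogs once);
`min_denominator` is available as an alternative strategy. Genomes join a
cluster at ≥ 35% shared gene content (connected components, labels A, B, C,
… by decreasing size), and the proteome network joins nodes at ≥ 25% — by
construction a supergraph of the cluster graph. Cluster labels here are
synthetic and size-ordered; they are not the historical cluster letters of
any curated database, and subcluster assignment is out of scope.

### PEST mining

Role phams (PT, WXG, Imm) are seeded by profile homology; each pham gets at
most one role (best score wins, conflicts recorded). The neighborhood
network starts from PT phams and repeatedly adds the phams of genes within
two ORFs (rank distance, strand-blind, no contig wraparound) of any member
gene of a network pham, genome-wide, until no new pham appears; the result
equals the seed-containing components of the pham rank-adjacency graph,
which is how the tests verify it. The alternative reading — only seed genes
anchor expansion — is available as `pest_expansion = "seeds_only"`.
Cassettes are read off as the contiguous same-strand run of role-bearing
genes around each PT gene, in transcription order: `WXG,PT,Imm` is the
three-gene architecture, `WXG,WXG,PT,Imm` the four-gene one, anything else
with a PT is reported incomplete.

Superfamilies group PT phams by their conserved N-terminal secretion domain
(window: 200 aa). Per-pham profiles are compared by the cosine similarity
of mean-centered column log-odds vectors over the best ungapped offset with
at least 100 overlapping columns. Centering and normalization matter: raw
dot products scale with profile depth and inherit a positive offset from the
shared background structure of log-odds columns, which can bridge unrelated
families; the normalized score separates same-family (≥ 0.80) from
unrelated (≤ 0.09) pairs on the generator's own distributions, and the
threshold defaults to 0.4. Requiring 100 overlapping columns (half the
window) prevents short chance overlaps from linking families. Components
are labeled PEST1, PEST2, PEST3 by decreasing size; further components are
`unassigned-k`. Conservation profiles (modal-residue frequency per column,
gaps excluded from the numerator only, 15-column moving average) recover
WXG/linker/TOX boundaries by thresholding at the profile mean.

## The synthetic corpus

`generate_corpus()` emulates the study conditions at desk scale: 20 draft
assemblies sharing one ~110 kb chromosomal backbone (i.i.d. background DNA
at GC 0.66, ~90 decoy genes, per-strain substitutions confined to
intergenic gaps at rate 0.002), five attB loci (three inside tRNA genes,
one in the tmRNA gene, one intergenic; cores 40-50 bp), and eight reference
phages (~15-18 kb, core + integrase/capsid/archetype genes + core) in three
labeled clusters. Planted elements: 30 intact prophages (exact reference
copies integrated at their cognate attB), 10 prophages split across contig
ends at a mid-genome breakpoint, 8 PICIs, 25 PEST cassettes from 3 toxin
archetypes (8% amino-acid mutation on the conserved domains), 6 exact
defective remnants, plus 5 contig-end-truncated and 5
bacterially-contaminated decoy elements that the QC filter must omit. Two
fixture-design constraints keep the benchmark honest rather than easy:
archetype families are drawn without replacement within one phage, and the
bases abutting each att core are forced to differ from the host bases
flanking the attB core — otherwise chance one-base repeat extensions make
the *planted truth*, not the detector, ambiguous. Generator and detectors
share no logic.

What the corpus does not emulate: indels and rearrangements, gene-calling
noise, codon bias and realistic oligonucleotide composition, horizontal
exchange between phage lineages, and assembly artifacts beyond clean
breaks. Passing the recovery tests therefore demonstrates correctness of
the algorithms under substitution-only divergence at these scales, not
field performance on real draft assemblies, where a gapped aligner and real
HMM profiles should be plugged into the homology contracts.

## Worked example

```{r example}
library(prophagr)

corpus <- generate_corpus(seed = 1)
report <- run_pipeline(corpus$assemblies, corpus$db, corpus$profile_db,
                       corpus$genes,
                       reference = corpus$reference,
                       reference_features = corpus$reference_features)
report
glance(report)

# clade-style summary table
grouping <- setNames(rep(c("cladeA", "cladeB"), each = 10),
                     names(corpus$assemblies))
summarize_corpus(report, grouping)

# attB catalog with tRNA/tmRNA overlap annotation
report$attB

# PEST cassettes with architectures and superfamilies
dplyr::count(report$cassettes, architecture, superfamily)
```

## Numerical choices and degenerate inputs

Problem sizes throughout (backbone ~110 kb, phages ~15-18 kb, 20 assemblies)
were chosen so a full corpus run completes in a few minutes on one CPU while
still exercising every code path several times over. Determinism is
end-to-end: the generator takes one seed, the pipeline takes none beyond its
config, and two runs with the same inputs produce byte-identical report
bundles (verified by hashing in the tests). Degenerate inputs are defined,
not accidental: empty protein sets produce empty pham sets; contigs shorter
than the window form a single clipped window; single-fragment splices are
`partial`; consensus groups with an empty intersection are split at the
largest start-coordinate gap with a warning; a corrupt assembly fails in
isolation while the rest of the corpus completes, with the failure recorded
in the report.

## Known limitations

The ungapped aligner will fragment alignments across indels; pham identity
uses a unit substitution matrix rather than BLOSUM, which is conservative
for distant homologs; att cores shorter than the significance length at the
default window size (about 24 bp) are only recoverable by lowering
`core_alpha`/`boundary_search_bp`, mirroring the real difficulty of
predicting serine-integrase sites; and cluster labels are corpus-local. The
region classifier trusts its profile database: categories missing from the
database are invisible to it.
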