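---
title: "Methods: curating and analysing NifB protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating and analysing NifB protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nifb)
```

NifB is the radical-SAM maturase that synthesizes NifB-co, the [8Fe-9S-C]
cluster that is the obligate precursor of the active-site cofactors of all
three nitrogenases (FeMo-co, FeV-co and FeFe-co). Public annotations of NifB
are noisy: because the NifX domain occurs in NifB, NifX, NifY and NafY,
stand-alone NifX proteins are routinely mis-annotated as NifB. This package
implements a pipeline for working with candidate NifB databases: a
motif-fingerprint filter that removes such false positives, a three-class
domain-architecture classifier, per-taxon architecture frequency tables,
distance phylogenetics for domain-split trees, and a synthetic-data
generator that provides ground truth for every stage.

## The fingerprint filter

Experimentally validated NifB proteins share six motifs strictly conserved
in the SAM-radical domain, in N-to-C order:

| motif | pattern | role |
|---|---|---|
| HPC | `HPC` | SAM-radical domain |
| AdoMet triad | `Cx3Cx2C` | cysteines ligating the SAM-binding [4Fe-4S] cluster; common to radical-SAM enzymes |
| ExRP | `ExRP` | SAM-radical domain |
| AGPG | `AGPG` | SAM-radical domain |
| TxTxN | `TxTxN` | SAM-radical domain |
| Cx2CRxDAxG | `Cx2CRxDAxG` | SAM-radical domain |

The pattern grammar is deliberately small: uppercase canonical residue
letters are literals, a lowercase `x` is exactly one arbitrary residue, and
an integer immediately after `x` repeats the wildcard. There are no
position-specific scores, profiles or back-references; the filter is meant
to be strict and auditable. Two semantic choices matter:

* An `X` (unknown residue) in the input matches wildcards but never
  literals — an unknown residue cannot *confirm* a strictly conserved
  position, and the filter's stated bias is to prefer losing true positives
  over admitting false ones.
* `match_fingerprint()` requires the six motifs in N-to-C order with
  non-overlapping placements. Order enforcement is a package decision (the
  motifs are always drawn in a fixed order along the domain); because every
  pattern has a fixed span, greedy leftmost placement is earliest-end
  interval scheduling and is provably optimal, so the backtracking search
  the implementation performs only matters for hypothetical variable-span
  patterns. `ordered = FALSE` relaxes the check to mere presence.

A sequence passing all six motifs is accepted as NifB; `curate()` applies
this to a database and reports the reduction. The reduction fraction is
reported as computed (e.g. removing 101 of 390 candidates is 0.259), never
restated as a rounder figure. Records that fail are not discarded silently:
`reclassify_rejected()` scans them for a NifX-like domain, reproducing the
observation that most rejected candidates are mis-annotated NifX proteins
(they lack the AdoMet `Cx3Cx2C` motif but carry NifX homology).

### Motif discovery

`discover_fingerprint()` inverts the process used to define the fingerprint:
given an alignment of proteins of proven function it reads off maximal runs
of conserved columns. A column is a literal when it is gap-free and one
residue reaches `min_conservation` (default 1.0); gap-free non-conserved
columns inside a run become wildcards. Runs break at gap columns and at
wildcard stretches longer than `max_wildcard_run`. The default
`max_wildcard_run = 3` is dictated by the fingerprint itself: the AdoMet
motif `Cx3Cx2C` contains a run of three wildcards, so any smaller cap would
split the motif that defines the family. Patterns must start and end on a
literal and contain at least `min_motif_len = 2` literals.

## Architecture classification

Three architectures occur in nature: a stand-alone SAM-radical domain (all
Euryarchaeota and a minority of Bacteria), SAM + C-terminal NifX-like domain
(the dominant bacterial form, the product of an ancestral gene fusion), and
a three-domain form with an additional NifN-like domain, confined to
Firmicutes.

The SAM-radical domain is located by the fingerprint (span = first motif
start to last motif end, score 1 by construction). The NifX-like and
NifN-like domains are located by local alignment (BLOSUM62, affine gaps with
open 11 / extend 1 — conventional protein defaults) against a reference
panel of template sequences, a self-contained replacement for profile
database queries that avoids any dependence on an external database version.
A domain is called at identity ≥ 0.35 over ≥ 50 aligned columns; the
threshold sits far above the empirical null (the best local-alignment
identity of random 150-mers against the panel stays below 0.35 across
hundreds of trials — this is tested) and far below the identity of any
genuine homolog the generator plants (≥ 0.5).

Classification order encodes the curation logic: fingerprint first, so a
record failing it is `NOT_NIFB` no matter what homology domains it carries.
For survivors, NifX-like is searched C-terminal to the SAM span and
NifN-like in both flanking regions. One labelling rule is a package
decision: since the three-domain architecture arose as a NifN fusion to the
SAM+NifX form, a NifN-like hit is only attached when a NifX-like domain is
also present; an isolated SAM+NifN combination (never produced by the
generator, and not among the three labels) would be reported as `SINGLE`
rather than invent a fourth class.

`architecture_frequencies()` tabulates calls per (superkingdom, group) with
counts and integer percentages. Percentages round half up, mirroring how
such tables are conventionally printed; this is also why printed rows can
total 99–101 while the underlying counts are exact.

## Phylogenetics

The tree path is deliberately the distance path: progressive alignment,
conserved-block trimming, Poisson-corrected p-distances, neighbor joining,
outgroup rooting. Likelihood and Bayesian estimation are out of scope; NJ
is exact on additive matrices, which gives the estimator a sharp, testable
correctness criterion.

* `align_progressive()` is a small guide-tree + profile–profile
  Needleman–Wunsch aligner (sum-of-pairs BLOSUM62 column scores, linear gap
  penalty −8, deterministic diagonal-first tie-breaks). It exists so the
  downstream stages are exercisable end to end; production alignments can be
  ingested with `read_fasta(..., gaps = TRUE)`.
* `select_blocks()` removes poorly aligned segments before tree building.
  Defaults mirror the canonical conserved-block trimming defaults: a column
  is conserved when its modal residue reaches 0.5 of rows, highly conserved
  at 0.85; runs of ≥ 8 consecutive non-conserved columns break blocks;
  blocks are trimmed to highly conserved flanks and dropped below 10
  columns. With `allow_gaps = FALSE` (default) any gap-containing column is
  excluded outright and splits blocks — the behaviour of the trimming tools
  this emulates. Retained block lengths are data- and aligner-dependent, so
  the package logs its own block report rather than asserting any published
  length.
* `pdistance()` uses pairwise deletion and, by default, the Poisson
  correction d = −ln(1−p). Saturated pairs (p = 1) and pairs with no
  comparable columns are hard errors naming the offending sequences, never
  silent NA.
* `nj_tree()` implements canonical neighbor joining with two determinism
  rules: ties in the join criterion are broken by the lexicographically
  smallest pair of cluster labels (a cluster is labelled by its smallest
  member leaf), and negative estimated branch lengths are clamped to zero.
  Runs are therefore bit-reproducible. Correctness is tested against
  closed forms (2 and 3 taxa) and by topology recovery from random additive
  matrices, and cross-checked against an independent NJ implementation.
* `root_tree()` places the root at the midpoint of the outgroup's pendant
  branch. Trees are `ape::phylo` objects and round-trip through Newick.

## The synthetic-data generator

`generate_dataset()` builds labelled datasets with the statistical structure
the analysis assumes. A genuine record is
`[NifN-like + linker]? + flank + motif1 + spacer + … + motif6 + flank +
[linker + NifX-like]?`: motif literals are planted exactly, wildcard
positions and spacers are uniform draws, and homology domains are template
copies mutated to a configured identity (default 0.8). Contaminants are
mutated NifX-template copies with no planted motifs, rejection-sampled to
guarantee fingerprint failure. Substitution noise (default 0) never touches
motif literal positions, so ground-truth labels remain exact at any noise
level; a separate ablation option overwrites a named motif to create
fingerprint-failing NifB-like decoys.

Defaults are the conditions the validation suite runs under: four taxa
(three bacterial groups plus an all-single-domain Euryarchaeota group), 160
genuine records, and a 0.2 contaminant fraction, for 200 records total. The
per-group architecture proportions echo the published per-phylum
distribution — the two-domain form dominating Bacteria, the Firmicutes
carrying all three forms at 0.55/0.32/0.13, Euryarchaeota entirely
single-domain. (The printed per-phylum percentages 55/33/13 total 101 after
rounding; proportions here must sum to exactly 1, so the two-domain share
absorbs the rounding slack.) Largest-remainder rounding converts proportions
to integer counts, so configured frequencies are reproduced *exactly* on
noise-free data rather than in expectation. Shipped NifX-like/NifN-like
templates are fixed synthetic sequences with no biological claim attached
(the NifX template is screened to contain no `Cx3Cx2C` occurrence).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: real spacer/domain length distributions, indels,
compositional bias, correlated substitutions, motif degeneracy in genuine
NifB proteins (real curation loses some true positives by design), and
phylogenetic structure (sequences are i.i.d. given their label, so
generator data cannot validate tree *accuracy* on real families, only the
estimator's exactness on additive inputs).

## In-silico computations

`average_mass()` sums standard average (not monoisotopic) residue masses
plus one water — the right scale for comparing a theoretical mass with a
gel-filtration estimate. `insilico_pcr()` anneals the 3'-terminal
`anneal_len` bases (default 15) of each primer at a unique template site,
extends annealing 5'-ward as far as the primer matches, and appends
non-annealing tails to the product while excluding them from template
coordinates. `translate_cds()` applies the standard code, refusing frames
with internal stops. `synthetic_truncation_template()` builds a synthetic
1404-nt CDS plus a primer pair whose product coding region is the first
1008 bp, reproducing the published truncation arithmetic (468-aa full-length
protein; 336-aa C-terminally truncated variant) without requiring the real
accession sequence, which is not redistributed here. For the same reason the
published 46.8 kDa theoretical mass is not asserted anywhere: it requires
the real protein sequence, which users can supply to `average_mass()`
themselves (computing it with and without any purification tag is
recommended, since printed values rarely state tag inclusion).

## Numerical and degenerate-input conventions

* Coordinates are 1-based and inclusive on both ends in every report.
* Empty FASTA input, empty datasets and empty fingerprints are errors;
  a sequence shorter than a pattern span scans to an empty hit list.
* A two-taxon NJ "tree" is represented as two half-length pendant edges
  (the `phylo` structure requires an internal node); the leaf-to-leaf path
  equals the input distance.
* The generator saves and restores the caller's RNG state; identical
  configurations and seeds give byte-identical output files.

## Problem sizes in the validation suite

The test suite validates the motif scanner against a brute-force
exhaustive-offset oracle on 1,000 random (sequence, pattern) pairs, block
selection against a column-by-column rule oracle on 200 random alignments,
NJ on 100 random additive matrices of 4–10 leaves (plus closed-form branch
lengths), and pipeline closure on the default 200-record dataset; these
sizes keep the full suite comfortably within a few minutes on one core
while leaving each property's failure modes nowhere to hide.
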