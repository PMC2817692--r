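---
title: "Detecting REPs, RAYTs and BIMEs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting REPs, RAYTs and BIMEs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repbime)
```

## The elements

Repetitive extragenic palindromes (REPs) are short (~20-35 nt) repeats that
occur in hundreds of copies in many gammaproteobacterial genomes, almost
always between genes.  Structurally, a REP is

```
leading + head + spacer + left_arm + loop + right_arm + tail
```

where the *head* is the conserved tetranucleotide GT(A/G)G that defines the
element's orientation, the *arms* form a GC-rich palindromic stem
(`right_arm` is the reverse complement of `left_arm`), and the *loop* is the
short noncomplementary middle.  In the *Pseudomonas*/*Xanthomonas* lineage a
GA dinucleotide *spacer* separates head and stem; short *leading* and
*trailing* bases round out several published consensi.

REP-associated tyrosine transposases (RAYTs) are IS200/IS605-related
proteins whose genes are flanked by two REP copies in inverted orientation.
Their diagnostic residues are an N-terminal conserved threonine, the
catalytic H-phi-H triad (phi hydrophobic), an NP(L/V)(R/K)xG motif near the
C-terminus, and the nucleophilic tyrosine adjacent to it.  Bacterial
interspersed mosaic elements (BIMEs) are composite repeats of regularly
spaced REPs in alternating orientations, built from tandem "basic modules"
(an inverted REP pair with its intervening and trailing segments).

This vignette documents the models, the tunable parameters and the design
choices behind the package's implementation of the full in-silico pipeline:
REP structural parsing, RAYT motif classification, flank discovery, genome
scanning, BIME decomposition, coevolution testing, and the synthetic-data
generator that makes all of it testable with known ground truth.

## The REP parser

`parse_rep_strict()` searches all decompositions of a candidate sequence
(at most 60 nt) under the constraints

| parameter     | default | meaning                                      |
|---------------|---------|----------------------------------------------|
| `min_arm`     | 5 nt    | minimum stem arm length                      |
| `max_loop`    | 12 nt   | maximum loop length                          |
| `max_spacer`  | 2 nt    | head-to-stem spacer (covers the GA dinucleotide) |
| `max_leading` | 1 nt    | bases allowed before the head                |
| `max_tail`    | 6 nt    | trailing bases after the right arm           |

and returns the decomposition maximizing arm length, tie-broken by smaller
loop, then smaller spacer, leading and tail.  No published source defines a
canonical decomposition where several exist; arm maximization is this
package's convention, and the strict parser is contract-tested against an
exhaustive brute-force enumeration on sequences up to 40 nt.

`parse_rep_relaxed()` aligns the arms as an imperfect stem, allowing up to
`max_interruptions = 2` mismatch-or-bulge events (a bulge is an unpaired
run of at most `max_bulge = 4` bases and counts as one event, whatever its
length).  The bounded-event stem alignment runs in compiled code.  A
strictly parsable input always returns its strict decomposition with zero
interruptions; otherwise the parser minimizes interruption events, then
maximizes paired bases.  One consequence worth knowing: for the
enterobacterial (E. coli-type) consensus, the minimal-event decomposition
pairs unequal arms across a single 3-nt bulge (one interruption), whereas a
mismatch-only reading of the same palindrome shows two interruptions.  Both
describe the same imperfect stem; the event count depends on the alignment
convention, which is why the classifier thresholds events rather than
asserting a particular count.

Arm GC content is reported (`arm_gc`) but never used as a filter: a hard
GC cutoff would reject enterobacterial arms, whose GATAAG-containing stems
are not especially GC-rich.  `N` bases never match anything, including
another `N`.

## RAYT motif classification

`find_motifs()` quantifies the prose definitions: "near the N-terminus"
becomes the first 40 residues (`nterm_window`), and "adjacent to the
nucleophilic tyrosine" becomes a tyrosine within 6 residues downstream of
the NP(L/V)(R/K)xG match (`adjacency_window`); no source states distances,
so both windows are configurable.  The hydrophobic set for phi is
A, V, L, I, M, F.  A protein is RAYT-like iff all four features are present
in the canonical order.  This is deliberately a motif classifier, not a
profile HMM: the discriminating features are few, strong and positional,
and a transparent rule keeps the decision auditable.

## Flank discovery and consensus derivation

`find_flanking_reps()` searches a 700-bp window on each side of a candidate
CDS (flanks are described as very close to the gene, but no bound is
published; 700 bp is configurable and generous).  Enumeration is
anchor-first: candidate substrings of 18-45 nt (bracketing all published
consensi) are seeded at GT(A/G)G occurrences on either strand and parsed
structurally.  Accepted elements are reported as canonical *core spans* -
head through right-arm end, leading and trailing bases trimmed - because a
de novo detector has no way to decide whether adjacent background bases
"belong" to the element.

The flank pair is the mutually inverted pair (opposite strands, one
sequence at least 80% identical to the reverse complement of the other)
closest to the CDS; nearest-to-CDS is this package's convention where
several REP-like elements occupy a window.  `derive_consensus()`
orientation-normalizes both flanks to the head-5' strand and emits a one- or
two-variant (dimorphic) consensus, upstream variant first.

Two behaviors deserve a note.  First, random DNA contains chance
GT(A/G)G-anchored palindromes surprisingly often (roughly a third of
random 700-bp windows at 60% GC contain a strict-parsable candidate, and
almost all contain a relaxed-parsable one), so "no flank found" is a
meaningful statement only under the strict parser; the relaxed fallback is
applied per side only when the strict enumeration finds nothing.  Pair
confirmation is robust to these spurious candidates because an unrelated
palindrome almost never reaches 80% identity to the true flank's reverse
complement.  Second, arm maximization means a planted element can be
extended by coincidentally complementary neighboring bases; the simulator
redraws such backgrounds (see below) so that recovery tests are exact.

## Genome scanning and copy counts

`scan_genome()` matches each consensus variant against both strands
allowing 0-2 substitutions (no indels: published copy counts are
consensus-length window matches, and indel-tolerant matching would change
them unverifiably).  Matching delegates to `Biostrings::matchPattern()` and
is contract-tested against a naive counting oracle.  Overlapping hits of
one family are deduplicated keeping the lowest mismatch count, then the
leftmost, then the plus strand, then the lower variant (so a perfectly
palindromic query, which matches both strands at one locus, yields exactly
one occurrence).  `summarize_counts()` reports the cumulative
exact / <=1 / <=2-mismatch triple from a single 2-mismatch scan; this is
contract-equal to three independent scans.  Contigs are scanned
independently; wrap-around matching on circular genomes is out of scope.

`presence_abundance_matrix()` tabulates counts across genomes and families.
The fold ratio between rayt-bearing and rayt-lacking genomes is a ratio of
geometric means of exact counts; a +1 offset is applied (to both groups)
only when a zero count is present, so small-sample contrasts with no zeros
are reported exactly.

## BIME clustering and decomposition

Occurrences at most `max_gap = 250` bp apart (end-to-start) chain into one
cluster; no spacing threshold is published, and 250 bp comfortably contains
the known composite repeats (e.g. the 89-bp P. fluorescens R0 unit) while
staying far below the background spacing of dispersed copies.  Classes
follow the orientation grammar: one REP is solitary; two inverted REPs are
a doublet (BIME-1-like); three or more in alternating orientations are
modular (the classic BIME); anything else is atypical.  Hybrid clusters mix
families.

`decompose_modules()` brackets modules greedily left to right (REPs 1+2
with the following segment, then 3+4, ...), attaching an unpaired final REP
to the last module as a flagged terminal half-module.  Published
descriptions of the basic module differ between an inverted-pair reading
and a direct-repeat reading; this package follows the inverted-pair
bracketing used in the composite-repeat diagrams, and the left-to-right
anchor is its own convention (the diagrams do not state one).

`label_segments()` pools all inter-REP segments and greedily assigns
letters: a segment joins the first label whose representative it matches at
>= 90% global-alignment identity with a length ratio >= 0.8, else founds a
new letter.  Labeling is orientation-sensitive.  Greedy first-fit makes the
partition dependent on input order only through letter names, which is the
property the tests assert.

`assess_rayt_association()` reports `adjacent` when a flanking REP of the
rayt gene is a member of the cluster, and `terminus_captured` when the
cluster span additionally covers the CDS 3'-terminal boundary (the
captured-terminus configuration in which the gene's 3' end becomes part of
an inter-REP segment).

## Identity, trees and congruence

`global_identity()` computes a Needleman-Wunsch global alignment (default
+1/-1 match/mismatch, -2 per gapped column) via `Biostrings`; percent
identity is matches over aligned columns excluding terminal-gap columns, so
a fragment aligned against an extension of itself scores 100%.
`build_nj_tree()` applies neighbor-joining (`ape::nj`) to pairwise
p-distances from the same aligner, and `rf_distance()` is the
Robinson-Foulds split distance on unrooted topologies (`ape::dist.topo`).
The coevolution claim is tested as RF = 0 between the RAYT-protein tree and
the REP-DNA tree - topology congruence only.  Branch lengths are not
compared: p-distance NJ is a deterministic, reimplementable stand-in for
the multiple-alignment guide trees used historically, and only the
topology statement is reproducible.

## The synthetic-data generator

`simulate_genome()` emulates the genomic architecture the pipeline targets,
with full ground truth:

* i.i.d. background at 60% GC by default (typical of the high-GC
  gammaproteobacteria carrying these elements), rejection-sampled so that
  no chance hit of any supplied consensus exists at up to 2 mismatches;
* dispersed solitary copies, inverted doublets (30-120 bp internal gaps),
  modular clusters with chosen module counts, and optional two-family
  hybrid clusters; inter-REP segments are drawn from a small reusable pool
  (30-80 bp) so segment-label recovery is testable;
* per-copy mutation counts k drawn from {0, 1, 2} with probabilities
  (0.7, 0.2, 0.1) by default - "slightly modified" copies differing in a
  few positions, while staying within the scanner's 2-mismatch tolerance so
  that recovered mismatch counts equal planted counts exactly;
* optionally a motif-complete 153-residue rayt-like CDS flanked by two
  inverted REP copies (palindrome-preserving mutations on request), plus
  unrelated neighbor CDSs;
* a placement scheme keeping planted elements >= 300 bp apart (beyond
  `max_gap`, so planted clusters never merge) and a final verification pass:
  the assembled genome is rescanned and the flank pair re-detected, and the
  genome is redrawn if any truth entry is not reproduced - this is what
  makes exact-recovery properties well-posed under an arm-maximizing
  parser.

Mutation is substitution-only, matching the scanner's model; there are no
indels, no rate heterogeneity and no codon model.  Passing recovery tests
on these genomes therefore demonstrates the pipeline's correctness on its
own model, not robustness to indel-rich or low-complexity real sequence.
Real genomes also contain REP-like structures the generator does not plant
(degenerate copies beyond 2 mismatches, nested clusters), which is why the
optional real-genome mode simply reuses the same scanner on user-fetched
assemblies.

`simulate_ortholog_pair()` derives two descendant genomes, mutating each
neighbor CDS at 5% per residue per lineage and the rayt CDS at a 2x
multiplier by default; mutation acts at the amino-acid level (each hit site
moves to one of the 19 other residues) and is re-encoded through a fixed
codon table, so stop codons cannot arise.  Flanking REPs receive 0-1
palindrome-preserving substitution events, mirroring the few point
mutations observed between ortholog flanks.

`simulate_coevolved_families()` evolves the ancestral protein and REP
independently down one guide tree.  The default is a six-taxon tree with
long internal (0.08-0.15 subs/site) and short terminal (0.06-0.10)
branches - six well-separated families, each sampled close to its ancestor,
which is the regime in which congruent protein and REP phylograms are
observable at all from a ~30-nt repeat.  REP sites drift at 1.5x the
protein rate by default (repeat DNA outside the protein's structural
constraint evolves faster).  These defaults were fixed once at design time
with a pilot simulation: under them the protein NJ tree matches the guide
in 100/100 seeded replicates and REP/protein congruence (RF = 0) holds in
~96/100; a balanced tree with equal rates, for comparison, drops
congruence below 60% purely through NJ noise on a 32-nt sequence -
a sampling limit, not an implementation defect.

## Problem sizes used by the tests

The packaged test-suite and the acceptance script exercise: the scanner vs
naive-counting oracle on 50-kb random genomes (100 in the test suite, 25 in
the acceptance script); strict-parser vs brute-force enumeration on ~180
sequences up to 40 nt; planted-structure recovery on 40-kb genomes carrying
43 REP copies in solitary, doublet, modular (m = 2-5) and hybrid
arrangements (50 and 25 replicates respectively); and 100 replicates each
of the coevolution and rate-contrast simulations.  These sizes give every
property enough replication to be meaningful while keeping a full run in
the minutes range on one core.

## Known limitations

* Substitution-only matching: a REP copy with an indel is invisible to the
  scanner (and to the published count convention it reproduces).
* The motif classifier encodes only the named diagnostic motifs; it does
  not reproduce a full reference alignment, and an unrelated protein
  carrying all four features in order would be called RAYT-like.
* Relaxed parsing is permissive on random sequence; de novo discovery
  should treat relaxed-only candidates as hypotheses to be confirmed by a
  mutually inverted partner or by genome-wide abundance.
* NJ on ~30-nt repeats is noisy; congruence statements are statistical
  (rates over seeded replicates), not per-instance guarantees.
* Real-genome copy counts depend on using exactly the published consensus
  variants; the packaged table ships them verbatim for that purpose.
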