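# repbime

Detection and characterization of **repetitive extragenic palindromes
(REPs)**, their cognate **REP-associated tyrosine transposases (RAYTs)** and
composite **bacterial interspersed mosaic elements (BIMEs)** in bacterial
genome sequences.

REPs are short (~20-35 nt) repeats found in hundreds of copies in many
gammaproteobacterial genomes, nearly always between genes.  Each consists of
a conserved `GT(A/G)G` "head" followed by a GC-rich, often imperfect
palindrome:

```
leading + head + spacer + left_arm + loop + right_arm + tail
            |                |        |         |
         GT(A/G)G          stem     middle   revcomp(left_arm)
```

RAYTs are IS200/IS605-related transposases whose genes are flanked by two
REPs in inverted orientation — an organization reminiscent of a transposable
element.  Their diagnostic residues are an N-terminal conserved threonine,
the catalytic H-&phi;-H triad, an `NP(L/V)(R/K)xG` motif near the
C-terminus, and the adjacent nucleophilic tyrosine.  BIMEs are arrays of
regularly spaced REPs in alternating orientations, decomposable into tandem
"basic modules" (an inverted REP pair plus its intervening segments).

The package implements the complete in-silico pipeline around these
elements, for microbial genomicists who want to find and characterize them
in assemblies or to study their dynamics in simulation:

* **rep parsing** — `parse_rep_strict()`, `parse_rep_relaxed()`,
  `classify_rep()`: structural decomposition of candidate sequences, exact
  or tolerating up to 2 mismatch/bulge stem interruptions;
* **RAYT classification** — `find_motifs()`, `is_rayt_like()`:
  conserved-residue signature on protein sequences;
* **flank discovery** — `find_flanking_reps()`, `derive_consensus()`:
  locate the inverted REP pair around a transposase CDS and derive the
  family consensus (dimorphic where the two flanks differ);
* **genome scanning** — `scan_genome()`, `summarize_counts()`,
  `presence_abundance_matrix()`, `extragenic_fraction()`: mismatch-tolerant
  (0-2 substitutions) copy counting on both strands, BED/TSV output;
* **BIMEs** — `cluster_occurrences()`, `classify_cluster()`,
  `decompose_modules()`, `label_segments()`, `assess_rayt_association()`:
  solitary/doublet/modular/atypical classes, module bracketing, inter-REP
  segment letters, hybrid detection;
* **coevolution** — `global_identity()`, `build_nj_tree()`,
  `rf_distance()`, `ortholog_rate_contrast()`: NJ topologies of RAYT
  proteins vs REP sequences and the substitution-rate contrast between
  rayt genes and their neighbors;
* **simulation** — `simulate_genome()`, `simulate_ortholog_pair()`,
  `simulate_coevolved_families()`: synthetic genomes with complete ground
  truth, so every stage is testable without downloading anything;
* **pipeline** — `run_pipeline()`: all stages chained end to end from a
  FASTA + GFF3 (+ optional protein FASTA / consensus TSV) configuration.

A curated consensus table for 27 published RAYT-associated REP families
(with their host strains and reported copy counts) ships in
`inst/extdata/rep_consensus.tsv` and loads with `load_rep_consensi()`.

## Worked example

```r
library(repbime)

## published consensi
cons <- load_rep_consensi()
cons[["Smal4"]]
#> REP consensus Smal4 (Stenotrophomonas maltophilia K279a): 1 variant(s)
#>   [0] GGTAGTGCCGGCCGCTGGCCGGCA (loop 3 nt, arm 8 nt)

parse_rep_strict("TGTAGAGCCGAGCCCATGCTCGGCT")   # the Smal1 consensus
#> REP structure (strict mode): T|GTAG||AGCCGAGC(8)|CCAT(4)|GCTCGGCT(8)|
#>   interruptions: 0, arm GC: 0.75

## a synthetic genome with known truth: 28 planted REP copies, doublets,
## modular BIMEs and a rayt locus
sim <- simulate_genome(seed = 1, length = 50000)
sim
#> Simulated genome: 50000 bp, GC 0.60, 28 planted REP copies, 5 cluster(s),
#> rayt locus planted

## discover the flanking pair de novo and derive the family consensus
rl <- sim$truth$rayt_locus
fl <- find_flanking_reps(sim$genome, rl$cds_start, rl$cds_end)
fl$flank_confirmed
#> TRUE
derived <- derive_consensus(fl$upstream, fl$downstream, family_id = "SmalDemo")

## genome-wide copy counts at 0 / <=1 / <=2 mismatches
summarize_counts(sim$genome, derived)
#> REP copies: 17/25/28 (exact / <=1 mm / <=2 mm)

## BIME structure
occ <- scan_genome(sim$genome, derived, max_mm = 2, genome_label = "sim")
cl  <- cluster_occurrences(occ, sim$genome)
table(vapply(cl, `[[`, "", "cluster_class"))
#>  doublet  modular solitary
#>        3        2       12
render_cluster(cl[[which(vapply(cl, `[[`, "", "cluster_class") == "modular")[1]]])
#> [<SmalDemo a SmalDemo> | b] [<SmalDemo b SmalDemo> | a] [<SmalDemo a SmalDemo>]

## REP/RAYT coevolution: congruent NJ topologies
fam <- simulate_coevolved_families(seed = 1)
rf_distance(build_nj_tree(fam$proteins), build_nj_tree(fam$reps))
#> 0
```

The copy-count triple (17 exact copies of 28 planted) reflects the
generator's per-copy mutation model — each planted copy carries 0, 1 or 2
substitutions — and the scanner recovers every copy with its exact mismatch
count.  The three-module rendering shows the alternating-orientation
structure with lettered inter-REP segments (`a` reused across modules, as
in real modular BIMEs).  An RF distance of 0 means the RAYT protein tree
and the REP sequence tree have identical topologies.

Real assemblies are analyzed the same way: `run_pipeline(list(genome_fasta
= ..., gff3 = ..., out_dir = ...))` classifies the annotated CDS products,
finds flanking REPs around RAYT-like genes, derives consensi, scans, and
writes BED/TSV/JSON reports.  A thin command-line wrapper lives in
`inst/scripts/repbime-cli.R`.

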