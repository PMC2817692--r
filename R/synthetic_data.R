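# Synthetic genomes with fully known ground truth.
#
# The generator emulates the genomic architecture the pipeline targets:
# a rayt-like CDS flanked by two inverted REP copies, dispersed solitary
# REPs with a per-copy mutation distribution, REP doublets, modular (and
# optionally hybrid) BIME clusters with reusable inter-REP segments, and
# ortholog genome pairs in which the rayt gene diverges faster than its
# neighbors.  Backgrounds are rejection-sampled to be free of chance
# consensus hits, and the assembled genome is re-verified against the truth
# ledger with the scanner before being returned.  Seeds are mandatory; no
# global random state is used.

.CODON_TABLE <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

#' Random DNA string at a given GC content
#'
#' @param n Length in bp.
#' @param gc GC fraction.
#' @return DNA string.  Uses the current RNG state (callers seed it).
#' @export
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Deterministic RAYT-like protein template
#'
#' A 153-residue synthetic protein carrying the four diagnostic RAYT
#' features in their canonical order: N-terminal threonine (position 3),
#' H-phi-H triad, NP(L/V)(R/K)xG motif near the C-terminus and the adjacent
#' catalytic tyrosine.  Filler segments are pseudo-random but fixed, and
#' exclude H and P so that no accidental motif copies arise.
#'
#' @return Amino-acid string.
#' @export
rayt_protein_template <- function() {
  filler_alphabet <- setdiff(.AA_LETTERS, c("H", "P"))
  withr::with_seed(20100119L, {
    f1 <- paste(sample(filler_alphabet, 52, replace = TRUE), collapse = "")
    f2 <- paste(sample(filler_alphabet, 70, replace = TRUE), collapse = "")
    f3 <- paste(sample(filler_alphabet, 18, replace = TRUE), collapse = "")
  })
  paste0("MKT", f1, "HLH", f2, "NPLRYG", "Y", f3)
}

random_protein <- function(n) {
  # proline-free so the NP(L/V)(R/K)xG motif can never arise by chance
  paste(sample(setdiff(.AA_LETTERS, "P"), n, replace = TRUE), collapse = "")
}

encode_protein <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste0(paste(.CODON_TABLE[aa], collapse = ""), "TAA")
}

mutate_protein <- function(protein, rate) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(aa)) < rate)
  for (i in hit) {
    aa[i] <- sample(setdiff(.AA_LETTERS, aa[i]), 1L)
  }
  list(protein = paste(aa, collapse = ""), n_subs = length(hit))
}

#' Mutate a REP consensus by exactly k substitution events
#'
#' In the default mode, exactly `k` distinct positions are substituted to a
#' different base (Hamming distance exactly `k`).  In palindrome-preserving
#' mode the positions are drawn from the arm and loop sites of the strict
#' parse, and an arm substitution is mirrored by the complementary
#' substitution on the other arm, so the element still strict-parses with
#' the same arm length (one event may then change two positions).
#'
#' @param consensus DNA string (must strict-parse in palindrome-preserving
#'   mode).
#' @param k Number of substitution events; must not exceed the sequence
#'   (or eligible-site) length.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @param palindrome_preserving Apply complementary arm mutations (default
#'   `FALSE`).
#' @return Mutated DNA string with attribute `n_changed` (Hamming distance
#'   to the input).
#' @export
mutate_consensus <- function(consensus, k, seed = NULL,
                             palindrome_preserving = FALSE) {
  consensus <- validate_dna(consensus)
  n <- nchar(consensus)
  if (k > n) stop("k exceeds sequence length")
  run <- function() {
    ch <- strsplit(consensus, "", fixed = TRUE)[[1L]]
    if (k == 0L) {
      out <- consensus
      attr(out, "n_changed") <- 0L
      return(out)
    }
    if (!palindrome_preserving) {
      pos <- sample(n, k)
      for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
      out <- paste(ch, collapse = "")
      attr(out, "n_changed") <- as.integer(k)
      return(out)
    }
    st <- parse_rep_strict(consensus)
    if (is.null(st)) {
      stop("palindrome-preserving mode requires a strict-parsable consensus")
    }
    arm_off <- nchar(st$leading) + 4L + nchar(st$spacer)
    a <- nchar(st$left_arm)
    loop_off <- arm_off + a
    lp <- nchar(st$loop)
    eligible <- c(seq_len(a) + arm_off, seq_len(lp) + loop_off)
    if (k > length(eligible)) stop("k exceeds number of eligible sites")
    pos <- sample(eligible, k)
    changed <- integer(0)
    for (i in pos) {
      new <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
      ch[i] <- new
      changed <- c(changed, i)
      if (i <= loop_off) {             # arm site: mirror on the right arm
        j <- loop_off + lp + (a - (i - arm_off) + 1L)
        ch[j] <- chartr("ACGT", "TGCA", new)
        changed <- c(changed, j)
      }
    }
    out <- paste(ch, collapse = "")
    attr(out, "n_changed") <-
      sum(strsplit(out, "", fixed = TRUE)[[1L]] !=
            strsplit(consensus, "", fixed = TRUE)[[1L]])
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

default_sim_consensi <- function() {
  load_rep_consensi()[c("Smal4", "Smal3")]
}

# plan one planted element; returns list(width, build(start) -> list(seq, reps))
# reps rows: family, variant_index, offset(start within element), strand, seq, n_mut

plant_copy <- function(consensus, mutation_probs) {
  vi <- sample(length(consensus$variants), 1L)
  k <- sample(0:2, 1L, prob = mutation_probs)
  seq <- mutate_consensus(consensus$variants[vi], k)
  list(variant_index = vi - 1L, seq = as.character(seq),
       n_mut = attr(seq, "n_changed"))
}

#' Simulate a genome with planted REP architecture and known truth
#'
#' Generates an i.i.d. background at the stated GC content,
#' rejection-sampled to contain no chance hit of any supplied consensus at
#' up to 2 mismatches, then plants: `n_solitary` dispersed REP copies,
#' `n_doublets` inverted REP doublets, modular BIME clusters with the module
#' counts in `n_modular`, `n_hybrid` two-family modular clusters, and (if
#' `rayt = TRUE`) a motif-complete rayt-like CDS flanked by two inverted REP
#' copies, plus `n_neighbor_cds` unrelated CDSs.  Every planted copy is
#' mutated by k ~ `mutation_probs` on \{0, 1, 2\} substitutions.  The
#' assembled genome is re-scanned and checked against the truth ledger
#' before being returned; identical seed and parameters give byte-identical
#' output.
#'
#' @param seed Integer seed (mandatory).
#' @param length Genome length in bp (default 50000).
#' @param gc Background GC fraction (default 0.6, typical for the
#'   high-GC gammaproteobacteria that carry these elements).
#' @param consensi List of [rep_consensus] (default: the packaged Smal4 and
#'   Smal3 families).  Family 1 is used for all plantings except hybrid
#'   clusters, which alternate families 1 and 2.
#' @param n_solitary,n_doublets Numbers of solitary copies and doublets.
#' @param n_modular Integer vector of module counts; one modular cluster is
#'   planted per entry (a cluster with m modules contains 2m alternating
#'   REPs).
#' @param n_hybrid Number of two-family modular clusters (each 2 modules).
#' @param mutation_probs Probabilities of k = 0, 1, 2 substitutions per
#'   planted copy.
#' @param rayt Plant the rayt locus (default `TRUE`).
#' @param flank_mut_events Palindrome-preserving mutation events applied to
#'   the upstream/downstream flank copies (default `c(0, 0)`, i.e. exact
#'   copies; set e.g. `c(0, 1)` for a dimorphic flank pair).
#' @param n_neighbor_cds Number of unrelated CDSs planted (default 2).
#' @param doublet_gap Range of inter-REP gaps inside doublets and the rayt
#'   locus (bp).
#' @param segment_len Range of inter-REP segment lengths in clusters (bp).
#' @param segment_pool Number of distinct segment sequences available for
#'   reuse across cluster gaps.
#' @param max_tries Maximum regeneration attempts for background rejection
#'   sampling and final verification.
#' @return A `rep_simulation` list: `genome` (DNA string), `annotation`
#'   (CDS data frame, 0-based half-open), `truth` (a `simulation_truth`
#'   ledger with `planted_reps`, `planted_clusters`, `rayt_locus`,
#'   `segment_pool` and the generator parameters).
#' @export
simulate_genome <- function(seed, length = 50000L, gc = 0.6,
                            consensi = NULL, n_solitary = 10L,
                            n_doublets = 3L, n_modular = c(2L, 3L),
                            n_hybrid = 0L,
                            mutation_probs = c(0.7, 0.2, 0.1),
                            rayt = TRUE, flank_mut_events = c(0L, 0L),
                            n_neighbor_cds = 2L,
                            doublet_gap = c(30L, 120L),
                            segment_len = c(30L, 80L), segment_pool = 3L,
                            max_tries = 20L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.null(consensi)) consensi <- default_sim_consensi()
  if (inherits(consensi, "rep_consensus")) consensi <- list(consensi)
  if (n_hybrid > 0L && length(consensi) < 2L) {
    stop("hybrid clusters require at least two consensus families")
  }
  withr::with_seed(as.integer(seed), {
    for (attempt in seq_len(max_tries)) {
      sim <- try(simulate_genome_once(
        genome_len = as.integer(length), gc = gc, consensi = consensi,
        n_solitary = n_solitary, n_doublets = n_doublets,
        n_modular = n_modular, n_hybrid = n_hybrid,
        mutation_probs = mutation_probs, rayt = rayt,
        flank_mut_events = flank_mut_events,
        n_neighbor_cds = n_neighbor_cds, doublet_gap = doublet_gap,
        segment_len = segment_len, segment_pool = segment_pool,
        max_tries = max_tries
      ), silent = TRUE)
      if (!inherits(sim, "try-error")) {
        sim$truth$seed <- as.integer(seed)
        return(sim)
      }
      if (!grepl("retryable", attr(sim, "condition")$message)) {
        stop(attr(sim, "condition"))
      }
    }
    stop("failed to generate a verified genome in ", max_tries, " attempts")
  })
}

simulate_genome_once <- function(genome_len, gc, consensi, n_solitary,
                                 n_doublets, n_modular, n_hybrid,
                                 mutation_probs, rayt, flank_mut_events,
                                 n_neighbor_cds, doublet_gap, segment_len,
                                 segment_pool, max_tries) {
  fam1 <- consensi[[1L]]
  glabel <- "sim_genome"

  # --- segment pool for cluster gaps (shared, to exercise label reuse)
  seg_pool <- vapply(seq_len(segment_pool), function(i) {
    random_dna(sample(segment_len[1L]:segment_len[2L], 1L), gc)
  }, character(1L))

  # --- element plans -------------------------------------------------------
  elements <- list()
  reps_rows <- list()
  cluster_rows <- list()
  segment_map <- list()
  add_element <- function(seq, reps, cds = NULL) {
    elements[[length(elements) + 1L]] <<- list(seq = seq, reps = reps,
                                               cds = cds)
  }
  oriented_to_plus <- function(seq, strand) {
    if (strand == "+") seq else revcomp(seq)
  }

  for (i in seq_len(n_solitary)) {
    cp <- plant_copy(fam1, mutation_probs)
    strand <- sample(c("+", "-"), 1L)
    add_element(oriented_to_plus(cp$seq, strand), list(list(
      family = fam1$family_id, variant_index = cp$variant_index,
      offset = 0L, len = nchar(cp$seq), strand = strand, n_mut = cp$n_mut,
      role = "solitary", cluster = paste0("sol", i)
    )))
  }

  make_cluster <- function(n_copies, fams, cluster_id, role) {
    strand0 <- sample(c("+", "-"), 1L)
    pieces <- character(0)
    reps <- list()
    seg_ids <- integer(0)
    off <- 0L
    for (j in seq_len(n_copies)) {
      fam <- fams[[(j - 1L) %% length(fams) + 1L]]
      cp <- plant_copy(fam, mutation_probs)
      strand <- if (j %% 2L == 1L) strand0 else setdiff(c("+", "-"), strand0)
      pseq <- oriented_to_plus(cp$seq, strand)
      pieces <- c(pieces, pseq)
      reps[[j]] <- list(family = fam$family_id,
                        variant_index = cp$variant_index, offset = off,
                        len = nchar(pseq), strand = strand,
                        n_mut = cp$n_mut, role = role, cluster = cluster_id)
      off <- off + nchar(pseq)
      if (j < n_copies) {
        si <- sample(segment_pool, 1L)
        seg_ids <- c(seg_ids, si)
        pieces <- c(pieces, seg_pool[si])
        off <- off + nchar(seg_pool[si])
      }
    }
    segment_map[[cluster_id]] <<- seg_ids
    cluster_rows[[length(cluster_rows) + 1L]] <<- data.frame(
      cluster_id = cluster_id, class = if (n_copies == 2L) "doublet" else
        "modular", module_count = n_copies %/% 2L, n_occ = n_copies,
      families = paste(unique(vapply(reps, `[[`, "", "family")),
                       collapse = ","),
      hybrid = length(unique(vapply(reps, `[[`, "", "family"))) > 1L,
      stringsAsFactors = FALSE
    )
    add_element(paste(pieces, collapse = ""), reps)
  }

  for (i in seq_len(n_doublets)) {
    # doublets use a short random gap, not the segment pool
    strand0 <- sample(c("+", "-"), 1L)
    cp1 <- plant_copy(fam1, mutation_probs)
    cp2 <- plant_copy(fam1, mutation_probs)
    gap <- random_dna(sample(doublet_gap[1L]:doublet_gap[2L], 1L), gc)
    s1 <- oriented_to_plus(cp1$seq, strand0)
    s2 <- oriented_to_plus(cp2$seq, setdiff(c("+", "-"), strand0))
    cid <- paste0("dbl", i)
    add_element(paste0(s1, gap, s2), list(
      list(family = fam1$family_id, variant_index = cp1$variant_index,
           offset = 0L, len = nchar(s1), strand = strand0, n_mut = cp1$n_mut,
           role = "doublet", cluster = cid),
      list(family = fam1$family_id, variant_index = cp2$variant_index,
           offset = nchar(s1) + nchar(gap), len = nchar(s2),
           strand = setdiff(c("+", "-"), strand0), n_mut = cp2$n_mut,
           role = "doublet", cluster = cid)
    ))
    cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
      cluster_id = cid, class = "doublet", module_count = 1L, n_occ = 2L,
      families = fam1$family_id, hybrid = FALSE, stringsAsFactors = FALSE
    )
  }

  for (i in seq_along(n_modular)) {
    make_cluster(2L * n_modular[i], list(fam1), paste0("mod", i), "modular")
  }
  for (i in seq_len(n_hybrid)) {
    make_cluster(4L, consensi[1:2], paste0("hyb", i), "hybrid")
  }

  # --- rayt locus and neighbor CDSs ---------------------------------------
  rayt_protein <- NULL
  if (rayt) {
    rayt_protein <- rayt_protein_template()
    cds_seq <- encode_protein(rayt_protein)
    up_seq <- mutate_consensus(fam1$variants[1L], flank_mut_events[1L],
                               palindrome_preserving = TRUE)
    down_seq <- mutate_consensus(fam1$variants[1L], flank_mut_events[2L],
                                 palindrome_preserving = TRUE)
    gap1 <- random_dna(sample(doublet_gap[1L]:doublet_gap[2L], 1L), gc)
    gap2 <- random_dna(sample(doublet_gap[1L]:doublet_gap[2L], 1L), gc)
    up_plus <- as.character(up_seq)                       # head-5' upstream
    down_plus <- revcomp(as.character(down_seq))          # inverted downstream
    eseq <- paste0(up_plus, gap1, cds_seq, gap2, down_plus)
    cds_off <- nchar(up_plus) + nchar(gap1)
    add_element(eseq, list(
      list(family = fam1$family_id, variant_index = 0L, offset = 0L,
           len = nchar(up_plus), strand = "+",
           n_mut = attr(up_seq, "n_changed"), role = "flank_up",
           cluster = "rayt"),
      list(family = fam1$family_id, variant_index = 0L,
           offset = nchar(eseq) - nchar(down_plus), len = nchar(down_plus),
           strand = "-", n_mut = attr(down_seq, "n_changed"),
           role = "flank_down", cluster = "rayt")
    ), cds = list(id = "rayt", offset = cds_off, len = nchar(cds_seq),
                  strand = "+", protein = rayt_protein))
  }
  for (i in seq_len(n_neighbor_cds)) {
    prot <- random_protein(180L)
    cds_seq <- encode_protein(prot)
    add_element(cds_seq, list(), cds = list(id = paste0("cds", i),
                                            offset = 0L,
                                            len = nchar(cds_seq),
                                            strand = "+", protein = prot))
  }

  widths <- vapply(elements, function(e) nchar(e$seq), integer(1L))
  if (sum(widths) >= 0.2 * genome_len) {
    stop("infeasible packing: planted span exceeds 20% of genome length")
  }

  # --- placement (largest first, min separation so clusters never merge) --
  sep <- 300L
  margin <- 50L
  ord <- order(widths, decreasing = TRUE)
  pos <- integer(length(elements))
  placed_s <- integer(0)
  placed_e <- integer(0)
  for (ei in ord) {
    w <- widths[ei]
    ok <- FALSE
    for (try_i in seq_len(2000L)) {
      s <- sample(margin:(genome_len - w - margin), 1L)
      if (!any(s - sep < placed_e & s + w + sep > placed_s)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("infeasible packing: could not place all elements")
    pos[ei] <- s
    placed_s <- c(placed_s, s)
    placed_e <- c(placed_e, s + w)
  }

  # --- background, rejection-sampled to be consensus-hit-free -------------
  background <- NULL
  for (try_i in seq_len(max_tries)) {
    bg <- random_dna(genome_len, gc)
    nhit <- sum(vapply(consensi, function(cs) {
      nrow(scan_genome(bg, cs, max_mm = 2L))
    }, integer(1L)))
    if (nhit == 0L) {
      background <- bg
      break
    }
  }
  if (is.null(background)) {
    stop("failed to draw a consensus-free background (extreme GC?)")
  }

  # --- assembly ------------------------------------------------------------
  ordp <- order(pos)
  pieces <- character(0)
  cursor <- 0L
  for (ei in ordp) {
    pieces <- c(pieces, substr(background, cursor + 1L, pos[ei]),
                elements[[ei]]$seq)
    cursor <- pos[ei] + widths[ei]
  }
  pieces <- c(pieces, substr(background, cursor + 1L, genome_len))
  genome <- paste(pieces, collapse = "")
  stopifnot(nchar(genome) == genome_len)

  # --- truth tables --------------------------------------------------------
  rep_list <- list()
  ann_list <- list()
  rayt_locus <- NULL
  for (ei in seq_along(elements)) {
    el <- elements[[ei]]
    for (r in el$reps) {
      s0 <- pos[ei] + r$offset
      core <- c(NA_integer_, NA_integer_)
      if (r$role %in% c("flank_up", "flank_down")) {
        oriented <- if (r$strand == "+") {
          substr(genome, s0 + 1L, s0 + r$len)
        } else {
          revcomp(substr(genome, s0 + 1L, s0 + r$len))
        }
        st <- parse_rep_strict(oriented)
        lead <- nchar(st$leading)
        tail_n <- nchar(st$tail)
        core <- if (r$strand == "+") {
          c(s0 + lead, s0 + r$len - tail_n)
        } else {
          c(s0 + tail_n, s0 + r$len - lead)
        }
      }
      rep_list[[length(rep_list) + 1L]] <- data.frame(
        family_id = r$family, variant_index = r$variant_index,
        start = s0, end = s0 + r$len, strand = r$strand,
        n_mutations = r$n_mut, role = r$role, cluster_id = r$cluster,
        core_start = core[1L], core_end = core[2L], stringsAsFactors = FALSE
      )
    }
    if (!is.null(el$cds)) {
      cs <- pos[ei] + el$cds$offset
      ann_list[[length(ann_list) + 1L]] <- data.frame(
        seqid = glabel, id = el$cds$id, type = "CDS", start = cs,
        end = cs + el$cds$len, strand = el$cds$strand,
        stringsAsFactors = FALSE
      )
      if (el$cds$id == "rayt") {
        flanks <- el$reps
        rayt_locus <- list(
          cds_start = cs, cds_end = cs + el$cds$len, strand = el$cds$strand,
          protein = el$cds$protein,
          upstream_offset = cs - (pos[ei] + flanks[[1L]]$offset +
                                    flanks[[1L]]$len),
          downstream_offset = (pos[ei] + flanks[[2L]]$offset) -
            (cs + el$cds$len)
        )
      }
    }
  }
  planted_reps <- if (length(rep_list)) do.call(rbind, rep_list) else
    data.frame()
  if (nrow(planted_reps)) {
    planted_reps <- planted_reps[order(planted_reps$start), , drop = FALSE]
    rownames(planted_reps) <- NULL
  }
  annotation <- if (length(ann_list)) do.call(rbind, ann_list) else
    data.frame(seqid = character(), id = character(), type = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)

  truth <- structure(
    list(seed = NA_integer_, genome_length = genome_len, gc = gc,
         families = lapply(consensi, function(cs)
           list(family_id = cs$family_id, variants = cs$variants)),
         planted_reps = planted_reps,
         planted_clusters = if (length(cluster_rows))
           do.call(rbind, cluster_rows) else data.frame(),
         segment_map = segment_map,
         segment_pool = seg_pool,
         rayt_locus = rayt_locus),
    class = "simulation_truth"
  )

  # --- verification: scan must reproduce the truth exactly ----------------
  # flank cores must be unambiguous: chance background complementarity next
  # to a planted flank can extend the maximal palindrome; such genomes are
  # redrawn
  if (!is.null(rayt_locus)) {
    fl_t <- planted_reps[planted_reps$role %in% c("flank_up", "flank_down"), ]
    fl_d <- suppressWarnings(find_flanking_reps(
      genome, rayt_locus$cds_start, rayt_locus$cds_end))
    ok <- fl_d$flank_confirmed &&
      identical(fl_d$upstream$start,
                fl_t$core_start[fl_t$role == "flank_up"]) &&
      identical(fl_d$upstream$end, fl_t$core_end[fl_t$role == "flank_up"]) &&
      identical(fl_d$downstream$start,
                fl_t$core_start[fl_t$role == "flank_down"]) &&
      identical(fl_d$downstream$end,
                fl_t$core_end[fl_t$role == "flank_down"])
    if (!ok) stop("retryable: ambiguous flank palindrome in background")
  }
  for (cs in consensi) {
    occ <- scan_genome(genome, cs, max_mm = 2L, genome_label = glabel)
    tr <- planted_reps[planted_reps$family_id == cs$family_id, , drop = FALSE]
    same <- nrow(occ) == nrow(tr) &&
      all(occ$start == tr$start) && all(occ$end == tr$end) &&
      all(occ$strand == tr$strand) && all(occ$mismatches == tr$n_mutations)
    if (!same) stop("retryable: assembled genome failed truth verification")
  }

  structure(list(genome = genome, annotation = annotation, truth = truth,
                 genome_label = glabel),
            class = "rep_simulation")
}

#' @export
print.rep_simulation <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    "Simulated genome: %d bp, GC %.2f, %d planted REP copies, %d cluster(s)%s\n",
    tr$genome_length, tr$gc, nrow(tr$planted_reps),
    if (is.data.frame(tr$planted_clusters)) nrow(tr$planted_clusters) else 0L,
    if (!is.null(tr$rayt_locus)) ", rayt locus planted" else ""))
  invisible(x)
}

#' Simulate an ortholog genome pair with an accelerated rayt gene
#'
#' Derives two descendant genomes from a simulated ancestor
#' (a [simulate_genome()] result with a rayt locus): in each lineage every
#' neighbor CDS is mutated at `background_rate` per residue and the rayt CDS
#' at `rayt_rate_multiplier` times that rate (amino-acid-level substitution
#' model, so no stop codons can arise).  The second lineage's flanking REP
#' copies receive 0-1 palindrome-preserving substitution events each,
#' mirroring the few point mutations observed between ortholog flanks.
#'
#' @param sim A `rep_simulation` with `rayt = TRUE`.
#' @param rayt_rate_multiplier Rate multiplier for the rayt CDS (>= 1).
#' @param background_rate Per-residue substitution probability for neighbor
#'   CDSs, per lineage.
#' @param flank_events Pool of per-flank palindrome-preserving event counts
#'   (default `0:1`).
#' @param seed Integer seed.
#' @return List with `genomes` (two DNA strings), `proteins` (per lineage:
#'   named list rayt + neighbors), `annotation`, and `truth` (per-gene
#'   substitution counts per lineage, flank events).
#' @export
simulate_ortholog_pair <- function(sim, rayt_rate_multiplier = 2,
                                   background_rate = 0.05,
                                   flank_events = 0:1, seed) {
  stopifnot(inherits(sim, "rep_simulation"))
  if (is.null(sim$truth$rayt_locus)) {
    stop("the base simulation must contain a rayt locus")
  }
  if (rayt_rate_multiplier < 1) stop("multiplier must be >= 1")
  withr::with_seed(as.integer(seed), {
    ann <- sim$annotation
    truth_rows <- list()
    lineages <- vector("list", 2L)
    for (lg in 1:2) {
      genome <- sim$genome
      prots <- list()
      for (ai in seq_len(nrow(ann))) {
        id <- ann$id[ai]
        rate <- if (id == "rayt") rayt_rate_multiplier * background_rate else
          background_rate
        cds_nt <- substr(genome, ann$start[ai] + 1L, ann$end[ai])
        protein <- if (id == "rayt") sim$truth$rayt_locus$protein else
          translate_cds(cds_nt)
        mut <- mutate_protein(protein, rate)
        prots[[id]] <- mut$protein
        substr(genome, ann$start[ai] + 1L, ann$end[ai]) <-
          encode_protein(mut$protein)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene = id, lineage = lg, n_aa_subs = mut$n_subs,
          stringsAsFactors = FALSE
        )
      }
      if (lg == 2L) {
        fl <- sim$truth$planted_reps
        fl <- fl[fl$role %in% c("flank_up", "flank_down"), , drop = FALSE]
        for (fi in seq_len(nrow(fl))) {
          oriented <- if (fl$strand[fi] == "+") {
            substr(genome, fl$start[fi] + 1L, fl$end[fi])
          } else {
            revcomp(substr(genome, fl$start[fi] + 1L, fl$end[fi]))
          }
          k <- sample(flank_events, 1L)
          mutated <- mutate_consensus(oriented, k,
                                      palindrome_preserving = TRUE)
          plus <- if (fl$strand[fi] == "+") as.character(mutated) else
            revcomp(as.character(mutated))
          substr(genome, fl$start[fi] + 1L, fl$end[fi]) <- plus
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            gene = paste0(fl$role[fi], "_rep"), lineage = lg,
            n_aa_subs = attr(mutated, "n_changed"), stringsAsFactors = FALSE
          )
        }
      }
      lineages[[lg]] <- list(genome = genome, proteins = prots)
    }
    list(
      genomes = c(lineages[[1L]]$genome, lineages[[2L]]$genome),
      proteins = list(lineages[[1L]]$proteins, lineages[[2L]]$proteins),
      annotation = ann,
      truth = do.call(rbind, truth_rows)
    )
  })
}

translate_cds <- function(cds_nt) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds_nt)))
  sub("\\*$", "", aa)
}

default_guide_tree <- function() {
  # six families that are well separated from each other (long internal
  # branches) but each sampled close to its flanking-REP ancestor (short
  # terminal branches) - the situation in which congruent REP/RAYT
  # phylograms are observable despite the short REP sequence
  ape::read.tree(text = paste0(
    "(((A:0.06,B:0.06):0.15,(C:0.06,D:0.06):0.15):0.08,",
    "(E:0.10,F:0.10):0.08);"))
}

default_ancestral_rep <- function() {
  # 32-nt GC-rich REP: GTAG head, 12-nt arms, 4-nt loop
  arm <- "CCGGCTGAGCGC"
  paste0("GTAG", arm, "ATTA", revcomp(arm))
}

#' Simulate coevolving RAYT/REP families down a guide tree
#'
#' The ancestral protein and REP sequence evolve independently down the same
#' resolved guide tree; each edge applies per-site substitutions with
#' probability `rate * branch length` (protein and REP rates separately).
#' The returned truth is the guide topology itself, so congruence of the
#' reconstructed protein and REP trees can be tested.
#'
#' @param seed Integer seed.
#' @param guide_tree Resolved `phylo` tree (default: a fixed 6-taxon tree
#'   with branch lengths in expected substitutions per site).
#' @param ancestral_protein Ancestral RAYT protein (default
#'   [rayt_protein_template()], 153 aa).
#' @param ancestral_rep Ancestral REP DNA (default: a 32-nt GC-rich
#'   palindrome).
#' @param protein_rate,rep_rate Rate multipliers applied to branch lengths
#'   (default 1 and 1.5: repeat DNA outside the protein's structural
#'   constraint drifts faster than the protein itself).
#' @return List with `proteins` and `reps` (named character vectors, one per
#'   tip) and `tree` (the guide tree).
#' @export
simulate_coevolved_families <- function(seed, guide_tree = NULL,
                                        ancestral_protein =
                                          rayt_protein_template(),
                                        ancestral_rep =
                                          default_ancestral_rep(),
                                        protein_rate = 1, rep_rate = 1.5) {
  if (is.null(guide_tree)) guide_tree <- default_guide_tree()
  stopifnot(inherits(guide_tree, "phylo"))
  if (!ape::is.binary(guide_tree) || !ape::is.rooted(guide_tree)) {
    stop("guide tree must be fully resolved")
  }
  guide_tree <- ape::reorder.phylo(guide_tree, "cladewise")
  evolve <- function(seq, p, alphabet) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(ch)) < p)
    for (i in hit) ch[i] <- sample(setdiff(alphabet, ch[i]), 1L)
    paste(ch, collapse = "")
  }
  withr::with_seed(as.integer(seed), {
    ntip <- length(guide_tree$tip.label)
    nnode <- ntip + guide_tree$Nnode
    prot <- character(nnode)
    rep_seq <- character(nnode)
    root <- ntip + 1L
    prot[root] <- ancestral_protein
    rep_seq[root] <- ancestral_rep
    # edges in preorder: parents always precede children in ape's cladewise
    # edge matrix rooted at ntip+1
    edges <- guide_tree$edge
    bl <- guide_tree$edge.length
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]
      child <- edges[e, 2L]
      prot[child] <- evolve(prot[par], min(0.95, protein_rate * bl[e]),
                            .AA_LETTERS)
      rep_seq[child] <- evolve(rep_seq[par], min(0.95, rep_rate * bl[e]),
                               c("A", "C", "G", "T"))
    }
    list(
      proteins = setNames(prot[seq_len(ntip)], guide_tree$tip.label),
      reps = setNames(rep_seq[seq_len(ntip)], guide_tree$tip.label),
      tree = guide_tree
    )
  })
}

#' Write simulation outputs to standard files
#'
#' Writes the genome as FASTA, the CDS annotation as GFF3 and the truth
#' ledger as JSON into a directory.
#'
#' @param sim A `rep_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisible named vector of the written paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "rep_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "annotation.gff3")
  tj <- file.path(dir, "truth.json")
  gs <- Biostrings::DNAStringSet(sim$genome)
  names(gs) <- sim$genome_label
  Biostrings::writeXStringSet(gs, fa)
  write_gff3(sim$annotation, gff)
  write_truth_json(sim$truth, tj)
  invisible(c(fasta = fa, gff3 = gff, truth = tj))
}

#' Serialize / restore a simulation truth ledger
#'
#' @param truth A `simulation_truth`.
#' @param path JSON file.
#' @return `write_truth_json` the path (invisibly); `read_truth_json` the
#'   restored `simulation_truth`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_reps <- as.data.frame(x$planted_reps,
                                  stringsAsFactors = FALSE)
  x$planted_clusters <- as.data.frame(x$planted_clusters,
                                      stringsAsFactors = FALSE)
  structure(x, class = "simulation_truth")
}
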