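# Genome-wide mismatch-tolerant REP scanning and copy counting.
#
# Matching is substitution-only over fixed-length windows (the published copy
# counts are consensus-length exact-window matches; indel-tolerant search
# would change them unverifiably).  All intervals are 0-based half-open; the
# strand is the one on which the head reads GT[AG]G.

count_mismatches <- function(hits, pattern) {
  # hits: character vector of same-length substrings
  pv <- utf8ToInt(pattern)
  vapply(hits, function(h) sum(utf8ToInt(h) != pv), integer(1L),
         USE.NAMES = FALSE)
}

empty_occurrences <- function() {
  data.frame(genome = character(), start = integer(), end = integer(),
             strand = character(), family_id = character(),
             variant_index = integer(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

#' Scan a genome for occurrences of a REP consensus
#'
#' Finds every position, on both strands, where some variant of the family
#' matches with at most `max_mm` substitutions (no indels).  Overlapping hits
#' of the family are deduplicated keeping the lowest mismatch count, then the
#' leftmost start, then the plus strand, then the lower variant index.
#'
#' @param genome DNA string (one contig).
#' @param consensus A [rep_consensus], or a character vector of variant
#'   sequences.
#' @param max_mm Maximum number of substitutions (0, 1 or 2).
#' @param genome_label Label recorded in the `genome` column.
#' @return Data frame of occurrences with columns `genome`, `start`, `end`
#'   (0-based half-open), `strand`, `family_id`, `variant_index` (0-based)
#'   and `mismatches`, sorted by `start`.
#' @export
scan_genome <- function(genome, consensus, max_mm = 0L,
                        genome_label = "genome") {
  genome <- validate_dna(genome, "genome")
  stopifnot(max_mm %in% 0:2)
  if (is.character(consensus)) {
    # raw query patterns: no structural validation, just DNA
    consensus <- structure(
      list(family_id = "query", host = NA_character_,
           variants = vapply(consensus, validate_dna, character(1L),
                             USE.NAMES = FALSE),
           structures = NULL),
      class = "rep_consensus")
  }
  stopifnot(inherits(consensus, "rep_consensus"))
  variants <- consensus$variants
  if (length(variants) == 0L || any(nchar(variants) == 0L)) {
    stop("empty consensus")
  }
  if (nchar(genome) < max(nchar(variants))) {
    stop("genome shorter than the consensus")
  }
  subj <- Biostrings::DNAString(genome)
  rows <- list()
  for (vi in seq_along(variants)) {
    v <- variants[vi]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") v else revcomp(v)
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                    max.mismatch = max_mm)
      if (length(m) == 0L) next
      s <- BiocGenerics::start(m)
      e <- BiocGenerics::end(m)
      mm <- count_mismatches(substring(genome, s, e), pat)
      rows[[length(rows) + 1L]] <- data.frame(
        genome = genome_label, start = s - 1L, end = e, strand = strand,
        family_id = consensus$family_id, variant_index = vi - 1L,
        mismatches = mm, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_occurrences())
  occ <- do.call(rbind, rows)
  occ <- occ[occ$mismatches <= max_mm, , drop = FALSE]
  dedup_occurrences(occ)
}

# Greedy overlap dedup with the documented priority order.
dedup_occurrences <- function(occ) {
  if (nrow(occ) == 0L) return(occ)
  ord <- order(occ$mismatches, occ$start,
               match(occ$strand, c("+", "-")), occ$variant_index)
  occ <- occ[ord, , drop = FALSE]
  kept_s <- integer(0)
  kept_e <- integer(0)
  keep <- logical(nrow(occ))
  for (i in seq_len(nrow(occ))) {
    s <- occ$start[i]; e <- occ$end[i]
    if (!any(s < kept_e & e > kept_s)) {
      keep[i] <- TRUE
      kept_s <- c(kept_s, s)
      kept_e <- c(kept_e, e)
    }
  }
  occ <- occ[keep, , drop = FALSE]
  occ <- occ[order(occ$start), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Copy-count summary for one family in one genome
#'
#' Cumulative occurrence counts at 0, <=1 and <=2 substitutions, computed
#' from a single scan at 2 mismatches with post-hoc thresholds (equivalent to
#' three independent scans; this equivalence is contract-tested).
#'
#' @inheritParams scan_genome
#' @return A `rep_count_summary` list with integer fields `n_exact`, `n_le1`,
#'   `n_le2`.
#' @export
summarize_counts <- function(genome, consensus, genome_label = "genome") {
  occ <- scan_genome(genome, consensus, max_mm = 2L,
                     genome_label = genome_label)
  structure(
    list(n_exact = sum(occ$mismatches == 0L),
         n_le1 = sum(occ$mismatches <= 1L),
         n_le2 = nrow(occ)),
    class = "rep_count_summary"
  )
}

#' @export
print.rep_count_summary <- function(x, ...) {
  cat(sprintf("REP copies: %d/%d/%d (exact / <=1 mm / <=2 mm)\n",
              x$n_exact, x$n_le1, x$n_le2))
  invisible(x)
}

#' Presence/abundance matrix of REP families across genomes
#'
#' Scans every genome for every family and tabulates the copy-count
#' summaries, mirroring a presence/absence-of-RAYT comparison: when
#' `rayt_status` is supplied, a per-family fold ratio between rayt-bearing
#' and rayt-lacking genomes is computed as the ratio of geometric means of
#' exact counts (counts are offset by +1 in both groups only when a zero
#' count is present).
#'
#' @param genomes Named list (or character vector) of genome DNA strings.
#' @param consensi List of [rep_consensus] objects.
#' @param rayt_status Optional logical matrix (`genomes x families`) or named
#'   logical vector per genome stating whether the cognate rayt gene is
#'   present.
#' @return A `rep_presence_matrix` list: `counts` (long data frame),
#'   `n_exact` (genome x family matrix), `presence` (logical matrix) and
#'   `fold_ratio` (named numeric per family, `NA` without `rayt_status`).
#' @export
presence_abundance_matrix <- function(genomes, consensi, rayt_status = NULL) {
  if (is.character(genomes)) genomes <- as.list(genomes)
  stopifnot(length(genomes) >= 1L, length(consensi) >= 1L)
  if (is.null(names(genomes))) {
    names(genomes) <- paste0("genome", seq_along(genomes))
  }
  fam_ids <- vapply(consensi, function(x) x$family_id, character(1L))
  rows <- list()
  for (g in names(genomes)) {
    for (ci in seq_along(consensi)) {
      cs <- summarize_counts(genomes[[g]], consensi[[ci]], genome_label = g)
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g, family_id = fam_ids[ci], n_exact = cs$n_exact,
        n_le1 = cs$n_le1, n_le2 = cs$n_le2, stringsAsFactors = FALSE
      )
    }
  }
  counts <- do.call(rbind, rows)
  n_exact <- matrix(counts$n_exact, nrow = length(genomes), byrow = TRUE,
                    dimnames = list(names(genomes), fam_ids))
  fold <- setNames(rep(NA_real_, length(fam_ids)), fam_ids)
  if (!is.null(rayt_status)) {
    if (is.vector(rayt_status)) {
      rayt_status <- matrix(rayt_status[names(genomes)],
                            nrow = length(genomes), ncol = length(fam_ids),
                            dimnames = list(names(genomes), fam_ids))
    }
    for (f in fam_ids) {
      bearing <- n_exact[rayt_status[, f] %in% TRUE, f]
      lacking <- n_exact[rayt_status[, f] %in% FALSE, f]
      if (length(bearing) > 0L && length(lacking) > 0L) {
        off <- if (any(c(bearing, lacking) == 0L)) 1 else 0
        gm <- function(x) exp(mean(log(x + off)))
        fold[f] <- gm(bearing) / gm(lacking)
      }
    }
  }
  structure(
    list(counts = counts, n_exact = n_exact, presence = n_exact > 0L,
         fold_ratio = fold),
    class = "rep_presence_matrix"
  )
}

#' @export
print.rep_presence_matrix <- function(x, ...) {
  cat("REP presence/abundance (exact copies):\n")
  print(x$n_exact)
  if (any(!is.na(x$fold_ratio))) {
    cat("fold ratio (rayt-bearing / rayt-lacking, geometric mean):\n")
    print(round(x$fold_ratio, 2))
  }
  invisible(x)
}

#' Fraction of REP occurrences outside annotated coding sequences
#'
#' Occurrences partially overlapping a CDS count as genic.
#'
#' @param occurrences Occurrence data frame as from [scan_genome()].
#' @param cds Data frame of CDS intervals with 0-based half-open `start`,
#'   `end` columns.
#' @return Fraction in \[0, 1\], or `NA` for an empty occurrence list.
#' @export
extragenic_fraction <- function(occurrences, cds) {
  if (nrow(occurrences) == 0L) return(NA_real_)
  if (is.null(cds) || nrow(cds) == 0L) return(1.0)
  occ_r <- IRanges::IRanges(start = occurrences$start + 1L,
                            end = occurrences$end)
  cds_r <- IRanges::IRanges(start = cds$start + 1L, end = cds$end)
  genic <- IRanges::countOverlaps(occ_r, cds_r, minoverlap = 1L) > 0L
  mean(!genic)
}

#' Write occurrences as BED6
#'
#' 0-based half-open intervals; `name` is `family:variant`, `score` the
#' mismatch count.  Reading and re-writing a BED file is byte-idempotent.
#'
#' @param occurrences Occurrence data frame as from [scan_genome()].
#' @param path Output file.
#' @export
write_bed <- function(occurrences, path) {
  bed <- data.frame(
    chrom = occurrences$genome,
    start = occurrences$start,
    end = occurrences$end,
    name = paste0(occurrences$family_id, ":", occurrences$variant_index),
    score = occurrences$mismatches,
    strand = occurrences$strand,
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file back into an occurrence data frame
#'
#' @param path BED6 file as written by [write_bed()].
#' @return Occurrence data frame.
#' @export
read_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand"))
  fam <- sub(":[^:]*$", "", bed$name)
  vi <- as.integer(sub("^.*:", "", bed$name))
  data.frame(genome = bed$chrom, start = bed$start, end = bed$end,
             strand = bed$strand, family_id = fam, variant_index = vi,
             mismatches = bed$score, stringsAsFactors = FALSE)
}
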