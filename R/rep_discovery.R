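# Discovery of inverted REP pairs flanking candidate rayt CDSs.
#
# Candidate enumeration is anchor-first: every GT[AG]G occurrence (on either
# strand) inside the search windows seeds candidate substrings, which are
# parsed structurally.  Accepted elements are reported as canonical "core"
# spans - head through right-arm end, leading and tail trimmed - because a
# de novo detector cannot decide whether adjacent background bases belong to
# the element.

# all (1-based) start positions of a regex, overlapping matches included
regex_positions <- function(pattern, text) {
  m <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Enumerate classify_rep-accepted REP elements in genome[win_start, win_end)
# (0-based half-open).  Returns a data.frame of core occurrences.
enumerate_rep_candidates <- function(genome, win_start, win_end,
                                     min_arm = 5L, len_range = c(18L, 45L),
                                     relaxed = FALSE, ...) {
  win_seq <- substr(genome, win_start + 1L, win_end)
  wlen <- nchar(win_seq)
  out <- list()
  add <- function(start0, end0, strand, oriented, st) {
    out[[length(out) + 1L]] <<- data.frame(
      start = as.integer(start0), end = as.integer(end0), strand = strand,
      seq = oriented,
      arm = nchar(st$left_arm), loop = nchar(st$loop),
      spacer = nchar(st$spacer), interruptions = st$interruptions,
      stringsAsFactors = FALSE
    )
  }
  try_candidate <- function(cand, strand, head_anchor0) {
    st <- parse_rep_strict(cand, min_arm = min_arm, max_leading = 0L, ...)
    if (is.null(st) && relaxed) {
      st <- parse_rep_relaxed(cand, min_arm = min_arm, max_leading = 0L, ...)
    }
    if (is.null(st)) return()
    core_len <- nchar(cand) - nchar(st$tail)
    if (strand == "+") {
      add(head_anchor0, head_anchor0 + core_len, strand,
          substr(cand, 1L, core_len), st)
    } else {
      # anchor0 is the plus-strand end of the element (exclusive)
      add(head_anchor0 - core_len, head_anchor0, strand,
          substr(cand, 1L, core_len), st)
    }
  }
  lens <- len_range[1L]:len_range[2L]
  for (p in regex_positions("GT[AG]G", win_seq)) {          # plus strand
    for (L in lens) {
      if (p + L - 1L > wlen) break
      try_candidate(substr(win_seq, p, p + L - 1L), "+",
                    win_start + p - 1L)
    }
  }
  for (p in regex_positions("C[CT]AC", win_seq)) {          # minus strand
    endpos <- p + 3L                                         # 1-based inclusive
    for (L in lens) {
      if (endpos - L + 1L < 1L) break
      try_candidate(revcomp(substr(win_seq, endpos - L + 1L, endpos)), "-",
                    win_start + endpos)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), seq = character(),
                      arm = integer(), loop = integer(), spacer = integer(),
                      interruptions = integer(), stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, out)
  # one candidate per head anchor: max arm, then min loop, then min spacer
  anchor <- ifelse(cand$strand == "+", cand$start, cand$end)
  key <- paste(anchor, cand$strand)
  ord <- order(key, -cand$arm, cand$loop, cand$spacer)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(key[ord]), , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Find the inverted REP pair flanking a CDS
#'
#' Scans a window on each side of the CDS for structurally accepted REP
#' elements and returns the pair - one per side, in mutually inverted
#' orientation (opposite strands, one's sequence at least
#' `pair_identity_min` identical to the reverse complement of the other) -
#' closest to the CDS.  Elements are reported as canonical core spans
#' (GT(A/G)G head through right-arm end).
#'
#' @param genome DNA string (one contig).
#' @param cds_start,cds_end CDS interval, 0-based half-open.
#' @param cds_strand CDS strand (`"+"` or `"-"`); recorded but the search is
#'   strand-agnostic (flank inversion is relative to each other, not to the
#'   CDS).
#' @param window Search window on each side of the CDS in bp (default 700).
#' @param min_arm Minimum palindrome arm length (default 5).
#' @param pair_identity_min Minimum identity between one flank and the
#'   reverse complement of the other (default 0.8).
#' @param len_range Candidate element length range in nt (default 18-45,
#'   bracketing all published consensi).
#' @param relaxed Whether to retry candidate enumeration with the relaxed
#'   parser on a side where no strict element was found (default `TRUE`).
#' @return List with `upstream` and `downstream` (each a one-row data frame
#'   of the core occurrence, or `NULL` if absent) and `flank_confirmed`.
#' @export
find_flanking_reps <- function(genome, cds_start, cds_end, cds_strand = "+",
                               window = 700L, min_arm = 5L,
                               pair_identity_min = 0.8,
                               len_range = c(18L, 45L), relaxed = TRUE) {
  genome <- validate_dna(genome, "genome")
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  window <- as.integer(window)
  n <- nchar(genome)
  if (cds_start < 0L || cds_end > n || cds_start >= cds_end) {
    stop("CDS interval outside genome bounds")
  }
  up_start <- max(0L, cds_start - window)
  down_end <- min(n, cds_end + window)
  if (up_start > cds_start - window || down_end < cds_end + window) {
    warning("search window truncated at contig edge")
  }
  side <- function(ws, we) {
    if (we <= ws) return(NULL)
    cc <- enumerate_rep_candidates(genome, ws, we, min_arm = min_arm,
                                   len_range = len_range, relaxed = FALSE)
    if (nrow(cc) == 0L && relaxed) {
      cc <- enumerate_rep_candidates(genome, ws, we, min_arm = min_arm,
                                     len_range = len_range, relaxed = TRUE)
    }
    if (nrow(cc) == 0L) NULL else cc
  }
  up <- side(up_start, cds_start)
  down <- side(cds_end, down_end)
  pick <- function(cc, dist) {
    if (is.null(cc)) return(NULL)
    cc[order(dist(cc))[1L], , drop = FALSE]
  }
  up_dist <- function(cc) cds_start - cc$end
  down_dist <- function(cc) cc$start - cds_end
  upstream <- pick(up, up_dist)
  downstream <- pick(down, down_dist)
  flank_confirmed <- FALSE
  if (!is.null(up) && !is.null(down)) {
    # pairs in increasing combined distance; first mutually inverted pair wins
    grid <- expand.grid(i = seq_len(nrow(up)), j = seq_len(nrow(down)))
    grid$d <- up_dist(up)[grid$i] + down_dist(down)[grid$j]
    grid <- grid[order(grid$d), , drop = FALSE]
    for (k in seq_len(nrow(grid))) {
      ui <- up[grid$i[k], , drop = FALSE]
      dj <- down[grid$j[k], , drop = FALSE]
      if (ui$strand == dj$strand) next
      id <- global_identity(ui$seq, dj$seq)$percent_identity / 100
      if (id >= pair_identity_min) {
        upstream <- ui
        downstream <- dj
        flank_confirmed <- TRUE
        break
      }
    }
  }
  list(upstream = upstream, downstream = downstream,
       flank_confirmed = flank_confirmed)
}

#' Derive a REP family consensus from a confirmed flank pair
#'
#' Both flanks are orientation-normalized to the head-5' strand.  Identical
#' flanks give a single-variant consensus; differing flanks give a
#' two-variant (dimorphic) consensus with the upstream-derived variant
#' first.
#'
#' @param upstream,downstream One-row occurrence data frames as returned by
#'   [find_flanking_reps()] (fields `seq`, `strand`).
#' @param family_id Label for the new family.
#' @param host Host genome label.
#' @param pair_identity_min Minimum mutual identity (default 0.8).
#' @param ... Parser parameters forwarded to [rep_consensus()].
#' @return A [rep_consensus].
#' @export
derive_consensus <- function(upstream, downstream, family_id = "family1",
                             host = NA_character_, pair_identity_min = 0.8,
                             ...) {
  if (is.null(upstream) || is.null(downstream)) {
    stop("both flanks are required to derive a consensus")
  }
  if (upstream$strand == downstream$strand) {
    stop("flanks are not mutually inverted")
  }
  a <- toupper(upstream$seq)
  b <- toupper(downstream$seq)
  id <- global_identity(a, b)$percent_identity / 100
  if (id < pair_identity_min) {
    stop(sprintf("flank pair identity %.2f below threshold %.2f", id,
                 pair_identity_min))
  }
  variants <- if (a == b) a else c(a, b)
  rep_consensus(family_id, variants, host = host, ...)
}
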