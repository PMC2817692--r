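# Structural model of a REP element and parsers against it.
#
# A REP is decomposed as
#   leading + head + spacer + left_arm + loop + right_arm + tail
# where head matches GT[AG]G, right_arm is the (possibly imperfect) reverse
# complement of left_arm, the loop is the noncomplementary middle, and
# leading/spacer/tail are short bounded extensions.

.DNA_RE <- "^[ACGTN]*$"

validate_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string")
  }
  seq <- toupper(seq)
  if (!grepl(.DNA_RE, seq)) {
    stop(what, " contains non-DNA characters (allowed: A, C, G, T, N)")
  }
  seq
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over the alphabet A, C, G, T, N (lowercase accepted).
#' @return The reverse-complemented string; `N` maps to `N`.
#' @examples
#' revcomp("GTAG")  # "CTAC"
#' @export
revcomp <- function(seq) {
  seq <- validate_dna(seq)
  if (nchar(seq) == 0L) return("")
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

gc_fraction <- function(seq) {
  if (nchar(seq) == 0L) return(NA_real_)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mean(ch %in% c("G", "C"))
}

new_rep_structure <- function(leading, head, spacer, left_arm, loop,
                              right_arm, tail, interruptions = 0L,
                              mode = "strict") {
  structure(
    list(
      leading = leading, head = head, spacer = spacer,
      left_arm = left_arm, loop = loop, right_arm = right_arm, tail = tail,
      interruptions = as.integer(interruptions),
      arm_gc = gc_fraction(paste0(left_arm, right_arm)),
      mode = mode
    ),
    class = "rep_structure"
  )
}

#' @export
print.rep_structure <- function(x, ...) {
  cat(sprintf(
    "REP structure (%s mode): %s|%s|%s|%s(%d)|%s(%d)|%s(%d)|%s\n",
    x$mode, x$leading, x$head, x$spacer,
    x$left_arm, nchar(x$left_arm), x$loop, nchar(x$loop),
    x$right_arm, nchar(x$right_arm), x$tail
  ))
  cat(sprintf("  interruptions: %d, arm GC: %.2f\n", x$interruptions, x$arm_gc))
  invisible(x)
}

#' @export
as.character.rep_structure <- function(x, ...) {
  paste0(x$leading, x$head, x$spacer, x$left_arm, x$loop, x$right_arm, x$tail)
}

#' Serialize a parsed REP structure to JSON
#'
#' @param x A `rep_structure`.
#' @param path Optional file to write to; if `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
rep_structure_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "rep_structure"))
  j <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}

#' Strict REP structural parser
#'
#' Decomposes a candidate sequence into
#' `leading + head + spacer + left_arm + loop + right_arm + tail` such that
#' the head matches `GT[AG]G` and the right arm is the exact reverse
#' complement of the left arm.  Among all valid decompositions the parser
#' returns the one maximizing arm length, tie-broken by smaller loop, then
#' smaller spacer, then smaller leading offset, then smaller tail.
#'
#' @param seq DNA string, at most 60 nt.
#' @param min_arm Minimum arm length (default 5).
#' @param max_loop Maximum loop length (default 12).
#' @param max_spacer Maximum spacer length between head and left arm
#'   (default 2; covers the GA dinucleotide of Pseudomonas/Xanthomonas REPs).
#' @param max_leading Maximum number of bases before the head (default 1).
#' @param max_tail Maximum number of trailing bases after the right arm
#'   (default 6).
#' @return A [rep_structure] object, or `NULL` if no decomposition reaches
#'   `min_arm`.
#' @examples
#' parse_rep_strict("TGTAGAGCCGAGCCCATGCTCGGCT")
#' @export
parse_rep_strict <- function(seq, min_arm = 5L, max_loop = 12L,
                             max_spacer = 2L, max_leading = 1L,
                             max_tail = 6L) {
  seq <- validate_dna(seq)
  n <- nchar(seq)
  if (n > 60L) stop("sequence longer than 60 nt; not a plausible REP")
  if (n < 4L + 2L * min_arm) return(NULL)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- chartr("ACGTN", "TGCAN", seq)
  chc <- strsplit(comp, "", fixed = TRUE)[[1L]]

  best <- NULL
  best_key <- NULL
  for (l in 0:max_leading) {
    if (l + 4L > n) break
    head <- substr(seq, l + 1L, l + 4L)
    if (!grepl("^GT[AG]G$", head)) next
    for (s in 0:max_spacer) {
      off <- l + 4L + s          # 0-based offset of the arm+loop+arm+tail core
      m_all <- n - off
      if (m_all < 2L * min_arm) next
      for (t in 0:min(max_tail, m_all - 2L * min_arm)) {
        m <- m_all - t
        a_max <- m %/% 2L
        for (a in a_max:min_arm) {
          loop_len <- m - 2L * a
          if (loop_len > max_loop) break  # loop grows as a shrinks
          li <- (off + 1L):(off + a)
          ri <- (off + a + loop_len + a):(off + a + loop_len + 1L)
          # right arm must equal revcomp(left arm); N never matches
          if (all(ch[ri] == chc[li]) && !any(ch[li] == "N")) {
            key <- c(-a, loop_len, s, l, t)
            if (is.null(best_key) ||
                isTRUE(vec_less(key, best_key))) {
              best_key <- key
              best <- list(l = l, s = s, a = a, loop = loop_len, t = t,
                           off = off)
            }
          }
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  with(best, new_rep_structure(
    leading   = substr(seq, 1L, l),
    head      = substr(seq, l + 1L, l + 4L),
    spacer    = substr(seq, l + 5L, l + 4L + s),
    left_arm  = substr(seq, off + 1L, off + a),
    loop      = substr(seq, off + a + 1L, off + a + loop),
    right_arm = substr(seq, off + a + loop + 1L, off + 2L * a + loop),
    tail      = substr(seq, off + 2L * a + loop + 1L, nchar(seq)),
    interruptions = 0L, mode = "strict"
  ))
}

# lexicographic "a < b" for equal-length numeric keys
vec_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Relaxed REP structural parser
#'
#' Like [parse_rep_strict()], but the two arms are aligned as an imperfect
#' stem allowing up to `max_interruptions` mismatch-or-bulge events (a bulge
#' is an unpaired run of at most `max_bulge` bases on either arm and counts
#' as one event).  A strictly parsable sequence always returns its strict
#' decomposition with `interruptions = 0`.  Otherwise the decomposition with
#' the fewest interruption events is chosen, tie-broken by most paired
#' matches, then smaller loop, spacer, leading and tail.
#'
#' @inheritParams parse_rep_strict
#' @param max_interruptions Maximum number of stem interruption events
#'   (default 2).
#' @param max_bulge Maximum length of one bulge run (default 4).
#' @return A [rep_structure] object, or `NULL`.
#' @export
parse_rep_relaxed <- function(seq, min_arm = 5L, max_interruptions = 2L,
                              max_bulge = 4L, max_loop = 12L,
                              max_spacer = 2L, max_leading = 1L,
                              max_tail = 6L) {
  seq <- validate_dna(seq)
  n <- nchar(seq)
  if (n > 60L) stop("sequence longer than 60 nt; not a plausible REP")
  strict <- parse_rep_strict(seq, min_arm = min_arm, max_loop = max_loop,
                             max_spacer = max_spacer,
                             max_leading = max_leading, max_tail = max_tail)
  if (!is.null(strict)) {
    strict$mode <- "relaxed"
    return(strict)
  }
  best <- NULL
  best_key <- NULL
  for (l in 0:max_leading) {
    if (l + 4L > n) break
    head <- substr(seq, l + 1L, l + 4L)
    if (!grepl("^GT[AG]G$", head)) next
    for (s in 0:max_spacer) {
      off <- l + 4L + s
      if (n - off < 2L * min_arm) next
      core <- substr(seq, off + 1L, n)
      hit <- cpp_relaxed_search(core, as.integer(min_arm),
                                as.integer(max_loop), as.integer(max_tail),
                                as.integer(max_interruptions),
                                as.integer(max_bulge))
      if (hit[1L] == 0L) next
      # hit = (found, left_len, loop_len, right_len, tail_len, events, matches)
      key <- c(hit[6L], -hit[7L], hit[3L], s, l, hit[5L])
      if (is.null(best_key) || vec_less(key, best_key)) {
        best_key <- key
        best <- list(l = l, s = s, off = off, a = hit[2L], loop = hit[3L],
                     r = hit[4L], t = hit[5L], ev = hit[6L])
      }
    }
  }
  if (is.null(best)) return(NULL)
  with(best, new_rep_structure(
    leading   = substr(seq, 1L, l),
    head      = substr(seq, l + 1L, l + 4L),
    spacer    = substr(seq, l + 5L, l + 4L + s),
    left_arm  = substr(seq, off + 1L, off + a),
    loop      = substr(seq, off + a + 1L, off + a + loop),
    right_arm = substr(seq, off + a + loop + 1L, off + a + loop + r),
    tail      = substr(seq, off + a + loop + r + 1L, nchar(seq)),
    interruptions = ev, mode = "relaxed"
  ))
}

#' Classify a sequence as a REP element
#'
#' A sequence is accepted iff it parses under the strict parser, or under the
#' relaxed parser with at most `max_interruptions` interruption events.  The
#' arm GC fraction is reported in the structure but never used as a filter
#' (enterobacterial arms would fail a hard GC cutoff).
#'
#' @inheritParams parse_rep_relaxed
#' @param relaxed Whether to fall back to the relaxed parser when the strict
#'   parse fails (default `TRUE`).
#' @return A list with elements `accepted` (logical), `structure`
#'   ([rep_structure] or `NULL`) and `mode` (`"strict"`, `"relaxed"` or
#'   `NA`).
#' @examples
#' classify_rep("GGTAGTGCCGGCCGCTGGCCGGCA")$accepted
#' @export
classify_rep <- function(seq, min_arm = 5L, max_interruptions = 2L,
                         max_bulge = 4L, max_loop = 12L, max_spacer = 2L,
                         max_leading = 1L, max_tail = 6L, relaxed = TRUE) {
  st <- parse_rep_strict(seq, min_arm = min_arm, max_loop = max_loop,
                         max_spacer = max_spacer, max_leading = max_leading,
                         max_tail = max_tail)
  if (!is.null(st)) {
    return(list(accepted = TRUE, structure = st, mode = "strict"))
  }
  if (relaxed) {
    rx <- parse_rep_relaxed(seq, min_arm = min_arm,
                            max_interruptions = max_interruptions,
                            max_bulge = max_bulge, max_loop = max_loop,
                            max_spacer = max_spacer,
                            max_leading = max_leading, max_tail = max_tail)
    if (!is.null(rx)) {
      return(list(accepted = TRUE, structure = rx, mode = "relaxed"))
    }
  }
  list(accepted = FALSE, structure = NULL, mode = NA_character_)
}

#' Construct a REP family consensus
#'
#' A consensus holds one or two (dimorphic) variant sequences of a REP
#' family, each of which must be accepted by [classify_rep()].  Dimorphic
#' variants arise when the two REP copies flanking a rayt gene differ;
#' the upstream-derived variant is listed first by convention.
#'
#' @param family_id Short family label (e.g. `"Smal4"`).
#' @param variants Character vector of 1 or 2 DNA strings (uppercased on
#'   ingest).
#' @param host Host genome label.
#' @param ... Parser parameters forwarded to [classify_rep()].
#' @return A `rep_consensus` object with fields `family_id`, `host`,
#'   `variants` and `structures`.
#' @export
rep_consensus <- function(family_id, variants, host = NA_character_, ...) {
  stopifnot(is.character(variants), length(variants) %in% 1:2)
  variants <- toupper(variants)
  if (length(variants) == 2L && variants[1L] == variants[2L]) {
    stop("dimorphic variants must differ in at least one position")
  }
  structures <- lapply(variants, function(v) {
    cl <- classify_rep(v, ...)
    if (!cl$accepted) {
      stop("variant of family ", family_id, " is not an acceptable REP: ", v)
    }
    cl$structure
  })
  structure(
    list(family_id = family_id, host = host, variants = variants,
         structures = structures),
    class = "rep_consensus"
  )
}

#' @export
print.rep_consensus <- function(x, ...) {
  cat(sprintf("REP consensus %s (%s): %d variant(s)\n", x$family_id,
              ifelse(is.na(x$host), "unknown host", x$host),
              length(x$variants)))
  for (i in seq_along(x$variants)) {
    cat(sprintf("  [%d] %s (loop %d nt, arm %d nt)\n", i - 1L, x$variants[i],
                nchar(x$structures[[i]]$loop),
                nchar(x$structures[[i]]$left_arm)))
  }
  invisible(x)
}

#' Load packaged or user REP consensus definitions
#'
#' Reads a tab-separated consensus table with columns `family_id`, `host`,
#' `variant_index` and `sequence` (additional columns are carried along as an
#' attribute).  The packaged table ships the published consensus set for 27
#' RAYT-associated REP families; lowercase letters mark intra-genomic
#' variable positions and are uppercased on ingest.
#'
#' @param path Path to a consensus TSV; defaults to the packaged table.
#' @param ... Parser parameters forwarded to [rep_consensus()].
#' @return Named list of [rep_consensus] objects.
#' @examples
#' consensi <- load_rep_consensi()
#' consensi[["Smal4"]]
#' @export
load_rep_consensi <- function(path = NULL, ...) {
  if (is.null(path)) {
    path <- system.file("extdata", "rep_consensus.tsv", package = "repbime")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "host", "variant_index", "sequence")
  if (!all(need %in% names(tab))) {
    stop("consensus table must have columns ", paste(need, collapse = ", "))
  }
  fams <- unique(tab$family_id)
  out <- lapply(fams, function(f) {
    rows <- tab[tab$family_id == f, , drop = FALSE]
    rows <- rows[order(rows$variant_index), , drop = FALSE]
    rep_consensus(f, rows$sequence, host = rows$host[1L], ...)
  })
  names(out) <- fams
  attr(out, "table") <- tab
  out
}
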