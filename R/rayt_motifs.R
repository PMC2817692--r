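# RAYT motif signature.
#
# RAYTs (REP-associated tyrosine transposases) share the catalytic core of
# IS200/IS605 transposases - a histidine-hydrophobic-histidine triad and a
# nucleophilic tyrosine - plus two diagnostic features absent from typical
# IS200/IS605 enzymes: a fully conserved threonine near the N-terminus and an
# NP(L/V)(R/K)xG motif close to the C-terminus, adjacent to the catalytic
# tyrosine.

.AA_RE <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

validate_protein <- function(protein, min_len = 50L) {
  if (!is.character(protein) || length(protein) != 1L || is.na(protein)) {
    stop("protein must be a single character string")
  }
  protein <- toupper(protein)
  if (!grepl(.AA_RE, protein)) {
    stop("protein contains non-amino-acid characters")
  }
  if (nchar(protein) < min_len) {
    stop("protein shorter than ", min_len, " residues")
  }
  protein
}

#' Locate the RAYT diagnostic motifs in a protein sequence
#'
#' Reports the first occurrence, within its search window, of each of the
#' four RAYT-diagnostic features: the conserved N-terminal threonine, the
#' H-phi-H triad (phi hydrophobic), the NP(L/V)(R/K)xG motif (x = any
#' residue) and the catalytic tyrosine adjacent to it.  The sequence is
#' RAYT-like iff all four are present with the N-terminal threonine upstream
#' of the H-phi-H triad, which is upstream of NP(L/V)(R/K)xG, and the
#' tyrosine within `adjacency_window` residues downstream of that motif.
#'
#' @param protein Amino-acid string (>= 50 residues, standard alphabet).
#' @param nterm_window Window (residues from the N-terminus) in which the
#'   conserved threonine is sought; default 40.
#' @param adjacency_window Number of residues downstream of the
#'   NP(L/V)(R/K)xG match in which the catalytic tyrosine is sought;
#'   default 6.
#' @param hydrophobic_set Residues accepted as phi in H-phi-H; default
#'   A, V, L, I, M, F.
#' @return A `motif_hits` list with 1-based positions `nterm_thr`, `hxh`,
#'   `npg`, `cat_tyr` (each `NA` if absent) and the flag `rayt_like`.
#' @examples
#' p <- paste0("MKT", strrep("A", 20), "HLH", strrep("G", 60),
#'             "NPLRYG", "Y", strrep("A", 20))
#' find_motifs(p)$rayt_like
#' @export
find_motifs <- function(protein, nterm_window = 40L, adjacency_window = 6L,
                        hydrophobic_set = c("A", "V", "L", "I", "M", "F")) {
  protein <- validate_protein(protein)
  first_match <- function(pattern, text, offset = 0L) {
    m <- regexpr(pattern, text)
    if (m == -1L) NA_integer_ else as.integer(m) + offset
  }
  nterm_thr <- first_match("T", substr(protein, 1L, nterm_window))
  phi <- paste(hydrophobic_set, collapse = "")
  hxh <- first_match(paste0("H[", phi, "]H"), protein)
  npg <- first_match("NP[LV][RK].G", protein)
  cat_tyr <- NA_integer_
  if (!is.na(npg)) {
    win_start <- npg + 6L
    win <- substr(protein, win_start, win_start + adjacency_window - 1L)
    cat_tyr <- first_match("Y", win, offset = win_start - 1L)
  }
  rayt_like <- !is.na(nterm_thr) && !is.na(hxh) && !is.na(npg) &&
    !is.na(cat_tyr) && nterm_thr < hxh && hxh < npg
  structure(
    list(nterm_thr = nterm_thr, hxh = hxh, npg = npg, cat_tyr = cat_tyr,
         rayt_like = rayt_like),
    class = "motif_hits"
  )
}

#' @export
print.motif_hits <- function(x, ...) {
  fmt <- function(p) if (is.na(p)) "-" else as.character(p)
  cat(sprintf(
    "RAYT motif hits: Thr(N-term)=%s  H-phi-H=%s  NP(L/V)(R/K)xG=%s  Tyr=%s  -> %s\n",
    fmt(x$nterm_thr), fmt(x$hxh), fmt(x$npg), fmt(x$cat_tyr),
    if (x$rayt_like) "RAYT-like" else "not RAYT-like"
  ))
  invisible(x)
}

#' Is a protein RAYT-like?
#'
#' Convenience wrapper around [find_motifs()]; see there for the motif
#' definition.
#'
#' @inheritParams find_motifs
#' @return Logical flag.
#' @export
is_rayt_like <- function(protein, nterm_window = 40L, adjacency_window = 6L,
                         hydrophobic_set = c("A", "V", "L", "I", "M", "F")) {
  find_motifs(protein, nterm_window = nterm_window,
              adjacency_window = adjacency_window,
              hydrophobic_set = hydrophobic_set)$rayt_like
}

#' Motif report for a set of proteins
#'
#' @param proteins Named character vector of amino-acid sequences (or an
#'   `AAStringSet`).
#' @param path Optional TSV file to write the report to (one row per
#'   sequence).
#' @param ... Parameters forwarded to [find_motifs()].
#' @return Data frame with columns `name`, `nterm_thr`, `hxh`, `npg`,
#'   `cat_tyr`, `rayt_like`.
#' @export
motif_report <- function(proteins, path = NULL, ...) {
  if (is(proteins, "AAStringSet")) {
    proteins <- setNames(as.character(proteins), names(proteins))
  }
  stopifnot(is.character(proteins))
  if (is.null(names(proteins))) {
    names(proteins) <- paste0("seq", seq_along(proteins))
  }
  rows <- lapply(names(proteins), function(nm) {
    h <- find_motifs(proteins[[nm]], ...)
    data.frame(name = nm, nterm_thr = h$nterm_thr, hxh = h$hxh, npg = h$npg,
               cat_tyr = h$cat_tyr, rayt_like = h$rayt_like,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
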