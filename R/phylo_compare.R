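# Pairwise identity, NJ trees and topology congruence.
#
# The coevolution analysis compares the NJ topology of RAYT protein
# sequences with that of their cognate REP DNA sequences; only topology
# congruence (Robinson-Foulds distance 0), not branch lengths, is assessed.
# Distances are p-distances over optimal pairwise global alignments - a
# deterministic, reimplementable substitute for multiple-alignment guide
# trees.

.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

seq_alphabet <- function(x) {
  if (grepl(.DNA_RE, x)) "DNA" else if (grepl(.AA_RE, x)) "AA" else
    stop("sequence is neither DNA nor protein: ", substr(x, 1, 20))
}

# match/mismatch substitution matrix; N never matches anything (DNA only)
sub_matrix <- function(alphabet, match, mismatch) {
  letters <- if (alphabet == "DNA") c("A", "C", "G", "T", "N") else .AA_LETTERS
  m <- matrix(mismatch, nrow = length(letters), ncol = length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  if (alphabet == "DNA") m["N", "N"] <- mismatch
  m
}

#' Percent identity over an optimal global alignment
#'
#' Needleman-Wunsch global alignment with linear gap penalties.  Percent
#' identity is the number of identical columns divided by the number of
#' aligned columns excluding terminal-gap columns, so a sequence aligned
#' against an extension of itself scores 100%.
#'
#' @param a,b Sequences (both DNA or both protein; mixed alphabets are
#'   rejected).
#' @param match,mismatch,gap Scoring parameters (defaults +1/-1/-2; the gap
#'   penalty is per gapped column).
#' @return An `identity_result` list: `percent_identity`, `aligned_columns`,
#'   `match_columns`, `substitution_columns`, `indel_columns`,
#'   `terminal_gap_columns`.
#' @examples
#' global_identity("ACGT", "ACGTACGT")$percent_identity  # 100
#' @export
global_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L,
            length(b) == 1L)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  al_a <- seq_alphabet(a); al_b <- seq_alphabet(b)
  # an all-ACGT protein fragment is indistinguishable from DNA; only a
  # genuine DNA/AA mixture is an error
  if (al_a != al_b) {
    if (al_a == "DNA" || al_b == "DNA") stop("mixed DNA/protein alphabets")
  }
  alphabet <- if (al_a == "DNA" && al_b == "DNA") "DNA" else "AA"
  sm <- sub_matrix(alphabet, match, mismatch)
  cls <- if (alphabet == "DNA") Biostrings::DNAString else
    Biostrings::AAString
  pwa <- Biostrings::pairwiseAlignment(
    cls(a), cls(b), type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = abs(gap)
  )
  identity_from_pwa(pwa, nchar(a), nchar(b), alphabet)
}

# Column bookkeeping from one pairwiseAlignment result.  The pattern()/
# subject() views cover the alignment without its terminal-gap regions, so
# the identity denominator is simply their column count.
identity_from_pwa <- function(pwa, na, nb, alphabet) {
  va <- strsplit(as.character(Biostrings::pattern(pwa)), "")[[1L]]
  vb <- strsplit(as.character(Biostrings::subject(pwa)), "")[[1L]]
  gapcol <- va == "-" | vb == "-"
  core_cols <- length(va)
  consumed_a <- sum(va != "-")
  consumed_b <- sum(vb != "-")
  terminal <- (na - consumed_a) + (nb - consumed_b)
  is_match <- !gapcol & va == vb &
    !(alphabet == "DNA" & va == "N")  # N never matches, even against N
  matches <- sum(is_match)
  subs <- sum(!gapcol) - matches
  indels <- sum(gapcol) + terminal
  structure(
    list(percent_identity = 100 * matches / core_cols,
         aligned_columns = core_cols + terminal,
         match_columns = matches,
         substitution_columns = subs,
         indel_columns = indels,
         terminal_gap_columns = terminal),
    class = "identity_result"
  )
}

# Batched identities of one subject against many patterns (same scoring
# path as global_identity; used for distance matrices).
global_identity_many <- function(patterns, subject, alphabet,
                                 match = 1, mismatch = -1, gap = -2) {
  sm <- sub_matrix(alphabet, match, mismatch)
  set_cls <- if (alphabet == "DNA") Biostrings::DNAStringSet else
    Biostrings::AAStringSet
  pwa <- Biostrings::pairwiseAlignment(
    set_cls(patterns), set_cls(subject)[[1L]], type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = abs(gap)
  )
  pa <- as.character(Biostrings::pattern(pwa))
  pb <- as.character(Biostrings::subject(pwa))
  vapply(seq_along(patterns), function(i) {
    va <- strsplit(pa[i], "")[[1L]]
    vb <- strsplit(pb[i], "")[[1L]]
    gapcol <- va == "-" | vb == "-"
    is_match <- !gapcol & va == vb & !(alphabet == "DNA" & va == "N")
    100 * sum(is_match) / length(va)
  }, numeric(1L))
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf(
    "identity %.1f%% over %d columns (%d match, %d subst, %d indel, %d terminal-gap)\n",
    x$percent_identity, x$aligned_columns, x$match_columns,
    x$substitution_columns, x$indel_columns, x$terminal_gap_columns))
  invisible(x)
}

#' Ortholog substitution-rate contrast
#'
#' Compares the percent identity of an orthologous RAYT protein pair with
#' the identities of neighboring orthologous gene products.  RAYTs evolve
#' markedly faster than the products of surrounding host genes; the flag is
#' true iff the RAYT identity is below the minimum neighbor identity.
#'
#' @param rayt_pair Character vector of the two orthologous RAYT protein
#'   sequences.
#' @param neighbor_pairs List of length-2 character vectors of neighboring
#'   orthologous protein pairs (at least one).
#' @param ... Scoring parameters forwarded to [global_identity()].
#' @return List with `rayt_identity`, `neighbor_identities` and
#'   `rayt_slower_flag`.
#' @export
ortholog_rate_contrast <- function(rayt_pair, neighbor_pairs, ...) {
  stopifnot(is.character(rayt_pair), length(rayt_pair) == 2L)
  if (!is.list(neighbor_pairs) || length(neighbor_pairs) == 0L) {
    stop("at least one neighbor pair is required")
  }
  rayt_id <- global_identity(rayt_pair[1L], rayt_pair[2L],
                             ...)$percent_identity
  nb <- vapply(neighbor_pairs, function(p) {
    stopifnot(length(p) == 2L)
    global_identity(p[1L], p[2L], ...)$percent_identity
  }, numeric(1L))
  list(rayt_identity = rayt_id, neighbor_identities = nb,
       rayt_slower_flag = rayt_id < min(nb))
}

#' Neighbor-joining tree from pairwise alignment p-distances
#'
#' Builds the pairwise distance matrix from global-alignment p-distances
#' (1 - identity/100, terminal gaps excluded) and applies standard
#' neighbor-joining.  Deterministic given the input order.
#'
#' @param seqs Named character vector of >= 3 sequences (all DNA or all
#'   protein).
#' @param ... Scoring parameters forwarded to [global_identity()].
#' @return An [ape::phylo] tree whose tip labels are the input names.
#' @export
build_nj_tree <- function(seqs, ...) {
  stopifnot(is.character(seqs))
  if (length(seqs) < 3L) stop("at least 3 sequences are required")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  alphabets <- vapply(seqs, seq_alphabet, character(1L))
  alphabet <- if (all(alphabets == "DNA")) "DNA" else "AA"
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (j in 2:n) {
    ids <- global_identity_many(seqs[seq_len(j - 1L)], seqs[[j]], alphabet,
                                ...)
    d[seq_len(j - 1L), j] <- d[j, seq_len(j - 1L)] <- 1 - ids / 100
  }
  ape::nj(stats::as.dist(d))
}

#' Robinson-Foulds distance between two unrooted topologies
#'
#' Symmetric-difference count of bipartitions; 0 means identical topology.
#'
#' @param t1,t2 Trees of class `phylo` with identical leaf sets.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  as.integer(ape::dist.topo(ape::unroot(t1), ape::unroot(t2),
                            method = "PH85"))
}

#' Write a tree in newick format
#'
#' @param tree `phylo` tree.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
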