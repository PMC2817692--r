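# Clustering of REP occurrences into composite structures (BIMEs).
#
# A cluster is a maximal run of occurrences separated by at most max_gap bp.
# Classes: solitary (1 REP), doublet (2 inverted REPs, BIME-1-like), modular
# (>= 3 REPs in alternating orientations, the classic BIME), atypical
# (anything else).  Modular clusters decompose into "basic modules": an
# inverted REP pair with its intervening segment, plus the trailing segment
# connecting head-to-tail to the next module.

new_rep_cluster <- function(genome_label, occurrences, gaps) {
  cl <- structure(
    list(genome = genome_label, occurrences = occurrences, gaps = gaps,
         cluster_class = NA_character_,
         hybrid = length(unique(occurrences$family_id)) > 1L,
         segment_labels = NULL,
         rayt_association = "none"),
    class = "rep_cluster"
  )
  cl$cluster_class <- classify_cluster(cl)
  cl
}

#' @export
print.rep_cluster <- function(x, ...) {
  cat(sprintf("REP cluster (%s%s): %d occurrence(s), span %d-%d\n",
              x$cluster_class, if (x$hybrid) ", hybrid" else "",
              nrow(x$occurrences), min(x$occurrences$start),
              max(x$occurrences$end)))
  cat(" ", render_cluster(x), "\n")
  invisible(x)
}

#' Chain REP occurrences into clusters
#'
#' Single-linkage chaining: consecutive occurrences at most `max_gap` bp
#' apart (end-to-start) belong to one cluster; singletons become solitary
#' clusters.
#'
#' @param occurrences Occurrence data frame sorted by `start` (as produced
#'   by [scan_genome()]; unsorted input is rejected).  Occurrences of
#'   several families may be pooled to detect hybrid clusters.
#' @param genome DNA string of the scanned contig (inter-REP segments are
#'   extracted from it).
#' @param max_gap Maximum end-to-start distance within a cluster (default
#'   250 bp).
#' @return List of `rep_cluster` objects, each with its `cluster_class`
#'   assigned by [classify_cluster()].
#' @export
cluster_occurrences <- function(occurrences, genome, max_gap = 250L) {
  genome <- validate_dna(genome, "genome")
  if (nrow(occurrences) == 0L) return(list())
  if (is.unsorted(occurrences$start)) {
    stop("occurrences must be sorted by start")
  }
  n <- nrow(occurrences)
  gap_after <- c(occurrences$start[-1L] - occurrences$end[-n], Inf)
  breaks <- which(gap_after > max_gap)
  starts <- c(1L, head(breaks, -1L) + 1L)
  clusters <- vector("list", length(breaks))
  for (k in seq_along(breaks)) {
    idx <- starts[k]:breaks[k]
    occ <- occurrences[idx, , drop = FALSE]
    rownames(occ) <- NULL
    gaps <- character(0)
    if (length(idx) > 1L) {
      gaps <- substring(genome, occ$end[-nrow(occ)] + 1L, occ$start[-1L])
    }
    clusters[[k]] <- new_rep_cluster(occ$genome[1L], occ, gaps)
  }
  clusters
}

#' Classify a REP cluster
#'
#' @param cluster A `rep_cluster`.
#' @return One of `"solitary"`, `"doublet"`, `"modular"`, `"atypical"`.
#' @export
classify_cluster <- function(cluster) {
  strands <- cluster$occurrences$strand
  n <- length(strands)
  if (n == 1L) return("solitary")
  alternating <- all(strands[-1L] != strands[-n])
  if (n == 2L) return(if (alternating) "doublet" else "atypical")
  if (alternating) "modular" else "atypical"
}

#' Decompose a modular BIME into basic modules
#'
#' Greedy left-to-right bracketing: occurrences 1+2 form module 1 (with the
#' segment to occurrence 3 as its trailing segment), 3+4 module 2, and so
#' on.  An unpaired final occurrence attaches to the last module as a
#' flagged terminal half-module.
#'
#' @param cluster A `rep_cluster` of class `"modular"`.
#' @return List of `basic_module` objects (fields `first_rep`,
#'   `inter_segment`, `second_rep`, `trailing_segment`, `terminal_half`,
#'   `extra_rep`).
#' @export
decompose_modules <- function(cluster) {
  stopifnot(inherits(cluster, "rep_cluster"))
  if (cluster$cluster_class != "modular") {
    stop("cluster is not modular")
  }
  occ <- cluster$occurrences
  gaps <- cluster$gaps
  n <- nrow(occ)
  n_mod <- n %/% 2L
  modules <- vector("list", n_mod)
  for (k in seq_len(n_mod)) {
    i <- 2L * k - 1L
    modules[[k]] <- structure(
      list(first_rep = occ[i, , drop = FALSE],
           inter_segment = gaps[i],
           second_rep = occ[i + 1L, , drop = FALSE],
           trailing_segment = if (i + 1L < n) gaps[i + 1L] else
             NA_character_,
           terminal_half = FALSE, extra_rep = NULL),
      class = "basic_module"
    )
  }
  if (n %% 2L == 1L) {
    modules[[n_mod]]$terminal_half <- TRUE
    modules[[n_mod]]$extra_rep <- occ[n, , drop = FALSE]
  }
  modules
}

next_label <- function(k) {
  # a, b, ..., z, aa, ab, ...
  if (k <= 26L) letters[k] else
    paste0(letters[(k - 1L) %/% 26L], letters[(k - 1L) %% 26L + 1L])
}

#' Label inter-REP segments by sequence identity
#'
#' All inter-REP segments of the input clusters are pooled and greedily
#' partitioned: a segment joins the first existing label whose
#' representative (first member) it matches at `identity_min` or better over
#' a global alignment, with a length ratio of at least `length_ratio_min`;
#' otherwise it founds a new label.  Letters are assigned a, b, c, ... in
#' order of first appearance.  Labeling is orientation-sensitive: a segment
#' equal to another's reverse complement gets a distinct letter.
#'
#' @param clusters List of `rep_cluster` objects.
#' @param identity_min Minimum global-alignment identity (fraction; default
#'   0.9).
#' @param length_ratio_min Minimum shorter/longer length ratio (default
#'   0.8).
#' @return List (parallel to `clusters`) of character vectors of labels, one
#'   per gap.
#' @export
label_segments <- function(clusters, identity_min = 0.9,
                           length_ratio_min = 0.8) {
  reps <- character(0)   # label representatives, in founding order
  assign_label <- function(seg) {
    for (li in seq_along(reps)) {
      r <- reps[li]
      if (nchar(seg) == 0L || nchar(r) == 0L) {
        if (nchar(seg) == 0L && nchar(r) == 0L) return(next_label(li))
        next
      }
      ratio <- min(nchar(seg), nchar(r)) / max(nchar(seg), nchar(r))
      if (ratio < length_ratio_min) next
      id <- global_identity(seg, r)$percent_identity / 100
      if (id >= identity_min) return(next_label(li))
    }
    reps <<- c(reps, seg)
    next_label(length(reps))
  }
  lapply(clusters, function(cl) {
    vapply(cl$gaps, assign_label, character(1L), USE.NAMES = FALSE)
  })
}

#' Assess the association of a cluster with a rayt gene
#'
#' `"adjacent"` when a flanking REP of the rayt gene is a member occurrence
#' of the cluster; `"terminus_captured"` when additionally the cluster span
#' covers the 3'-terminal boundary of the CDS (the rayt 3' end, with the
#' sequence up to the downstream REP, is then integrated into the BIME as
#' part of an inter-REP segment).
#'
#' @param cluster A `rep_cluster`.
#' @param cds_start,cds_end CDS interval, 0-based half-open.
#' @param cds_strand CDS strand; determines which boundary is the 3' end.
#' @param flanks Optional list with `upstream`/`downstream` occurrence rows
#'   (as from [find_flanking_reps()]); when supplied, flank membership is
#'   decided by interval overlap with cluster members.  Otherwise any member
#'   occurrence within `window` bp of a CDS boundary counts as flanking.
#' @param window Flank search window used in the fallback membership test
#'   (default 700 bp).
#' @return One of `"none"`, `"adjacent"`, `"terminus_captured"`.
#' @export
assess_rayt_association <- function(cluster, cds_start, cds_end,
                                    cds_strand = "+", flanks = NULL,
                                    window = 700L) {
  occ <- cluster$occurrences
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  if (!is.null(flanks)) {
    member <- FALSE
    for (fl in flanks[c("upstream", "downstream")]) {
      if (is.null(fl)) next
      member <- member || any(overlaps(occ$start, occ$end, fl$start, fl$end))
    }
  } else {
    upstream_gap <- cds_start - occ$end      # >= 0 when occ left of CDS
    downstream_gap <- occ$start - cds_end    # >= 0 when occ right of CDS
    member <- any((upstream_gap >= 0L & upstream_gap <= window) |
                    (downstream_gap >= 0L & downstream_gap <= window))
  }
  if (!member) return("none")
  span_s <- min(occ$start)
  span_e <- max(occ$end)
  p3 <- if (cds_strand == "+") cds_end else cds_start
  # 3' terminal boundary of the CDS inside the cluster span
  if (span_s < p3 && p3 < span_e) "terminus_captured" else "adjacent"
}

#' Text rendering of a cluster
#'
#' One-line schematic in the style used for BIME diagrams, e.g.
#' `"[Smal4> a <Smal4 | a] [Smal4> b <Smal4]"` for a two-module BIME.
#'
#' @param cluster A `rep_cluster`.
#' @param labels Optional character vector of segment labels (one per gap);
#'   defaults to labeling the cluster's own gaps.
#' @return Character scalar.
#' @export
render_cluster <- function(cluster, labels = NULL) {
  if (is.null(labels)) labels <- label_segments(list(cluster))[[1L]]
  occ <- cluster$occurrences
  arrow <- function(i) {
    if (occ$strand[i] == "+") paste0(occ$family_id[i], ">") else
      paste0("<", occ$family_id[i])
  }
  n <- nrow(occ)
  if (cluster$cluster_class != "modular") {
    parts <- character(0)
    for (i in seq_len(n)) {
      parts <- c(parts, arrow(i))
      if (i < n) parts <- c(parts, labels[i])
    }
    return(paste(parts, collapse = " "))
  }
  out <- character(0)
  i <- 1L
  while (i + 1L <= n) {
    piece <- paste(arrow(i), labels[i], arrow(i + 1L))
    if (i + 1L < n) piece <- paste(piece, "|", labels[i + 1L])
    out <- c(out, paste0("[", piece, "]"))
    i <- i + 2L
  }
  if (i == n) out <- c(out, paste0(arrow(i), "*"))
  paste(out, collapse = " ")
}

#' JSON report for a list of clusters
#'
#' @param clusters List of `rep_cluster` objects.
#' @param labels Optional label list as from [label_segments()]; computed if
#'   missing.
#' @param path Optional output file.
#' @return JSON string (invisibly when written).
#' @export
cluster_report_json <- function(clusters, labels = NULL, path = NULL) {
  if (is.null(labels)) labels <- label_segments(clusters)
  payload <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    list(genome = cl$genome, class = cl$cluster_class, hybrid = cl$hybrid,
         occurrences = cl$occurrences, segment_labels = labels[[i]],
         rayt_association = cl$rayt_association,
         rendering = render_cluster(cl, labels[[i]]))
  })
  j <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                        dataframe = "rows")
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}
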