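# File formats, configuration and the end-to-end pipeline driver.
#
# Coordinate policy: internal coordinates are 0-based half-open everywhere.
# BED stays 0-based on output; GFF3 (1-based inclusive) is converted at the
# read/write boundary - the single conversion site in the package.

#' Read a FASTA file
#'
#' @param path FASTA file (multi-record allowed).
#' @param type `"DNA"` or `"AA"`.
#' @return Named character vector of uppercased sequences; names are the
#'   first word of each header, full headers are kept in the
#'   `descriptions` attribute.  Empty files and duplicate IDs are rejected.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  desc <- names(set)
  ids <- sub("\\s.*$", "", desc)
  if (anyDuplicated(ids)) stop("duplicate sequence IDs in ", path)
  out <- setNames(toupper(as.character(set)), ids)
  attr(out, "descriptions") <- setNames(desc, ids)
  out
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param type `"DNA"` or `"AA"`.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read CDS features from a GFF3 file
#'
#' GFF3 coordinates (1-based inclusive) are converted to the package's
#' internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param feature_types Feature types to keep (default `"CDS"`).
#' @param contig_lengths Optional named integer vector; features outside
#'   their contig bounds are rejected.
#' @return Data frame with columns `seqid`, `id`, `type`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_gff3 <- function(path, feature_types = "CDS", contig_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (nrow(df) > 0L && any(df$start < 1L)) {
    stop("GFF3 contains non-positive coordinates")
  }
  df <- df[df$type %in% feature_types, , drop = FALSE]
  id <- if ("ID" %in% names(df)) as.character(df$ID) else
    paste0("feature", seq_len(nrow(df)))
  id[is.na(id)] <- paste0("feature", which(is.na(id)))
  out <- data.frame(
    seqid = as.character(df$seqnames), id = id,
    type = as.character(df$type), start = df$start - 1L, end = df$end,
    strand = as.character(df$strand), stringsAsFactors = FALSE
  )
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[out$seqid]
    if (any(is.na(lim)) || any(out$end > lim) || any(out$start < 0L)) {
      stop("GFF3 feature outside contig bounds")
    }
  }
  rownames(out) <- NULL
  out
}

#' Write CDS features as GFF3
#'
#' @param features Data frame with `seqid`, `id`, `type`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param path Output file.
#' @export
write_gff3 <- function(features, path) {
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand
  )
  gr$type <- features$type
  gr$ID <- features$id
  gr$phase <- ifelse(features$type == "CDS", 0L, NA_integer_)
  gr$source <- "repbime"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

.CONFIG_KEYS <- c("genome_fasta", "gff3", "proteins_fasta", "consensus_tsv",
                  "out_dir", "seed", "window", "max_mm", "max_gap",
                  "min_arm", "pair_identity_min", "identity_min",
                  "verbosity")

default_config <- function() {
  list(genome_fasta = NULL, gff3 = NULL, proteins_fasta = NULL,
       consensus_tsv = NULL, out_dir = "repbime_out", seed = 1L,
       window = 700L, max_mm = 2L, max_gap = 250L, min_arm = 5L,
       pair_identity_min = 0.8, identity_min = 0.9, verbosity = 1L)
}

#' Read a key=value pipeline configuration file
#'
#' Unknown keys are rejected; missing keys take the documented stage
#' defaults.
#'
#' @param path Plain-text file of `key=value` lines (`#` comments allowed).
#' @return Named list (a complete effective configuration).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  unknown <- setdiff(keys, .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- default_config()
  num_keys <- c("seed", "window", "max_mm", "max_gap", "min_arm",
                "verbosity")
  dbl_keys <- c("pair_identity_min", "identity_min")
  for (i in seq_along(keys)) {
    k <- keys[i]
    cfg[[k]] <- if (k %in% num_keys) as.integer(vals[i]) else
      if (k %in% dbl_keys) as.numeric(vals[i]) else vals[i]
  }
  cfg
}

merge_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    return(read_config(config))
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- default_config()
  cfg[names(config)] <- config
  cfg
}

pipeline_log <- function(cfg, log_path, ...) {
  msg <- sprintf("[repbime %s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(...))
  if (cfg$verbosity > 0L) message(msg)
  cat(msg, "\n", file = log_path, append = TRUE)
}

hashed_tsv <- function(df, path, config_hash) {
  con <- file(path, "w")
  cat(sprintf("# config_md5=%s\n", config_hash), file = con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(path)
}

#' Run the full REP/RAYT/BIME analysis pipeline
#'
#' Chains the stages end to end: protein motif classification, flank REP
#' discovery around RAYT-like CDSs, consensus derivation, genome-wide
#' mismatch-tolerant scanning, cluster/BIME decomposition with segment
#' labeling, rayt-association assessment and summary tables.  Deterministic
#' given the configuration and inputs; all outputs (BED, TSV, JSON and a
#' log) are written into `out_dir` together with the effective
#' configuration and its MD5 hash.
#'
#' @param config A named list of configuration values, or the path to a
#'   `key=value` configuration file; see [read_config()] for keys.  Required
#'   keys: `genome_fasta`, `gff3`.  When `proteins_fasta` is absent, CDS
#'   translations are used.  `consensus_tsv` adds user-supplied families to
#'   the scan.
#' @return The report list (invisibly): motif table, RAYT candidates,
#'   derived consensi, occurrence table, count summaries, clusters and
#'   associations, extragenic fraction.
#' @export
run_pipeline <- function(config) {
  cfg <- merge_config(config)
  if (is.null(cfg$genome_fasta) || is.null(cfg$gff3)) {
    stop("config stage 'input': genome_fasta and gff3 are required")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # echo effective config; its hash is stamped into every table
  cfg_path <- file.path(cfg$out_dir, "effective_config.txt")
  writeLines(paste0(names(cfg), "=",
                    vapply(cfg, function(x)
                      if (is.null(x)) "" else as.character(x), "")),
             cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  cat("", file = log_path)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  genomes <- stage("input", read_fasta(cfg$genome_fasta, type = "DNA"))
  contig_lengths <- setNames(nchar(genomes), names(genomes))
  cds <- stage("input", read_gff3(cfg$gff3,
                                  contig_lengths = contig_lengths))
  pipeline_log(cfg, log_path, "read %d contig(s), %d CDS feature(s)",
               length(genomes), nrow(cds))

  # --- proteins ------------------------------------------------------------
  proteins <- stage("motifs", {
    if (!is.null(cfg$proteins_fasta)) {
      as.list(read_fasta(cfg$proteins_fasta, type = "AA"))
    } else {
      out <- list()
      for (i in seq_len(nrow(cds))) {
        nt <- substr(genomes[[cds$seqid[i]]], cds$start[i] + 1L, cds$end[i])
        if (cds$strand[i] == "-") nt <- revcomp(nt)
        out[[cds$id[i]]] <- translate_cds(nt)
      }
      out
    }
  })
  motifs <- stage("motifs", motif_report(unlist(proteins)))
  hashed_tsv(motifs, file.path(cfg$out_dir, "motifs.tsv"), config_hash)
  pipeline_log(cfg, log_path, "motif classification: %d/%d RAYT-like",
               sum(motifs$rayt_like), nrow(motifs))

  # --- flank discovery and consensus derivation ---------------------------
  candidates <- list()
  consensi <- list()
  for (i in seq_len(nrow(cds))) {
    id <- cds$id[i]
    if (!id %in% motifs$name[motifs$rayt_like]) next
    fl <- stage("find-flanks", find_flanking_reps(
      genomes[[cds$seqid[i]]], cds$start[i], cds$end[i],
      cds_strand = cds$strand[i], window = cfg$window,
      min_arm = cfg$min_arm, pair_identity_min = cfg$pair_identity_min
    ))
    cand <- list(genome = cds$seqid[i], cds_id = id,
                 cds_start = cds$start[i], cds_end = cds$end[i],
                 cds_strand = cds$strand[i], upstream = fl$upstream,
                 downstream = fl$downstream,
                 flank_confirmed = fl$flank_confirmed)
    candidates[[id]] <- cand
    if (fl$flank_confirmed) {
      consensi[[id]] <- stage("consensus", derive_consensus(
        fl$upstream, fl$downstream, family_id = id,
        host = cds$seqid[i], pair_identity_min = cfg$pair_identity_min
      ))
    }
  }
  if (length(candidates) == 0L) {
    pipeline_log(cfg, log_path, "no RAYT candidate found")
  }

  # --- user-supplied consensi ---------------------------------------------
  if (!is.null(cfg$consensus_tsv)) {
    user <- stage("consensus", load_rep_consensi(cfg$consensus_tsv))
    consensi <- c(consensi, user[setdiff(names(user), names(consensi))])
  }
  if (length(consensi)) {
    ctab <- do.call(rbind, lapply(consensi, function(cs) {
      data.frame(family_id = cs$family_id, host = cs$host,
                 variant_index = seq_along(cs$variants) - 1L,
                 sequence = cs$variants, stringsAsFactors = FALSE)
    }))
    hashed_tsv(ctab, file.path(cfg$out_dir, "consensus.tsv"), config_hash)
  }

  # --- genome-wide scan ----------------------------------------------------
  occurrences <- empty_occurrences()
  summaries <- list()
  for (gname in names(genomes)) {
    for (cs in consensi) {
      occ <- stage("scan", scan_genome(genomes[[gname]], cs,
                                       max_mm = cfg$max_mm,
                                       genome_label = gname))
      occurrences <- rbind(occurrences, occ)
      summaries[[length(summaries) + 1L]] <- data.frame(
        genome = gname, family_id = cs$family_id,
        n_exact = sum(occ$mismatches == 0L),
        n_le1 = sum(occ$mismatches <= 1L), n_le2 = nrow(occ),
        stringsAsFactors = FALSE
      )
    }
  }
  occurrences <- occurrences[order(occurrences$genome, occurrences$start), ,
                             drop = FALSE]
  rownames(occurrences) <- NULL
  write_bed(occurrences, file.path(cfg$out_dir, "occurrences.bed"))
  counts <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame()
  if (nrow(counts)) {
    hashed_tsv(counts, file.path(cfg$out_dir, "rep_counts.tsv"), config_hash)
  }
  pipeline_log(cfg, log_path, "scan: %d occurrence(s) of %d family/ies",
               nrow(occurrences), length(consensi))

  # --- clustering / BIMEs --------------------------------------------------
  clusters <- list()
  labels <- list()
  associations <- list()
  for (gname in names(genomes)) {
    occ_g <- occurrences[occurrences$genome == gname, , drop = FALSE]
    rownames(occ_g) <- NULL
    cl_g <- stage("bimes", cluster_occurrences(occ_g, genomes[[gname]],
                                               max_gap = cfg$max_gap))
    lab_g <- stage("bimes", label_segments(cl_g,
                                           identity_min = cfg$identity_min))
    for (k in seq_along(cl_g)) {
      for (cand in candidates) {
        if (cand$genome != gname) next
        assoc <- assess_rayt_association(
          cl_g[[k]], cand$cds_start, cand$cds_end, cand$cds_strand,
          flanks = cand[c("upstream", "downstream")], window = cfg$window
        )
        if (assoc != "none") {
          cl_g[[k]]$rayt_association <- assoc
          associations[[length(associations) + 1L]] <- data.frame(
            genome = gname, cds_id = cand$cds_id, cluster = k,
            association = assoc, stringsAsFactors = FALSE
          )
        }
      }
    }
    clusters[[gname]] <- cl_g
    labels[[gname]] <- lab_g
  }
  all_clusters <- do.call(c, unname(clusters))
  all_labels <- do.call(c, unname(labels))
  if (length(all_clusters)) {
    cluster_report_json(all_clusters, all_labels,
                        file.path(cfg$out_dir, "clusters.json"))
  }

  # --- summary report ------------------------------------------------------
  exfrac <- extragenic_fraction(occurrences, cds)
  report <- list(
    config = cfg[!vapply(cfg, is.null, logical(1L))],
    config_md5 = config_hash,
    motifs = motifs,
    candidates = lapply(candidates, function(cand) {
      cand[c("genome", "cds_id", "flank_confirmed")]
    }),
    counts = counts,
    n_occurrences = nrow(occurrences),
    cluster_classes = table(vapply(all_clusters, `[[`, "", "cluster_class")),
    associations = if (length(associations)) do.call(rbind, associations)
      else data.frame(),
    extragenic_fraction = exfrac
  )
  jsonlite::write_json(
    list(config_md5 = config_hash, counts = counts,
         n_occurrences = nrow(occurrences),
         extragenic_fraction = exfrac,
         rayt_candidates = names(candidates),
         confirmed = names(consensi)),
    file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
  )
  pipeline_log(cfg, log_path, "done; outputs in %s", cfg$out_dir)
  invisible(report)
}
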