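# Shared fixture builders (everything is generated in code; no stored data).

SMAL4 <- "GGTAGTGCCGGCCGCTGGCCGGCA"
SMAL4_CORE <- "GTAGTGCCGGCCGCTGGCCGGCA"

smal4_consensus <- function() load_rep_consensi()[["Smal4"]]

# motif-complete synthetic protein from the classifier's documentation
motif_protein <- function() {
  paste0("MKT", strrep("A", 20), "HLH", strrep("G", 60), "NPLRYG", "Y",
         strrep("A", 20))
}

# plant plus-strand sequences into a background at fixed 0-based offsets
plant_at <- function(background, inserts, offsets) {
  g <- background
  for (i in seq_along(inserts)) {
    substr(g, offsets[i] + 1L, offsets[i] + nchar(inserts[i])) <- inserts[i]
  }
  g
}

# occurrence data frame for hand-built cluster tests
occ_df <- function(starts, ends, strands, family = "fam",
                   genome = "g") {
  data.frame(genome = genome, start = as.integer(starts),
             end = as.integer(ends), strand = strands, family_id = family,
             variant_index = 0L, mismatches = 0L, stringsAsFactors = FALSE)
}

# random REP-free background of the given length (checked against a
# consensus list at <= 2 mismatches)
clean_background <- function(n, consensi, gc = 0.6) {
  repeat {
    bg <- random_dna(n, gc)
    hits <- sum(vapply(consensi, function(cs)
      nrow(scan_genome(bg, cs, max_mm = 2L)), integer(1)))
    if (hits == 0L) return(bg)
  }
}
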