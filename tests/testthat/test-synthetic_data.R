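test_that("simulation is deterministic per seed and respects its ledger", {
  s1 <- simulate_genome(seed = 101, length = 20000, n_solitary = 4,
                        n_doublets = 1, n_modular = 2)
  s2 <- simulate_genome(seed = 101, length = 20000, n_solitary = 4,
                        n_doublets = 1, n_modular = 2)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth$planted_reps, s2$truth$planted_reps)
  s3 <- simulate_genome(seed = 102, length = 20000, n_solitary = 4,
                        n_doublets = 1, n_modular = 2)
  expect_false(identical(s1$genome, s3$genome))

  # planted intervals are mutually non-overlapping
  tr <- s1$truth$planted_reps
  expect_true(all(tr$start[-1] >= head(tr$end, -1)))
  # recorded mutation counts match a rescan (the generator also verifies
  # this internally before returning)
  occ <- scan_genome(s1$genome, default_sim_consensi()[[1]], 2)
  sm4 <- tr[tr$family_id == "Smal4", ]
  expect_identical(occ$mismatches, sm4$n_mutations)
  expect_identical(occ$start, sm4$start)
})

test_that("consensus mutation has exact Hamming behavior", {
  expect_identical(as.character(mutate_consensus(SMAL4, 0, seed = 1)),
                   SMAL4)
  m2 <- mutate_consensus(SMAL4, 2, seed = 2)
  diff <- mapply(function(a, b) a != b,
                 strsplit(SMAL4, "")[[1]],
                 strsplit(as.character(m2), "")[[1]])
  expect_identical(sum(diff), 2L)
  expect_identical(attr(m2, "n_changed"), 2L)
  expect_error(mutate_consensus("ACGT", 5), "exceeds")

  # palindrome-preserving mode keeps the strict parse and arm length
  st0 <- parse_rep_strict(SMAL4)
  for (s in 1:10) {
    mp <- mutate_consensus(SMAL4, 1, seed = s, palindrome_preserving = TRUE)
    st <- parse_rep_strict(as.character(mp))
    expect_false(is.null(st))
    expect_identical(nchar(st$left_arm), nchar(st0$left_arm))
  }
})

test_that("forcing zero mutations gives exact planted counts; rayt=off plants no RAYT", {
  sim <- simulate_genome(seed = 55, length = 20000, n_solitary = 5,
                         n_doublets = 0, n_modular = integer(0),
                         mutation_probs = c(1, 0, 0), rayt = FALSE,
                         consensi = load_rep_consensi()["Smal4"])
  cnt <- summarize_counts(sim$genome, load_rep_consensi()[["Smal4"]])
  expect_identical(cnt$n_exact, 5L)
  expect_identical(cnt$n_le2, 5L)
  # no CDS in a rayt-off genome is RAYT-like
  ann <- sim$annotation
  for (i in seq_len(nrow(ann))) {
    nt <- substr(sim$genome, ann$start[i] + 1L, ann$end[i])
    expect_false(is_rayt_like(repbime:::translate_cds(nt)))
  }
  expect_null(sim$truth$rayt_locus)

  # the planted rayt CDS, by contrast, is motif-complete
  sim2 <- simulate_genome(seed = 56, length = 20000, n_solitary = 2,
                          n_doublets = 0, n_modular = integer(0))
  expect_true(is_rayt_like(sim2$truth$rayt_locus$protein))

  expect_error(simulate_genome(seed = 57, length = 3000, n_solitary = 40),
               "packing")
})

test_that("truth ledger round-trips through JSON", {
  sim <- simulate_genome(seed = 77, length = 20000, n_solitary = 6,
                         n_doublets = 1, n_modular = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  back <- read_truth_json(path)
  expect_identical(back$seed, sim$truth$seed)
  expect_identical(back$genome_length, sim$truth$genome_length)
  expect_equal(as.data.frame(back$planted_reps),
               sim$truth$planted_reps)
  expect_identical(back$rayt_locus$cds_start, sim$truth$rayt_locus$cds_start)
  expect_identical(unlist(back$segment_map), unlist(sim$truth$segment_map))
})

test_that("ortholog pair simulation accelerates only the rayt gene", {
  base <- simulate_genome(seed = 42, length = 20000, n_solitary = 4,
                          n_doublets = 1, n_modular = 2)
  op <- simulate_ortholog_pair(base, rayt_rate_multiplier = 2,
                               background_rate = 0.05, seed = 8)
  expect_length(op$genomes, 2L)
  expect_false(op$genomes[1] == op$genomes[2])
  # recorded substitution counts match the protein differences vs ancestor
  anc <- base$truth$rayt_locus$protein
  for (lg in 1:2) {
    got <- sum(strsplit(op$proteins[[lg]]$rayt, "")[[1]] !=
                 strsplit(anc, "")[[1]])
    want <- op$truth$n_aa_subs[op$truth$gene == "rayt" &
                                 op$truth$lineage == lg]
    expect_identical(got, as.integer(want))
  }
  # flank REPs remain acceptable REPs after palindrome-preserving mutation
  fl <- base$truth$planted_reps
  fl <- fl[fl$role %in% c("flank_up", "flank_down"), ]
  for (gi in 1:2) {
    for (fi in seq_len(nrow(fl))) {
      plus <- substr(op$genomes[gi], fl$start[fi] + 1L, fl$end[fi])
      oriented <- if (fl$strand[fi] == "+") plus else revcomp(plus)
      expect_true(classify_rep(oriented)$accepted)
    }
  }
  expect_error(simulate_ortholog_pair(base, rayt_rate_multiplier = 0.5,
                                      seed = 1), "multiplier")
})

test_that("a null rate multiplier leaves rayt and neighbors statistically equal", {
  base <- simulate_genome(seed = 43, length = 20000, n_solitary = 2,
                          n_doublets = 0, n_modular = integer(0))
  rayt_id <- nb_id <- numeric(30)
  for (r in 1:30) {
    op <- simulate_ortholog_pair(base, rayt_rate_multiplier = 1,
                                 background_rate = 0.05, seed = 6000 + r)
    rayt_id[r] <- global_identity(op$proteins[[1]]$rayt,
                                  op$proteins[[2]]$rayt)$percent_identity
    nb_id[r] <- global_identity(op$proteins[[1]]$cds1,
                                op$proteins[[2]]$cds1)$percent_identity
  }
  # both evolve at the same rate; mean identities within sampling error
  expect_lt(abs(mean(rayt_id) - mean(nb_id)), 3)
})

test_that("coevolution generator respects rates and the guide tree", {
  fam0 <- simulate_coevolved_families(seed = 1, protein_rate = 0,
                                      rep_rate = 0)
  expect_true(all(fam0$proteins == fam0$proteins[[1]]))
  expect_true(all(fam0$reps == fam0$reps[[1]]))
  fam <- simulate_coevolved_families(seed = 2)
  expect_identical(sort(names(fam$proteins)), sort(fam$tree$tip.label))
  expect_length(fam$reps, length(fam$tree$tip.label))
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(simulate_coevolved_families(seed = 3, guide_tree = star),
               "resolved")
})

test_that("simulation outputs write to standard formats", {
  sim <- simulate_genome(seed = 88, length = 20000, n_solitary = 3,
                         n_doublets = 1, n_modular = 2)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  fa <- read_fasta(paths["fasta"])
  expect_identical(unname(fa[1]), sim$genome)
  gff <- read_gff3(paths["gff3"])
  expect_identical(nrow(gff), nrow(sim$annotation))
  expect_identical(gff$start, sim$annotation$start)
})
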