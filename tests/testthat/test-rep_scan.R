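test_that("scanner recovers planted copies with their mismatch counts", {
  cs <- smal4_consensus()
  withr::with_seed(31, {
    bg <- clean_background(50000, list(cs))
    copies <- c(
      rep(SMAL4, 5),
      vapply(1:2, function(i)
        as.character(mutate_consensus(SMAL4, 1)), character(1)),
      as.character(mutate_consensus(SMAL4, 2))
    )
    offsets <- seq(1000, by = 500, length.out = 8)
  })
  genome <- plant_at(bg, copies, offsets)
  occ <- scan_genome(genome, cs, max_mm = 2)
  expect_identical(nrow(occ), 8L)
  expect_identical(sort(occ$mismatches),
                   c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 2L))
  expect_identical(occ$start, as.integer(offsets))
  cnt <- summarize_counts(genome, cs)
  expect_identical(c(cnt$n_exact, cnt$n_le1, cnt$n_le2), c(5L, 7L, 8L))
  # clean background alone yields nothing
  expect_identical(nrow(scan_genome(bg, cs, max_mm = 2)), 0L)
  empty <- summarize_counts(bg, cs)
  expect_identical(c(empty$n_exact, empty$n_le1, empty$n_le2), c(0L, 0L, 0L))
  expect_error(scan_genome(genome, rep_consensus("x", character(0))))
})

test_that("a minus-strand copy is reported on the minus strand at the same locus", {
  cs <- smal4_consensus()
  withr::with_seed(32, bg <- clean_background(4000, list(cs)))
  genome <- plant_at(bg, revcomp(SMAL4), 2000L)
  occ <- scan_genome(genome, cs, max_mm = 0)
  expect_identical(nrow(occ), 1L)
  expect_identical(occ$strand, "-")
  expect_identical(occ$start, 2000L)
  expect_identical(occ$end, 2000L + nchar(SMAL4))
})

test_that("a perfectly palindromic query yields one deduplicated occurrence", {
  half <- "GACGTCGGATCG"
  pal <- paste0(half, revcomp(half))   # equals its own reverse complement
  withr::with_seed(33, bg <- random_dna(3000, 0.5))
  genome <- plant_at(bg, pal, 1500L)
  occ <- scan_genome(genome, pal, max_mm = 0)
  occ <- occ[occ$start == 1500L, , drop = FALSE]
  expect_identical(nrow(occ), 1L)
  expect_identical(occ$strand, "+")
})

test_that("scanner matches the naive oracle and is monotone in the mismatch cap", {
  cs <- smal4_consensus()
  withr::with_seed(34, {
    for (rep_i in 1:10) {
      bg <- random_dna(20000, runif(1, 0.4, 0.7))
      offs <- sort(sample(seq(100, 19000, by = 60), 4))
      ins <- vapply(seq_along(offs), function(i) {
        s <- as.character(mutate_consensus(SMAL4, sample(0:2, 1)))
        if (runif(1) < 0.5) s else revcomp(s)
      }, character(1))
      genome <- plant_at(bg, ins, offs)
      prev <- NULL
      for (k in 0:2) {
        occ <- scan_genome(genome, cs, max_mm = k)
        want <- naive_scan(genome, SMAL4, max_mm = k)
        expect_setequal(paste(occ$start, occ$strand),
                        paste(want$start, want$strand))
        if (!is.null(prev)) {
          expect_true(all(paste(prev$start, prev$strand) %in%
                            paste(occ$start, occ$strand)))
        }
        prev <- occ
      }
    }
  })
})

test_that("single-scan count summary equals three independent scans", {
  sim <- simulate_genome(seed = 210, length = 30000, n_solitary = 8,
                         n_doublets = 1, n_modular = 2, rayt = FALSE)
  cs <- default_sim_consensi()[[1]]
  cnt <- summarize_counts(sim$genome, cs)
  expect_identical(cnt$n_exact, nrow(scan_genome(sim$genome, cs, 0)))
  expect_identical(cnt$n_le1, nrow(scan_genome(sim$genome, cs, 1)))
  expect_identical(cnt$n_le2, nrow(scan_genome(sim$genome, cs, 2)))
})

test_that("presence/abundance matrix contrasts rayt-bearing and rayt-free genomes", {
  cons <- load_rep_consensi()["Smal4"]
  bearing <- simulate_genome(seed = 61, length = 80000, n_solitary = 98,
                             n_doublets = 0, n_modular = integer(0),
                             consensi = cons,
                             mutation_probs = c(1, 0, 0), rayt = TRUE,
                             n_neighbor_cds = 0)
  lacking <- simulate_genome(seed = 62, length = 20000, n_solitary = 5,
                             n_doublets = 0, n_modular = integer(0),
                             consensi = cons,
                             mutation_probs = c(1, 0, 0), rayt = FALSE,
                             n_neighbor_cds = 0)
  pm <- presence_abundance_matrix(
    list(bearing = bearing$genome, lacking = lacking$genome), cons,
    rayt_status = c(bearing = TRUE, lacking = FALSE))
  # 98 solitary + 2 flanking copies
  expect_identical(unname(pm$n_exact["bearing", "Smal4"]), 100L)
  expect_identical(unname(pm$n_exact["lacking", "Smal4"]), 5L)
  expect_equal(unname(pm$fold_ratio["Smal4"]), 20)
  expect_true(pm$presence["bearing", "Smal4"])

  # single genome x single family reduces to summarize_counts
  one <- presence_abundance_matrix(list(g = lacking$genome), cons)
  cnt <- summarize_counts(lacking$genome, cons[[1]])
  expect_identical(unname(one$n_exact["g", "Smal4"]), cnt$n_exact)

  # family absent everywhere gives an all-zero column
  absent <- load_rep_consensi()["Cbur"]
  pm0 <- presence_abundance_matrix(list(g = lacking$genome), absent)
  expect_identical(unname(pm0$n_exact["g", "Cbur"]), 0L)
})

test_that("extragenic fraction counts partial CDS overlaps as genic", {
  occ <- occ_df(c(10, 100, 200, 300), c(30, 120, 220, 320),
                c("+", "+", "-", "+"))
  cds <- data.frame(start = 210L, end = 400L)
  expect_equal(extragenic_fraction(occ, cds), 0.5)  # 200-220 and 300-320 hit
  cds2 <- data.frame(start = 215L, end = 218L)      # inside one occurrence
  expect_equal(extragenic_fraction(occ, cds2), 0.75)
  expect_true(is.na(extragenic_fraction(occ[0, ], cds)))
  expect_equal(extragenic_fraction(occ, cds[0, ]), 1.0)
})

test_that("BED round trip is byte-idempotent", {
  sim <- simulate_genome(seed = 77, length = 20000, n_solitary = 6,
                         n_doublets = 1, n_modular = 2, rayt = FALSE)
  occ <- scan_genome(sim$genome, default_sim_consensi()[[1]], 2,
                     genome_label = "sim_genome")
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(occ, p1)
  back <- read_bed(p1)
  write_bed(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(back$start, occ$start)
  expect_identical(back$strand, occ$strand)
})
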