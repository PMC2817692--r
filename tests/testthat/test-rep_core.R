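test_that("revcomp handles the basic contract and is an involution", {
  expect_identical(revcomp("GTAG"), "CTAC")
  expect_identical(revcomp(""), "")
  expect_identical(revcomp("ANCT"), "AGNT")
  expect_error(revcomp("ACGU"), "non-DNA")
  withr::with_seed(11, {
    for (i in 1:50) {
      x <- random_dna(sample(1:40, 1), runif(1, 0.2, 0.8))
      expect_identical(revcomp(revcomp(x)), x)
    }
  })
})

test_that("strict parser reproduces the published consensus decompositions", {
  s <- parse_rep_strict("TGTAGAGCCGAGCCCATGCTCGGCT")
  expect_identical(
    unclass(s)[c("leading", "head", "spacer", "left_arm", "loop",
                 "right_arm", "tail")],
    list(leading = "T", head = "GTAG", spacer = "", left_arm = "AGCCGAGC",
         loop = "CCAT", right_arm = "GCTCGGCT", tail = ""))

  s <- parse_rep_strict("GTAGGTTGGGCTGAGCTTGCGAAGCCCAAC")
  expect_identical(s$head, "GTAG")
  expect_identical(s$left_arm, "GTTGGGCT")
  expect_identical(s$loop, "GAGCTTGCGA")
  expect_identical(s$right_arm, "AGCCCAAC")

  # GA spacer between head and palindrome (Pseudomonas-type element)
  s <- parse_rep_strict("TGTGGGAGCGGGCGTGCCCGCGAAT")
  expect_identical(
    unclass(s)[c("leading", "head", "spacer", "left_arm", "loop",
                 "right_arm", "tail")],
    list(leading = "T", head = "GTGG", spacer = "GA", left_arm = "GCGGGC",
         loop = "GT", right_arm = "GCCCGC", tail = "GAAT"))

  expect_error(parse_rep_strict(strrep("A", 61)), "longer")
  expect_error(parse_rep_strict("GTAGXX"), "non-DNA")
})

test_that("strict parser agrees with exhaustive decomposition enumeration", {
  cons <- load_rep_consensi()
  pool <- unlist(lapply(cons, `[[`, "variants"), use.names = FALSE)
  withr::with_seed(202, {
    cases <- c(
      pool,
      vapply(1:60, function(i) {
        as.character(mutate_consensus(sample(pool, 1), sample(0:2, 1)))
      }, character(1)),
      vapply(1:60, function(i) random_dna(sample(12:40, 1), 0.55),
             character(1))
    )
  })
  cases <- cases[nchar(cases) <= 40]
  for (sq in cases) {
    got <- parse_rep_strict(sq)
    want <- oracle_parse_strict(sq)
    if (is.null(want)) {
      expect_null(got, label = sq)
    } else {
      expect_identical(
        unclass(got)[c("leading", "head", "spacer", "left_arm", "loop",
                       "right_arm", "tail")],
        want[c("leading", "head", "spacer", "left_arm", "loop",
               "right_arm", "tail")],
        label = sq)
    }
  }
})

test_that("accepted parses reconstruct their input exactly", {
  withr::with_seed(7, {
    for (i in 1:1000) {
      a <- sample(5:12, 1)
      arm <- random_dna(a, runif(1, 0.4, 0.9))
      sq <- paste0(
        c("", "T", "G", "A")[sample(4, 1)],
        sample(c("GTAG", "GTGG"), 1),
        c("", "GA")[sample(2, 1)],
        arm, random_dna(sample(0:8, 1), 0.5), revcomp(arm),
        random_dna(sample(0:4, 1), 0.5)
      )
      st <- classify_rep(sq)
      expect_true(st$accepted, label = sq)
      expect_identical(as.character(st$structure), sq, label = sq)
    }
  })
})

test_that("the six Stenotrophomonas consensi have 2-4 nt loops and parse strictly", {
  cons <- load_rep_consensi()
  sten <- c("Smal1", "Smal2", "Smal3", "Smal4", "S_sp1", "S_sp2")
  loops <- vapply(sten, function(f)
    nchar(cons[[f]]$structures[[1]]$loop), integer(1))
  expect_identical(min(loops), 2L)
  expect_identical(max(loops), 4L)
  modes <- vapply(sten, function(f)
    classify_rep(cons[[f]]$variants[1])$mode, character(1))
  expect_true(all(modes == "strict"))
})

test_that("relaxed parser subsumes strict parses with zero interruptions", {
  cons <- load_rep_consensi()
  for (f in c("Smal1", "Cbur", "Pput1", "Hinf")) {
    v <- cons[[f]]$variants[1]
    st <- parse_rep_strict(v)
    rx <- parse_rep_relaxed(v)
    expect_identical(rx$interruptions, 0L)
    expect_identical(
      unclass(rx)[c("leading", "head", "spacer", "left_arm", "loop",
                    "right_arm", "tail")],
      unclass(st)[c("leading", "head", "spacer", "left_arm", "loop",
                    "right_arm", "tail")])
  }
})

test_that("relaxed parser counts a constructed bulge as one interruption", {
  arm <- "CCCGGG"
  base <- paste0("GTAG", arm, "TTCCCAAA", revcomp(arm))
  expect_identical(parse_rep_relaxed(base)$interruptions, 0L)
  # insert one base into the middle of the right arm
  bulged <- paste0("GTAG", arm, "TTCCCAAA", "CCCT", "GGG")
  rx <- parse_rep_relaxed(bulged)
  expect_false(is.null(rx))
  expect_identical(rx$interruptions, 1L)
})

test_that("the enterobacterial consensus parses relaxed with an interrupted stem", {
  # the E. coli-type palindrome is imperfect; under the minimal-event
  # criterion the best decomposition carries one bulge interruption
  rx <- parse_rep_relaxed("GTAGGACGGATAAGGCGTTCACGCCGCATCCGGCA")
  expect_false(is.null(rx))
  expect_identical(rx$interruptions, 1L)
  cl <- classify_rep("GTAGGACGGATAAGGCGTTCACGCCGCATCCGGCA")
  expect_true(cl$accepted)
  expect_identical(cl$mode, "relaxed")
  expect_lte(cl$structure$interruptions, 2L)
})

test_that("classification enforces the head motif and strand convention", {
  expect_false(classify_rep("ACGTACGTACGTACGTACGT")$accepted)
  v <- "TGTAGAGCCGAGCCCATGCTCGGCT"
  expect_true(classify_rep(v)$accepted)
  # the head is strand-defining: the reverse complement is rejected as
  # given, but the element is recovered by scanning the minus strand
  expect_false(classify_rep(revcomp(v))$accepted)
  genome <- plant_at(clean_window(), revcomp(v), 300L)
  occ <- scan_genome(genome, rep_consensus("Smal1", v), max_mm = 0)
  expect_identical(nrow(occ), 1L)
  expect_identical(occ$strand, "-")
  expect_identical(occ$start, 300L)
})

test_that("consensus construction validates variants and dimorphism", {
  expect_error(rep_consensus("x", c(SMAL4, SMAL4)), "differ")
  expect_error(rep_consensus("x", "ACGTACGTACGT"), "not an acceptable")
  cs <- rep_consensus("x", c(SMAL4, as.character(
    mutate_consensus(SMAL4, 1, seed = 3, palindrome_preserving = TRUE))))
  expect_length(cs$variants, 2L)
  # every packaged family variant parses
  cons <- load_rep_consensi()
  expect_length(cons, 27L)
})
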