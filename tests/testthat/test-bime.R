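test_that("gap-threshold chaining forms the expected clusters", {
  withr::with_seed(21, genome <- random_dna(3000, 0.5))
  w <- 24L
  starts <- cumsum(c(100L, w + 40L, w + 40L, w + 400L, w + 40L))
  occ <- occ_df(starts, starts + w, c("+", "-", "+", "-", "+"))
  cl <- cluster_occurrences(occ, genome, max_gap = 250)
  expect_length(cl, 2L)
  expect_identical(vapply(cl, function(x) nrow(x$occurrences), integer(1)),
                   c(3L, 2L))
  expect_identical(nchar(cl[[1]]$gaps), c(40L, 40L))
  expect_identical(cl[[1]]$gaps[1],
                   substr(genome, starts[1] + w + 1L, starts[2]))

  single <- cluster_occurrences(occ[1, ], genome)
  expect_length(single, 1L)
  expect_identical(single[[1]]$cluster_class, "solitary")
  expect_length(cluster_occurrences(occ[0, ], genome), 0L)
  expect_error(cluster_occurrences(occ[c(3, 1), ], genome), "sorted")
})

test_that("cluster classes follow the orientation grammar", {
  withr::with_seed(22, genome <- random_dna(3000, 0.5))
  mk <- function(strands, gap = 45L) {
    w <- 24L
    starts <- cumsum(c(100L, rep(w + gap, length(strands) - 1L)))
    cluster_occurrences(occ_df(starts, starts + w, strands), genome)[[1]]
  }
  expect_identical(mk(c("+", "-"))$cluster_class, "doublet")
  expect_identical(mk(c("-", "+"))$cluster_class, "doublet")
  expect_identical(mk(c("+", "+"))$cluster_class, "atypical")
  expect_identical(mk(c("+", "-", "+", "-", "+", "-"))$cluster_class,
                   "modular")
  expect_identical(mk(c("+", "+", "-"))$cluster_class, "atypical")
})

test_that("modular decomposition brackets modules left to right", {
  withr::with_seed(23, genome <- random_dna(4000, 0.5))
  mk <- function(n) {
    strands <- rep(c("+", "-"), length.out = n)
    w <- 24L
    starts <- cumsum(c(100L, rep(w + 50L, n - 1L)))
    cluster_occurrences(occ_df(starts, starts + w, strands), genome)[[1]]
  }
  m6 <- decompose_modules(mk(6))
  expect_length(m6, 3L)
  expect_false(any(vapply(m6, `[[`, logical(1), "terminal_half")))
  # trailing segment of module 1 is the gap to occurrence 3
  expect_identical(m6[[1]]$trailing_segment, mk(6)$gaps[2])
  expect_true(is.na(m6[[3]]$trailing_segment))

  expect_length(decompose_modules(mk(4)), 2L)

  m5 <- decompose_modules(mk(5))
  expect_length(m5, 2L)
  expect_true(m5[[2]]$terminal_half)
  expect_false(is.null(m5[[2]]$extra_rep))

  expect_error(decompose_modules(
    cluster_occurrences(occ_df(100, 124, "+"), genome)[[1]]), "not modular")
})

test_that("segment labeling partitions gaps by identity, orientation-sensitively", {
  withr::with_seed(24, {
    genome <- random_dna(2000, 0.5)
    S <- random_dna(50, 0.5)
    T_ <- random_dna(50, 0.5)
  })
  w <- 24L
  mkcl <- function(gaps) {
    starts <- integer(length(gaps) + 1L)
    starts[1] <- 100L
    for (i in seq_along(gaps)) {
      starts[i + 1L] <- starts[i] + w + nchar(gaps[i])
    }
    g2 <- genome
    for (i in seq_along(gaps)) {
      substr(g2, starts[i] + w + 1L, starts[i + 1L]) <- gaps[i]
    }
    cluster_occurrences(
      occ_df(starts, starts + w, rep(c("+", "-"), length.out =
                                       length(starts))), g2)[[1]]
  }
  labs <- label_segments(list(mkcl(c(S, S, T_))))
  expect_identical(labs[[1]], c("a", "a", "b"))
  expect_identical(label_segments(list(mkcl(c(S, S, S))))[[1]],
                   c("a", "a", "a"))
  expect_identical(label_segments(list(mkcl(c(S, revcomp(S)))))[[1]],
                   c("a", "b"))
  # near-identical segments share a label at the default 0.9 threshold
  S_mut <- as.character(mutate_consensus(S, 2))
  expect_identical(label_segments(list(mkcl(c(S, S_mut))))[[1]],
                   c("a", "a"))
  # the partition is invariant to cluster order, up to letter renaming
  cl1 <- mkcl(c(S, T_)); cl2 <- mkcl(c(T_, T_))
  l_a <- label_segments(list(cl1, cl2))
  l_b <- label_segments(list(cl2, cl1))
  part <- function(l) {
    flat <- unlist(l)
    split(seq_along(flat), match(flat, unique(flat)))
  }
  expect_identical(unname(part(list(l_a[[1]], l_a[[2]]))),
                   unname(part(list(l_b[[2]], l_b[[1]]))))
})

test_that("rayt association distinguishes adjacency from 3' terminus capture", {
  withr::with_seed(25, genome <- random_dna(6000, 0.5))
  w <- 24L
  starts <- cumsum(c(3000L, w + 50L, w + 50L, w + 50L))
  cl <- cluster_occurrences(
    occ_df(starts, starts + w, c("+", "-", "+", "-")), genome)[[1]]
  span <- c(min(cl$occurrences$start), max(cl$occurrences$end))

  # CDS upstream of the cluster; its downstream flank is the first member
  flanks <- list(upstream = NULL,
                 downstream = data.frame(start = starts[1],
                                         end = starts[1] + w))
  expect_identical(
    assess_rayt_association(cl, 2000L, 2900L, "+", flanks = flanks),
    "adjacent")
  # CDS whose 3' boundary lies inside the cluster span
  expect_identical(
    assess_rayt_association(cl, 2000L, span[1] + 60L, "+", flanks = flanks),
    "terminus_captured")
  # minus-strand CDS: the 3' end is the left boundary
  expect_identical(
    assess_rayt_association(cl, span[1] + 60L, 5000L, "-", flanks = flanks),
    "terminus_captured")
  # distant cluster, no flank membership
  far <- list(upstream = NULL,
              downstream = data.frame(start = 500L, end = 524L))
  expect_identical(
    assess_rayt_association(cl, 100L, 400L, "+", flanks = far), "none")
})

test_that("module counts and hybrid flags are recovered from simulated BIMEs", {
  for (r in 1:5) {
    sim <- simulate_genome(seed = 900 + r, length = 40000, n_solitary = 3,
                           n_doublets = 2, n_modular = c(2, 3, 4, 5),
                           n_hybrid = 1, rayt = FALSE)
    cons <- default_sim_consensi()
    occ <- do.call(rbind, lapply(cons, function(cs)
      scan_genome(sim$genome, cs, 2, genome_label = "sim_genome")))
    occ <- occ[order(occ$start), ]
    rownames(occ) <- NULL
    cl <- cluster_occurrences(occ, sim$genome)
    classes <- vapply(cl, `[[`, "", "cluster_class")
    expect_identical(sum(classes == "doublet"), 2L)   # zero false negatives
    mods <- sort(vapply(cl[classes == "modular"], function(x)
      length(decompose_modules(x)), integer(1)))
    expect_identical(mods, c(2L, 2L, 3L, 4L, 5L))     # incl. hybrid (2 mod)
    expect_identical(sum(vapply(cl, `[[`, logical(1), "hybrid")), 1L)
  }
})

test_that("cluster rendering shows bracketed modules with segment letters", {
  withr::with_seed(26, genome <- random_dna(2000, 0.5))
  w <- 24L
  starts <- cumsum(c(100L, w + 40L, w + 40L, w + 40L))
  cl <- cluster_occurrences(
    occ_df(starts, starts + w, c("+", "-", "+", "-"), family = "Smal4"),
    genome)[[1]]
  txt <- render_cluster(cl)
  expect_match(txt, "^\\[Smal4> a <Smal4 \\| b\\] \\[Smal4> c <Smal4\\]$")
  j <- cluster_report_json(list(cl))
  expect_match(as.character(j), "modular")
})
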