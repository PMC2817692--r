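# Independent oracles: deliberately naive re-implementations used only to
# check the package's optimized paths.

# Exhaustive strict-parse oracle: enumerate every decomposition
# leading + head + spacer + left + loop + right + tail and rank candidates
# by the documented order (max arm, min loop, min spacer, min leading,
# min tail).  Written without sharing code with parse_rep_strict.
oracle_parse_strict <- function(seq, min_arm = 5, max_loop = 12,
                                max_spacer = 2, max_leading = 1,
                                max_tail = 6) {
  seq <- toupper(seq)
  n <- nchar(seq)
  rc <- function(x) {
    if (nchar(x) == 0) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }
  cands <- list()
  for (l in 0:max_leading) for (s in 0:max_spacer) {
    for (a in min_arm:n) for (loop in 0:max_loop) for (t in 0:max_tail) {
      if (l + 4 + s + 2 * a + loop + t != n) next
      head <- substr(seq, l + 1, l + 4)
      if (!(head %in% c("GTAG", "GTGG"))) next
      off <- l + 4 + s
      left <- substr(seq, off + 1, off + a)
      right <- substr(seq, off + a + loop + 1, off + a + loop + a)
      if (grepl("N", left) || right != rc(left)) next
      cands[[length(cands) + 1]] <- list(
        leading = substr(seq, 1, l), head = head,
        spacer = substr(seq, l + 5, l + 4 + s), left_arm = left,
        loop = substr(seq, off + a + 1, off + a + loop),
        right_arm = right, tail = substr(seq, off + 2 * a + loop + 1, n),
        a = a, loop_len = loop, s = s, l = l, t = t
      )
    }
  }
  if (length(cands) == 0) return(NULL)
  key <- vapply(cands, function(x)
    sprintf("%03d-%03d-%03d-%03d-%03d", 999 - x$a, x$loop_len, x$s, x$l,
            x$t), character(1))
  cands[[order(key)[1]]]
}

# Naive mismatch scan of one pattern over both strands (no dedup).
naive_scan <- function(genome, pattern, max_mm = 0) {
  g <- strsplit(genome, "")[[1]]
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x),
                                       "")[[1]]), collapse = "")
  one_strand <- function(p) {
    pv <- strsplit(p, "")[[1]]
    m <- length(pv)
    n <- length(g)
    if (n < m) return(integer(0))
    mm <- integer(n - m + 1)
    for (j in seq_len(m)) {
      mm <- mm + (g[j:(n - m + j)] != pv[j])
    }
    which(mm <= max_mm)
  }
  plus <- one_strand(pattern)
  minus <- one_strand(rc(pattern))
  data.frame(
    start = c(plus, minus) - 1L,
    strand = rep(c("+", "-"), c(length(plus), length(minus)))
  )
}

# Least-squares topology fit for 4 taxa: returns the taxon paired with
# taxon 1 in the best of the three unrooted topologies.
oracle_4taxon_topology <- function(d) {
  taxa <- rownames(d)
  fits <- sapply(taxa[2:4], function(p) {
    rest <- setdiff(taxa[2:4], p)
    # topology (1,p | rest): design matrix of path sums over 5 branches
    pairs <- t(combn(taxa, 2))
    branch_names <- c(taxa[1], p, rest, "internal")
    X <- matrix(0, nrow(pairs), 5, dimnames = list(NULL, branch_names))
    same <- function(x, y) {
      (x %in% c(taxa[1], p) && y %in% c(taxa[1], p)) ||
        (x %in% rest && y %in% rest)
    }
    y <- numeric(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      X[r, a] <- 1; X[r, b] <- 1
      if (!same(a, b)) X[r, "internal"] <- 1
      y[r] <- d[a, b]
    }
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  })
  names(which.min(fits))
}

# 700-bp window guaranteed free of strict REP candidates (for tests that
# assert the absence of a flank).
clean_window <- function(gc = 0.6, width = 700) {
  repeat {
    w <- random_dna(width, gc)
    if (nrow(repbime:::enumerate_rep_candidates(w, 0L, width)) == 0L) {
      return(w)
    }
  }
}
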