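test_that("sequence sets validate and FASTA abundance headers round-trip", {
  expect_error(sequence_set("a", "ACXT"), "invalid")
  expect_error(sequence_set(c("a", "a"), c("AC", "GT")), "duplicate")
  recs <- sequence_set(c("r1", "r2"), c("ACGT", "AC-T"), c(10L, 3L))
  path <- tempfile(fileext = ".fa")
  write_fasta_abund(recs, path)
  back <- read_fasta_abund(path)
  expect_equal(back$seq, recs$seq)
  expect_equal(back$abundance, recs$abundance)
  # size-free headers default to abundance 1
  writeLines(c(">plain", "ACGT"), path)
  expect_equal(read_fasta_abund(path)$abundance, 1L)
})

test_that("dereplication merges duplicates and prefixes, conserving reads", {
  recs <- sequence_set(paste0("r", 1:3), rep("ACGT", 3))
  d <- dereplicate(recs, "full")
  expect_equal(nrow(d), 1)
  expect_equal(d$abundance, 3L)
  recs2 <- sequence_set(c("short", "long"), c("ACGT", "ACGTTT"))
  dp <- dereplicate(recs2, "prefix")
  expect_equal(dp$seq, "ACGTTT")
  expect_equal(dp$abundance, 2L)
  # full mode keeps the distinct prefix separate
  expect_equal(nrow(dereplicate(recs2, "full")), 2)
})

test_that("prefix dereplication matches a quadratic oracle on random sets", {
  set.seed(17)
  for (rep in 1:3) {
    lens <- sample(4:8, 50, replace = TRUE)
    seqs <- vapply(lens, function(l)
      paste(sample(c("A", "C"), l, replace = TRUE), collapse = ""),
      character(1))
    recs <- sequence_set(paste0("r", 1:50), seqs)
    d <- dereplicate(recs, "prefix")
    # oracle: a sequence survives iff no OTHER distinct sequence has it as a
    # proper prefix; every read is absorbed somewhere
    uniq <- unique(seqs)
    survives <- vapply(uniq, function(s)
      !any(uniq != s & startsWith(uniq, s)), logical(1))
    expect_setequal(d$seq, uniq[survives])
    expect_equal(sum(d$abundance), 50)
  }
})

test_that("eachgap distance follows terminal-gap and gap-column rules", {
  expect_equal(pairwise_distance("ACGT", "ACGT"), 0)
  expect_equal(pairwise_distance("--ACGT", "TTACGT"), 0)   # terminal gaps out
  expect_equal(pairwise_distance("ACG-T", "ACGAT"), 0.2)   # internal gap = 1
  expect_equal(pairwise_distance("AC--GT", "AC--GT"), 0)   # gap-gap excluded
  expect_equal(pairwise_distance("A-CT", "AGCT"), 0.25)
  expect_error(pairwise_distance("AC", "ACG"), "equal length")
  # symmetry and identity-of-indiscernibles over the comparable span
  set.seed(2)
  for (i in 1:20) {
    s1 <- paste(sample(c("A", "C", "G", "T", "-"), 12, TRUE), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T", "-"), 12, TRUE), collapse = "")
    if (grepl("^[-]*$", s1) || grepl("^[-]*$", s2)) next
    d12 <- tryCatch(pairwise_distance(s1, s2), error = function(e) NA)
    if (is.na(d12)) next
    expect_equal(d12, pairwise_distance(s2, s1))
    expect_equal(d12, oracle_eachgap(s1, s2))
  }
})

test_that("preclustering is greedy by abundance, not true single linkage", {
  recs <- sequence_set(c("a", "b"), c("ACGTACGT", "ACGTACGT"), c(5L, 2L))
  p <- precluster(recs, max_diffs = 2)
  expect_equal(nrow(p), 1)
  expect_equal(p$abundance, 7L)
  # 1-diff pair merges under max_diffs 2
  recs2 <- sequence_set(c("big", "small"), c("AAAAAAAA", "AAAAAAAT"),
                        c(100L, 1L))
  p2 <- precluster(recs2, max_diffs = 2)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$abundance, 101L)
  # chain A-B-C, 1 diff apart, max_diffs 1: B merges into A, C is retained
  # (2 diffs from A; greedy never compares C to the absorbed B)
  chain <- sequence_set(c("A", "B", "C"),
                        c("AAAAAA", "AAAAAT", "AAAATT"), c(9L, 5L, 2L))
  p3 <- precluster(chain, max_diffs = 1)
  expect_equal(sort(p3$id), c("A", "C"))
  expect_equal(p3$abundance[p3$id == "A"], 14L)
  expect_equal(sum(p3$abundance), 16L)
})

test_that("OTU clustering matches brute-force average linkage on random sets", {
  set.seed(23)
  for (rep in 1:25) {
    seqs <- random_seqs(10, 30, seed = 1000 + rep)
    recs <- sequence_set(paste0("q", 1:10), seqs,
                         sample(1:20, 10, replace = TRUE))
    thr <- sample(c(0.03, 0.1, 0.25, 0.4), 1)
    otus <- cluster_otus(recs, threshold = thr)
    oracle <- oracle_average_linkage(distance_matrix(recs), thr)
    expect_true(same_partition(otus$membership[recs$id], oracle))
    # representatives are the most abundant members
    for (k in seq_along(otus$clusters)) {
      ids <- otus$clusters[[k]]
      ab <- recs$abundance[match(ids, recs$id)]
      expect_equal(max(ab),
                   recs$abundance[recs$id == otus$representatives[k]])
    }
  }
})

test_that("OTU count is monotone in threshold with correct limits", {
  recs <- sequence_set(paste0("q", 1:8), random_seqs(8, 40, seed = 5))
  n_otus <- vapply(c(0, 0.05, 0.2, 0.5, 1),
                   function(t) length(cluster_otus(recs, t)$clusters),
                   numeric(1))
  expect_true(all(diff(n_otus) <= 0))
  expect_equal(n_otus[length(n_otus)], 1)      # threshold 1: one OTU
  same <- sequence_set(c("x", "y"), rep("ACGTACGT", 2))
  expect_equal(length(cluster_otus(same, 0)$clusters), 1)
  far <- sequence_set(c("x", "y"), c("AAAAAAAAAA", "ATATAAAAAA"))
  expect_equal(length(cluster_otus(far, 0.03)$clusters), 2)
})

test_that("cross-site shared OTUs recover the planted design", {
  set.seed(41)
  shared <- random_seqs(5, 50, seed = 61)
  privA <- random_seqs(5, 50, seed = 62)
  privB <- random_seqs(5, 50, seed = 63)
  siteA <- sequence_set(paste0("a", 1:10), c(shared, privA),
                        sample(5:50, 10))
  siteB <- sequence_set(paste0("b", 1:10), c(shared, privB),
                        sample(5:50, 10))
  res <- shared_otus(list(A = siteA, B = siteB))
  expect_length(res$shared, 5)
  # identical representative sets: every cluster spans both sites
  res2 <- shared_otus(list(A = siteA, B = siteA))
  expect_equal(unname(rowSums(res2$presence)), rep(2, nrow(res2$presence)))
  # all-distant representatives share nothing
  res3 <- shared_otus(list(A = sequence_set("a", "AAAAAAAAAA"),
                           B = sequence_set("b", "TTTTTTTTTT")))
  expect_length(res3$shared, 0)
})

test_that("k-mismatch mapping equals a sliding-window oracle", {
  set.seed(29)
  refs <- sequence_set(paste0("ref", 1:5), random_seqs(5, 60, seed = 71))
  # queries: substrings of references with 0-3 planted mutations + randoms
  qseq <- character(0)
  for (i in 1:15) {
    r <- sample(5, 1); start <- sample(1:40, 1)
    q <- substr(refs$seq[r], start, start + 19)
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      pos <- sample(20, nmut)
      ch <- strsplit(q, "")[[1]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      q <- paste(ch, collapse = "")
    }
    qseq <- c(qseq, q)
  }
  qseq <- c(qseq, random_seqs(5, 20, seed = 72))
  queries <- sequence_set(paste0("q", seq_along(qseq)), qseq)

  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  oracle <- function(qs, rs, k) {
    hits <- list()
    for (qi in seq_len(nrow(qs))) for (ri in seq_len(nrow(rs))) {
      for (strand in c("+", "-")) {
        q <- if (strand == "+") qs$seq[qi] else revcomp(qs$seq[qi])
        L <- nchar(q); R <- nchar(rs$seq[ri])
        if (L > R) next
        for (off in 1:(R - L + 1)) {
          mm <- sum(strsplit(q, "")[[1]] !=
                      strsplit(substr(rs$seq[ri], off, off + L - 1), "")[[1]])
          if (mm <= k)
            hits[[length(hits) + 1]] <- data.frame(
              query = qs$id[qi], reference = rs$id[ri], offset = off,
              strand = strand, mismatches = mm)
        }
      }
    }
    if (!length(hits)) return(NULL)
    do.call(rbind, hits)
  }
  for (k in c(0, 2)) {
    got <- kmismatch_map(queries, refs, max_mismatches = k)
    want <- oracle(queries, refs, k)
    key <- function(df) sort(paste(df$query, df$reference, df$offset,
                                   df$strand, df$mismatches))
    expect_equal(key(got), if (is.null(want)) character(0) else key(want))
  }
  # max 2 hits are a superset of max 0 hits
  h0 <- kmismatch_map(queries, refs, 0)
  h2 <- kmismatch_map(queries, refs, 2)
  k0 <- paste(h0$query, h0$reference, h0$offset, h0$strand)
  k2 <- paste(h2$query, h2$reference, h2$offset, h2$strand)
  expect_true(all(k0 %in% k2))
})

test_that("contaminant screen reports genus counts and read fractions", {
  ct <- make_table(rbind(c(95, 3, 2), c(50, 0, 50)),
                   taxa = c("Bacillus", "Rheinheimera", "Pseudomonas"))
  none <- contaminant_screen(ct, character(0))
  expect_equal(none$n_contaminant_genera, c(0L, 0L))
  expect_equal(none$contaminant_abundance, c(0, 0))
  all3 <- contaminant_screen(ct, c("Bacillus", "Rheinheimera", "Pseudomonas"))
  expect_equal(all3$contaminant_abundance, c(1, 1))
  some <- contaminant_screen(ct, c("Rheinheimera", "Pseudomonas"))
  expect_equal(some$n_contaminant_genera, c(2L, 1L))
  expect_equal(some$contaminant_abundance, c(0.05, 0.5))
  # demo contaminant list fixture is usable directly
  demo <- load_fixture("contaminant_genera_demo")
  expect_true("Rheinheimera" %in% demo)
})
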