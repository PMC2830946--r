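test_that("gap-excluded similarity matches hand-built alignments", {
  s <- random_seq(20)
  expect_equal(pair_similarity(s, s), 100)

  # 19 identities over 20 gap-free columns
  a <- "ACGTACGTACGTACGTACGT"
  b <- "ACGTACGTACATACGTACGT"
  expect_equal(pair_similarity(a, b), 95)

  # a single insertion is a gap column: not considered
  expect_equal(pair_similarity("ACGTACGTAC", "ACGTTACGTAC"), 100)
})

test_that("similarity is symmetric and in range on random pairs", {
  set.seed(12)
  for (i in 1:40) {
    a <- random_seq(sample(15:50, 1))
    b <- mutate_seq(a, n_sub = sample(0:5, 1), n_ins = sample(0:2, 1),
                    n_del = sample(0:2, 1))
    sab <- pair_similarity(a, b)
    sba <- pair_similarity(b, a)
    expect_equal(sab, sba)
    expect_true(sab >= 0 && sab <= 100)
  }
})

test_that("alignment scores agree with an independent aligner", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(21)
  for (i in 1:30) {
    a <- random_seq(sample(20:60, 1))
    b <- mutate_seq(a, n_sub = sample(0:6, 1), n_ins = sample(0:3, 1),
                    n_del = sample(0:3, 1))
    ours <- align_global(a, b)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    expect_equal(ours$score, Biostrings::score(ref))
  }
})

test_that("cross-sample copy numbers sum within-cutoff target frequencies", {
  q <- data.frame(id = c("q1", "q2"),
                  sequence = c("ACGTACGTACGTACGTGGGG", "TTTTTTTTTTGGGGGGGGGG"),
                  frequency = c(4L, 2L), stringsAsFactors = FALSE)
  tgt <- data.frame(
    id = c("t1", "t2", "t3"),
    sequence = c("ACGTACGTACGTACGTGGGG",      # identical to q1
                 "ACGTTACGTACGTACGTGGGG",     # q1 + 1-base insertion
                 "ACGTACGTACGTACGTGGCC"),     # 2 substitutions vs q1 (90%)
    frequency = c(7L, 3L, 5L), stringsAsFactors = FALSE)
  out <- match_across_samples(q, list(T1 = tgt), cutoff = 100)
  expect_equal(names(out), c("query_id", "self_copies", "T1"))
  expect_equal(out$self_copies, c(4L, 2L))
  expect_equal(out$T1, c(10L, 0L))   # identical + indel variant; q2 matches none

  # a lower cutoff admits the 90% variant as well
  out90 <- match_across_samples(q, list(T1 = tgt), cutoff = 90)
  expect_equal(out90$T1[1], 15L)

  # best-hit-only counts just the most similar within-cutoff sequence
  best <- match_across_samples(q, list(T1 = tgt), cutoff = 90,
                               best_hit_only = TRUE)
  expect_equal(best$T1[1], 7L)
})

test_that("raising the cutoff never increases a copy number", {
  set.seed(33)
  base <- random_seq(40)
  q <- data.frame(id = "q", sequence = base, frequency = 1L,
                  stringsAsFactors = FALSE)
  tgt <- data.frame(
    id = sprintf("t%d", 1:6),
    sequence = c(base, vapply(1:5, function(i) {
      mutate_seq(base, n_sub = sample(0:4, 1), n_ins = sample(0:1, 1))
    }, "")),
    frequency = sample(1:9, 6, replace = TRUE), stringsAsFactors = FALSE)
  cuts <- c(80, 90, 95, 97, 100)
  vals <- vapply(cuts, function(ct) {
    match_across_samples(q, list(T1 = tgt), cutoff = ct)$T1
  }, 0L)
  expect_true(all(diff(vals) <= 0))
})

test_that("matching a sample against itself at cutoff 100 finds each query", {
  set.seed(44)
  nr <- dereplicate(sample(c("ACGTACGTACGTACGTAGTC", "TTGGCCAATTGGCCAATACG",
                             "GACTGACTGACTGACTGACT"), 30, replace = TRUE))
  nr$id <- sprintf("u%d", seq_len(nrow(nr)))
  out <- match_across_samples(nr, list(self = nr), cutoff = 100)
  expect_true(all(out$self >= out$self_copies))
})

test_that("overlap tables lay out query, self and target columns", {
  q <- data.frame(id = "q1", sequence = "ACGTACGT", frequency = 3L,
                  stringsAsFactors = FALSE)
  t1 <- data.frame(id = "a", sequence = "ACGTACGT", frequency = 2L,
                   stringsAsFactors = FALSE)
  empty <- data.frame(id = character(), sequence = character(),
                      frequency = integer(), stringsAsFactors = FALSE)
  rows <- match_across_samples(q, list(S2 = t1, S3 = empty, S4 = t1,
                                       S5 = empty, S6 = t1), cutoff = 100)
  f <- tempfile()
  write_overlap_table(rows, f)
  tab <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(ncol(tab), 7L)  # query + self + 5 targets
  expect_equal(names(tab)[3:7], c("S2", "S3", "S4", "S5", "S6"))
  expect_equal(unlist(tab[1, 3:7], use.names = FALSE), c(2L, 0L, 2L, 0L, 2L))

  # empty query set -> header-only file
  rows0 <- match_across_samples(empty, list(S2 = t1), cutoff = 100)
  write_overlap_table(rows0, f)
  expect_equal(length(readLines(f)), 1L)
})
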