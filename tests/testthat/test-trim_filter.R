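ADAPTER <- "CTGAGACTGCCAAGGCACAC"  # 20 bp

test_that("adapter B is trimmed where found and reads without it are dropped", {
  target <- "ACGTACGTACGTACGTACGTACGTACGT"
  r <- make_reads(c(paste0(target, ADAPTER),           # exact occurrence
                    paste0(target, "GGGGGGGGGGGGGGGGGGGG"),  # none
                    paste0(target, "CAGAGACTGCCAAGGCACAC"),  # 1 mismatch
                    paste0(target, substr(ADAPTER, 1, 12)))) # truncated at 3'
  out <- trim_adapter(r, ADAPTER, 0.1)
  expect_equal(out$kept$id, c("r001", "r003", "r004"))
  expect_true(all(out$kept$sequence == target))
  expect_equal(unique(vapply(out$kept$qualities, length, 1L)), nchar(target))
  expect_equal(out$discarded$id, "r002")
  expect_equal(length(out$kept) + length(out$discarded), length(r))
})

test_that("adapter scanning agrees with a brute-force offset/mismatch oracle", {
  set.seed(42)
  for (i in 1:60) {
    L <- sample(30:90, 1)
    s <- random_seq(L)
    # half the time, plant a (possibly mutated/truncated) adapter
    if (i %% 2 == 0) {
      keep_len <- sample(c(nchar(ADAPTER), nchar(ADAPTER), 12), 1)
      ad <- mutate_seq(substr(ADAPTER, 1, keep_len), n_sub = sample(0:2, 1))
      s <- paste0(substr(s, 1, L - nchar(ad)), ad)
    }
    frac <- sample(c(0, 0.05, 0.1, 0.2), 1)
    got <- trim_adapter(make_reads(s), ADAPTER, frac)
    exp_pos <- adapter_pos_oracle(s, ADAPTER, frac)
    if (exp_pos > 1) {
      expect_equal(got$kept$sequence, substr(s, 1, exp_pos - 1))
    } else {
      expect_equal(length(got$kept), 0L)
    }
  }
})

test_that("reads containing any N are discarded", {
  out <- filter_ambiguous(make_reads(c("ACGTACGT", "ACNT", "NNNN")))
  expect_equal(out$kept$sequence, "ACGTACGT")
  expect_equal(out$discarded$sequence, c("ACNT", "NNNN"))
})

test_that("low-frequency removal counts exact full strings over the pool", {
  r <- make_reads(c("AAAA", "AAAA", "CCCC"))
  out <- filter_low_frequency(r, 2)
  expect_equal(out$kept$sequence, c("AAAA", "AAAA"))
  expect_equal(out$discarded$sequence, "CCCC")

  # min copy number 1 is the identity
  out1 <- filter_low_frequency(r, 1)
  expect_identical(out1$kept$sequence, r$sequence)
  expect_equal(length(out1$discarded), 0L)

  r2 <- make_reads(c("AATT", "AATT", "AATT", "GGCC", "TTGG"))
  out2 <- filter_low_frequency(r2, 2)
  expect_equal(length(out2$kept), 3L)
})

test_that("demultiplexing assigns by exact 5' barcode and strips it", {
  bcs <- c(S1 = "ACGT", S2 = "TGCA")
  r <- make_reads(c("ACGTAAAA", "TGCACCCC", "GGGGTTTT", "ACGT"))
  out <- demultiplex(r, bcs)
  expect_equal(out$samples$S1$sequence, "AAAA")
  expect_equal(out$samples$S2$sequence, "CCCC")
  expect_equal(vapply(out$samples$S1$qualities, length, 1L), 4L)
  # no-barcode-match reads (and reads exhausted by the barcode) are unassigned
  expect_equal(out$unassigned$id, c("r003", "r004"))
  # partition invariant
  expect_equal(sum(vapply(out$samples, length, 1L)) + length(out$unassigned),
               length(r))
})

test_that("demultiplexing is skipped without barcodes", {
  r <- make_reads(c("ACGTAAAA", "TGCACCCC"))
  out <- demultiplex(r, character())
  expect_named(out$samples, "sample1")
  expect_identical(out$samples$sample1$sequence, r$sequence)
  expect_equal(length(out$unassigned), 0L)
})

test_that("length filtering uses an inclusive window", {
  r <- make_reads(c(random_seq(99), random_seq(100), random_seq(250),
                    random_seq(500), random_seq(501)))
  out <- filter_length(r, 100, 500)
  expect_equal(out$kept$id, c("r002", "r003", "r004"))
  expect_equal(out$discarded$id, c("r001", "r005"))
})

PRIMER <- "AACCTGGTTGATCCTGCCAGT"

test_that("the boundary consensus is the modal window, ties lexicographic", {
  wins <- c(rep("ACGTACGT", 6), rep("GGGGCCCC", 4))
  r <- make_reads(paste0(PRIMER, wins, "TTTTTTTT"))
  cons <- compute_boundary_consensus(r, PRIMER)
  expect_equal(cons$motif, "ACGTACGT")
  expect_equal(cons$support, 6L)
  expect_equal(cons$n_eligible, 10L)

  tied <- make_reads(paste0(PRIMER, c(rep("TTTTAAAA", 5), rep("AAAATTTT", 5)),
                            "GG"))
  expect_equal(compute_boundary_consensus(tied, PRIMER)$motif, "AAAATTTT")

  # no read long enough to supply a window -> undefined
  short <- make_reads(paste0(PRIMER, "ACG"))
  expect_error(compute_boundary_consensus(short, PRIMER), "undefined")
})

test_that("the boundary filter discards one-base shifts and keeps clean reads", {
  cons <- "GCCTAAGC"
  tail8 <- "ATCGTGCA"
  clean <- paste0(PRIMER, cons, tail8, "ACGT")
  plus1 <- paste0(PRIMER, "T", cons, tail8, "ACG")   # +1: duplicated primer end
  minus1 <- paste0(PRIMER, substr(cons, 2, 8), tail8, "ACGTA")  # -1: first base lost
  r <- make_reads(c(clean, plus1, minus1))
  keep <- boundary_keep(r, cons, PRIMER, threshold = 3)
  expect_identical(keep, c(TRUE, FALSE, FALSE))

  # a read exactly primer+8 long has no +1 window; distant -1 window keeps it
  exact <- make_reads(paste0(PRIMER, cons))
  expect_true(boundary_keep(exact, cons, PRIMER))

  # exempting exact zero-offset matches protects homopolymer-like targets
  repeat_read <- make_reads(paste0(PRIMER, strrep("A", 16)))
  expect_false(boundary_keep(repeat_read, "AAAAAAAA", PRIMER))
  expect_true(boundary_keep(repeat_read, "AAAAAAAA", PRIMER,
                            exempt_exact = TRUE))
})

test_that("boundary decisions match a brute-force hamming oracle", {
  set.seed(7)
  cons <- "GCCTAAGC"
  for (i in 1:40) {
    target <- random_seq(sample(9:30, 1))
    r <- make_reads(paste0(PRIMER, target))
    keep <- boundary_keep(r, cons, PRIMER, threshold = 3)
    p <- nchar(PRIMER); L <- nchar(r$sequence)
    s <- r$sequence
    disc <- FALSE
    if (L >= p + 9 &&
        hamming_oracle(substr(s, p + 2, p + 9), cons) < 3) disc <- TRUE
    if (!disc && L >= p + 7 &&
        hamming_oracle(substr(s, p, p + 7), cons) < 3) disc <- TRUE
    expect_identical(keep, !disc)
  }
})

test_that("primer clipping requires perfect identity at both ends", {
  REV <- "TGATCCTTCTGCAGGTTCACCTAC"
  rc_rev <- reverse_complement(REV)
  target <- "GCCTAAGCATCGTGCAACGT"
  good <- paste0(PRIMER, target, rc_rev)
  bad_fwd <- paste0(mutate_seq(PRIMER, n_sub = 1), target, rc_rev)
  no_rev <- paste0(PRIMER, target, "AAAAAAAAAAAAAAAAAAAAAAAA")
  out <- trim_primers(make_reads(c(good, bad_fwd, no_rev)), PRIMER, REV)
  expect_equal(out$kept$sequence, target)
  expect_equal(vapply(out$kept$qualities, length, 1L), nchar(target))
  expect_equal(length(out$discarded), 2L)

  # literal-orientation matching is available as a switch
  lit <- paste0(PRIMER, target, REV)
  expect_equal(trim_primers(make_reads(lit), PRIMER, REV,
                            reverse_literal = TRUE)$kept$sequence, target)
  expect_equal(length(trim_primers(make_reads(lit), PRIMER, REV)$kept), 0L)
})

test_that("mean quality averages the remaining bases; threshold is strict", {
  r <- amplicon_reads("q1", "ACG", list(c(20L, 30L, 40L)))
  expect_equal(mean_quality(r), 30)
  # mean exactly at the threshold is kept: only strictly lower is discarded
  expect_equal(length(filter_quality(r, 30)$kept), 1L)
  expect_equal(length(filter_quality(r, 30.0001)$kept), 0L)
  bad <- r; bad$qualities <- list(integer(0))
  expect_error(mean_quality(bad), "undefined")
})

test_that("dereplication collapses exact duplicates, ranked by frequency", {
  out <- dereplicate(c("AC", "AC", "AG"), sample = "S1")
  expect_equal(out$sequence, c("AC", "AG"))
  expect_equal(out$frequency, c(2L, 1L))
  expect_equal(out$rank, 1:2)
  expect_equal(unique(out$sample), "S1")

  # indels are informative: variants differing by an indel stay separate
  out2 <- dereplicate(c("ACGT", "ACGGT"))
  expect_equal(nrow(out2), 2L)

  # equal frequencies -> deterministic lexicographic order
  out3 <- dereplicate(c("TT", "AA", "GG"))
  expect_equal(out3$sequence, c("AA", "GG", "TT"))
})

test_that("dereplication conserves read counts over random pools", {
  set.seed(5)
  for (i in 1:25) {
    pool <- sample(c("AAAA", "CCCC", "GGTT", "ACGT", "TTAA"),
                   sample(1:60, 1), replace = TRUE)
    out <- dereplicate(pool)
    expect_equal(sum(out$frequency), length(pool))
    expect_true(all(diff(out$frequency) <= 0))
    expect_equal(out$rank, seq_len(nrow(out)))
    expect_false(anyDuplicated(out$sequence) > 0)
  }
})
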