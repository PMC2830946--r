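#' Trim adapter B from the 3' end of each read
#'
#' Scans every read for an occurrence of the adapter-B sequence and truncates
#' the read (sequence and qualities) at the occurrence start. The search is
#' ungapped over all offsets and tolerates `ceiling(max_mismatch_fraction x
#' matched length)` mismatches; at the 3' end a truncated adapter prefix of
#' at least half the adapter length is accepted, since reads often end inside
#' the adapter. The leftmost acceptable occurrence wins. Reads with no
#' acceptable occurrence -- or whose occurrence leaves no sequence -- are
#' rejected: an undetected adapter means the amplicon was not read through.
#'
#' @param reads an [amplicon_reads] object.
#' @param adapter adapter-B sequence.
#' @param max_mismatch_fraction tolerated mismatch fraction.
#' @return A list with `kept` (trimmed reads) and `discarded` (untouched
#'   rejected reads), both [amplicon_reads].
#' @export
trim_adapter <- function(reads, adapter, max_mismatch_fraction = 0.1) {
  stopifnot(inherits(reads, "amplicon_reads"), nzchar(adapter))
  pos <- adapter_scan_cpp(reads$sequence, toupper(adapter),
                          max_mismatch_fraction)
  keep <- pos > 1L  # pos 1 would leave an empty read
  kept <- reads[keep]
  at <- pos[keep]
  kept$sequence <- substr(kept$sequence, 1L, at - 1L)
  kept$qualities <- mapply(function(q, p) q[seq_len(p - 1L)],
                           kept$qualities, at, SIMPLIFY = FALSE)
  list(kept = kept, discarded = reads[!keep])
}

#' Remove reads containing ambiguous bases
#'
#' A read is discarded if its sequence contains one or more `N`s.
#'
#' @param reads an [amplicon_reads] object.
#' @return A list with `kept` and `discarded` [amplicon_reads].
#' @export
filter_ambiguous <- function(reads) {
  stopifnot(inherits(reads, "amplicon_reads"))
  keep <- !grepl("N", reads$sequence, fixed = TRUE)
  list(kept = reads[keep], discarded = reads[!keep])
}

#' Remove low-frequency sequence variants from the pooled read set
#'
#' Counts exact full-string occurrences of every sequence over the pool and
#' discards reads whose sequence occurs fewer than `min_copy_number` times.
#' This runs on the pooled, still-barcoded reads (before demultiplexing), so
#' copy numbers accumulate across identical reads of the same sample;
#' `min_copy_number = 1` is the identity.
#'
#' @param reads an [amplicon_reads] object.
#' @param min_copy_number integer >= 1.
#' @return A list with `kept` and `discarded` [amplicon_reads].
#' @export
filter_low_frequency <- function(reads, min_copy_number) {
  stopifnot(inherits(reads, "amplicon_reads"), min_copy_number >= 1)
  if (min_copy_number == 1 || length(reads) == 0) {
    return(list(kept = reads, discarded = reads[integer(0)]))
  }
  tab <- table(reads$sequence)
  keep <- as.vector(tab[reads$sequence]) >= min_copy_number
  list(kept = reads[keep], discarded = reads[!keep])
}

#' Separate pooled reads into samples by 5' barcode
#'
#' A read is assigned to a sample when its 5' prefix equals that sample's
#' barcode exactly; the barcode bases and their qualities are then removed.
#' Reads matching no barcode are discarded. Barcodes must be unique and of
#' equal length (validated by [pipeline_config()]), so assignment is
#' unambiguous. With an empty barcode set the step is skipped and all reads
#' are returned under a single sample.
#'
#' @param reads an [amplicon_reads] object.
#' @param barcodes named character vector (sample name -> barcode), possibly
#'   empty.
#' @param single_sample_name sample name used when `barcodes` is empty.
#' @return A list with `samples` (named list of [amplicon_reads], barcode
#'   removed) and `unassigned` ([amplicon_reads]).
#' @export
demultiplex <- function(reads, barcodes, single_sample_name = "sample1") {
  stopifnot(inherits(reads, "amplicon_reads"))
  if (length(barcodes) == 0) {
    out <- list(reads)
    names(out) <- single_sample_name
    return(list(samples = out, unassigned = reads[integer(0)]))
  }
  if (is.null(names(barcodes)) || anyDuplicated(barcodes) ||
      length(unique(nchar(barcodes))) > 1) {
    stop("barcodes must be named, unique and of equal length", call. = FALSE)
  }
  blen <- nchar(barcodes[[1]])
  prefix <- substr(reads$sequence, 1L, blen)
  idx <- match(prefix, barcodes)
  idx[nchar(reads$sequence) <= blen] <- NA_integer_  # nothing left after barcode
  samples <- lapply(seq_along(barcodes), function(i) {
    r <- reads[which(idx == i)]
    r$sequence <- substr(r$sequence, blen + 1L, nchar(r$sequence))
    r$qualities <- lapply(r$qualities, function(q) q[-seq_len(blen)])
    r
  })
  names(samples) <- names(barcodes)
  list(samples = samples, unassigned = reads[is.na(idx)])
}

#' Filter reads by length window
#'
#' Keeps reads whose current length (adapter- and barcode-stripped, primers
#' still attached) lies in the inclusive window `[min_length, max_length]`.
#'
#' @param reads an [amplicon_reads] object.
#' @param min_length,max_length inclusive bounds in bp.
#' @return A list with `kept` and `discarded` [amplicon_reads].
#' @export
filter_length <- function(reads, min_length, max_length) {
  stopifnot(inherits(reads, "amplicon_reads"), min_length <= max_length)
  len <- nchar(reads$sequence)
  keep <- len >= min_length & len <= max_length
  list(kept = reads[keep], discarded = reads[!keep])
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Boundary consensus at the primer/target junction
#'
#' Pyrosequencing preferentially produces length errors in homopolymer runs;
#' at the junction between a PCR primer and the target these shift the whole
#' target by one base, which exact primer matching cannot detect. As a
#' reference for detecting such shifts, this function scans the
#' `window`-bp stretch of target immediately 3' of the forward primer in
#' every read that starts with the primer exactly, and returns the modal
#' motif (ties broken lexicographically, for determinism) with its support.
#'
#' @param reads an [amplicon_reads] object (post length filter).
#' @param forward_primer forward primer sequence.
#' @param window motif width in bp (default 8).
#' @return A `boundary_consensus` object: list with `motif`, `support`,
#'   `n_eligible`, `primer` and `window`.
#' @export
compute_boundary_consensus <- function(reads, forward_primer, window = 8L) {
  stopifnot(inherits(reads, "amplicon_reads"))
  p <- nchar(forward_primer)
  eligible <- startsWith(reads$sequence, forward_primer) &
    nchar(reads$sequence) >= p + window
  if (!any(eligible)) {
    stop("boundary consensus undefined: no read supplies a full ",
         window, " bp window after the forward primer", call. = FALSE)
  }
  win <- substr(reads$sequence[eligible], p + 1L, p + window)
  tab <- table(win)
  best <- max(tab)
  motif <- sort(names(tab)[tab == best])[1]
  structure(list(motif = motif, support = as.integer(best),
                 n_eligible = sum(eligible), primer = forward_primer,
                 window = as.integer(window)),
            class = "boundary_consensus")
}

#' @export
print.boundary_consensus <- function(x, ...) {
  cat(sprintf("boundary consensus: %s (support %d of %d eligible reads)\n",
              x$motif, x$support, x$n_eligible))
  invisible(x)
}

#' Flag reads carrying a one-base boundary shift
#'
#' Compares the boundary consensus motif against each read's +1 and -1
#' offset windows relative to the primer/target junction. A read unaffected
#' by a homopolymer boundary error disagrees with the consensus at both
#' offsets, while a read whose target is shifted by one base matches it
#' almost perfectly at one of them; reads with fewer than `threshold`
#' mismatches at either offset are therefore marked for discarding. An
#' offset whose window would run past the read end is skipped.
#'
#' @param reads an [amplicon_reads] object; only reads beginning with the
#'   exact forward primer should be passed.
#' @param consensus a [compute_boundary_consensus()] result (or a motif
#'   string).
#' @param forward_primer forward primer sequence.
#' @param threshold mismatch threshold (default 3): discard when `< threshold`.
#' @param exempt_exact keep reads whose zero-offset window equals the
#'   consensus exactly, regardless of the offset comparisons.
#' @return Logical vector, `TRUE` for reads to keep.
#' @export
boundary_keep <- function(reads, consensus, forward_primer, threshold = 3L,
                          exempt_exact = FALSE) {
  stopifnot(inherits(reads, "amplicon_reads"))
  motif <- if (inherits(consensus, "boundary_consensus")) consensus$motif else consensus
  w <- nchar(motif)
  p <- nchar(forward_primer)
  n <- length(reads)
  keep <- rep(TRUE, n)
  if (n == 0) return(keep)
  len <- nchar(reads$sequence)
  cons <- strsplit(motif, "")[[1]]
  seqs <- strsplit(reads$sequence, "")
  for (i in seq_len(n)) {
    if (exempt_exact && len[i] >= p + w &&
        identical(seqs[[i]][(p + 1):(p + w)], cons)) next
    # +1 offset: window starts one base later (insertion at the junction)
    if (len[i] >= p + w + 1L &&
        sum(seqs[[i]][(p + 2):(p + w + 1)] != cons) < threshold) {
      keep[i] <- FALSE
      next
    }
    # -1 offset: window starts on the primer's last base (deletion)
    if (p >= 1L && len[i] >= p + w - 1L &&
        sum(seqs[[i]][p:(p + w - 1)] != cons) < threshold) {
      keep[i] <- FALSE
    }
  }
  keep
}

#' Remove PCR primers requiring perfect identity
#'
#' A read must start with the forward primer exactly and end with the
#' reverse complement of the reverse primer exactly (or the literal reverse
#' primer when `reverse_literal` is `TRUE`); both are removed from sequence
#' and qualities. Reads failing either check, or left with no target bases,
#' are rejected.
#'
#' @param reads an [amplicon_reads] object.
#' @param forward_primer,reverse_primer primer sequences.
#' @param reverse_literal match the reverse primer literally instead of
#'   reverse-complemented.
#' @return A list with `kept` (primer-stripped reads) and `discarded`.
#' @export
trim_primers <- function(reads, forward_primer, reverse_primer,
                         reverse_literal = FALSE) {
  stopifnot(inherits(reads, "amplicon_reads"))
  fwd <- toupper(forward_primer)
  rev3 <- if (reverse_literal) toupper(reverse_primer) else
    reverse_complement(toupper(reverse_primer))
  p <- nchar(fwd); r <- nchar(rev3)
  keep <- startsWith(reads$sequence, fwd) &
    endsWith(reads$sequence, rev3) &
    nchar(reads$sequence) > p + r
  kept <- reads[keep]
  kept$sequence <- substr(kept$sequence, p + 1L, nchar(kept$sequence) - r)
  kept$qualities <- lapply(kept$qualities, function(q) {
    q[(p + 1L):(length(q) - r)]
  })
  list(kept = kept, discarded = reads[!keep])
}

#' Mean per-base quality of each read
#'
#' Arithmetic mean of the quality scores currently attached to each read.
#' In the pipeline this is called after adapter, barcode and primer bases
#' (and their qualities) have been removed, so the mean covers the target
#' region only.
#'
#' @param reads an [amplicon_reads] object.
#' @return Numeric vector of means.
#' @export
mean_quality <- function(reads) {
  stopifnot(inherits(reads, "amplicon_reads"))
  if (any(vapply(reads$qualities, length, 1L) == 0)) {
    stop("mean quality undefined for a read with no quality values",
         call. = FALSE)
  }
  vapply(reads$qualities, mean, 0)
}

#' Discard reads with low mean quality
#'
#' Keeps reads whose mean target-region quality is `>= min_mean_quality`
#' (the comparison is strict on the discard side: only means strictly below
#' the threshold are discarded, with no rounding).
#'
#' @param reads an [amplicon_reads] object.
#' @param min_mean_quality threshold.
#' @return A list with `kept` and `discarded` [amplicon_reads].
#' @export
filter_quality <- function(reads, min_mean_quality) {
  stopifnot(inherits(reads, "amplicon_reads"))
  if (length(reads) == 0) return(list(kept = reads, discarded = reads))
  keep <- mean_quality(reads) >= min_mean_quality
  list(kept = reads[keep], discarded = reads[!keep])
}

#' Collapse reads to a non-redundant, frequency-annotated set
#'
#' Groups fully trimmed reads by exact string identity -- indels are
#' informative, so sequences differing only by an indel stay separate --
#' and returns one record per unique sequence with its copy number,
#' ranked by frequency in descending order (ties broken by lexicographic
#' sequence order for determinism). The sum of frequencies equals the
#' number of input reads.
#'
#' @param reads an [amplicon_reads] object (fully trimmed) or a character
#'   vector of sequences.
#' @param sample sample name recorded in the output.
#' @return A `data.frame` with columns `sample`, `sequence`, `frequency`,
#'   `rank`.
#' @export
dereplicate <- function(reads, sample = "sample1") {
  seqs <- if (inherits(reads, "amplicon_reads")) reads$sequence else
    as.character(reads)
  if (length(seqs) == 0) {
    return(data.frame(sample = character(), sequence = character(),
                      frequency = integer(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(seqs)
  ord <- order(-as.vector(tab), names(tab))
  data.frame(sample = sample,
             sequence = names(tab)[ord],
             frequency = as.integer(tab[ord]),
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}
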