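#' Defect rates for the read simulator
#'
#' Per-read probabilities (realised as deterministic per-sample counts,
#' `round(rate * n)`) of each injected defect class. The defaults emulate
#' the loss profile of a deeply multiplexed 454 amplicon survey: roughly
#' 40% of raw reads fail one of the seven filters, with incomplete adapter
#' read-through and low-frequency (singleton) variants dominating, and
#' smaller contributions from ambiguous bases, foreign barcodes, length
#' outliers, primer synthesis errors, boundary homopolymer slips and
#' low-quality reads.
#'
#' @param no_adapter read lacks adapter B (discarded at step 1).
#' @param ambiguous read contains an `N` (step 2).
#' @param singleton read's full sequence is unique in the pool (step 3).
#' @param bad_barcode 5' tag matches no configured barcode (step 4).
#' @param out_of_length amplicon far outside the length window (step 5).
#' @param primer_mutation substitution inside the forward primer (step 6).
#' @param boundary_indel one-base homopolymer slip at the primer/target
#'   junction, split between +1 and -1 (step 6, boundary filter).
#' @param low_quality base qualities drawn from the low-quality band
#'   (step 7).
#' @return Named numeric vector of rates (each in `[0, 1]`, summing to at
#'   most 1; the remainder of each sample is clean reads).
#' @export
sim_defect_rates <- function(no_adapter = 0.15, ambiguous = 0.04,
                             singleton = 0.10, bad_barcode = 0.02,
                             out_of_length = 0.01, primer_mutation = 0.04,
                             boundary_indel = 0.04, low_quality = 0.02) {
  r <- c(no_adapter = no_adapter, ambiguous = ambiguous,
         singleton = singleton, bad_barcode = bad_barcode,
         out_of_length = out_of_length, primer_mutation = primer_mutation,
         boundary_indel = boundary_indel, low_quality = low_quality)
  if (any(r < 0 | r > 1)) stop("defect rates must lie in [0, 1]", call. = FALSE)
  if (sum(r) > 1) stop("defect rates must sum to at most 1", call. = FALSE)
  r
}

#' Default configuration for simulated datasets
#'
#' Three multiplexed samples with 6-bp barcodes, 18S-style PCR primers, a
#' 20-bp adapter B, a [100, 170] bp length window on the primer-bearing
#' read, mean-quality threshold 20 (clean bases are drawn from [30, 40] and
#' low-quality bases from [5, 15], so classification is unambiguous) and a
#' pooled copy-number threshold of 2.
#'
#' @return A [pipeline_config()] object.
#' @export
default_sim_config <- function() {
  pipeline_config(
    adapter_b = "CTGAGACTGCCAAGGCACAC",
    forward_primer = "AACCTGGTTGATCCTGCCAGT",
    reverse_primer = "TGATCCTTCTGCAGGTTCACCTAC",
    min_length = 100L, max_length = 170L,
    barcodes = c(S1 = "ACAGTC", S2 = "CGTCAG", S3 = "GTACGA"),
    min_mean_quality = 20, min_copy_number = 2L,
    similarity_cutoff = 100, seed = 42L)
}

# target prefix shared by every simulated variant: guarantees the boundary
# consensus is its first <window> bases and that a clean read disagrees with
# the consensus at both the +1 and -1 offsets.
sim_target_prefix <- function(config) {
  prefix <- "GCCTAAGCATCGTGCA"
  w <- config$boundary_window
  thr <- config$boundary_mismatch_threshold
  cons <- substr(prefix, 1, w)
  plus1 <- substr(prefix, 2, w + 1)
  minus1 <- paste0(substr(config$forward_primer,
                          nchar(config$forward_primer),
                          nchar(config$forward_primer)),
                   substr(prefix, 1, w - 1))
  stopifnot(hamming(cons, plus1) >= thr, hamming(cons, minus1) >= thr)
  prefix
}

#' Inject a one-base homopolymer slip at a primer/target junction
#'
#' Emulates the dominant 454 error mode at the end of a PCR primer: `"+1"`
#' inserts a duplicate of the primer's final base at the junction, `"-1"`
#' deletes the first target base. Qualities are edited in step with the
#' sequence so length pairing is preserved.
#'
#' @param sequence read sequence containing the primer.
#' @param qualities integer quality vector of the same length.
#' @param junction 1-based position of the primer's last base within
#'   `sequence`.
#' @param direction `"+1"` or `"-1"`.
#' @return A list with mutated `sequence` and `qualities`.
#' @export
inject_boundary_indel <- function(sequence, qualities, junction,
                                  direction = c("+1", "-1")) {
  direction <- match.arg(direction)
  L <- nchar(sequence)
  stopifnot(length(qualities) == L, junction >= 1, junction < L)
  if (L - junction < 9) stop("target too short for a boundary indel",
                             call. = FALSE)
  head_s <- substr(sequence, 1, junction)
  tail_s <- substr(sequence, junction + 1, L)
  if (direction == "+1") {
    list(sequence = paste0(head_s, substr(head_s, junction, junction), tail_s),
         qualities = as.integer(c(qualities[1:junction], qualities[junction],
                                  qualities[(junction + 1):L])))
  } else {
    list(sequence = paste0(head_s, substr(tail_s, 2, nchar(tail_s))),
         qualities = as.integer(qualities[-(junction + 1)]))
  }
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# split `total` into groups of >= min_copy, skewed towards the first group
alloc_counts <- function(total, min_copy, k = 5L) {
  if (total == 0) return(integer(0))
  if (total < min_copy) {
    stop("too few reads to build a group clearing min_copy_number; ",
         "increase n_per_sample", call. = FALSE)
  }
  k <- max(1L, min(k, total %/% min_copy))
  cnt <- rep(min_copy, k)
  rem <- total - k * min_copy
  w <- 2^((k - 1):0)
  extra <- floor(rem * w / sum(w))
  cnt <- cnt + extra
  cnt[1] <- cnt[1] + rem - sum(extra)
  as.integer(cnt)
}

#' Simulate a multiplexed 454-style dataset with known ground truth
#'
#' Builds reads as `barcode + forward primer + target + rc(reverse primer)
#' + adapter B` from a small panel of divergent target variants shared
#' across samples, then injects at most one defect per read according to
#' `defect_rates`. Every defect class within a sample is constructed as a
#' block of identical reads, so its pooled copy number clears the
#' low-frequency filter and each read reaches exactly the step its defect
#' violates; the manifest therefore states each read's fate by
#' construction. Output is deterministic for a fixed seed.
#'
#' @param config a [pipeline_config()]; defaults to [default_sim_config()].
#' @param n_per_sample reads per sample.
#' @param defect_rates a [sim_defect_rates()] vector.
#' @param seed integer seed (mandatory; overrides `config$seed`).
#' @param target_length clean target length in bp.
#' @param n_variants number of clean target variants shared by all samples.
#' @return A `simulated_reads` object: list with `reads` (raw
#'   [amplicon_reads], shuffled), `truth` (manifest `data.frame` with
#'   columns `id`, `sample`, `defects`, `expected_fate`, `target`) and
#'   `config`.
#' @export
simulate_sample_set <- function(config = default_sim_config(),
                                n_per_sample = 500L,
                                defect_rates = sim_defect_rates(),
                                seed = config$seed,
                                target_length = 110L,
                                n_variants = 5L) {
  stopifnot(inherits(config, "pipeline_config"))
  defect_rates <- sim_defect_rates(
    no_adapter = defect_rates[["no_adapter"]],
    ambiguous = defect_rates[["ambiguous"]],
    singleton = defect_rates[["singleton"]],
    bad_barcode = defect_rates[["bad_barcode"]],
    out_of_length = defect_rates[["out_of_length"]],
    primer_mutation = defect_rates[["primer_mutation"]],
    boundary_indel = defect_rates[["boundary_indel"]],
    low_quality = defect_rates[["low_quality"]])
  single_sample <- length(config$barcodes) == 0
  if (single_sample && defect_rates[["bad_barcode"]] > 0) {
    stop("bad_barcode defects require configured barcodes", call. = FALSE)
  }
  set.seed(as.integer(seed))

  prefix <- sim_target_prefix(config)
  if (target_length <= nchar(prefix) + 10) {
    stop("target_length too short for the shared prefix", call. = FALSE)
  }
  fwd <- config$forward_primer
  rev3 <- reverse_complement(config$reverse_primer)
  p <- nchar(fwd)
  amplen <- function(tlen) p + tlen + nchar(rev3)
  if (amplen(target_length) < config$min_length ||
      amplen(target_length) > config$max_length) {
    stop("target_length puts clean amplicons outside the length window",
         call. = FALSE)
  }
  variants <- vapply(seq_len(n_variants), function(i) {
    paste0(prefix, random_dna(target_length - nchar(prefix)))
  }, "")

  barcodes <- if (single_sample) c(sample1 = "") else config$barcodes
  wrong_bc <- NULL
  if (!single_sample) {
    blen <- nchar(barcodes[[1]])
    for (cand in c(strrep("T", blen), strrep("G", blen), strrep("C", blen))) {
      if (!cand %in% barcodes) { wrong_bc <- cand; break }
    }
  }
  mutate_primer <- function(primer) {
    pos <- 10L
    base <- substr(primer, pos, pos)
    sub <- c(A = "C", C = "A", G = "T", T = "G")[[base]]
    paste0(substr(primer, 1, pos - 1), sub,
           substr(primer, pos + 1, nchar(primer)))
  }
  bad_fwd <- mutate_primer(fwd)
  qual_for <- function(len, low) {
    if (low) sample(5:15, len, replace = TRUE) else
      sample(30:40, len, replace = TRUE)
  }
  short_target <- substr(variants[1], 1, 30)
  pick_variant <- function(i) variants[((i - 1) %% n_variants) + 1]

  ids <- character(0); seqs <- character(0); quals <- list()
  samples <- character(0); defects <- character(0); fates <- character(0)
  emit <- function(sample, target, defect, fate,
                   barcode_seq, fwd_seq, with_adapter = TRUE, low = FALSE,
                   boundary_dir = NULL) {
    core <- paste0(fwd_seq, target, rev3)
    seq <- paste0(barcode_seq, core,
                  if (with_adapter) config$adapter_b else "")
    q <- qual_for(nchar(seq), low)
    if (!is.null(boundary_dir)) {
      junction <- nchar(barcode_seq) + nchar(fwd_seq)
      m <- inject_boundary_indel(seq, q, junction, boundary_dir)
      seq <- m$sequence; q <- m$qualities
    }
    ids <<- c(ids, "pending")
    seqs <<- c(seqs, seq)
    quals[[length(quals) + 1]] <<- q
    samples <<- c(samples, sample)
    defects <<- c(defects,
                  if (is.null(boundary_dir)) defect else
                    paste0(defect, ":", boundary_dir))
    fates <<- c(fates, fate)
  }

  for (s in names(barcodes)) {
    bc <- barcodes[[s]]
    n <- as.integer(n_per_sample)
    cnt <- round(defect_rates * n)
    while (sum(cnt) > n) cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
    n_clean <- n - sum(cnt)
    min_copy <- config$min_copy_number
    for (cls in c("bad_barcode", "out_of_length", "primer_mutation",
                  "low_quality")) {
      if (cnt[[cls]] > 0 && cnt[[cls]] < min_copy) {
        stop(sprintf(
          "class '%s' would form a group below min_copy_number; increase %s",
          cls, "n_per_sample or the rate"), call. = FALSE)
      }
    }
    # clean reads across variants, each variant clearing min_copy
    for (v in seq_along(alloc <- alloc_counts(n_clean, min_copy, n_variants))) {
      for (i in seq_len(alloc[v])) {
        emit(s, variants[v], "none", "kept", bc, fwd)
      }
    }
    for (i in seq_len(cnt[["no_adapter"]])) {
      emit(s, pick_variant(1), "no_adapter", "adapter_b_removal", bc, fwd,
           with_adapter = FALSE)
    }
    if (cnt[["ambiguous"]] > 0) {
      tgt <- pick_variant(1)
      substr(tgt, 20, 20) <- "N"
      for (i in seq_len(cnt[["ambiguous"]])) {
        emit(s, tgt, "ambiguous_base", "ambiguity_filter", bc, fwd)
      }
    }
    for (i in seq_len(cnt[["singleton"]])) {
      tgt <- paste0(prefix, random_dna(target_length - nchar(prefix)))
      emit(s, tgt, "singleton", "low_frequency_removal", bc, fwd)
    }
    for (i in seq_len(cnt[["bad_barcode"]])) {
      emit(s, pick_variant(1), "bad_barcode", "demultiplex", wrong_bc, fwd)
    }
    for (i in seq_len(cnt[["out_of_length"]])) {
      emit(s, short_target, "out_of_length", "length_filter", bc, fwd)
    }
    for (i in seq_len(cnt[["primer_mutation"]])) {
      emit(s, pick_variant(2), "primer_mutation", "primer_removal", bc,
           bad_fwd)
    }
    nb <- cnt[["boundary_indel"]]
    if (nb > 0) {
      n_plus <- if (nb >= 2 * min_copy) nb %/% 2L else nb
      if (nb < min_copy) {
        stop("boundary_indel group below min_copy_number; increase ",
             "n_per_sample or the rate", call. = FALSE)
      }
      dirs <- c(rep("+1", n_plus), rep("-1", nb - n_plus))
      for (d in dirs) {
        emit(s, pick_variant(1), "boundary_indel", "primer_removal", bc, fwd,
             boundary_dir = d)
      }
    }
    for (i in seq_len(cnt[["low_quality"]])) {
      emit(s, pick_variant(3), "low_quality", "quality_filter", bc, fwd,
           low = TRUE)
    }
  }

  ord <- sample(length(seqs))
  ids <- sprintf("READ%06d", seq_along(ord))
  # a read lacking its adapter must really have no acceptable occurrence
  no_ad <- which(defects == "no_adapter")[seq_len(min(5L, sum(defects == "no_adapter")))]
  if (length(no_ad)) {
    stopifnot(all(adapter_scan_cpp(seqs[no_ad], config$adapter_b,
                                   config$adapter_max_mismatch_fraction) == 0L))
  }
  reads <- amplicon_reads(ids, seqs[ord], quals[ord])
  truth <- data.frame(id = ids, sample = samples[ord],
                      defects = defects[ord], expected_fate = fates[ord],
                      target = NA_character_, stringsAsFactors = FALSE)
  truth$target <- vapply(seq_along(ord), function(i) {
    if (truth$defects[i] == "none") {
      r <- seqs[ord[i]]
      substr(r, nchar(barcodes[[truth$sample[i]]]) + p + 1,
             nchar(r) - nchar(rev3) - nchar(config$adapter_b))
    } else NA_character_
  }, "")
  structure(list(reads = reads, truth = truth, config = config),
            class = "simulated_reads")
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("simulated_reads: %d reads, %d sample(s)\n",
              length(x$reads), length(unique(x$truth$sample))))
  print(table(x$truth$expected_fate))
  invisible(x)
}

#' Expected per-step accounting from a simulation manifest
#'
#' Translates the per-read expected fates of a [simulate_sample_set()]
#' manifest into the per-step `n_in`/`n_kept`/`n_discarded` table that a
#' pipeline run over the same reads must reproduce.
#'
#' @param truth the `truth` data frame of a `simulated_reads` object.
#' @return A [step_report()].
#' @export
manifest_step_counts <- function(truth) {
  n <- nrow(truth)
  n_in <- integer(length(step_names))
  n_kept <- integer(length(step_names))
  for (i in seq_along(step_names)) {
    n_in[i] <- n
    n <- n - sum(truth$expected_fate == step_names[i])
    n_kept[i] <- n
  }
  step_report(step_names, n_in, n_kept, n_in - n_kept)
}

#' Write simulated data to disk
#'
#' Writes `reads.fasta`, `reads.qual` and the ground-truth manifest
#' `truth.tsv` into `dir`.
#'
#' @param sim a `simulated_reads` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulated <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_reads"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$reads, file.path(dir, "reads.fasta"))
  write_qual(sim$reads, file.path(dir, "reads.qual"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
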