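step_names <- c("adapter_b_removal", "ambiguity_filter",
                "low_frequency_removal", "demultiplex", "length_filter",
                "primer_removal", "quality_filter")

#' Per-step read accounting
#'
#' Builds the accounting table of a pipeline run: one row per step with the
#' number of reads entering, kept and discarded. Construction enforces the
#' conservation identity `n_in == n_kept + n_discarded` on every row.
#'
#' @param step character vector of step names.
#' @param n_in,n_kept,n_discarded integer vectors.
#' @return A `step_report` data frame.
#' @export
step_report <- function(step, n_in, n_kept, n_discarded) {
  n_in <- as.integer(n_in); n_kept <- as.integer(n_kept)
  n_discarded <- as.integer(n_discarded)
  if (any(n_in < 0 | n_kept < 0 | n_discarded < 0)) {
    stop("step counts must be non-negative", call. = FALSE)
  }
  if (any(n_in != n_kept + n_discarded)) {
    stop("step accounting violated: n_in != n_kept + n_discarded",
         call. = FALSE)
  }
  structure(data.frame(step = step, n_in = n_in, n_kept = n_kept,
                       n_discarded = n_discarded, stringsAsFactors = FALSE),
            class = c("step_report", "data.frame"))
}

#' @export
print.step_report <- function(x, ...) {
  cat("read accounting per step\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("total: %d in, %d kept, %d discarded\n",
              x$n_in[1], x$n_kept[nrow(x)], sum(x$n_discarded)))
  invisible(x)
}

#' Run the full trimming and filtering pipeline
#'
#' Applies the seven processing steps in their fixed order -- adapter-B
#' trimming, ambiguity filtering, pooled low-frequency removal, barcode
#' demultiplexing, length filtering, primer removal with the homopolymer
#' boundary filter, and mean-quality filtering -- then dereplicates each
#' sample into a frequency-annotated non-redundant set. Low-frequency
#' removal happens before demultiplexing so copy numbers are counted over
#' the pooled (still-barcoded) data, which lets several datasets be combined
#' to protect true low-frequency variants. Quality filtering is last, so
#' reads made singletons by it remain in the data set.
#'
#' The boundary consensus is computed once over all demultiplexed,
#' length-filtered reads (all samples share the primer pair); when no read
#' supplies a full boundary window the boundary filter is skipped.
#'
#' @param config a [pipeline_config()] object.
#' @param fasta,qual input file paths, passed to [read_paired_fasta_qual()];
#'   alternatively supply `reads` directly.
#' @param reads an [amplicon_reads] object (overrides `fasta`/`qual`).
#' @return A `pipeline_result`: list with `samples` (per sample: `reads`,
#'   the trimmed redundant set, and `nr`, the [dereplicate()] table),
#'   `steps` (a [step_report()]), `n_input` and `config`.
#' @export
run_pipeline <- function(config, fasta = NULL, qual = NULL, reads = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(reads)) {
    if (is.null(fasta) || is.null(qual)) {
      stop("supply either 'reads' or both 'fasta' and 'qual'", call. = FALSE)
    }
    reads <- read_paired_fasta_qual(fasta, qual)
  }
  n_input <- length(reads)
  counts <- list()
  tally <- function(name, n_in, n_kept) {
    counts[[length(counts) + 1]] <<- list(name, n_in, n_kept)
  }

  s1 <- trim_adapter(reads, config$adapter_b,
                     config$adapter_max_mismatch_fraction)
  tally(step_names[1], length(reads), length(s1$kept))

  s2 <- filter_ambiguous(s1$kept)
  tally(step_names[2], length(s1$kept), length(s2$kept))

  s3 <- filter_low_frequency(s2$kept, config$min_copy_number)
  tally(step_names[3], length(s2$kept), length(s3$kept))

  s4 <- demultiplex(s3$kept, config$barcodes)
  n4 <- sum(vapply(s4$samples, length, 1L))
  tally(step_names[4], length(s3$kept), n4)

  s5 <- lapply(s4$samples, filter_length,
               min_length = config$min_length, max_length = config$max_length)
  kept5 <- lapply(s5, `[[`, "kept")
  n5 <- sum(vapply(kept5, length, 1L))
  tally(step_names[5], n4, n5)

  # step 6: boundary filter on primer-bearing reads, then exact primer removal
  pooled5 <- do.call(c, unname(kept5))
  cons <- tryCatch(
    compute_boundary_consensus(pooled5, config$forward_primer,
                               config$boundary_window),
    error = function(e) NULL)
  strip6 <- function(r) {
    ok <- rep(TRUE, length(r))
    if (!is.null(cons)) {
      primer_ok <- startsWith(r$sequence, config$forward_primer)
      ok[primer_ok] <- boundary_keep(
        r[primer_ok], cons, config$forward_primer,
        config$boundary_mismatch_threshold, config$exempt_exact_boundary)
      if (config$boundary_both_junctions) {
        ok <- ok & boundary_keep_reverse(r, config)
      }
    }
    res <- trim_primers(r[ok], config$forward_primer, config$reverse_primer,
                        config$reverse_primer_literal)
    res$n_in <- length(r)
    res
  }
  s6 <- lapply(kept5, strip6)
  kept6 <- lapply(s6, `[[`, "kept")
  n6 <- sum(vapply(kept6, length, 1L))
  tally(step_names[6], n5, n6)

  s7 <- lapply(kept6, filter_quality, min_mean_quality = config$min_mean_quality)
  kept7 <- lapply(s7, `[[`, "kept")
  n7 <- sum(vapply(kept7, length, 1L))
  tally(step_names[7], n6, n7)

  samples <- lapply(names(kept7), function(s) {
    list(reads = kept7[[s]], nr = dereplicate(kept7[[s]], sample = s))
  })
  names(samples) <- names(kept7)

  steps <- step_report(
    step = vapply(counts, `[[`, "", 1),
    n_in = vapply(counts, `[[`, 1, 2),
    n_kept = vapply(counts, `[[`, 1, 3),
    n_discarded = vapply(counts, `[[`, 1, 2) - vapply(counts, `[[`, 1, 3)
  )
  structure(list(samples = samples, steps = steps, n_input = n_input,
                 boundary_consensus = cons, config = config),
            class = "pipeline_result")
}

# boundary filter at the reverse primer/target junction (optional):
# mirrored by reverse-complementing the reads so the junction becomes
# primer + target in the forward orientation.
boundary_keep_reverse <- function(r, config) {
  if (length(r) == 0) return(logical(0))
  rc <- reverse_complement(r$sequence)
  rcreads <- amplicon_reads(r$id, rc, lapply(r$qualities, rev))
  primer <- config$reverse_primer
  ok <- rep(TRUE, length(r))
  eligible <- startsWith(rc, primer)
  if (!any(eligible)) return(ok)
  cons <- tryCatch(
    compute_boundary_consensus(rcreads, primer, config$boundary_window),
    error = function(e) NULL)
  if (is.null(cons)) return(ok)
  ok[eligible] <- boundary_keep(rcreads[eligible], cons, primer,
                                config$boundary_mismatch_threshold,
                                config$exempt_exact_boundary)
  ok
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d input reads -> %d retained (%.1f%%)\n",
              x$n_input, x$steps$n_kept[nrow(x$steps)],
              if (x$n_input) 100 * x$steps$n_kept[nrow(x$steps)] / x$n_input else 0))
  print(x$steps)
  for (s in names(x$samples)) {
    cat(sprintf("sample %s: %d reads, %d unique sequences\n", s,
                length(x$samples[[s]]$reads), nrow(x$samples[[s]]$nr)))
  }
  invisible(x)
}

#' @export
summary.pipeline_result <- function(object, ...) {
  data.frame(
    sample = names(object$samples),
    n_reads = vapply(object$samples, function(s) length(s$reads), 1L),
    n_unique = vapply(object$samples, function(s) nrow(s$nr), 1L),
    top_frequency = vapply(object$samples, function(s) {
      if (nrow(s$nr)) s$nr$frequency[1] else 0L
    }, 1L),
    row.names = NULL, stringsAsFactors = FALSE)
}

nr_header <- function(sample, rank, frequency) {
  sprintf("%s_NR%06d;size=%d", sample, rank, frequency)
}

#' Write per-sample pipeline outputs
#'
#' Writes, for every sample, the redundant trimmed reads
#' (`<sample>.trimmed.fasta` / `<sample>.trimmed.qual`), the non-redundant
#' set (`<sample>.nr.fasta`, headers `<sample>_NR<rank>;size=<frequency>`)
#' and the shared accounting table `steps.tsv`.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(result$samples)) {
    smp <- result$samples[[s]]
    write_fasta(smp$reads, file.path(dir, paste0(s, ".trimmed.fasta")))
    write_qual(smp$reads, file.path(dir, paste0(s, ".trimmed.qual")))
    nr <- smp$nr
    lines <- if (nrow(nr)) {
      paste0(">", nr_header(nr$sample, nr$rank, nr$frequency), "\n",
             nr$sequence)
    } else character(0)
    writeLines(lines, file.path(dir, paste0(s, ".nr.fasta")))
  }
  write.table(result$steps, file.path(dir, "steps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a non-redundant FASTA file with size annotations
#'
#' Parses the `;size=<frequency>` annotation written by
#' [write_pipeline_outputs()] (and understood by common amplicon tools).
#'
#' @param path path to a non-redundant FASTA file.
#' @return A `data.frame` with columns `id`, `sequence`, `frequency`.
#' @export
read_nr_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("[[:space:]].*$", "", names(seqs))
  m <- regmatches(ids, regexpr(";size=[0-9]+", ids))
  if (length(seqs) && length(m) != length(ids)) {
    stop("missing ';size=' frequency annotation in ", path, call. = FALSE)
  }
  data.frame(id = sub(";size=[0-9]+.*$", "", ids),
             sequence = as.character(seqs),
             frequency = as.integer(sub(";size=", "", m, fixed = TRUE)),
             stringsAsFactors = FALSE)
}
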