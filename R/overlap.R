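#' Copy numbers of query sequences across samples
#'
#' For every non-redundant query sequence, reports its copy number in its
#' own sample and in each target sample: the sum of frequencies of all
#' target sequences whose gap-excluded similarity to the query is at least
#' `cutoff` percent (zero when none). A cutoff of 100 groups exactly the
#' sequences that are identical once gaps are ignored, so indel-only
#' variants are still counted together. With `best_hit_only = TRUE` only the
#' single most similar within-cutoff target sequence contributes (ties
#' resolved by longer gap-free span, then by target id).
#'
#' @param query_nr query sample as a `data.frame` with columns `id`,
#'   `sequence`, `frequency` (see [read_nr_fasta()]).
#' @param target_nr_sets named list of target samples in the same format.
#' @param cutoff percent similarity cutoff in (0, 100].
#' @param best_hit_only count only the best target hit per query.
#' @param engine alignment function, see [align_global()].
#' @return A `data.frame`: `query_id`, `self_copies`, then one copy-number
#'   column per target sample, in the order given.
#' @export
match_across_samples <- function(query_nr, target_nr_sets, cutoff = 100,
                                 best_hit_only = FALSE,
                                 engine = align_global) {
  check_nr(query_nr, "query")
  if (is.null(names(target_nr_sets)) || any(!nzchar(names(target_nr_sets)))) {
    stop("target_nr_sets must be a named list", call. = FALSE)
  }
  for (t in names(target_nr_sets)) check_nr(target_nr_sets[[t]], t)
  out <- data.frame(query_id = query_nr$id,
                    self_copies = as.integer(query_nr$frequency),
                    stringsAsFactors = FALSE)
  for (t in names(target_nr_sets)) {
    tgt <- target_nr_sets[[t]]
    out[[t]] <- vapply(query_nr$sequence, function(q) {
      if (nrow(tgt) == 0) return(0L)
      alns <- lapply(tgt$sequence, engine, a = q)
      sims <- vapply(alns, alignment_similarity, 0)
      hit <- !is.na(sims) & sims >= cutoff
      if (!any(hit)) return(0L)
      if (best_hit_only) {
        spans <- vapply(alns, alignment_span, 0)
        ord <- order(-sims, -spans, tgt$id)
        ord <- ord[hit[ord]][1]
        as.integer(tgt$frequency[ord])
      } else {
        as.integer(sum(tgt$frequency[hit]))
      }
    }, 0L, USE.NAMES = FALSE)
  }
  out
}

check_nr <- function(x, label) {
  if (!is.data.frame(x) || !all(c("id", "sequence", "frequency") %in% names(x))) {
    stop(sprintf(
      "non-redundant set '%s' must have columns id, sequence, frequency",
      label), call. = FALSE)
  }
  invisible(x)
}

#' Write the cross-sample overlap table
#'
#' Tab-separated output: query id, copy number in the query's own sample,
#' then one copy-number column per target sample in configured order. An
#' empty query set yields a header-only file.
#'
#' @param rows a [match_across_samples()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_overlap_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
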