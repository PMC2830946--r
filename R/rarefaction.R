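#' Pairwise genetic distance matrix of non-redundant sequences
#'
#' Distances are `1 - similarity/100` under the gap-excluded similarity of
#' [pair_similarity()] when the internal engine is used; pairs with no
#' gap-free aligned column (undefined similarity) get distance 1. An
#' external distance engine can be substituted as a function
#' `(a, b) -> distance`, whose values are passed through untransformed.
#'
#' @param sequences named character vector of unique sequences (>= 2), or a
#'   non-redundant `data.frame` as from [read_nr_fasta()].
#' @param engine `"internal"` or a function `(a, b) -> distance in [0, 1]`.
#' @return A symmetric numeric matrix with zero diagonal and sequence ids as
#'   dimnames.
#' @export
pairwise_distances <- function(sequences, engine = "internal") {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$id)
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  n <- length(sequences)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  dfun <- if (is.function(engine)) engine else function(a, b) {
    s <- pair_similarity(a, b)
    if (is.na(s)) 1 else 1 - s / 100
  }
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- dfun(sequences[[i]], sequences[[j]])
    }
  }
  d
}

#' Write clustering-tool input files (distance + names)
#'
#' Writes the pairwise distances in column format (`idA idB distance`, one
#' lower-triangle pair per line) together with a names file mapping each
#' representative id to a comma-joined list of replicate ids. A sequence of
#' frequency `f` expands to itself plus `f - 1` synthetic `_dupN` ids, so a
#' downstream clustering tool weights abundances correctly.
#'
#' @param d distance matrix from [pairwise_distances()].
#' @param frequencies named integer vector (id -> copy number) covering all
#'   ids in `d`.
#' @param dir output directory (created if missing).
#' @param prefix basename for the two files (`<prefix>.dist`,
#'   `<prefix>.names`).
#' @param format `"column"` (pairwise lines) or `"phylip"` (square matrix).
#' @return Character vector with the two file paths, invisibly.
#' @export
write_mothur_inputs <- function(d, frequencies, dir, prefix = "sample",
                                format = c("column", "phylip")) {
  format <- match.arg(format)
  ids <- rownames(d)
  if (!all(ids %in% names(frequencies))) {
    stop("frequencies missing for some ids", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dist_path <- file.path(dir, paste0(prefix, ".dist"))
  names_path <- file.path(dir, paste0(prefix, ".names"))
  if (format == "column") {
    lines <- character(0)
    if (length(ids) >= 2) {
      pairs <- which(lower.tri(d), arr.ind = TRUE)
      lines <- sprintf("%s %s %s", ids[pairs[, "row"]], ids[pairs[, "col"]],
                       format(d[pairs], trim = TRUE))
    }
    writeLines(lines, dist_path)
  } else {
    con <- file(dist_path, "w")
    writeLines(sprintf("%d", length(ids)), con)
    for (i in seq_along(ids)) {
      writeLines(paste(c(ids[i], format(d[i, ], trim = TRUE)), collapse = "\t"),
                 con)
    }
    close(con)
  }
  expand <- vapply(ids, function(id) {
    f <- as.integer(frequencies[[id]])
    reps <- if (f > 1) c(id, paste0(id, "_dup", seq_len(f - 1))) else id
    paste(reps, collapse = ",")
  }, "")
  writeLines(paste(ids, expand, sep = "\t"), names_path)
  invisible(c(dist_path, names_path))
}

#' Group sequences at a similarity cutoff
#'
#' Single-linkage grouping: two sequences belong to the same group when they
#' are connected by a chain of pairs whose gap-excluded similarity is at
#' least `cutoff` percent. Group abundances are the summed frequencies of
#' their members; at a cutoff of 100 this pools indel-only variants into one
#' abundance.
#'
#' @param nr non-redundant `data.frame` (`id`, `sequence`, `frequency`).
#' @param cutoff percent similarity cutoff in (0, 100].
#' @param engine alignment function, see [align_global()].
#' @return A `data.frame` with columns `group` (integer id), `members`
#'   (comma-joined ids) and `abundance`, sorted by descending abundance.
#' @export
abundance_groups <- function(nr, cutoff = 100, engine = align_global) {
  check_nr(nr, "abundance input")
  n <- nrow(nr)
  if (n == 0) {
    return(data.frame(group = integer(), members = character(),
                      abundance = integer(), stringsAsFactors = FALSE))
  }
  edges <- matrix(0L, 0, 2)
  if (n >= 2) {
    pr <- t(combn(n, 2))
    sim <- apply(pr, 1, function(ij) {
      pair_similarity(nr$sequence[ij[1]], nr$sequence[ij[2]], engine = engine)
    })
    hit <- !is.na(sim) & sim >= cutoff
    edges <- pr[hit, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership
  comp <- comp[as.character(seq_len(n))]
  agg <- lapply(split(seq_len(n), comp), function(ix) {
    list(members = paste(nr$id[ix], collapse = ","),
         abundance = sum(nr$frequency[ix]))
  })
  out <- data.frame(
    members = vapply(agg, `[[`, "", "members"),
    abundance = vapply(agg, function(a) as.integer(a$abundance), 1L),
    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$members), , drop = FALSE]
  data.frame(group = seq_len(nrow(out)), members = out$members,
             abundance = out$abundance, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write an abundance list for rarefaction software
#'
#' One integer per line: the summed frequency of each sequence group at the
#' similarity cutoff (see [abundance_groups()]), in descending order. The
#' counts sum to the total number of reads behind the non-redundant set.
#'
#' @inheritParams abundance_groups
#' @param path output file path.
#' @return The group table, invisibly.
#' @export
write_abundance_list <- function(nr, cutoff = 100, path,
                                 engine = align_global) {
  groups <- abundance_groups(nr, cutoff, engine)
  writeLines(as.character(groups$abundance), path)
  invisible(groups)
}
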