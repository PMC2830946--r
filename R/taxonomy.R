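#' Load a reference collection for taxonomy assignment
#'
#' A reference collection pairs reference sequences (FASTA; accession is the
#' first header token) with a taxid map giving, for each accession, the
#' taxon identifier used to look up its lineage.
#'
#' @param fasta path to the reference FASTA file.
#' @param taxid_map path to a two-column TSV (`accession`, `taxid`) with a
#'   header line, or a named integer vector.
#' @return A `reference_collection`: list with `sequences` (named character)
#'   and `taxids` (named integer).
#' @export
reference_collection <- function(fasta, taxid_map) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("[[:space:]].*$", "", names(seqs))
  if (is.character(taxid_map) && length(taxid_map) == 1 &&
      file.exists(taxid_map)) {
    tm <- read.table(taxid_map, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    taxids <- setNames(as.integer(tm[[2]]), tm[[1]])
  } else {
    taxids <- setNames(as.integer(taxid_map), names(taxid_map))
  }
  missing <- setdiff(ids, names(taxids))
  if (length(missing)) {
    stop("no taxid for reference accession(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(sequences = setNames(as.character(seqs), ids),
                 taxids = taxids[ids]),
            class = "reference_collection")
}

#' Search query sequences against a reference collection
#'
#' Runs a pluggable search provider over the queries and filters hits at the
#' e-value cutoff. The default provider aligns every query against every
#' reference sequence with the internal global aligner; its per-hit
#' statistics are a toy search model, deterministic and adequate for small
#' packaged references: `bitscore` is the alignment score,
#' `percent_identity` the gap-excluded similarity, and `evalue = m * n *
#' 2^-bitscore` (query length x subject length), which decreases
#' monotonically with score. For production-scale searches pass hits from an
#' external engine through [read_hit_table()] instead.
#'
#' @param queries named character vector of query sequences.
#' @param reference a [reference_collection()].
#' @param evalue_cutoff keep hits with `evalue <= evalue_cutoff`.
#' @param provider function `(queries, reference) -> data.frame` of hits
#'   with columns `query_id`, `subject_accession`, `percent_identity`,
#'   `evalue`, `bitscore`, `subject_taxid`.
#' @return A list: `hits` (data frame ordered by query, then ascending
#'   e-value, descending bitscore, accession) and `no_hit` (character vector
#'   of query ids with no hit under the cutoff).
#' @export
search_reference <- function(queries, reference, evalue_cutoff = 1e-3,
                             provider = align_hit_provider) {
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    stop("queries must be a named character vector", call. = FALSE)
  }
  hits <- provider(queries, reference)
  need <- c("query_id", "subject_accession", "percent_identity", "evalue",
            "bitscore", "subject_taxid")
  if (!all(need %in% names(hits))) {
    stop("search provider must return columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  hits <- hits[order(match(hits$query_id, names(queries)), hits$evalue,
                     -hits$bitscore, hits$subject_accession), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, no_hit = setdiff(names(queries), hits$query_id))
}

#' @rdname search_reference
#' @export
align_hit_provider <- function(queries, reference) {
  stopifnot(inherits(reference, "reference_collection"))
  rows <- list()
  for (q in names(queries)) {
    for (acc in names(reference$sequences)) {
      aln <- align_global(queries[[q]], reference$sequences[[acc]])
      sim <- alignment_similarity(aln)
      if (is.na(sim)) next
      rows[[length(rows) + 1]] <- data.frame(
        query_id = q, subject_accession = acc,
        percent_identity = sim,
        evalue = nchar(queries[[q]]) * nchar(reference$sequences[[acc]]) *
          2^(-aln$score),
        bitscore = aln$score,
        subject_taxid = unname(reference$taxids[[acc]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(), subject_accession = character(),
                      percent_identity = numeric(), evalue = numeric(),
                      bitscore = numeric(), subject_taxid = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read tabular search-engine output
#'
#' Reads the classic 12-column tabular alignment format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore) with a 13th subject-taxid column
#' appended, and maps it onto the hit schema used by [search_reference()].
#'
#' @param path path to the tabular file (no header, tab-separated).
#' @return A hit `data.frame` usable via
#'   `search_reference(..., provider = function(q, r) read_hit_table(path))`.
#' @export
read_hit_table <- function(path) {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 13) {
    stop("expected 13 columns (12-column tabular output + subject taxid) in ",
         path, call. = FALSE)
  }
  data.frame(query_id = as.character(tab[[1]]),
             subject_accession = as.character(tab[[2]]),
             percent_identity = as.numeric(tab[[3]]),
             evalue = as.numeric(tab[[11]]),
             bitscore = as.numeric(tab[[12]]),
             subject_taxid = as.integer(tab[[13]]),
             stringsAsFactors = FALSE)
}

#' Read a lineage table
#'
#' Two dialects are supported: a simple 4-column TSV with header
#' (`taxid`, `parent`, `rank`, `name`), and the NCBI taxonomy dump pair
#' (`nodes.dmp`, `names.dmp`, pipe-delimited; scientific names only).
#' The root node is the one whose parent equals itself.
#'
#' @param path path to the 4-column TSV.
#' @param nodes,names_file paths to `nodes.dmp` and `names.dmp`.
#' @return A `lineage_table` data frame with columns `taxid`, `parent`,
#'   `rank`, `name`.
#' @export
read_lineage_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
  need <- c("taxid", "parent", "rank", "name")
  if (!all(need %in% names(tab))) {
    stop("lineage table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lineage_table(tab$taxid, tab$parent, tab$rank, tab$name)
}

#' @rdname read_lineage_table
#' @export
read_ncbi_taxonomy <- function(nodes, names_file) {
  parse_dmp <- function(p) {
    lines <- readLines(p)
    lapply(strsplit(lines, "\t\\|\t?"), function(x) sub("\t\\|$", "", x))
  }
  nd <- parse_dmp(nodes)
  nm <- parse_dmp(names_file)
  nm <- nm[vapply(nm, function(x) length(x) >= 4 &&
                    grepl("scientific name", x[4]), TRUE)]
  name_of <- setNames(vapply(nm, `[`, "", 2), vapply(nm, `[`, "", 1))
  taxid <- as.integer(vapply(nd, `[`, "", 1))
  lineage_table(taxid,
                parent = as.integer(vapply(nd, `[`, "", 2)),
                rank = vapply(nd, `[`, "", 3),
                name = unname(name_of[as.character(taxid)]))
}

#' @rdname read_lineage_table
#' @param taxid,parent,rank,name vectors defining the taxonomy directly.
#' @export
lineage_table <- function(taxid, parent, rank, name) {
  tab <- data.frame(taxid = as.integer(taxid), parent = as.integer(parent),
                    rank = as.character(rank), name = as.character(name),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$taxid)) {
    stop("duplicate taxid in lineage table", call. = FALSE)
  }
  structure(tab, class = c("lineage_table", "data.frame"))
}

#' Resolve the root-to-leaf lineage of a taxon
#'
#' Walks parent pointers from `taxid` to the root (a node whose parent is
#' itself or missing) and returns the path root-first. Unknown taxids and
#' parent-pointer cycles are errors.
#'
#' @param taxid integer taxon id.
#' @param table a [lineage_table()].
#' @return A `lineage` data frame with columns `taxid`, `rank`, `name`,
#'   ordered root to leaf; the leaf name is the taxon's own name.
#' @export
resolve_lineage <- function(taxid, table) {
  stopifnot(inherits(table, "lineage_table"))
  idx <- match(as.integer(taxid), table$taxid)
  if (is.na(idx)) stop("unknown taxid: ", taxid, call. = FALSE)
  path <- integer(0)
  seen <- integer(0)
  while (!is.na(idx)) {
    if (table$taxid[idx] %in% seen) {
      stop("cycle detected in lineage table at taxid ", table$taxid[idx],
           call. = FALSE)
    }
    seen <- c(seen, table$taxid[idx])
    path <- c(idx, path)
    parent <- table$parent[idx]
    if (is.na(parent) || parent == table$taxid[idx]) break
    idx <- match(parent, table$taxid)
    if (is.na(idx)) {
      stop("parent taxid ", parent, " missing from lineage table",
           call. = FALSE)
    }
  }
  structure(data.frame(taxid = table$taxid[path], rank = table$rank[path],
                       name = table$name[path], stringsAsFactors = FALSE),
            class = c("lineage", "data.frame"))
}

lineage_path_string <- function(lineage) {
  paste(lineage$name, collapse = ";")
}

#' Select the best reference hit for one query
#'
#' Implements the documented tie-breaking cascade: (1) keep the hits with
#' the minimal e-value; (2) among those, keep the maximal bitscore (distinct
#' alignments can share a printed e-value); (3) a single survivor is the
#' best hit (`single_best`); (4) otherwise keep the hits whose lineage is
#' deepest -- the most detailed taxonomic classification -- and if one
#' remains (or all tied lineages are identical) resolve as `deepest_path`;
#' (5) with conflicting equal-depth lineages, apply the majority rule per
#' rank from the root down: the deepest rank at which a strict majority of
#' the tied lineages agree wins and the assignment is truncated there
#' (`majority_rule`); (6) no strict majority at the first rank leaves the
#' tie `unresolved` and the first hit by accession order is reported,
#' flagged. Hits whose taxid cannot be resolved are excluded with a
#' warning; if none remain the query has no assignment (`NULL`).
#'
#' @param hits `data.frame` of hits for one query (see [search_reference()]).
#' @param table a [lineage_table()].
#' @return A `taxonomy_assignment`: list with `query_id`, `hit` (chosen hit
#'   row), `lineage`, `tie_count` (hits tied on e-value and bitscore) and
#'   `resolved_by`; or `NULL` when no hit has a resolvable lineage.
#' @export
select_best <- function(hits, table) {
  stopifnot(is.data.frame(hits), nrow(hits) >= 1)
  if (length(unique(hits$query_id)) != 1) {
    stop("select_best expects hits of a single query", call. = FALSE)
  }
  h <- hits[hits$evalue == min(hits$evalue), , drop = FALSE]
  h <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
  h <- h[order(h$subject_accession), , drop = FALSE]
  lin <- lapply(h$subject_taxid, function(tx) {
    tryCatch(resolve_lineage(tx, table), error = function(e) NULL)
  })
  bad <- vapply(lin, is.null, TRUE)
  if (any(bad)) {
    warning("lineage unavailable for taxid(s): ",
            paste(unique(h$subject_taxid[bad]), collapse = ", "),
            call. = FALSE)
    h <- h[!bad, , drop = FALSE]
    lin <- lin[!bad]
  }
  if (nrow(h) == 0) return(NULL)
  tie_count <- nrow(h)
  mk <- function(i, lineage, how) {
    structure(list(query_id = h$query_id[i], hit = h[i, , drop = FALSE],
                   lineage = lineage, tie_count = tie_count,
                   resolved_by = how),
              class = "taxonomy_assignment")
  }
  if (nrow(h) == 1) return(mk(1, lin[[1]], "single_best"))

  depth <- vapply(lin, nrow, 1L)
  deepest <- depth == max(depth)
  h <- h[deepest, , drop = FALSE]
  lin <- lin[deepest]
  keys <- vapply(lin, function(l) paste(l$rank, l$name, sep = ":", collapse = "|"), "")
  if (sum(deepest) == 1 || length(unique(keys)) == 1) {
    return(mk(1, lin[[1]], "deepest_path"))
  }

  # majority rule over the tied set, from the root down: at depth l, a
  # length-l prefix shared by a strict majority of the k tied lineages wins;
  # the deepest winning depth is the truncation point. The reported lineage
  # is therefore a prefix of more than half of the tied lineages.
  k <- nrow(h)
  d <- max(vapply(lin, nrow, 1L))
  agreed <- 0L
  winner_idx <- 1L
  for (lvl in seq_len(d)) {
    pre <- vapply(lin, function(l) {
      if (nrow(l) < lvl) return(NA_character_)
      paste(l$rank[seq_len(lvl)], l$name[seq_len(lvl)],
            sep = ":", collapse = "|")
    }, "")
    tab <- table(pre[!is.na(pre)])
    if (length(tab) && max(tab) > k / 2) {
      agreed <- lvl
      winner_idx <- which(pre == names(tab)[which.max(tab)])[1]
    } else {
      break
    }
  }
  if (agreed == 0L) {
    return(mk(1, lin[[1]], "unresolved"))
  }
  mk(winner_idx, lin[[winner_idx]][seq_len(agreed), , drop = FALSE],
     "majority_rule")
}

#' Assign taxonomy to all queries of a search result
#'
#' @param search a [search_reference()] result.
#' @param table a [lineage_table()].
#' @return Named list of `taxonomy_assignment` objects (queries with no hit
#'   are omitted; their ids remain available in `search$no_hit`).
#' @export
assign_taxonomy <- function(search, table) {
  hits <- search$hits
  out <- lapply(split(hits, hits$query_id), select_best, table = table)
  out[!vapply(out, is.null, TRUE)]
}

#' @export
print.taxonomy_assignment <- function(x, ...) {
  cat(sprintf("%s -> %s (%.1f%% identity, e-value %.3g) [%s]\n  %s\n",
              x$query_id, x$hit$subject_accession, x$hit$percent_identity,
              x$hit$evalue, x$resolved_by, lineage_path_string(x$lineage)))
  invisible(x)
}

#' Write the taxonomy assignment table
#'
#' Six tab-separated columns per assignment: query id, percent similarity,
#' e-value, closest reference accession, reference species name (the lineage
#' leaf) and the semicolon-joined taxonomic path. `group` restricts output
#' to assignments whose path contains the given name; `include_flag` appends
#' a seventh column with the tie-resolution state so unresolved assignments
#' are visible.
#'
#' @param assignments list of `taxonomy_assignment` objects
#'   (see [assign_taxonomy()]).
#' @param path output file path.
#' @param group optional taxonomic group filter (exact match against any
#'   path component, e.g. `"Chlorophyta"`).
#' @param include_flag append the `resolved_by` column.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(assignments, path, group = NULL,
                                 include_flag = FALSE) {
  rows <- lapply(assignments, function(a) {
    data.frame(query = a$query_id,
               percent_similarity = a$hit$percent_identity,
               evalue = a$hit$evalue,
               accession = a$hit$subject_accession,
               species_name = a$lineage$name[nrow(a$lineage)],
               taxonomic_path = lineage_path_string(a$lineage),
               resolved_by = a$resolved_by,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), percent_similarity = numeric(),
               evalue = numeric(), accession = character(),
               species_name = character(), taxonomic_path = character(),
               resolved_by = character(), stringsAsFactors = FALSE)
  if (!is.null(group)) {
    keep <- vapply(strsplit(tab$taxonomic_path, ";", fixed = TRUE),
                   function(p) group %in% p, TRUE)
    tab <- tab[keep, , drop = FALSE]
  }
  if (!include_flag) tab$resolved_by <- NULL
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
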