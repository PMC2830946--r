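#' Construct a set of amplicon reads
#'
#' An `amplicon_reads` object holds 454-style reads: one identifier, one DNA
#' sequence and one vector of per-base quality scores per read. Sequences are
#' uppercase-normalised on construction; `N` is the only ambiguity code kept,
#' any other non-`ACGT` letter is converted to `N` with a warning.
#'
#' @param id character vector of read identifiers (no whitespace).
#' @param sequence character vector of DNA sequences, same length as `id`.
#' @param qualities list of integer vectors (phred-like, 0-60), one per read,
#'   each as long as the corresponding sequence.
#' @return An `amplicon_reads` object: a list with elements `id`, `sequence`
#'   and `qualities`.
#' @examples
#' reads <- amplicon_reads("r1", "acgtn", list(c(30L, 31L, 32L, 33L, 10L)))
#' reads$sequence
#' @export
amplicon_reads <- function(id, sequence, qualities) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != length(id)) {
    stop("'id' and 'sequence' must have the same length", call. = FALSE)
  }
  if (!is.list(qualities) || length(qualities) != length(id)) {
    stop("'qualities' must be a list with one vector per read", call. = FALSE)
  }
  if (any(grepl("[[:space:]]", id))) {
    stop("read identifiers must not contain whitespace", call. = FALSE)
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequences are not allowed: ",
         paste(id[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", sequence))) {
    warning("non-ACGTN letters converted to N", call. = FALSE)
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  qualities <- lapply(qualities, function(q) as.integer(q))
  bad <- which(vapply(qualities, length, 1L) != nchar(sequence))
  if (length(bad)) {
    stop("sequence/quality length mismatch for read(s): ",
         paste(id[bad], collapse = ", "), call. = FALSE)
  }
  rng <- range(c(0L, unlist(qualities, use.names = FALSE)))
  if (rng[1] < 0L || rng[2] > 60L) {
    stop("quality values must be integers in [0, 60]", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, qualities = qualities),
            class = "amplicon_reads")
}

#' @export
length.amplicon_reads <- function(x) length(x$id)

#' @export
`[.amplicon_reads` <- function(x, i) {
  structure(list(id = x$id[i], sequence = x$sequence[i],
                 qualities = x$qualities[i]),
            class = "amplicon_reads")
}

#' @export
c.amplicon_reads <- function(...) {
  parts <- list(...)
  structure(list(
    id = unlist(lapply(parts, `[[`, "id"), use.names = FALSE),
    sequence = unlist(lapply(parts, `[[`, "sequence"), use.names = FALSE),
    qualities = do.call(c, lapply(parts, `[[`, "qualities"))
  ), class = "amplicon_reads")
}

#' @export
print.amplicon_reads <- function(x, ...) {
  n <- length(x)
  cat(sprintf("amplicon_reads: %d read%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    lens <- nchar(x$sequence)
    cat(sprintf("  length range: %d-%d bp\n", min(lens), max(lens)))
    show <- seq_len(min(3L, n))
    for (i in show) {
      s <- x$sequence[i]
      cat(sprintf("  %s  %s%s\n", x$id[i],
                  substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
    }
    if (n > 3L) cat("  ...\n")
  }
  invisible(x)
}

#' Read a FASTA file and its parallel .qual file as paired reads
#'
#' The 454 platform emits sequences as FASTA plus a `.qual` file with
#' FASTA-style headers and whitespace-separated integer quality scores.
#' Pairing is strict: records must appear in the same order with identical
#' identifiers in both files, and every record's quality vector must match
#' its sequence length; any violation is an error naming the offending
#' record.
#'
#' @param fasta path to the FASTA file.
#' @param qual path to the matching `.qual` file.
#' @return An [amplicon_reads] object.
#' @export
read_paired_fasta_qual <- function(fasta, qual) {
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta, call. = FALSE)
  if (!file.exists(qual)) stop(".qual file not found: ", qual, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("[[:space:]].*$", "", names(seqs))
  q <- read_qual_records(qual)
  if (length(q$id) != length(ids)) {
    stop(sprintf("FASTA has %d records but .qual has %d",
                 length(ids), length(q$id)), call. = FALSE)
  }
  mism <- which(ids != q$id)
  if (length(mism)) {
    stop(sprintf("FASTA/.qual identifier mismatch at record %d: '%s' vs '%s'",
                 mism[1], ids[mism[1]], q$id[mism[1]]), call. = FALSE)
  }
  amplicon_reads(ids, as.character(seqs), q$qualities)
}

read_qual_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1]) {
    stop("malformed .qual file (does not start with '>'): ", path,
         call. = FALSE)
  }
  rec <- cumsum(hdr)
  ids <- sub("[[:space:]].*$", "", sub("^>", "", lines[hdr]))
  quals <- lapply(split(lines[!hdr], rec[!hdr]), function(x) {
    as.integer(strsplit(paste(x, collapse = " "), "[[:space:]]+")[[1]])
  })
  # records with no body lines (possible for trailing truncation) -> integer(0)
  out <- rep(list(integer(0)), length(ids))
  out[as.integer(names(quals))] <- quals
  list(id = ids, qualities = out)
}

#' Write reads as FASTA / .qual files
#'
#' Sequences are written one per line (unwrapped); qualities as
#' space-separated integers under a matching FASTA-style header. A read set
#' written with both functions round-trips through
#' [read_paired_fasta_qual()].
#'
#' @param reads an [amplicon_reads] object (may be empty).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  stopifnot(inherits(reads, "amplicon_reads"))
  if (length(reads) == 0) {
    writeLines(character(0), path)
  } else {
    writeLines(paste0(">", reads$id, "\n", reads$sequence), path, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_qual <- function(reads, path) {
  stopifnot(inherits(reads, "amplicon_reads"))
  if (length(reads) == 0) {
    writeLines(character(0), path)
  } else {
    body <- vapply(reads$qualities, paste, "", collapse = " ")
    writeLines(paste0(">", reads$id, "\n", body), path, sep = "\n")
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over `ACGTN`.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}
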