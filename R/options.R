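#' Pipeline configuration
#'
#' Collects every user parameter shared by the pipeline stages. All stages of
#' the package read their settings from one of these objects, normally built
#' from an options file via [parse_options()].
#'
#' @param adapter_b adapter-B sequence expected at the 3' end of each read.
#' @param forward_primer,reverse_primer PCR primer sequences (5'->3' on their
#'   own strands); the reverse primer is located on the read as its reverse
#'   complement unless `reverse_primer_literal` is `TRUE`.
#' @param min_length,max_length inclusive length window (bp) applied to the
#'   adapter- and barcode-stripped read (primers still attached).
#' @param barcodes named character vector mapping sample name to barcode
#'   sequence; empty means single-sample mode (demultiplexing skipped).
#' @param adapter_max_mismatch_fraction tolerated mismatch fraction when
#'   locating adapter B (mismatches <= ceiling(fraction x matched length)).
#' @param min_mean_quality reads whose mean target-region quality is strictly
#'   below this are discarded.
#' @param min_copy_number pooled copy-number threshold for the low-frequency
#'   filter; 1 disables it.
#' @param boundary_window width (bp) of the target window adjacent to the
#'   forward primer used for the homopolymer boundary filter.
#' @param boundary_mismatch_threshold reads with fewer than this many
#'   mismatches between the boundary consensus and their +1 or -1 offset
#'   window are discarded.
#' @param similarity_cutoff percent similarity used when grouping sequences
#'   across samples or for abundance lists.
#' @param seed integer seed (used by the read simulator only).
#' @param reverse_primer_literal match the reverse primer in literal
#'   orientation at the 3' end instead of reverse-complemented.
#' @param boundary_both_junctions also apply the boundary filter at the
#'   reverse primer/target junction.
#' @param exempt_exact_boundary exempt reads whose zero-offset window equals
#'   the boundary consensus exactly (tandem-repeat false-positive
#'   mitigation).
#' @return A validated `pipeline_config` object.
#' @seealso [parse_options()], [run_pipeline()]
#' @export
pipeline_config <- function(adapter_b,
                            forward_primer,
                            reverse_primer,
                            min_length,
                            max_length,
                            barcodes = character(),
                            adapter_max_mismatch_fraction = 0.1,
                            min_mean_quality = 20,
                            min_copy_number = 2L,
                            boundary_window = 8L,
                            boundary_mismatch_threshold = 3L,
                            similarity_cutoff = 100,
                            seed = 1L,
                            reverse_primer_literal = FALSE,
                            boundary_both_junctions = FALSE,
                            exempt_exact_boundary = FALSE) {
  cfg <- structure(list(
    adapter_b = toupper(adapter_b),
    forward_primer = toupper(forward_primer),
    reverse_primer = toupper(reverse_primer),
    min_length = as.integer(min_length),
    max_length = as.integer(max_length),
    barcodes = setNames(toupper(as.character(barcodes)), names(barcodes)),
    adapter_max_mismatch_fraction = as.numeric(adapter_max_mismatch_fraction),
    min_mean_quality = as.numeric(min_mean_quality),
    min_copy_number = as.integer(min_copy_number),
    boundary_window = as.integer(boundary_window),
    boundary_mismatch_threshold = as.integer(boundary_mismatch_threshold),
    similarity_cutoff = as.numeric(similarity_cutoff),
    seed = as.integer(seed),
    reverse_primer_literal = isTRUE(reverse_primer_literal),
    boundary_both_junctions = isTRUE(boundary_both_junctions),
    exempt_exact_boundary = isTRUE(exempt_exact_boundary)
  ), class = "pipeline_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  fail <- function(key, msg) {
    stop(sprintf("invalid configuration: %s (%s)", key, msg), call. = FALSE)
  }
  for (key in c("adapter_b", "forward_primer", "reverse_primer")) {
    v <- cfg[[key]]
    if (length(v) != 1 || is.na(v) || !nzchar(v) || grepl("[^ACGT]", v)) {
      fail(key, "must be a non-empty DNA sequence over ACGT")
    }
  }
  if (is.na(cfg$min_length) || is.na(cfg$max_length) ||
      cfg$min_length < 1L || cfg$max_length < 1L) {
    fail("min_length/max_length", "must be positive integers")
  }
  if (cfg$min_length > cfg$max_length) {
    fail("min_length", "must not exceed max_length")
  }
  if (length(cfg$barcodes)) {
    if (is.null(names(cfg$barcodes)) || any(!nzchar(names(cfg$barcodes)))) {
      fail("barcodes", "every barcode needs a sample name")
    }
    if (anyDuplicated(names(cfg$barcodes))) {
      fail("barcodes", "duplicate sample names")
    }
    if (anyDuplicated(cfg$barcodes)) fail("barcodes", "duplicate barcode sequences")
    if (any(grepl("[^ACGT]", cfg$barcodes))) fail("barcodes", "must be DNA over ACGT")
    if (length(unique(nchar(cfg$barcodes))) != 1L) {
      fail("barcodes", "must all have equal length")
    }
  }
  if (is.na(cfg$adapter_max_mismatch_fraction) ||
      cfg$adapter_max_mismatch_fraction < 0 ||
      cfg$adapter_max_mismatch_fraction > 1) {
    fail("adapter_max_mismatch_fraction", "must lie in [0, 1]")
  }
  if (is.na(cfg$min_mean_quality) || cfg$min_mean_quality < 0) {
    fail("min_mean_quality", "must be non-negative")
  }
  if (is.na(cfg$min_copy_number) || cfg$min_copy_number < 1L) {
    fail("min_copy_number", "must be an integer >= 1")
  }
  if (is.na(cfg$boundary_window) || cfg$boundary_window < 1L) {
    fail("boundary_window", "must be a positive integer")
  }
  if (is.na(cfg$boundary_mismatch_threshold) ||
      cfg$boundary_mismatch_threshold < 0L) {
    fail("boundary_mismatch_threshold", "must be a non-negative integer")
  }
  if (is.na(cfg$similarity_cutoff) || cfg$similarity_cutoff <= 0 ||
      cfg$similarity_cutoff > 100) {
    fail("similarity_cutoff", "must lie in (0, 100]")
  }
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  cat(sprintf("  adapter B            : %s (mismatch fraction %.2f)\n",
              x$adapter_b, x$adapter_max_mismatch_fraction))
  cat(sprintf("  primers (fwd / rev)  : %s / %s%s\n", x$forward_primer,
              x$reverse_primer,
              if (x$reverse_primer_literal) " [literal 3' match]" else ""))
  if (length(x$barcodes)) {
    cat(sprintf("  samples              : %s\n",
                paste(sprintf("%s=%s", names(x$barcodes), x$barcodes),
                      collapse = ", ")))
  } else {
    cat("  samples              : single-sample mode (no barcodes)\n")
  }
  cat(sprintf("  length window        : [%d, %d] bp\n", x$min_length, x$max_length))
  cat(sprintf("  min mean quality     : %g\n", x$min_mean_quality))
  cat(sprintf("  min copy number      : %d\n", x$min_copy_number))
  cat(sprintf("  boundary filter      : %d bp window, < %d mismatches\n",
              x$boundary_window, x$boundary_mismatch_threshold))
  cat(sprintf("  similarity cutoff    : %g%%\n", x$similarity_cutoff))
  invisible(x)
}

# documented option-file vocabulary: KEY = (required, parser)
option_keys <- function() {
  int1 <- function(x) as.integer(x)
  num1 <- function(x) as.numeric(x)
  chr1 <- function(x) toupper(trimws(x))
  lgl1 <- function(x) toupper(trimws(x)) %in% c("TRUE", "T", "YES", "1")
  list(
    ADAPTER_B = list(TRUE, chr1, "adapter_b"),
    FORWARD_PRIMER = list(TRUE, chr1, "forward_primer"),
    REVERSE_PRIMER = list(TRUE, chr1, "reverse_primer"),
    MIN_LEN = list(TRUE, int1, "min_length"),
    MAX_LEN = list(TRUE, int1, "max_length"),
    ADAPTER_MAX_MISMATCH_FRACTION = list(FALSE, num1, "adapter_max_mismatch_fraction"),
    MIN_MEAN_QUALITY = list(FALSE, num1, "min_mean_quality"),
    MIN_COPY_NUMBER = list(FALSE, int1, "min_copy_number"),
    BOUNDARY_WINDOW = list(FALSE, int1, "boundary_window"),
    BOUNDARY_MISMATCH_THRESHOLD = list(FALSE, int1, "boundary_mismatch_threshold"),
    SIMILARITY_CUTOFF = list(FALSE, num1, "similarity_cutoff"),
    SEED = list(FALSE, int1, "seed"),
    REVERSE_PRIMER_LITERAL = list(FALSE, lgl1, "reverse_primer_literal"),
    BOUNDARY_BOTH_JUNCTIONS = list(FALSE, lgl1, "boundary_both_junctions"),
    EXEMPT_EXACT_BOUNDARY = list(FALSE, lgl1, "exempt_exact_boundary")
  )
}

#' Parse an options file into a pipeline configuration
#'
#' The options file is plain text with one `KEY=value` entry per line; `#`
#' starts a comment and keys are case-insensitive. Barcodes are given as
#' `BARCODE_<sample>=<sequence>`, one line per sample (omit them for
#' single-sample data). Required keys are `ADAPTER_B`, `FORWARD_PRIMER`,
#' `REVERSE_PRIMER`, `MIN_LEN` and `MAX_LEN`; all other keys fall back to the
#' defaults of [pipeline_config()]. Unknown keys produce a warning, missing
#' required keys an error naming the key.
#'
#' @param path path to the options file.
#' @return A validated [pipeline_config()] object.
#' @examples
#' f <- tempfile()
#' writeLines(c("ADAPTER_B=CTGAGACTGCCAAGGCACAC",
#'              "FORWARD_PRIMER=AACCTGGTTGATCCTGCCAGT",
#'              "REVERSE_PRIMER=TGATCCTTCTGCAGGTTCACCTAC",
#'              "MIN_LEN=100", "MAX_LEN=500",
#'              "BARCODE_S1=ACAGTC  # first sample"), f)
#' parse_options(f)
#' @export
parse_options <- function(path) {
  if (!file.exists(path)) stop("options file not found: ", path, call. = FALSE)
  lines <- sub("#.*$", "", readLines(path))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) {
    stop("malformed options line (expected KEY=value): ", lines[bad][1],
         call. = FALSE)
  }
  key_raw <- trimws(sub("=.*$", "", lines))
  val <- trimws(sub("^[^=]*=", "", lines))
  key <- toupper(key_raw)
  if (anyDuplicated(key)) {
    stop("duplicate option key: ", key[duplicated(key)][1], call. = FALSE)
  }

  is_bc <- grepl("^BARCODE_", key)
  barcodes <- setNames(toupper(val[is_bc]), sub("^[Bb][Aa][Rr][Cc][Oo][Dd][Ee]_", "", key_raw[is_bc]))

  keys <- option_keys()
  known <- key[!is_bc] %in% names(keys)
  if (any(!known)) {
    warning("unknown option key(s) ignored: ",
            paste(key[!is_bc][!known], collapse = ", "), call. = FALSE)
  }
  args <- list(barcodes = barcodes)
  for (k in key[!is_bc][known]) {
    spec <- keys[[k]]
    v <- spec[[2]](val[key == k])
    if (length(v) != 1 || (is.na(v) && !is.logical(v))) {
      stop(sprintf("malformed value for option %s: '%s'", k, val[key == k]),
           call. = FALSE)
    }
    args[[spec[[3]]]] <- v
  }
  required <- names(keys)[vapply(keys, `[[`, TRUE, 1)]
  missing <- setdiff(required, key[!is_bc][known])
  if (length(missing)) {
    stop("missing required option key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, args)
}
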