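# Independent oracles and small fixture builders used across the suite.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a sequence with substitutions and indels (for realistic pairs)
mutate_seq <- function(s, n_sub = 0, n_ins = 0, n_del = 0) {
  x <- strsplit(s, "")[[1]]
  if (n_sub > 0) {
    i <- sample(length(x), n_sub)
    x[i] <- vapply(x[i], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
  }
  for (k in seq_len(n_del)) x <- x[-sample(length(x), 1)]
  for (k in seq_len(n_ins)) {
    at <- sample(length(x) + 1, 1)
    x <- append(x, sample(c("A", "C", "G", "T"), 1), after = at - 1)
  }
  paste(x, collapse = "")
}

make_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs)),
                       qual = 35L) {
  amplicon_reads(ids, seqs, lapply(nchar(seqs), function(n) rep(qual, n)))
}

# pure-R Needleman-Wunsch with linear gaps and the same documented
# deterministic traceback (diagonal, then gap in b, then gap in a)
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- (0:n) * gap
  S[1, ] <- (0:m) * gap
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(
        S[i, j] + if (av[i] == bv[j]) match else mismatch,
        S[i, j + 1] + gap,
        S[i + 1, j] + gap)
    }
  }
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = S[n + 1, m + 1])
}

similarity_oracle <- function(a, b) {
  aln <- nw_oracle(a, b)
  ca <- strsplit(aln$a, "")[[1]]; cb <- strsplit(aln$b, "")[[1]]
  gf <- ca != "-" & cb != "-"
  if (!any(gf)) return(NA_real_)
  100 * sum(ca[gf] == cb[gf]) / sum(gf)
}

hamming_oracle <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force adapter locator mirroring the documented rule
adapter_pos_oracle <- function(seq, adapter, frac) {
  alen <- nchar(adapter)
  L <- nchar(seq)
  for (i in seq_len(L)) {
    mlen <- min(alen, L - i + 1)
    if (mlen < alen && mlen < ceiling(alen / 2)) next
    allowed <- ceiling(frac * mlen - 1e-9)
    mm <- hamming_oracle(substr(seq, i, i + mlen - 1), substr(adapter, 1, mlen))
    if (mm <= allowed) return(i)
  }
  0L
}

toy_lineage <- function() {
  read_lineage_table(system.file("extdata", "toy_lineage.tsv",
                                 package = "ampliclean"))
}

toy_reference <- function() {
  reference_collection(
    system.file("extdata", "toy_reference.fasta", package = "ampliclean"),
    system.file("extdata", "toy_reference_taxids.tsv", package = "ampliclean"))
}

# brute-force re-statement of the best-hit tie-breaking cascade, written as
# plain loops against a lineage *table* (own parent walker, not the package's)
select_best_oracle <- function(hits, tab) {
  walk <- function(tx) {
    path <- list()
    repeat {
      row <- tab[tab$taxid == tx, ]
      if (nrow(row) == 0) return(NULL)
      path <- c(list(c(rank = row$rank, name = row$name)), path)
      if (is.na(row$parent) || row$parent == row$taxid) break
      tx <- row$parent
    }
    path
  }
  h <- hits[hits$evalue == min(hits$evalue), , drop = FALSE]
  h <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
  h <- h[order(h$subject_accession), , drop = FALSE]
  lins <- lapply(h$subject_taxid, walk)
  ok <- !vapply(lins, is.null, TRUE)
  h <- h[ok, , drop = FALSE]; lins <- lins[ok]
  if (nrow(h) == 0) return(NULL)
  path_names <- function(l) vapply(l, function(x) x[["name"]], "")
  path_key <- function(l) paste(vapply(l, paste, "", collapse = ":"),
                                collapse = "|")
  if (nrow(h) == 1) {
    return(list(accession = h$subject_accession[1],
                names = path_names(lins[[1]]), resolved_by = "single_best"))
  }
  depth <- vapply(lins, length, 1L)
  keep <- depth == max(depth)
  h <- h[keep, , drop = FALSE]; lins <- lins[keep]
  if (nrow(h) == 1 || length(unique(vapply(lins, path_key, ""))) == 1) {
    return(list(accession = h$subject_accession[1],
                names = path_names(lins[[1]]), resolved_by = "deepest_path"))
  }
  k <- nrow(h)
  best_lvl <- 0L; best_i <- 1L
  for (lvl in seq_len(max(depth))) {
    keys <- vapply(lins, function(l) path_key(l[seq_len(lvl)]), "")
    counts <- table(keys)
    if (max(counts) > k / 2) {
      best_lvl <- lvl
      best_i <- which(keys == names(counts)[which.max(counts)])[1]
    } else break
  }
  if (best_lvl == 0L) {
    return(list(accession = h$subject_accession[1],
                names = path_names(lins[[1]]), resolved_by = "unresolved"))
  }
  list(accession = h$subject_accession[best_i],
       names = path_names(lins[[best_i]][seq_len(best_lvl)]),
       resolved_by = "majority_rule")
}
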