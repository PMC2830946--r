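test_that("lineages resolve root-to-leaf from the toy table", {
  lt <- toy_lineage()
  lin <- resolve_lineage(13, lt)
  expect_equal(lin$name, c("Root", "Eukaryota", "Chlorophyta",
                           "Chlorophyceae", "Chlamydomonas",
                           "Chlamydomonas_reinhardtii"))
  expect_equal(nrow(resolve_lineage(1, lt)), 1L)  # root taxon
  expect_equal(nrow(resolve_lineage(31, lt)), 4L) # shallower branch
  expect_error(resolve_lineage(999, lt), "unknown taxid")

  cyc <- lineage_table(c(1, 2, 3), c(3, 1, 2), c("a", "b", "c"),
                       c("A", "B", "C"))
  expect_error(resolve_lineage(3, cyc), "cycle")
})

test_that("the NCBI dump dialect parses to the same structure", {
  nodes <- tempfile(); nms <- tempfile()
  writeLines(c("1\t|\t1\t|\troot\t|",
               "2\t|\t1\t|\tsuperkingdom\t|",
               "10\t|\t2\t|\tphylum\t|"), nodes)
  writeLines(c("1\t|\tRoot\t|\t\t|\tscientific name\t|",
               "1\t|\tall\t|\t\t|\tsynonym\t|",
               "2\t|\tEukaryota\t|\t\t|\tscientific name\t|",
               "10\t|\tChlorophyta\t|\t\t|\tscientific name\t|"), nms)
  lt <- read_ncbi_taxonomy(nodes, nms)
  lin <- resolve_lineage(10, lt)
  expect_equal(lin$name, c("Root", "Eukaryota", "Chlorophyta"))
  expect_equal(lin$rank, c("root", "superkingdom", "phylum"))
})

test_that("reference search finds identical sequences at 100% identity", {
  ref <- toy_reference()
  q <- c(hit1 = unname(ref$sequences[["REF001"]]),
         none = random_seq(120))
  set.seed(1)
  sr <- search_reference(q, ref, evalue_cutoff = 1e-6)
  h1 <- sr$hits[sr$hits$query_id == "hit1", ]
  expect_equal(h1$subject_accession[1], "REF001")
  expect_equal(h1$percent_identity[1], 100)
  expect_equal(h1$subject_taxid[1], 13L)
  # hits are ordered by ascending e-value within query
  expect_true(all(diff(h1$evalue) >= 0))
  expect_true("none" %in% sr$no_hit)
})

test_that("best-hit selection follows the documented tie-break cascade", {
  lt <- toy_lineage()
  hit <- function(acc, ev, bs, tx) {
    data.frame(query_id = "q", subject_accession = acc, percent_identity = 99,
               evalue = ev, bitscore = bs, subject_taxid = tx,
               stringsAsFactors = FALSE)
  }
  # single hit
  a <- select_best(hit("REF003", 1e-20, 50, 23), lt)
  expect_equal(a$resolved_by, "single_best")
  expect_equal(a$hit$subject_accession, "REF003")

  # equal e-value, different depth: most detailed classification wins
  a <- select_best(rbind(hit("A1", 1e-20, 50, 31),    # depth 4
                         hit("A2", 1e-20, 50, 13)), lt)  # depth 6
  expect_equal(a$resolved_by, "deepest_path")
  expect_equal(a$hit$subject_accession, "A2")
  expect_equal(a$lineage$name[nrow(a$lineage)], "Chlamydomonas_reinhardtii")

  # lower e-value trumps depth
  a <- select_best(rbind(hit("A1", 1e-30, 60, 31),
                         hit("A2", 1e-20, 50, 13)), lt)
  expect_equal(a$hit$subject_accession, "A1")

  # bitscore is a secondary numeric tie-break before lineage depth
  a <- select_best(rbind(hit("A1", 1e-20, 60, 31),
                         hit("A2", 1e-20, 50, 13)), lt)
  expect_equal(a$hit$subject_accession, "A1")
  expect_equal(a$resolved_by, "single_best")

  # three equal-depth species, two sharing the Chlamydomonas path at species
  # level disagree -> majority rule truncates at the deepest majority rank
  a <- select_best(rbind(hit("A1", 1e-20, 50, 13),
                         hit("A2", 1e-20, 50, 14),
                         hit("A3", 1e-20, 50, 23)), lt)
  expect_equal(a$resolved_by, "majority_rule")
  expect_equal(a$lineage$name[nrow(a$lineage)], "Chlamydomonas")
  expect_equal(a$tie_count, 3L)

  # no strict majority anywhere -> unresolved, first accession reported
  lt2 <- lineage_table(c(1, 2, 3), c(1, 2, 3), c("root", "root", "root"),
                       c("R1", "R2", "R3"))
  a <- select_best(rbind(hit("B2", 1e-10, 40, 2), hit("B1", 1e-10, 40, 1)),
                   lt2)
  expect_equal(a$resolved_by, "unresolved")
  expect_equal(a$hit$subject_accession, "B1")

  # unknown taxid hits are excluded with a warning
  expect_warning(
    a <- select_best(rbind(hit("C1", 1e-10, 40, 13), hit("C2", 1e-10, 40, 999)),
                     lt), "999")
  expect_equal(a$hit$subject_accession, "C1")
  expect_warning(expect_null(select_best(hit("C2", 1e-10, 40, 999), lt)))
})

test_that("the chosen hit always carries the minimal e-value of its query", {
  lt <- toy_lineage()
  set.seed(99)
  taxids <- c(13L, 14L, 15L, 23L, 31L, 40L)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    hits <- data.frame(
      query_id = "q",
      subject_accession = sprintf("ACC%02d", sample(99, k)),
      percent_identity = runif(k, 80, 100),
      evalue = sample(c(1e-30, 1e-20, 1e-10), k, replace = TRUE),
      bitscore = sample(40:60, k, replace = TRUE),
      subject_taxid = sample(taxids, k, replace = TRUE),
      stringsAsFactors = FALSE)
    a <- select_best(hits, lt)
    expect_equal(a$hit$evalue, min(hits$evalue))
  }
})

test_that("the taxonomy table has the six documented columns, filters and flags", {
  ref <- toy_reference()
  lt <- toy_lineage()
  q <- setNames(as.character(ref$sequences[c("REF001", "REF003")]),
                c("S1_NR000001", "S1_NR000002"))
  sr <- search_reference(q, ref, evalue_cutoff = 1e-6)
  asn <- assign_taxonomy(sr, lt)
  f <- tempfile()
  write_taxonomy_table(asn, f)
  tab <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(names(tab), c("query", "percent_similarity", "evalue",
                             "accession", "species_name", "taxonomic_path"))
  expect_equal(nrow(tab), 2L)
  expect_match(tab$taxonomic_path[1], "Chlorophyta")
  expect_true(grepl(";", tab$taxonomic_path[1], fixed = TRUE))

  write_taxonomy_table(asn, f, group = "Ciliophora")
  tab <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(tab$query, "S1_NR000002")

  write_taxonomy_table(asn, f, include_flag = TRUE)
  tab <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(names(tab)[7], "resolved_by")
  expect_true(all(tab$resolved_by == "single_best"))
})
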