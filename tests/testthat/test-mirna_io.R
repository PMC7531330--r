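test_that("read_mature_fasta normalizes, filters and deduplicates", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "mix.fa")
  writeLines(c(">mtr-miR5754 Medicago truncatula",
               "TAUUGCACGG",
               ">hsa-miR-92a-3p",
               "UAUUGCACUCGUCCCGGCCUCC",
               ">eca-unknown-1",
               "ACGUACGUACGU",
               ">dup-x", "AAAA",
               ">dup-x", "aaaa"), fa)
  res <- read_mature_fasta(fa)
  expect_equal(nrow(res), 4L)
  expect_equal(res$sequence[1], "UAUUGCACGG")   # T -> U
  expect_equal(res$species_prefix[1:3], c("mtr", "hsa", "eca"))
  expect_equal(sum(res$id == "dup-x"), 1L)      # identical dup collapsed

  filtered <- read_mature_fasta(fa, taxon_filter = c("hsa", "mtr"))
  expect_equal(filtered$id, c("mtr-miR5754", "hsa-miR-92a-3p"))
})

test_that("read_mature_fasta handles empty files and rejects bad input", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.fa")
  file.create(empty)
  expect_equal(nrow(read_mature_fasta(empty)), 0L)

  conflict <- file.path(dir, "conflict.fa")
  writeLines(c(">a-x", "AAAA", ">a-x", "CCCC"), conflict)
  expect_error(read_mature_fasta(conflict), "conflicting")

  nohyphen <- file.path(dir, "nohyphen.fa")
  writeLines(c(">plainid", "ACGU"), nohyphen)
  expect_error(read_mature_fasta(nohyphen), "species prefix")

  ambiguous <- file.path(dir, "amb.fa")
  writeLines(c(">a-x", "ACGUN"), ambiguous)
  expect_error(read_mature_fasta(ambiguous), "invalid residue")
})

test_that("FASTA round-trip preserves records, including via gzip", {
  dir <- withr::local_tempdir()
  set.seed(42)
  df <- data.frame(id = sprintf("gma-sim-%d", 1:5),
                   species_prefix = "gma",
                   sequence = rand_rna(5),
                   stringsAsFactors = FALSE)
  plain <- file.path(dir, "rt.fa")
  write_mature_fasta(df, plain)
  expect_equal(read_mature_fasta(plain), df)

  gz <- file.path(dir, "rt.fa.gz")
  write_mature_fasta(df, gz)
  expect_equal(read_mature_fasta(gz), df)
})

test_that("sequence normalization is idempotent", {
  set.seed(7)
  seqs <- rand_rna(20)
  expect_identical(normalize_rna(seqs), seqs)
  expect_identical(normalize_rna(normalize_rna(chartr("U", "t", seqs))),
                   seqs)
})

test_that("partition_by_kingdom routes records and counts the unclassified", {
  df <- data.frame(id = c("hsa-x", "gma-y", "eca-z"),
                   species_prefix = c("hsa", "gma", "eca"),
                   sequence = c("ACGUACGU", "ACGUACGU", "ACGUACGU"),
                   stringsAsFactors = FALSE)
  res <- partition_by_kingdom(df)
  expect_equal(res$human$id, "hsa-x")
  expect_equal(res$plant$id, "gma-y")
  expect_equal(res$n_dropped, 1L)
  expect_error(partition_by_kingdom(df, "hsa", c("hsa", "gma")), "disjoint")
})

test_that("interaction table parsing merges duplicates and rejects empty evidence", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "int.tsv")
  writeLines(c("mirna_id\tgene\tevidence",
               "hsa-miR-34a-5p\tTP53\tLuciferase reporter assay|Western blot",
               "hsa-miR-34a-5p\ttp53\tqRT-PCR",
               "hsa-miR-92a-3p\tPTEN\t",
               "hsa-miR-25-3p\tCDKN1A\tMicroarray;Western blot"), path)
  res <- read_interaction_table(path)
  expect_equal(nrow(res), 2L)
  expect_equal(attr(res, "n_rejected"), 1L)
  tp53 <- res[res$gene_symbol == "TP53", ]
  expect_setequal(tp53$evidence[[1]],
                  c("Luciferase reporter assay", "Western blot", "qRT-PCR"))
  expect_error(read_interaction_table({
    p2 <- file.path(dir, "bad.tsv")
    writeLines(c("mirna_id\tgene", "a\tb"), p2)
    p2
  }), "evidence")
})

test_that("count matrix IO validates cells, flags zeros and round-trips groups", {
  dir <- withr::local_tempdir()
  counts <- matrix(c(0L, 5L, 0L, 7L, 0L, 9L), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  counts["g1", ] <- 0L
  path <- file.path(dir, "counts.tsv")
  groups <- c(s1 = "treated", s2 = "control")
  write_count_matrix(counts, path, groups = groups)
  res <- read_count_matrix(path)
  expect_identical(res$counts, counts)
  expect_identical(res$groups, groups)
  expect_identical(unname(res$all_zero), c(TRUE, FALSE, FALSE))

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("gene\ts1\ts2", "g1\t-3\t2"), bad)
  expect_error(read_count_matrix(bad), "row 1")

  sidecar <- file.path(dir, "groups.tsv")
  writeLines(c("sample\tgroup", "s1\ttreated", "s2\tcontrol"), sidecar)
  plain <- file.path(dir, "plain.tsv")
  write_count_matrix(counts, plain)
  res2 <- read_count_matrix(plain, groups_path = sidecar)
  expect_identical(res2$groups, groups)
})

test_that("GMT reader uppercases, deduplicates and validates lines", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  writeLines(c("S1\tdesc\ta\tB", "S2\tdesc\tX\tx\tY"), path)
  sets <- read_gene_sets(path)
  expect_equal(sets$S1, c("A", "B"))
  expect_equal(sets$S2, c("X", "Y"))

  empty <- file.path(dir, "empty.gmt")
  file.create(empty)
  expect_length(read_gene_sets(empty), 0L)

  bad <- file.path(dir, "bad.gmt")
  writeLines("S1\tonly-two", bad)
  expect_error(read_gene_sets(bad), "line 1")
})
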