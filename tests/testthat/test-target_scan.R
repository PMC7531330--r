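test_that("perfect reverse-complement window scores the hand-computed sum", {
  withr::with_seed(21, {
    mir <- rand_rna(1, 21L)
  })
  window <- reverse_complement(mir)
  p <- scan_params()
  res <- align_complementarity(mir, window, p)
  # 7 seed positions (2-8) at wc_reward * seed_scale, 14 others at wc_reward
  expect_equal(res$score, 7 * p$wc_reward * p$seed_scale + 14 * p$wc_reward)
  expect_equal(res$alignment[2], strrep("|", 21))
  expect_equal(c(res$w_start, res$w_end), c(1L, 21L))
  expect_equal(c(res$m_start, res$m_end), c(1L, 21L))
})

test_that("non-pairable input yields a zero-score empty alignment", {
  res <- align_complementarity(strrep("A", 21), strrep("A", 30))
  expect_equal(res$score, 0)
  expect_equal(res$alignment, c("", "", ""))
})

test_that("a single wobble lowers the score by the reward difference", {
  mir <- "ACGUACGUACGUACGGACGUA"           # position 15 is G
  window <- reverse_complement(mir)        # window position 7 pairs it (C)
  p <- scan_params()
  base <- align_complementarity(mir, window, p)$score
  wob <- window
  substr(wob, 7, 7) <- "U"                 # G:C -> G:U outside the seed span
  res <- align_complementarity(mir, wob, p)
  expect_equal(res$score, base - (p$wc_reward - p$wobble_reward))
  expect_equal(substr(res$alignment[2], 7, 7), ":")
})

test_that("duplex_mfe reproduces the hand-summed GC helix and the sentinel", {
  nn <- nn_table("turner2004")
  expected <- nn$duplex_init +
    nn$stack["GC", "CG"] + nn$stack["CG", "GC"] + nn$stack["GC", "CG"] +
    nn$stack["CG", "GC"] + nn$stack["GC", "CG"]
  expect_equal(duplex_mfe("GCGCGC", "GCGCGC"), expected)
  expect_true(is.na(duplex_mfe("AAAA", "AAAA")))
})

test_that("duplex_mfe equals exhaustive structure enumeration on short strands", {
  withr::with_seed(33, {
    for (rep in 1:30) {
      s1 <- paste(sample(c("A", "C", "G", "U"), sample(2:9, 1), replace = TRUE),
                  collapse = "")
      s2 <- paste(sample(c("A", "C", "G", "U"), sample(2:9, 1), replace = TRUE),
                  collapse = "")
      expect_equal(duplex_mfe(s1, s2), oracle_duplex_mfe(s1, s2),
                   info = paste(s1, s2))
    }
  })
})

test_that("duplex_mfe is strand-exchange symmetric", {
  withr::with_seed(34, {
    for (rep in 1:15) {
      s <- rand_rna(2, c(4L, 12L))
      expect_equal(duplex_mfe(s[1], s[2]), duplex_mfe(s[2], s[1]))
    }
  })
})

test_that("extending a helix by a terminal complementary pair never raises the MFE", {
  withr::with_seed(35, {
    for (rep in 1:10) {
      s1 <- rand_rna(1, c(5L, 8L))
      s2 <- reverse_complement(s1)
      x <- sample(c("A", "C", "G", "U"), 1)
      y <- chartr("ACGU", "UGCA", x)
      e0 <- duplex_mfe(s1, s2)
      e1 <- duplex_mfe(paste0(s1, x), paste0(y, s2))
      expect_lte(e1, e0)
    }
  })
})

test_that("both packaged nearest-neighbor tables load and agree on stacks", {
  t04 <- nn_table("turner2004")
  t99 <- nn_table("turner1999")
  expect_equal(dim(t04$stack), c(6L, 6L))
  expect_equal(t04$stack["GC", "GC"], -3.3)   # 5'GG3'/3'CC5'
  expect_equal(t99$ninio_m, 0.5)
  expect_equal(t04$duplex_init, 4.1)
  # strand-exchange symmetry of the stack table itself
  rev2 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (p1 in rownames(t04$stack)) for (p2 in colnames(t04$stack)) {
    expect_equal(t04$stack[p1, p2], t04$stack[rev2(p2), rev2(p1)])
  }
})

test_that("scan_transcript recovers planted sites at their coordinates", {
  withr::with_seed(55, {
    mir <- data.frame(id = "gma-sim-1", species_prefix = "gma",
                      sequence = rand_rna(1, 21L), stringsAsFactors = FALSE)
  })
  stringent <- scan_params(score_threshold = 180)
  sim <- gen_transcript_with_sites(mir, data.frame(mirna_id = "gma-sim-1",
                                                   start = 101L),
                                   length = 200L, seed = 56)
  sites <- scan_transcript(mir, sim$transcript, stringent)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 101L)
  expect_equal(sites$end, 121L)
  expect_lte(sites$mfe_kcal_mol, 0)

  two <- gen_transcript_with_sites(mir, data.frame(mirna_id = "gma-sim-1",
                                                   start = c(20L, 120L)),
                                   length = 200L, seed = 57)
  sites2 <- scan_transcript(mir, two$transcript, stringent)
  expect_equal(sites2$start, c(20L, 120L))
  expect_false(is.unsorted(sites2$start))
})

test_that("scans without planted complementarity return no sites and are deterministic", {
  withr::with_seed(58, {
    mir <- list(id = "m", sequence = rand_rna(1, 21L))
    none <- gen_transcript_with_sites(
      data.frame(id = "m", sequence = mir$sequence, stringsAsFactors = FALSE),
      sites = NULL, length = 300L, seed = 59)
  })
  stringent <- scan_params(score_threshold = 180)
  s <- scan_transcript(mir, none$transcript, stringent)
  expect_equal(nrow(s), 0L)

  planted <- gen_transcript_with_sites(
    data.frame(id = "m", sequence = mir$sequence, stringsAsFactors = FALSE),
    data.frame(mirna_id = "m", start = 50L), length = 300L, seed = 60)
  a <- scan_transcript(mir, planted$transcript, stringent)
  renamed <- planted$transcript
  renamed$id <- "other-name"
  b <- scan_transcript(mir, renamed, stringent)
  expect_equal(a[setdiff(names(a), "transcript_id")],
               b[setdiff(names(b), "transcript_id")])
})

test_that("scan_params validates its invariants", {
  expect_error(scan_params(gap_open = 1), "gap")
  expect_error(scan_params(seed_scale = 0.5), "seed_scale")
  p <- scan_params(score_threshold = 90, nn_table_id = "turner1999")
  expect_s3_class(p, "xkmir_scan_params")
})
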