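test_that("size factors follow median-of-ratios", {
  m <- cbind(s1 = c(5L, 10L, 20L), s2 = c(5L, 10L, 20L))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = c(2, 4, 8), s2 = c(4, 8, 16))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # scaling one of n samples by c multiplies its factor by c^((n-1)/n)
  # and every other factor by c^(-1/n)
  withr::with_seed(88, {
    m3 <- matrix(rpois(300, 200) + 1L, ncol = 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  })
  f0 <- size_factors(m3)
  m3s <- m3
  m3s[, "b"] <- m3s[, "b"] * 3L
  f1 <- size_factors(m3s)
  expect_equal(f1[["b"]], f0[["b"]] * 3^(2 / 3), tolerance = 1e-9)
  expect_equal(f1[["a"]], f0[["a"]] * 3^(-1 / 3), tolerance = 1e-9)

  expect_error(size_factors(cbind(c(0, 1), c(1, 0))), "all-positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  withr::with_seed(89, {
    m <- matrix(rpois(2000, 150) + 1L, ncol = 4,
                dimnames = list(sprintf("g%d", 1:500), sprintf("s%d", 1:4)))
  })
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("fisher_gene equals hypergeometric enumeration", {
  expect_equal(fisher_gene(0, 0, 100, 100), 1)
  expect_equal(fisher_gene(10, 0, 100, 100), oracle_fisher(10, 0, 100, 100),
               tolerance = 1e-12)
  # row swap (condition exchange) leaves the two-sided p unchanged
  expect_equal(fisher_gene(7, 2, 50, 60), fisher_gene(2, 7, 60, 50))
  withr::with_seed(90, {
    for (rep in 1:40) {
      NT <- sample(5:500, 1)
      NC <- sample(5:500, 1)
      aT <- sample(0:NT, 1)
      aC <- sample(0:NC, 1)
      expect_equal(fisher_gene(aT, aC, NT, NC), oracle_fisher(aT, aC, NT, NC),
                   tolerance = 1e-12,
                   info = sprintf("aT=%d aC=%d NT=%d NC=%d", aT, aC, NT, NC))
    }
  })
  expect_error(fisher_gene(-1, 0, 10, 10), "counts")
})

test_that("bh_adjust applies the step-up formula and preserves order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  withr::with_seed(91, {
    p <- runif(200)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
  })
})

test_that("identical groups produce no significant calls", {
  withr::with_seed(92, {
    half <- matrix(rpois(400, 80) + 1L, ncol = 2)
  })
  counts <- cbind(half, half)
  colnames(counts) <- c("T1", "T2", "C1", "C2")
  rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  groups <- setNames(c("treated", "treated", "control", "control"),
                     colnames(counts))
  res <- call_de(counts, groups)
  expect_equal(res$summary$n_sig, 0L)
  expect_true(all(res$calls$fc == 1))
})

test_that("call_de matches an independent step-by-step recomputation on a toy matrix", {
  counts <- rbind(
    g1 = c(1200L, 1180L, 300L, 310L),   # strong up
    g2 = c(40L, 42L, 170L, 160L),       # strong down
    g3 = c(500L, 510L, 505L, 498L),     # null
    g4 = c(90L, 88L, 92L, 95L),         # null
    g5 = c(12L, 14L, 10L, 11L)          # low counts, null
  )
  colnames(counts) <- c("T1", "T2", "C1", "C2")
  groups <- setNames(c("treated", "treated", "control", "control"),
                     colnames(counts))
  res <- call_de(counts, groups)

  # independent recomputation: factors, pooled tables, enumerated Fisher,
  # hand BH, pseudo-counted fold change
  geo <- exp(rowMeans(log(counts)))
  sf <- apply(counts / geo, 2, median)
  normed <- sweep(counts, 2, sf, "/")
  pooled_t <- rowSums(round(normed[, 1:2]))
  pooled_c <- rowSums(round(normed[, 3:4]))
  NT <- sum(pooled_t); NC <- sum(pooled_c)
  p <- mapply(oracle_fisher, pooled_t, pooled_c, NT, NC)
  q <- oracle_bh(p)
  fc <- (rowMeans(normed[, 1:2]) + 0.5) / (rowMeans(normed[, 3:4]) + 0.5)
  sig <- q <= 0.05 & pmax(fc, 1 / fc) >= 1.5

  expect_equal(res$calls$p, unname(p), tolerance = 1e-12)
  expect_equal(res$calls$q, unname(q), tolerance = 1e-12)
  expect_equal(res$calls$fc, unname(fc), tolerance = 1e-12)
  expect_equal(res$calls$significant, unname(sig))
  expect_setequal(res$calls$gene_id[res$calls$significant], c("g1", "g2"))
  expect_equal(res$calls$direction[1:2], c("up", "down"))
})

test_that("call_de is invariant to sample scalings absorbed by size factors", {
  withr::with_seed(93, {
    counts <- matrix(4L * (rpois(800, 100) + 1L), ncol = 4,
                     dimnames = list(sprintf("g%d", 1:200),
                                     c("T1", "T2", "C1", "C2")))
  })
  groups <- setNames(c("treated", "treated", "control", "control"),
                     colnames(counts))
  scale <- c(2, 0.5, 1, 1)               # product 1: geometric means unchanged
  scaled <- sweep(counts, 2, scale, "*")
  a <- call_de(counts, groups)
  b <- call_de(scaled, groups)
  expect_equal(a$calls, b$calls, tolerance = 1e-12)
})

test_that("planted fold changes are called in the planted direction", {
  sim <- gen_count_matrix(500, c(3L, 3L), lib_size_mean = 2e5,
                          de_frac = 0.1, log2fc = 2, dispersion = 0.1,
                          seed = 42)
  res <- call_de(sim$counts, sim$groups, biotype_map = sim$biotypes)
  planted <- sim$truth$planted_de
  called <- res$calls[res$calls$significant &
                      res$calls$gene_id %in% names(planted), ]
  expect_gt(nrow(called), 0L)
  expect_true(all(
    (called$direction == "up") == (planted[called$gene_id] > 0)))
  # untested genes (all-zero) are excluded from the BH family
  expect_true(all(is.na(res$calls$q[rowSums(sim$counts) == 0])))
})

test_that("biotype proportions are reported over significant calls", {
  sim <- gen_count_matrix(400, c(3L, 3L), lib_size_mean = 2e5,
                          de_frac = 0.2, log2fc = 3, dispersion = 0.01,
                          seed = 43)
  res <- call_de(sim$counts, sim$groups, biotype_map = sim$biotypes)
  props <- unlist(res$summary$biotype_proportions)
  expect_equal(sum(props), 1, tolerance = 1e-6)
  expect_equal(res$summary$n_sig, res$summary$n_up + res$summary$n_down)
})
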