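# Independent brute-force oracles used to validate the package's optimized
# implementations, plus small fixture builders. Oracles deliberately use
# direct enumeration / vectorized full products, never the code paths they
# check.

rand_rna <- function(n, len_range = c(16L, 24L)) {
  if (length(len_range) == 1L) len_range <- rep(len_range, 2L)
  choices <- seq.int(len_range[1], len_range[2])
  lens <- choices[sample.int(length(choices), n, replace = TRUE)]
  vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
  }, character(1))
}

rand_universe <- function(n_h, n_p, len_range = c(16L, 24L)) {
  list(
    humans = data.frame(id = sprintf("hsa-r-%03d", seq_len(n_h)),
                        sequence = rand_rna(n_h, len_range),
                        stringsAsFactors = FALSE),
    plants = data.frame(id = sprintf("gma-r-%03d", seq_len(n_p)),
                        sequence = rand_rna(n_p, len_range),
                        stringsAsFactors = FALSE)
  )
}

# full-Cartesian-product seed comparison by direct substring equality
oracle_match_all <- function(humans, plants) {
  idx <- expand.grid(h = seq_len(nrow(humans)), p = seq_len(nrow(plants)))
  hs <- humans$sequence[idx$h]
  ps <- plants$sequence[idx$p]
  long <- nchar(hs) >= 8L & nchar(ps) >= 8L
  ok7 <- nchar(hs) >= 7L & nchar(ps) >= 7L
  m28 <- long & substr(hs, 2, 8) == substr(ps, 2, 8)
  m27 <- ok7 & substr(hs, 2, 7) == substr(ps, 2, 7) & !m28
  m38 <- long & substr(hs, 3, 8) == substr(ps, 3, 8) & !m28
  any_m <- m28 | m27 | m38
  frames <- character(sum(any_m))
  sub27 <- m27[any_m]; sub38 <- m38[any_m]; sub28 <- m28[any_m]
  frames[sub28] <- "F2_8"
  frames[sub27 & sub38] <- "F2_7,F3_8"
  frames[sub27 & !sub38] <- "F2_7"
  frames[!sub27 & sub38] <- "F3_8"
  out <- data.frame(human_id = humans$id[idx$h[any_m]],
                    plant_id = plants$id[idx$p[any_m]],
                    frames = frames, stringsAsFactors = FALSE)
  out <- out[order(out$human_id, out$plant_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
oracle_fisher <- function(aT, aC, NT, NC) {
  S <- aT + aC
  if (S == 0) return(1)
  xs <- max(0, S - NC):min(S, NT)
  probs <- stats::dhyper(xs, NT, NC, S)
  p_obs <- stats::dhyper(aT, NT, NC, S)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-applied Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# exhaustive upper-tail hypergeometric by combinatorial enumeration
oracle_hyper_tail <- function(k, K, N, n) {
  xs <- max(0, n - (N - K)):min(K, n)
  xs <- xs[xs >= k]
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# exhaustive duplex structure enumeration under the same nearest-neighbor
# parameter data, independent of the DP
oracle_duplex_mfe <- function(s1, s2, nn_id = "turner2004") {
  nn <- xkmir::nn_table(nn_id)
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  allowed <- c("AU", "UA", "CG", "GC", "GU", "UG")
  closing <- c("AU", "UA", "GU", "UG")
  n1 <- length(a); n2 <- length(b)
  pr <- function(i, j) paste0(a[i], b[j])
  term <- function(p) if (p %in% closing) nn$terminal_au else 0
  loop_e <- function(p1, p2, l1, l2) {
    if (l1 == 0 && l2 == 0) return(nn$stack[p1, p2])
    s <- l1 + l2
    if (s > 30) return(Inf)
    if (l1 == 0 || l2 == 0) {
      return(nn$bulge[s] + if (s == 1) nn$stack[p1, p2] else 0)
    }
    nn$internal[s] + min(nn$ninio_max, nn$ninio_m * abs(l1 - l2))
  }
  best <- Inf
  extend <- function(i, j, e, has_stack) {
    if (has_stack) {
      tot <- e + term(pr(i, j))
      if (tot < best) best <<- tot
    }
    if (i < n1 && j > 1) {
      for (i2 in (i + 1):n1) {
        for (j2 in seq_len(j - 1)) {
          p2 <- pr(i2, j2)
          if (!p2 %in% allowed) next
          le <- loop_e(pr(i, j), p2, i2 - i - 1, j - j2 - 1)
          if (!is.finite(le)) next
          extend(i2, j2, e + le, has_stack || (i2 == i + 1 && j2 == j - 1))
        }
      }
    }
  }
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      p <- pr(i, j)
      if (p %in% allowed) extend(i, j, nn$duplex_init + term(p), FALSE)
    }
  }
  if (is.finite(best)) best else NA_real_
}

# exhaustive enumeration of all global alignments, maximizing match count
# then minimizing alignment length (tiny sequences only)
oracle_global_identity <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- c(matches = -1, len = Inf)
  recurse <- function(i, j, matches, len) {
    if (i > length(A) && j > length(B)) {
      if (matches > best["matches"] ||
          (matches == best["matches"] && len < best["len"])) {
        best <<- c(matches = matches, len = len)
      }
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      recurse(i + 1, j + 1, matches + (A[i] == B[j]), len + 1)
    }
    if (i <= length(A)) recurse(i + 1, j, matches, len + 1)
    if (j <= length(B)) recurse(i, j + 1, matches, len + 1)
  }
  recurse(1L, 1L, 0L, 0L)
  100 * best[["matches"]] / best[["len"]]
}

write_tmp_fasta <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile("mirna", tmpdir = dir, fileext = ".fa")
  xkmir::write_mature_fasta(df, path)
  path
}
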