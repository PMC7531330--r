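# miRanda-style two-phase target-site prediction: a weighted local
# complementarity alignment proposes candidate sites, then a
# nearest-neighbor duplex free-energy calculation filters them.

#' Parameters for miRanda-style target scanning
#'
#' Defaults follow the complementarity scoring commonly cited for the
#' miRanda tool: Watson-Crick pair +5, G:U wobble +2, mismatch -3, affine
#' gaps (open -9, extend -4), a 5' scaling factor of 4 applied over the
#' miRNA seed positions 2-8, and a score threshold of 140. The energy
#' threshold keeps only sites whose duplex is predicted stable (MFE <= 0
#' kcal/mol by default).
#'
#' @param wc_reward,wobble_reward,mismatch_penalty Per-position alignment
#'   scores (dimensionless).
#' @param gap_open,gap_extend Affine gap penalties, both `<= 0`.
#' @param seed_scale Multiplicative weight (`>= 1`) applied to positions of
#'   the miRNA inside `scale_span`.
#' @param scale_span Length-2 integer vector of 1-based miRNA 5' positions
#'   covered by `seed_scale`.
#' @param score_threshold Minimum alignment score for a candidate site.
#' @param energy_threshold Maximum duplex MFE (kcal/mol) for a reported site.
#' @param max_sites_per_transcript Cap on non-overlapping sites returned.
#' @param nn_table_id Nearest-neighbor parameter set for [duplex_mfe()].
#' @return A named list of class `xkmir_scan_params`.
#' @export
scan_params <- function(wc_reward = 5, wobble_reward = 2, mismatch_penalty = -3,
                        gap_open = -9, gap_extend = -4,
                        seed_scale = 4, scale_span = c(2L, 8L),
                        score_threshold = 140, energy_threshold = 0,
                        max_sites_per_transcript = 10L,
                        nn_table_id = "turner2004") {
  if (gap_open > 0 || gap_extend > 0) {
    stop("gap penalties must be <= 0", call. = FALSE)
  }
  if (seed_scale < 1) stop("seed_scale must be >= 1", call. = FALSE)
  assert_scalar_number(score_threshold, "score_threshold")
  assert_scalar_number(energy_threshold, "energy_threshold")
  structure(list(wc_reward = wc_reward, wobble_reward = wobble_reward,
                 mismatch_penalty = mismatch_penalty, gap_open = gap_open,
                 gap_extend = gap_extend, seed_scale = seed_scale,
                 scale_span = as.integer(scale_span),
                 score_threshold = score_threshold,
                 energy_threshold = energy_threshold,
                 max_sites_per_transcript = as.integer(max_sites_per_transcript),
                 nn_table_id = nn_table_id),
            class = "xkmir_scan_params")
}

comp_score_fun <- function(params) {
  wc <- c("AU", "UA", "GC", "CG")
  wob <- c("GU", "UG")
  function(mb, tb) {
    p <- paste0(mb, tb)
    if (p %in% wc) params$wc_reward
    else if (p %in% wob) params$wobble_reward
    else params$mismatch_penalty
  }
}

pair_symbol <- function(mb, tb) {
  p <- paste0(mb, tb)
  if (p %in% c("AU", "UA", "GC", "CG")) "|"
  else if (p %in% c("GU", "UG")) ":"
  else " "
}

#' Local complementarity alignment of a miRNA against a sequence window
#'
#' Smith-Waterman-style local alignment of the reversed miRNA (3'->5')
#' against the window (5'->3') under complementarity scoring with affine
#' gaps; substitution scores at miRNA positions inside `scale_span` are
#' multiplied by `seed_scale`. Returns the maximal-scoring local alignment
#' (ties: smallest window start, then shortest alignment).
#'
#' @param mirna miRNA sequence string (5'->3') or record with `$sequence`.
#' @param window Window sequence string (5'->3'), length >= 6.
#' @param params [scan_params()] object.
#' @return List with `score`, `alignment` (character vector: miRNA 3'->5',
#'   pairing line, window 5'->3'), `w_start`/`w_end` (1-based window
#'   coordinates) and `m_start`/`m_end` (1-based miRNA 5'->3' coordinates);
#'   a zero-score result has empty alignment strings.
#' @export
align_complementarity <- function(mirna, window, params = scan_params()) {
  m <- as_mirna_record(mirna, "mirna")$sequence
  if (nchar(window) < 6L) stop("window must be >= 6 nt", call. = FALSE)
  sw_align(m, window, params, mask = NULL)
}

# core affine-gap local DP; `mask` is a logical over target positions that
# may not participate in any alignment column
sw_align <- function(mirna_seq, target_seq, params, mask = NULL) {
  q <- rev(strsplit(mirna_seq, "", fixed = TRUE)[[1]])   # miRNA 3'->5'
  tt <- strsplit(target_seq, "", fixed = TRUE)[[1]]
  mlen <- length(q)
  tl <- length(tt)
  mpos <- mlen:1                                          # 5'-based position of q[j]
  w <- ifelse(mpos >= params$scale_span[1] & mpos <= params$scale_span[2],
              params$seed_scale, 1)
  sc <- comp_score_fun(params)
  sub <- matrix(0, tl, mlen)
  for (j in seq_len(mlen)) {
    for (i in seq_len(tl)) sub[i, j] <- sc(q[j], tt[i]) * w[j]
  }
  if (!is.null(mask) && any(mask)) sub[mask, ] <- -Inf

  neg <- -Inf
  M <- matrix(neg, tl + 1L, mlen + 1L)
  Ix <- matrix(neg, tl + 1L, mlen + 1L)  # gap in miRNA (consumes target base)
  Iy <- matrix(neg, tl + 1L, mlen + 1L)  # gap in target (consumes miRNA base)
  pM <- matrix(0L, tl + 1L, mlen + 1L)   # 0 fresh start, 1 M, 2 Ix, 3 Iy
  pIx <- matrix(0L, tl + 1L, mlen + 1L)  # 1 open (from M), 2 extend
  pIy <- matrix(0L, tl + 1L, mlen + 1L)
  go <- params$gap_open
  ge <- params$gap_extend
  best <- 0
  ends <- list()
  for (i in seq_len(tl)) {
    i1 <- i + 1L
    block_t <- !is.null(mask) && mask[i]
    for (j in seq_len(mlen)) {
      j1 <- j + 1L
      # Ix: consume target base i against a gap
      if (!block_t) {
        open_x <- M[i, j1] + go
        ext_x <- Ix[i, j1] + ge
        if (open_x >= ext_x) {
          Ix[i1, j1] <- open_x; pIx[i1, j1] <- 1L
        } else {
          Ix[i1, j1] <- ext_x; pIx[i1, j1] <- 2L
        }
      }
      # Iy: consume miRNA base j against a gap
      open_y <- M[i1, j] + go
      ext_y <- Iy[i1, j] + ge
      if (open_y >= ext_y) {
        Iy[i1, j1] <- open_y; pIy[i1, j1] <- 1L
      } else {
        Iy[i1, j1] <- ext_y; pIy[i1, j1] <- 2L
      }
      # M: pair column (i, j)
      s <- sub[i, j]
      if (is.finite(s)) {
        prevs <- c(0, M[i, j], Ix[i, j], Iy[i, j])
        k <- which.max(prevs)
        val <- prevs[k] + s
        if (val >= 0) {
          M[i1, j1] <- val
          pM[i1, j1] <- k - 1L
          if (val > best + 1e-9) {
            best <- val
            ends <- list(c(i, j))
          } else if (best > 0 && abs(val - best) <= 1e-9) {
            ends <- c(ends, list(c(i, j)))
          }
        }
      }
    }
  }
  if (best <= 0 || !length(ends)) {
    return(list(score = 0, alignment = c("", "", ""),
                w_start = NA_integer_, w_end = NA_integer_,
                m_start = NA_integer_, m_end = NA_integer_))
  }
  cand <- lapply(ends, function(e) {
    traceback_local(e[1], e[2], pM, pIx, pIy, q, tt)
  })
  starts <- vapply(cand, `[[`, numeric(1), "w_start")
  lens <- vapply(cand, function(x) nchar(x$alignment[1]), numeric(1))
  pick <- order(starts, lens)[1]
  res <- cand[[pick]]
  res$score <- best
  res$m_start <- mlen - res$q_end + 1L   # convert q (3'->5') to 5'-based
  res$m_end <- mlen - res$q_start + 1L
  res$q_start <- res$q_end <- NULL
  res
}

traceback_local <- function(i, j, pM, pIx, pIy, q, tt) {
  ai <- character(); ap <- character(); at <- character()
  state <- 1L  # 1 = M, 2 = Ix, 3 = Iy
  wi <- i; wj <- j
  end_i <- i; end_j <- j
  repeat {
    if (state == 1L) {
      ai <- c(q[wj], ai)
      at <- c(tt[wi], at)
      ap <- c(pair_symbol(q[wj], tt[wi]), ap)
      nxt <- pM[wi + 1L, wj + 1L]
      wi <- wi - 1L; wj <- wj - 1L
      if (nxt == 0L) break
      state <- nxt
    } else if (state == 2L) {
      ai <- c("-", ai); ap <- c(" ", ap); at <- c(tt[wi], at)
      nxt <- pIx[wi + 1L, wj + 1L]
      wi <- wi - 1L
      state <- if (nxt == 1L) 1L else 2L
    } else {
      ai <- c(q[wj], ai); ap <- c(" ", ap); at <- c("-", at)
      nxt <- pIy[wi + 1L, wj + 1L]
      wj <- wj - 1L
      state <- if (nxt == 1L) 1L else 3L
    }
  }
  list(alignment = c(paste(ai, collapse = ""), paste(ap, collapse = ""),
                     paste(at, collapse = "")),
       w_start = wi + 1L,
       w_end = end_i,
       q_start = wj + 1L,
       q_end = end_j)
}

#' Minimum free energy of an intermolecular RNA:RNA duplex
#'
#' Computes the lowest free energy over all pseudoknot-free, antiparallel
#' intermolecular pairings of the two strands under a nearest-neighbor
#' model: stacking increments for adjacent pairs, size-dependent bulge and
#' interior-loop penalties with a Ninio asymmetry term, a duplex initiation
#' term, and terminal A:U / G:U penalties. Structures must contain at least
#' one stacked pair (two directly adjacent base pairs); when none exists the
#' no-duplex sentinel `NA` is returned. Loops larger than 30 nt are
#' disallowed.
#'
#' @param strand1,strand2 RNA sequences (5'->3'), length >= 2.
#' @param nn_table_id Parameter set id or path, see [nn_table()].
#' @return MFE in kcal/mol (<= more stable), or `NA_real_` when no
#'   qualifying duplex exists. Symmetric under strand exchange.
#' @examples
#' duplex_mfe("GCGCGC", "GCGCGC")
#' duplex_mfe("AAAA", "AAAA")  # NA: no complementary pairs
#' @export
duplex_mfe <- function(strand1, strand2, nn_table_id = "turner2004") {
  s1 <- strsplit(normalize_rna(strand1), "", fixed = TRUE)[[1]]
  s2 <- strsplit(normalize_rna(strand2), "", fixed = TRUE)[[1]]
  n1 <- length(s1)
  n2 <- length(s2)
  if (n1 < 2L || n2 < 2L) stop("strands must be >= 2 nt", call. = FALSE)
  nn <- nn_table(nn_table_id)
  maxloop <- 30L

  pairs <- outer(s1, s2, paste0)
  ok <- matrix(pairs %in% ALLOWED_PAIRS, n1, n2)
  if (!any(ok)) return(NA_real_)

  # E0/E1: best energy of a partial duplex whose last (3'-most on strand 1)
  # pair is (i, j); E1 additionally requires >= 1 stacked pair so far.
  # Both include the initiation term and the terminal penalty of the FIRST
  # pair only.
  E0 <- matrix(Inf, n1, n2)
  E1 <- matrix(Inf, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      if (!ok[i, j]) next
      pij <- pairs[i, j]
      E0[i, j] <- nn$duplex_init + terminal_penalty(pij, nn)
      for (p in seq.int(max(1L, i - maxloop - 1L), i - 1L)) {
        if (p < 1L || p >= i) next
        l1 <- i - p - 1L
        qlo <- j + 1L
        qhi <- min(n2, j + maxloop + 1L)
        if (qlo > qhi) next
        for (qq in qlo:qhi) {
          if (!ok[p, qq]) next
          if (!is.finite(E0[p, qq]) && !is.finite(E1[p, qq])) next
          l2 <- qq - j - 1L
          le <- loop_energy(pairs[p, qq], pij, l1, l2, nn)
          if (!is.finite(le)) next
          if (l1 == 0L && l2 == 0L) {
            cand <- min(E0[p, qq], E1[p, qq]) + le
            if (cand < E1[i, j]) E1[i, j] <- cand
          } else {
            if (is.finite(E0[p, qq]) && E0[p, qq] + le < E0[i, j]) {
              E0[i, j] <- E0[p, qq] + le
            }
            if (is.finite(E1[p, qq]) && E1[p, qq] + le < E1[i, j]) {
              E1[i, j] <- E1[p, qq] + le
            }
          }
        }
      }
    }
  }
  close_term <- matrix(0, n1, n2)
  close_term[ok] <- terminal_penalty(pairs[ok], nn)
  total <- E1 + close_term
  mfe <- suppressWarnings(min(total[is.finite(total)]))
  if (!is.finite(mfe)) return(NA_real_)
  mfe
}

#' Scan a transcript for miRNA target sites
#'
#' Runs the weighted complementarity alignment over the whole transcript,
#' extracts the best-scoring non-overlapping candidate sites (best first;
#' ties resolved leftmost), evaluates the duplex MFE of the full miRNA
#' against each aligned transcript region, and reports sites passing both
#' the score and the energy threshold, sorted by start coordinate.
#' Coordinates are 1-based inclusive on the transcript; a site's reported
#' "position" is its start.
#'
#' @param mirna Record with `id`, `sequence`, or a plain sequence string.
#' @param transcript Record with `id`, `sequence`, or a plain string.
#' @param params [scan_params()] object.
#' @return data.frame with columns `mirna_id`, `transcript_id`, `start`,
#'   `end`, `score`, `mfe_kcal_mol`, `aln_mirna`, `aln_pairs`, `aln_target`.
#' @export
scan_transcript <- function(mirna, transcript, params = scan_params()) {
  m <- as_mirna_record(mirna, "mirna")
  tr <- as_mirna_record(transcript, "transcript")
  tl <- nchar(tr$sequence)
  mask <- rep(FALSE, tl)
  sites <- list()
  for (k in seq_len(params$max_sites_per_transcript)) {
    hit <- sw_align(m$sequence, tr$sequence, params, mask = mask)
    if (hit$score < params$score_threshold || is.na(hit$w_start)) break
    mask[hit$w_start:hit$w_end] <- TRUE
    mfe <- duplex_mfe(m$sequence,
                      substr(tr$sequence, hit$w_start, hit$w_end),
                      nn_table_id = params$nn_table_id)
    if (is.na(mfe) || mfe > params$energy_threshold) next
    sites[[length(sites) + 1L]] <- data.frame(
      mirna_id = m$id, transcript_id = tr$id,
      start = hit$w_start, end = hit$w_end,
      score = hit$score, mfe_kcal_mol = mfe,
      aln_mirna = hit$alignment[1], aln_pairs = hit$alignment[2],
      aln_target = hit$alignment[3], stringsAsFactors = FALSE)
  }
  if (!length(sites)) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      mfe_kcal_mol = numeric(), aln_mirna = character(),
                      aln_pairs = character(), aln_target = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, sites)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write predicted target sites as TSV
#'
#' The header records the scan parameters and the nearest-neighbor table id.
#'
#' @param sites data.frame from [scan_transcript()].
#' @param path Output path.
#' @param params The [scan_params()] used.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, params = scan_params()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- params[setdiff(names(params), "")]
  writeLines(sprintf("# %s=%s", names(meta),
                     vapply(meta, function(x) paste(x, collapse = ","),
                            character(1))), con)
  utils::write.table(sites, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
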