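# Count-based differential expression: median-of-ratios normalization,
# per-gene Fisher's exact test on pooled normalized counts, BH FDR and a
# fold-change filter, plus a biotype breakdown of the significant calls.

#' Median-of-ratios size factors
#'
#' For each gene the geometric mean of its counts across samples is
#' computed; each sample's scaling factor is the median over genes of
#' count / geometric mean. Genes with a zero geometric mean (a zero in any
#' sample) are excluded from the factor computation but retained in the
#' matrix.
#'
#' @param counts Numeric matrix, genes x samples.
#' @return Named numeric vector of positive per-sample size factors.
#' @examples
#' m <- cbind(s1 = c(2, 4, 8), s2 = c(4, 8, 16))
#' size_factors(m)  # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  qualifying <- rowSums(counts <= 0) == 0L
  if (!any(qualifying)) {
    stop("no gene with all-positive counts; size factors undefined",
         call. = FALSE)
  }
  log_geo <- rowMeans(log(counts[qualifying, , drop = FALSE]))
  ratios <- exp(log(counts[qualifying, , drop = FALSE]) - log_geo)
  setNames(apply(ratios, 2L, stats::median), colnames(counts))
}

#' Normalize a count matrix by its size factors
#'
#' @param counts Numeric matrix, genes x samples.
#' @param factors Optional precomputed factors from [size_factors()].
#' @return List with `normalized` (matrix counts / factor), `size_factors`
#'   and the raw `counts`.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  list(normalized = sweep(as.matrix(counts), 2L, factors, "/"),
       size_factors = factors,
       counts = as.matrix(counts))
}

#' Two-sided Fisher's exact test for one gene
#'
#' Tests the 2x2 table `[[aT, NT-aT], [aC, NC-aC]]` of a gene's pooled
#' treated/control counts against the pooled library totals; the two-sided
#' p-value is the sum of probabilities of all tables at least as extreme as
#' the observed one.
#'
#' @param aT,aC Pooled (rounded normalized) counts in treated and control.
#' @param NT,NC Pooled treated and control totals.
#' @return Two-sided p-value.
#' @export
fisher_gene <- function(aT, aC, NT, NC) {
  if (any(c(aT, aC, NT, NC) < 0) || aT > NT || aC > NC) {
    stop("counts must satisfy 0 <= aT <= NT and 0 <= aC <= NC", call. = FALSE)
  }
  if (aT + aC == 0) return(1)
  tab <- matrix(c(aT, NT - aT, aC, NC - aC), nrow = 2, byrow = TRUE)
  min(1, stats::fisher.test(tab)$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed and
#'   propagated).
#' @return Adjusted q-values in input order, `q >= p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression calls from a count matrix
#'
#' The full count-based procedure: median-of-ratios normalization, pooling
#' of replicates per condition (sums of rounded normalized counts),
#' per-gene two-sided Fisher's exact test against the pooled totals, BH
#' adjustment over all tested genes, fold change as the ratio of mean
#' normalized counts with a pseudo-count, and the significance filter
#' q <= `alpha` and absolute fold change >= `fc_min`. Genes with zero
#' counts in both conditions are not tested and do not enter the BH family.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Named character vector sample -> group with exactly two
#'   levels.
#' @param treated,control Group labels; default `"treated"` / `"control"`.
#' @param alpha FDR threshold (default 0.05).
#' @param fc_min Absolute fold-change threshold (default 1.5), applied as
#'   `max(fc, 1/fc) >= fc_min`.
#' @param biotype_map Optional named character vector gene -> biotype
#'   (`protein_coding`, `lncRNA`, anything else -> `other`).
#' @param pseudo Pseudo-count added to each group mean in the fold change
#'   (default 0.5).
#' @return List with `calls` (data.frame: `gene_id`, `fc`, `log2fc`, `p`,
#'   `q`, `direction`, `biotype`, `significant`) and `summary` (list:
#'   `n_tested`, `n_sig`, `n_up`, `n_down`, `biotype_proportions`,
#'   `size_factors`).
#' @export
call_de <- function(counts, groups, treated = "treated", control = "control",
                    alpha = 0.05, fc_min = 1.5, biotype_map = NULL,
                    pseudo = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts)) {
      stop("groups must be named by sample or match ncol(counts)", call. = FALSE)
    }
    names(groups) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing)) {
    stop(sprintf("no group for sample(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  groups <- groups[colnames(counts)]
  bad <- setdiff(unique(groups), c(treated, control))
  if (length(bad)) {
    stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  t_cols <- names(groups)[groups == treated]
  c_cols <- names(groups)[groups == control]
  if (!length(t_cols) || !length(c_cols)) {
    stop("each condition needs at least one sample", call. = FALSE)
  }

  nrm <- normalize_counts(counts)
  normed <- nrm$normalized
  pooled_t <- rowSums(round(normed[, t_cols, drop = FALSE]))
  pooled_c <- rowSums(round(normed[, c_cols, drop = FALSE]))
  NT <- sum(pooled_t)
  NC <- sum(pooled_c)

  tested <- pooled_t + pooled_c > 0
  p <- rep(NA_real_, nrow(counts))
  p[tested] <- vapply(which(tested), function(i) {
    fisher_gene(pooled_t[i], pooled_c[i], NT, NC)
  }, numeric(1))
  q <- rep(NA_real_, nrow(counts))
  q[tested] <- bh_adjust(p[tested])

  mean_t <- rowMeans(normed[, t_cols, drop = FALSE])
  mean_c <- rowMeans(normed[, c_cols, drop = FALSE])
  fc <- (mean_t + pseudo) / (mean_c + pseudo)
  abs_fc <- pmax(fc, 1 / fc)

  genes <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  biotype <- rep("other", nrow(counts))
  if (!is.null(biotype_map)) {
    hit <- biotype_map[toupper(genes)]
    biotype[!is.na(hit)] <- hit[!is.na(hit)]
  }
  significant <- tested & !is.na(q) & q <= alpha & abs_fc >= fc_min
  direction <- ifelse(fc >= 1, "up", "down")

  calls <- data.frame(gene_id = genes, fc = fc, log2fc = log2(fc),
                      p = p, q = q, direction = direction,
                      biotype = biotype, significant = significant,
                      stringsAsFactors = FALSE, row.names = NULL)
  sig <- calls[calls$significant, , drop = FALSE]
  bio_prop <- if (nrow(sig)) {
    prop.table(table(factor(sig$biotype,
                            levels = c("protein_coding", "lncRNA", "other"))))
  } else {
    setNames(rep(NA_real_, 3), c("protein_coding", "lncRNA", "other"))
  }
  list(calls = calls,
       summary = list(n_tested = sum(tested),
                      n_sig = nrow(sig),
                      n_up = sum(sig$direction == "up"),
                      n_down = sum(sig$direction == "down"),
                      biotype_proportions = as.list(round(as.numeric(bio_prop), 6)) |>
                        setNames(c("protein_coding", "lncRNA", "other")),
                      size_factors = as.list(round(nrm$size_factors, 6))))
}
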