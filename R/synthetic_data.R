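# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes: miRNA universes with planted seed matches,
# transcripts with planted complementarity sites, and negative-binomial
# count matrices with planted fold changes. Every generator is a pure
# function of its parameters including the seed, and records its planted
# truth.

random_rna <- function(n, length_range, gc = 0.5) {
  lens <- if (length(length_range) == 1L) {
    rep(length_range, n)
  } else {
    choices <- seq.int(length_range[1], length_range[2])
    choices[sample.int(length(choices), n, replace = TRUE)]
  }
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  vapply(lens, function(L) {
    paste(sample(RNA_ALPHABET, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}

#' Simulate a human + plant mature-miRNA universe with planted seed matches
#'
#' Sequences are i.i.d. uniform over A/C/G/U with lengths drawn from
#' `length_range` (mature miRNAs are 16-24 nt). For every planted pair the
#' plant sequence's frame positions are overwritten with the human's frame
#' substring, so planted truth holds by construction regardless of
#' background collisions.
#'
#' @param n_human,n_plant Number of human and plant records.
#' @param planted data.frame with columns `frame` (`F2_7`/`F2_8`/`F3_8`) and
#'   `count`, or NULL for none.
#' @param length_range Length-2 integer vector, both `>= 8`.
#' @param seed Integer RNG seed.
#' @return List with `human`, `plant` (data.frames as from
#'   [read_mature_fasta()]) and `truth` (list with `planted_matches`
#'   data.frame and the generator parameters).
#' @export
gen_mirna_universe <- function(n_human, n_plant, planted = NULL,
                               length_range = c(16L, 24L), seed) {
  if (min(length_range) < 8L) {
    stop("length_range must be >= 8 so all seed frames exist", call. = FALSE)
  }
  n_planted <- if (is.null(planted)) 0L else sum(planted$count)
  if (n_planted > n_human || n_planted > n_plant) {
    stop("more planted pairs than available records", call. = FALSE)
  }
  plant_prefixes <- c("gma", "mtr", "zma")
  withr::with_seed(as.integer(seed), {
    human <- data.frame(
      id = sprintf("hsa-sim-miR-%04d", seq_len(n_human)),
      species_prefix = "hsa",
      sequence = random_rna(n_human, length_range),
      stringsAsFactors = FALSE)
    prefix <- plant_prefixes[(seq_len(max(n_plant, 1L)) - 1L) %% 3L + 1L][seq_len(n_plant)]
    plant <- data.frame(
      id = sprintf("%s-sim-miR-%04d", prefix, seq_len(n_plant)),
      species_prefix = prefix,
      sequence = random_rna(n_plant, length_range),
      stringsAsFactors = FALSE)

    truth <- data.frame(human_id = character(), plant_id = character(),
                        frame = character(), stringsAsFactors = FALSE)
    if (n_planted > 0L) {
      h_idx <- sample(n_human, n_planted)
      p_idx <- sample(n_plant, n_planted)
      k <- 0L
      for (r in seq_len(nrow(planted))) {
        fr <- frame_row(planted$frame[r])
        for (dup in seq_len(planted$count[r])) {
          k <- k + 1L
          hi <- h_idx[k]; pi <- p_idx[k]
          seedstr <- substr(human$sequence[hi], fr$start,
                            fr$start + fr$length - 1L)
          s <- plant$sequence[pi]
          substr(s, fr$start, fr$start + fr$length - 1L) <- seedstr
          plant$sequence[pi] <- s
          truth <- rbind(truth, data.frame(human_id = human$id[hi],
                                           plant_id = plant$id[pi],
                                           frame = fr$name,
                                           stringsAsFactors = FALSE))
        }
      }
    }
    list(human = human, plant = plant,
         truth = list(planted_matches = truth,
                      params = list(n_human = n_human, n_plant = n_plant,
                                    length_range = length_range, seed = seed)))
  })
}

#' Simulate a transcript with planted miRNA binding sites
#'
#' Background bases are i.i.d. with the requested GC content; each planted
#' site region is replaced by the exact reverse complement of its miRNA, so
#' a complementarity scan must recover it.
#'
#' @param mirnas data.frame with `id`, `sequence`.
#' @param sites data.frame with columns `mirna_id`, `start` (1-based), or
#'   NULL/empty for none. Sites must be in bounds and non-overlapping.
#' @param length Transcript length.
#' @param gc Background GC fraction.
#' @param seed Integer RNG seed.
#' @param id Transcript identifier.
#' @return List with `transcript` (list `id`, `sequence`) and `truth`
#'   (planted sites with start/end, parameters).
#' @export
gen_transcript_with_sites <- function(mirnas, sites, length, gc = 0.5, seed,
                                      id = "sim-transcript-1") {
  withr::with_seed(as.integer(seed), {
    seq <- random_rna(1L, length, gc = gc)
    placed <- data.frame(mirna_id = character(), transcript_id = character(),
                         start = integer(), end = integer(),
                         stringsAsFactors = FALSE)
    if (!is.null(sites) && nrow(sites)) {
      idx <- match(sites$mirna_id, mirnas$id)
      if (anyNA(idx)) {
        stop("site refers to unknown miRNA id", call. = FALSE)
      }
      mlen <- nchar(mirnas$sequence[idx])
      start <- as.integer(sites$start)
      end <- start + mlen - 1L
      if (any(start < 1L) || any(end > length)) {
        stop("planted site out of transcript bounds", call. = FALSE)
      }
      ord <- order(start)
      if (any(start[ord][-1] <= end[ord][-length(end)])) {
        stop("planted sites overlap", call. = FALSE)
      }
      for (k in seq_along(idx)) {
        substr(seq, start[k], end[k]) <- reverse_complement(mirnas$sequence[idx[k]])
      }
      placed <- data.frame(mirna_id = sites$mirna_id, transcript_id = id,
                           start = start, end = end, stringsAsFactors = FALSE)
    }
    list(transcript = list(id = id, sequence = seq),
         truth = list(planted_sites = placed,
                      params = list(length = length, gc = gc, seed = seed)))
  })
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Gene baseline abundances are log-normal and scaled to the target library
#' size; counts are negative-binomial with gene-level dispersion
#' (`dispersion = 0` degenerates to Poisson). A fraction `de_frac` of genes
#' has its treated-condition mean multiplied by `2^(+/- log2fc)` with random
#' sign. Per-sample library-size factors are drawn log-normally and
#' recorded. Biotypes are assigned by `biotype_frac`.
#'
#' @param n_genes Number of genes.
#' @param reps_per_group Length-2 integer vector `(treated, control)`.
#' @param lib_size_mean Expected library size per sample.
#' @param de_frac Fraction of genes with a planted effect, in `[0, 1]`.
#' @param log2fc Magnitude of the planted log2 fold change.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2). The
#'   default 0.01 corresponds to a biological coefficient of variation of
#'   0.1, typical of genetically identical cultured cell lines.
#' @param biotype_frac Named fractions over `protein_coding`, `lncRNA`,
#'   `other`.
#' @param seed Integer RNG seed.
#' @return List with `counts` (integer matrix), `groups` (named vector),
#'   `biotypes` (named vector), and `truth` (list: `planted_de` named
#'   signed-log2fc vector, `lib_factors`, parameters).
#' @export
gen_count_matrix <- function(n_genes, reps_per_group = c(3L, 3L),
                             lib_size_mean = 1e6, de_frac = 0, log2fc = 1,
                             dispersion = 0.01,
                             biotype_frac = c(protein_coding = 0.7,
                                              lncRNA = 0.15, other = 0.15),
                             seed) {
  stopifnot(de_frac >= 0, de_frac <= 1, dispersion >= 0)
  n_t <- reps_per_group[1]
  n_c <- reps_per_group[2]
  withr::with_seed(as.integer(seed), {
    base <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1.5)
    props <- base / sum(base)
    mu0 <- props * lib_size_mean

    n_de <- round(de_frac * n_genes)
    de_idx <- if (n_de > 0) sample(n_genes, n_de) else integer()
    sign <- sample(c(-1, 1), n_de, replace = TRUE)
    effect <- rep(0, n_genes)
    effect[de_idx] <- sign * log2fc

    samples <- c(sprintf("T%d", seq_len(n_t)), sprintf("C%d", seq_len(n_c)))
    groups <- setNames(rep(c("treated", "control"), c(n_t, n_c)), samples)
    lib_factors <- setNames(stats::rlnorm(n_t + n_c, 0, 0.1), samples)

    counts <- matrix(0L, n_genes, n_t + n_c,
                     dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                                     samples))
    for (s in seq_along(samples)) {
      mu <- mu0 * lib_factors[s]
      if (groups[s] == "treated") mu <- mu * 2^effect
      counts[, s] <- if (dispersion == 0) {
        stats::rpois(n_genes, mu)
      } else {
        stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
      }
    }
    storage.mode(counts) <- "integer"
    biotypes <- setNames(
      sample(names(biotype_frac), n_genes, replace = TRUE,
             prob = as.numeric(biotype_frac)),
      rownames(counts))
    planted <- setNames(effect[de_idx], rownames(counts)[de_idx])
    list(counts = counts, groups = groups, biotypes = biotypes,
         truth = list(planted_de = planted,
                      lib_factors = lib_factors,
                      params = list(n_genes = n_genes,
                                    reps_per_group = reps_per_group,
                                    lib_size_mean = lib_size_mean,
                                    de_frac = de_frac, log2fc = log2fc,
                                    dispersion = dispersion, seed = seed)))
  })
}
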