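# From matched human miRNAs to candidate functional-analog plant miRNAs:
# validated-target extraction under a strong-evidence whitelist, gene-set
# over-representation, and back-mapping of a selected human set to plant
# partners.

#' Default strong-evidence whitelist
#'
#' The canonical strong experimental evidence types for validated
#' miRNA-target interactions: luciferase reporter assay, Western blotting
#' and RT-qPCR.
#'
#' @return Character vector of canonical evidence labels.
#' @export
default_evidence_whitelist <- function() {
  c("luciferase reporter assay", "western blot", "qrt-pcr")
}

evidence_synonyms <- function() {
  path <- system.file("extdata", "evidence_synonyms.tsv", package = "xkmir")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  setNames(tolower(df$canonical), tolower(df$label))
}

canonicalize_evidence <- function(labels) {
  syn <- evidence_synonyms()
  lab <- tolower(trimws(labels))
  mapped <- unname(syn[lab])
  ifelse(is.na(mapped), lab, mapped)
}

#' Validated target genes of a miRNA set under strong evidence
#'
#' Keeps interaction records whose evidence set intersects the whitelist
#' (case-insensitive, after applying the packaged synonym table, e.g.
#' "Western blotting" = "Western blot", "RT-qPCR" = "qRT-PCR") and whose
#' miRNA is in `mirna_ids`.
#'
#' @param records data.frame from [read_interaction_table()].
#' @param mirna_ids Non-empty character vector of miRNA identifiers.
#' @param whitelist Character vector of evidence labels (canonical or
#'   synonym forms).
#' @return List with `by_mirna` (named list miRNA -> sorted gene vector) and
#'   `genes` (sorted union).
#' @export
strong_evidence_targets <- function(records, mirna_ids,
                                    whitelist = default_evidence_whitelist()) {
  if (!length(mirna_ids)) stop("mirna_ids must be non-empty", call. = FALSE)
  if (!length(whitelist)) stop("whitelist must be non-empty", call. = FALSE)
  wl <- unique(canonicalize_evidence(whitelist))
  keep <- records$mirna_id %in% mirna_ids &
    vapply(records$evidence, function(ev) {
      any(canonicalize_evidence(ev) %in% wl)
    }, logical(1))
  kept <- records[keep, , drop = FALSE]
  by_mirna <- lapply(split(kept$gene_symbol, kept$mirna_id), function(g) {
    sort(unique(g))
  })
  list(by_mirna = by_mirna, genes = sort(unique(kept$gene_symbol)))
}

#' Hypergeometric over-representation of a gene selection in gene sets
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the selection and the set, given the
#' background universe; each set is intersected with the background before
#' testing. P-values are Benjamini-Hochberg adjusted across all sets.
#'
#' @param selection Character vector of genes, must be a subset of
#'   `background`.
#' @param sets Named list of gene vectors (e.g. from [read_gene_sets()]).
#' @param background Character vector: the gene universe.
#' @return data.frame with columns `set_name`, `overlap_count`, `set_size`,
#'   `selection_size`, `background_size`, `p`, `q`, sorted by `p` then
#'   `set_name`.
#' @export
overrepresentation <- function(selection, sets, background) {
  selection <- unique(toupper(selection))
  background <- unique(toupper(background))
  offenders <- setdiff(selection, background)
  if (length(offenders)) {
    stop(sprintf("selection gene(s) outside background: %s",
                 paste(utils::head(offenders, 5), collapse = ", ")),
         call. = FALSE)
  }
  N <- length(background)
  n <- length(selection)
  res <- lapply(names(sets), function(nm) {
    K <- length(intersect(toupper(sets[[nm]]), background))
    k <- length(intersect(toupper(sets[[nm]]), selection))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = K,
               selection_size = n, background_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(set_name = character(), overlap_count = integer(),
                      set_size = integer(), selection_size = integer(),
                      background_size = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict seed matches to a selected human miRNA set
#'
#' Given the seed-match table and a set of selected human miRNAs, returns
#' the matching pairs and the distinct plant partners (the candidate
#' functional analogs). Selected ids absent from the match table produce a
#' warning and are skipped.
#'
#' @param matches data.frame from [match_all()] (or [read_matches()]).
#' @param selected_human Character vector of human miRNA ids.
#' @return List with `pairs` (subset of `matches`), `plants` (sorted
#'   distinct plant ids) and `unknown_human` (skipped ids).
#' @export
select_analog_pairs <- function(matches, selected_human) {
  known <- unique(matches$human_id)
  unknown <- setdiff(selected_human, known)
  if (length(unknown)) {
    warning(sprintf("selected human id(s) not present in matches: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  pairs <- matches[matches$human_id %in% selected_human, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       plants = sort(unique(pairs$plant_id)),
       unknown_human = unknown)
}

#' Load the packaged human-plant seed-comparison fixture
#'
#' A 20-pair regression fixture of human-plant miRNA seed matches over seven
#' crop-plant miRNAs, stored as plain TSV with per-frame seed strings.
#' Obvious OCR artifacts in the transcribed source were corrected; the
#' corrections are documented in the file header.
#'
#' @return data.frame in [match_all()] layout.
#' @export
read_seed_fixture <- function() {
  path <- system.file("extdata", "seed_pairs_fixture.tsv", package = "xkmir")
  read_matches(path)
}
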