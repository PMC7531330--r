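# Readers/writers for the external formats the pipeline touches. Every
# reader normalizes on the way in (T->U, uppercase, strict alphabet) so
# downstream modules see one canonical representation.

#' Read mature miRNAs from a miRBase-style FASTA file
#'
#' Headers follow the miRBase mature-FASTA dialect, `>id [free text]`; the
#' identifier must carry a species prefix before the first hyphen (e.g.
#' `hsa-miR-92a-3p`, `mtr-miR5754`). Sequences are normalized with
#' [normalize_rna()]. Duplicate identifiers with identical sequence are
#' collapsed silently; duplicates with conflicting sequences are an error.
#' Gzip-compressed files are accepted.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @param taxon_filter Optional character vector of species prefixes; when
#'   given, only records with one of these prefixes are returned.
#' @return A data.frame with columns `id`, `species_prefix`, `sequence`,
#'   input order preserved.
#' @export
read_mature_fasta <- function(path, taxon_filter = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    return(data.frame(id = character(), species_prefix = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) {
    stop(sprintf("malformed FASTA header with no id token at record %d",
                 which(!nzchar(ids))[1]), call. = FALSE)
  }
  no_hyphen <- !grepl("-", ids, fixed = TRUE)
  if (any(no_hyphen)) {
    stop(sprintf(
      "id '%s' (record %d) has no species prefix (expected '<prefix>-...')",
      ids[no_hyphen][1], which(no_hyphen)[1]), call. = FALSE)
  }
  sequence <- normalize_rna(as.character(seqs))
  prefix <- tolower(sub("-.*$", "", ids))
  out <- data.frame(id = ids, species_prefix = prefix, sequence = sequence,
                    stringsAsFactors = FALSE, row.names = NULL)

  # duplicate ids: identical sequence -> drop silently; conflicting -> error
  if (anyDuplicated(out$id)) {
    conflict <- vapply(split(out$sequence, out$id), function(s) {
      length(unique(s)) > 1L
    }, logical(1))
    if (any(conflict)) {
      stop(sprintf("duplicate id '%s' with conflicting sequences",
                   names(conflict)[conflict][1]), call. = FALSE)
    }
    out <- out[!duplicated(out$id), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(taxon_filter)) {
    out <- out[out$species_prefix %in% tolower(taxon_filter), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write mature miRNAs to FASTA
#'
#' @param mirnas data.frame as returned by [read_mature_fasta()].
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_mature_fasta <- function(mirnas, path) {
  stopifnot(all(c("id", "sequence") %in% names(mirnas)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(mirnas)) {
    writeLines(paste0(">", mirnas$id, "\n", mirnas$sequence), con)
  }
  invisible(path)
}

#' Split a miRNA collection into human and plant partitions
#'
#' Records whose species prefix is in neither set are dropped and counted.
#'
#' @param mirnas data.frame from [read_mature_fasta()].
#' @param human_prefixes,plant_prefixes Disjoint character vectors of
#'   lowercase species prefixes.
#' @return A list with elements `human`, `plant` (data.frames) and
#'   `n_dropped` (integer count of unclassified records).
#' @export
partition_by_kingdom <- function(mirnas,
                                 human_prefixes = "hsa",
                                 plant_prefixes = c("gma", "mtr", "zma")) {
  human_prefixes <- tolower(human_prefixes)
  plant_prefixes <- tolower(plant_prefixes)
  if (length(intersect(human_prefixes, plant_prefixes))) {
    stop("human and plant prefix sets must be disjoint", call. = FALSE)
  }
  is_h <- mirnas$species_prefix %in% human_prefixes
  is_p <- mirnas$species_prefix %in% plant_prefixes
  res <- list(
    human = mirnas[is_h, , drop = FALSE],
    plant = mirnas[is_p, , drop = FALSE],
    n_dropped = sum(!is_h & !is_p)
  )
  rownames(res$human) <- rownames(res$plant) <- NULL
  res
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  df <- utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a miRNA-target interaction table
#'
#' Tab-separated with columns `mirna_id`, `gene`, `evidence` (miRTarBase-like;
#' evidence labels separated by `|` or `;`). Rows with an empty evidence cell
#' are rejected and counted. Duplicate (miRNA, gene) rows are merged with the
#' union of their evidence labels; gene symbols are uppercased, evidence
#' labels trimmed with case preserved.
#'
#' @param path Path to a TSV file (optionally gzipped).
#' @return data.frame with columns `mirna_id`, `gene_symbol` and a list
#'   column `evidence`; attribute `n_rejected` counts dropped rows.
#' @export
read_interaction_table <- function(path) {
  df <- read_tsv_checked(path, c("mirna_id", "gene", "evidence"),
                         "interaction table")
  ev <- strsplit(as.character(df$evidence), "[|;]")
  ev <- lapply(ev, function(x) unique(trimws(x[nzchar(trimws(x))])))
  keep <- lengths(ev) > 0L
  n_rejected <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  ev <- ev[keep]
  key <- paste(df$mirna_id, toupper(df$gene), sep = "\r")
  split_ev <- lapply(split(ev, key), function(lst) {
    sort(unique(unlist(lst)))
  })
  first <- !duplicated(key)
  out <- data.frame(mirna_id = df$mirna_id[first],
                    gene_symbol = toupper(df$gene[first]),
                    stringsAsFactors = FALSE)
  out$evidence <- unname(split_ev[key[first]])
  out <- out[order(out$mirna_id, out$gene_symbol, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Read a gene-by-sample count matrix
#'
#' TSV with gene identifiers in the first column and one integer column per
#' sample. Sample-to-group assignment can be encoded in the header as
#' `sample:group`, or supplied as a two-column (`sample`, `group`) sidecar
#' TSV via `groups_path`. Genes whose counts are zero in every sample are
#' retained but flagged.
#'
#' @param path Counts TSV (optionally gzipped).
#' @param groups_path Optional sidecar TSV mapping samples to groups.
#' @return List with `counts` (integer matrix, genes x samples), `groups`
#'   (named character vector or NULL) and `all_zero` (named logical flag per
#'   gene).
#' @export
read_count_matrix <- function(path, groups_path = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  df <- utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("count matrix needs a gene column plus >=1 sample", call. = FALSE)
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at row %d (gene '%s'), sample column %d: '%s'",
                 bad[1, 1], genes[bad[1, 1]], bad[1, 2],
                 as.character(df[bad[1, 1], bad[1, 2] + 1L])), call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes

  groups <- NULL
  header <- colnames(mat)
  if (all(grepl(":", header, fixed = TRUE))) {
    samples <- sub(":.*$", "", header)
    groups <- setNames(sub("^[^:]*:", "", header), samples)
    colnames(mat) <- samples
  }
  if (!is.null(groups_path)) {
    gdf <- read_tsv_checked(groups_path, c("sample", "group"), "group sidecar")
    groups <- setNames(as.character(gdf$group), as.character(gdf$sample))
    missing <- setdiff(colnames(mat), names(groups))
    if (length(missing)) {
      stop(sprintf("group sidecar missing sample(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    groups <- groups[colnames(mat)]
  }
  list(counts = mat,
       groups = groups,
       all_zero = setNames(rowSums(mat) == 0L, genes))
}

#' Write a count matrix (with optional header-encoded groups)
#'
#' @param counts Integer matrix, genes x samples.
#' @param path Output TSV path.
#' @param groups Optional named character vector sample -> group; when given,
#'   column headers are written as `sample:group` so [read_count_matrix()]
#'   round-trips the assignment.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, groups = NULL) {
  header <- colnames(counts)
  if (!is.null(groups)) {
    header <- paste(colnames(counts), groups[colnames(counts)], sep = ":")
  }
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", header)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then one or more gene symbols, all
#' tab-separated. Genes are uppercased and deduplicated per set.
#'
#' @param path GMT file (optionally gzipped).
#' @return Named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop(sprintf("GMT parse error: line %d has fewer than 3 fields",
                 which(short)[1]), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  setNames(sets, vapply(fields, `[[`, character(1), 1L))
}

#' Read a gene -> biotype annotation table
#'
#' TSV with columns `gene` and `biotype`; biotypes outside
#' `protein_coding`/`lncRNA` are mapped to `other`.
#'
#' @param path TSV file.
#' @return Named character vector gene -> biotype.
#' @export
read_biotype_table <- function(path) {
  df <- read_tsv_checked(path, c("gene", "biotype"), "biotype table")
  bt <- as.character(df$biotype)
  bt[!bt %in% c("protein_coding", "lncRNA")] <- "other"
  setNames(bt, toupper(as.character(df$gene)))
}

#' Read an entity -> cancer-role annotation table
#'
#' TSV with columns `entity_id` and `roles` (labels from
#' oncogene / tumor_suppressor / prognostic_biomarker / diagnostic_biomarker,
#' separated by `|` or `;`). Rows with no role are an error.
#'
#' @param path TSV file.
#' @return data.frame with `entity_id` and list column `roles`.
#' @export
read_role_table <- function(path) {
  df <- read_tsv_checked(path, c("entity_id", "roles"), "role table")
  raw <- as.character(df$roles)
  raw[is.na(raw)] <- ""
  roles <- strsplit(raw, "[|;]")
  roles <- lapply(roles, function(x) unique(trimws(x[nzchar(trimws(x))])))
  if (any(lengths(roles) == 0L)) {
    stop(sprintf("role table: empty roles at row %d",
                 which(lengths(roles) == 0L)[1]), call. = FALSE)
  }
  out <- data.frame(entity_id = as.character(df$entity_id),
                    stringsAsFactors = FALSE)
  out$roles <- roles
  out
}
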