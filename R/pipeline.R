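# Orchestration of the discovery pipeline (integration -> seed comparison ->
# candidate selection) plus the optional target-scan and DE stages, from a
# single validated config, with a machine-readable manifest for provenance.

CONFIG_KEYS <- c("human_fasta", "plant_fasta", "matches", "human_prefixes",
                 "plant_prefixes", "interactions", "evidence_whitelist",
                 "genesets", "background", "selected_human", "transcripts",
                 "scan", "counts", "groups", "biotypes", "alpha", "fc_min",
                 "treated", "control", "seed")

#' Validate a pipeline configuration
#'
#' @param config Named list, or path to a YAML file.
#' @return The validated config list, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown)) {
    stop(sprintf("config schema error: unknown key(s) %s",
                 paste(sQuote(unknown), collapse = ", ")), call. = FALSE)
  }
  if (is.null(config$matches)) {
    for (key in c("human_fasta", "plant_fasta")) {
      if (is.null(config[[key]])) {
        stop(sprintf("config schema error: missing required key '%s'", key),
             call. = FALSE)
      }
    }
  }
  config$human_prefixes <- config$human_prefixes %||% "hsa"
  config$plant_prefixes <- config$plant_prefixes %||% c("gma", "mtr", "zma")
  config$alpha <- config$alpha %||% 0.05
  config$fc_min <- config$fc_min %||% 1.5
  config
}

stage_guard <- function(stage, manifest_env, expr) {
  tryCatch(expr, error = function(e) {
    manifest_env$manifest$failed_stage <- stage
    manifest_env$manifest$error <- conditionMessage(e)
    write_manifest(manifest_env)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

write_manifest <- function(env) {
  env$manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(env$manifest,
                       file.path(env$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

new_manifest_env <- function(config, out_dir) {
  digests <- list()
  for (key in c("human_fasta", "plant_fasta", "interactions", "genesets",
                "transcripts", "counts", "groups", "biotypes")) {
    if (!is.null(config[[key]]) && is.character(config[[key]]) &&
        file.exists(config[[key]])) {
      digests[[key]] <- unname(tools::md5sum(config[[key]]))
    }
  }
  env <- new.env()
  env$out_dir <- out_dir
  env$manifest <- list(
    tool = "xkmir",
    version = as.character(utils::packageVersion("xkmir")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_digests = digests,
    stage_rows = list())
  env
}

read_id_list <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    lines <- readLines(x)
    trimws(lines[nzchar(trimws(lines))])
  } else {
    as.character(x)
  }
}

#' Run the discovery pipeline (integration, seed comparison, selection)
#'
#' Reads the human and plant mature-miRNA FASTAs, finds all perfect
#' same-frame seed matches, optionally extracts strong-evidence validated
#' targets and tests gene-set over-representation, restricts the matches to
#' a selected human miRNA set, and writes `matches.tsv`, a `candidates/`
#' directory, `summary.json` and `manifest.json` into `out_dir`.
#'
#' @param config List or YAML path, see [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_discovery <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new_manifest_env(config, out_dir)

  precomputed <- !is.null(config$matches)
  inputs <- stage_guard("mirna_io", env, {
    if (precomputed) {
      list(human = NULL, plant = NULL)
    } else {
      list(human = read_mature_fasta(config$human_fasta,
                                     taxon_filter = config$human_prefixes),
           plant = read_mature_fasta(config$plant_fasta,
                                     taxon_filter = config$plant_prefixes))
    }
  })
  env$manifest$stage_rows$mirna_io <-
    list(n_human = if (precomputed) NA else nrow(inputs$human),
         n_plant = if (precomputed) NA else nrow(inputs$plant))

  matches <- stage_guard("seed_match", env, {
    m <- if (precomputed) read_matches(config$matches) else
      match_all(inputs$human, inputs$plant)
    write_matches(m, file.path(out_dir, "matches.tsv"))
    m
  })
  msum <- match_summary(matches)
  env$manifest$stage_rows$seed_match <- list(n_pairs = msum$n_pairs)

  sel <- stage_guard("candidate_selection", env, {
    cand_dir <- file.path(out_dir, "candidates")
    dir.create(cand_dir, showWarnings = FALSE)
    enrichment <- NULL
    genes <- character()
    if (!is.null(config$interactions)) {
      records <- read_interaction_table(config$interactions)
      wl <- config$evidence_whitelist %||% default_evidence_whitelist()
      tg <- strong_evidence_targets(records, unique(matches$human_id), wl)
      genes <- tg$genes
      writeLines(genes, file.path(cand_dir, "genes.tsv"))
      if (!is.null(config$genesets) && length(genes)) {
        sets <- read_gene_sets(config$genesets)
        background <- if (!is.null(config$background)) {
          toupper(read_id_list(config$background))
        } else {
          unique(records$gene_symbol)
        }
        enrichment <- overrepresentation(intersect(genes, background), sets,
                                         background)
        utils::write.table(enrichment, file.path(cand_dir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    selected <- if (!is.null(config$selected_human)) {
      read_id_list(config$selected_human)
    } else {
      unique(matches$human_id)
    }
    pairs <- select_analog_pairs(matches, selected)
    write_matches(pairs$pairs, file.path(cand_dir, "pairs.tsv"))
    writeLines(pairs$plants, file.path(cand_dir, "plants.txt"))
    list(pairs = pairs, genes = genes, enrichment = enrichment,
         selected = selected)
  })
  env$manifest$stage_rows$candidate_selection <-
    list(n_selected_human = length(unique(sel$pairs$pairs$human_id)),
         n_plant = length(sel$pairs$plants),
         n_target_genes = length(sel$genes))

  summary <- list(
    n_human_input = if (precomputed) NA else nrow(inputs$human),
    n_plant_input = if (precomputed) NA else nrow(inputs$plant),
    n_human_matched = msum$n_human_matched,
    n_plant_matched = msum$n_plant_matched,
    n_pairs = msum$n_pairs,
    frame_counts = as.list(msum$frame_counts),
    n_selected_human = length(unique(sel$pairs$pairs$human_id)),
    n_selected_plant = length(sel$pairs$plants),
    selected_plants = sel$pairs$plants)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(env)
  invisible(summary)
}

#' Run the full pipeline (discovery plus target scan and DE)
#'
#' Extends [run_discovery()]: when the config has a `transcripts` FASTA the
#' selected plant miRNAs are scanned against every transcript
#' (`sites.tsv`); when it has a `counts` matrix the DE procedure runs
#' (`de.tsv` plus `de_summary.json`). Either stage is skipped when its
#' inputs are absent.
#'
#' @inheritParams run_discovery
#' @return The (extended) summary list, invisibly.
#' @export
run_full <- function(config, out_dir) {
  config <- validate_config(config)
  summary <- run_discovery(config, out_dir)
  env <- new_manifest_env(config, out_dir)
  env$manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                      simplifyVector = FALSE)

  if (!is.null(config$transcripts)) {
    sites <- stage_guard("target_scan", env, {
      plants <- read_mature_fasta(config$plant_fasta,
                                  taxon_filter = config$plant_prefixes)
      selected_plants <- readLines(file.path(out_dir, "candidates", "plants.txt"))
      scanset <- plants[plants$id %in% selected_plants, , drop = FALSE]
      if (!nrow(scanset)) scanset <- plants
      transcripts <- read_transcripts(config$transcripts)
      params <- do.call(scan_params, config$scan %||% list())
      all_sites <- list()
      for (ti in seq_len(nrow(transcripts))) {
        for (mi in seq_len(nrow(scanset))) {
          s <- scan_transcript(scanset[mi, ], transcripts[ti, ], params)
          if (nrow(s)) all_sites[[length(all_sites) + 1L]] <- s
        }
      }
      sites <- if (length(all_sites)) do.call(rbind, all_sites) else
        scan_transcript(scanset[1, ], list(id = "x", sequence = "AAAAAAAA"),
                        params)[0, ]
      write_sites(sites, file.path(out_dir, "sites.tsv"), params)
      sites
    })
    env$manifest$stage_rows$target_scan <- list(n_sites = nrow(sites))
    summary$n_sites <- nrow(sites)
  }

  if (!is.null(config$counts)) {
    de <- stage_guard("de_analysis", env, {
      cm <- read_count_matrix(config$counts, groups_path = config$groups)
      if (is.null(cm$groups)) stop("counts given without group assignment",
                                   call. = FALSE)
      biomap <- if (!is.null(config$biotypes)) {
        read_biotype_table(config$biotypes)
      } else NULL
      res <- call_de(cm$counts, cm$groups,
                     treated = config$treated %||% "treated",
                     control = config$control %||% "control",
                     alpha = config$alpha, fc_min = config$fc_min,
                     biotype_map = biomap)
      utils::write.table(res$calls, file.path(out_dir, "de.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(res$summary, file.path(out_dir, "de_summary.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      res
    })
    env$manifest$stage_rows$de_analysis <- de$summary["n_sig"]
    summary$n_sig <- de$summary$n_sig
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(env)
  invisible(summary)
}

#' Read transcripts from FASTA
#'
#' @param path FASTA path (optionally gzipped).
#' @return data.frame with columns `id`, `sequence` (normalized RNA).
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  data.frame(id = ids, sequence = normalize_rna(as.character(seqs)),
             stringsAsFactors = FALSE)
}
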