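# Seed-frame extraction and human-plant perfect seed matching.
#
# Animal miRNA targeting is driven by the seed, the 5' region of the mature
# miRNA. Three canonical frames are used: the 6mer (positions 2-7), the 7mer
# (2-8) and the offset-6mer (3-8). A plant miRNA is a candidate functional
# analog of a human miRNA when the two carry an identical subsequence at the
# same frame positions.

SEED_FRAMES <- data.frame(
  name = c("F2_7", "F2_8", "F3_8"),
  start = c(2L, 2L, 3L),
  length = c(6L, 7L, 6L),
  stringsAsFactors = FALSE
)

#' The three canonical seed frames
#'
#' @return data.frame with columns `name` (`F2_7`, `F2_8`, `F3_8`), `start`
#'   (1-based position on the mature sequence) and `length`.
#' @export
seed_frames <- function() SEED_FRAMES

frame_row <- function(frame) {
  i <- match(frame, SEED_FRAMES$name)
  if (is.na(i)) {
    stop(sprintf("unknown seed frame '%s' (use F2_7, F2_8 or F3_8)", frame),
         call. = FALSE)
  }
  SEED_FRAMES[i, ]
}

#' Extract a seed subsequence at a fixed frame
#'
#' @param sequence Character vector of normalized RNA sequences.
#' @param frame One of `"F2_7"`, `"F2_8"`, `"F3_8"`.
#' @return Character vector of seed strings (6 or 7 nt).
#' @examples
#' extract_seed("AUCGAUCG", "F2_7")  # "UCGAUC"
#' @export
extract_seed <- function(sequence, frame) {
  fr <- frame_row(frame)
  need <- fr$start + fr$length - 1L
  too_short <- nchar(sequence) < need
  if (any(too_short)) {
    stop(sprintf("sequence of length %d too short for frame %s (needs >= %d nt)",
                 nchar(sequence[too_short][1]), frame, need), call. = FALSE)
  }
  substr(sequence, fr$start, need)
}

seed_or_na <- function(sequence, frame) {
  fr <- frame_row(frame)
  need <- fr$start + fr$length - 1L
  out <- rep(NA_character_, length(sequence))
  ok <- nchar(sequence) >= need
  out[ok] <- substr(sequence[ok], fr$start, need)
  out
}

#' Classify one human-plant miRNA pair by shared seed frames
#'
#' Compares the two sequences frame-by-frame at identical positions. If the
#' 7mer (2-8) matches, the contained 6mer and offset-6mer frames are
#' subsumed and only `F2_8` is reported; note that simultaneous 2-7 and 3-8
#' identity implies 2-8 identity, so such pairs also collapse to `F2_8`.
#'
#' @param human,plant Either a single sequence string or a list/one-row
#'   data.frame with fields `id` and `sequence`.
#' @return `NULL` when no frame matches, otherwise a list with `human_id`,
#'   `plant_id`, `frames` (character vector) and `seed_by_frame` (named
#'   character vector).
#' @export
classify_pair <- function(human, plant) {
  h <- as_mirna_record(human, "human")
  p <- as_mirna_record(plant, "plant")
  frames <- character()
  seeds <- character()
  s28h <- seed_or_na(h$sequence, "F2_8")
  s28p <- seed_or_na(p$sequence, "F2_8")
  if (!is.na(s28h) && !is.na(s28p) && s28h == s28p) {
    frames <- "F2_8"
    seeds <- c(F2_8 = s28h)
  } else {
    for (fr in c("F2_7", "F3_8")) {
      sh <- seed_or_na(h$sequence, fr)
      sp <- seed_or_na(p$sequence, fr)
      if (!is.na(sh) && !is.na(sp) && sh == sp) {
        frames <- c(frames, fr)
        seeds[[fr]] <- sh
      }
    }
  }
  if (!length(frames)) return(NULL)
  list(human_id = h$id, plant_id = p$id, frames = frames, seed_by_frame = seeds)
}

as_mirna_record <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    return(list(id = what, sequence = x))
  }
  if (is.data.frame(x)) x <- as.list(x[1L, ])
  if (!is.list(x) || is.null(x$sequence)) {
    stop(sprintf("'%s' must be a sequence string or a record with $sequence", what),
         call. = FALSE)
  }
  list(id = x$id %||% what, sequence = x$sequence)
}

#' Find all human-plant pairs with a perfect same-frame seed match
#'
#' Equivalent to running [classify_pair()] over the full Cartesian product,
#' but indexes plants by their frame seeds so large collections stay fast.
#' Output is sorted lexicographically by (human_id, plant_id) so runs are
#' byte-reproducible.
#'
#' @param humans,plants data.frames with columns `id`, `sequence`.
#' @return data.frame with columns `human_id`, `plant_id`, `frames`
#'   (comma-joined, sorted), `seed_2_7`, `seed_2_8`, `seed_3_8` (NA for
#'   unreported frames).
#' @export
match_all <- function(humans, plants) {
  empty <- data.frame(human_id = character(), plant_id = character(),
                      frames = character(), seed_2_7 = character(),
                      seed_2_8 = character(), seed_3_8 = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(humans) || !nrow(plants)) return(empty)

  # candidate pairs via hash-join on each frame's seed string
  cand_h <- integer()
  cand_p <- integer()
  for (fr in SEED_FRAMES$name) {
    sh <- seed_or_na(humans$sequence, fr)
    sp <- seed_or_na(plants$sequence, fr)
    ph <- which(!is.na(sh))
    pp <- which(!is.na(sp))
    if (!length(ph) || !length(pp)) next
    idx <- split(pp, sp[pp])
    hit <- idx[sh[ph]]
    n_per <- lengths(hit)
    take <- n_per > 0L
    if (!any(take)) next
    cand_h <- c(cand_h, rep(ph[take], n_per[take]))
    cand_p <- c(cand_p, unlist(hit[take], use.names = FALSE))
  }
  if (!length(cand_h)) return(empty)
  key <- paste(cand_h, cand_p)
  first <- !duplicated(key)
  cand_h <- cand_h[first]
  cand_p <- cand_p[first]

  hseq <- humans$sequence[cand_h]
  pseq <- plants$sequence[cand_p]
  m28 <- matched_at(hseq, pseq, "F2_8")
  m27 <- matched_at(hseq, pseq, "F2_7") & !m28
  m38 <- matched_at(hseq, pseq, "F3_8") & !m28

  frames <- character(length(cand_h))
  frames[m28] <- "F2_8"
  frames[m27 & m38] <- "F2_7,F3_8"
  frames[m27 & !m38] <- "F2_7"
  frames[!m27 & m38] <- "F3_8"

  out <- data.frame(
    human_id = humans$id[cand_h],
    plant_id = plants$id[cand_p],
    frames = frames,
    seed_2_7 = ifelse(m27, seed_or_na(hseq, "F2_7"), NA_character_),
    seed_2_8 = ifelse(m28, seed_or_na(hseq, "F2_8"), NA_character_),
    seed_3_8 = ifelse(m38, seed_or_na(hseq, "F3_8"), NA_character_),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$human_id, out$plant_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

matched_at <- function(hseq, pseq, frame) {
  sh <- seed_or_na(hseq, frame)
  sp <- seed_or_na(pseq, frame)
  !is.na(sh) & !is.na(sp) & sh == sp
}

#' Summarise a seed-match table
#'
#' @param matches data.frame from [match_all()].
#' @return List with `n_human_matched`, `n_plant_matched`, `n_pairs` and
#'   `frame_counts` (named integer vector over reported frame combinations,
#'   split on single frames).
#' @export
match_summary <- function(matches) {
  frame_tab <- table(unlist(strsplit(matches$frames, ",", fixed = TRUE)))
  counts <- setNames(integer(3), SEED_FRAMES$name)
  counts[names(frame_tab)] <- as.integer(frame_tab)
  list(
    n_human_matched = length(unique(matches$human_id)),
    n_plant_matched = length(unique(matches$plant_id)),
    n_pairs = nrow(matches),
    frame_counts = counts
  )
}

#' Write a seed-match table as TSV
#'
#' @param matches data.frame from [match_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a seed-match table written by [write_matches()]
#'
#' @param path TSV path.
#' @return data.frame in [match_all()] layout.
#' @export
read_matches <- function(path) {
  df <- read_tsv_checked(path, c("human_id", "plant_id", "frames"),
                         "match table")
  for (col in c("seed_2_7", "seed_2_8", "seed_3_8")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    v <- as.character(df[[col]])
    v[is.na(v) | !nzchar(v)] <- NA_character_
    df[[col]] <- v
  }
  df
}
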