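`%||%` <- function(x, y) if (is.null(x)) y else x

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize an RNA sequence
#'
#' Uppercases and converts T to U. Any residue outside `A/C/G/U` after
#' normalization (including N and IUPAC ambiguity codes) is an error: seed
#' matching requires exact residues, so ambiguous records are rejected
#' rather than silently skipped. The function is idempotent.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length over the `A/C/G/U` alphabet.
#' @examples
#' normalize_rna("taTtgcacgg")
#' @export
normalize_rna <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    offender <- gsub("[ACGU]", "", out[bad][1])
    stop(sprintf(
      "invalid residue(s) '%s' in sequence %d ('%s'); only A/C/G/U (or T) allowed",
      substr(offender, 1, 5), which(bad)[1], substr(x[bad][1], 1, 30)
    ), call. = FALSE)
  }
  if (any(!nzchar(out))) {
    stop("empty sequence not allowed", call. = FALSE)
  }
  out
}

#' Reverse complement of an RNA sequence
#'
#' @param x Character vector of normalized RNA sequences (5'->3').
#' @return Character vector of reverse complements (5'->3').
#' @export
reverse_complement <- function(x) {
  flipped <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(flipped, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1))
}

rev_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
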