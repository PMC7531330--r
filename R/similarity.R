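# Whole-sequence global-alignment similarity profiling.
#
# Scoring is deliberately minimal: a global alignment maximizing the count
# of identically matched positions (match +1, mismatch 0, gap 0), with
# percent identity = matches / alignment length. Among alignments with the
# maximal match count the shortest alignment (fewest gap columns) defines
# the denominator. This is the simplest scheme consistent with a plain
# "percent similarity" and is symmetric in its two arguments; published
# decade-bin counts obtained with unspecified alignment tools are therefore
# not comparable at face value and are not treated as verification targets.

#' Percent identity under a match-count-maximizing global alignment
#'
#' @param a,b Non-empty RNA sequence strings.
#' @return Percent identity in `[0, 100]`; 100 iff `a == b`.
#' @examples
#' global_identity("ACGU", "ACGA")  # 75
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(A)
  lb <- length(B)
  # M[i,j]: max matches aligning a[1..i] with b[1..j];
  # P[i,j]: max paired columns among alignments achieving M[i,j]
  # (alignment length = la + lb - paired columns, so max P = min length).
  M <- matrix(0L, la + 1L, lb + 1L)
  P <- matrix(0L, la + 1L, lb + 1L)
  for (i in seq_len(la)) {
    Ai <- A[i]
    for (j in seq_len(lb)) {
      diag_m <- M[i, j] + (Ai == B[j])
      diag_p <- P[i, j] + 1L
      up_m <- M[i, j + 1L]
      up_p <- P[i, j + 1L]
      left_m <- M[i + 1L, j]
      left_p <- P[i + 1L, j]
      best <- max(diag_m, up_m, left_m)
      bp <- -1L
      if (diag_m == best && diag_p > bp) bp <- diag_p
      if (up_m == best && up_p > bp) bp <- up_p
      if (left_m == best && left_p > bp) bp <- left_p
      M[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- bp
    }
  }
  matches <- M[la + 1L, lb + 1L]
  aln_len <- la + lb - P[la + 1L, lb + 1L]
  100 * matches / aln_len
}

best_identities <- function(queries, subjects) {
  vapply(queries$sequence, function(q) {
    max(vapply(subjects$sequence, function(s) global_identity(q, s), numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

identity_histogram <- function(best) {
  breaks <- c(60, 70, 80, 90, 100)
  labels <- c("[60,70)", "[70,80)", "[80,90)", "[90,100]")
  counts <- c(sum(best >= 60 & best < 70), sum(best >= 70 & best < 80),
              sum(best >= 80 & best < 90), sum(best >= 90 & best <= 100))
  setNames(as.integer(counts), labels)
}

#' Similarity profile of queries against subjects and a random background
#'
#' For every query the best identity over all subjects is recorded, together
#' with counts per decade bin (60-70, 70-80, 80-90, 90-100). The same
#' profile is computed against a seeded background of i.i.d. uniform-base
#' sequences whose lengths are resampled from the query length distribution.
#'
#' @param queries,subjects data.frames with columns `id`, `sequence`.
#' @param background List with elements `n` (number of background sequences)
#'   and `seed` (integer); `NULL` disables the background profile.
#' @return List with `vs_subjects` and (unless disabled) `vs_background`,
#'   each a list of `best_identity` (named numeric) and `histogram`.
#' @export
similarity_profile <- function(queries, subjects,
                               background = list(n = nrow(subjects), seed = 1L)) {
  stopifnot(nrow(queries) > 0L, nrow(subjects) > 0L)
  best_s <- setNames(best_identities(queries, subjects), queries$id)
  out <- list(vs_subjects = list(best_identity = best_s,
                                 histogram = identity_histogram(best_s)))
  if (!is.null(background)) {
    if (is.null(background$seed)) stop("background needs a seed", call. = FALSE)
    n <- background$n %||% nrow(subjects)
    lens <- nchar(queries$sequence)
    bg <- withr::with_seed(as.integer(background$seed), {
      bl <- sample(lens, n, replace = TRUE)
      vapply(bl, function(L) {
        paste(sample(RNA_ALPHABET, L, replace = TRUE), collapse = "")
      }, character(1))
    })
    bg_df <- data.frame(id = sprintf("bg-%d", seq_len(n)), sequence = bg,
                        stringsAsFactors = FALSE)
    best_b <- setNames(best_identities(queries, bg_df), queries$id)
    out$vs_background <- list(best_identity = best_b,
                              histogram = identity_histogram(best_b))
  }
  out
}
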