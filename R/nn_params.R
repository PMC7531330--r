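# Nearest-neighbor duplex free-energy parameter sets.
#
# Two published parameter compilations ship as plain-text tables under
# inst/extdata (Turner 2004, the current standard, and Turner 1999, the
# vintage used by miRanda-era folding code). Users may point `nn_table_id`
# at any TSV in the same layout.

ALLOWED_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

nn_cache <- new.env(parent = emptyenv())

#' Load a nearest-neighbor duplex parameter set
#'
#' @param id `"turner2004"` (default), `"turner1999"`, or a path to a TSV in
#'   the packaged layout (columns `category`, `k1`, `k2`, `value`).
#' @return List with `stack` (6x6 matrix over base pairs), `bulge` and
#'   `internal` (numeric, loop sizes 1..30), `duplex_init`, `terminal_au`,
#'   `ninio_m`, `ninio_max` and `id`.
#' @export
nn_table <- function(id = "turner2004") {
  key <- as.character(id)
  if (!is.null(nn_cache[[key]])) return(nn_cache[[key]])
  path <- if (file.exists(key)) {
    key
  } else {
    p <- system.file("extdata", sprintf("nn_%s.tsv", key), package = "xkmir")
    if (!nzchar(p)) {
      stop(sprintf("unknown nearest-neighbor table '%s'", key), call. = FALSE)
    }
    p
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "numeric"))
  stk <- df[df$category == "stack", ]
  S <- matrix(Inf, 6, 6, dimnames = list(ALLOWED_PAIRS, ALLOWED_PAIRS))
  S[cbind(stk$k1, stk$k2)] <- stk$value
  get_loop <- function(cat) {
    sub <- df[df$category == cat, ]
    v <- rep(Inf, 30)
    v[as.integer(sub$k1)] <- sub$value
    v
  }
  misc <- df[df$category == "misc", ]
  mv <- setNames(misc$value, misc$k1)
  out <- list(stack = S,
              bulge = get_loop("bulge"),
              internal = get_loop("internal"),
              duplex_init = unname(mv[["duplex_init"]]),
              terminal_au = unname(mv[["terminal_au"]]),
              ninio_m = unname(mv[["ninio_m"]]),
              ninio_max = unname(mv[["ninio_max"]]),
              id = key)
  nn_cache[[key]] <- out
  out
}

pair_code <- function(b1, b2) {
  p <- paste0(b1, b2)
  ifelse(p %in% ALLOWED_PAIRS, p, NA_character_)
}

terminal_penalty <- function(pair, nn) {
  ifelse(pair %in% c("AU", "UA", "GU", "UG"), nn$terminal_au, 0)
}

# energy of the loop closed by consecutive duplex pairs `p_prev` -> `p_next`
# with l1 unpaired bases on strand 1 and l2 on strand 2
loop_energy <- function(p_prev, p_next, l1, l2, nn) {
  if (l1 == 0L && l2 == 0L) {
    return(nn$stack[p_prev, p_next])
  }
  size <- l1 + l2
  if (size > 30L) return(Inf)
  if (l1 == 0L || l2 == 0L) {
    e <- nn$bulge[size]
    if (size == 1L) e <- e + nn$stack[p_prev, p_next]  # 1-bulges keep helix stacking
    return(e)
  }
  nn$internal[size] + min(nn$ninio_max, nn$ninio_m * abs(l1 - l2))
}
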