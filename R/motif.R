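# Degenerate motif patterns and scanning.

#' Degenerate motif pattern
#'
#' Parses patterns written in the dashed field notation, e.g.
#' \code{"V-(R/K)-P"} or \code{"K-K-K-X-K-K"}: each dash-separated token
#' is a fixed residue, an alternative set in parentheses, or the wildcard
#' \code{X}.
#'
#' @param pattern Pattern string.
#' @param name Optional motif name.
#' @param region Optional anchor-region label (e.g. "b5-L57").
#' @return list with class "motif_pattern"; \code{tokens} is a list of
#'   allowed residue sets (NULL = wildcard).
#' @export
motif_pattern <- function(pattern, name = pattern, region = NA_character_) {
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1L]]
  if (!length(toks)) stop("empty motif pattern", call. = FALSE)
  tokens <- lapply(toks, function(t) {
    t <- trimws(t)
    if (t == "X") return(NULL)
    if (grepl("^\\(.*\\)$", t)) {
      alts <- strsplit(gsub("[()]", "", t), "/", fixed = TRUE)[[1L]]
      alts <- toupper(trimws(alts))
      if (!length(alts) || !all(alts %in% AA20))
        stop("invalid alternative set in motif token: ", t, call. = FALSE)
      return(alts)
    }
    t <- toupper(t)
    if (!t %in% AA20) stop("invalid motif token: ", t, call. = FALSE)
    t
  })
  structure(list(name = name, pattern = pattern, tokens = tokens,
                 region = region),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif %s> %s (%d tokens%s)\n", x$name, x$pattern,
              length(x$tokens),
              if (!is.na(x$region)) paste0(", region ", x$region) else ""))
  invisible(x)
}

#' Scan a sequence for a degenerate motif
#'
#' Reports every window matching the pattern token-wise, left to right.
#' Matches may overlap. Coordinates are 0-based half-open.
#'
#' @param seq Amino-acid string (may be empty).
#' @param pattern A [motif_pattern()] or pattern string.
#' @return data.frame with columns start, end (0 rows if no match).
#' @examples
#' scan_motif("AVKPA", "V-(R/K)-P")   # one match at (1, 4)
#' @export
scan_motif <- function(seq, pattern) {
  if (is.character(pattern)) pattern <- motif_pattern(pattern)
  if (!nzchar(seq))
    return(data.frame(start = integer(0), end = integer(0)))
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  k <- length(pattern$tokens)
  n <- length(ch)
  if (n < k) return(data.frame(start = integer(0), end = integer(0)))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    tok <- pattern$tokens[[j]]
    if (is.null(tok)) next
    ok <- ok & ch[seq.int(j, n - k + j)] %in% tok
  }
  starts <- which(ok) - 1L
  data.frame(start = starts, end = starts + k)
}
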