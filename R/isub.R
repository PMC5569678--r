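# I-Sub string similarity: commonality minus difference plus a Winkler-style
# prefix refinement. Operates on whole strings (case-insensitively); term
# matching feeds it the space-joined local description.

# Longest common substring of a and b, returned as c(start_a, start_b, len)
# (len 0 when the strings share no character). Deterministic tie-break:
# smallest start in a, then smallest start in b.
longest_common_substring <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0 || nb == 0) return(c(0L, 0L, 0L))
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- c(0L, 0L, 0L)
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    match_j <- which(bv == av[i])
    for (j in match_j) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best[3]) {
        best <- c(i - cur[j] + 1L, j - cur[j] + 1L, cur[j])
      }
    }
    prev <- cur
  }
  best
}

#' I-Sub string similarity
#'
#' An improved string matcher that scores both the commonalities and the
#' differences of two strings. Commonality iteratively removes maximal common
#' substrings; difference combines the unmatched fractions of both strings
#' through a product parameterized by a difference weight of 0.6; a Winkler
#' refinement adds `0.1 * min(4, common prefix) * (1 - Comm)`. The raw value
#' lies in [-1, 1] and is clamped to [0, 1].
#'
#' @param s1,s2 Strings, compared case-insensitively.
#' @return Similarity in `[0, 1]`; 0 when either string is empty.
#' @export
#' @examples
#' isub_similarity("drug", "Drug")      # 1
#' isub_similarity("phenotype", "predominantly phenotypes")
isub_similarity <- function(s1, s2) {
  s1 <- tolower(s1); s2 <- tolower(s2)
  l1 <- nchar(s1); l2 <- nchar(s2)
  if (l1 == 0 || l2 == 0) return(0)

  # common prefix of the original strings, before any removal
  maxpref <- min(4L, l1, l2)
  pref <- 0L
  while (pref < maxpref &&
         substr(s1, pref + 1L, pref + 1L) == substr(s2, pref + 1L, pref + 1L)) {
    pref <- pref + 1L
  }

  a <- s1; b <- s2
  common <- 0L
  repeat {
    lcs <- longest_common_substring(a, b)
    if (lcs[3] == 0L) break
    common <- common + lcs[3]
    a <- paste0(substr(a, 1L, lcs[1] - 1L), substr(a, lcs[1] + lcs[3], nchar(a)))
    b <- paste0(substr(b, 1L, lcs[2] - 1L), substr(b, lcs[2] + lcs[3], nchar(b)))
  }
  comm <- 2 * common / (l1 + l2)

  u1 <- (l1 - common) / l1
  u2 <- (l2 - common) / l2
  p <- 0.6
  denom <- p + (1 - p) * (u1 + u2 - u1 * u2)
  diff <- if (denom == 0) 0 else (u1 * u2) / denom

  winkler <- 0.1 * pref * (1 - comm)
  min(1, max(0, comm - diff + winkler))
}
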