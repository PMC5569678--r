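# Independent oracle implementations used across tests. These deliberately
# share no code with the package internals.

# Brute-force cosine over the explicit union vocabulary.
cosine_oracle <- function(w1, w2) {
  vocab <- union(names(w1), names(w2))
  if (length(vocab) == 0) return(0)
  v1 <- vapply(vocab, function(t) if (t %in% names(w1)) w1[[t]] else 0, numeric(1))
  v2 <- vapply(vocab, function(t) if (t %in% names(w2)) w2[[t]] else 0, numeric(1))
  n1 <- sqrt(sum(v1 * v1)); n2 <- sqrt(sum(v2 * v2))
  if (n1 == 0 || n2 == 0) return(0)
  sum(v1 * v2) / (n1 * n2)
}

# Literal transcription of the I-Sub formula, coded independently: the
# longest common substring is found by enumerating substrings of the shorter
# string in decreasing length (the package uses dynamic programming).
isub_oracle <- function(s1, s2) {
  s1 <- tolower(s1); s2 <- tolower(s2)
  l1 <- nchar(s1); l2 <- nchar(s2)
  if (l1 == 0 || l2 == 0) return(0)

  prefix_len <- 0L
  for (k in seq_len(min(4L, l1, l2))) {
    if (substr(s1, k, k) == substr(s2, k, k)) prefix_len <- k else break
  }

  find_lcs <- function(a, b) {
    if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    na <- nchar(a)
    for (len in rev(seq_len(na))) {
      for (start in seq_len(na - len + 1L)) {
        sub <- substr(a, start, start + len - 1L)
        if (grepl(sub, b, fixed = TRUE)) return(sub)
      }
    }
    ""
  }
  remove_first <- function(x, sub) {
    at <- regexpr(sub, x, fixed = TRUE)
    paste0(substr(x, 1L, at - 1L), substr(x, at + nchar(sub), nchar(x)))
  }
  a <- s1; b <- s2; matched <- 0L
  repeat {
    sub <- find_lcs(a, b)
    if (!nzchar(sub)) break
    matched <- matched + nchar(sub)
    a <- remove_first(a, sub)
    b <- remove_first(b, sub)
  }
  comm <- 2 * matched / (l1 + l2)
  u1 <- (l1 - matched) / l1
  u2 <- (l2 - matched) / l2
  p <- 0.6
  den <- p + (1 - p) * (u1 + u2 - u1 * u2)
  diff <- if (den == 0) 0 else u1 * u2 / den
  wink <- 0.1 * prefix_len * (1 - comm)
  min(1, max(0, comm - diff + wink))
}

random_vdoc <- function(max_tokens = 20) {
  vocab <- c("drug", "gene", "disease", "protein", "pathway", "small",
             "molecule", "label", "target", "omim", "kegg", "phenotype")
  k <- sample.int(max_tokens, 1)
  toks <- sample(vocab, k, replace = TRUE)
  w <- tapply(stats::runif(k, 0.1, 3), toks, sum)
  structure(as.numeric(w), names = names(w), class = "virtual_document")
}

random_word <- function(min_len = 1, max_len = 12) {
  n <- sample(seq(min_len, max_len), 1)
  paste(sample(letters[1:8], n, replace = TRUE), collapse = "")
}

# Direct application of the query-interface token grammar: ^[CPS]:\w+ for
# constraints (tag letters case-insensitive), ^(?![CPS]:)\w* free text, a tag
# prefix without a well-formed name is malformed.
classify_token_oracle <- function(tok) {
  if (grepl("^[Cc]:", tok)) {
    if (grepl("^[Cc]:\\w+$", tok)) "class" else "malformed"
  } else if (grepl("^[Pp]:", tok)) {
    if (grepl("^[Pp]:\\w+$", tok)) "property" else "malformed"
  } else if (grepl("^[Ss]:", tok)) {
    if (grepl("^[Ss]:\\w+$", tok)) "dataset" else "malformed"
  } else {
    "plain"
  }
}

classify_token_package <- function(tok) {
  q <- tryCatch(parse_ease(tok), error = function(e) NULL)
  if (is.null(q)) return("malformed")
  if (length(q$plain)) "plain"
  else if (length(q$classes)) "class"
  else if (length(q$properties)) "property"
  else "dataset"
}

random_ease_query <- function(pool = c("alpha", "beta", "gamma", "delta")) {
  nkw <- sample(0:3, 1); ncl <- sample(0:2, 1)
  npr <- sample(0:2, 1); nds <- sample(0:2, 1)
  if (nkw + ncl + npr + nds == 0) nkw <- 1
  structure(list(plain = if (nkw) replicate(nkw, random_word(2, 8)) else character(0),
                 classes = if (ncl) replicate(ncl, random_word(2, 8)) else character(0),
                 properties = if (npr) replicate(npr, random_word(2, 8)) else character(0),
                 datasets = if (nds) replicate(nds, random_word(2, 8)) else character(0)),
            class = "ease_query")
}
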