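# RDF readers and writer.
#
# Triples live in a plain data.frame with columns:
#   s     subject IRI or blank node id ("_:b1")
#   p     predicate IRI
#   o     object IRI, blank node id, or literal lexical form
#   o_lit TRUE when o is a literal
#   lang  language tag or NA
#   dtype datatype IRI or NA
# The set is kept duplicate-free.

empty_triples <- function() {
  data.frame(s = character(0), p = character(0), o = character(0),
             o_lit = logical(0), lang = character(0), dtype = character(0),
             stringsAsFactors = FALSE)
}

make_triples <- function(s, p, o, o_lit = FALSE, lang = NA_character_,
                         dtype = NA_character_) {
  data.frame(s = s, p = p, o = o, o_lit = o_lit, lang = lang, dtype = dtype,
             stringsAsFactors = FALSE)
}

dedup_triples <- function(tr) {
  if (nrow(tr) == 0) return(tr)
  key <- paste(tr$s, tr$p, tr$o, tr$o_lit, tr$lang, tr$dtype, sep = "\r")
  tr <- tr[!duplicated(key), , drop = FALSE]
  rownames(tr) <- NULL
  tr
}

# ---- N-Triples escaping -----------------------------------------------------

nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

nt_unescape <- function(x) {
  vapply(x, function(s) {
    out <- character(0)
    i <- 1L; n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch == "\\" && i < n) {
        nxt <- substr(s, i + 1L, i + 1L)
        if (nxt == "u") {
          code <- substr(s, i + 2L, i + 5L)
          out <- c(out, intToUtf8(strtoi(code, 16L)))
          i <- i + 6L
        } else if (nxt == "U") {
          code <- substr(s, i + 2L, i + 9L)
          out <- c(out, intToUtf8(strtoi(code, 16L)))
          i <- i + 10L
        } else {
          out <- c(out, switch(nxt, n = "\n", r = "\r", t = "\t",
                               "\\" = "\\", "\"" = "\"", "'" = "'", nxt))
          i <- i + 2L
        }
      } else {
        out <- c(out, ch)
        i <- i + 1L
      }
    }
    paste0(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

format_nt_term <- function(value, is_literal, lang, dtype) {
  if (is_literal) {
    lit <- paste0("\"", nt_escape(value), "\"")
    if (!is.na(lang) && nzchar(lang)) {
      paste0(lit, "@", lang)
    } else if (!is.na(dtype) && nzchar(dtype)) {
      paste0(lit, "^^<", dtype, ">")
    } else lit
  } else if (startsWith(value, "_:")) {
    value
  } else {
    paste0("<", value, ">")
  }
}

# ---- N-Triples parser -------------------------------------------------------

NT_TERM <- paste0(
  "(<[^>]*>",                                  # IRI
  "|_:[A-Za-z0-9][A-Za-z0-9_.-]*",             # blank node
  "|\"(?:[^\"\\\\]|\\\\.)*\"",                 # literal
  "(?:@[A-Za-z][A-Za-z0-9-]*|\\^\\^<[^>]*>)?)" # lang / datatype suffix
)

parse_nt_term <- function(tok) {
  if (startsWith(tok, "<")) {
    list(value = substr(tok, 2L, nchar(tok) - 1L), lit = FALSE,
         lang = NA_character_, dtype = NA_character_)
  } else if (startsWith(tok, "_:")) {
    list(value = tok, lit = FALSE, lang = NA_character_, dtype = NA_character_)
  } else {
    lang <- NA_character_; dtype <- NA_character_
    body <- tok
    m <- regexpr("\\^\\^<[^>]*>$", tok)
    if (m > 0) {
      dtype <- substr(tok, m + 3L, nchar(tok) - 1L)
      body <- substr(tok, 1L, m - 1L)
    } else {
      m <- regexpr("@[A-Za-z][A-Za-z0-9-]*$", tok)
      if (m > 0) {
        lang <- substr(tok, m + 1L, nchar(tok))
        body <- substr(tok, 1L, m - 1L)
      }
    }
    list(value = nt_unescape(substr(body, 2L, nchar(body) - 1L)), lit = TRUE,
         lang = lang, dtype = dtype)
  }
}

parse_ntriples <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_triples())
  pat <- paste0("^", NT_TERM, "\\s+", NT_TERM, "\\s+", NT_TERM, "\\s*\\.$")
  rows <- lapply(seq_along(lines), function(i) {
    m <- regmatches(lines[i], regexec(pat, lines[i], perl = TRUE))[[1]]
    if (length(m) < 4) {
      stop(sprintf("N-Triples parse failure at line %d: %s", i, lines[i]),
           call. = FALSE)
    }
    s <- parse_nt_term(m[2]); p <- parse_nt_term(m[3]); o <- parse_nt_term(m[4])
    make_triples(s$value, p$value, o$value, o$lit, o$lang, o$dtype)
  })
  dedup_triples(do.call(rbind, rows))
}

# ---- Turtle parser (pragmatic subset) ---------------------------------------
#
# Supports: @prefix/@base (and SPARQL-style PREFIX/BASE), prefixed names, 'a',
# IRIs, blank node labels, [] anonymous nodes, object lists (','), predicate
# lists (';'), string literals (single/double/triple-quoted) with @lang or
# ^^datatype, integers/decimals/booleans, and comments.

turtle_tokenize <- function(text) {
  n <- nchar(text)
  toks <- character(0)
  lns <- integer(0)
  i <- 1L; line <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "#") {
      while (i <= n && substr(text, i, i) != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (j < 0) stop(sprintf("Turtle parse failure at line %d: unterminated IRI", line), call. = FALSE)
      toks <- c(toks, substr(text, i, i + j - 1L)); lns <- c(lns, line)
      i <- i + j
      next
    }
    if (ch == "\"" || ch == "'") {
      q3 <- substr(text, i, i + 2L)
      quote <- if (q3 == strrep(ch, 3L)) q3 else ch
      j <- i + nchar(quote)
      while (j <= n) {
        if (substr(text, j, j) == "\\") { j <- j + 2L; next }
        if (substr(text, j, j + nchar(quote) - 1L) == quote) break
        if (substr(text, j, j) == "\n") line <- line + 1L
        j <- j + 1L
      }
      if (j > n) stop(sprintf("Turtle parse failure at line %d: unterminated string", line), call. = FALSE)
      j <- j + nchar(quote) - 1L
      # attach any @lang or ^^ suffix to the literal token
      tok <- substr(text, i, j)
      rest <- substr(text, j + 1L, n)
      m <- regexpr("^(@[A-Za-z][A-Za-z0-9-]*|\\^\\^)", rest)
      if (m > 0) {
        suf <- regmatches(rest, m)
        tok <- paste0(tok, suf)
        j <- j + attr(m, "match.length")
      }
      toks <- c(toks, tok); lns <- c(lns, line)
      i <- j + 1L
      next
    }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      # '.' inside a decimal is handled by the number branch below
      toks <- c(toks, ch); lns <- c(lns, line)
      i <- i + 1L
      next
    }
    rest <- substr(text, i, n)
    m <- regexpr("^[+-]?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?", rest)
    if (m > 0) {
      toks <- c(toks, regmatches(rest, m)); lns <- c(lns, line)
      i <- i + attr(m, "match.length")
      next
    }
    m <- regexpr("^[^[:space:]<>\"'.;,\\[\\]()#]+", rest, perl = TRUE)
    if (m > 0) {
      toks <- c(toks, regmatches(rest, m)); lns <- c(lns, line)
      i <- i + attr(m, "match.length")
      next
    }
    stop(sprintf("Turtle parse failure at line %d near '%s'", line,
                 substr(text, i, i + 20L)), call. = FALSE)
  }
  list(tokens = toks, lines = lns)
}

parse_turtle <- function(text) {
  tk <- turtle_tokenize(paste(text, collapse = "\n"))
  toks <- tk$tokens; lns <- tk$lines
  prefixes <- c()
  base <- ""
  acc <- empty_triples()
  bnode_n <- 0L
  pos <- 1L
  npos <- length(toks)

  fail <- function(msg) {
    ln <- if (pos <= npos) lns[pos] else if (npos > 0) lns[npos] else 1L
    stop(sprintf("Turtle parse failure at line %d: %s", ln, msg), call. = FALSE)
  }
  peek <- function() if (pos <= npos) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  expect <- function(t) {
    if (is.na(peek()) || peek() != t) fail(sprintf("expected '%s', got '%s'", t, peek()))
    advance()
  }
  new_bnode <- function() {
    bnode_n <<- bnode_n + 1L
    sprintf("_:genid%d", bnode_n)
  }
  resolve_iri <- function(iri) {
    if (grepl("^[a-zA-Z][a-zA-Z0-9+.-]*:", iri)) iri else paste0(base, iri)
  }
  expand_pname <- function(tok) {
    cpos <- regexpr(":", tok, fixed = TRUE)
    if (cpos < 0) fail(sprintf("expected an RDF term, got '%s'", tok))
    pfx <- substr(tok, 1L, cpos)
    loc <- substr(tok, cpos + 1L, nchar(tok))
    if (!pfx %in% names(prefixes)) fail(sprintf("undeclared prefix '%s'", pfx))
    paste0(prefixes[[pfx]], loc)
  }
  emit <- function(s, p, o) {
    acc <<- rbind(acc, make_triples(s, p, o$value, o$lit, o$lang, o$dtype))
  }
  node <- function(v) list(value = v, lit = FALSE, lang = NA_character_,
                           dtype = NA_character_)

  parse_object <- function(subject_ctx) {
    tok <- peek()
    if (is.na(tok)) fail("unexpected end of input")
    if (startsWith(tok, "<")) {
      advance()
      return(node(resolve_iri(substr(tok, 2L, nchar(tok) - 1L))))
    }
    if (startsWith(tok, "\"") || startsWith(tok, "'")) {
      advance()
      lang <- NA_character_; dtype <- NA_character_
      body <- tok
      if (endsWith(body, "^^")) {
        body <- substr(body, 1L, nchar(body) - 2L)
        dt <- parse_object(subject_ctx)
        dtype <- dt$value
      } else {
        m <- regexpr("@[A-Za-z][A-Za-z0-9-]*$", body)
        if (m > 0) {
          lang <- substr(body, m + 1L, nchar(body))
          body <- substr(body, 1L, m - 1L)
        }
      }
      q <- if (startsWith(body, "\"\"\"") || startsWith(body, "'''")) 3L else 1L
      lex <- nt_unescape(substr(body, q + 1L, nchar(body) - q))
      return(list(value = lex, lit = TRUE, lang = lang, dtype = dtype))
    }
    if (tok == "[") {
      advance()
      b <- new_bnode()
      if (!is.na(peek()) && peek() != "]") parse_predicate_object_list(b)
      expect("]")
      return(node(b))
    }
    if (startsWith(tok, "_:")) { advance(); return(node(tok)) }
    if (grepl("^[+-]?[0-9]", tok)) {
      advance()
      dt <- if (grepl("[.eE]", tok)) paste0(XSD_NS, "decimal") else paste0(XSD_NS, "integer")
      return(list(value = tok, lit = TRUE, lang = NA_character_, dtype = dt))
    }
    if (tok %in% c("true", "false")) {
      advance()
      return(list(value = tok, lit = TRUE, lang = NA_character_,
                  dtype = paste0(XSD_NS, "boolean")))
    }
    advance()
    node(expand_pname(tok))
  }

  parse_predicate <- function() {
    tok <- peek()
    if (is.na(tok)) fail("unexpected end of input")
    if (tok == "a") { advance(); return(RDF_TYPE) }
    if (startsWith(tok, "<")) {
      advance()
      return(resolve_iri(substr(tok, 2L, nchar(tok) - 1L)))
    }
    advance()
    expand_pname(tok)
  }

  parse_predicate_object_list <- function(subj) {
    repeat {
      p <- parse_predicate()
      repeat {
        o <- parse_object(subj)
        emit(subj, p, o)
        if (!is.na(peek()) && peek() == ",") { advance(); next }
        break
      }
      if (!is.na(peek()) && peek() == ";") {
        advance()
        # allow trailing ';' before '.' or ']'
        if (!is.na(peek()) && peek() %in% c(".", "]")) break
        next
      }
      break
    }
  }

  while (!is.na(peek())) {
    tok <- peek()
    if (tok %in% c("@prefix", "PREFIX", "prefix")) {
      advance()
      pfx <- peek(); advance()
      iri_tok <- peek(); advance()
      if (!startsWith(iri_tok, "<")) fail("prefix IRI must be <...>")
      prefixes[[pfx]] <- resolve_iri(substr(iri_tok, 2L, nchar(iri_tok) - 1L))
      if (tok == "@prefix") expect(".")
      next
    }
    if (tok %in% c("@base", "BASE", "base")) {
      advance()
      iri_tok <- peek(); advance()
      base <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      if (tok == "@base") expect(".")
      next
    }
    subj <- parse_object(NULL)
    if (subj$lit) fail("literal cannot be a subject")
    parse_predicate_object_list(subj$value)
    expect(".")
  }
  dedup_triples(acc)
}

# ---- RDF/XML parser ---------------------------------------------------------

parse_rdfxml <- function(path_or_text) {
  doc <- tryCatch(xml2::read_xml(path_or_text),
                  error = function(e) stop(sprintf("RDF/XML parse failure: %s",
                                                   conditionMessage(e)), call. = FALSE))
  acc <- new.env()
  acc$rows <- list()
  acc$bn <- 0L
  emit <- function(s, p, o, lit = FALSE, lang = NA_character_, dtype = NA_character_) {
    acc$rows[[length(acc$rows) + 1L]] <- make_triples(s, p, o, lit, lang, dtype)
  }
  elem_iri <- function(nd) {
    ns <- xml2::xml_ns(nd)
    nm <- xml2::xml_name(nd, ns = ns)
    # xml_name with ns gives "prefix:local"; resolve through the ns map
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[1] %in% names(ns)) {
      paste0(ns[[parts[1]]], parts[2])
    } else {
      nm
    }
  }
  node_id <- function(nd) {
    about <- xml2::xml_attr(nd, "about")
    if (!is.na(about)) return(about)
    nid <- xml2::xml_attr(nd, "nodeID")
    if (!is.na(nid)) return(paste0("_:", nid))
    idv <- xml2::xml_attr(nd, "ID")
    if (!is.na(idv)) return(paste0("#", idv))
    acc$bn <- acc$bn + 1L
    sprintf("_:genid%d", acc$bn)
  }
  walk_node <- function(nd) {
    subj <- node_id(nd)
    ei <- elem_iri(nd)
    if (ei != paste0(RDF_NS, "Description")) emit(subj, RDF_TYPE, ei)
    for (prop in xml2::xml_children(nd)) {
      pred <- elem_iri(prop)
      res <- xml2::xml_attr(prop, "resource")
      nid <- xml2::xml_attr(prop, "nodeID")
      kids <- xml2::xml_children(prop)
      if (!is.na(res)) {
        emit(subj, pred, res)
      } else if (!is.na(nid)) {
        emit(subj, pred, paste0("_:", nid))
      } else if (length(kids) > 0) {
        obj <- walk_node(kids[[1]])
        emit(subj, pred, obj)
      } else {
        lang <- xml2::xml_attr(prop, "lang")
        dtype <- xml2::xml_attr(prop, "datatype")
        emit(subj, pred, xml2::xml_text(prop), lit = TRUE,
             lang = if (is.na(lang)) NA_character_ else lang,
             dtype = if (is.na(dtype)) NA_character_ else dtype)
      }
    }
    subj
  }
  for (nd in xml2::xml_children(doc)) walk_node(nd)
  if (length(acc$rows) == 0) return(empty_triples())
  dedup_triples(do.call(rbind, acc$rows))
}

# ---- Canonical writer -------------------------------------------------------

#' Write a graph as canonical N-Triples
#'
#' One triple per line, duplicate-free, lines sorted bytewise — so two graphs
#' with equal triple sets serialize to byte-identical files. The output is
#' also valid Turtle.
#'
#' @param graph A [dataset_graph()].
#' @param path Output file path; with `path = NULL` the lines are returned.
#' @return Invisibly (or visibly for `path = NULL`) the character vector of
#'   sorted triple lines.
#' @export
write_ntriples <- function(graph, path = NULL) {
  tr <- graph$triples
  lines <- if (nrow(tr) == 0) character(0) else {
    vapply(seq_len(nrow(tr)), function(i) {
      paste(format_nt_term(tr$s[i], FALSE, NA, NA),
            format_nt_term(tr$p[i], FALSE, NA, NA),
            format_nt_term(tr$o[i], tr$o_lit[i], tr$lang[i], tr$dtype[i]),
            ".")
    }, character(1))
  }
  lines <- sort(unique(lines), method = "radix")
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

# ---- Loading ----------------------------------------------------------------

#' Load an RDF dataset
#'
#' Reads a local RDF file (Turtle, N-Triples or RDF/XML) or registers a
#' SPARQL 1.1 endpoint, producing the in-memory graph object the rest of the
#' package works with.
#'
#' @param source File path, or endpoint URL for `format = "endpoint"`.
#' @param format One of `"turtle"`, `"ntriples"`, `"rdfxml"`, `"endpoint"`;
#'   the default guesses from the file extension.
#' @param dataset_name Identifier of the dataset; defaults to the file stem.
#' @param graph_iri Optional named-graph IRI used by the named-graph SPARQL
#'   dialect.
#' @return A `dataset_graph` object.
#' @export
load_graph <- function(source, format = NULL, dataset_name = NULL,
                       graph_iri = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(source)),
                     ttl = "turtle", turtle = "turtle",
                     nt = "ntriples", ntriples = "ntriples",
                     rdf = "rdfxml", xml = "rdfxml", owl = "rdfxml",
                     stop("Cannot guess RDF format from extension of ", source,
                          call. = FALSE))
  }
  format <- match.arg(format, c("turtle", "ntriples", "rdfxml", "endpoint"))
  if (is.null(dataset_name)) {
    dataset_name <- tools::file_path_sans_ext(basename(source))
  }
  if (format == "endpoint") {
    return(dataset_graph(dataset_name, triples = empty_triples(),
                         source = source, graph_iri = graph_iri,
                         endpoint = source))
  }
  if (!file.exists(source)) {
    stop("RDF source does not exist: ", source, call. = FALSE)
  }
  text <- readLines(source, warn = FALSE, encoding = "UTF-8")
  triples <- switch(format,
                    turtle   = parse_turtle(text),
                    ntriples = parse_ntriples(text),
                    rdfxml   = parse_rdfxml(paste(text, collapse = "\n")))
  dataset_graph(dataset_name, triples = triples, source = source,
                graph_iri = graph_iri)
}

# ---- Dataset registry -------------------------------------------------------

#' Read a dataset registry file
#'
#' YAML mapping `datasets: {name: {source, format, graph_iri}}` naming the
#' datasets available to federated search.
#'
#' @param path Registry file path.
#' @return A named list of registry entries (class `dataset_registry`).
#' @export
read_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$datasets %||% cfg
  reg <- lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    list(dataset_name = nm, source = e$source,
         format = e$format %||% NULL, graph_iri = e$graph_iri %||% NULL)
  })
  names(reg) <- names(entries)
  structure(reg, class = "dataset_registry")
}

#' Build a registry from loaded graphs
#'
#' @param graphs A list of `dataset_graph` objects.
#' @return A `dataset_registry` whose entries carry the graphs in memory.
#' @export
registry_from_graphs <- function(graphs) {
  nms <- vapply(graphs, function(g) g$dataset_name, character(1))
  reg <- lapply(graphs, function(g) {
    list(dataset_name = g$dataset_name, source = g$source,
         format = NULL, graph_iri = g$graph_iri, graph = g)
  })
  names(reg) <- nms
  structure(reg, class = "dataset_registry")
}

registry_graph <- function(registry, name) {
  entry <- registry[[name]]
  if (is.null(entry)) stop("Unknown dataset: ", name, call. = FALSE)
  if (!is.null(entry$graph)) return(entry$graph)
  load_graph(entry$source, format = entry$format, dataset_name = name,
             graph_iri = entry$graph_iri)
}

# ---- SPARQL protocol client -------------------------------------------------

#' Run a SPARQL SELECT against an endpoint
#'
#' Minimal SPARQL 1.1 Protocol client (GET with JSON results). Only used for
#' endpoint-backed graphs; local graphs are evaluated in memory.
#'
#' @param endpoint Endpoint URL.
#' @param query SPARQL SELECT string.
#' @return A data.frame with one column per selected variable.
#' @export
sparql_select <- function(endpoint, query) {
  url <- paste0(endpoint, if (grepl("\\?", endpoint)) "&" else "?",
                "query=", utils::URLencode(query, reserved = TRUE),
                "&format=application%2Fsparql-results%2Bjson")
  res <- tryCatch(jsonlite::fromJSON(url, simplifyVector = FALSE),
                  error = function(e) stop("SPARQL endpoint unreachable: ",
                                           endpoint, " (", conditionMessage(e), ")",
                                           call. = FALSE))
  vars <- unlist(res$head$vars)
  rows <- res$results$bindings
  out <- lapply(vars, function(v) {
    vapply(rows, function(b) b[[v]]$value %||% NA_character_, character(1))
  })
  names(out) <- vars
  as.data.frame(out, stringsAsFactors = FALSE)
}
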