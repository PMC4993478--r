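# Readers and writers for the RDF serializations accepted at schema level.
# Literal-valued objects are parsed but marked, so the graph builder can drop
# and count them; blank nodes are carried through as "_:" identifiers.

#' Read triples from an N-Triples file
#'
#' Parses a line-oriented N-Triples document into a triple table. Objects that
#' are literals are kept with `object = NA` and the literal text in
#' `literal`, so callers can count dropped instance statements.
#'
#' @param path Path to a `.nt` file.
#' @return A data.frame with columns `subject`, `predicate`, `object`
#'   (NA for literal objects) and `literal`.
#' @export
read_ntriples <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read N-Triples file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(empty_triples())
  }
  pat <- "^(<[^>]*>|_:[A-Za-z0-9._-]+)\\s+<([^>]*)>\\s+(.*?)\\s*\\.\\s*$"
  m <- regmatches(lines, regexec(pat, lines))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed N-Triples line(s) in ", path, ": ",
         paste(utils::head(lines[bad], 3L), collapse = " | "), call. = FALSE)
  }
  subj <- vapply(m, `[`, "", 2L)
  pred <- vapply(m, `[`, "", 3L)
  obj_raw <- vapply(m, `[`, "", 4L)
  subj <- ifelse(startsWith(subj, "<"), substr(subj, 2L, nchar(subj) - 1L), subj)
  is_uri <- startsWith(obj_raw, "<")
  is_bnode <- startsWith(obj_raw, "_:")
  obj <- rep(NA_character_, length(obj_raw))
  obj[is_uri] <- substr(obj_raw[is_uri], 2L, nchar(obj_raw[is_uri]) - 1L)
  obj[is_bnode] <- obj_raw[is_bnode]
  literal <- ifelse(is_uri | is_bnode, NA_character_, obj_raw)
  data.frame(subject = subj, predicate = pred, object = obj,
             literal = literal, stringsAsFactors = FALSE)
}

empty_triples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), literal = character(),
             stringsAsFactors = FALSE)
}

# Tokenizer for the Turtle subset: IRIs, prefixed names, blank nodes,
# literals (language/datatype tags), keywords and punctuation.
turtle_tokens <- function(text) {
  # strip comments outside of quoted strings / IRIs
  text <- gsub("(?<![<\"])#[^\n]*", "", text, perl = TRUE)
  pat <- paste0(
    "<[^>]*>",
    "|\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^<[^>]*>|\\^\\^[A-Za-z][\\w.-]*:[\\w.-]*|@[A-Za-z][A-Za-z0-9-]*)?",
    "|'(?:[^'\\\\]|\\\\.)*'",
    "|_:[A-Za-z0-9._-]+",
    "|@prefix|@base|\\bPREFIX\\b|\\bBASE\\b",
    "|[A-Za-z][\\w.-]*:[^\\s;,.\\]\\)]*",
    "|:[^\\s;,.\\]\\)]+",
    "|\\ba\\b",
    "|[;,.]",
    "|[+-]?[0-9][\\w.]*",
    "|\\S+"
  )
  regmatches(text, gregexpr(pat, text, perl = TRUE))[[1L]]
}

#' Read triples from a Turtle file
#'
#' Supports the common Turtle subset used by vocabulary dumps: `@prefix` /
#' `PREFIX` declarations, prefixed names, absolute IRIs, the `a` keyword,
#' `;` and `,` continuation lists, comments, and plain/typed/lang literals
#' (kept as literal objects). Blank-node property lists are not supported.
#'
#' @inheritParams read_ntriples
#' @return As [read_ntriples()].
#' @export
read_turtle <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read Turtle file: ", path, call. = FALSE)
  }
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  toks <- turtle_tokens(text)
  toks <- toks[nzchar(toks)]
  prefixes <- character()
  base <- ""
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

  expand <- function(tok) {
    if (startsWith(tok, "<")) {
      uri <- substr(tok, 2L, nchar(tok) - 1L)
      if (nzchar(base) && !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", uri)) {
        uri <- paste0(base, uri)
      }
      return(list(kind = "uri", value = uri))
    }
    if (startsWith(tok, "_:")) return(list(kind = "uri", value = tok))
    if (tok == "a") return(list(kind = "uri", value = rdf_type))
    if (startsWith(tok, "\"") || startsWith(tok, "'")) {
      return(list(kind = "literal", value = tok))
    }
    if (grepl("^[A-Za-z][\\w.-]*:", tok, perl = TRUE) || startsWith(tok, ":")) {
      pre <- sub(":.*$", "", tok)
      local <- sub("^[^:]*:", "", tok)
      if (!is.na(prefixes[pre]) && pre %in% names(prefixes)) {
        return(list(kind = "uri", value = paste0(prefixes[[pre]], local)))
      }
      # absolute IRI written without <> (e.g. http://...) or unknown prefix
      if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", tok)) {
        return(list(kind = "uri", value = tok))
      }
      stop("undeclared Turtle prefix '", pre, ":' in token ", tok, call. = FALSE)
    }
    list(kind = "literal", value = tok)
  }

  rows <- list()
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    tok <- toks[i]
    if (tok %in% c("@prefix", "PREFIX")) {
      pre <- sub(":$", "", toks[i + 1L])
      iri <- toks[i + 2L]
      prefixes[pre] <- substr(iri, 2L, nchar(iri) - 1L)
      i <- i + 3L
      if (i <= n && toks[i] == ".") i <- i + 1L
      next
    }
    if (tok %in% c("@base", "BASE")) {
      iri <- toks[i + 1L]
      base <- substr(iri, 2L, nchar(iri) - 1L)
      i <- i + 2L
      if (i <= n && toks[i] == ".") i <- i + 1L
      next
    }
    subj <- expand(tok)
    if (subj$kind != "uri") stop("Turtle parse error: literal subject ", tok, call. = FALSE)
    i <- i + 1L
    repeat {                                  # predicate-object lists
      pred <- expand(toks[i])
      i <- i + 1L
      repeat {                                # object lists
        obj <- expand(toks[i])
        i <- i + 1L
        rows[[length(rows) + 1L]] <- c(
          subj$value, pred$value,
          if (obj$kind == "uri") obj$value else NA_character_,
          if (obj$kind == "uri") NA_character_ else obj$value
        )
        if (i <= n && toks[i] == ",") { i <- i + 1L; next }
        break
      }
      if (i <= n && toks[i] == ";") {
        i <- i + 1L
        if (i <= n && toks[i] %in% c(".", ";")) next  # trailing ;
        if (i > n) break
        next
      }
      break
    }
    if (i <= n && toks[i] == ".") i <- i + 1L
  }
  if (length(rows) == 0L) return(empty_triples())
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("subject", "predicate", "object", "literal")
  out
}

#' Read triples from an RDF/XML file
#'
#' Handles the node-centric RDF/XML style: `rdf:Description` or typed-node
#' elements with `rdf:about`/`rdf:nodeID`, property elements with
#' `rdf:resource` or nested node elements, and text-content literals.
#'
#' @inheritParams read_ntriples
#' @return As [read_ntriples()].
#' @export
read_rdfxml <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read RDF/XML file: ", path, call. = FALSE)
  }
  rdf_ns <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  doc <- xml2::read_xml(path)
  rows <- list()

  node_uri <- function(node) {
    about <- xml2::xml_attr(node, "about")
    if (!is.na(about)) return(about)
    id <- xml2::xml_attr(node, "ID")
    if (!is.na(id)) return(paste0("#", id))
    nid <- xml2::xml_attr(node, "nodeID")
    if (!is.na(nid)) return(paste0("_:", nid))
    paste0("_:genid", length(rows) + 1L)
  }
  qname_uri <- function(node) {
    ns <- xml2::xml_ns(doc)
    full <- xml2::xml_name(node, ns = ns)
    if (grepl(":", full, fixed = TRUE)) {
      pre <- sub(":.*$", "", full)
      paste0(unname(ns[[pre]]), sub("^[^:]*:", "", full))
    } else {
      full
    }
  }
  walk <- function(node) {
    subj <- node_uri(node)
    qn <- qname_uri(node)
    if (qn != paste0(rdf_ns, "Description")) {
      rows[[length(rows) + 1L]] <<- c(subj, paste0(rdf_ns, "type"), qn, NA_character_)
    }
    for (prop in xml2::xml_children(node)) {
      pred <- qname_uri(prop)
      res <- xml2::xml_attr(prop, "resource")
      kids <- xml2::xml_children(prop)
      if (!is.na(res)) {
        rows[[length(rows) + 1L]] <<- c(subj, pred, res, NA_character_)
      } else if (length(kids) > 0L) {
        child_uri <- node_uri(kids[[1L]])
        rows[[length(rows) + 1L]] <<- c(subj, pred, child_uri, NA_character_)
        walk(kids[[1L]])
      } else {
        txt <- xml2::xml_text(prop)
        rows[[length(rows) + 1L]] <<- c(subj, pred, NA_character_, txt)
      }
    }
  }
  for (node in xml2::xml_children(doc)) walk(node)
  if (length(rows) == 0L) return(empty_triples())
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("subject", "predicate", "object", "literal")
  out
}

#' Read a triple file, dispatching on serialization
#'
#' @param path Input file.
#' @param format One of `"ntriples"`, `"turtle"`, `"rdfxml"`, or `NULL` to
#'   infer from the file extension (`.nt`, `.ttl`, `.rdf`/`.owl`/`.xml`).
#' @return As [read_ntriples()].
#' @export
read_rdf <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      nt = "ntriples", ntriples = "ntriples",
      ttl = "turtle", turtle = "turtle",
      rdf = "rdfxml", owl = "rdfxml", xml = "rdfxml",
      stop("cannot infer RDF serialization from extension: ", path, call. = FALSE)
    )
  }
  format <- match.arg(format, c("ntriples", "turtle", "rdfxml"))
  switch(format,
    ntriples = read_ntriples(path),
    turtle = read_turtle(path),
    rdfxml = read_rdfxml(path)
  )
}

#' Write triples as sorted N-Triples
#'
#' Lines are emitted in lexicographic order so repeated runs produce
#' byte-identical, diff-stable files. Only URI-object triples are written.
#' The same body is valid Turtle, so `format = "turtle"` writes identical
#' statements under a `.ttl`-appropriate convention.
#'
#' @param triples Data frame with `subject`, `predicate`, `object` columns.
#' @param path Output file.
#' @param format `"ntriples"` or `"turtle"`.
#' @return `path`, invisibly.
#' @export
write_ntriples <- function(triples, path, format = c("ntriples", "turtle")) {
  format <- match.arg(format)
  keep <- !is.na(triples$object)
  tr <- triples[keep, , drop = FALSE]
  term <- function(x) ifelse(startsWith(x, "_:"), x, paste0("<", x, ">"))
  lines <- sprintf("%s %s %s .", term(tr$subject), term(tr$predicate), term(tr$object))
  lines <- sort(unique(lines), method = "radix")
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write triples to: ", path, call. = FALSE)
  invisible(path)
}

#' Read a two-column TSV mapping namespace prefixes to domain names
#'
#' @param path TSV with columns `prefix` (absolute URI prefix) and `domain`
#'   (short domain token); a header row is optional.
#' @return Named character vector: `domain` names keyed by URI prefix.
#' @export
read_namespace_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("namespace map needs two tab-separated columns", call. = FALSE)
  if (identical(tolower(df[1, 1]), "prefix")) df <- df[-1, , drop = FALSE]
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a two-column TSV mapping source concept URIs to target URIs
#'
#' Used for concept normalization tables (e.g. mapping domain concepts onto
#' shared upper-ontology classes).
#'
#' @param path TSV with columns `source` and `target`.
#' @return Named character vector: target URI keyed by source URI.
#' @export
read_concept_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("concept map needs two tab-separated columns", call. = FALSE)
  if (identical(tolower(df[1, 1]), "source")) df <- df[-1, , drop = FALSE]
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
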