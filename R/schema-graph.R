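# The heterogeneous schema graph: a directed graph alternating concept nodes
# and predicate nodes, every node labelled with the domain (source vocabulary)
# its namespace belongs to. All pattern mining, association scoring and
# clustering operate on this object.

BUILTIN_NAMESPACES <- c(
  "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  "http://www.w3.org/2000/01/rdf-schema#",
  "http://www.w3.org/2002/07/owl#",
  "http://www.w3.org/2001/XMLSchema#"
)

#' Remove RDF/RDFS/OWL/XSD built-in predicates from a triple table
#'
#' Only domain-specific predicates take part in neighborhood patterns, so
#' statements whose predicate lives in the RDF, RDFS, OWL or XML Schema
#' namespaces are dropped. The order of surviving rows is preserved.
#'
#' @param triples Data frame with at least a `predicate` column.
#' @return The filtered data frame.
#' @export
filter_builtins <- function(triples) {
  if (nrow(triples) == 0L) return(triples)
  builtin <- Reduce(`|`, lapply(BUILTIN_NAMESPACES, function(ns) {
    startsWith(triples$predicate, ns)
  }))
  triples[!builtin, , drop = FALSE]
}

#' Assign a domain to each URI by longest-matching namespace prefix
#'
#' @param uris Character vector of absolute URIs.
#' @param namespace_map Named character vector: domain name keyed by URI
#'   prefix (see [read_namespace_map()]).
#' @param strict If `TRUE`, an unmatched URI is an error listing the URI;
#'   if `FALSE`, unmatched URIs get domain `"unknown"`.
#' @return Character vector of domain names.
#' @export
assign_domains <- function(uris, namespace_map, strict = TRUE) {
  prefixes <- names(namespace_map)
  ord <- order(nchar(prefixes), decreasing = TRUE)   # longest prefix wins
  prefixes <- prefixes[ord]
  domains <- unname(namespace_map)[ord]
  out <- rep(NA_character_, length(uris))
  for (k in seq_along(prefixes)) {
    hit <- is.na(out) & startsWith(uris, prefixes[k])
    out[hit] <- domains[k]
  }
  if (anyNA(out)) {
    if (strict) {
      stop("no domain for URI(s): ",
           paste(utils::head(unique(uris[is.na(out)]), 5L), collapse = ", "),
           call. = FALSE)
    }
    out[is.na(out)] <- "unknown"
  }
  out
}

apply_concept_map <- function(uris, mapping) {
  if (is.null(mapping) || length(mapping) == 0L) return(uris)
  if (anyDuplicated(names(mapping))) {
    stop("concept map is not a function: duplicated source URI", call. = FALSE)
  }
  # reject cycles (a -> b -> ... -> a); chains are fine, applied once
  for (src in names(mapping)) {
    seen <- src
    cur <- src
    while (cur %in% names(mapping)) {
      cur <- unname(mapping[[cur]])
      if (cur %in% seen) stop("cyclic concept mapping at: ", src, call. = FALSE)
      seen <- c(seen, cur)
    }
  }
  hit <- uris %in% names(mapping)
  uris[hit] <- unname(mapping[uris[hit]])          # single application
  uris
}

#' Build a heterogeneous schema graph from a triple table
#'
#' Drops literal-valued triples (counting them), removes built-in
#' predicates, applies an optional concept-normalization map before node
#' creation, collapses repeated (S,P,O) statements into one schema edge with
#' an occurrence count, and labels every concept and predicate with a domain
#' by longest-matching namespace prefix.
#'
#' @param triples Data frame with `subject`, `predicate`, `object` columns
#'   (an optional `literal` column marks literal objects, `object = NA`).
#' @param namespace_map Named character vector: domain name keyed by URI
#'   prefix.
#' @param concept_map Optional named character vector mapping concept URIs
#'   onto normalized target URIs (applied once, then nodes merged).
#' @param strict Domain-assignment policy, see [assign_domains()].
#' @return An object of class `schema_graph`: a list with elements
#'   `triples` (collapsed schema edges with `count`), `concepts`,
#'   `predicates` (node tables with `uri`, `domain`, degrees), `cp`
#'   (per-predicate subject/object concept sets), `domains`, and
#'   `n_literals_dropped`.
#' @export
schema_graph <- function(triples, namespace_map, concept_map = NULL,
                         strict = TRUE) {
  stopifnot(is.data.frame(triples),
            all(c("subject", "predicate", "object") %in% names(triples)))
  n_lit <- sum(is.na(triples$object))
  tr <- triples[!is.na(triples$object), c("subject", "predicate", "object"),
                drop = FALSE]
  tr <- filter_builtins(tr)
  # blank nodes carry no namespace; schema level drops them like literals
  bn <- startsWith(tr$subject, "_:") | startsWith(tr$object, "_:")
  tr <- tr[!bn, , drop = FALSE]
  tr$subject <- apply_concept_map(tr$subject, concept_map)
  tr$object <- apply_concept_map(tr$object, concept_map)

  if (nrow(tr) > 0L) {
    key <- paste(tr$subject, tr$predicate, tr$object, sep = "\r")
    agg <- table(key)
    first <- !duplicated(key)
    tr <- tr[first, , drop = FALSE]
    tr$count <- as.integer(agg[paste(tr$subject, tr$predicate, tr$object,
                                     sep = "\r")])
    tr <- tr[order(tr$predicate, tr$subject, tr$object, method = "radix"), ,
             drop = FALSE]
    rownames(tr) <- NULL
  } else {
    tr$count <- integer()
  }

  pred_uris <- sort(unique(tr$predicate), method = "radix")
  con_uris <- sort(unique(c(tr$subject, tr$object)), method = "radix")

  cp <- lapply(pred_uris, function(p) {
    rows <- tr[tr$predicate == p, , drop = FALSE]
    list(subjects = sort(unique(rows$subject), method = "radix"),
         objects = sort(unique(rows$object), method = "radix"))
  })
  names(cp) <- pred_uris

  concepts <- data.frame(
    uri = con_uris,
    domain = if (length(con_uris)) assign_domains(con_uris, namespace_map, strict)
             else character(),
    in_degree = vapply(con_uris, function(u) sum(tr$object == u), 1L),
    out_degree = vapply(con_uris, function(u) sum(tr$subject == u), 1L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  predicates <- data.frame(
    uri = pred_uris,
    domain = if (length(pred_uris)) assign_domains(pred_uris, namespace_map, strict)
             else character(),
    in_degree = vapply(pred_uris, function(p)
      length(unique(tr$subject[tr$predicate == p])), 1L),
    out_degree = vapply(pred_uris, function(p)
      length(unique(tr$object[tr$predicate == p])), 1L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  domains <- sort(unique(c(concepts$domain, predicates$domain)), method = "radix")

  g <- structure(
    list(triples = tr, concepts = concepts, predicates = predicates,
         cp = cp, domains = domains, namespace_map = namespace_map,
         n_literals_dropped = n_lit),
    class = "schema_graph"
  )
  validate_schema_graph(g)
  g
}

validate_schema_graph <- function(g) {
  for (p in names(g$cp)) {
    if (length(g$cp[[p]]$subjects) == 0L || length(g$cp[[p]]$objects) == 0L) {
      stop("predicate without both subject and object edges: ", p, call. = FALSE)
    }
  }
  if (any(g$triples$subject %in% g$predicates$uri) ||
      any(g$triples$object %in% g$predicates$uri)) {
    stop("alternation violated: a URI is used both as concept and predicate",
         call. = FALSE)
  }
  invisible(g)
}

#' Load one or more ontology files into a schema graph
#'
#' @param paths Character vector of RDF files.
#' @param namespace_map Named character vector (domain by URI prefix) or the
#'   path of a two-column TSV.
#' @param format Serialization passed to [read_rdf()]; `NULL` infers per file.
#' @param concept_map Optional normalization map (named vector or TSV path).
#' @param strict Domain-assignment policy.
#' @return A `schema_graph`.
#' @export
load_ontologies <- function(paths, namespace_map, format = NULL,
                            concept_map = NULL, strict = TRUE) {
  if (is.character(namespace_map) && length(namespace_map) == 1L &&
      file.exists(namespace_map)) {
    namespace_map <- read_namespace_map(namespace_map)
  }
  if (is.character(concept_map) && length(concept_map) == 1L &&
      file.exists(concept_map)) {
    concept_map <- read_concept_map(concept_map)
  }
  parts <- lapply(paths, read_rdf, format = format)
  schema_graph(do.call(rbind, parts), namespace_map,
               concept_map = concept_map, strict = strict)
}

#' Re-apply a concept-normalization map to an existing graph
#'
#' Mapped concept URIs are replaced by their targets; colliding nodes merge
#' and every predicate's concept sets are updated.
#'
#' @param graph A `schema_graph`.
#' @param mapping Named character vector, target URI keyed by source URI.
#' @return A new `schema_graph`.
#' @export
normalize_concepts <- function(graph, mapping) {
  stopifnot(inherits(graph, "schema_graph"))
  if (is.null(mapping) || length(mapping) == 0L) return(graph)
  tr <- graph$triples
  tr$subject <- apply_concept_map(tr$subject, mapping)
  tr$object <- apply_concept_map(tr$object, mapping)
  tr <- tr[rep(seq_len(nrow(tr)), tr$count), c("subject", "predicate", "object"),
           drop = FALSE]
  schema_graph(tr, graph$namespace_map, strict = FALSE)
}

#' Concept neighborhood of a predicate
#'
#' The set C(P): every concept directly connected to predicate `p`
#' regardless of direction (its subjects union its objects).
#'
#' @param graph A `schema_graph`.
#' @param p Predicate URI.
#' @return Sorted character vector of concept URIs.
#' @export
concept_neighborhood <- function(graph, p) {
  stopifnot(inherits(graph, "schema_graph"))
  if (!p %in% names(graph$cp)) {
    stop("unknown predicate: ", p, call. = FALSE)
  }
  sort(unique(c(graph$cp[[p]]$subjects, graph$cp[[p]]$objects)), method = "radix")
}

#' Convert a schema graph to an igraph object
#'
#' Nodes are concepts and predicates (attribute `kind`), edges the directed
#' subject-role (concept to predicate) and object-role (predicate to
#' concept) links, with occurrence counts as weights.
#'
#' @param graph A `schema_graph`.
#' @return An igraph directed graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "schema_graph"))
  tr <- graph$triples
  sub_edges <- unique(data.frame(from = tr$subject, to = tr$predicate,
                                 stringsAsFactors = FALSE))
  obj_edges <- unique(data.frame(from = tr$predicate, to = tr$object,
                                 stringsAsFactors = FALSE))
  nodes <- data.frame(
    name = c(graph$concepts$uri, graph$predicates$uri),
    kind = c(rep("concept", nrow(graph$concepts)),
             rep("predicate", nrow(graph$predicates))),
    domain = c(graph$concepts$domain, graph$predicates$domain),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(rbind(sub_edges, obj_edges),
                                directed = TRUE, vertices = nodes)
}

#' Export a schema graph
#'
#' @param graph A `schema_graph`.
#' @param path Output file.
#' @param format `"ntriples"`, `"turtle"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_schema_graph <- function(graph, path,
                               format = c("ntriples", "turtle", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  } else {
    tr <- graph$triples[rep(seq_len(nrow(graph$triples)), graph$triples$count), ,
                        drop = FALSE]
    write_ntriples(tr, path, format = format)
  }
  invisible(path)
}

#' @export
print.schema_graph <- function(x, ...) {
  cat("Heterogeneous schema graph\n")
  cat(sprintf("  %d concepts, %d predicates, %d schema edges (%d statements)\n",
              nrow(x$concepts), nrow(x$predicates), nrow(x$triples),
              sum(x$triples$count)))
  cat(sprintf("  domains (%d): %s\n", length(x$domains),
              paste(x$domains, collapse = ", ")))
  if (x$n_literals_dropped > 0L) {
    cat(sprintf("  (%d literal-valued statements dropped)\n", x$n_literals_dropped))
  }
  invisible(x)
}

#' @export
summary.schema_graph <- function(object, ...) {
  per_dom <- do.call(rbind, lapply(object$domains, function(d) {
    data.frame(domain = d,
               predicates = sum(object$predicates$domain == d),
               concepts = sum(object$concepts$domain == d),
               stringsAsFactors = FALSE)
  }))
  structure(list(graph = object, per_domain = per_dom),
            class = "summary.schema_graph")
}

#' @export
print.summary.schema_graph <- function(x, ...) {
  print(x$graph)
  cat("\nPer-domain node counts:\n")
  print(x$per_domain, row.names = FALSE)
  invisible(x)
}
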