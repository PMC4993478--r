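# Rankings, per-topic statistics, and the domain-collaboration graph with
# role classification.

pattern_pred_sets <- function(patterns) {
  strsplit(patterns$predicates, "|", fixed = TRUE)
}

cross_domain_items <- function(patterns) {
  cr <- patterns[patterns$cross_domain, , drop = FALSE]
  list(
    predicates = sort(unique(unlist(pattern_pred_sets(cr))), method = "radix"),
    concepts = sort(unique(unlist(strsplit(cr$anchors, "|", fixed = TRUE))),
                    method = "radix")
  )
}

#' Rank concepts or predicates by degree
#'
#' Popularity is in-degree plus out-degree on the schema graph (per-
#' direction scores retained). With `scope = "cross_domain"` only nodes
#' taking part in at least one cross-domain pattern are ranked: predicates
#' that are members, concepts that are anchors. Participation is judged on
#' the share patterns and directed connector chains; the non-directional
#' relaxation is excluded since it marks nearly every connected predicate
#' and would make the scope vacuous. Ties are ordered lexicographically by
#' URI so the ranking is input-order independent.
#'
#' @param graph A `schema_graph`.
#' @param kind `"predicate"` or `"concept"`.
#' @param scope `"all"` or `"cross_domain"`.
#' @param top_k Truncation cutoff (default 40).
#' @param patterns Patterns for the participation test; when `NULL`,
#'   Provider/Consumer/Reacher/DC patterns are mined on the fly.
#' @return Data frame `uri`, `domain`, `in_degree`, `out_degree`, `score`,
#'   sorted non-increasing by score.
#' @export
rank_nodes <- function(graph, kind = c("predicate", "concept"),
                       scope = c("all", "cross_domain"), top_k = 40L,
                       patterns = NULL) {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  tab <- if (kind == "predicate") graph$predicates else graph$concepts
  if (nrow(tab) == 0L) {
    return(data.frame(uri = character(), domain = character(),
                      in_degree = integer(), out_degree = integer(),
                      score = integer(), stringsAsFactors = FALSE))
  }
  if (scope == "cross_domain") {
    if (is.null(patterns)) {
      patterns <- mine_patterns(graph, c("PROVIDER", "CONSUMER", "REACHER", "DC"))
    }
    keep <- cross_domain_items(patterns)
    tab <- tab[tab$uri %in%
                 (if (kind == "predicate") keep$predicates else keep$concepts),
               , drop = FALSE]
  }
  tab$score <- tab$in_degree + tab$out_degree
  tab <- tab[order(-tab$score, tab$uri, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, top_k)
}

#' Rank topics by cross-domain features
#'
#' Per topic: the number of member predicates participating in cross-domain
#' patterns, popularity (summed member in+out degrees), and verity (the
#' number of domains). Topics are ordered lexicographically by those three
#' keys (then id for determinism).
#'
#' @param topics Topic list (or a `phal` object).
#' @param graph A `schema_graph`.
#' @param patterns Mined patterns (mined on the fly when `NULL`).
#' @return Data frame `topic`, `cross_domain_predicates`, `popularity`,
#'   `verity`, sorted by rank.
#' @export
topic_feature_rank <- function(topics, graph, patterns = NULL) {
  if (inherits(topics, "phal")) topics <- topics$topics
  if (is.null(patterns)) patterns <- mine_patterns(graph)
  cross_preds <- cross_domain_items(patterns)$predicates
  deg <- stats::setNames(graph$predicates$in_degree + graph$predicates$out_degree,
                         graph$predicates$uri)
  dom <- pred_domain(graph)
  df <- do.call(rbind, lapply(topics, function(tp) {
    data.frame(
      topic = tp$id,
      cross_domain_predicates = sum(tp$predicates %in% cross_preds),
      popularity = sum(deg[tp$predicates], na.rm = TRUE),
      verity = length(unique(dom[tp$predicates])),
      stringsAsFactors = FALSE
    )
  }))
  df <- df[order(-df$cross_domain_predicates, -df$popularity, -df$verity,
                 df$topic), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Rank topics by contained pattern counts
#'
#' A pattern counts for a topic only when all its predicates fall inside
#' the topic; per-type counts and the total are reported.
#'
#' @param topics Topic list (or a `phal` object).
#' @param patterns Mined patterns.
#' @return Data frame with per-type columns and `total`, sorted by total.
#' @export
topic_pattern_rank <- function(topics, patterns) {
  if (inherits(topics, "phal")) topics <- topics$topics
  psets <- pattern_pred_sets(patterns)
  df <- do.call(rbind, lapply(topics, function(tp) {
    inside <- vapply(psets, function(s) all(s %in% tp$predicates), TRUE)
    counts <- vapply(PATTERN_TYPES, function(tpy) {
      sum(inside & patterns$type == tpy)
    }, 1L)
    out <- data.frame(topic = tp$id, stringsAsFactors = FALSE)
    for (tpy in PATTERN_TYPES) out[[tolower(tpy)]] <- counts[[tpy]]
    out$total <- sum(counts)
    out
  }))
  df <- df[order(-df$total, df$topic), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-topic statistics
#'
#' Counts nodes and edges of the topic-induced subgraph (member predicates,
#' their induced concepts, and the incident schema edges), the density
#' `D = 2E / (N (N - 1))` (0 when `N < 2`), the mean association score over
#' member predicate pairs with positive association, the diversity (number
#' of domains), and summed member degrees.
#'
#' @param topic A topic record (list with `predicates`).
#' @param graph A `schema_graph`.
#' @param matrix Association matrix used for the mean association score.
#' @return One-row data frame.
#' @export
topic_stats <- function(topic, graph, matrix) {
  preds <- topic$predicates
  stopifnot(length(preds) >= 1L)
  cs <- sort(unique(unlist(lapply(preds, concept_neighborhood, graph = graph))),
             method = "radix")
  tr <- graph$triples[graph$triples$predicate %in% preds, , drop = FALSE]
  sub_edges <- unique(paste(tr$subject, tr$predicate, sep = "\r"))
  obj_edges <- unique(paste(tr$predicate, tr$object, sep = "\r"))
  n_nodes <- length(preds) + length(cs)
  n_edges <- length(sub_edges) + length(obj_edges)
  density <- if (n_nodes >= 2L) 2 * n_edges / (n_nodes * (n_nodes - 1)) else 0
  mean_assoc <- 0
  if (length(preds) >= 2L) {
    sub <- matrix[preds, preds, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    vals <- vals[vals > 0]
    if (length(vals) > 0L) mean_assoc <- mean(vals)
  }
  ptab <- graph$predicates[graph$predicates$uri %in% preds, , drop = FALSE]
  data.frame(
    topic = if (!is.null(topic$id)) topic$id else NA_integer_,
    n_predicates = length(preds), n_concepts = length(cs),
    n_nodes = n_nodes, n_edges = n_edges, density = density,
    mean_association = mean_assoc,
    diversity = length(unique(ptab$domain)),
    in_degree = sum(ptab$in_degree), out_degree = sum(ptab$out_degree),
    stringsAsFactors = FALSE
  )
}

#' Build the domain-collaboration graph
#'
#' Restricts patterns to those whose predicates all sit in the top-K
#' predicate ranking, then adds directed domain-to-domain edges for the
#' information flow each cross-domain pattern implies: the sharing
#' predicates' domains point at the shared object's domain (Provider), the
#' shared subject's domain points at each predicate's domain (Consumer),
#' source predicate domain points at target predicate domain (Reacher),
#' and connectivity chains contribute the consecutive predicate-domain
#' hops from start to end. Parallel contributions accumulate as edge
#' weight; self-loops (same domain) are discarded.
#'
#' @param patterns Mined patterns.
#' @param graph A `schema_graph`.
#' @param top_k Ranking cutoff (default 40).
#' @param ranking Optional precomputed predicate ranking; computed from the
#'   graph when `NULL`.
#' @return Object of class `cdnp_dcg`: list with `nodes` (domain,
#'   in/out degree) and `edges` (from, to, weight).
#' @export
build_domain_collaboration <- function(patterns, graph, top_k = 40L,
                                       ranking = NULL) {
  if (is.null(ranking)) ranking <- rank_nodes(graph, "predicate", top_k = top_k)
  top_preds <- utils::head(ranking$uri, top_k)
  pdom <- pred_domain(graph)
  cdom <- stats::setNames(graph$concepts$domain, graph$concepts$uri)
  psets <- pattern_pred_sets(patterns)
  keep <- vapply(psets, function(s) all(s %in% top_preds), TRUE)
  pats <- patterns[keep, , drop = FALSE]
  psets <- psets[keep]
  asets <- strsplit(pats$anchors, "|", fixed = TRUE)

  from <- character(); to <- character()
  for (r in seq_len(nrow(pats))) {
    preds <- psets[[r]]
    anchors <- asets[[r]]
    tp <- pats$type[r]
    if (tp == "PROVIDER") {
      tgt <- cdom[[anchors[1L]]]
      for (p in preds) { from <- c(from, pdom[[p]]); to <- c(to, tgt) }
    } else if (tp == "CONSUMER") {
      src <- cdom[[anchors[1L]]]
      for (p in preds) { from <- c(from, src); to <- c(to, pdom[[p]]) }
    } else if (tp == "REACHER") {
      from <- c(from, pdom[[preds[1L]]])
      to <- c(to, pdom[[preds[2L]]])
    } else {                     # DC / NDC: consecutive hops start -> end
      for (t in seq_len(length(preds) - 1L)) {
        from <- c(from, pdom[[preds[t]]])
        to <- c(to, pdom[[preds[t + 1L]]])
      }
    }
  }
  keep_edge <- from != to
  from <- from[keep_edge]; to <- to[keep_edge]
  doms <- sort(unique(c(graph$domains, from, to)), method = "radix")
  if (length(from) > 0L) {
    key <- paste(from, to, sep = "\r")
    agg <- table(key)
    first <- !duplicated(key)
    edges <- data.frame(from = from[first], to = to[first],
                        weight = as.integer(agg[key[first]]),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = integer(), stringsAsFactors = FALSE)
  }
  nodes <- data.frame(
    domain = doms,
    in_degree = vapply(doms, function(d) sum(edges$weight[edges$to == d]), 1L),
    out_degree = vapply(doms, function(d) sum(edges$weight[edges$from == d]), 1L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(nodes = nodes, edges = edges), class = "cdnp_dcg")
}

#' @export
print.cdnp_dcg <- function(x, ...) {
  cat(sprintf("Domain collaboration graph: %d domains, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Classify collaboration roles per domain
#'
#' Degree-based roles: Provider (out-degree exceeds in-degree by more than
#' the tolerance), Consumer (the reverse), Balancer (in- and out-degree
#' within tolerance of each other). Topology-based roles: Bridger (an
#' intermediate node on a shortest directed path between two other domains,
#' with both in- and out-edges), Hub (total degree at least one standard
#' deviation above the mean). Roles are not exclusive.
#'
#' @param dcg A `cdnp_dcg`.
#' @param balance_tol Relative tolerance for the degree-balance rules
#'   (default 0.2).
#' @return Data frame `domain`, `in_degree`, `out_degree`, `roles`
#'   (comma-separated).
#' @export
classify_domain_roles <- function(dcg, balance_tol = 0.2) {
  nodes <- dcg$nodes
  edges <- dcg$edges
  total <- nodes$in_degree + nodes$out_degree
  hub_cut <- mean(total) + stats::sd(total)
  if (is.na(hub_cut)) hub_cut <- Inf

  on_path <- rep(FALSE, nrow(nodes))
  names(on_path) <- nodes$domain
  if (nrow(edges) > 0L && nrow(nodes) > 2L) {
    ig <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                        directed = TRUE,
                                        vertices = nodes$domain)
    for (s in nodes$domain) {
      sp <- suppressWarnings(
        igraph::all_shortest_paths(ig, from = s, mode = "out")$vpaths
      )
      for (p in sp) {
        nm <- names(p)
        if (length(nm) >= 3L) {
          on_path[nm[-c(1L, length(nm))]] <- TRUE
        }
      }
    }
  }

  roles <- character(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    ind <- nodes$in_degree[i]; outd <- nodes$out_degree[i]
    r <- character()
    if (outd > ind * (1 + balance_tol)) r <- c(r, "Provider")
    if (ind > outd * (1 + balance_tol)) r <- c(r, "Consumer")
    if (max(ind, outd) == 0 || abs(ind - outd) <= balance_tol * max(ind, outd)) {
      r <- c(r, "Balancer")
    }
    if (on_path[nodes$domain[i]] && ind > 0 && outd > 0) r <- c(r, "Bridger")
    if (total[i] >= hub_cut && total[i] > 0) r <- c(r, "Hub")
    roles[i] <- paste(r, collapse = ",")
  }
  data.frame(domain = nodes$domain, in_degree = nodes$in_degree,
             out_degree = nodes$out_degree, roles = roles,
             stringsAsFactors = FALSE)
}

#' Export a domain-collaboration graph as GraphML
#'
#' Node attributes carry degrees and the comma-separated role set.
#'
#' @param dcg A `cdnp_dcg`.
#' @param path Output file.
#' @param balance_tol Passed to [classify_domain_roles()].
#' @return `path`, invisibly.
#' @export
write_dcg_graphml <- function(dcg, path, balance_tol = 0.2) {
  roles <- classify_domain_roles(dcg, balance_tol)
  verts <- merge(dcg$nodes, roles[, c("domain", "roles")], by = "domain")
  verts <- verts[order(verts$domain, method = "radix"), , drop = FALSE]
  names(verts)[1L] <- "name"
  ig <- igraph::graph_from_data_frame(dcg$edges, directed = TRUE,
                                      vertices = verts)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
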