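# Enumeration of the five predicate neighborhood patterns.
#
# Share patterns (two predicates around one shared concept):
#   Provider  -- common object;   Consumer -- common subject;
#   Reacher   -- object of the first is subject of the second (ordered).
# Connectivity patterns (chains of >= 3 predicates linked Reacher-style):
#   DC  -- edge directions respected;  NDC -- directions ignored.
#
# Share patterns are mined within- and cross-domain and flagged; DC/NDC are
# emitted only when cross-domain. A chain of m predicates is admissible when
# its predicates are pairwise distinct, its m-1 bridging concepts are
# pairwise distinct, and the direction-ignoring distance between its end
# predicates lies in [2, B].

PATTERN_TYPES <- c("PROVIDER", "CONSUMER", "REACHER", "DC", "NDC")

pattern_row <- function(type, predicates, anchors, domains) {
  data.frame(
    type = type,
    predicates = paste(predicates, collapse = "|"),
    anchors = paste(anchors, collapse = "|"),
    domains = paste(sort(unique(domains), method = "radix"), collapse = "|"),
    n_predicates = length(predicates),
    cross_domain = length(unique(domains)) >= 2L,
    stringsAsFactors = FALSE
  )
}

empty_patterns <- function() {
  data.frame(type = character(), predicates = character(),
             anchors = character(), domains = character(),
             n_predicates = integer(), cross_domain = logical(),
             stringsAsFactors = FALSE)
}

pred_domain <- function(graph) {
  stats::setNames(graph$predicates$domain, graph$predicates$uri)
}

sort_patterns <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(match(df$type, PATTERN_TYPES), df$predicates, df$anchors,
                 method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

mine_share <- function(graph, role, type) {
  dom <- pred_domain(graph)
  sets <- lapply(graph$cp, `[[`, role)
  concepts <- sort(unique(unlist(sets)), method = "radix")
  rows <- list()
  for (cc in concepts) {
    preds <- names(sets)[vapply(sets, function(s) cc %in% s, TRUE)]
    if (length(preds) < 2L) next
    preds <- sort(preds, method = "radix")
    idx <- utils::combn(length(preds), 2L)
    for (k in seq_len(ncol(idx))) {
      pair <- preds[idx[, k]]
      rows[[length(rows) + 1L]] <- pattern_row(type, pair, cc, dom[pair])
    }
  }
  if (length(rows) == 0L) return(empty_patterns())
  sort_patterns(do.call(rbind, rows))
}

#' Mine Provider patterns (predicate pairs sharing a common object)
#'
#' One pattern per unordered predicate pair and shared object concept; the
#' `cross_domain` flag records whether the two predicates come from
#' different domains.
#'
#' @param graph A `schema_graph`.
#' @return Pattern data frame (`type`, `|`-joined `predicates` and
#'   `anchors`, `domains`, `n_predicates`, `cross_domain`).
#' @export
mine_provider <- function(graph) mine_share(graph, "objects", "PROVIDER")

#' Mine Consumer patterns (predicate pairs sharing a common subject)
#' @inheritParams mine_provider
#' @return Pattern data frame, see [mine_provider()].
#' @export
mine_consumer <- function(graph) mine_share(graph, "subjects", "CONSUMER")

#' Mine Reacher patterns (object of one predicate is subject of another)
#'
#' Ordered pairs (Pi, Pj), Pi != Pj, where some object concept of Pi equals
#' a subject concept of Pj; the shared concept is the anchor.
#'
#' @inheritParams mine_provider
#' @return Pattern data frame, see [mine_provider()].
#' @export
mine_reacher <- function(graph) {
  dom <- pred_domain(graph)
  preds <- names(graph$cp)
  rows <- list()
  for (pi in preds) {
    for (pj in preds) {
      if (pi == pj) next
      shared <- intersect(graph$cp[[pi]]$objects, graph$cp[[pj]]$subjects)
      for (cc in shared) {
        rows[[length(rows) + 1L]] <- pattern_row("REACHER", c(pi, pj), cc,
                                                 dom[c(pi, pj)])
      }
    }
  }
  if (length(rows) == 0L) return(empty_patterns())
  sort_patterns(do.call(rbind, rows))
}

# Directed Reacher links: list per predicate of (next predicate, anchor).
reacher_links <- function(graph) {
  preds <- names(graph$cp)
  out <- stats::setNames(vector("list", length(preds)), preds)
  for (pi in preds) {
    links <- list()
    for (pj in preds) {
      if (pi == pj) next
      shared <- intersect(graph$cp[[pi]]$objects, graph$cp[[pj]]$subjects)
      for (cc in shared) links[[length(links) + 1L]] <- c(pj, cc)
    }
    out[[pi]] <- links
  }
  out
}

# Undirected shared-concept links with every shared concept as an anchor.
share_links <- function(graph) {
  preds <- names(graph$cp)
  csets <- lapply(preds, function(p) concept_neighborhood(graph, p))
  names(csets) <- preds
  out <- stats::setNames(vector("list", length(preds)), preds)
  for (pi in preds) {
    links <- list()
    for (pj in preds) {
      if (pi == pj) next
      for (cc in intersect(csets[[pi]], csets[[pj]])) {
        links[[length(links) + 1L]] <- c(pj, cc)
      }
    }
    out[[pi]] <- links
  }
  out
}

# Depth-first enumeration of admissible chains over a link structure.
chain_mine <- function(graph, links, boundary, canonicalize) {
  dom <- pred_domain(graph)
  ldist <- predicate_distances(graph)
  preds <- names(graph$cp)
  found <- new.env(parent = emptyenv())
  rows <- list()

  emit <- function(chain, anchors) {
    ends_l <- ldist[chain[1L], chain[length(chain)]]
    if (!is.finite(ends_l) || ends_l < 2L || ends_l > boundary) return()
    if (length(unique(dom[chain])) < 2L) return()
    key_chain <- chain
    key_anch <- anchors
    if (canonicalize) {
      rev_chain <- rev(chain)
      if (paste(rev_chain, collapse = "|") < paste(chain, collapse = "|")) {
        key_chain <- rev_chain
        key_anch <- rev(anchors)
      }
    }
    key <- paste(key_chain, collapse = "|")
    prev <- get0(key, envir = found)
    anch_str <- paste(key_anch, collapse = "|")
    if (is.null(prev) || anch_str < prev$anchors) {
      assign(key, list(chain = key_chain, anchors = anch_str), envir = found)
    }
  }

  walk <- function(chain, anchors) {
    last <- chain[length(chain)]
    for (link in links[[last]]) {
      nxt <- link[1L]
      cc <- link[2L]
      if (nxt %in% chain || cc %in% anchors) next    # simple path
      chain2 <- c(chain, nxt)
      anchors2 <- c(anchors, cc)
      if (length(chain2) >= 3L) emit(chain2, anchors2)
      if (length(chain2) < boundary + 1L) walk(chain2, anchors2)
    }
  }
  for (p in preds) walk(p, character())

  keys <- ls(found)
  if (length(keys) == 0L) return(empty_patterns())
  for (key in keys) {
    rec <- get(key, envir = found)
    chain <- rec$chain
    rows[[length(rows) + 1L]] <- pattern_row(
      if (canonicalize) "NDC" else "DC",
      chain, strsplit(rec$anchors, "|", fixed = TRUE)[[1L]], dom[chain]
    )
  }
  sort_patterns(do.call(rbind, rows))
}

#' Mine Directional Connector patterns
#'
#' Direction-respecting chains of 3 to B+1 distinct predicates joined by
#' Reacher links through distinct bridging concepts, whose end predicates
#' are 2..B apart; emitted only when the chain spans at least two domains.
#'
#' @param graph A `schema_graph`.
#' @param boundary Topic boundary B (maximum predicate distance), `B >= 2`.
#' @return Pattern data frame, see [mine_provider()].
#' @export
mine_dc <- function(graph, boundary = 3L) {
  stopifnot(boundary >= 2L)
  chain_mine(graph, reacher_links(graph), boundary, canonicalize = FALSE)
}

#' Mine Non-Directional Connector patterns
#'
#' As [mine_dc()] but on the undirected schema graph: consecutive chain
#' predicates only need to share a concept in any role, and a chain equals
#' its reversal (the lexicographically smaller orientation is kept). Every
#' DC chain's predicate sequence also appears here.
#'
#' @inheritParams mine_dc
#' @return Pattern data frame, see [mine_provider()].
#' @export
mine_ndc <- function(graph, boundary = 3L) {
  stopifnot(boundary >= 2L)
  chain_mine(graph, share_links(graph), boundary, canonicalize = TRUE)
}

#' Mine all five pattern types
#'
#' @param graph A `schema_graph`.
#' @param types Subset of `c("PROVIDER","CONSUMER","REACHER","DC","NDC")`.
#' @param boundary Topic boundary for the connectivity miners.
#' @return Pattern data frame sorted by (type, predicates).
#' @export
mine_patterns <- function(graph, types = PATTERN_TYPES, boundary = 3L) {
  types <- match.arg(types, PATTERN_TYPES, several.ok = TRUE)
  parts <- list()
  if ("PROVIDER" %in% types) parts$provider <- mine_provider(graph)
  if ("CONSUMER" %in% types) parts$consumer <- mine_consumer(graph)
  if ("REACHER" %in% types) parts$reacher <- mine_reacher(graph)
  if ("DC" %in% types) parts$dc <- mine_dc(graph, boundary)
  if ("NDC" %in% types) parts$ndc <- mine_ndc(graph, boundary)
  sort_patterns(do.call(rbind, c(parts, list(make.row.names = FALSE))))
}

#' Tabulate a pattern census
#'
#' Per-type totals, cross-domain counts and cross-domain fractions, plus a
#' grand-total row. Types with no patterns are reported as 0/0 with
#' fraction 0.
#'
#' @param patterns Pattern data frame from [mine_patterns()].
#' @return Data frame with columns `type`, `total`, `cross_domain`,
#'   `fraction_cross`.
#' @export
summarize_patterns <- function(patterns) {
  rows <- lapply(PATTERN_TYPES, function(tp) {
    sub <- patterns[patterns$type == tp, , drop = FALSE]
    n <- nrow(sub)
    nc <- sum(sub$cross_domain)
    data.frame(type = tp, total = n, cross_domain = nc,
               fraction_cross = if (n > 0L) nc / n else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- sum(out$total)
  cross <- sum(out$cross_domain)
  rbind(out, data.frame(type = "TOTAL", total = total, cross_domain = cross,
                        fraction_cross = if (total > 0L) cross / total else 0,
                        stringsAsFactors = FALSE))
}

#' Write patterns or a census as TSV
#'
#' @param x Data frame (patterns or census).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
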