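# Predicate-based bottom-up topic clustering.
#
# Phase 1 builds a merge tree by average-linkage agglomeration on the
# element distance 1 - PA' (diversity-reweighted association). Each level
# of the tree merges every mutual-nearest-neighbour cluster pair at once
# (ties broken lexicographically), so the tree is shallow and its middle
# level is a meaningful resolution; each merge is still recorded as a
# binary pair, which keeps the tree convertible to an hclust dendrogram.
#
# Phase 2 takes the active cluster set at level Mid = roundup(H/2):
# multi-member clusters become topics 2..|T|+1, clusters still singleton at
# that level are pooled into the special Topic 1.
#
# Phase 3 refines topics with the mined connectivity patterns: an in-topic
# predicate pair two or three steps apart pulls its bridging predicates
# into the topic, which lets a predicate belong to several topics.

#' Element distance between two predicates
#'
#' One minus the (reweighted) association: 0 on the diagonal or for fully
#' associated pairs, 1 for pairs with no association inside the boundary.
#'
#' @param matrix Association matrix.
#' @param m,n Predicate URIs.
#' @return Value in `[0, 1]`.
#' @export
element_distance <- function(matrix, m, n) {
  if (!m %in% rownames(matrix)) stop("unknown predicate: ", m, call. = FALSE)
  if (!n %in% rownames(matrix)) stop("unknown predicate: ", n, call. = FALSE)
  1 - unname(matrix[m, n])
}

#' Average-linkage distance between two disjoint topics
#'
#' @param dist Element distance matrix (predicate URIs as dimnames).
#' @param p,q Character vectors of member predicate URIs; must be disjoint
#'   and non-empty.
#' @return Mean element distance over the cross product.
#' @export
topic_distance <- function(dist, p, q) {
  if (length(p) == 0L || length(q) == 0L) {
    stop("topic_distance needs non-empty topics", call. = FALSE)
  }
  if (length(intersect(p, q)) > 0L) {
    stop("topic_distance needs disjoint topics", call. = FALSE)
  }
  mean(dist[p, q, drop = FALSE])
}

cluster_label <- function(members) paste(sort(members, method = "radix"),
                                         collapse = "\x1f")

#' Build the agglomerative merge tree
#'
#' Starts from one singleton cluster per predicate. At each level all
#' mutual-nearest-neighbour cluster pairs (under average linkage on the
#' element distances, ties broken lexicographically by sorted member URIs)
#' are merged, the active set is snapshotted, and the process repeats until
#' a single cluster remains.
#'
#' @param predicates Character vector of predicate URIs.
#' @param dist Element distance matrix covering them.
#' @return An object of class `cdnp_tree`: list with `levels` (active
#'   cluster sets by level, names "0".."H"), `merges` (data frame of binary
#'   merge records), `height`, and `predicates`.
#' @export
hac_build <- function(predicates, dist) {
  stopifnot(length(predicates) >= 1L)
  predicates <- sort(predicates, method = "radix")
  active <- lapply(predicates, identity)
  names(active) <- vapply(active, cluster_label, "")
  active <- active[order(names(active), method = "radix")]
  levels <- list(`0` = active)
  merges <- list()
  lvl <- 0L

  while (length(active) > 1L) {
    k <- length(active)
    labs <- names(active)
    dmat <- matrix(Inf, k, k)
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        dd <- topic_distance(dist, active[[a]], active[[b]])
        dmat[a, b] <- dd
        dmat[b, a] <- dd
      }
    }
    # nearest neighbour of each cluster, ties -> lexicographically smallest
    nn <- integer(k)
    for (a in seq_len(k)) {
      best <- min(dmat[a, ])
      cand <- which(dmat[a, ] == best)
      nn[a] <- cand[order(labs[cand], method = "radix")][1L]
    }
    mutual <- which(nn[nn] == seq_len(k) & seq_len(k) < nn)
    if (length(mutual) == 0L) {           # safeguard: merge the global best
      best <- which(dmat == min(dmat), arr.ind = TRUE)[1L, ]
      mutual <- min(best)
      nn[mutual] <- max(best)
    }
    lvl <- lvl + 1L
    for (a in mutual) {
      b <- nn[a]
      u <- sort(c(active[[a]], active[[b]]), method = "radix")
      merges[[length(merges) + 1L]] <- data.frame(
        level = lvl, parent = cluster_label(u),
        child1 = labs[a], child2 = labs[b], size = length(u),
        stringsAsFactors = FALSE
      )
    }
    drop_idx <- c(mutual, nn[mutual])
    new_clusters <- lapply(mutual, function(a) {
      sort(c(active[[a]], active[[nn[a]]]), method = "radix")
    })
    active <- active[-drop_idx]
    for (u in new_clusters) active[[cluster_label(u)]] <- u
    active <- active[order(names(active), method = "radix")]
    levels[[as.character(lvl)]] <- active
  }

  structure(
    list(levels = lapply(levels, unname), height = lvl,
         merges = if (length(merges)) do.call(rbind, merges) else
           data.frame(level = integer(), parent = character(),
                      child1 = character(), child2 = character(),
                      size = integer(), stringsAsFactors = FALSE),
         predicates = predicates),
    class = "cdnp_tree"
  )
}

#' Extract the mid-level cluster set of a merge tree
#'
#' `Mid = ceiling(H/2)`; if no cluster set was recorded at that level the
#' level index is decremented until one is found.
#'
#' @param tree A `cdnp_tree`.
#' @return List with `mid` (the level used) and `topics` (list of member
#'   vectors).
#' @export
extract_mid_topics <- function(tree) {
  stopifnot(inherits(tree, "cdnp_tree"))
  mid <- ceiling(tree$height / 2)
  while (mid > 0 && !as.character(mid) %in% names(tree$levels)) {
    mid <- mid - 1L
  }
  list(mid = mid, topics = tree$levels[[as.character(mid)]])
}

#' Assemble the final topic set with singleton pooling
#'
#' Mid-level topics get ids 2..|T|+1. Remainder topics of size one are
#' pooled into the special Topic 1; multi-member remainders get ids from
#' |T|+2 on.
#'
#' @param mid_topics List of member vectors (the extracted mid-level
#'   topics).
#' @param remaining List of member vectors not covered by `mid_topics`.
#' @param graph Optional `schema_graph` used to attach induced concepts and
#'   domains to each topic.
#' @param level Level the mid topics came from (stored on each topic).
#' @return List of topic records (`id`, `predicates`, `concepts`,
#'   `domains`, `level`), ordered by id; the pool topic, when present, has
#'   id 1.
#' @export
assemble_final_topics <- function(mid_topics, remaining = list(),
                                  graph = NULL, level = NA_integer_) {
  singles <- Filter(function(z) length(z) == 1L, remaining)
  multis <- Filter(function(z) length(z) > 1L, remaining)
  n_mid <- length(mid_topics)
  topics <- list()
  if (length(singles) > 0L) {
    topics[[length(topics) + 1L]] <- list(
      id = 1L, predicates = sort(unlist(singles), method = "radix"),
      level = level, pool = TRUE
    )
  }
  for (i in seq_along(mid_topics)) {
    topics[[length(topics) + 1L]] <- list(
      id = i + 1L, predicates = sort(mid_topics[[i]], method = "radix"),
      level = level, pool = FALSE
    )
  }
  for (i in seq_along(multis)) {
    topics[[length(topics) + 1L]] <- list(
      id = n_mid + 1L + i, predicates = sort(multis[[i]], method = "radix"),
      level = level, pool = FALSE
    )
  }
  topics <- topics[order(vapply(topics, `[[`, 1L, "id"))]
  if (!is.null(graph)) topics <- lapply(topics, annotate_topic, graph = graph)
  topics
}

annotate_topic <- function(topic, graph) {
  cs <- sort(unique(unlist(lapply(topic$predicates, concept_neighborhood,
                                  graph = graph))), method = "radix")
  dom <- pred_domain(graph)
  topic$concepts <- cs
  topic$domains <- sort(unique(unname(dom[topic$predicates])), method = "radix")
  topic
}

#' Refine topics with connectivity patterns
#'
#' For every in-topic predicate pair at distance 2, the bridging predicates
#' of the cross-domain connectivity chains joining them are added to the
#' topic; at distance 3 both intermediates of each chain are added. By
#' default the bridges are looked up directly on the predicate distance
#' matrix (equivalent to consulting the mined chains, since every bridge on
#' a shortest path carries pairwise-distinct anchors); a mined pattern
#' table can be supplied instead. Applied to a fixed point, so refining
#' twice changes nothing; topics only ever grow, and a predicate may end up
#' in several topics.
#'
#' @param topics Topic list from [assemble_final_topics()].
#' @param graph A `schema_graph`.
#' @param patterns Optional connectivity patterns (rows of type
#'   `DC`/`NDC`); when `NULL` bridges are derived from the distance matrix.
#' @param boundary Topic boundary B.
#' @return The refined topic list.
#' @export
refine_topics <- function(topics, graph, patterns = NULL, boundary = 3L) {
  d <- predicate_distances(graph)
  dom <- pred_domain(graph)

  if (!is.null(patterns)) {
    conn <- patterns[patterns$type %in% c("DC", "NDC"), , drop = FALSE]
    chains <- strsplit(conn$predicates, "|", fixed = TRUE)
    ends_key <- vapply(chains, function(ch) {
      cluster_label(c(ch[1L], ch[length(ch)]))
    }, "")
    bridges_for <- function(pi, pj, l) {
      hit <- which(ends_key == cluster_label(c(pi, pj)))
      out <- character()
      for (h in hit) {
        ch <- chains[[h]]
        if (length(ch) == l + 1) {               # d=2 -> 3 preds, d=3 -> 4
          out <- c(out, ch[-c(1L, length(ch))])
        }
      }
      unique(out)
    }
  } else {
    preds <- rownames(d)
    bridges_for <- function(pi, pj, l) {
      if (l == 2) {
        ks <- preds[d[pi, ] == 1 & d[, pj] == 1]
        ks[vapply(ks, function(k) {
          length(unique(dom[c(pi, k, pj)])) >= 2L
        }, TRUE)]
      } else {
        out <- character()
        k1s <- preds[d[pi, ] == 1 & d[, pj] == 2]
        for (k1 in k1s) {
          k2s <- preds[d[k1, ] == 1 & d[, pj] == 1 & d[pi, ] == 2]
          for (k2 in k2s) {
            if (length(unique(dom[c(pi, k1, k2, pj)])) >= 2L) {
              out <- c(out, k1, k2)
            }
          }
        }
        unique(out)
      }
    }
  }

  refine_one <- function(members) {
    repeat {
      added <- character()
      mm <- members[members %in% rownames(d)]
      if (length(mm) >= 2L) {
        pairs <- utils::combn(sort(mm, method = "radix"), 2L)
        for (k in seq_len(ncol(pairs))) {
          pi <- pairs[1L, k]; pj <- pairs[2L, k]
          l <- d[pi, pj]
          if (!is.finite(l) || l < 2 || l > min(3, boundary)) next
          added <- c(added, setdiff(bridges_for(pi, pj, l), members))
        }
      }
      if (length(added) == 0L) break
      members <- sort(unique(c(members, added)), method = "radix")
    }
    members
  }

  out <- lapply(topics, function(tp) {
    if (isTRUE(tp$pool)) return(tp)             # the singleton pool stays
    tp$predicates <- refine_one(tp$predicates)
    tp
  })
  lapply(out, annotate_topic, graph = graph)
}

#' Predicate topic discovery
#'
#' Runs the full bottom-up pipeline on a schema graph: raw association
#' matrix, cross-domain diversity reweighting, agglomerative merge tree,
#' mid-level topic extraction with singleton pooling, and
#' connectivity-based refinement. Deterministic for a given graph and
#' configuration.
#'
#' @param graph A `schema_graph`.
#' @param boundary Topic boundary B (default 3).
#' @param refine Apply the connectivity refinement (default `TRUE`).
#' @return An object of class `phal`: list with the merge `tree`, `mid`
#'   level, `topics` (refined, overlapping) and `topics_initial` (before
#'   refinement), the `association` matrices (`raw`, `reweighted`), and
#'   `boundary`.
#' @export
phal <- function(graph, boundary = 3L, refine = TRUE) {
  stopifnot(inherits(graph, "schema_graph"))
  raw <- predicate_association(graph, boundary)
  rw <- reweight_cross_domain(raw, graph)
  dist <- 1 - unclass(rw)
  tree <- hac_build(names(graph$cp), dist)
  mid <- extract_mid_topics(tree)
  sizes <- lengths(mid$topics)
  initial <- assemble_final_topics(mid$topics[sizes > 1L],
                                   mid$topics[sizes == 1L],
                                   graph = graph, level = mid$mid)
  final <- if (refine) refine_topics(initial, graph, boundary = boundary)
           else initial
  structure(
    list(graph = graph, tree = tree, mid = mid$mid,
         topics = final, topics_initial = initial,
         association = list(raw = raw, reweighted = rw),
         boundary = boundary),
    class = "phal"
  )
}

#' Topic membership table
#'
#' @param x A `phal` object (or topic list).
#' @param initial Use the pre-refinement topics.
#' @return Data frame with `predicate` and `topic` columns (one row per
#'   membership; refined topics may repeat predicates).
#' @export
topic_membership <- function(x, initial = FALSE) {
  topics <- if (inherits(x, "phal")) {
    if (initial) x$topics_initial else x$topics
  } else x
  do.call(rbind, lapply(topics, function(tp) {
    data.frame(predicate = tp$predicates, topic = tp$id,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.phal <- function(x, ...) {
  cat("Predicate topic hierarchy\n")
  cat(sprintf("  %d predicates, merge tree height %d, mid level %d\n",
              length(x$tree$predicates), x$tree$height, x$mid))
  n_pool <- sum(vapply(x$topics, function(tp) isTRUE(tp$pool), TRUE))
  cat(sprintf("  %d final topics (%s), boundary B = %d\n",
              length(x$topics),
              if (n_pool > 0) "incl. singleton pool" else "no singleton pool",
              x$boundary))
  invisible(x)
}

#' @export
summary.phal <- function(object, ...) {
  df <- do.call(rbind, lapply(object$topics, function(tp) {
    data.frame(topic = tp$id, predicates = length(tp$predicates),
               concepts = length(tp$concepts),
               domains = length(tp$domains),
               pool = isTRUE(tp$pool), stringsAsFactors = FALSE)
  }))
  structure(list(phal = object, table = df), class = "summary.phal")
}

#' @export
print.summary.phal <- function(x, ...) {
  print(x$phal)
  cat("\nTopics:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Convert the merge tree to an hclust object
#'
#' Merge heights are the tree levels, so simultaneous merges share a
#' height; useful for plotting the hierarchy as a dendrogram.
#'
#' @param x A `phal` object or `cdnp_tree`.
#' @param ... Unused.
#' @return An `hclust` object.
#' @export
as.hclust.phal <- function(x, ...) {
  tree <- if (inherits(x, "phal")) x$tree else x
  preds <- tree$predicates
  n <- length(preds)
  if (n < 2L) stop("need at least two predicates for a dendrogram", call. = FALSE)
  m <- tree$merges
  id_of <- stats::setNames(-seq_len(n), vapply(preds, cluster_label, ""))
  merge <- matrix(0L, nrow(m), 2L)
  for (r in seq_len(nrow(m))) {
    merge[r, ] <- sort(c(id_of[[m$child1[r]]], id_of[[m$child2[r]]]))
    id_of[[m$parent[r]]] <- r
  }
  leaf_order <- function(node) {
    if (node < 0L) return(-node)
    c(leaf_order(merge[node, 1L]), leaf_order(merge[node, 2L]))
  }
  hc <- list(merge = merge, height = as.numeric(m$level),
             order = leaf_order(nrow(merge)),
             labels = preds, method = "average-linkage rounds",
             call = match.call(), dist.method = "1 - association")
  class(hc) <- "hclust"
  hc
}

#' @export
as.hclust.cdnp_tree <- as.hclust.phal

#' Plot the merge tree as a dendrogram
#'
#' @param x A `phal` object.
#' @param ... Passed to `plot.hclust`.
#' @export
plot.phal <- function(x, ...) {
  plot(stats::as.hclust(x), ...)
  invisible(x)
}

#' Export a topic hierarchy as JSON
#'
#' Writes the merge tree (levels and merges), the mid level, and the final
#' topics with ids, predicates, induced concepts and domains.
#'
#' @param x A `phal` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_topics_json <- function(x, path) {
  stopifnot(inherits(x, "phal"))
  payload <- list(
    height = x$tree$height,
    mid_level = x$mid,
    boundary = x$boundary,
    levels = lapply(x$tree$levels, function(lv) lapply(lv, identity)),
    merges = x$tree$merges,
    topics = lapply(x$topics, function(tp) {
      list(id = tp$id, pool = isTRUE(tp$pool), predicates = tp$predicates,
           concepts = tp$concepts, domains = tp$domains)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
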