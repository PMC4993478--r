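# Predicate association measures.
#
# Distance l(Pi,Pj): number of concept nodes on the shortest undirected
# alternating path between two predicate nodes (0 for identical predicates,
# 1 when they share a concept, Inf when unreachable).
#
# Share association   SA = |C(Pi) n C(Pj)|^2 / (|C(Pi)| * |C(Pj)|)
# Connectivity assoc. CA = max over shortest bridging chains of the product
#                          of the component share associations (computed by
#                          dynamic programming over split points)
# Predicate matrix    PA = SA for l <= 1, CA for 2 <= l <= B, 0 beyond B
# Diversity weight    DW up-weights cross-domain links from neighborhood
#                          association means.

#' Direction-ignoring predicate distance matrix
#'
#' Two predicates are at distance 1 when they share at least one concept;
#' longer distances follow shortest paths in that shared-concept graph,
#' which equals the number of concept nodes separating the two predicates
#' on the alternating schema graph.
#'
#' @param graph A `schema_graph`.
#' @return Symmetric numeric matrix (`Inf` = unreachable), dimnames are
#'   predicate URIs.
#' @export
predicate_distances <- function(graph) {
  stopifnot(inherits(graph, "schema_graph"))
  preds <- names(graph$cp)
  n <- length(preds)
  if (n == 0L) {
    return(matrix(numeric(), 0L, 0L, dimnames = list(NULL, NULL)))
  }
  inc <- concept_incidence(graph)
  shared <- tcrossprod(inc)                    # counts of shared concepts
  adj <- shared > 0
  diag(adj) <- FALSE
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(ig)
  dimnames(d) <- list(preds, preds)
  d
}

# Binary predicate x concept incidence matrix over C(P).
concept_incidence <- function(graph) {
  preds <- names(graph$cp)
  cons <- graph$concepts$uri
  inc <- matrix(0L, length(preds), length(cons), dimnames = list(preds, cons))
  for (p in preds) {
    inc[p, concept_neighborhood(graph, p)] <- 1L
  }
  inc
}

#' Association distance between two predicates
#'
#' @param graph A `schema_graph`.
#' @param pi,pj Predicate URIs.
#' @return A nonnegative integer, or `Inf` when the predicates are not
#'   connected by any undirected path.
#' @export
association_distance <- function(graph, pi, pj) {
  d <- predicate_distances(graph)
  if (!pi %in% rownames(d)) stop("unknown predicate: ", pi, call. = FALSE)
  if (!pj %in% rownames(d)) stop("unknown predicate: ", pj, call. = FALSE)
  unname(d[pi, pj])
}

share_association_matrix <- function(graph) {
  inc <- concept_incidence(graph)
  if (nrow(inc) == 0L) return(inc)
  sizes <- rowSums(inc)
  inter <- tcrossprod(inc)
  sa <- inter^2 / outer(sizes, sizes)
  diag(sa) <- 1
  sa
}

#' Share association between two predicates
#'
#' 1 for identical predicates, 0 for unreachable ones, otherwise the
#' squared shared-concept count over the product of the neighborhood sizes.
#'
#' @inheritParams association_distance
#' @return Value in `[0, 1]`.
#' @export
share_association <- function(graph, pi, pj) {
  sa <- share_association_matrix(graph)
  if (!pi %in% rownames(sa)) stop("unknown predicate: ", pi, call. = FALSE)
  if (!pj %in% rownames(sa)) stop("unknown predicate: ", pj, call. = FALSE)
  unname(sa[pi, pj])
}

# Core DP shared by connectivity_association() and the full matrix:
# for each distance d = 2..B, the best product over chains that follow
# shortest paths, split at the first hop. Returns the PA matrix and, when
# requested, the argmax chain per pair.
pa_matrix_core <- function(graph, boundary) {
  d <- predicate_distances(graph)
  sa <- share_association_matrix(graph)
  n <- nrow(d)
  pa <- matrix(0, n, n, dimnames = dimnames(d))
  if (n == 0L) return(list(pa = pa, d = d, sa = sa))
  pa[d <= 1] <- sa[d <= 1]
  diag(pa) <- 1
  if (boundary >= 2L && n > 2L) {
    for (dd in 2:boundary) {
      idx <- which(d == dd, arr.ind = TRUE)
      idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
      if (nrow(idx) == 0L) next
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1L]; j <- idx[r, 2L]
        ks <- which(d[i, ] == 1 & d[, j] == dd - 1)
        if (length(ks) == 0L) next
        vals <- sa[i, ks] * pa[ks, j]
        best <- max(vals)
        pa[i, j] <- best
        pa[j, i] <- best
      }
    }
  }
  list(pa = pa, d = d, sa = sa)
}

#' Connectivity association between two predicates
#'
#' Defined for predicate pairs at distance `2 <= l <= B`: the maximum over
#' bridging chains (dynamic programming over split points along shortest
#' paths) of the product of the component share associations. Pairs beyond
#' the boundary get 0.
#'
#' @inheritParams association_distance
#' @param boundary Topic boundary B.
#' @param with_chain If `TRUE`, also return one optimal bridging chain and
#'   its share-association factors.
#' @return Value in `[0, 1]`, or a list when `with_chain = TRUE`.
#' @export
connectivity_association <- function(graph, pi, pj, boundary = 3L,
                                     with_chain = FALSE) {
  d <- predicate_distances(graph)
  if (!pi %in% rownames(d)) stop("unknown predicate: ", pi, call. = FALSE)
  if (!pj %in% rownames(d)) stop("unknown predicate: ", pj, call. = FALSE)
  l <- d[pi, pj]
  if (is.finite(l) && l < 2) {
    stop("connectivity association requires l(Pi,Pj) >= 2, got l = ", l,
         call. = FALSE)
  }
  if (!is.finite(l) || l > boundary) {
    if (with_chain) return(list(value = 0, chain = character(), factors = numeric()))
    return(0)
  }
  core <- pa_matrix_core(graph, boundary)
  value <- unname(core$pa[pi, pj])
  if (!with_chain) return(value)
  # reconstruct one optimal shortest chain greedily
  sa <- core$sa
  chain <- pi
  cur <- pi
  remaining <- l
  while (remaining > 1) {
    ks <- which(d[cur, ] == 1 & d[, pj] == remaining - 1)
    vals <- sa[cur, ks] * core$pa[ks, pj]
    cur <- colnames(d)[ks[which.max(vals)]]
    chain <- c(chain, cur)
    remaining <- remaining - 1
  }
  chain <- c(chain, pj)
  factors <- vapply(seq_len(length(chain) - 1L), function(t) {
    sa[chain[t], chain[t + 1L]]
  }, 1.0)
  list(value = value, chain = chain, factors = factors)
}

#' Predicate association matrix
#'
#' Symmetric predicate-by-predicate matrix with unit diagonal: share
#' association for pairs at distance <= 1, connectivity association for
#' pairs at distance 2..B, and 0 beyond the boundary.
#'
#' @param graph A `schema_graph`.
#' @param boundary Topic boundary B.
#' @return Matrix of class `cdnp_assoc` with attributes `variant = "raw"`
#'   and `boundary`.
#' @export
predicate_association <- function(graph, boundary = 3L) {
  core <- pa_matrix_core(graph, boundary)
  structure(core$pa, variant = "raw", boundary = boundary,
            class = c("cdnp_assoc", "matrix", "array"))
}

#' Mean association weight between a predicate and its direct neighbors
#'
#' The arithmetic mean of the association-matrix entries between `p` and
#' every predicate at distance 1 (its direct share partners); 0 for a
#' predicate with no neighbors.
#'
#' @param matrix Association matrix (predicate URIs as dimnames).
#' @param graph A `schema_graph`.
#' @param p Predicate URI.
#' @return Value in `[0, 1]`.
#' @export
neighborhood_weight <- function(matrix, graph, p) {
  d <- predicate_distances(graph)
  if (!p %in% rownames(d)) stop("unknown predicate: ", p, call. = FALSE)
  nb <- colnames(d)[which(d[p, ] == 1)]
  if (length(nb) == 0L) return(0)
  mean(matrix[p, nb])
}

neighborhood_weights <- function(matrix, graph) {
  preds <- names(graph$cp)
  vapply(preds, function(p) neighborhood_weight(matrix, graph, p), 1.0)
}

#' Cross-domain diversity weight
#'
#' For a cross-domain predicate pair with similarity weight `sw` and
#' per-predicate neighborhood means `wi`, `wj`:
#' when `sw < (sw + wi)/2` the weight is raised to
#' `max((sw + wi)/2, (sw + wj)/2)`, otherwise it stays `sw`. The result is
#' never below `sw`.
#'
#' @param sw Pairwise similarity weight in `[0, 1]`.
#' @param wi,wj Neighborhood association means in `[0, 1]` (vectorized).
#' @return Diversity weight in `[0, 1]`.
#' @export
diversity_weight <- function(sw, wi, wj) {
  vals <- c(sw, wi, wj)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("diversity_weight inputs must lie in [0, 1]", call. = FALSE)
  }
  ifelse(sw < (sw + wi) / 2, pmax((sw + wi) / 2, (sw + wj) / 2), sw)
}

#' Reweight cross-domain entries of an association matrix
#'
#' Every cross-domain predicate pair with a positive association is raised
#' to its diversity weight, computed from the raw matrix's neighborhood
#' means; same-domain entries are untouched. To keep the matrix symmetric
#' the larger neighborhood mean takes the role of the first predicate in
#' [diversity_weight()] (the worked result is unchanged either way).
#'
#' @param matrix Raw association matrix from [predicate_association()].
#' @param graph The `schema_graph` it was computed on.
#' @return Matrix of class `cdnp_assoc` with `variant = "diversity"`.
#' @export
reweight_cross_domain <- function(matrix, graph) {
  w <- neighborhood_weights(matrix, graph)
  dom <- pred_domain(graph)
  preds <- rownames(matrix)
  out <- unclass(matrix)
  if (length(preds) > 1L) {
    for (a in seq_len(length(preds) - 1L)) {
      for (b in (a + 1L):length(preds)) {
        pa <- out[a, b]
        if (pa <= 0) next
        if (dom[preds[a]] == dom[preds[b]]) next
        wi <- max(w[preds[a]], w[preds[b]])
        wj <- min(w[preds[a]], w[preds[b]])
        dw <- diversity_weight(pa, wi, wj)
        out[a, b] <- dw
        out[b, a] <- dw
      }
    }
  }
  structure(out, variant = "diversity", boundary = attr(matrix, "boundary"),
            class = c("cdnp_assoc", "matrix", "array"))
}

#' Export an association matrix
#'
#' @param matrix A `cdnp_assoc` matrix.
#' @param path Output file.
#' @param format `"dense"` (TSV matrix) or `"edges"` (sparse edge-list TSV
#'   of positive off-diagonal entries).
#' @return `path`, invisibly.
#' @export
write_association <- function(matrix, path, format = c("dense", "edges")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- data.frame(predicate = rownames(matrix),
                     as.data.frame(unclass(matrix), check.names = FALSE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(upper.tri(matrix) & matrix > 0, arr.ind = TRUE)
    df <- data.frame(from = rownames(matrix)[idx[, 1L]],
                     to = colnames(matrix)[idx[, 2L]],
                     association = matrix[idx])
    df <- df[order(df$from, df$to, method = "radix"), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
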