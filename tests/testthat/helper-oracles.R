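# Independent brute-force oracles: every check here works directly from the
# pattern/association definitions (set intersections, exhaustive tuple
# enumeration, breadth-first search, path-product maximization) and shares
# no code with the package implementations it verifies.

toy_A <- "http://example.org/A/"
toy_B <- "http://example.org/B/"
toy_uri <- function(x) {
  ifelse(startsWith(x, "A:"), paste0(toy_A, substring(x, 3L)),
         paste0(toy_B, substring(x, 3L)))
}

# --- random schema-graph soups -------------------------------------------

random_soup <- function(seed, n_preds = NULL) {
  set.seed(seed)
  nd <- sample(2:4, 1L)
  doms <- paste0("d", seq_len(nd))
  ns <- setNames(paste0("http://x.org/", doms, "/"), doms)
  if (is.null(n_preds)) n_preds <- sample(6:14, 1L)
  pdom <- sample(doms, n_preds, replace = TRUE)
  preds <- paste0(ns[pdom], "p", seq_len(n_preds))
  concepts <- unlist(lapply(doms, function(d) {
    paste0(ns[[d]], "c", seq_len(sample(3:5, 1L)))
  }))
  rows <- lapply(seq_len(n_preds), function(i) {
    k <- sample(1:2, 1L)
    data.frame(subject = sample(concepts, k, replace = TRUE),
               predicate = preds[i],
               object = sample(concepts, k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  tr <- unique(do.call(rbind, rows))
  # drop degenerate self-loop-only rows sometimes produced; keep graph valid
  schema_graph(tr, setNames(doms, unname(ns)), strict = FALSE)
}

# --- raw accessors straight from the triple table ------------------------

oracle_subjects <- function(g, p) unique(g$triples$subject[g$triples$predicate == p])
oracle_objects <- function(g, p) unique(g$triples$object[g$triples$predicate == p])
oracle_cset <- function(g, p) unique(c(oracle_subjects(g, p), oracle_objects(g, p)))
oracle_dom <- function(g) setNames(g$predicates$domain, g$predicates$uri)

# --- share-pattern oracles (Definition-level pair enumeration) -----------

oracle_share_patterns <- function(g, role = c("objects", "subjects")) {
  role <- match.arg(role)
  preds <- g$predicates$uri
  get <- if (role == "objects") oracle_objects else oracle_subjects
  out <- character()
  if (length(preds) >= 2L) {
    for (i in seq_along(preds)) {
      for (j in seq_along(preds)) {
        if (i >= j) next
        shared <- intersect(get(g, preds[i]), get(g, preds[j]))
        for (cc in shared) {
          pair <- sort(c(preds[i], preds[j]))
          out <- c(out, paste(pair[1L], pair[2L], cc, sep = " "))
        }
      }
    }
  }
  sort(unique(out))
}

oracle_reacher_patterns <- function(g) {
  preds <- g$predicates$uri
  out <- character()
  for (pi in preds) {
    for (pj in preds) {
      if (pi == pj) next
      shared <- intersect(oracle_objects(g, pi), oracle_subjects(g, pj))
      for (cc in shared) out <- c(out, paste(pi, pj, cc, sep = " "))
    }
  }
  sort(unique(out))
}

# --- predicate distances by hand-rolled BFS ------------------------------

oracle_distances <- function(g) {
  preds <- g$predicates$uri
  n <- length(preds)
  adj <- matrix(FALSE, n, n, dimnames = list(preds, preds))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          length(intersect(oracle_cset(g, preds[i]), oracle_cset(g, preds[j]))) > 0L) {
        adj[i, j] <- TRUE
      }
    }
  }
  d <- matrix(Inf, n, n, dimnames = list(preds, preds))
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier) > 0L) {
      lev <- lev + 1
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ])) {
          if (!is.finite(d[s, w])) {
            d[s, w] <- lev
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
  }
  d
}

# --- connectivity-chain oracle: exhaustive tuple enumeration -------------

# A directed link pi -> pj exists through anchor c when c is an object of pi
# and a subject of pj; an undirected link when c is in both concept sets.
oracle_chain_anchors <- function(g, pi, pj, directed) {
  if (directed) {
    intersect(oracle_objects(g, pi), oracle_subjects(g, pj))
  } else {
    intersect(oracle_cset(g, pi), oracle_cset(g, pj))
  }
}

# TRUE when the chain admits an anchor assignment with pairwise-distinct
# concepts (checked by depth-first assignment).
oracle_anchors_ok <- function(anchor_sets) {
  assign_next <- function(k, used) {
    if (k > length(anchor_sets)) return(TRUE)
    for (cc in setdiff(anchor_sets[[k]], used)) {
      if (assign_next(k + 1L, c(used, cc))) return(TRUE)
    }
    FALSE
  }
  assign_next(1L, character())
}

oracle_chains <- function(g, boundary = 3L, directed = TRUE) {
  preds <- g$predicates$uri
  dom <- oracle_dom(g)
  d <- oracle_distances(g)
  out <- character()
  grow <- function(chain) {
    if (length(chain) >= 3L) {
      ends_l <- d[chain[1L], chain[length(chain)]]
      sets <- lapply(seq_len(length(chain) - 1L), function(t) {
        oracle_chain_anchors(g, chain[t], chain[t + 1L], directed)
      })
      if (is.finite(ends_l) && ends_l >= 2 && ends_l <= boundary &&
          length(unique(dom[chain])) >= 2L && oracle_anchors_ok(sets)) {
        key <- chain
        if (!directed) {
          rv <- rev(chain)
          if (paste(rv, collapse = "|") < paste(chain, collapse = "|")) key <- rv
        }
        out <<- c(out, paste(key, collapse = "|"))
      }
    }
    if (length(chain) >= boundary + 1L) return()
    for (nxt in preds) {
      if (nxt %in% chain) next
      if (length(oracle_chain_anchors(g, chain[length(chain)], nxt, directed)) > 0L) {
        grow(c(chain, nxt))
      }
    }
  }
  for (p in preds) grow(p)
  sort(unique(out))
}

# --- association oracles --------------------------------------------------

oracle_sa <- function(g, pi, pj) {
  if (pi == pj) return(1)
  ci <- oracle_cset(g, pi)
  cj <- oracle_cset(g, pj)
  length(intersect(ci, cj))^2 / (length(ci) * length(cj))
}

# Max product of share associations over simple shortest predicate paths.
oracle_ca <- function(g, pi, pj, boundary = 3L) {
  d <- oracle_distances(g)
  l <- d[pi, pj]
  if (!is.finite(l) || l > boundary) return(0)
  stopifnot(l >= 2)
  preds <- g$predicates$uri
  best <- 0
  walk <- function(chain, prod) {
    last <- chain[length(chain)]
    if (length(chain) - 1L == l) {
      if (last == pj) best <<- max(best, prod)
      return()
    }
    for (nxt in preds) {
      if (nxt %in% chain) next
      if (d[last, nxt] == 1 && d[nxt, pj] == l - (length(chain))) {
        walk(c(chain, nxt), prod * oracle_sa(g, last, nxt))
      }
    }
  }
  walk(pi, 1)
  best
}

# Helper: pattern table rows -> comparable key strings.
pattern_keys <- function(df, with_anchor = TRUE) {
  if (nrow(df) == 0L) return(character())
  if (with_anchor) {
    sort(paste(gsub("\\|", " ", df$predicates), df$anchors))
  } else {
    sort(df$predicates)
  }
}
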