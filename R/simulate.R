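# Seeded synthetic multi-domain vocabularies with planted topic structure
# and plantable pattern motifs, plus the small canonical two-domain toy
# fixture used throughout the tests and documentation.

TOY_NS <- c(A = "http://example.org/A/", B = "http://example.org/B/")

#' Namespace map for the toy fixtures
#' @return Named character vector: domain name keyed by URI prefix.
#' @export
toy_namespace_map <- function() stats::setNames(names(TOY_NS), unname(TOY_NS))

#' The canonical two-domain toy triple set
#'
#' Five schema triples over domains A and B: `A:C1 -p1-> A:C2`,
#' `B:C3 -p2-> A:C2`, `A:C2 -p3-> B:C4`, `B:C3 -p4-> B:C5` and (optionally)
#' `B:C4 -p5-> B:C6`, which extends the Reacher chain p1/p2 -> p3 into
#' directional connector chains.
#'
#' @param include_p5 Include the fifth triple (default `TRUE`).
#' @return Triple data frame (`subject`, `predicate`, `object`).
#' @export
toy_triples <- function(include_p5 = TRUE) {
  A <- TOY_NS[["A"]]; B <- TOY_NS[["B"]]
  tr <- data.frame(
    subject = c(paste0(A, "C1"), paste0(B, "C3"), paste0(A, "C2"),
                 paste0(B, "C3"), paste0(B, "C4")),
    predicate = c(paste0(A, "p1"), paste0(B, "p2"), paste0(A, "p3"),
                   paste0(B, "p4"), paste0(B, "p5")),
    object = c(paste0(A, "C2"), paste0(A, "C2"), paste0(B, "C4"),
                paste0(B, "C5"), paste0(B, "C6")),
    stringsAsFactors = FALSE
  )
  if (!include_p5) tr <- tr[1:4, , drop = FALSE]
  tr
}

#' The toy schema graph
#' @inheritParams toy_triples
#' @return A `schema_graph` over domains A and B.
#' @export
toy_graph <- function(include_p5 = TRUE) {
  schema_graph(toy_triples(include_p5), toy_namespace_map())
}

#' The worked diversity-weighting scenario
#'
#' A small cross-domain graph plus a companion weight table: predicate
#' `A:P3` shares a concept with `B:P4` (pairwise weight 0.2) and has two
#' further neighbors with weights 0.5 and 0.8; `B:P4` has two further
#' neighbors with weights 0.2 and 0.3. The neighborhood means are then 0.5
#' and 0.2333..., and the diversity weight of the P3-P4 link is 0.35.
#'
#' @return List with `graph` (a `schema_graph`), `weights` (the companion
#'   association matrix), and the URIs `p3`, `p4`.
#' @export
toy_fig_weights <- function() {
  A <- TOY_NS[["A"]]; B <- TOY_NS[["B"]]
  p <- function(ns, x) paste0(ns, x)
  tr <- data.frame(
    subject = c(p(A, "S3"), p(B, "S4"), p(A, "Sa"), p(A, "Sb"),
                 p(B, "Sc"), p(B, "Sd")),
    predicate = c(p(A, "P3"), p(B, "P4"), p(A, "Pa"), p(A, "Pb"),
                   p(B, "Pc"), p(B, "Pd")),
    object = c(p(A, "X"), p(A, "X"), p(A, "S3"), p(A, "S3"),
                p(B, "S4"), p(B, "S4")),
    stringsAsFactors = FALSE
  )
  g <- schema_graph(tr, toy_namespace_map())
  preds <- names(g$cp)
  w <- matrix(0, length(preds), length(preds), dimnames = list(preds, preds))
  diag(w) <- 1
  set_w <- function(a, b, v) {
    w[p(A, a) == rownames(w) | p(B, a) == rownames(w),
      p(A, b) == colnames(w) | p(B, b) == colnames(w)] <<- v
    w[p(A, b) == rownames(w) | p(B, b) == rownames(w),
      p(A, a) == colnames(w) | p(B, a) == colnames(w)] <<- v
  }
  set_w("P3", "P4", 0.2)
  set_w("P3", "Pa", 0.5)
  set_w("P3", "Pb", 0.8)
  set_w("P4", "Pc", 0.2)
  set_w("P4", "Pd", 0.3)
  diag(w) <- 1
  w <- structure(w, variant = "raw", boundary = 3L,
                 class = c("cdnp_assoc", "matrix", "array"))
  list(graph = g, weights = w, p3 = p(A, "P3"), p4 = p(B, "P4"))
}

#' Generator configuration for synthetic multi-domain vocabularies
#'
#' Defaults describe the study conditions used throughout the tests: four
#' domains of ten predicates each, three planted cross-domain topics, a 0.6
#' within-topic and 0.05 cross-topic share probability.
#'
#' @param n_domains Number of domains (namespaces).
#' @param predicates_per_domain Predicates per domain.
#' @param concepts_per_domain Size of each domain's private concept pool.
#' @param n_topics Number of planted topics.
#' @param within_share_prob Probability that a within-topic predicate pair
#'   shares a concept.
#' @param cross_share_prob Probability that a cross-topic predicate pair is
#'   bridged.
#' @param hubs_per_topic Shared hub concepts per planted topic.
#' @param planted_motifs Optional data frame (`type`, `count`) of pattern
#'   motifs to plant verbatim.
#' @param seed Integer seed; the generator is deterministic given the
#'   configuration.
#' @return A list of class `cdnp_gen_config`.
#' @export
generator_config <- function(n_domains = 4L, predicates_per_domain = 10L,
                             concepts_per_domain = 12L, n_topics = 3L,
                             within_share_prob = 0.6, cross_share_prob = 0.05,
                             hubs_per_topic = 3L, planted_motifs = NULL,
                             seed = 1L) {
  cfg <- list(n_domains = as.integer(n_domains),
              predicates_per_domain = as.integer(predicates_per_domain),
              concepts_per_domain = as.integer(concepts_per_domain),
              n_topics = as.integer(n_topics),
              within_share_prob = within_share_prob,
              cross_share_prob = cross_share_prob,
              hubs_per_topic = as.integer(hubs_per_topic),
              planted_motifs = planted_motifs,
              seed = as.integer(seed))
  stopifnot(cfg$n_domains >= 1L, cfg$predicates_per_domain >= 1L,
            cfg$concepts_per_domain >= 1L, cfg$n_topics >= 1L,
            cfg$within_share_prob >= 0, cfg$within_share_prob <= 1,
            cfg$cross_share_prob >= 0, cfg$cross_share_prob <= 1)
  class(cfg) <- "cdnp_gen_config"
  cfg
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multi-domain vocabulary
#'
#' Emits namespace-prefixed schema triples over `n_domains` domains.
#' Every predicate gets a backbone triple from a private subject to one of
#' its planted topic's hub concepts. Within-topic predicate pairs
#' additionally co-attach to a topic hub (as a shared object or shared
#' subject) with probability `within_share_prob`; cross-topic pairs are
#' bridged Reacher-style through a fresh concept with probability
#' `cross_share_prob`. Requested motifs are planted verbatim on dedicated
#' predicate pairs/chains.
#'
#' @param config A [generator_config()].
#' @return List with `triples`, `namespace_map`, `truth` (named integer
#'   topic assignment per predicate plus planted motif records), and
#'   `config`.
#' @export
simulate_vocabulary <- function(config = generator_config()) {
  stopifnot(inherits(config, "cdnp_gen_config"))
  with_seed(config$seed, {
    nd <- config$n_domains
    ppd <- config$predicates_per_domain
    doms <- sprintf("dom%02d", seq_len(nd))
    ns <- stats::setNames(sprintf("http://example.org/%s/", doms), doms)
    preds <- unlist(lapply(doms, function(d) {
      sprintf("%sp%02d", ns[[d]], seq_len(ppd))
    }))
    pdoms <- rep(doms, each = ppd)
    np <- length(preds)

    topic_of <- stats::setNames(
      sample(rep_len(seq_len(config$n_topics), np)), preds
    )
    hubs <- lapply(seq_len(config$n_topics), function(t) {
      hd <- sample(doms, config$hubs_per_topic, replace = TRUE)
      sprintf("%shub_t%d_%d", ns[hd], t, seq_len(config$hubs_per_topic))
    })

    subj <- character(); pred <- character(); obj <- character()
    add <- function(s, p, o) {
      subj <<- c(subj, s); pred <<- c(pred, p); obj <<- c(obj, o)
    }
    private <- stats::setNames(
      sprintf("%ss_%s", ns[pdoms], sub("^.*/", "", preds)), preds
    )

    # Motif predicates are reserved up front (interleaved across domains so
    # chains span domains) and excluded from the background share process,
    # which keeps the planted motifs verbatim.
    reserved <- character()
    if (!is.null(config$planted_motifs)) {
      pm <- config$planted_motifs
      need <- sum(ifelse(pm$type %in% c("DC", "NDC"), 3L, 2L) * pm$count)
      if (need > np) stop("more motifs requested than predicate slots",
                          call. = FALSE)
      interleaved <- as.vector(matrix(preds, nrow = nd, byrow = TRUE))
      reserved <- interleaved[seq_len(need)]
    }

    for (i in seq_len(np)) {
      if (preds[i] %in% reserved) next
      h <- sample(hubs[[topic_of[[preds[i]]]]], 1L)
      add(private[[preds[i]]], preds[i], h)
    }
    for (a in seq_len(np - 1L)) {
      for (b in (a + 1L):np) {
        pa <- preds[a]; pb <- preds[b]
        if (pa %in% reserved || pb %in% reserved) next
        if (topic_of[[pa]] == topic_of[[pb]]) {
          if (stats::runif(1) < config$within_share_prob) {
            h <- sample(hubs[[topic_of[[pa]]]], 1L)
            if (stats::runif(1) < 0.5) {       # provider-style: shared object
              add(private[[pa]], pa, h); add(private[[pb]], pb, h)
            } else {                            # consumer-style: shared subject
              add(h, pa, private[[pa]]); add(h, pb, private[[pb]])
            }
          }
        } else if (stats::runif(1) < config$cross_share_prob) {
          bridge <- sprintf("%sbridge_%d_%d", ns[pdoms[a]], a, b)
          add(private[[pa]], pa, bridge)        # Reacher: obj(pa) = subj(pb)
          add(bridge, pb, private[[pb]])
        }
      }
    }

    motifs <- list()
    if (!is.null(config$planted_motifs)) {
      pm <- config$planted_motifs
      slot <- 0L
      take <- function(k) {
        out <- reserved[slot + seq_len(k)]
        slot <<- slot + k
        out
      }
      for (r in seq_len(nrow(pm))) {
        for (rep in seq_len(pm$count[r])) {
          tp <- pm$type[r]
          if (tp %in% c("PROVIDER", "CONSUMER", "REACHER")) {
            pp <- take(2L)
            cc <- sprintf("%smotif_%s_%d_%d", ns[[1L]], tolower(tp), r, rep)
            if (tp == "PROVIDER") {
              add(private[[pp[1L]]], pp[1L], cc)
              add(private[[pp[2L]]], pp[2L], cc)
            } else if (tp == "CONSUMER") {
              add(cc, pp[1L], private[[pp[1L]]])
              add(cc, pp[2L], private[[pp[2L]]])
            } else {
              add(private[[pp[1L]]], pp[1L], cc)
              add(cc, pp[2L], private[[pp[2L]]])
            }
            motifs[[length(motifs) + 1L]] <-
              list(type = tp, predicates = pp, anchors = cc)
          } else {
            pp <- take(3L)
            c1 <- sprintf("%smotif_%s_%d_%d_a", ns[[1L]], tolower(tp), r, rep)
            c2 <- sprintf("%smotif_%s_%d_%d_b", ns[[2L]], tolower(tp), r, rep)
            add(private[[pp[1L]]], pp[1L], c1)
            add(c1, pp[2L], c2)
            add(c2, pp[3L], private[[pp[3L]]])
            motifs[[length(motifs) + 1L]] <-
              list(type = tp, predicates = pp, anchors = c(c1, c2))
          }
        }
      }
    }

    triples <- unique(data.frame(subject = subj, predicate = pred,
                                 object = obj, stringsAsFactors = FALSE))
    triples <- triples[order(triples$subject, triples$predicate,
                             triples$object, method = "radix"), , drop = FALSE]
    rownames(triples) <- NULL
    list(triples = triples,
         namespace_map = stats::setNames(doms, unname(ns)),
         truth = list(topic = topic_of, motifs = motifs),
         config = config)
  })
}

#' Generate and build a synthetic schema graph
#'
#' @inheritParams simulate_vocabulary
#' @return List with `graph` (a `schema_graph`) and the `truth` /
#'   `triples` / `config` elements of [simulate_vocabulary()].
#' @export
simulate_schema_graph <- function(config = generator_config()) {
  sim <- simulate_vocabulary(config)
  sim$graph <- schema_graph(sim$triples, sim$namespace_map)
  sim
}

#' Write generated triples (or any triple table) to an RDF fixture file
#'
#' @param triples Triple data frame.
#' @param path Output file.
#' @param format `"ntriples"` or `"turtle"`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(triples, path, format = c("ntriples", "turtle")) {
  write_ntriples(triples, path, format = match.arg(format))
}
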