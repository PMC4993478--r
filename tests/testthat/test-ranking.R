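test_that("degree ranking puts the busiest toy concept first", {
  g <- toy_graph()
  rk <- rank_nodes(g, "concept")
  expect_equal(rk$uri[1L], toy_uri("A:C2"))     # touches p1, p2, p3
  expect_equal(rk$score[1L], 3L)
  empty <- schema_graph(toy_triples()[0, ], toy_namespace_map())
  expect_equal(nrow(rank_nodes(empty, "predicate")), 0L)
})

test_that("cross-domain scope drops nodes outside cross-domain patterns", {
  g <- toy_graph(include_p5 = FALSE)
  rk <- rank_nodes(g, "predicate", scope = "cross_domain")
  expect_false(toy_uri("B:p4") %in% rk$uri)     # only in the within-B pair
  expect_true(toy_uri("A:p1") %in% rk$uri)
})

test_that("rankings are invariant to input row order", {
  tr <- toy_triples()
  g1 <- toy_graph()
  g2 <- schema_graph(tr[c(5, 3, 1, 4, 2), ], toy_namespace_map())
  expect_identical(rank_nodes(g1, "concept"), rank_nodes(g2, "concept"))
  expect_identical(rank_nodes(g1, "predicate"), rank_nodes(g2, "predicate"))
})

test_that("topic feature ranking orders by cross-domain count then popularity", {
  g <- toy_graph()
  pats <- mine_patterns(g)
  topics <- list(
    list(id = 2L, predicates = toy_uri(c("A:p1", "A:p3", "B:p5")), pool = FALSE),
    list(id = 3L, predicates = toy_uri("B:p4"), pool = FALSE)
  )
  rk <- topic_feature_rank(topics, g, pats)
  expect_equal(rk$topic, c(2L, 3L))
  expect_equal(rk$verity, c(2L, 1L))            # A+B vs single domain
  # adding one more cross-domain predicate outranks an otherwise equal topic
  t2 <- list(list(id = 2L, predicates = toy_uri(c("A:p1", "B:p2")), pool = FALSE),
             list(id = 3L, predicates = toy_uri(c("A:p1", "B:p2", "A:p3")),
                  pool = FALSE))
  rk2 <- topic_feature_rank(t2, g, pats)
  expect_equal(rk2$topic[1L], 3L)
})

test_that("topic pattern ranking only counts fully contained patterns", {
  g <- toy_graph(include_p5 = FALSE)
  pats <- mine_patterns(g)
  topics <- list(
    list(id = 2L, predicates = toy_uri(c("A:p1", "B:p2", "A:p3")), pool = FALSE),
    list(id = 3L, predicates = toy_uri("B:p4"), pool = FALSE)
  )
  rk <- topic_pattern_rank(topics, pats)
  row2 <- rk[rk$topic == 2L, ]
  expect_equal(row2$provider, 1L)
  expect_equal(row2$reacher, 2L)
  expect_equal(row2$total, 3L)                   # 1 Provider + 2 Reacher
  expect_equal(rk$total[rk$topic == 3L], 0L)
  # the Consumer pair straddles both topics, so neither counts it
  expect_equal(sum(rk$consumer), 0L)
})

test_that("topic statistics reproduce the density closed form", {
  g <- toy_graph()
  st <- topic_stats(list(id = 2L, predicates = toy_uri(c("A:p1", "B:p2"))),
                    g, predicate_association(g))
  # members touch C1, C2, C3: N = 2 + 3, E = 4 legs
  expect_equal(st$n_nodes, 5L)
  expect_equal(st$n_edges, 4L)
  expect_equal(st$density, 2 * 4 / (5 * 4))
  expect_equal(st$mean_association, 0.25)
  # a triangle-equivalent subgraph (N = 3, E = 3) is fully dense
  tr <- data.frame(subject = c("http://x.org/c1", "http://x.org/c2"),
                   predicate = "http://x.org/p",
                   object = c("http://x.org/c2", "http://x.org/c2"),
                   stringsAsFactors = FALSE)
  g2 <- schema_graph(tr, c("http://x.org/" = "x"))
  st2 <- topic_stats(list(id = 1L, predicates = "http://x.org/p"), g2,
                     predicate_association(g2))
  expect_equal(st2$n_nodes, 3L)
  expect_equal(st2$n_edges, 3L)
  expect_equal(st2$density, 1)
})

test_that("density stays consistent with its node and edge counts", {
  for (seed in c(2, 6)) {
    g <- random_soup(seed)
    fit <- phal(g)
    pa <- fit$association$raw
    for (tp in fit$topics) {
      st <- topic_stats(tp, g, pa)
      if (st$n_nodes >= 2L) {
        expect_equal(st$density,
                     2 * st$n_edges / (st$n_nodes * (st$n_nodes - 1)))
      }
    }
  }
})

test_that("provider patterns point the sharing domains at the anchor domain", {
  g <- toy_graph(include_p5 = FALSE)
  pats <- mine_patterns(g, "PROVIDER")
  dcg <- build_domain_collaboration(pats, g)
  # anchor C2 is in A; p1 (A) -> A collapses, p2 (B) -> A survives
  expect_equal(dcg$edges$from, "B")
  expect_equal(dcg$edges$to, "A")
  # with no cross-domain pattern the domains stay isolated
  empty_dcg <- build_domain_collaboration(empty_patterns(), g)
  expect_equal(nrow(empty_dcg$edges), 0L)
  expect_setequal(empty_dcg$nodes$domain, c("A", "B"))
})

test_that("edge multiplicity accumulates supporting patterns", {
  g <- toy_graph()
  pats <- mine_patterns(g)
  dcg <- build_domain_collaboration(pats, g)
  expect_true(all(dcg$edges$weight >= 1L))
  expect_equal(sum(dcg$nodes$out_degree), sum(dcg$edges$weight))
  expect_equal(sum(dcg$nodes$in_degree), sum(dcg$edges$weight))
})

test_that("domain roles follow the degree and topology rules", {
  dcg <- structure(list(
    nodes = data.frame(domain = c("X", "Y", "Z"),
                       in_degree = c(0L, 5L, 5L),
                       out_degree = c(5L, 5L, 1L), stringsAsFactors = FALSE),
    edges = data.frame(from = c("X", "Y"), to = c("Y", "Z"),
                       weight = c(5L, 5L), stringsAsFactors = FALSE)
  ), class = "cdnp_dcg")
  roles <- classify_domain_roles(dcg)
  by_dom <- setNames(strsplit(roles$roles, ",", fixed = TRUE), roles$domain)
  expect_true("Provider" %in% by_dom$X)          # out 5, in 0
  expect_true("Balancer" %in% by_dom$Y)          # in = out
  expect_true("Bridger" %in% by_dom$Y)           # middle of X -> Y -> Z
  expect_true("Consumer" %in% by_dom$Z)
  expect_false("Bridger" %in% by_dom$X)
})

test_that("roles export to GraphML with attributes attached", {
  g <- toy_graph()
  dcg <- build_domain_collaboration(mine_patterns(g), g)
  f <- tempfile(fileext = ".graphml")
  write_dcg_graphml(dcg, f)
  doc <- xml2::read_xml(f)
  txt <- as.character(doc)
  expect_match(txt, "roles")
  expect_match(txt, "graphml")
})
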