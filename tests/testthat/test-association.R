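# Fixture values (SA = 0.25, l(p1,p5) = 2, CA = 0.0625, diamond CA = 0.0625)
# were first computed with the helper oracles / by direct set enumeration on
# the triple tables, then frozen here.

toy_p <- function(x) toy_uri(x)

test_that("association distance counts concepts on shortest undirected paths", {
  g <- toy_graph()
  expect_equal(association_distance(g, toy_p("A:p1"), toy_p("A:p1")), 0)
  expect_equal(association_distance(g, toy_p("A:p1"), toy_p("B:p2")), 1)
  expect_equal(association_distance(g, toy_p("A:p1"), toy_p("B:p5")), 2)
  expect_equal(association_distance(g, toy_p("B:p4"), toy_p("B:p5")), 3)
  expect_error(association_distance(g, "http://x.org/q", toy_p("A:p1")),
               "unknown")
  for (seed in 1:6) {
    gg <- random_soup(seed)
    expect_equal(unname(predicate_distances(gg)), unname(oracle_distances(gg)))
  }
})

test_that("share association follows the squared-overlap formula", {
  g <- toy_graph()
  expect_equal(share_association(g, toy_p("A:p1"), toy_p("A:p1")), 1)
  expect_equal(share_association(g, toy_p("A:p1"), toy_p("B:p2")), 0.25)
  expect_equal(share_association(g, toy_p("A:p1"), toy_p("B:p5")), 0)  # l = 2
  # disconnected predicates associate at 0
  tr <- rbind(toy_triples(),
              data.frame(subject = "http://example.org/A/Z1",
                         predicate = "http://example.org/A/pz",
                         object = "http://example.org/A/Z2"))
  g2 <- schema_graph(tr, toy_namespace_map())
  expect_equal(share_association(g2, toy_p("A:p1"), toy_p("A:pz")), 0)
})

test_that("connectivity association multiplies along the best bridge", {
  g <- toy_graph()
  expect_equal(connectivity_association(g, toy_p("A:p1"), toy_p("B:p5")),
               0.25 * 0.25)
  expect_error(connectivity_association(g, toy_p("A:p1"), toy_p("B:p2")),
               "l\\(Pi,Pj\\) >= 2")
  # beyond the boundary the association is cut to zero
  expect_equal(connectivity_association(g, toy_p("B:p4"), toy_p("B:p5"),
                                        boundary = 2L), 0)
})

test_that("the diamond graph takes the larger of two bridge products", {
  x <- "http://x.org/"; y <- "http://y.org/"
  tr <- data.frame(
    subject = c(paste0(x, "c1"), paste0(x, "c1"), paste0(x, "c3"),
                 paste0(y, "x1"), paste0(x, "c2")),
    predicate = c(paste0(x, "I"), paste0(x, "K1"), paste0(y, "K2"),
                   paste0(y, "K2"), paste0(y, "J")),
    object = c(paste0(x, "c3"), paste0(x, "c2"), paste0(x, "c4"),
                paste0(y, "x2"), paste0(x, "c4")),
    stringsAsFactors = FALSE
  )
  g <- schema_graph(tr, setNames(c("x", "y"), c(x, y)))
  # route via K1: SA = (1/4) * (1/4); route via K2: SA = (1/8) * (1/8)
  res <- connectivity_association(g, paste0(x, "I"), paste0(y, "J"),
                                  with_chain = TRUE)
  expect_equal(res$value, 0.0625)
  expect_equal(res$chain[2L], paste0(x, "K1"))
  expect_equal(res$value, oracle_ca(g, paste0(x, "I"), paste0(y, "J")))
})

test_that("dynamic programming equals exhaustive path-product maximization", {
  for (seed in 1:10) {
    g <- random_soup(seed)
    d <- oracle_distances(g)
    idx <- which(is.finite(d) & d >= 2 & d <= 3 & upper.tri(d), arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    for (r in seq_len(nrow(idx))) {
      pi <- rownames(d)[idx[r, 1L]]
      pj <- colnames(d)[idx[r, 2L]]
      expect_equal(connectivity_association(g, pi, pj), oracle_ca(g, pi, pj),
                   info = paste("seed", seed, pi, pj))
    }
  }
})

test_that("the association matrix agrees entry-wise with the formulas", {
  for (seed in c(3, 7, 11)) {
    g <- random_soup(seed)
    pa <- predicate_association(g)
    d <- oracle_distances(g)
    expect_true(isSymmetric(unclass(pa)))
    expect_true(all(diag(pa) == 1))
    expect_true(all(pa >= 0 & pa <= 1))
    for (i in rownames(d)) {
      for (j in colnames(d)) {
        expected <- if (i == j) 1
          else if (!is.finite(d[i, j]) || d[i, j] > 3) 0
          else if (d[i, j] <= 1) oracle_sa(g, i, j)
          else oracle_ca(g, i, j)
        expect_equal(pa[i, j], expected, info = paste(seed, i, j))
      }
    }
  }
})

test_that("neighborhood weights average the incident edge weights", {
  fw <- toy_fig_weights()
  expect_equal(neighborhood_weight(fw$weights, fw$graph, fw$p3), 0.5)
  expect_equal(neighborhood_weight(fw$weights, fw$graph, fw$p4), 0.2333,
               tolerance = 1e-3)
  # an isolated predicate has weight 0
  tr <- rbind(toy_triples(),
              data.frame(subject = "http://example.org/A/Z1",
                         predicate = "http://example.org/A/pz",
                         object = "http://example.org/A/Z2"))
  g2 <- schema_graph(tr, toy_namespace_map())
  pa <- predicate_association(g2)
  expect_equal(neighborhood_weight(pa, g2, "http://example.org/A/pz"), 0)
})

test_that("the diversity weight follows the two-branch rule", {
  expect_equal(diversity_weight(0.2, 0.5, 0.2333), 0.35)
  expect_equal(diversity_weight(0.9, 0.1, 0.1), 0.9)    # condition fails
  expect_equal(diversity_weight(0.4, 0.4, 0.4), 0.4)    # branches coincide
  expect_error(diversity_weight(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("cross-domain reweighting raises entries and keeps symmetry", {
  fw <- toy_fig_weights()
  rw <- reweight_cross_domain(fw$weights, fw$graph)
  expect_equal(rw[fw$p3, fw$p4], 0.35)
  expect_equal(rw[fw$p4, fw$p3], 0.35)
  # same-domain entries untouched
  pa <- "http://example.org/A/Pa"
  expect_equal(rw[fw$p3, pa], fw$weights[fw$p3, pa])
  for (seed in c(2, 5, 9)) {
    g <- random_soup(seed)
    raw <- predicate_association(g)
    rw2 <- reweight_cross_domain(raw, g)
    expect_true(isSymmetric(unclass(rw2)))
    expect_true(all(rw2 >= unclass(raw) - 1e-12))
    dom <- oracle_dom(g)
    same <- outer(dom[rownames(raw)], dom[colnames(raw)], "==")
    expect_equal(unclass(rw2)[same], unclass(raw)[same])
  }
  # a single-domain graph is a no-op
  g1 <- schema_graph(toy_triples()[c(1, 3), ],
                     c("http://example.org/" = "all"))
  raw1 <- predicate_association(g1)
  expect_equal(unclass(reweight_cross_domain(raw1, g1)), unclass(raw1),
               ignore_attr = TRUE)
})
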