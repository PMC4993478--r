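test_that("element distance complements the association matrix", {
  fw <- toy_fig_weights()
  expect_equal(element_distance(fw$weights, fw$p3, fw$p3), 0)
  expect_equal(element_distance(fw$weights, fw$p3, fw$p4), 0.8)
  pa <- "http://example.org/A/Pa"
  pc <- "http://example.org/B/Pc"
  expect_equal(element_distance(fw$weights, pa, pc), 1)   # no association
})

test_that("topic distance is the mean over the cross product", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "c"] <- d["c", "a"] <- 0.2
  d["b", "c"] <- d["c", "b"] <- 0.4
  expect_equal(topic_distance(d, c("a", "b"), "c"), 0.3)
  expect_equal(topic_distance(d, "a", "c"), 0.2)
  expect_error(topic_distance(d, c("a", "b"), c("b", "c")), "disjoint")
  dd <- matrix(0.7, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(topic_distance(dd, c("a", "b"), c("c", "d")), 0.7)
})

test_that("the merge tree agglomerates closest pairs first", {
  d <- matrix(0.9, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.1
  tree <- hac_build(c("a", "b", "c"), d)
  expect_equal(tree$height, 2L)
  expect_equal(sort(tree$merges$parent[tree$merges$level == 1]),
               cluster_label(c("a", "b")))
  expect_equal(lengths(tree$levels[["2"]]), 3L)
  # degenerate single-predicate input
  t1 <- hac_build("solo", matrix(0, 1, 1, dimnames = list("solo", "solo")))
  expect_equal(t1$height, 0L)
  expect_equal(t1$levels[["0"]][[1L]], "solo")
})

test_that("leaves are conserved and the active set shrinks every level", {
  for (seed in c(4, 8)) {
    g <- random_soup(seed, n_preds = 12)
    rw <- reweight_cross_domain(predicate_association(g), g)
    tree <- hac_build(names(g$cp), 1 - unclass(rw))
    sizes <- vapply(tree$levels, function(lv) sum(lengths(lv)), 1L)
    expect_true(all(sizes == length(g$cp)))          # leaf conservation
    counts <- vapply(tree$levels, length, 1L)
    expect_true(all(diff(counts[order(as.integer(names(counts)))]) <= -1L))
    expect_equal(unname(counts[as.character(tree$height)]), 1L)
  }
})

test_that("mid-level extraction uses the rounded-up half height", {
  d <- matrix(0.9, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.1
  tree <- hac_build(c("a", "b", "c"), d)       # H = 2
  mid <- extract_mid_topics(tree)
  expect_equal(mid$mid, 1)
  expect_setequal(vapply(mid$topics, cluster_label, ""),
                  c(cluster_label(c("a", "b")), "c"))
  t1 <- hac_build("solo", matrix(0, 1, 1, dimnames = list("solo", "solo")))
  m1 <- extract_mid_topics(t1)
  expect_equal(m1$mid, 0)
  expect_equal(m1$topics[[1L]], "solo")
})

test_that("final-topic assembly pools singletons and numbers remainders", {
  # no singleton remainders -> no pool topic
  t0 <- assemble_final_topics(list(c("a", "b")), list())
  expect_equal(vapply(t0, `[[`, 1L, "id"), 2L)
  # two singleton remainders join the special first topic
  t1 <- assemble_final_topics(list(c("a", "b")), list("x", "y"))
  expect_equal(t1[[1L]]$id, 1L)
  expect_setequal(t1[[1L]]$predicates, c("x", "y"))
  expect_true(t1[[1L]]$pool)
  # 5 mid topics + 2 multi-member remainders -> remainder ids 7 and 8
  mids <- lapply(1:5, function(i) paste0("m", i, letters[1:2]))
  rem <- list(c("r1", "r2"), c("r3", "r4"))
  t2 <- assemble_final_topics(mids, rem)
  expect_equal(vapply(t2, `[[`, 1L, "id"), c(2:6, 7L, 8L))
})

test_that("refinement adds bridging predicates and is idempotent", {
  g <- toy_graph()
  topic <- list(list(id = 2L, predicates = toy_uri(c("A:p1", "B:p5")),
                     pool = FALSE))
  ref <- refine_topics(topic, g)
  expect_setequal(ref[[1L]]$predicates, toy_uri(c("A:p1", "A:p3", "B:p5")))
  expect_equal(ref[[1L]]$domains, c("A", "B"))
  ref2 <- refine_topics(ref, g)
  expect_equal(ref2[[1L]]$predicates, ref[[1L]]$predicates)
  # a topic with no connectivity pair is untouched
  t2 <- refine_topics(list(list(id = 3L, predicates = toy_uri(c("A:p1", "B:p2")),
                                pool = FALSE)), g)
  expect_setequal(t2[[1L]]$predicates, toy_uri(c("A:p1", "B:p2")))
})

test_that("distance-derived bridges equal the mined connectivity chains", {
  for (seed in c(1, 5, 9)) {
    g <- random_soup(seed)
    pats <- mine_patterns(g, c("DC", "NDC"))
    fit <- phal(g, refine = FALSE)
    a <- refine_topics(fit$topics_initial, g)
    b <- refine_topics(fit$topics_initial, g, patterns = pats)
    expect_equal(lapply(a, `[[`, "predicates"), lapply(b, `[[`, "predicates"),
                 info = paste("seed", seed))
  }
})

test_that("the full pipeline covers every predicate deterministically", {
  g <- toy_graph()
  fit <- phal(g)
  expect_s3_class(fit, "phal")
  mem <- topic_membership(fit)
  expect_setequal(unique(mem$predicate), names(g$cp))
  expect_identical(phal(g)$topics, fit$topics)        # rerun identical
})

test_that("structural invariants hold across seeded synthetic graphs", {
  for (seed in 1:6) {
    sim <- simulate_schema_graph(generator_config(seed = seed))
    fit <- phal(sim$graph)
    preds <- names(sim$graph$cp)
    # coverage before and after refinement
    expect_setequal(topic_membership(fit, initial = TRUE)$predicate, preds)
    expect_setequal(topic_membership(fit)$predicate, preds)
    # hard partition before refinement
    mem0 <- topic_membership(fit, initial = TRUE)
    expect_equal(anyDuplicated(mem0$predicate), 0L)
    # refinement only grows topics
    for (k in seq_along(fit$topics)) {
      expect_true(all(fit$topics_initial[[k]]$predicates %in%
                        fit$topics[[k]]$predicates))
    }
  }
})

test_that("the merge tree converts to a plottable dendrogram", {
  g <- toy_graph()
  hc <- stats::as.hclust(phal(g))
  expect_s3_class(hc, "hclust")
  expect_equal(length(hc$labels), 5L)
  expect_equal(nrow(hc$merge), 4L)
  expect_true(all(diff(hc$height) >= 0))
  expect_setequal(hc$order, 1:5)
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  plot(phal(g))
  grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("topic hierarchies serialize to JSON with full coverage", {
  g <- toy_graph()
  fit <- phal(g)
  f <- tempfile(fileext = ".json")
  write_topics_json(fit, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$height, fit$tree$height)
  got <- unique(unlist(lapply(parsed$topics, function(tp) unlist(tp$predicates))))
  expect_setequal(got, names(g$cp))
})
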