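test_that("hypergeometric tail matches brute-force enumeration", {
  # worked example: N=10, K=4, n=5, k=3 -> 66/252
  bg <- sprintf("g%02d", 1:10)
  term <- bg[1:4]
  query <- c(bg[1:3], bg[9:10])
  rec <- test_overrepresentation(query, term, bg)
  expect_equal(rec$k, 3)
  expect_equal(rec$p, 66 / 252, tolerance = 1e-12)
  expect_equal(rec$p, brute_hyper_tail(10, 4, 5, 3), tolerance = 1e-12)

  # random small configurations against the enumeration oracle
  set.seed(7)
  for (rep in 1:20) {
    N <- sample(5:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    bg <- sprintf("x%02d", 1:N)
    term <- sample(bg, K)
    query <- sample(bg, n)
    k <- length(intersect(query, term))
    rec <- test_overrepresentation(query, term, bg)
    expect_equal(rec$p, brute_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("degenerate hypergeometric cases follow the tail definition", {
  bg <- letters[1:10]
  expect_equal(test_overrepresentation(bg[5:9], bg[1:4], bg)$p, 1)  # k = 0
  rec <- test_overrepresentation(bg, bg[1:4], bg)  # query = background
  expect_equal(rec$k, rec$K)
  expect_equal(rec$p, 1)
  expect_error(test_overrepresentation(letters[1:2], letters[1:2],
                                       character(0)), "empty background")
  expect_error(test_overrepresentation(c("z", "a"), letters[1:3], letters[1:5]),
               "query must be a subset")
})

test_that("BH adjustment equals the hand-executed step-up", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(adjust_bh(p), hand_bh(p), tolerance = 1e-12)
  }
  p_raw <- runif(10)
  q_raw <- adjust_bh(p_raw)
  expect_true(all(diff(q_raw[order(p_raw)]) >= 0))  # monotone in sorted-p order
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("top-term extraction is per-ontology with deterministic ties", {
  recs <- data.frame(
    cluster = "c1",
    term = sprintf("T%02d", 1:8),
    ontology = c(rep("BP", 6), "CC", "CC"),
    k = c(5, 4, 3, 2, 2, 9, 1, 1),
    q = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.05, 0.2, 0.3))
  top <- suppressMessages(top_terms_per_cluster(recs, per_ontology = 5))
  bp <- top$term[top$ontology == "BP"]
  expect_length(bp, 5)
  # tie at rank 5 (q = 0.05): T06 wins on larger k over T05
  expect_true("T06" %in% bp && !("T05" %in% bp))
  expect_equal(top$term[top$ontology == "CC"], c("T07", "T08"))  # short list

  # repeated invocation is deterministic
  top2 <- suppressMessages(top_terms_per_cluster(recs, per_ontology = 5))
  expect_identical(top, top2)
})

test_that("full per-cluster extraction yields 5 KEGG + 15 GO terms", {
  co <- generate_cohort(cohort_config(seed = 21))
  ann <- generate_annotation(co$truth, n_background_terms = 60,
                             term_size_range = c(5, 30), seed = 22)
  clusters <- split(names(co$truth$protein_shapes), co$truth$protein_shapes)
  enr <- cluster_enrichment(clusters, ann,
                            background = names(co$truth$protein_shapes))
  one <- enr[enr$cluster == "monotone_up", ]
  top <- suppressMessages(top_terms_per_cluster(one))
  expect_lte(nrow(top), 20)
  counts <- table(top$ontology)
  expect_true(all(counts <= 5))
})

test_that("core and pivotal flags follow the cluster-count thresholds", {
  sets <- list(c1 = c("a", "b"), c2 = c("a", "c"), c3 = c("a", "b"),
               c4 = c("d"), c5 = c("a", "b"), c6 = c("a"))
  rep <- co_pathway_analysis(sets)
  a <- rep$terms[rep$terms$term == "a", ]
  expect_equal(a$n_clusters, 5)
  expect_true(a$core && a$pivotal)
  b <- rep$terms[rep$terms$term == "b", ]
  expect_equal(b$n_clusters, 3)
  expect_true(b$core)
  expect_false(b$pivotal)
  d <- rep$terms[rep$terms$term == "d", ]
  expect_false(d$core || d$pivotal)
  expect_true(all(rep$terms$core[rep$terms$pivotal]))  # pivotal => core
})

test_that("upset exclusive intersections partition the term union", {
  set.seed(9)
  terms <- sprintf("t%02d", 1:10)
  sets <- lapply(1:6, function(i) sample(terms, sample(3:8, 1)))
  names(sets) <- sprintf("c%d", 1:6)
  rep <- co_pathway_analysis(sets)
  expect_equal(sum(rep$upset$size), length(unique(unlist(sets))))
  # brute-force oracle: count terms per exact cluster signature
  sig <- vapply(sort(unique(unlist(sets))), function(t)
    paste(names(sets)[vapply(sets, function(s) t %in% s, logical(1))],
          collapse = ","), character(1))
  oracle <- table(sig)
  got <- stats::setNames(rep$upset$size, rep$upset$combination)
  expect_equal(got[names(oracle)], stats::setNames(as.integer(oracle),
                                                   names(oracle)))
})

test_that("co-pathway analysis is invariant to cluster order", {
  sets <- list(c1 = c("a", "b"), c2 = c("a", "c"), c3 = c("b", "c"),
               c4 = c("a"), c5 = c("c"), c6 = c("a", "b", "c"))
  r1 <- co_pathway_analysis(sets)
  r2 <- co_pathway_analysis(rev(sets))
  expect_equal(r1$terms$n_clusters[order(r1$terms$term)],
               r2$terms$n_clusters[order(r2$terms$term)])
  expect_equal(sort(r1$terms$term[r1$terms$core]),
               sort(r2$terms$term[r2$terms$core]))
})

test_that("bridge-cluster term sharing splits shared and exclusive sets", {
  expect_equal(shared_bridge_terms(c("x", "y"), c("x", "y")),
               list(shared = c("x", "y"), up_only = character(0),
                    down_only = character(0)))
  expect_equal(shared_bridge_terms("x", "y")$shared, character(0))
  co <- generate_cohort(cohort_config(seed = 31))
  ann <- generate_annotation(co$truth, n_background_terms = 10, seed = 32)
  # plant one term into both monotone shapes by union
  both <- unique(c(ann$members$PLANTED_MONOTONE_UP,
                   ann$members$PLANTED_MONOTONE_DOWN))
  ann$members$SHARED_BOTH <- both
  ann$ontology["SHARED_BOTH"] <- "BP"
  clusters <- split(names(co$truth$protein_shapes), co$truth$protein_shapes)
  enr <- cluster_enrichment(clusters, ann,
                            background = names(co$truth$protein_shapes))
  tops <- lapply(split(enr, enr$cluster),
                 function(d) suppressMessages(top_terms_per_cluster(d))$term)
  sh <- shared_bridge_terms(tops$monotone_up, tops$monotone_down)
  expect_true("SHARED_BOTH" %in% sh$shared)
})

test_that("planted terms attain the smallest q in their target cluster", {
  hits <- 0
  for (seed in 1:10) {
    co <- generate_cohort(cohort_config(seed = seed))
    ann <- generate_annotation(co$truth, n_background_terms = 30,
                               seed = seed + 100)
    query <- names(co$truth$protein_shapes)[
      co$truth$protein_shapes == "monotone_up"]
    enr <- cluster_enrichment(list(up = query), ann,
                              background = names(co$truth$protein_shapes))
    best <- enr$term[which.min(enr$q)]
    if (best == "PLANTED_MONOTONE_UP") hits <- hits + 1
  }
  expect_gte(hits, 10 * 0.95)
})
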