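test_that("stage profiles are per-stage arithmetic means in fixed order", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  st <- toy_study(mat, c("normal", "MCI", "AD"))
  prof <- compute_stage_profiles(st)
  expect_equal(colnames(prof), c("normal", "MCI", "AD"))
  expect_equal(unclass(prof)[, ], mat, ignore_attr = TRUE)

  # against an independent per-stage averaging oracle on a random matrix
  set.seed(1)
  m2 <- matrix(rnorm(60), 4, 15,
               dimnames = list(letters[1:4], sprintf("s%d", 1:15)))
  stages <- rep(c("normal", "MCI", "AD"), each = 5)
  st2 <- toy_study(m2, stages)
  prof2 <- compute_stage_profiles(st2)
  for (stg in c("normal", "MCI", "AD")) {
    oracle <- apply(m2[, stages == stg], 1, function(r) sum(r) / length(r))
    expect_equal(unname(prof2[, stg]), unname(oracle), tolerance = 1e-12)
  }

  expect_error(compute_stage_profiles(toy_study(m2[, 1:5], stages[1:5])),
               "empty stage: MCI")
})

test_that("standardization gives population z-scores and reports exclusions", {
  prof <- compute_stage_profiles(toy_study(
    matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
           dimnames = list(c("A", "B"), c("s1", "s2", "s3"))),
    c("normal", "MCI", "AD")))
  z <- standardize_profiles(prof)
  expect_equal(unname(z["A", ]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(attr(z, "excluded"), "B")
  expect_equal(rowMeans(z), c(A = 0), tolerance = 1e-9)
  expect_equal(sqrt(rowMeans(z^2)), c(A = 1), tolerance = 1e-9)
  expect_error(standardize_profiles(z), "already standardized")
})

test_that("fuzzifier heuristic matches its formula and behaves sanely", {
  expect_equal(estimate_fuzzifier(360, 3), 4.075909, tolerance = 1e-6)
  ns <- c(3, 10, 100, 1000, 1e6)
  ds <- c(1, 3, 10, 100)
  for (d in ds) {
    ms <- vapply(ns, estimate_fuzzifier, numeric(1), n_dims = d)
    expect_true(all(ms > 1))
    expect_true(all(diff(ms) < 0))  # decreasing in N at fixed D
  }
  expect_error(estimate_fuzzifier(2, 3), "n_features")
})

test_that("single-cluster fit is the identity solution", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  fit <- fit_fuzzy_cmeans(X, c = 1, m = 2, seed = 1)
  expect_equal(unname(fit$membership[, 1]), rep(1, 10))
  expect_equal(unname(fit$centroids[1, ]), unname(colMeans(X)),
               tolerance = 1e-9)
})

test_that("planted two-cluster structure is recovered exactly", {
  X <- rbind(matrix(rep(c(-1, 0, 1), each = 3), 3) + 0.05 * matrix(rnorm(9), 3),
             matrix(rep(c(1, 0, -1), each = 3), 3) + 0.05 * matrix(rnorm(9), 3))
  rownames(X) <- sprintf("p%d", 1:6)
  fit <- fit_fuzzy_cmeans(X, c = 2, m = 1.25, seed = 3)
  hard <- apply(fit$membership, 1, which.max)
  oracle <- best_two_partition(X)
  expect_equal(length(unique(paste(hard, oracle))), 2)  # same 2-partition
})

test_that("memberships are simplex-valued and the objective never increases", {
  co <- generate_cohort(cohort_config(seed = 5))
  z <- standardize_profiles(compute_stage_profiles(co$study))
  fit <- fit_fuzzy_cmeans(z, c = 6, m = "auto", seed = 2)
  expect_equal(unname(rowSums(fit$membership)), rep(1, nrow(z)),
               tolerance = 1e-9)
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
})

test_that("a point coincident with a centroid takes membership one", {
  X <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(5, 5, 5), c(5, 5, 4))
  fit <- fit_fuzzy_cmeans(X, c = 2, m = 2, seed = 4)
  u <- predict(fit, fit$centroids)
  expect_equal(unname(diag(u)), c(1, 1))
})

test_that("soft assignments agree with an independent fuzzy c-means fit", {
  skip_if_not_installed("e1071")
  co <- generate_cohort(cohort_config(
    n_per_shape = c(monotone_up = 20, monotone_down = 20, peak = 20),
    effect_delta = 1.5, noise_sd = 0.3, seed = 6))
  z <- standardize_profiles(compute_stage_profiles(co$study))
  fit <- fit_fuzzy_cmeans(z, c = 3, m = 2, tol = 1e-9, seed = 2)
  ref <- e1071::cmeans(unclass(z), centers = fit$centroids, m = 2,
                       iter.max = 500)
  expect_equal(unname(fit$membership), unname(ref$membership),
               tolerance = 1e-4)
  expect_equal(unname(fit$centroids), unname(ref$centers), tolerance = 1e-4)
})

test_that("near-hard fuzzifier reproduces the exhaustive k-means partition", {
  X <- rbind(matrix(rep(c(-1.2, 0, 1.2), each = 3), 3) + 0.02 * matrix(rnorm(9), 3),
             matrix(rep(c(1.2, 0, -1.2), each = 3), 3) + 0.02 * matrix(rnorm(9), 3))
  rownames(X) <- sprintf("p%d", 1:6)
  fit <- fit_fuzzy_cmeans(X, c = 2, m = 1.05, seed = 5)
  hard <- apply(fit$membership, 1, which.max)
  expect_equal(length(unique(paste(hard, best_two_partition(X)))), 2)
  expect_gt(min(apply(fit$membership, 1, max)), 0.99)
})

test_that("trajectory classification covers all sign patterns", {
  eps <- 0.05
  expect_equal(classify_trajectory(c(-1, 0, 1)), "monotone_up")
  expect_equal(classify_trajectory(c(0, 0, 0)), "flat")
  cases <- expand.grid(d1 = c(-1, 0, 1), d2 = c(-1, 0, 1))
  for (i in seq_len(nrow(cases))) {
    d1 <- cases$d1[i]; d2 <- cases$d2[i]
    lab <- classify_trajectory(c(0, d1, d1 + d2), eps)
    want <- if (d1 > eps && d2 > eps) "monotone_up"
      else if (d1 < -eps && d2 < -eps) "monotone_down"
      else if (d1 < -eps && d2 > eps) "valley"
      else if (d1 > eps && d2 < -eps) "peak" else "flat"
    expect_equal(lab, want, info = sprintf("d1=%g d2=%g", d1, d2))
  }
  # scale invariance of monotone labels on standardized centroids
  expect_equal(classify_trajectory(3 * c(-1, 0, 1)), "monotone_up")
  expect_equal(classify_trajectory(0.2 * c(1, 0, -1)), "monotone_down")
})

test_that("bridge clusters are the monotone centroids, proteins by argmax", {
  cen <- rbind(c(-1, 0, 1), c(1, 0, -1), c(0, 1, 0))
  U <- rbind(c(0.8, 0.1, 0.1), c(0.2, 0.7, 0.1), c(0.1, 0.2, 0.7),
             c(0.6, 0.3, 0.1))
  rownames(U) <- sprintf("P%d", 1:4)
  model <- structure(list(centroids = cen, membership = U, c = 3, m = 2),
                     class = "fcm_fit")
  det <- detect_bridge_clusters(model)
  expect_equal(det$bridge_clusters, c(1, 2))
  expect_equal(det$bridge_proteins,
               list(cluster_1 = c("P1", "P4"), cluster_2 = "P2"))
  expect_length(det$ties, 0)

  # min-membership filter off by default, applied when requested
  det2 <- detect_bridge_clusters(model, min_membership = 0.7)
  expect_equal(det2$bridge_proteins$cluster_1, "P1")
})

test_that("an all-flat noiseless cohort has no clusterable structure", {
  co <- generate_cohort(cohort_config(n_per_shape = c(flat = 40),
                                      noise_sd = 0, seed = 8))
  z <- standardize_profiles(compute_stage_profiles(co$study))
  expect_equal(nrow(z), 0)                 # all zero-variance, all excluded
  expect_length(attr(z, "excluded"), 40)
  # and a model whose centroids are all flat has zero bridge clusters
  model <- structure(list(centroids = rbind(c(0, 0.01, 0), c(0.02, 0, 0.01)),
                          membership = matrix(0.5, 4, 2,
                                              dimnames = list(sprintf("P%d", 1:4),
                                                              NULL)),
                          c = 2, m = 2), class = "fcm_fit")
  expect_length(detect_bridge_clusters(model)$bridge_clusters, 0)
})

test_that("sample K-means separates stages on strong bridge signal", {
  co <- generate_cohort(cohort_config(effect_delta = 2, noise_sd = 0.2,
                                      seed = 9))
  z <- standardize_profiles(compute_stage_profiles(co$study))
  fit <- fit_fuzzy_cmeans(z, c = 6, m = "auto", seed = 2)
  det <- detect_bridge_clusters(fit)
  bridge <- unlist(det$bridge_proteins, use.names = FALSE)
  sk <- cluster_samples_kmeans(co$study, bridge, k = 3, seed = 3, model = fit)
  cl <- sk$sample_clusters
  stages <- co$study$stages[names(cl)]
  expect_false(any(cl[stages == "AD"] %in% cl[stages == "normal"]))
  # membership-sorted protein order is a permutation of the bridge set,
  # in descending order of each protein's membership in its own cluster
  expect_setequal(sk$protein_order, bridge)
  U <- fit$membership[sk$protein_order, , drop = FALSE]
  own <- U[cbind(seq_len(nrow(U)), apply(U, 1, which.max))]
  expect_true(all(diff(own) <= 1e-12))
})

test_that("degenerate sample K-means settings behave as specified", {
  co <- generate_cohort(cohort_config(
    n_per_shape = c(monotone_up = 10), stage_sizes = c(2, 2, 2), seed = 10))
  prot <- rownames(co$study$matrix)
  sk <- cluster_samples_kmeans(co$study, prot, k = 6, seed = 1)
  expect_equal(sort(unname(sk$sample_clusters)), 1:6)  # one sample per cluster
  expect_equal(sk$kmeans$tot.withinss, 0)
  expect_error(cluster_samples_kmeans(co$study, prot, k = 7, seed = 1),
               "exceeds")
  expect_error(cluster_samples_kmeans(co$study, character(0), k = 2),
               "non-empty")
})

test_that("hard assignments are invariant to protein input order", {
  co <- generate_cohort(cohort_config(effect_delta = 1.5, noise_sd = 0.3,
                                      seed = 12))
  z <- standardize_profiles(compute_stage_profiles(co$study))
  fit1 <- fit_fuzzy_cmeans(z, c = 6, m = "auto", seed = 4)
  perm <- sample(nrow(z))
  fit2 <- fit_fuzzy_cmeans(z[perm, ], c = 6, m = "auto", seed = 4)
  part1 <- apply(fit1$membership, 1, which.max)
  part2 <- apply(fit2$membership, 1, which.max)[rownames(z)]
  # same partition up to cluster relabelling
  tab <- table(part1, part2)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})
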