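# Stage profiles, fuzzy c-means soft clustering, trajectory labelling and
# bridge-cluster detection.

#' Per-stage mean expression profiles
#'
#' Arithmetic mean of log2 values per (protein, stage), stage order fixed as
#' (normal, MCI, AD). Missing values are dropped per protein and stage.
#'
#' @param study an `expression_study`.
#' @return numeric matrix proteins x 3 with class attribute
#'   `stage_profiles` and attribute `standardized = FALSE`.
#' @export
compute_stage_profiles <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  for (st in STAGES) {
    if (!any(study$stages == st)) stop("empty stage: ", st)
  }
  prof <- sapply(STAGES, function(st) {
    cols <- names(study$stages)[study$stages == st]
    rowMeans(study$matrix[, cols, drop = FALSE], na.rm = TRUE)
  })
  prof <- matrix(prof, ncol = 3,
                 dimnames = list(rownames(study$matrix), STAGES))
  structure(prof, class = c("stage_profiles", "matrix"),
            standardized = FALSE, excluded = character(0))
}

#' Standardize stage profiles per protein
#'
#' Subtracts each protein's triple mean and divides by the population SD
#' (denominator n) of the triple, so retained rows have mean 0 and
#' population SD 1. Zero-variance proteins cannot be standardized; they are
#' excluded and listed in the `excluded` attribute.
#'
#' @param profiles unstandardized `stage_profiles`.
#' @return standardized `stage_profiles` (possibly fewer rows), with
#'   attributes `standardized = TRUE` and `excluded`.
#' @export
standardize_profiles <- function(profiles) {
  if (isTRUE(attr(profiles, "standardized")))
    stop("profiles are already standardized")
  m <- rowMeans(profiles)
  centered <- profiles - m
  psd <- sqrt(rowMeans(centered^2))
  keep <- psd > 0 & !is.na(psd)
  z <- centered[keep, , drop = FALSE] / psd[keep]
  structure(z, class = c("stage_profiles", "matrix"), standardized = TRUE,
            excluded = rownames(profiles)[!keep])
}

#' Fuzzifier heuristic for fuzzy c-means
#'
#' Feature-dimension heuristic used by soft-clustering reference
#' implementations for expression profiles:
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`
#' with `N` features (proteins) and `D` dimensions (stages). Always > 1.
#'
#' @param n_features number of profiles (>= 3).
#' @param n_dims profile dimensionality (>= 1).
#' @return the fuzzifier m.
#' @export
estimate_fuzzifier <- function(n_features, n_dims) {
  if (n_features < 3 || n_dims < 1)
    stop("need n_features >= 3 and n_dims >= 1")
  N <- n_features; D <- n_dims
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fit fuzzy c-means on standardized stage profiles
#'
#' Minimizes `J = sum_i sum_k u_ik^m ||x_i - c_k||^2` by the standard
#' alternating updates: memberships
#' `u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))` and centroids
#' `c_k = sum_i u_ik^m x_i / sum_i u_ik^m`. Centroids are initialized by
#' seeded sampling of `c` distinct data points. Convergence when the largest
#' membership change falls below `tol`. A point coincident with a centroid
#' receives membership 1 there and 0 elsewhere.
#'
#' @param profiles standardized `stage_profiles` (or any numeric matrix).
#' @param c number of clusters (default 6, the trajectory archetype count
#'   observed in three-stage cognitive-decline proteomes).
#' @param m fuzzifier > 1, or `"auto"` for [estimate_fuzzifier()].
#' @param tol convergence tolerance on max |delta U| (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @param seed integer seed for centroid initialization.
#' @return object of class `fcm_fit`: `centroids` (c x D), `membership`
#'   (N x c, rows sum to 1), `objective`, `objective_trace`, `iterations`,
#'   `c`, `m`, `seed`.
#' @export
fit_fuzzy_cmeans <- function(profiles, c = 6, m = "auto", tol = 1e-6,
                             max_iter = 1000, seed = 1L) {
  X <- unclass(profiles)
  attr(X, "standardized") <- NULL; attr(X, "excluded") <- NULL
  X <- as.matrix(X)
  N <- nrow(X)
  if (c < 1) stop("c must be >= 1")
  if (c > N) stop("c = ", c, " exceeds the ", N, " retained proteins")
  if (identical(m, "auto")) m <- estimate_fuzzifier(N, ncol(X))
  if (!is.numeric(m) || m <= 1) stop("fuzzifier m must be > 1")

  set.seed(seed)
  # sample c data points with distinct coordinates as initial centroids;
  # sampling happens in a canonical (value-sorted) row order so the fit is
  # invariant to the input order of the proteins
  canon <- do.call(order, as.data.frame(X))
  idx <- canon[sample.int(N, c)]
  tries <- 0
  while (anyDuplicated(X[idx, , drop = FALSE]) && tries < 100) {
    idx <- canon[sample.int(N, c)]
    tries <- tries + 1
  }
  centroids <- X[idx, , drop = FALSE]

  memberships_for <- function(cen) {
    d2 <- outer(rowSums(X^2), rep(1, nrow(cen))) +
      outer(rep(1, N), rowSums(cen^2)) - 2 * X %*% t(cen)
    d2[d2 < 0] <- 0
    u <- matrix(0, N, nrow(cen))
    zero <- d2 <= .Machine$double.eps
    has_zero <- rowSums(zero) > 0
    w <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
    u[!has_zero, ] <- w / rowSums(w)
    if (any(has_zero)) {
      hz <- which(has_zero)
      u[hz, ] <- 0
      first_zero <- apply(zero[hz, , drop = FALSE], 1, which.max)
      u[cbind(hz, first_zero)] <- 1
    }
    list(u = u, d2 = d2)
  }

  U <- NULL
  trace <- numeric(0)
  iter <- 0
  repeat {
    iter <- iter + 1
    upd <- memberships_for(centroids)
    U_new <- upd$u
    um <- U_new^m
    centroids <- t(um) %*% X / colSums(um)
    d2 <- outer(rowSums(X^2), rep(1, c)) + outer(rep(1, N), rowSums(centroids^2)) -
      2 * X %*% t(centroids)
    d2[d2 < 0] <- 0
    trace <- c(trace, sum(um * d2))
    delta <- if (is.null(U)) Inf else max(abs(U_new - U))
    U <- U_new
    if (delta < tol || iter >= max_iter) break
  }
  dimnames(U) <- list(rownames(X), sprintf("cluster_%d", seq_len(c)))
  dimnames(centroids) <- list(sprintf("cluster_%d", seq_len(c)), colnames(X))
  structure(list(centroids = centroids, membership = U,
                 objective = trace[length(trace)], objective_trace = trace,
                 iterations = iter, c = c, m = m, seed = as.integer(seed)),
            class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Fuzzy c-means fit:", nrow(x$membership), "profiles,", x$c,
      "clusters, m =", format(x$m, digits = 4), "\n")
  cat("converged after", x$iterations, "iterations, J =",
      format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.fcm_fit <- function(object, epsilon = 0.05, ...) {
  lab <- classify_trajectory(object$centroids, epsilon)
  hard <- apply(object$membership, 1, which.max)
  lab$n_proteins <- as.integer(table(factor(hard, seq_len(object$c))))
  cat("Fuzzy c-means,", object$c, "clusters over", nrow(object$membership),
      "profiles (m =", format(object$m, digits = 4), ")\n\n")
  print(lab, row.names = FALSE)
  invisible(lab)
}

#' @export
coef.fcm_fit <- function(object, ...) object$centroids

#' @export
fitted.fcm_fit <- function(object, ...) {
  hard <- apply(object$membership, 1, which.max)
  out <- object$centroids[hard, , drop = FALSE]
  rownames(out) <- rownames(object$membership)
  out
}

#' Membership of new profiles under a fitted model
#'
#' @param object an `fcm_fit`.
#' @param newdata numeric matrix with the same dimensionality as the fit.
#' @param ... unused.
#' @return membership matrix, rows summing to 1.
#' @export
predict.fcm_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  cen <- object$centroids
  m <- object$m
  d2 <- outer(rowSums(X^2), rep(1, nrow(cen))) +
    outer(rep(1, nrow(X)), rowSums(cen^2)) - 2 * X %*% t(cen)
  d2[d2 < 0] <- 0
  u <- matrix(0, nrow(X), nrow(cen), dimnames = list(rownames(X), rownames(cen)))
  zero <- d2 <= .Machine$double.eps
  has_zero <- rowSums(zero) > 0
  w <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
  u[!has_zero, ] <- w / rowSums(w)
  if (any(has_zero)) {
    hz <- which(has_zero)
    first_zero <- apply(zero[hz, , drop = FALSE], 1, which.max)
    u[cbind(hz, first_zero)] <- 1
  }
  u
}

#' Classify a centroid trajectory over (normal, MCI, AD)
#'
#' With step deltas `d1 = MCI - normal` and `d2 = AD - MCI`:
#' `monotone_up` if both exceed `epsilon`, `monotone_down` if both are below
#' `-epsilon`, `valley` if falling then rising, `peak` if rising then
#' falling, `flat` otherwise. With only three points, the tolerance keeps
#' numerical noise from being labelled monotone.
#'
#' @param centroid ordered triple, or a matrix of row triples.
#' @param epsilon monotonicity tolerance in standardized units (default 0.05).
#' @return for one triple, a character label; for a matrix, a data.frame
#'   with `cluster`, `delta1`, `delta2`, `label`.
#' @export
classify_trajectory <- function(centroid, epsilon = 0.05) {
  if (is.matrix(centroid)) {
    d1 <- centroid[, 2] - centroid[, 1]
    d2 <- centroid[, 3] - centroid[, 2]
    lab <- ifelse(d1 > epsilon & d2 > epsilon, "monotone_up",
           ifelse(d1 < -epsilon & d2 < -epsilon, "monotone_down",
           ifelse(d1 < -epsilon & d2 > epsilon, "valley",
           ifelse(d1 > epsilon & d2 < -epsilon, "peak", "flat"))))
    return(data.frame(cluster = seq_len(nrow(centroid)), delta1 = d1,
                      delta2 = d2, label = lab, row.names = NULL))
  }
  classify_trajectory(matrix(centroid, nrow = 1), epsilon)$label
}

#' Detect bridge clusters and bridge proteins
#'
#' Bridge clusters are exactly the clusters whose centroid trajectory is
#' monotone (up or down). Bridge proteins are the proteins hard-assigned
#' (argmax membership) to a bridge cluster; argmax ties are broken by lowest
#' cluster index and the tied proteins reported. An optional minimum
#' membership cutoff is available but off by default, since every cluster
#' protein counts as a bridge protein.
#'
#' @param model an `fcm_fit`.
#' @param epsilon monotonicity tolerance (default 0.05).
#' @param min_membership optional cutoff in `[0, 1]`; proteins whose maximal
#'   membership falls below it are not called.
#' @return list: `bridge_clusters` (integer ids), `labels` (per-cluster
#'   trajectory labels), `bridge_proteins` (named list per bridge cluster),
#'   `assignments` (hard cluster per protein), `ties` (proteins with tied
#'   argmax).
#' @export
detect_bridge_clusters <- function(model, epsilon = 0.05, min_membership = NULL) {
  stopifnot(inherits(model, "fcm_fit"))
  lab <- classify_trajectory(model$centroids, epsilon)
  bridge <- lab$cluster[lab$label %in% c("monotone_up", "monotone_down")]
  U <- model$membership
  hard <- apply(U, 1, which.max)  # which.max takes the lowest index on ties
  maxu <- U[cbind(seq_len(nrow(U)), hard)]
  ties <- rownames(U)[apply(U, 1, function(r) sum(r == max(r)) > 1)]
  called <- if (is.null(min_membership)) rep(TRUE, nrow(U)) else maxu >= min_membership
  bridge_proteins <- lapply(bridge, function(k) {
    rownames(U)[hard == k & called]
  })
  names(bridge_proteins) <- sprintf("cluster_%d", bridge)
  list(bridge_clusters = bridge, labels = lab,
       bridge_proteins = bridge_proteins,
       assignments = stats::setNames(hard, rownames(U)), ties = ties)
}

#' K-means clustering of samples on bridge-protein profiles
#'
#' Lloyd's K-means (Euclidean) on sample vectors restricted to the given
#' bridge proteins, with seeded initialization by sampling `k` distinct
#' sample profiles. Default `k = 3`, splitting samples into groups that
#' separate declining from normal cognition when the bridge signal is
#' strong. When the fitted soft-clustering model is supplied, bridge
#' proteins are also returned sorted by descending membership in their own
#' cluster (the heatmap row ordering).
#'
#' @param study an `expression_study`.
#' @param bridge_proteins character vector of protein ids.
#' @param k number of sample clusters (default 3).
#' @param seed integer seed.
#' @param model optional `fcm_fit` for membership-sorted protein order.
#' @return list: `sample_clusters` (named integer vector), `kmeans` (the
#'   `stats::kmeans` fit), `protein_order`.
#' @export
cluster_samples_kmeans <- function(study, bridge_proteins, k = 3, seed = 1L,
                                   model = NULL) {
  stopifnot(inherits(study, "expression_study"))
  if (length(bridge_proteins) == 0) stop("bridge_proteins must be non-empty")
  S <- t(study$matrix[bridge_proteins, , drop = FALSE])
  if (k > nrow(S)) stop("k = ", k, " exceeds the ", nrow(S), " samples")
  set.seed(seed)
  km <- NULL
  # Lloyd iterations can empty a cluster under an unlucky seeded start;
  # retry with freshly sampled distinct sample profiles (seeded sequence,
  # so the whole procedure stays deterministic)
  for (attempt in 1:25) {
    centers <- S[sample.int(nrow(S), k), , drop = FALSE]
    if (anyDuplicated(centers)) next
    emptied <- FALSE
    km <- withCallingHandlers(
      stats::kmeans(S, centers = centers, algorithm = "Lloyd", iter.max = 100),
      warning = function(w) {
        if (grepl("empty cluster", conditionMessage(w))) {
          emptied <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (!emptied) break
  }
  if (is.null(km)) stop("could not find k distinct sample profiles")
  protein_order <- bridge_proteins
  if (!is.null(model)) {
    U <- model$membership[bridge_proteins, , drop = FALSE]
    hard <- apply(U, 1, which.max)
    own <- U[cbind(seq_len(nrow(U)), hard)]
    protein_order <- bridge_proteins[order(-own)]
  }
  list(sample_clusters = stats::setNames(km$cluster, rownames(S)), kmeans = km,
       protein_order = protein_order)
}
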