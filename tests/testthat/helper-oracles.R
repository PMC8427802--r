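# Independent oracles used across test files. Deliberately brute-force and
# slow: they must not share code paths with the implementation.

# Exact hypergeometric upper tail by enumerating every n-draw from a
# background of size N containing K marked elements (feasible for N <= 12).
brute_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  sum(hits >= k) / ncol(draws)
}

# Hand-executed BH step-up: q_(i) = min_{j>=i} p_(j) * m / j, capped at 1.
hand_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Best hard 2-partition of points by exhaustive assignment enumeration
# (minimum total within-cluster squared distance to the cluster means).
best_two_partition <- function(X) {
  n <- nrow(X)
  best <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {   # up to symmetry, cluster of point 1 fixed
    grp <- c(0, as.integer(intToBits(mask))[seq_len(n - 1)])
    if (length(unique(grp)) < 2) next
    ss <- 0
    for (g in unique(grp)) {
      pts <- X[grp == g, , drop = FALSE]
      ctr <- colMeans(pts)
      ss <- ss + sum(sweep(pts, 2, ctr)^2)
    }
    if (is.null(best) || ss < best$ss) best <- list(ss = ss, grp = grp)
  }
  best$grp
}

# Brute-force betweenness by enumerating every simple path between every
# node pair and keeping the shortest ones. adj: logical adjacency matrix.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_simple_paths <- function(s, t) {
    res <- list()
    dfs <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1L]] <<- path
        return()
      }
      for (w in which(adj[v, ])) if (!(w %in% path)) dfs(c(path, w))
    }
    dfs(s)
    res
  }
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    paths <- all_simple_paths(s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    for (p in shortest) {
      interior <- p[-c(1, length(p))]
      btw[interior] <- btw[interior] + 1 / sigma
    }
  }
  btw
}

# Random connected-ish undirected graph as an edge data.frame.
random_graph_edges <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  data.frame(protein1 = pairs[1, keep], protein2 = pairs[2, keep],
             combined_score = rep(900L, sum(keep)), stringsAsFactors = FALSE)
}

# Small three-stage study built directly from a matrix.
toy_study <- function(mat, stages) {
  structure(list(matrix = mat,
                 stages = stats::setNames(stages, colnames(mat))),
            class = "expression_study")
}
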