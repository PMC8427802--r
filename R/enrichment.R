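# Hypergeometric over-representation per cluster, BH adjustment, top-term
# extraction and core/pivotal co-regulation logic.

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`
#' where `N` is the background size, `K` the term size in the background,
#' `n` the query size and `k` the query/term overlap. The tail is an exact
#' sum over the hypergeometric mass.
#'
#' @param query protein set of interest (e.g. one cluster's proteins).
#' @param term annotation set, must be a subset of the background.
#' @param background universe of identifiable proteins.
#' @return one-row data.frame: `k`, `n`, `K`, `N`, `p`, `hits`
#'   (comma-separated overlap).
#' @export
test_overrepresentation <- function(query, term, background) {
  if (length(background) == 0) stop("empty background")
  background <- unique(background)
  query <- unique(query); term <- unique(term)
  if (!all(term %in% background)) stop("term must be a subset of the background")
  if (!all(query %in% background)) stop("query must be a subset of the background")
  k <- length(intersect(query, term))
  n <- length(query); K <- length(term); N <- length(background)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, n = n, K = K, N = N, p = p,
             hits = paste(sort(intersect(query, term)), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1 and mapped back to input
#' order.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values in input order.
#' @export
adjust_bh <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment of every annotation term in every cluster
#'
#' Runs [test_overrepresentation()] for each (cluster, term) pair, with BH
#' adjustment applied within each (cluster, ontology) stratum by default
#' (mirroring per-ontology top-term extraction) or globally per cluster.
#' Terms outside `[min_term_size, max_term_size]` within the background are
#' skipped to avoid degenerate tests.
#'
#' @param clusters named list of protein sets (one per cluster).
#' @param annotation an `annotation_sets`.
#' @param background protein universe; defaults to the union of cluster
#'   members (the identified proteome).
#' @param min_term_size,max_term_size term-size window (defaults 3 and 500).
#' @param bh_scope `"per_ontology"` (default) or `"global"`.
#' @return data.frame of `EnrichmentRecord`s: `cluster`, `term`, `ontology`,
#'   `k`, `n`, `K`, `N`, `p`, `q`, `hits`.
#' @export
cluster_enrichment <- function(clusters, annotation, background = NULL,
                               min_term_size = 3, max_term_size = 500,
                               bh_scope = c("per_ontology", "global")) {
  bh_scope <- match.arg(bh_scope)
  if (is.null(background)) background <- unique(unlist(clusters))
  rows <- list()
  for (cl in names(clusters)) {
    query <- intersect(clusters[[cl]], background)
    for (term in names(annotation$members)) {
      mem <- intersect(annotation$members[[term]], background)
      if (length(mem) < min_term_size || length(mem) > max_term_size) next
      rec <- test_overrepresentation(query, mem, background)
      rec$cluster <- cl; rec$term <- term
      rec$ontology <- annotation$ontology[[term]]
      rows[[length(rows) + 1L]] <- rec
    }
  }
  if (length(rows) == 0)
    return(data.frame(cluster = character(0), term = character(0),
                      ontology = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), hits = character(0)))
  df <- do.call(rbind, rows)
  strata <- if (bh_scope == "per_ontology")
    interaction(df$cluster, df$ontology, drop = TRUE) else factor(df$cluster)
  df$q <- NA_real_
  for (s in levels(strata)) {
    i <- strata == s
    df$q[i] <- adjust_bh(df$p[i])
  }
  df[, c("cluster", "term", "ontology", "k", "n", "K", "N", "p", "q", "hits")]
}

#' Top enriched terms per ontology for one cluster
#'
#' Per ontology (BP, CC, MF, KEGG), the `per_ontology` terms with the
#' smallest q-value; ties in q are broken by larger overlap `k`, then
#' lexicographic term id (and reported via a message when invoked). The
#' union per cluster has up to `4 * per_ontology` terms.
#'
#' @param cluster_records enrichment rows for a single cluster.
#' @param per_ontology terms kept per ontology (default 5).
#' @return data.frame of the selected rows, ranked within ontology.
#' @export
top_terms_per_cluster <- function(cluster_records, per_ontology = 5) {
  stopifnot(length(unique(cluster_records$cluster)) <= 1)
  out <- list()
  for (onto in intersect(c("BP", "CC", "MF", "KEGG"),
                         unique(cluster_records$ontology))) {
    sub <- cluster_records[cluster_records$ontology == onto, , drop = FALSE]
    ord <- order(sub$q, -sub$k, sub$term)
    keep <- head(ord, per_ontology)
    boundary <- per_ontology
    if (nrow(sub) > boundary &&
        isTRUE(sub$q[ord[boundary]] == sub$q[ord[boundary + 1]]))
      message("tie at rank ", boundary, " in ontology ", onto,
              " broken by (k, term id)")
    out[[onto]] <- sub[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Core/pivotal co-pathway analysis across cluster top-term lists
#'
#' Maps every term to the set of clusters whose top-term lists contain it.
#' Terms in at least 3 lists are core pathways; terms in at least 5 are
#' pivotal (pivotal implies core). Also emits all exclusive upset
#' intersection sizes (terms whose cluster set equals each non-empty cluster
#' combination exactly).
#'
#' @param per_cluster_top_terms named list of character term vectors, one per
#'   cluster.
#' @param core_min,pivotal_min membership thresholds (defaults 3 and 5).
#' @return list of class `co_pathway_report`: `terms` (data.frame `term`,
#'   `n_clusters`, `clusters`, `core`, `pivotal`) and `upset` (data.frame
#'   `combination`, `degree`, `size` over non-empty exclusive combinations).
#' @export
co_pathway_analysis <- function(per_cluster_top_terms, core_min = 3,
                                pivotal_min = 5) {
  cl_names <- names(per_cluster_top_terms)
  if (is.null(cl_names)) cl_names <- sprintf("cluster_%d",
                                             seq_along(per_cluster_top_terms))
  all_terms <- sort(unique(unlist(per_cluster_top_terms)))
  if (length(all_terms) == 0) {
    return(structure(list(
      terms = data.frame(term = character(0), n_clusters = integer(0),
                         clusters = character(0), core = logical(0),
                         pivotal = logical(0)),
      upset = data.frame(combination = character(0), degree = integer(0),
                         size = integer(0))), class = "co_pathway_report"))
  }
  in_cluster <- vapply(per_cluster_top_terms, function(s) all_terms %in% s,
                       logical(length(all_terms)))
  in_cluster <- matrix(in_cluster, nrow = length(all_terms),
                       dimnames = list(all_terms, cl_names))
  n_cl <- rowSums(in_cluster)
  terms <- data.frame(
    term = all_terms, n_clusters = n_cl,
    clusters = apply(in_cluster, 1, function(r) paste(cl_names[r], collapse = ",")),
    core = n_cl >= core_min, pivotal = n_cl >= pivotal_min,
    row.names = NULL, stringsAsFactors = FALSE)

  sig <- apply(in_cluster, 1, function(r) paste(cl_names[r], collapse = ","))
  tab <- table(sig)
  upset <- data.frame(combination = names(tab),
                      degree = vapply(strsplit(names(tab), ","), length,
                                      integer(1)),
                      size = as.integer(tab), row.names = NULL,
                      stringsAsFactors = FALSE)
  upset <- upset[order(-upset$degree, upset$combination), , drop = FALSE]
  rownames(upset) <- NULL
  structure(list(terms = terms, upset = upset), class = "co_pathway_report")
}

#' @export
print.co_pathway_report <- function(x, ...) {
  cat("co-pathway report:", nrow(x$terms), "terms;",
      sum(x$terms$core), "core (>=3 clusters),",
      sum(x$terms$pivotal), "pivotal (>=5 clusters)\n")
  invisible(x)
}

#' Terms shared between the two bridge clusters
#'
#' Splits the top-term lists of the rising and falling bridge clusters into
#' the shared set and the two exclusive sets (chord-diagram data).
#'
#' @param top_terms_up,top_terms_down character term vectors.
#' @return list `shared`, `up_only`, `down_only`.
#' @export
shared_bridge_terms <- function(top_terms_up, top_terms_down) {
  list(shared = sort(intersect(top_terms_up, top_terms_down)),
       up_only = sort(setdiff(top_terms_up, top_terms_down)),
       down_only = sort(setdiff(top_terms_down, top_terms_up)))
}
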