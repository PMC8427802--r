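# End-to-end orchestration: profiles -> soft clustering -> bridge clusters ->
# enrichment -> differential expression -> key proteins -> sample K-means ->
# network centralities, with optional ELISA calibration.

# Per-stage seeds are derived deterministically from the global seed by
# hashing the stage name, so stages are isolated without seed collisions.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full marker-discovery pipeline
#'
#' Executes: stage profiles, per-protein standardization, fuzzy c-means
#' (default 6 clusters), trajectory labelling, bridge-cluster detection,
#' per-cluster enrichment with core/pivotal pathway logic, the three
#' pairwise differential-expression calls, key-protein intersection, sample
#' K-means on bridge proteins (default k = 3), interaction-network
#' centralities with the key-protein connecting paths, and optional ELISA
#' calibration. Identical configuration and seed reproduce identical
#' outputs.
#'
#' @param study an `expression_study`.
#' @param annotation optional `annotation_sets` for enrichment.
#' @param edges optional interaction edge list (data.frame).
#' @param plates optional named list of `plate_data` (must include `CD81`
#'   for normalized comparisons; other entries are treated as markers).
#' @param out_dir optional directory for report tables.
#' @param clusters number of soft clusters (default 6).
#' @param fuzzifier `"auto"` (default) or a numeric m > 1.
#' @param epsilon monotonicity tolerance (default 0.05).
#' @param kmeans_k sample clusters (default 3).
#' @param p_thresh,lfc_thresh DEP thresholds (defaults 0.05 and 0.5).
#' @param score_threshold edge-score gate when `edges` carries raw scores
#'   (default 400); applied only by the file reader, not here.
#' @param tol,max_iter fuzzy c-means convergence controls.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return object of class `exo_pipeline` with elements `profiles`, `model`,
#'   `bridge`, `cluster_table`, `centroid_table`, `sample_clusters`,
#'   `enrichment`, `top_terms`, `co_pathways`, `shared_terms`, `deps`,
#'   `dep_sets`, `key_proteins`, `graph`, `centralities`, `key_paths`,
#'   `calibration`, `summary`, and a `manifest` when `out_dir` is given.
#' @export
run_full_pipeline <- function(study, annotation = NULL, edges = NULL,
                              plates = NULL, out_dir = NULL,
                              clusters = 6, fuzzifier = "auto", epsilon = 0.05,
                              kmeans_k = 3, p_thresh = 0.05, lfc_thresh = 0.5,
                              score_threshold = 400, tol = 1e-6,
                              max_iter = 1000, seed = 1L) {
  stopifnot(inherits(study, "expression_study"))
  res <- list()

  profiles <- compute_stage_profiles(study)
  z <- standardize_profiles(profiles)
  model <- fit_fuzzy_cmeans(z, c = clusters, m = fuzzifier, tol = tol,
                            max_iter = max_iter,
                            seed = stage_seed(seed, "fcm"))
  bridge <- detect_bridge_clusters(model, epsilon)
  res$profiles <- profiles
  res$model <- model
  res$bridge <- bridge

  hard <- bridge$assignments
  res$cluster_table <- data.frame(
    protein = names(hard), cluster = unname(hard),
    label = bridge$labels$label[unname(hard)],
    bridge = unname(hard) %in% bridge$bridge_clusters,
    membership = round(model$membership[cbind(seq_along(hard), hard)], 6),
    stringsAsFactors = FALSE)
  res$centroid_table <- data.frame(cluster = seq_len(model$c),
                                   model$centroids, bridge$labels[, c("delta1",
                                   "delta2", "label")], row.names = NULL)

  all_bridge <- unlist(bridge$bridge_proteins, use.names = FALSE)
  if (length(all_bridge) >= kmeans_k) {
    sk <- cluster_samples_kmeans(study, all_bridge, k = kmeans_k,
                                 seed = stage_seed(seed, "kmeans"),
                                 model = model)
    res$sample_clusters <- data.frame(sample = names(sk$sample_clusters),
                                      stage = unname(study$stages[names(sk$sample_clusters)]),
                                      cluster = unname(sk$sample_clusters),
                                      stringsAsFactors = FALSE)
    res$protein_order <- sk$protein_order
  } else {
    res$sample_clusters <- data.frame(sample = character(0),
                                      stage = character(0),
                                      cluster = integer(0))
  }

  cluster_sets <- split(names(hard), unname(hard))
  names(cluster_sets) <- sprintf("cluster_%s", names(cluster_sets))
  if (!is.null(annotation)) {
    enr <- cluster_enrichment(cluster_sets, annotation,
                              background = rownames(study$matrix))
    res$enrichment <- enr
    tops <- lapply(split(enr, enr$cluster), top_terms_per_cluster)
    res$top_terms <- lapply(tops, function(d) d$term)
    res$co_pathways <- co_pathway_analysis(res$top_terms)
    bl <- bridge$labels
    up_cl <- sprintf("cluster_%d", bl$cluster[bl$label == "monotone_up"])
    dn_cl <- sprintf("cluster_%d", bl$cluster[bl$label == "monotone_down"])
    res$shared_terms <- shared_bridge_terms(
      unlist(res$top_terms[intersect(up_cl, names(res$top_terms))]),
      unlist(res$top_terms[intersect(dn_cl, names(res$top_terms))]))
  } else {
    res$enrichment <- data.frame()
    res$co_pathways <- co_pathway_analysis(list())
  }

  dep_sets <- lapply(names(COMPARISONS), function(cmp)
    call_deps(study, cmp, p_thresh = p_thresh, lfc_thresh = lfc_thresh))
  names(dep_sets) <- names(COMPARISONS)
  res$dep_sets <- dep_sets
  res$deps <- do.call(rbind, lapply(names(dep_sets), function(cmp) {
    d <- as.data.frame(dep_sets[[cmp]])
    if (nrow(d)) d$comparison <- cmp else d$comparison <- character(0)
    d
  }))
  trends <- stats::setNames(bridge$labels$label,
                            sprintf("cluster_%d", bridge$labels$cluster))
  res$key_proteins <- find_key_proteins(bridge$bridge_proteins, dep_sets,
                                        cluster_trends = trends)

  if (!is.null(edges)) {
    g <- build_graph(edges, node_universe = if (length(all_bridge))
      all_bridge else NULL)
    res$graph <- g
    res$centralities <- centrality_table(g)
    key <- intersect(res$key_proteins$union, igraph::V(g)$name)
    res$key_paths <- list()
    if (length(key) >= 2) {
      pairs <- utils::combn(sort(key), 2)
      for (j in seq_len(ncol(pairs))) {
        nm <- paste(pairs[, j], collapse = "-")
        res$key_paths[[nm]] <- shortest_paths_between(g, pairs[1, j],
                                                      pairs[2, j])
      }
    }
  } else {
    res$centralities <- data.frame(node = character(0), degree = integer(0),
                                   betweenness = numeric(0),
                                   betweenness_normalized = numeric(0))
  }

  if (!is.null(plates)) {
    res$calibration <- calibrate_plates(plates)
  }

  res$summary <- list(
    n_proteins = nrow(study$matrix), n_samples = ncol(study$matrix),
    clusters = clusters, fuzzifier = model$m,
    bridge_clusters = bridge$bridge_clusters,
    n_bridge_proteins = vapply(bridge$bridge_proteins, length, integer(1)),
    n_deps = vapply(dep_sets, function(d) sum(d$dep), integer(1)),
    key_proteins = res$key_proteins$union,
    n_core_pathways = sum(res$co_pathways$terms$core),
    n_pivotal_pathways = sum(res$co_pathways$terms$pivotal),
    seed = seed)

  out <- structure(res, class = "exo_pipeline")
  if (!is.null(out_dir)) out$manifest <- write_report_tables(out, out_dir)
  out
}

# Fit each plate's standards, invert the unknowns, and when a CD81 plate is
# present normalize each marker to it.
calibrate_plates <- function(plates) {
  curves <- lapply(plates, function(p) fit_standard_curve(p$standards))
  conc <- lapply(names(plates), function(nm) {
    inv <- invert_curve(curves[[nm]], plates[[nm]]$unknowns$od)
    data.frame(plate = nm, id = plates[[nm]]$unknowns$id, od = inv$od,
               concentration = inv$concentration, in_range = inv$in_range,
               stringsAsFactors = FALSE)
  })
  conc <- do.call(rbind, conc)
  tests <- data.frame()
  if ("CD81" %in% names(plates)) {
    cd81 <- conc[conc$plate == "CD81", ]
    for (nm in setdiff(names(plates), "CD81")) {
      mk <- conc[conc$plate == nm, ]
      shared <- intersect(mk$id, cd81$id)
      if (length(shared) < 4) next
      rel <- normalize_to_cd81(mk$concentration[match(shared, mk$id)],
                               cd81$concentration[match(shared, cd81$id)])
      grp <- sub("_.*", "", shared)
      if (length(unique(grp)) >= 2) {
        tst <- try(compare_groups(rel$ratio, grp), silent = TRUE)
        if (!inherits(tst, "try-error")) {
          tst$marker <- nm
          tests <- rbind(tests, tst)
        }
      }
    }
  }
  list(curves = curves, concentrations = conc, tests = tests)
}

#' @export
print.exo_pipeline <- function(x, ...) {
  s <- x$summary
  cat("exomarker pipeline:", s$n_proteins, "proteins x", s$n_samples,
      "samples\n")
  cat("  soft clusters:", s$clusters, "(m =", format(s$fuzzifier, digits = 4),
      "); bridge clusters:", paste(s$bridge_clusters, collapse = ", "), "\n")
  cat("  bridge proteins:", paste(sprintf("%s=%d", names(s$n_bridge_proteins),
                                          s$n_bridge_proteins), collapse = ", "), "\n")
  cat("  DEPs:", paste(sprintf("%s=%d", names(s$n_deps), s$n_deps),
                       collapse = ", "), "\n")
  cat("  key proteins:", if (length(s$key_proteins))
    paste(s$key_proteins, collapse = ", ") else "(none)", "\n")
  if (!is.null(s$n_core_pathways))
    cat("  core pathways:", s$n_core_pathways, "; pivotal:",
        s$n_pivotal_pathways, "\n")
  invisible(x)
}
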