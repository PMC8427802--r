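# Pairwise differential expression on log2 intensities and key-protein
# intersection with bridge proteins.

COMPARISONS <- list(MCIvsN = c("MCI", "normal"),
                    ADvsN = c("AD", "normal"),
                    ADvsMCI = c("AD", "MCI"))

#' Log2 fold change from log2-scale group values
#'
#' `mean(log2 values of group 1) - mean(log2 values of group 2)`; since the
#' stored values are already log2 intensities, this equals the log2 of the
#' ratio of geometric means on the original scale. Inputs must not be
#' re-logged.
#'
#' @param group1,group2 numeric log2-scale vectors (>= 1 value each; NA
#'   dropped).
#' @return the log2 fold change.
#' @export
log2_fold_change <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]; group2 <- group2[!is.na(group2)]
  if (length(group1) == 0 || length(group2) == 0)
    stop("both groups need at least one value")
  mean(group1) - mean(group2)
}

#' Two-sample t-test on log2 values
#'
#' Two-sided Student (pooled variance, the default) or Welch t-test. When
#' both groups have zero variance the test statistic is undefined; the
#' convention used is p = 1 (t = 0) for equal means and p = 0 (t = +-Inf)
#' for unequal means, reported via the `degenerate` flag.
#'
#' @param group1,group2 numeric vectors (>= 2 values each after NA removal).
#' @param variant `"student"` or `"welch"`.
#' @return one-row data.frame `t`, `df`, `p`, `degenerate`.
#' @export
t_test_protein <- function(group1, group2, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  group1 <- group1[!is.na(group1)]; group2 <- group2[!is.na(group2)]
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs >= 2 values")
  if (stats::sd(group1) == 0 && stats::sd(group2) == 0) {
    eq <- mean(group1) == mean(group2)
    return(data.frame(t = if (eq) 0 else sign(mean(group1) - mean(group2)) * Inf,
                      df = NA_real_, p = if (eq) 1 else 0, degenerate = TRUE))
  }
  ht <- stats::t.test(group1, group2, var.equal = (variant == "student"))
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, degenerate = FALSE)
}

#' Call differentially expressed proteins for one pairwise comparison
#'
#' A protein is a DEP iff `p < p_thresh` and `|log2FC| >= lfc_thresh`
#' (defaults 0.05 and 0.5); the sign of the fold change sets the direction.
#' P-values are raw by default; BH adjustment is available via `adjust`
#' (DEPs are then gated on the adjusted values). Proteins with fewer than
#' two complete observations in either group are skipped and reported.
#'
#' @param study an `expression_study`.
#' @param comparison one of `"MCIvsN"`, `"ADvsN"`, `"ADvsMCI"`.
#' @param p_thresh,lfc_thresh DEP thresholds.
#' @param variant t-test variant, `"student"` (default) or `"welch"`.
#' @param adjust apply BH to the p-values before thresholding (default
#'   FALSE, matching the raw-p criterion).
#' @return object of class `dep_set`: data.frame `protein`, `log2FC`, `t`,
#'   `p` (and `q` when adjusted), `dep`, `direction`, with attributes
#'   `comparison`, `thresholds`, `skipped`.
#' @export
call_deps <- function(study, comparison = c("MCIvsN", "ADvsN", "ADvsMCI"),
                      p_thresh = 0.05, lfc_thresh = 0.5,
                      variant = c("student", "welch"), adjust = FALSE) {
  comparison <- match.arg(comparison)
  variant <- match.arg(variant)
  pair <- COMPARISONS[[comparison]]
  g1_cols <- names(study$stages)[study$stages == pair[1]]
  g2_cols <- names(study$stages)[study$stages == pair[2]]
  if (length(g1_cols) == 0 || length(g2_cols) == 0)
    stop("comparison ", comparison, " needs samples in both stages")
  proteins <- rownames(study$matrix)
  skipped <- character(0)
  rows <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    v1 <- study$matrix[i, g1_cols]; v1 <- v1[!is.na(v1)]
    v2 <- study$matrix[i, g2_cols]; v2 <- v2[!is.na(v2)]
    if (length(v1) < 2 || length(v2) < 2) {
      skipped <- c(skipped, proteins[i])
      next
    }
    tt <- t_test_protein(v1, v2, variant)
    rows[[i]] <- data.frame(protein = proteins[i],
                            log2FC = log2_fold_change(v1, v2),
                            t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(protein = character(0), log2FC = numeric(0),
                     t = numeric(0), p = numeric(0))
  p_gate <- df$p
  if (adjust && nrow(df)) {
    df$q <- adjust_bh(df$p)
    p_gate <- df$q
  }
  df$dep <- p_gate < p_thresh & abs(df$log2FC) >= lfc_thresh
  df$direction <- ifelse(!df$dep, "none", ifelse(df$log2FC > 0, "up", "down"))
  rownames(df) <- NULL
  structure(df, class = c("dep_set", "data.frame"), comparison = comparison,
            thresholds = c(p = p_thresh, lfc = lfc_thresh), skipped = skipped)
}

#' Key proteins: bridge proteins that are also DEPs
#'
#' For every (bridge cluster, comparison) pair, the intersection of that
#' cluster's bridge proteins with the comparison's DEPs. Empty intersections
#' are retained as explicit empty entries. Direction concordance (whether a
#' key protein's fold-change sign matches its cluster's trend) is reported
#' separately, not used as a filter.
#'
#' @param bridge_sets named list of bridge-protein vectors per cluster.
#' @param dep_sets named list of `dep_set`s per comparison.
#' @param cluster_trends optional named character vector
#'   (`monotone_up`/`monotone_down` per cluster) for concordance reporting.
#' @return object of class `key_protein_report`: `table` (data.frame
#'   `cluster`, `comparison`, `n`, `proteins`, `concordant`), `union`
#'   (character vector of all key proteins).
#' @export
find_key_proteins <- function(bridge_sets, dep_sets, cluster_trends = NULL) {
  rows <- list()
  union_set <- character(0)
  for (cl in names(bridge_sets)) {
    for (cmp in names(dep_sets)) {
      dep <- dep_sets[[cmp]]
      dep_prot <- dep$protein[dep$dep]
      inter <- intersect(bridge_sets[[cl]], dep_prot)
      union_set <- union(union_set, inter)
      conc <- NA_integer_
      if (!is.null(cluster_trends) && !is.na(cluster_trends[cl]) &&
          length(inter)) {
        dir <- dep$direction[match(inter, dep$protein)]
        expect <- if (cluster_trends[[cl]] == "monotone_up") "up" else "down"
        conc <- sum(dir == expect)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, comparison = cmp, n = length(inter),
        proteins = paste(sort(inter), collapse = ","),
        concordant = conc, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
    else data.frame(cluster = character(0), comparison = character(0),
                    n = integer(0), proteins = character(0),
                    concordant = integer(0))
  structure(list(table = tab, union = sort(union_set)),
            class = "key_protein_report")
}

#' @export
print.key_protein_report <- function(x, ...) {
  cat("key proteins:", length(x$union), "distinct across",
      nrow(x$table), "(cluster x comparison) intersections\n")
  if (length(x$union)) cat(" ", paste(x$union, collapse = ", "), "\n")
  invisible(x)
}
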