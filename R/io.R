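# Readers and writers for the external formats the pipeline touches.
# Readers reject rather than silently coerce malformed input; every error
# names the offending location.

normalize_stage <- function(x) {
  key <- tolower(trimws(x))
  map <- c(normal = "normal", mci = "MCI", ad = "AD")
  out <- map[key]
  if (any(is.na(out)))
    stop("unknown stage label(s): ", paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected normal/MCI/AD, case-insensitive)")
  unname(out)
}

#' Write an expression study to TSV
#'
#' Writes the matrix (first column `protein`, header row of sample ids) and a
#' two-column sample sheet (`sample`, `stage`) at full double precision.
#'
#' @param study an `expression_study`.
#' @param path matrix TSV path.
#' @param sample_sheet_path sample sheet TSV path.
#' @return invisibly, the two paths.
#' @export
write_expression_matrix <- function(study, path, sample_sheet_path) {
  df <- data.frame(protein = rownames(study$matrix),
                   format(as.data.frame(study$matrix), digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample = names(study$stages), stage = unname(study$stages))
  utils::write.table(sheet, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, sample_sheet_path))
}

#' Read a log2 expression matrix plus sample sheet
#'
#' @param path TSV with first column protein ids and one column per sample.
#' @param sample_sheet_path two-column TSV (`sample`, `stage`); stage labels
#'   normal/MCI/AD (case-insensitive).
#' @return an `expression_study`.
#' @export
read_expression_matrix <- function(path, sample_sheet_path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (!file.exists(sample_sheet_path))
    stop("sample sheet not found: ", sample_sheet_path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("matrix must have a protein column and >= 1 sample")
  prot <- raw[[1]]
  dup <- prot[duplicated(prot)]
  if (length(dup))
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell '%s' at row %d (protein %s), column %d (%s)",
                 vals[bad[1, 1], bad[1, 2]], bad[1, 1], prot[bad[1, 1]],
                 bad[1, 2], colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(prot, colnames(vals))

  sheet <- utils::read.table(sample_sheet_path, sep = "\t", header = TRUE,
                             colClasses = "character", quote = "")
  if (!all(c("sample", "stage") %in% names(sheet)))
    stop("sample sheet needs columns 'sample' and 'stage'")
  if (anyDuplicated(sheet$sample))
    stop("duplicate sample id(s) in sheet: ",
         paste(unique(sheet$sample[duplicated(sheet$sample)]), collapse = ", "))
  missing <- setdiff(colnames(num), sheet$sample)
  if (length(missing))
    stop("sample(s) in matrix missing from sample sheet: ",
         paste(missing, collapse = ", "))
  stages <- stats::setNames(normalize_stage(sheet$stage), sheet$sample)
  stages <- stages[colnames(num)]
  structure(list(matrix = num, stages = stages), class = "expression_study")
}

#' Write annotation sets in GMT format
#'
#' One line per term: term id, ontology tag (in the GMT description field),
#' then member proteins, all tab-separated.
#'
#' @param annotation an `annotation_sets`.
#' @param path output path.
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(names(annotation$members), function(term) {
    paste(c(term, annotation$ontology[[term]], annotation$members[[term]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read annotation sets from GMT
#'
#' Field 1 is the term id; field 2 is parsed for an ontology tag (one of
#' BP/CC/MF/KEGG, defaulting to KEGG when absent); remaining fields are
#' member ids, deduplicated.
#'
#' @param path GMT path.
#' @return an `annotation_sets`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  members <- list(); ontology <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    term <- f[1]
    onto <- if (f[2] %in% c("BP", "CC", "MF", "KEGG")) f[2] else "KEGG"
    mem <- unique(f[-(1:2)])
    if (length(mem) == 0) stop("GMT line ", i, " defines an empty set")
    members[[term]] <- mem
    ontology[term] <- onto
  }
  structure(list(members = members, ontology = ontology), class = "annotation_sets")
}

#' Write an interaction edge list
#'
#' Three whitespace-separated columns: protein1, protein2, combined_score.
#'
#' @param edges data.frame with those columns.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges[, c("protein1", "protein2", "combined_score")],
                     path, sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and filter a STRING-style edge list
#'
#' Scores are auto-detected per file as either integers 0-999 or floats 0-1
#' (never mixed). Edges below `score_threshold` are dropped; undirected
#' duplicates are collapsed keeping the maximum score; self-loops are
#' removed. When the file is on the 0-1 scale and the threshold is > 1 it is
#' interpreted on the 0-999 scale and divided by 1000.
#'
#' @param path edge list path (optionally with a header line).
#' @param score_threshold minimum combined score (default 400, medium
#'   confidence on the 0-999 scale).
#' @return data.frame `protein1`, `protein2`, `combined_score`.
#' @export
read_edge_list <- function(path, score_threshold = 400) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  first <- strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]]
  if (length(first) < 3) stop("edge list needs 3 columns (protein1 protein2 score)")
  has_header <- is.na(suppressWarnings(as.numeric(first[3])))
  df <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("edge list needs 3 columns (protein1 protein2 score)")
  names(df)[1:3] <- c("protein1", "protein2", "combined_score")
  s <- df$combined_score
  if (!is.numeric(s)) stop("non-numeric score column in ", path)
  integer_like <- all(s == round(s))
  if (any(s > 1) && !integer_like)
    stop("mixed score scales in ", path,
         ": values > 1 must be integers on the 0-999 scale")
  scale999 <- any(s > 1)
  if (scale999) {
    if (any(s < 0 | s > 999)) stop("scores outside 0-999 in ", path)
  } else {
    if (any(s < 0 | s > 1)) stop("scores outside 0-1 in ", path)
    if (score_threshold > 1) score_threshold <- score_threshold / 1000
  }
  df <- df[s >= score_threshold, , drop = FALSE]
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  if (nrow(df)) {
    a <- pmin(df$protein1, df$protein2)
    b <- pmax(df$protein1, df$protein2)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -df$combined_score)
    df <- df[ord, ][!duplicated(key[ord]), , drop = FALSE]
    df$protein1 <- a[ord][!duplicated(key[ord])]
    df$protein2 <- b[ord][!duplicated(key[ord])]
  }
  rownames(df) <- NULL
  df[, c("protein1", "protein2", "combined_score")]
}

#' Write plate data as a two-row CSV
#'
#' Mirrors the kit-report layout: one `OD` row and one `ng/ml` row, standards
#' first (S0, S1, ...) then unknowns; unknown concentrations are left blank.
#'
#' @param plate a `plate_data`.
#' @param path output CSV path.
#' @export
write_plate_csv <- function(plate, path) {
  ns <- nrow(plate$standards); nu <- nrow(plate$unknowns)
  header <- c("", sprintf("S%d", seq_len(ns) - 1L),
              if (nu) plate$unknowns$id)
  od <- c("OD", format(c(plate$standards$od, plate$unknowns$od), digits = 15,
                       trim = TRUE))
  conc <- c("ng/ml", format(plate$standards$concentration, digits = 15,
                            trim = TRUE), rep("", nu))
  writeLines(c(paste(header, collapse = ","), paste(od, collapse = ","),
               paste(conc, collapse = ",")), path)
  invisible(path)
}

#' Read plate data from the two-row CSV layout
#'
#' @param path CSV written by [write_plate_csv()] or hand-built in the same
#'   layout: a header of well labels, an `OD` row and a `ng/ml` row; columns
#'   with a concentration are standards, columns without are unknowns.
#' @return a `plate_data`.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("plate file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3) stop("plate CSV needs header, OD row and ng/ml row")
  split1 <- strsplit(lines, ",", fixed = TRUE)
  header <- split1[[1]][-1]
  odrow <- split1[[2]]; concrow <- split1[[3]]
  if (odrow[1] != "OD" || concrow[1] != "ng/ml")
    stop("plate CSV rows must be labelled 'OD' and 'ng/ml'")
  od <- as.numeric(odrow[-1])
  conc <- suppressWarnings(as.numeric(concrow[-1]))
  conc <- c(conc, rep(NA_real_, length(od) - length(conc)))
  is_std <- !is.na(conc)
  structure(list(
    standards = data.frame(concentration = conc[is_std], od = od[is_std]),
    unknowns = data.frame(id = header[!is_std], od = od[!is_std],
                          true_concentration = NA_real_,
                          stringsAsFactors = FALSE)
  ), class = "plate_data")
}

#' Write the planted truth as JSON
#'
#' @param truth a `planted_truth`.
#' @param path output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(protein_shapes = as.list(truth$protein_shapes),
                            planted_path = truth$planted_path),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write all pipeline report tables plus a JSON summary
#'
#' Emits TSV tables for cluster memberships and trajectory labels, centroids,
#' sample clusters, enrichment, core/pivotal pathways, differential
#' expression, key proteins, centralities and (when present) calibration,
#' plus a machine-readable `summary.json`.
#'
#' @param results a pipeline result bundle (see [run_full_pipeline()]).
#' @param out_dir output directory, created if needed.
#' @return data.frame manifest (`file`, `rows`).
#' @export
write_report_tables <- function(results, out_dir) {
  if (length(results) == 0) stop("results bundle is empty")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  manifest <- list()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest[[length(manifest) + 1L]] <<- data.frame(file = name, rows = nrow(df))
  }
  put(results$cluster_table, "clusters.tsv")
  put(results$centroid_table, "centroids.tsv")
  put(results$sample_clusters, "sample_clusters.tsv")
  put(results$enrichment, "enrichment.tsv")
  put(results$co_pathways$terms, "core_pivotal_pathways.tsv")
  put(results$co_pathways$upset, "upset_counts.tsv")
  put(results$deps, "differential_expression.tsv")
  put(results$key_proteins$table, "key_proteins.tsv")
  put(results$centralities, "centralities.tsv")
  if (!is.null(results$calibration)) {
    put(results$calibration$concentrations, "calibration_concentrations.tsv")
    put(results$calibration$tests, "calibration_tests.tsv")
  }
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(results$summary, summary_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest[[length(manifest) + 1L]] <-
    data.frame(file = "summary.json", rows = NA_integer_)
  do.call(rbind, manifest)
}
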