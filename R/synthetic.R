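# Trajectory archetypes over the three cognitive stages (normal, MCI, AD).
# Offsets are symmetric around the MCI stage so that monotone / peak / valley
# detection thresholds are symmetric and analytically checkable.
TRAJECTORY_SHAPES <- c("monotone_up", "monotone_down", "valley", "peak", "flat")

STAGES <- c("normal", "MCI", "AD")

shape_offsets <- function(shape, delta) {
  switch(shape,
    monotone_up   = c(-delta, 0, delta),
    monotone_down = c(delta, 0, -delta),
    valley        = c(0, -delta, 0),
    peak          = c(0, delta, 0),
    flat          = c(0, 0, 0),
    stop("unknown trajectory shape: ", shape)
  )
}

#' Configuration for a synthetic three-stage cohort
#'
#' Encodes the study conditions the generator emulates: a cohort of proteins
#' with planted stage trajectories measured in five subjects per cognitive
#' stage. Defaults mirror the study design the package targets: 360 proteins
#' split over six trajectory archetypes (one rising, one falling, two concave,
#' two convex) and 5/5/5 samples for normal/MCI/AD.
#'
#' @param n_per_shape named integer vector of protein counts per trajectory
#'   shape (names from `monotone_up`, `monotone_down`, `valley`, `peak`,
#'   `flat`).
#' @param stage_sizes integer vector of length 3: samples per stage in the
#'   order (normal, MCI, AD).
#' @param effect_delta trajectory amplitude in log2 units (delta >= 0).
#' @param noise_sd Gaussian noise SD on log2 intensities (>= 0).
#' @param baseline_range per-protein baseline abundance interval, log2 units.
#' @param missing_rate optional missing-at-random rate in `[0, 1)`; 0 by
#'   default (robustness testing only).
#' @param seed integer seed; identical seeds reproduce the cohort exactly.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_shape = c(monotone_up = 60, monotone_down = 60,
                                          valley = 120, peak = 120, flat = 0),
                          stage_sizes = c(normal = 5, MCI = 5, AD = 5),
                          effect_delta = 1,
                          noise_sd = 0.5,
                          baseline_range = c(20, 30),
                          missing_rate = 0,
                          seed = 1L) {
  if (is.null(names(n_per_shape)) || !all(names(n_per_shape) %in% TRAJECTORY_SHAPES))
    stop("n_per_shape must be named with trajectory shapes: ",
         paste(TRAJECTORY_SHAPES, collapse = ", "))
  if (any(n_per_shape < 0) || any(n_per_shape != round(n_per_shape)))
    stop("n_per_shape counts must be non-negative integers")
  if (length(stage_sizes) != 3 || any(stage_sizes < 0))
    stop("stage_sizes must be three non-negative counts (normal, MCI, AD)")
  if (effect_delta < 0) stop("effect_delta must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(baseline_range) != 2 || diff(baseline_range) < 0)
    stop("baseline_range must be an increasing interval")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(
    list(n_per_shape = n_per_shape, stage_sizes = stats::setNames(stage_sizes, STAGES),
         effect_delta = effect_delta, noise_sd = noise_sd,
         baseline_range = baseline_range, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic expression study with planted trajectories
#'
#' Builds a log2 intensity matrix (proteins x samples) where each protein
#' follows `baseline + shape_offset(stage) + N(0, noise_sd)`. Shape offsets
#' over (normal, MCI, AD) are `(-d, 0, +d)` for `monotone_up`, `(+d, 0, -d)`
#' for `monotone_down`, `(0, -d, 0)` for `valley`, `(0, +d, 0)` for `peak`
#' and `(0, 0, 0)` for `flat`, with `d = effect_delta`.
#'
#' The planted truth records each protein's shape, and a guaranteed 4-node
#' interaction path from a rising protein through two falling proteins to a
#' falling endpoint, emulating a signalling cascade between one "up" and one
#' "down" marker.
#'
#' @param config a [cohort_config()].
#' @return list with elements `study` (class `expression_study`: `matrix`,
#'   `stages`) and `truth` (class `planted_truth`: `protein_shapes`,
#'   `planted_path`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n_prot <- sum(config$n_per_shape)
  n_samp <- sum(config$stage_sizes)
  if (n_prot == 0 || n_samp == 0)
    stop("empty study: cohort must have at least one protein and one sample")

  shapes <- rep(names(config$n_per_shape), config$n_per_shape)
  protein_ids <- sprintf("P%04d", seq_len(n_prot))
  names(shapes) <- protein_ids

  stage_of_sample <- rep(STAGES, config$stage_sizes)
  sample_ids <- unlist(lapply(STAGES, function(st) {
    k <- config$stage_sizes[[st]]
    if (k == 0) character(0)
    else sprintf("%s_%02d", c(normal = "N", MCI = "M", AD = "A")[[st]], seq_len(k))
  }))
  names(stage_of_sample) <- sample_ids

  set.seed(config$seed)
  baselines <- stats::runif(n_prot, config$baseline_range[1], config$baseline_range[2])
  stage_idx <- match(stage_of_sample, STAGES)
  mat <- matrix(NA_real_, n_prot, n_samp, dimnames = list(protein_ids, sample_ids))
  for (i in seq_len(n_prot)) {
    off <- shape_offsets(shapes[i], config$effect_delta)
    mat[i, ] <- baselines[i] + off[stage_idx] +
      stats::rnorm(n_samp, 0, config$noise_sd)
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(mat)) < config$missing_rate
    mat[drop] <- NA_real_
  }

  up <- protein_ids[shapes == "monotone_up"]
  dn <- protein_ids[shapes == "monotone_down"]
  planted_path <- if (length(up) >= 1 && length(dn) >= 3)
    c(up[1], dn[2], dn[3], dn[1]) else character(0)

  study <- structure(list(matrix = mat, stages = stage_of_sample),
                     class = "expression_study")
  truth <- structure(list(protein_shapes = shapes, planted_path = planted_path),
                     class = "planted_truth")
  list(study = study, truth = truth)
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$matrix), "proteins x", ncol(x$matrix), "samples\n")
  cat("stages:", paste(sprintf("%s=%d", STAGES, table(factor(x$stages, STAGES))),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Generate protein-set annotation with planted enriched terms
#'
#' Emits `n_background_terms` random sets drawn uniformly from all proteins
#' plus, per requested shape, one planted term drawn mostly (default 80%)
#' from that shape's proteins, so the planted term is strongly
#' over-represented in the matching trajectory cluster. Each term carries an
#' ontology tag from BP/CC/MF/KEGG.
#'
#' @param truth a `planted_truth` from [generate_cohort()].
#' @param n_background_terms number of random background sets.
#' @param term_size_range interval of set sizes.
#' @param shapes shapes that receive one planted term each.
#' @param purity fraction of a planted term drawn from its shape's proteins.
#' @param seed integer seed.
#' @return object of class `annotation_sets`: named list `members`, character
#'   vector `ontology` (one tag per term).
#' @export
generate_annotation <- function(truth, n_background_terms = 50,
                                term_size_range = c(10, 40),
                                shapes = c("monotone_up", "monotone_down"),
                                purity = 0.8, seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  all_prot <- names(truth$protein_shapes)
  if (length(all_prot) == 0) stop("planted truth is empty")
  if (max(term_size_range) > length(all_prot))
    stop("term_size_range exceeds protein count (", length(all_prot), ")")
  set.seed(seed)
  ontos <- c("BP", "CC", "MF", "KEGG")
  members <- list()
  ontology <- character(0)
  planted <- character(0)
  for (sh in shapes) {
    pool <- all_prot[truth$protein_shapes == sh]
    if (length(pool) == 0) next
    size <- min(20, length(all_prot))
    n_in <- min(ceiling(purity * size), length(pool))
    term <- sprintf("PLANTED_%s", toupper(sh))
    members[[term]] <- c(sample(pool, n_in),
                         sample(setdiff(all_prot, pool), size - n_in))
    ontology[term] <- "BP"
    planted <- c(planted, term)
  }
  if (n_background_terms > 0) {
    for (j in seq_len(n_background_terms)) {
      term <- sprintf("BG_%04d", j)
      size <- sample(seq(term_size_range[1], term_size_range[2]), 1)
      members[[term]] <- sample(all_prot, size)
      ontology[term] <- sample(ontos, 1)
    }
  }
  structure(list(members = members, ontology = ontology, planted = planted),
            class = "annotation_sets")
}

#' Generate an interaction edge list with a planted shortest path
#'
#' The planted path's consecutive pairs become edges with the maximal
#' combined score (999). Noise edges are drawn only among non-path nodes, so
#' by construction they can never create a shorter route between the planted
#' endpoints than the planted path itself.
#'
#' @param truth a `planted_truth` whose `planted_path` has >= 2 nodes.
#' @param n_noise_edges number of random edges among non-path proteins.
#' @param seed integer seed.
#' @return data.frame with columns `protein1`, `protein2`,
#'   `combined_score` (integers 0-999).
#' @export
generate_ppi_edges <- function(truth, n_noise_edges = 50, seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  path <- truth$planted_path
  if (length(path) < 2) stop("planted_path must have >= 2 nodes")
  set.seed(seed)
  edges <- data.frame(protein1 = path[-length(path)], protein2 = path[-1],
                      combined_score = 999L, stringsAsFactors = FALSE)
  others <- setdiff(names(truth$protein_shapes), path)
  if (n_noise_edges > 0 && length(others) >= 2) {
    seen <- character(0)
    rows <- list()
    while (length(rows) < n_noise_edges) {
      pair <- sort(sample(others, 2))
      key <- paste(pair, collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <-
        data.frame(protein1 = pair[1], protein2 = pair[2],
                   combined_score = sample(400:998, 1), stringsAsFactors = FALSE)
      if (length(seen) >= choose(length(others), 2)) break
    }
    edges <- rbind(edges, do.call(rbind, rows))
  }
  rownames(edges) <- NULL
  edges
}

#' Four-parameter logistic parameters
#'
#' `a` is the response at zero concentration, `d` the response at infinite
#' concentration, `c0` the inflection concentration (the midpoint of the
#' response) and `b` the slope factor.
#'
#' @param a,d,c0,b numeric scalars; `a != d`, `c0 > 0`.
#' @return named numeric vector of class `fourpl_params`.
#' @export
fourpl_params <- function(a, d, c0, b) {
  if (a == d) stop("non-monotone parameter combination: a = d gives a flat curve")
  if (c0 <= 0) stop("c0 must be > 0")
  structure(c(a = a, d = d, c0 = c0, b = b), class = "fourpl_params")
}

#' Evaluate the four-parameter logistic curve
#'
#' `OD(x) = d + (a - d) / (1 + (x / c0)^b)`, with the zero-concentration
#' point evaluated at its limit `a` (for `b > 0`).
#'
#' @param x concentrations (>= 0).
#' @param params a [fourpl_params()] or named vector with a, d, c0, b.
#' @return numeric responses.
#' @export
fourpl <- function(x, params) {
  a <- params[["a"]]; d <- params[["d"]]; c0 <- params[["c0"]]; b <- params[["b"]]
  r <- (x / c0)^b
  r[x == 0] <- if (b > 0) 0 else Inf
  d + (a - d) / (1 + r)
}

#' Generate a synthetic ELISA plate
#'
#' Produces standards and unknowns with `OD = fourpl(x) + N(0, noise_sd)`,
#' mirroring a kit plate with a standard dilution row and a sample row.
#'
#' @param curve_params a [fourpl_params()].
#' @param standard_concs standard concentrations, ng/ml (>= 5 points).
#' @param sample_concs true concentrations of the unknowns.
#' @param noise_sd OD noise SD.
#' @param seed integer seed.
#' @return object of class `plate_data`: data.frames `standards`
#'   (`concentration`, `od`) and `unknowns` (`id`, `od`, `true_concentration`).
#' @export
generate_elisa_plate <- function(curve_params,
                                 standard_concs = c(0, 0.156, 0.312, 0.625,
                                                    1.25, 2.5, 5),
                                 sample_concs = numeric(0),
                                 noise_sd = 0, seed = 1L) {
  if (curve_params[["a"]] == curve_params[["d"]])
    stop("non-monotone parameter combination: a = d")
  if (length(standard_concs) < 5) stop("at least 5 standards required")
  if (any(standard_concs < 0)) stop("concentrations must be non-negative")
  set.seed(seed)
  std_od <- fourpl(standard_concs, curve_params) +
    stats::rnorm(length(standard_concs), 0, noise_sd)
  unk_od <- fourpl(sample_concs, curve_params) +
    stats::rnorm(length(sample_concs), 0, noise_sd)
  structure(list(
    standards = data.frame(concentration = standard_concs, od = std_od),
    unknowns = if (length(sample_concs))
      data.frame(id = sprintf("U%02d", seq_along(sample_concs)), od = unk_od,
                 true_concentration = sample_concs, stringsAsFactors = FALSE)
    else data.frame(id = character(0), od = numeric(0),
                    true_concentration = numeric(0))
  ), class = "plate_data")
}
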