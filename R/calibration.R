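# ELISA calibration: four-parameter logistic standard curves, inverse
# prediction, CD81 normalization, and pairwise group comparison with
# significance stars.

#' Fit a four-parameter logistic standard curve
#'
#' Least-squares fit of `OD(x) = d + (a - d) / (1 + (x / c0)^b)` by
#' Levenberg-Marquardt, initialized at `a = min OD`, `d = max OD`,
#' `c0 = median positive concentration`, `b = 1`, with convergence tolerance
#' 1e-10 on the residual sum of squares. The zero-concentration standard is
#' handled as the lower-asymptote limit of the curve rather than excluded.
#' Standards that are not close to monotone (Spearman |rho| < 0.9) trigger a
#' recorded warning.
#'
#' @param standards data.frame with columns `concentration` and `od`
#'   (>= 5 points, concentrations non-negative).
#' @param weights optional per-standard weights for weighted least squares.
#' @return object of class `standard_curve`: `params` (a, d, c0, b),
#'   `standards`, `rss`, `dynamic_range` (open interval between the fitted
#'   asymptotes), `warnings`.
#' @export
fit_standard_curve <- function(standards, weights = NULL) {
  stopifnot(is.data.frame(standards),
            all(c("concentration", "od") %in% names(standards)))
  x <- standards$concentration; y <- standards$od
  if (length(x) < 5) stop("at least 5 standards are required")
  if (any(x < 0)) stop("concentrations must be non-negative")
  warn <- character(0)
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (is.na(rho) || abs(rho) < 0.9) {
    warn <- c(warn, sprintf("standards are not monotone (Spearman rho = %.3f)",
                            rho))
    warning(warn[length(warn)])
  }
  start <- list(a = min(y), d = max(y), c0 = stats::median(x[x > 0]), b = 1)
  args <- list(y ~ fourpl(x, c(a = a, d = d, c0 = c0, b = b)),
               start = start,
               lower = c(a = -Inf, d = -Inf, c0 = 1e-9, b = -Inf),
               control = minpack.lm::nls.lm.control(maxiter = 1000,
                                                    ftol = 1e-10))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
    error = function(e) stop("standard-curve fit failed: ", conditionMessage(e),
                             call. = FALSE))
  params <- coef(fit)
  rng <- sort(c(params[["a"]], params[["d"]]))
  structure(list(params = stats::setNames(as.numeric(params),
                                          c("a", "d", "c0", "b")),
                 standards = standards,
                 rss = sum(stats::resid(fit)^2),
                 dynamic_range = rng, warnings = warn),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  p <- x$params
  cat("4PL standard curve: OD(x) = d + (a-d)/(1+(x/c0)^b)\n")
  cat(sprintf("  a=%.4g  d=%.4g  c0=%.4g  b=%.4g   RSS=%.4g (%d standards)\n",
              p["a"], p["d"], p["c0"], p["b"], x$rss, nrow(x$standards)))
  cat(sprintf("  dynamic range (OD): (%.4g, %.4g)\n",
              x$dynamic_range[1], x$dynamic_range[2]))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) object$params

#' Predicted OD at given concentrations
#'
#' @param object a `standard_curve`.
#' @param newdata numeric concentrations (or data.frame with
#'   `concentration`).
#' @param ... unused.
#' @export
predict.standard_curve <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$concentration else newdata
  fourpl(x, object$params)
}

#' @export
residuals.standard_curve <- function(object, ...) {
  object$standards$od - predict(object, object$standards$concentration)
}

#' @export
plot.standard_curve <- function(x, ...) {
  s <- x$standards
  graphics::plot(s$concentration, s$od, xlab = "concentration (ng/ml)",
                 ylab = "OD", pch = 19, ...)
  xs <- seq(min(s$concentration), max(s$concentration), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}

#' Invert a standard curve: OD to concentration
#'
#' Closed-form inverse `x = c0 ((a - d)/(od - d) - 1)^(1/b)`. ODs outside
#' the curve's dynamic range (the open interval between the fitted
#' asymptotes) yield an explicit out-of-range status instead of a value.
#'
#' @param curve a `standard_curve`.
#' @param od numeric OD readings.
#' @return data.frame `od`, `concentration` (NA when out of range),
#'   `in_range`; the dynamic range is attached as attribute
#'   `dynamic_range`.
#' @export
invert_curve <- function(curve, od) {
  p <- curve$params
  lo <- curve$dynamic_range[1]; hi <- curve$dynamic_range[2]
  in_range <- od > lo & od < hi
  conc <- rep(NA_real_, length(od))
  r <- (p[["a"]] - p[["d"]]) / (od[in_range] - p[["d"]]) - 1
  conc[in_range] <- p[["c0"]] * r^(1 / p[["b"]])
  structure(data.frame(od = od, concentration = conc, in_range = in_range),
            dynamic_range = c(lo, hi))
}

#' Normalize marker concentrations to CD81
#'
#' Elementwise `marker / CD81` ratio per sample. Samples with zero, missing
#' or negative CD81 are flagged and excluded from downstream testing.
#'
#' @param marker,cd81 matched numeric concentration vectors.
#' @return data.frame `marker`, `cd81`, `ratio`, `flagged`.
#' @export
normalize_to_cd81 <- function(marker, cd81) {
  if (length(marker) != length(cd81))
    stop("marker and CD81 vectors must have equal length")
  flagged <- is.na(cd81) | cd81 <= 0
  ratio <- ifelse(flagged, NA_real_, marker / cd81)
  data.frame(marker = marker, cd81 = cd81, ratio = ratio, flagged = flagged)
}

#' Significance stars for p-values
#'
#' `****` p < 1e-4, `***` p < 1e-3, `**` p < 0.01, `*` p < 0.05, else `ns`.
#'
#' @param p numeric p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
                   labels = c("****", "***", "**", "*", "ns"), right = FALSE))
}

#' Pairwise group comparison with significance annotation
#'
#' All pairwise two-sided t-tests between groups (same variant convention as
#' the differential module), with significance stars. Groups with fewer than
#' two usable values are skipped and reported.
#'
#' @param values numeric vector (e.g. CD81-normalized ratios; NA excluded).
#' @param groups factor or character vector of group labels.
#' @param variant `"student"` (default) or `"welch"`.
#' @return data.frame `group1`, `group2`, `n1`, `n2`, `t`, `p`, `stars`,
#'   with skipped groups in attribute `skipped`.
#' @export
compare_groups <- function(values, groups, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  ok <- !is.na(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  lv <- unique(groups)
  sizes <- vapply(lv, function(g) sum(groups == g), integer(1))
  usable <- lv[sizes >= 2]
  skipped <- setdiff(lv, usable)
  if (length(usable) < 2)
    stop("need >= 2 groups with >= 2 samples each")
  rows <- list()
  for (i in seq_len(length(usable) - 1)) for (j in seq(i + 1, length(usable))) {
    g1 <- values[groups == usable[i]]; g2 <- values[groups == usable[j]]
    tt <- t_test_protein(g1, g2, variant)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = usable[i], group2 = usable[j], n1 = length(g1), n2 = length(g2),
      t = tt$t, p = tt$p, stars = significance_stars(tt$p),
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), skipped = skipped)
}
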