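#' Normality-routed two-group comparison of one feature
#'
#' Shapiro-Wilk is run per group at `alpha_normality`; if both groups are
#' consistent with normality an unpaired two-sided t-test is used, otherwise
#' a two-sided Mann-Whitney test (exact when both groups have <= 20
#' observations and no ties, normal approximation with continuity and tie
#' correction otherwise). A constant group is routed to Mann-Whitney.
#'
#' @param values_a,values_b Numeric vectors (>= 3 each).
#' @param alpha_normality Normality screening level (default 0.05).
#' @return List: `test` ("t" or "mann-whitney"), `p_value`, `mean_a`,
#'   `sem_a`, `mean_b`, `sem_b`, `shapiro_p` (length 2).
#' @export
route_and_test <- function(values_a, values_b, alpha_normality = 0.05) {
  if (length(values_a) < 3L || length(values_b) < 3L) {
    stop("each group needs at least 3 values")
  }
  sw <- vapply(list(values_a, values_b), function(v) {
    if (stats::sd(v) == 0) return(0)          # degenerate: not normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(sw >= alpha_normality)
  if (normal) {
    p <- stats::t.test(values_a, values_b, var.equal = TRUE)$p.value
    test <- "t"
  } else {
    exact <- length(values_a) <= 20L && length(values_b) <= 20L &&
      !any(duplicated(c(values_a, values_b)))
    p <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = exact,
                         correct = TRUE)$p.value)
    test <- "mann-whitney"
  }
  list(test = test, p_value = p,
       mean_a = mean(values_a),
       sem_a = stats::sd(values_a) / sqrt(length(values_a)),
       mean_b = mean(values_b),
       sem_b = stats::sd(values_b) / sqrt(length(values_b)),
       shapiro_p = sw)
}

#' Univariate comparison table over all catalog features
#'
#' One routed test per feature between the recurrence and non-recurrence
#' groups, reported as mean +/- SEM per group with the test used and its
#' p-value; features with p < `alpha` are flagged. No multiplicity
#' correction is applied.
#'
#' @param features Feature data.frame (patient_id + catalog columns).
#' @param labels Character vector, "R"/"NR" per patient.
#' @param alpha Significance flag level.
#' @param alpha_normality Normality screening level.
#' @return `data.frame`: feature, mean_R, sem_R, mean_NR, sem_NR, test, p,
#'   significant.
#' @export
comparison_table <- function(features, labels, alpha = 0.05,
                             alpha_normality = 0.05) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) stop("labels must contain two classes")
  cols <- setdiff(colnames(features), "patient_id")
  rows <- lapply(cols, function(fc) {
    r <- route_and_test(features[labels == "R", fc],
                        features[labels == "NR", fc], alpha_normality)
    data.frame(feature = fc, mean_R = r$mean_a, sem_R = r$sem_a,
               mean_NR = r$mean_b, sem_NR = r$sem_b, test = r$test,
               p = r$p_value, significant = r$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
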