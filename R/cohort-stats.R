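# Cohort-level statistics: group assignment from the motor-exam posture
# item, motor sub-scores, normality-gated two-group comparisons, Spearman
# correlation with interpretation bands, and simple linear regression.
# Standard tests come from stats/nortest; this layer adds the gating,
# banding, and reporting conventions.

#' Assign PD subgroups from the posture item of the motor exam
#'
#' PD rows are split on MDS-UPDRS-III item 3.13 (posture, rated 0-4): a
#' score of 2 or more assigns PwPA (with postural abnormalities), below 2
#' assigns PwtPA. Rows labelled `HC` are left unchanged.
#'
#' @param table cohort data.frame with columns `group` and `updrs_3_13`
#'   (the latter required for non-HC rows).
#' @return the table with `group` set to `HC`, `PwtPA`, or `PwPA`.
#' @export
assignGroups <- function(table) {
  if (!all(c("subject_id", "group") %in% names(table)))
    stop("cohort table needs subject_id and group columns")
  pd <- table$group != "HC"
  item <- table[["updrs_3_13"]]
  if (is.null(item)) item <- rep(NA_real_, nrow(table))
  bad <- pd & is.na(item)
  if (any(bad))
    stop("PD row(s) missing MDS-UPDRS-III 3.13: ",
         paste(table$subject_id[bad], collapse = ", "))
  if (any(!is.na(item) & (item < 0 | item > 4)))
    stop("MDS-UPDRS-III 3.13 must lie in 0..4")
  table$group[pd] <- ifelse(item[pd] >= 2, "PwPA", "PwtPA")
  table
}

.updrsItemSets <- list(
  tremor = c("3.15", "3.16", "3.17", "3.18"),
  bradykinesia = c("3.4", "3.5", "3.6", "3.7", "3.8", "3.9", "3.14"),
  gait = c("3.10", "3.11"))

#' Motor-exam sub-scores
#'
#' Tremor is the sum of items 3.15-3.18, bradykinesia of items 3.4-3.9 and
#' 3.14, gait of items 3.10 and 3.11. Laterality sub-items (e.g. `3.15a`,
#' `3.17R`) are summed into their numbered item as provided.
#'
#' @param items named numeric vector of item scores; names are item ids,
#'   optionally with a laterality suffix.
#' @return named numeric vector `c(tremor=, bradykinesia=, gait=)`.
#' @examples
#' updrsSubscores(c("3.15" = 1, "3.16" = 2, "3.17" = 0, "3.18" = 1,
#'                  "3.10" = 2, "3.11" = 1, "3.4" = 0, "3.5" = 0, "3.6" = 0,
#'                  "3.7" = 0, "3.8" = 0, "3.9" = 0, "3.14" = 0))
#' @export
updrsSubscores <- function(items) {
  if (is.null(names(items))) stop("items must be named by item id")
  one <- function(id) {
    hit <- grepl(paste0("^", gsub(".", "\\.", id, fixed = TRUE),
                        "([^0-9].*)?$"), names(items))
    if (!any(hit)) stop("missing MDS-UPDRS item '", id, "'")
    sum(items[hit])
  }
  vapply(.updrsItemSets, function(ids) sum(vapply(ids, one, 0)), 0)
}

# Lilliefors-corrected Kolmogorov-Smirnov normality gate. Samples below 8
# observations (where the Lilliefors approximation has essentially no power)
# or constant samples cannot support a normality claim and fall through to
# the rank-based test.
.isNormal <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 8L || stats::sd(x) == 0) return(FALSE)
  p <- tryCatch(nortest::lillie.test(x)$p.value, error = function(e) 0)
  p > alpha
}

#' Two-group comparison with a normality gate
#'
#' Numeric variables are gated per group by a Lilliefors-corrected
#' Kolmogorov-Smirnov test at alpha = 0.05: if both groups pass, Student's
#' two-sample t test runs, otherwise the Mann-Whitney U test (exact p for
#' small untied samples, normal approximation with continuity correction
#' otherwise). Groups below 8 observations cannot support a normality claim
#' and always use the rank-based test. Categorical variables use the chi-square test without
#' continuity correction. All tests are two-tailed.
#'
#' @param table cohort data.frame.
#' @param variable column to compare.
#' @param groups character pair of group labels; the special label `"PD"`
#'   pools `PwtPA` and `PwPA`.
#' @return a [GroupComparison-class].
#' @export
compareGroups <- function(table, variable, groups) {
  stopifnot(length(groups) == 2L, variable %in% names(table))
  g <- table$group
  pick <- function(lbl)
    if (lbl == "PD") g %in% c("PD", "PwtPA", "PwPA") else g == lbl
  x <- table[[variable]][pick(groups[1L])]
  y <- table[[variable]][pick(groups[2L])]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) && !length(y)) stop("variable '", variable, "' is all-missing")
  if (length(x) < 2L || length(y) < 2L)
    stop("need >= 2 observations per group")
  if (is.numeric(x)) {
    norm <- c(.isNormal(x), .isNormal(y))
    if (all(norm)) {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      test <- "t"
    } else {
      exact <- length(x) <= 12L && length(y) <= 12L &&
        !anyDuplicated(c(x, y))
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                                correct = TRUE))
      test <- "mann-whitney"
    }
  } else {
    tab <- table(factor(c(x, y)), rep(groups, c(length(x), length(y))))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    test <- "chi-square"
    norm <- c(NA, NA)
  }
  methods::new("GroupComparison", variable = variable,
               groups = as.character(groups), test = test,
               statistic = unname(ht$statistic), p = ht$p.value,
               normal = norm, n = c(length(x), length(y)))
}

#' Interpretation band for a correlation coefficient
#'
#' Thresholds on |rs|: below 0.10 negligible, 0.10-0.40 weak, 0.40-0.70
#' moderate, 0.70-0.90 strong, 0.90 and above very strong.
#'
#' @param rs correlation coefficient(s) in `[-1, 1]`.
#' @return character vector of band labels.
#' @export
correlationBand <- function(rs) {
  a <- abs(rs)
  ifelse(a < 0.10, "negligible",
         ifelse(a < 0.40, "weak",
                ifelse(a < 0.70, "moderate",
                       ifelse(a < 0.90, "strong", "very strong"))))
}

#' Spearman correlation with interpretation band
#'
#' Rank correlation with average ranks for ties, on pairwise-complete
#' observations; the two-tailed p-value comes from [stats::cor.test()].
#'
#' @param x,y paired numeric vectors.
#' @return a [CorrelationResult-class].
#' @export
spearmanCorr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  rs <- unname(ct$estimate)
  methods::new("CorrelationResult", rs = rs, p = ct$p.value,
               n = length(x), band = correlationBand(rs))
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on a single predictor `x`, on
#' pairwise-complete observations. The standardised slope is the slope of
#' the z-scored regression; adjusted R squared uses the one-predictor
#' formula `1 - (1 - R2) (n - 1) / (n - 2)` (negative values are possible
#' for null fits).
#'
#' @param y response vector.
#' @param x predictor vector.
#' @return a [RegressionResult-class].
#' @export
simpleRegression <- function(y, x) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  betaStd <- unname(stats::coef(fit)[2L]) * stats::sd(x) /
    if (stats::sd(y) > 0) stats::sd(y) else 1
  methods::new("RegressionResult",
               beta = unname(stats::coef(fit)[2L]), betaStd = betaStd,
               r2 = r2, adjR2 = 1 - (1 - r2) * (n - 1) / (n - 2),
               p = sm$coefficients[2L, 4L],
               intercept = unname(stats::coef(fit)[1L]), n = n)
}

#' Per-group summary of a cohort table
#'
#' Mean and SD of every numeric variable by group, in the layout of a
#' clinical characteristics table.
#'
#' @param cohort cohort data.frame with a `group` column.
#' @param variables columns to summarise; defaults to all numeric columns.
#' @return data.frame with columns `variable`, `group`, `mean`, `sd`, `n`.
#' @export
cohortSummary <- function(cohort, variables = NULL) {
  if (is.null(variables))
    variables <- names(cohort)[vapply(cohort, is.numeric, TRUE)]
  out <- list()
  for (v in variables)
    for (gr in unique(cohort$group)) {
      x <- cohort[[v]][cohort$group == gr]
      x <- x[!is.na(x)]
      out[[length(out) + 1L]] <- data.frame(
        variable = v, group = gr, mean = mean(x), sd = stats::sd(x),
        n = length(x))
    }
  do.call(rbind, out)
}
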