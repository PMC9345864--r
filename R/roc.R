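# ROC analysis. The empirical AUC, the threshold grid and the Youden
# maximisation follow fixed conventions (midpoint thresholds, ties counted
# one half, specificity-favouring tie-break) and are computed here directly;
# the DeLong 95% confidence interval is delegated to pROC.

#' Diagnostic-accuracy band for an AUC
#'
#' Below 0.7 low, 0.7 to 0.9 moderate, above 0.9 high.
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @return character vector of band labels.
#' @export
aucBand <- function(auc) {
  ifelse(auc < 0.7, "low", ifelse(auc <= 0.9, "moderate", "high"))
}

.binaryLabels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  u <- sort(unique(as.character(labels)))
  if (length(u) > 2L) stop("labels must be binary")
  as.integer(as.character(labels) == u[length(u)])
}

#' ROC curve with Youden-optimal cut-off
#'
#' The AUC is the Mann-Whitney (rank) statistic normalised by the product of
#' class sizes, with tied score pairs counted one half. Candidate thresholds
#' are the midpoints between adjacent distinct scores plus one sentinel
#' below the minimum and one above the maximum; scores at or above a
#' threshold classify positive. The returned cut-off maximises Youden's
#' J = sensitivity + specificity - 1, ties broken toward higher specificity
#' (the larger threshold). The 95% AUC confidence interval is DeLong's
#' normal approximation (bounds may exceed \[0, 1\], as such intervals do).
#'
#' @param scores numeric vector.
#' @param labels binary class labels (logical, 0/1 numeric, or a two-level
#'   factor/character whose larger level is the positive class).
#' @return an [ROCResult-class].
#' @export
rocYouden <- function(scores, labels) {
  lab <- .binaryLabels(labels)
  ok <- is.finite(scores) & !is.na(lab)
  scores <- scores[ok]; lab <- lab[ok]
  nPos <- sum(lab == 1L); nNeg <- sum(lab == 0L)
  if (nPos == 0L || nNeg == 0L) stop("single-class labels")

  r <- rank(scores)
  auc <- (sum(r[lab == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)

  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2 else numeric()
  cand <- c(s[1L] - 1, cand, s[length(s)] + 1)
  sens <- vapply(cand, function(ct) mean(scores[lab == 1L] >= ct), 0)
  spec <- vapply(cand, function(ct) mean(scores[lab == 0L] < ct), 0)
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[length(best)]  # larger threshold = higher specificity

  ci <- tryCatch(
    as.numeric(suppressWarnings(pROC::ci.auc(
      pROC::roc(response = lab, predictor = scores, levels = c(0L, 1L),
                direction = "<", quiet = TRUE),
      method = "delong")))[c(1L, 3L)],
    error = function(e) c(NA_real_, NA_real_))

  methods::new("ROCResult", auc = auc, ci = ci, cutoff = cand[best],
               sensitivity = 100 * sens[best], specificity = 100 * spec[best],
               youden = J[best], band = aucBand(auc),
               nPos = nPos, nNeg = nNeg)
}
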