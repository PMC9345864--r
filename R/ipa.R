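# The summary index. IPA is a fixed weighted sum of the six features; the
# weights are the published feature importances of the upstream
# decision-tree model and are used exactly as printed (they sum to 100.3%;
# renormalising would break the published worked examples).

#' Published feature weights for the index
#'
#' `IPA = 0.132 F1 + 0.126 F2 + 0.165 F3 + 0.113 F4 + 0.067 F5 + 0.400 F7`.
#'
#' @param F1,F2,F3,F4,F5,F7 weight overrides, unitless fractions >= 0.
#' @return named numeric vector of weights.
#' @export
ipaWeights <- function(F1 = 0.132, F2 = 0.126, F3 = 0.165, F4 = 0.113,
                       F5 = 0.067, F7 = 0.400) {
  w <- c(F1 = F1, F2 = F2, F3 = F3, F4 = F4, F5 = F5, F7 = F7)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  w
}

#' Published screening cut-offs for the index
#'
#' 12.96 separates PD patients from healthy controls; 20.14 separates PD
#' with postural abnormalities from PD without.
#'
#' @param pd,pa cut-off overrides, positive scores.
#' @return named numeric vector `c(pd=, pa=)`.
#' @export
ipaCutoffs <- function(pd = 12.96, pa = 20.14) {
  co <- c(pd = pd, pa = pa)
  if (any(!is.finite(co)) || any(co <= 0)) stop("cutoffs must be positive")
  co
}

.featureMatrix <- function(fv) {
  if (methods::is(fv, "FeatureVector"))
    return(matrix(featureValues(fv), 1L, dimnames = list(NULL, featureNames())))
  if (is.data.frame(fv)) {
    miss <- setdiff(featureNames(), names(fv))
    if (length(miss)) stop("missing feature column(s): ",
                           paste(miss, collapse = ", "))
    return(as.matrix(fv[, featureNames(), drop = FALSE]))
  }
  if (is.numeric(fv) && !is.null(names(fv)) &&
      all(featureNames() %in% names(fv)))
    return(matrix(fv[featureNames()], 1L,
                  dimnames = list(NULL, featureNames())))
  stop("fv must be a FeatureVector, a named numeric vector, or a data.frame")
}

#' Compute the index for postural abnormalities
#'
#' Linear, deterministic weighted sum of the six features. Because the index
#' is linear, the mean index of a cohort equals the index of the cohort's
#' mean feature vector.
#'
#' @param fv a [FeatureVector-class], a named numeric vector with elements
#'   `F1..F5, F7`, or a data.frame with those columns (one score per row).
#' @param weights feature weights, see [ipaWeights()].
#' @return numeric vector of index scores.
#' @examples
#' computeIPA(c(F1 = 1.9, F2 = 0.3, F3 = 10.5, F4 = 7.0, F5 = 3.1, F7 = 12.5))
#' @export
computeIPA <- function(fv, weights = ipaWeights()) {
  if (!identical(names(weights), featureNames()))
    stop("weights must be named F1 F2 F3 F4 F5 F7")
  drop(.featureMatrix(fv) %*% weights)
}

#' Classify index scores against the screening cut-offs
#'
#' Boundary scores classify positive (score >= cut-off).
#'
#' @param ipa numeric vector of index scores (or an [IPAResult-class] to
#'   re-classify).
#' @param cutoffs see [ipaCutoffs()].
#' @param weights weights recorded alongside the result.
#' @return an [IPAResult-class].
#' @export
classifyIPA <- function(ipa, cutoffs = ipaCutoffs(), weights = ipaWeights()) {
  if (methods::is(ipa, "IPAResult")) ipa <- ipaScore(ipa)
  if (!is.numeric(ipa) || any(!is.finite(ipa))) stop("ipa must be finite")
  ipa <- as.vector(ipa, "numeric")
  methods::new("IPAResult", ipa = ipa,
               pdLike = unname(ipa >= cutoffs["pd"]),
               paLike = unname(ipa >= cutoffs["pa"]),
               cutoffs = cutoffs, weights = weights)
}

#' Append index scores and classifications to a cohort table
#'
#' @param cohort data.frame with the six feature columns.
#' @param weights,cutoffs see [ipaWeights()], [ipaCutoffs()].
#' @param labels also append logical `pd_like` / `pa_like` columns.
#' @return the cohort with an `IPA` column (and optionally the labels).
#' @export
addIPA <- function(cohort, weights = ipaWeights(), cutoffs = ipaCutoffs(),
                   labels = FALSE) {
  cohort$IPA <- computeIPA(cohort, weights)
  if (labels) {
    res <- classifyIPA(cohort$IPA, cutoffs, weights)
    cohort$pd_like <- isPDLike(res)
    cohort$pa_like <- isPALike(res)
  }
  cohort
}
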