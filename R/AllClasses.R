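# Central S4 containers. Landmark recordings are stored long (one row per
# landmark per frame) so that IO, validity checks and feature extraction can
# all be vectorised over frames.

#' Anatomical landmark names
#'
#' The six body landmarks the posture features are defined on: midpoint of
#' head (MH), midpoint of neck (MN), 7th cervical spinous process (C7),
#' 5th lumbar spinous process (L5), vertebral fulcrum (FC, the most convex
#' point of the spine), and lateral malleolus (LM).
#' @export
landmarkNames <- function() c("MH", "MN", "C7", "L5", "FC", "LM")

#' Feature names
#'
#' Names of the six posture features: F1 lateral head flexion, F2 lateral
#' trunk flexion (coronal plane, degrees); F3 forward head flexion, F4 total
#' forward trunk flexion, F5 forward trunk flexion at the waist (sagittal
#' plane, degrees); F7 normalised spine convexity 100*D1/D2 (percent).
#' @export
featureNames <- function() c("F1", "F2", "F3", "F4", "F5", "F7")

.views <- c("frontal", "lateral")
.windowNames <- c("frontal_relaxed", "frontal_corrected",
                  "lateral_relaxed", "lateral_corrected")
.frameCols <- c("time_s", "view", "landmark", "x_m", "y_m", "z_m")

#' PostureSession: one recorded standing-posture session
#'
#' Holds the timestamped 3D landmark positions of one subject over the
#' acquisition protocol (relaxed and actively corrected stance, recorded
#' frontally and after a 90 degree turn laterally), plus the protocol window
#' boundaries. Coordinates are metres, X lateral, Y vertical up, Z camera
#' depth toward the subject.
#'
#' @slot subjectId character scalar.
#' @slot frames data.frame with columns `time_s`, `view`, `landmark`,
#'   `x_m`, `y_m`, `z_m`; one row per landmark per frame; every frame carries
#'   all six landmarks.
#' @slot windows data.frame with columns `window`, `start_s`, `end_s`;
#'   half-open intervals `[start, end)`, non-overlapping, each containing at
#'   least one frame of the matching view.
#' @export
setClass("PostureSession",
         slots = c(subjectId = "character",
                   frames = "data.frame",
                   windows = "data.frame"))

setValidity("PostureSession", function(object) {
  fr <- object@frames
  win <- object@windows
  if (length(object@subjectId) != 1L || is.na(object@subjectId))
    return("subjectId must be a single non-missing string")
  if (!all(.frameCols %in% names(fr)))
    return(paste("frames must have columns", paste(.frameCols, collapse = ", ")))
  if (nrow(fr) == 0L) return("session has no frames")
  coords <- as.matrix(fr[, c("x_m", "y_m", "z_m")])
  if (!all(is.finite(coords))) return("non-finite landmark coordinate")
  if (!is.numeric(fr$time_s) || any(!is.finite(fr$time_s)) || any(fr$time_s < 0))
    return("frame times must be finite and >= 0")
  if (!all(fr$view %in% .views)) return("view must be 'frontal' or 'lateral'")
  if (!all(fr$landmark %in% landmarkNames())) return("unknown landmark name")
  if (nrow(fr) %% 6L != 0L) return("incomplete frame: not all landmarks present")
  ord <- order(fr$view, fr$time_s, fr$landmark)
  d <- fr[ord, ]
  n6 <- nrow(d) / 6L
  blockLm <- matrix(d$landmark, nrow = 6L)
  if (!all(blockLm == sort(landmarkNames())))
    return("each frame must contain each of the six landmarks exactly once")
  blockT <- matrix(d$time_s, nrow = 6L)
  if (any(blockT != rep(blockT[1L, ], each = 6L)))
    return("each frame must contain each of the six landmarks exactly once")
  # alphabetical block order: C7 FC L5 LM MH MN
  yL5 <- d$y_m[seq(3L, by = 6L, length.out = n6)]
  yLM <- d$y_m[seq(4L, by = 6L, length.out = n6)]
  yMH <- d$y_m[seq(5L, by = 6L, length.out = n6)]
  if (!all(yMH > yL5 & yL5 > yLM))
    return("standing-subject ordering violated: need Y(MH) > Y(L5) > Y(LM)")
  if (!all(c("window", "start_s", "end_s") %in% names(win)))
    return("windows must have columns window, start_s, end_s")
  if (nrow(win) > 0L) {
    if (!all(win$window %in% .windowNames)) return("unknown window name")
    if (anyDuplicated(win$window)) return("duplicate window name")
    if (any(win$end_s <= win$start_s)) return("window end must exceed start")
    w <- win[order(win$start_s), ]
    if (nrow(w) > 1L && any(w$start_s[-1L] < w$end_s[-nrow(w)]))
      return("windows overlap")
    for (i in seq_len(nrow(win))) {
      v <- sub("_.*$", "", win$window[i])
      hit <- fr$view == v & fr$time_s >= win$start_s[i] & fr$time_s < win$end_s[i]
      if (!any(hit))
        return(sprintf("window '%s' contains no frames", win$window[i]))
    }
  }
  TRUE
})

#' Construct a PostureSession
#'
#' @param subjectId subject identifier.
#' @param frames long-format landmark table (see [PostureSession-class]).
#' @param windows protocol window table; defaults to windows inferred by the
#'   acquisition protocol via [inferWindows()].
#' @return a validated [PostureSession-class] object.
#' @export
postureSession <- function(subjectId, frames, windows = inferWindows(frames)) {
  frames <- as.data.frame(frames)
  windows <- as.data.frame(windows)
  methods::new("PostureSession", subjectId = as.character(subjectId),
               frames = frames, windows = windows)
}

#' @describeIn PostureSession-class compact display.
#' @param object a `PostureSession`.
#' @export
setMethod("show", "PostureSession", function(object) {
  nf <- nrow(object@frames) / 6L
  cat("PostureSession '", object@subjectId, "': ", nf, " frames, ",
      nrow(object@windows), " windows (",
      paste(object@windows$window, collapse = ", "), ")\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("subjectId", "PostureSession", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("sessionFrames", "PostureSession", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("sessionWindows", "PostureSession", function(x) x@windows)

#' FeatureVector: the six posture features of one session
#'
#' F1--F5 are angles in degrees, F7 is a percentage; each is the median over
#' the frames of its protocol window, with the number of frames used recorded
#' per feature.
#'
#' @slot values named numeric, names `F1 F2 F3 F4 F5 F7`.
#' @slot frameCounts named integer, frames contributing to each feature.
#' @slot aggregate aggregation rule applied over frames ("median").
#' @slot windowPolicy which stance fed the features ("relaxed" or "corrected").
#' @export
setClass("FeatureVector",
         slots = c(values = "numeric", frameCounts = "integer",
                   aggregate = "character", windowPolicy = "character"))

setValidity("FeatureVector", function(object) {
  v <- object@values
  if (!identical(names(v), featureNames()))
    return("values must be named F1 F2 F3 F4 F5 F7")
  if (any(!is.finite(v))) return("non-finite feature value")
  if (any(v[c("F1", "F2", "F3")] < 0) || any(v[c("F1", "F2", "F3")] > 90))
    return("F1, F2, F3 must lie in [0, 90] degrees")
  if (any(v[c("F4", "F5")] < 0) || any(v[c("F4", "F5")] > 180))
    return("F4, F5 must lie in [0, 180] degrees")
  if (v["F7"] < 0) return("F7 must be >= 0")
  if (!identical(names(object@frameCounts), featureNames()))
    return("frameCounts must be named F1 F2 F3 F4 F5 F7")
  if (any(object@frameCounts < 1L)) return("each feature needs >= 1 frame")
  TRUE
})

#' @describeIn FeatureVector-class compact display.
#' @param object a `FeatureVector`.
#' @export
setMethod("show", "FeatureVector", function(object) {
  cat("FeatureVector (", object@aggregate, " over ", object@windowPolicy,
      " windows):\n", sep = "")
  print(round(object@values, 3))
})

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureVector", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("frameCounts", "FeatureVector", function(x) x@frameCounts)

#' IPAResult: index scores with cut-off classifications
#'
#' The index for postural abnormalities (IPA) for one or more subjects,
#' together with the two screening classifications: `pdLike` (score at or
#' above the PD-vs-control cut-off, default 12.96) and `paLike` (score at or
#' above the with-vs-without-postural-abnormality cut-off, default 20.14).
#' Boundary scores classify positive.
#'
#' @slot ipa numeric vector of scores.
#' @slot pdLike,paLike logical vectors parallel to `ipa`.
#' @slot cutoffs named numeric `c(pd = ..., pa = ...)`.
#' @slot weights the feature weights used.
#' @export
setClass("IPAResult",
         slots = c(ipa = "numeric", pdLike = "logical", paLike = "logical",
                   cutoffs = "numeric", weights = "numeric"))

setValidity("IPAResult", function(object) {
  n <- length(object@ipa)
  if (length(object@pdLike) != n || length(object@paLike) != n)
    return("ipa, pdLike, paLike must have equal length")
  if (!identical(names(object@cutoffs), c("pd", "pa")))
    return("cutoffs must be named c(pd=, pa=)")
  if (any(object@cutoffs <= 0)) return("cutoffs must be positive")
  TRUE
})

#' @describeIn IPAResult-class compact display.
#' @param object an `IPAResult`.
#' @export
setMethod("show", "IPAResult", function(object) {
  cat("IPAResult: ", length(object@ipa), " score(s); cutoffs pd=",
      object@cutoffs["pd"], ", pa=", object@cutoffs["pa"], "\n", sep = "")
  print(utils::head(data.frame(ipa = object@ipa, pd_like = object@pdLike,
                               pa_like = object@paLike)))
})

#' @rdname accessors
#' @export
setMethod("ipaScore", "IPAResult", function(x) x@ipa)

#' @rdname accessors
#' @export
setMethod("isPDLike", "IPAResult", function(x) x@pdLike)

#' @rdname accessors
#' @export
setMethod("isPALike", "IPAResult", function(x) x@paLike)

#' ROCResult: ROC summary with Youden-optimal cut-off
#'
#' @slot auc area under the empirical ROC curve (Mann-Whitney formulation,
#'   ties counted one half).
#' @slot ci DeLong 95 percent confidence interval for the AUC (normal
#'   approximation; bounds may exceed \[0, 1\]).
#' @slot cutoff threshold maximising Youden's J (ties broken toward higher
#'   specificity); scores at or above the cut-off classify positive.
#' @slot sensitivity,specificity percent, at the optimal cut-off.
#' @slot youden J = sensitivity + specificity - 1 (as fractions).
#' @slot band diagnostic-accuracy band: below 0.7 "low", 0.7 to 0.9
#'   "moderate", above 0.9 "high".
#' @slot nPos,nNeg class sizes.
#' @export
setClass("ROCResult",
         slots = c(auc = "numeric", ci = "numeric", cutoff = "numeric",
                   sensitivity = "numeric", specificity = "numeric",
                   youden = "numeric", band = "character",
                   nPos = "integer", nNeg = "integer"))

setValidity("ROCResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  if (object@sensitivity < 0 || object@sensitivity > 100 ||
      object@specificity < 0 || object@specificity > 100)
    return("sensitivity/specificity must lie in [0, 100] percent")
  if (!object@band %in% c("low", "moderate", "high"))
    return("band must be low/moderate/high")
  if (!identical(object@band, aucBand(object@auc)))
    return("band inconsistent with auc")
  TRUE
})

#' @describeIn ROCResult-class compact display.
#' @param object an `ROCResult`.
#' @export
setMethod("show", "ROCResult", function(object) {
  cat(sprintf(paste0("ROCResult: AUC %.3f (95%% CI %.3f-%.3f, %s accuracy)\n",
                     "  cut-off %.4g: sensitivity %.2f%%, specificity %.2f%%,",
                     " Youden J %.3f  (n+ = %d, n- = %d)\n"),
              object@auc, object@ci[1], object@ci[2], object@band,
              object@cutoff, object@sensitivity, object@specificity,
              object@youden, object@nPos, object@nNeg))
})

#' @rdname accessors
#' @export
setMethod("aucValue", "ROCResult", function(x) x@auc)

#' @rdname accessors
#' @export
setMethod("optimalCutoff", "ROCResult", function(x) x@cutoff)

#' @rdname accessors
#' @export
setMethod("bandLabel", "ROCResult", function(x) x@band)

#' CorrelationResult: Spearman correlation with interpretation band
#'
#' @slot rs Spearman rank correlation coefficient.
#' @slot p two-tailed p-value.
#' @slot n number of complete pairs used.
#' @slot band qualitative band from |rs|: below 0.10 negligible, 0.10-0.40
#'   weak, 0.40-0.70 moderate, 0.70-0.90 strong, 0.90 and above very strong.
#' @export
setClass("CorrelationResult",
         slots = c(rs = "numeric", p = "numeric", n = "integer",
                   band = "character"))

setValidity("CorrelationResult", function(object) {
  if (abs(object@rs) > 1) return("rs must lie in [-1, 1]")
  if (!identical(object@band, correlationBand(object@rs)))
    return("band inconsistent with rs")
  TRUE
})

#' @describeIn CorrelationResult-class compact display.
#' @param object a `CorrelationResult`.
#' @export
setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Spearman rs = %.3f (%s), p = %.4g, n = %d\n",
              object@rs, object@band, object@p, object@n))
})

#' @rdname accessors
#' @export
setMethod("bandLabel", "CorrelationResult", function(x) x@band)

#' RegressionResult: simple linear regression summary
#'
#' @slot beta unstandardised slope.
#' @slot betaStd standardised slope (slope of the z-scored regression; equals
#'   the Pearson correlation in simple regression).
#' @slot r2 coefficient of determination.
#' @slot adjR2 adjusted R squared, `1 - (1 - R2) (n - 1) / (n - 2)`.
#' @slot p two-tailed p-value for the slope.
#' @slot intercept fitted intercept.
#' @slot n observations used.
#' @export
setClass("RegressionResult",
         slots = c(beta = "numeric", betaStd = "numeric", r2 = "numeric",
                   adjR2 = "numeric", p = "numeric", intercept = "numeric",
                   n = "integer"))

#' @describeIn RegressionResult-class compact display.
#' @param object a `RegressionResult`.
#' @export
setMethod("show", "RegressionResult", function(object) {
  cat(sprintf(paste0("Linear regression: beta = %.4g (std %.3f), ",
                     "adj R2 = %.4g, p = %.4g, n = %d\n"),
              object@beta, object@betaStd, object@adjR2, object@p, object@n))
})

#' GroupComparison: two-group test report
#'
#' Which test ran (normality-gated t versus Mann-Whitney, or chi-square for
#' categorical variables), its statistic and two-tailed p-value.
#'
#' @slot variable,groups what was compared.
#' @slot test one of "t", "mann-whitney", "chi-square".
#' @slot statistic test statistic.
#' @slot p two-tailed p-value.
#' @slot normal per-group normality-gate verdicts (NA for categorical).
#' @slot n per-group sample sizes.
#' @export
setClass("GroupComparison",
         slots = c(variable = "character", groups = "character",
                   test = "character", statistic = "numeric", p = "numeric",
                   normal = "logical", n = "integer"))

#' @describeIn GroupComparison-class compact display.
#' @param object a `GroupComparison`.
#' @export
setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("%s, %s vs %s: %s test, statistic = %.4g, p = %.4g\n",
              object@variable, object@groups[1], object@groups[2],
              object@test, object@statistic, object@p))
})
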