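# Feature extraction. Coronal-plane features (F1, F2) come from the
# frontal-view window, sagittal-plane features (F3, F4, F5, F7) from the
# lateral-view window of the selected stance; each feature is the median
# over its window's frames, robust to transient tracking glitches.

.windowFrames <- function(session, windowName) {
  win <- sessionWindows(session)
  row <- win[win$window == windowName, , drop = FALSE]
  if (nrow(row) == 0L)
    stop(sprintf("empty window: '%s' is not declared in this session",
                 windowName))
  fr <- sessionFrames(session)
  v <- sub("_.*$", "", windowName)
  fr <- fr[fr$view == v & fr$time_s >= row$start_s & fr$time_s < row$end_s, ]
  if (nrow(fr) == 0L)
    stop(sprintf("empty window: '%s' contains no frames", windowName))
  fr[order(fr$time_s), ]
}

# n_frames x 2 in-plane matrix for one landmark over a window's frames
.landmarkPlane <- function(fr, landmark, plane) {
  rows <- fr[fr$landmark == landmark, ]
  projectPoint(as.matrix(rows[, c("x_m", "y_m", "z_m")]), plane)
}

#' Extract the six posture features from a session
#'
#' Per frontal-view frame: F1 is the angle between the MH-C7 line and the
#' vertical, F2 between the C7-L5 line and the vertical, both on the coronal
#' projection. Per lateral-view frame, on the sagittal projection: F3 is the
#' MH-MN line angle to the vertical; F4 the deviation-from-collinearity
#' angle between the L5-LM and L5-C7 lines; F5 the same between L5-LM and
#' L5-FC; F7 is 100 times the perpendicular distance from FC to the
#' (infinite) C7-L5 line, divided by the C7-L5 distance. Each feature is the
#' median over its window's frames; frames with degenerate geometry are
#' dropped with a warning.
#'
#' @param session a [PostureSession-class].
#' @param windowPolicy which stance to use: `"relaxed"` (habitual posture,
#'   the default) or `"corrected"`.
#' @return a [FeatureVector-class].
#' @export
computeFeatures <- function(session, windowPolicy = c("relaxed", "corrected")) {
  windowPolicy <- match.arg(windowPolicy)
  frF <- .windowFrames(session, paste0("frontal_", windowPolicy))
  frL <- .windowFrames(session, paste0("lateral_", windowPolicy))

  MHc <- .landmarkPlane(frF, "MH", "coronal")
  C7c <- .landmarkPlane(frF, "C7", "coronal")
  L5c <- .landmarkPlane(frF, "L5", "coronal")
  f1 <- .angleToVerticalSafe(MHc, C7c)
  f2 <- .angleToVerticalSafe(C7c, L5c)
  okF <- is.finite(f1) & is.finite(f2)

  MHs <- .landmarkPlane(frL, "MH", "sagittal")
  MNs <- .landmarkPlane(frL, "MN", "sagittal")
  C7s <- .landmarkPlane(frL, "C7", "sagittal")
  L5s <- .landmarkPlane(frL, "L5", "sagittal")
  FCs <- .landmarkPlane(frL, "FC", "sagittal")
  LMs <- .landmarkPlane(frL, "LM", "sagittal")
  f3 <- .angleToVerticalSafe(MHs, MNs)
  f4 <- .angleBetweenSafe(L5s, LMs, L5s, C7s)
  f5 <- .angleBetweenSafe(L5s, LMs, L5s, FCs)
  d2 <- sqrt(rowSums((C7s - L5s)^2))
  f7 <- 100 * .perpDistanceSafe(FCs, C7s, L5s) / d2
  f7[d2 == 0] <- NA_real_
  okL <- is.finite(f3) & is.finite(f4) & is.finite(f5) & is.finite(f7)

  nBad <- sum(!okF) + sum(!okL)
  if (nBad > 0L)
    warning(sprintf("excluded %d frame(s) with degenerate geometry", nBad))
  if (!any(okF))
    stop(sprintf("all frames of window 'frontal_%s' are degenerate",
                 windowPolicy))
  if (!any(okL))
    stop(sprintf("all frames of window 'lateral_%s' are degenerate",
                 windowPolicy))

  vals <- c(F1 = stats::median(f1[okF]), F2 = stats::median(f2[okF]),
            F3 = stats::median(f3[okL]), F4 = stats::median(f4[okL]),
            F5 = stats::median(f5[okL]), F7 = stats::median(f7[okL]))
  counts <- c(F1 = sum(okF), F2 = sum(okF), F3 = sum(okL), F4 = sum(okL),
              F5 = sum(okL), F7 = sum(okL))
  storage.mode(counts) <- "integer"
  methods::new("FeatureVector", values = vals, frameCounts = counts,
               aggregate = "median", windowPolicy = windowPolicy)
}
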