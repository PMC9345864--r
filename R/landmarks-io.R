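# Recording IO. Two dialects are supported: a long landmark CSV
# (time_s,view,landmark,x_m,y_m,z_m; '#'-prefixed metadata lines may declare
# the subject and protocol windows) and Kinect-v2 skeleton JSONL (one JSON
# object per line with time_s, view and a joints map), from which the six
# anatomical landmarks are derived per frame. Numbers are written with 17
# significant digits so write/read round-trips are exact.

.fmtNum <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Infer protocol windows from frame times
#'
#' The acquisition protocol records 5 s of relaxed stance followed by 5 s of
#' actively corrected stance per view. When a file carries no window
#' metadata, windows are inferred per view from its earliest frame time:
#' `[t0, t0 + 5)` relaxed and `[t0 + 5, t0 + 10)` corrected; only windows
#' actually containing frames are declared.
#'
#' @param frames long-format landmark frame table.
#' @param windowLength window length in seconds (protocol default 5).
#' @return a window table with columns `window`, `start_s`, `end_s`.
#' @export
inferWindows <- function(frames, windowLength = 5) {
  out <- list()
  for (v in intersect(.views, unique(frames$view))) {
    tv <- frames$time_s[frames$view == v]
    t0 <- min(tv)
    for (phase in c("relaxed", "corrected")) {
      s <- if (phase == "relaxed") t0 else t0 + windowLength
      e <- s + windowLength
      if (any(tv >= s & tv < e))
        out[[length(out) + 1L]] <- data.frame(
          window = paste(v, phase, sep = "_"), start_s = s, end_s = e)
    }
  }
  if (!length(out))
    return(data.frame(window = character(), start_s = numeric(),
                      end_s = numeric()))
  do.call(rbind, out)
}

.checkFrameCompleteness <- function(frames) {
  key <- paste(frames$view, format(frames$time_s, digits = 17))
  byFrame <- split(seq_len(nrow(frames)), key)
  for (idx in byFrame) {
    have <- frames$landmark[idx]
    miss <- setdiff(landmarkNames(), have)
    if (length(miss))
      stop(sprintf("missing landmark '%s' in %s frame at time %g s",
                   miss[1L], frames$view[idx[1L]], frames$time_s[idx[1L]]))
    if (anyDuplicated(have))
      stop(sprintf("duplicated landmark '%s' at time %g s",
                   have[anyDuplicated(have)], frames$time_s[idx[1L]]))
    bad <- !is.finite(as.matrix(frames[idx, c("x_m", "y_m", "z_m")]))
    if (any(bad)) {
      r <- idx[which(rowSums(bad) > 0)[1L]]
      stop(sprintf("non-finite coordinate for landmark '%s' at time %g s",
                   frames$landmark[r], frames$time_s[r]))
    }
  }
  invisible(TRUE)
}

.parseMetaLines <- function(lines) {
  meta <- list(subject = NULL, windows = NULL)
  sub <- grep("^#\\s*subject:", lines, value = TRUE)
  if (length(sub))
    meta$subject <- trimws(sub("^#\\s*subject:", "", sub[1L]))
  wl <- grep("^#\\s*window:", lines, value = TRUE)
  if (length(wl)) {
    parts <- strsplit(trimws(sub("^#\\s*window:", "", wl)), "\\s+")
    meta$windows <- data.frame(
      window = vapply(parts, `[`, "", 1L),
      start_s = as.numeric(vapply(parts, `[`, "", 2L)),
      end_s = as.numeric(vapply(parts, `[`, "", 3L)))
  }
  meta
}

#' Read a landmark or skeleton recording
#'
#' @param path file to read.
#' @param dialect `"landmark_csv"` (long CSV of the six anatomical landmarks)
#'   or `"kinect_json"` (JSONL of 25-joint Kinect-v2 skeleton frames, from
#'   which landmarks are derived via [deriveLandmarks()]).
#' @param subjectId subject identifier; defaults to file metadata, else the
#'   file name.
#' @param mapping landmark-to-joint mapping passed to [deriveLandmarks()]
#'   (kinect_json only).
#' @return a validated [PostureSession-class]. Window boundaries come from
#'   file metadata when present, otherwise from [inferWindows()].
#' @export
readLandmarks <- function(path, dialect = c("landmark_csv", "kinect_json"),
                          subjectId = NULL, mapping = defaultJointMapping()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "landmark_csv") {
    meta <- .parseMetaLines(lines)
    body <- lines[!startsWith(lines, "#")]
    frames <- utils::read.csv(text = paste(body, collapse = "\n"),
                              stringsAsFactors = FALSE)
    need <- .frameCols
    if (!all(need %in% names(frames)))
      stop("landmark_csv must have columns ", paste(need, collapse = ","))
    .checkFrameCompleteness(frames)
  } else {
    meta <- list(subject = NULL, windows = NULL)
    rows <- list()
    for (ln in lines[nzchar(trimws(lines))]) {
      obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
      if (is.null(obj$time_s) && !is.null(obj$windows)) {
        meta$windows <- data.frame(
          window = names(obj$windows),
          start_s = vapply(obj$windows, `[`, 0, 1L),
          end_s = vapply(obj$windows, `[`, 0, 2L))
        if (!is.null(obj$subject)) meta$subject <- obj$subject
        next
      }
      joints <- do.call(rbind, obj$joints)
      lm <- tryCatch(deriveLandmarks(joints, mapping = mapping),
                     error = function(e)
                       stop(sprintf("frame at time %g s: %s", obj$time_s,
                                    conditionMessage(e)), call. = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = obj$time_s, view = obj$view, landmark = rownames(lm),
        x_m = lm[, 1L], y_m = lm[, 2L], z_m = lm[, 3L])
    }
    if (!length(rows)) stop("no skeleton frames in ", path)
    frames <- do.call(rbind, rows)
    rownames(frames) <- NULL
  }
  sid <- subjectId %||% meta$subject %||%
    tools::file_path_sans_ext(basename(path))
  win <- if (!is.null(meta$windows)) meta$windows else inferWindows(frames)
  postureSession(sid, frames, win)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a session as landmark CSV
#'
#' Emits `#subject:` and `#window:` metadata lines followed by the long CSV
#' body. Re-reading with [readLandmarks()] reproduces the session exactly.
#'
#' @param session a [PostureSession-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(session, path) {
  stopifnot(methods::is(session, "PostureSession"))
  fr <- sessionFrames(session)
  win <- sessionWindows(session)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#subject: ", subjectId(session)), con)
  if (nrow(win))
    writeLines(sprintf("#window: %s %.17g %.17g", win$window, win$start_s,
                       win$end_s), con)
  writeLines(paste(.frameCols, collapse = ","), con)
  writeLines(paste(.fmtNum(fr$time_s), fr$view, fr$landmark, .fmtNum(fr$x_m),
                   .fmtNum(fr$y_m), .fmtNum(fr$z_m), sep = ","), con)
  invisible(path)
}

#' Default Kinect-v2 joint mapping for the anatomical landmarks
#'
#' MH (midpoint of head) maps to Head, MN (midpoint of neck) to Neck, C7 to
#' SpineShoulder, L5 to SpineBase. LM is the midpoint of the available ankle
#' joints and FC is found on a spine curve, so neither appears here.
#' @export
defaultJointMapping <- function()
  c(MH = "Head", MN = "Neck", C7 = "SpineShoulder", L5 = "SpineBase")

#' Derive the six anatomical landmarks from a Kinect-v2 skeleton frame
#'
#' Directly mapped landmarks follow `mapping`. LM is the midpoint of
#' AnkleLeft and AnkleRight (a single ankle is used if only one is tracked).
#' FC, the vertebral fulcrum (most convex point of the spine), is located by
#' sampling a quadratic Bezier curve with control points SpineShoulder,
#' SpineMid, SpineBase at `nSamples` equally spaced parameter values and
#' taking the sample of maximal perpendicular distance to the C7-L5 line,
#' evaluated in the sagittal (depth-vertical) projection; ties break toward
#' the more cranial sample.
#'
#' @param joints named list or matrix (rownames = Kinect joint names) of 3D
#'   positions in metres.
#' @param mapping named character vector, landmark name to joint name.
#' @param nSamples Bezier samples for the FC search.
#' @return a 6 x 3 matrix of landmark positions, rows in
#'   [landmarkNames()] order.
#' @export
deriveLandmarks <- function(joints, mapping = defaultJointMapping(),
                            nSamples = 51L) {
  if (!is.matrix(joints)) joints <- do.call(rbind, as.list(joints))
  spine <- c("SpineShoulder", "SpineMid", "SpineBase")
  for (j in unique(c(unname(mapping), spine))) {
    if (!j %in% rownames(joints)) stop("missing joint '", j, "'")
    if (!all(is.finite(joints[j, ])))
      stop("non-finite coordinate for joint '", j, "'")
  }
  ank <- intersect(c("AnkleLeft", "AnkleRight"), rownames(joints))
  ank <- ank[vapply(ank, function(a) all(is.finite(joints[a, ])), TRUE)]
  if (!length(ank)) stop("both ankles missing")
  out <- matrix(NA_real_, 6L, 3L, dimnames = list(landmarkNames(), NULL))
  for (lmk in names(mapping)) out[lmk, ] <- joints[mapping[lmk], ]
  out["LM", ] <- colMeans(joints[ank, , drop = FALSE])
  out["FC", ] <- .spineFulcrum(joints[spine[1L], ], joints[spine[2L], ],
                               joints[spine[3L], ], out["C7", ], out["L5", ],
                               nSamples)
  out
}

# Quadratic Bezier B(t) = (1-t)^2 P0 + 2t(1-t) P1 + t^2 P2, t = 0 at the
# cranial end; distance to the C7-L5 line is measured in the sagittal (Z, Y)
# projection. Ties (within floating tolerance, e.g. a collinear spine where
# every sample is at distance 0) break toward the most cranial sample.
.spineFulcrum <- function(p0, p1, p2, c7, l5, nSamples = 51L) {
  t <- seq(0, 1, length.out = nSamples)
  B <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  bp <- cbind(B[, 3L], B[, 2L])
  c7p <- c(c7[3L], c7[2L])
  l5p <- c(l5[3L], l5[2L])
  if (all(c7p == l5p)) stop("degenerate spine: C7 and L5 coincide sagittally")
  d <- .perpDistanceSafe(bp, matrix(c7p, nSamples, 2L, byrow = TRUE),
                         matrix(l5p, nSamples, 2L, byrow = TRUE))
  B[which(d >= max(d) - 1e-12)[1L], ]
}

#' Write a cohort feature table as CSV
#'
#' Canonical column order: `subject_id`, `group`, the six features, `IPA`,
#' then any clinical-scale columns in their original order. Missing values
#' are written as empty cells; numeric values keep full precision, so
#' [readFeatures()] reproduces the table exactly.
#'
#' @param table cohort data.frame with at least a `subject_id` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(table, path) {
  table <- as.data.frame(table)
  if (!"subject_id" %in% names(table))
    stop("cohort table needs a 'subject_id' column")
  core <- intersect(c("subject_id", "group", featureNames(), "IPA"),
                    names(table))
  table <- table[, c(core, setdiff(names(table), core)), drop = FALSE]
  cols <- lapply(table, function(x) {
    if (is.numeric(x)) .fmtNum(x) else ifelse(is.na(x), "", as.character(x))
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(table), collapse = ","), con)
  if (nrow(table))
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' Read a cohort feature table written by [writeFeatures()]
#'
#' @param path CSV file.
#' @return a cohort data.frame; `subject_id` and `group` as character,
#'   everything else numeric.
#' @export
readFeatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (nm in intersect(c("subject_id", "group"), names(tab)))
    tab[[nm]] <- as.character(tab[[nm]])
  for (nm in setdiff(names(tab), c("subject_id", "group"))) {
    if (is.integer(tab[[nm]])) tab[[nm]] <- as.numeric(tab[[nm]])
    # an all-empty column carries no type information; treat as numeric
    if (is.logical(tab[[nm]]) && all(is.na(tab[[nm]])))
      tab[[nm]] <- as.numeric(tab[[nm]])
  }
  tab
}
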