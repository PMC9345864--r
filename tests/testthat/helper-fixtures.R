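# Fixtures are built in code. Random generators assume the caller has fixed
# the RNG state with set.seed().

# A random satisfiable target set: F4 - F5 >= 8 degrees keeps the fulcrum
# distance under the anatomical bound for F7 up to 150*sin(F4 - F5).
randomTargets <- function() {
  F4 <- runif(1, 8, 40)
  F5 <- runif(1, 0, F4 - 8)
  F7 <- runif(1, 0.5, min(35, 150 * sin((F4 - F5) * pi / 180)))
  featureTargets(F1 = runif(1, 0, 15), F2 = runif(1, 0, 10),
                 F3 = runif(1, 0, 50), F4 = F4, F5 = F5, F7 = F7)
}

# One random valid landmark layout per view as a named list of 3D points.
randomLandmarks <- function(view) {
  L5 <- c(runif(1, -0.1, 0.1), runif(1, 0.85, 0.95), runif(1, 1.9, 2.1))
  LM <- L5 + c(runif(1, -0.1, 0.1), -runif(1, 0.7, 0.9), runif(1, -0.1, 0.1))
  C7 <- L5 + c(runif(1, -0.2, 0.2), runif(1, 0.4, 0.55), runif(1, -0.3, 0.3))
  MH <- C7 + c(runif(1, -0.15, 0.15), runif(1, 0.15, 0.3),
               runif(1, -0.15, 0.15))
  MN <- C7 + 0.55 * (MH - C7) + c(runif(1, -0.02, 0.02), 0,
                                  runif(1, -0.02, 0.02))
  FC <- L5 + 0.5 * (C7 - L5) + c(runif(1, -0.05, 0.05), 0,
                                 runif(1, 0.005, 0.08))
  list(MH = MH, MN = MN, C7 = C7, L5 = L5, FC = FC, LM = LM)
}

framesFromLandmarks <- function(lms, time, view) {
  m <- do.call(rbind, lms[landmarkNames()])
  data.frame(time_s = time, view = view, landmark = landmarkNames(),
             x_m = m[, 1], y_m = m[, 2], z_m = m[, 3])
}

# Session with one random frontal and one random lateral frame.
randomSession <- function(id = "r") {
  fr <- rbind(framesFromLandmarks(randomLandmarks("frontal"), 0, "frontal"),
              framesFromLandmarks(randomLandmarks("lateral"), 10, "lateral"))
  win <- data.frame(window = c("frontal_relaxed", "lateral_relaxed"),
                    start_s = c(0, 10), end_s = c(5, 15))
  postureSession(id, fr, win)
}

# Independent trigonometric feature oracle on two landmark lists: explicit
# dot/cross-product formulas, no shared code with computeFeatures.
oracleFeatures <- function(lmF, lmL) {
  deg <- 180 / pi
  corr <- function(p) c(p[1], p[2])        # coronal: (x, y)
  sag <- function(p) c(p[3], p[2])         # sagittal: (z, y)
  lineVert <- function(a, b) {
    d <- b - a
    atan2(abs(d[1]), abs(d[2])) * deg
  }
  open180 <- function(o, a, b) {
    u <- a - o; w <- b - o
    180 - acos(min(1, max(-1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * deg
  }
  pdist <- function(p, a, b) {
    d <- b - a
    abs(d[1] * (p[2] - a[2]) - d[2] * (p[1] - a[1])) / sqrt(sum(d^2))
  }
  c7 <- sag(lmL$C7); l5 <- sag(lmL$L5)
  c(F1 = lineVert(corr(lmF$MH), corr(lmF$C7)),
    F2 = lineVert(corr(lmF$C7), corr(lmF$L5)),
    F3 = lineVert(sag(lmL$MH), sag(lmL$MN)),
    F4 = open180(l5, sag(lmL$LM), c7),
    F5 = open180(l5, sag(lmL$LM), sag(lmL$FC)),
    F7 = 100 * pdist(sag(lmL$FC), c7, l5) / sqrt(sum((c7 - l5)^2)))
}

# Brute-force pair-count AUC oracle (ties one half).
aucByPairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden scan over every achievable threshold (score >= cutoff).
bestYoudenByScan <- function(scores, labels) {
  cand <- c(sort(unique(scores)), max(scores) + 1)
  best <- -Inf
  for (ct in cand) {
    J <- mean(scores[labels == 1] >= ct) + mean(scores[labels == 0] < ct) - 1
    if (J > best) best <- J
  }
  best
}
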