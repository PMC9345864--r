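test_that("a minimal landmark CSV parses with inferred protocol windows", {
  set.seed(31)
  fr <- rbind(framesFromLandmarks(randomLandmarks("frontal"), 0, "frontal"),
              framesFromLandmarks(randomLandmarks("frontal"), 1 / 30,
                                  "frontal"))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(fr, f, row.names = FALSE, quote = FALSE)
  s <- readLandmarks(f)
  expect_s4_class(s, "PostureSession")
  expect_equal(nrow(sessionFrames(s)) / 6, 2)
  expect_equal(sessionWindows(s)$window, "frontal_relaxed")
  expect_equal(sessionWindows(s)$start_s, 0)
})

test_that("a missing landmark is reported with its name and frame time", {
  set.seed(32)
  fr <- framesFromLandmarks(randomLandmarks("frontal"), 0.5, "frontal")
  fr <- fr[fr$landmark != "C7", ]
  f <- tempfile(fileext = ".csv")
  utils::write.csv(fr, f, row.names = FALSE, quote = FALSE)
  expect_error(readLandmarks(f), "C7.*0\\.5")
})

test_that("session write/read round-trips exactly, metadata included", {
  s <- makePosture(featureTargets(5, 2, 30, 20, 10, 25), noiseSd = 0.004,
                   seed = 33, framesPerWindow = 10L, subjectId = "rt01")
  f <- tempfile(fileext = ".csv")
  writeLandmarks(s, f)
  s2 <- readLandmarks(f)
  expect_equal(subjectId(s2), "rt01")
  expect_identical(sessionFrames(s2)$x_m, sessionFrames(s)$x_m)
  expect_identical(sessionFrames(s2)$y_m, sessionFrames(s)$y_m)
  expect_identical(sessionFrames(s2)$z_m, sessionFrames(s)$z_m)
  w1 <- sessionWindows(s); w2 <- sessionWindows(s2)
  rownames(w1) <- rownames(w2) <- NULL
  expect_equal(w2, w1)
})

test_that("kinect_json frames derive the anatomical landmarks", {
  joints <- list(Head = c(0, 1.7, 2.0), Neck = c(0, 1.5, 2.0),
                 SpineShoulder = c(0, 1.4, 2.0), SpineMid = c(0, 1.1, 2.0),
                 SpineBase = c(0, 0.8, 2.0), AnkleLeft = c(-0.1, 0.1, 2.0),
                 AnkleRight = c(0.1, 0.1, 2.0))
  line <- jsonlite::toJSON(list(time_s = 0, view = "lateral",
                                joints = joints), auto_unbox = TRUE)
  f <- tempfile(fileext = ".jsonl")
  writeLines(line, f)
  s <- readLandmarks(f, dialect = "kinect_json")
  fr <- sessionFrames(s)
  mh <- fr[fr$landmark == "MH", c("x_m", "y_m", "z_m")]
  expect_equal(unlist(mh, use.names = FALSE), c(0, 1.7, 2.0))
  lm <- fr[fr$landmark == "LM", c("x_m", "y_m", "z_m")]
  expect_equal(unlist(lm, use.names = FALSE), c(0, 0.1, 2.0))
  # collinear spine: any sample ties at distance 0, cranial-most wins
  fc <- fr[fr$landmark == "FC", c("x_m", "y_m", "z_m")]
  expect_equal(unlist(fc, use.names = FALSE), c(0, 1.4, 2.0))
  expect_error(readLandmarks(f, dialect = "nonsense"))
})

test_that("fulcrum search matches a dense brute-force curve search", {
  joints <- rbind(Head = c(0, 1.7, 2.0), Neck = c(0, 1.5, 2.0),
                  SpineShoulder = c(0, 1.4, 2.0), SpineMid = c(0, 1.1, 1.9),
                  SpineBase = c(0, 0.8, 2.0), AnkleLeft = c(0, 0.1, 2.0))
  lm <- deriveLandmarks(joints)
  # brute force: 10,001-point sampling of the same quadratic Bezier,
  # distance to the vertical line Z = 2 in the (Y, Z) projection
  t <- seq(0, 1, length.out = 10001)
  B <- outer((1 - t)^2, joints["SpineShoulder", ]) +
    outer(2 * t * (1 - t), joints["SpineMid", ]) +
    outer(t^2, joints["SpineBase", ])
  dBrute <- abs(B[, 3] - 2.0)
  d51 <- abs(unname(lm["FC", 3]) - 2.0)
  expect_lt(abs(max(dBrute) - d51), 1e-3)
  # for this symmetric spine the apex is exact: D1 = 0.05 at t = 0.5
  expect_equal(d51, 0.05, tolerance = 1e-12)
  expect_equal(unname(lm["FC", 2]), 1.1, tolerance = 1e-12)
})

test_that("fulcrum distances from 51- and 10,001-point searches agree on random smooth spines", {
  set.seed(35)
  for (i in 1:20) {
    p0 <- c(0, 1.4, 2.0) + rnorm(3, 0, 0.02)
    p1 <- c(0, 1.1, 1.9) + rnorm(3, 0, 0.04)
    p2 <- c(0, 0.8, 2.0) + rnorm(3, 0, 0.02)
    d1 <- function(n) {
      t <- seq(0, 1, length.out = n)
      B <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
      u <- c(p2[3] - p0[3], p2[2] - p0[2])
      max(abs(u[1] * (B[, 2] - p0[2]) - u[2] * (B[, 3] - p0[3])) /
            sqrt(sum(u^2)))
    }
    fc <- PostureIPA:::.spineFulcrum(p0, p1, p2, p0, p2, 51L)
    u <- c(p2[3] - p0[3], p2[2] - p0[2])
    d51 <- abs(u[1] * (fc[2] - p0[2]) - u[2] * (fc[3] - p0[3])) / sqrt(sum(u^2))
    expect_lt(abs(d1(10001L) - d51), 1e-3)
  }
})

test_that("landmark derivation is translation-invariant and needs an ankle", {
  set.seed(36)
  joints <- rbind(Head = c(0.02, 1.7, 2.0), Neck = c(0, 1.5, 1.98),
                  SpineShoulder = c(0, 1.4, 2.0), SpineMid = c(0, 1.1, 1.93),
                  SpineBase = c(0, 0.8, 2.0), AnkleLeft = c(-0.1, 0.1, 2.0),
                  AnkleRight = c(0.1, 0.1, 2.05))
  base <- deriveLandmarks(joints)
  for (i in 1:10) {
    shift <- rnorm(3, 0, 0.5)
    moved <- deriveLandmarks(sweep(joints, 2, -shift))
    expect_equal(moved, sweep(base, 2, -shift), tolerance = 1e-9)
  }
  expect_error(deriveLandmarks(joints[rownames(joints) != "SpineMid", ]),
               "SpineMid")
  noAnkles <- joints[!rownames(joints) %in% c("AnkleLeft", "AnkleRight"), ]
  expect_error(deriveLandmarks(noAnkles), "both ankles missing")
})

test_that("feature-table CSV round-trips, including missing clinical cells", {
  empty <- data.frame(subject_id = character(), group = character(),
                      F1 = numeric())
  f <- tempfile(fileext = ".csv")
  writeFeatures(empty, f)
  expect_length(readLines(f), 1L)

  tab <- data.frame(subject_id = c("a", "b", "c"),
                    group = c("HC", "PwtPA", "PwPA"),
                    F1 = c(1.234567891234, 2, 3), F2 = c(0.1, 0.2, 0.3),
                    F3 = c(10, 20, 30), F4 = c(5, 6, 7), F5 = c(1, 2, 3),
                    F7 = c(10, 20, 30), MMSE = c(28, NA, 26),
                    BBS = c(NA, 50, NA))
  tab <- addIPA(tab)
  writeFeatures(tab, f)
  back <- readFeatures(f)
  # canonical column order: ids, features, IPA, then scales
  expect_equal(names(back), c("subject_id", "group", "F1", "F2", "F3", "F4",
                              "F5", "F7", "IPA", "MMSE", "BBS"))
  expect_identical(back$F1, tab$F1)
  expect_identical(back$IPA, tab$IPA)
  expect_identical(back$MMSE, tab$MMSE)
  expect_identical(back$BBS, tab$BBS)
  expect_identical(back$subject_id, tab$subject_id)
})
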