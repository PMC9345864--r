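test_that("PD subgroup assignment splits on posture item >= 2", {
  tab <- data.frame(subject_id = c("h1", "p1", "p2", "p3"),
                    group = c("HC", "PD", "PD", "PD"),
                    updrs_3_13 = c(NA, 2, 0, 4))
  out <- assignGroups(tab)
  expect_equal(out$group, c("HC", "PwPA", "PwtPA", "PwPA"))
  tab$updrs_3_13[2] <- NA
  expect_error(assignGroups(tab), "p1")
})

test_that("motor sub-scores sum their item lists, laterality included", {
  items <- c("3.15" = 1, "3.16" = 2, "3.17" = 0, "3.18" = 1,
             "3.10" = 2, "3.11" = 1,
             "3.4" = 0, "3.5" = 0, "3.6" = 0, "3.7" = 0, "3.8" = 0,
             "3.9" = 0, "3.14" = 0)
  ss <- updrsSubscores(items)
  expect_equal(ss, c(tremor = 4, bradykinesia = 0, gait = 3))
  expect_equal(unname(updrsSubscores(setNames(rep(0, 13), names(items)))),
               c(0, 0, 0))
  # laterality sub-items sum into their numbered item
  lat <- setNames(c(1, 2, 0, 1, 2, 0, rep(0, 9)),
                  c("3.15a", "3.15b", "3.16", "3.17L", "3.17R", "3.18",
                    names(items)[5:13]))
  expect_equal(unname(updrsSubscores(lat)["tremor"]), 6)
  expect_error(updrsSubscores(lat[-(1:2)]), "3\\.15")
})

test_that("two-group comparison gates on normality and matches an exact rank oracle", {
  # clearly normal-ish large samples -> t test
  set.seed(61)
  tab <- data.frame(subject_id = as.character(1:120),
                    group = rep(c("HC", "PwPA"), each = 60),
                    v = c(rnorm(60, 0, 1), rnorm(60, 1, 1)))
  cmp <- compareGroups(tab, "v", c("HC", "PwPA"))
  expect_equal(cmp@test, "t")
  expect_lt(cmp@p, 0.05)

  # fully separated small samples: U = 0; exact two-tailed p = 2/252 by
  # enumeration of all 252 rank splits
  tab2 <- data.frame(subject_id = as.character(1:10),
                     group = rep(c("a", "b"), each = 5),
                     v = c(1:5, 6:10))
  cmp2 <- compareGroups(tab2, "v", c("a", "b"))
  expect_equal(cmp2@test, "mann-whitney")
  splits <- utils::combn(10, 5)
  uStat <- apply(splits, 2, function(ix) sum(rank(1:10)[ix]) - 5 * 6 / 2)
  uObs <- 0
  pOneTail <- mean(uStat <= uObs)
  expect_equal(cmp2@p, 2 * pOneTail)
  expect_equal(2 * pOneTail, 2 / 252)

  # identical groups are never significant
  tab3 <- data.frame(subject_id = as.character(1:10),
                     group = rep(c("a", "b"), each = 5), v = rep(1:5, 2))
  cmp3 <- compareGroups(tab3, "v", c("a", "b"))
  expect_gt(cmp3@p, 0.99)

  # categorical: the published gender split is significant by chi-square
  tab4 <- data.frame(subject_id = as.character(1:100),
                     group = rep(c("PD", "HC"), c(70, 30)),
                     gender = c(rep(c("M", "F"), c(48, 22)),
                                rep(c("M", "F"), c(13, 17))))
  cmp4 <- compareGroups(tab4, "gender", c("PD", "HC"))
  expect_equal(cmp4@test, "chi-square")
  expect_lt(cmp4@p, 0.05)
  expect_equal(cmp4@p, 0.0177, tolerance = 0.01)

  expect_error(compareGroups(data.frame(subject_id = "x", group = "a",
                                        v = NA_real_), "v", c("a", "b")))
})

test_that("comparison p-values are invariant under common affine transforms", {
  set.seed(62)
  tab <- data.frame(subject_id = as.character(1:40),
                    group = rep(c("a", "b"), each = 20),
                    v = c(rnorm(20), rnorm(20, 0.8)))
  p0 <- compareGroups(tab, "v", c("a", "b"))@p
  tab$v <- 3.7 * tab$v - 11
  expect_equal(compareGroups(tab, "v", c("a", "b"))@p, p0, tolerance = 1e-9)
})

test_that("Spearman correlation matches a rank-Pearson oracle and bands correctly", {
  r <- spearmanCorr(1:10, (1:10)^3)
  expect_equal(r@rs, 1)
  expect_equal(bandLabel(r), "very strong")

  # hand-ranked case: d = (-1, 1, -1, 1, 0), sum d^2 = 4,
  # rs = 1 - 6*4/(5*24) = 0.8; rank-Pearson agrees
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  r2 <- spearmanCorr(x, y)
  expect_equal(r2@rs, cor(rank(x), rank(y)))
  expect_equal(r2@rs, 0.8)

  expect_equal(correlationBand(0.573), "moderate")
  expect_equal(correlationBand(c(0.05, -0.2, 0.45, -0.75, 0.95)),
               c("negligible", "weak", "moderate", "strong", "very strong"))

  # invariance under strictly monotone transforms of either variable
  set.seed(63)
  a <- rnorm(30); b <- rnorm(30)
  base <- spearmanCorr(a, b)@rs
  expect_equal(spearmanCorr(exp(a), b)@rs, base)
  expect_equal(spearmanCorr(a, qnorm(pnorm(b))^3 + 2 * b^3)@rs,
               spearmanCorr(a, b^3)@rs)
  expect_error(spearmanCorr(rep(1, 5), 1:5), "undefined correlation")
})

test_that("simple regression reports standardized beta and adjusted R2", {
  x <- 1:20
  fit <- suppressWarnings(simpleRegression(2 * x, x))
  expect_equal(fit@r2, 1)
  expect_equal(fit@adjR2, 1)
  expect_equal(fit@betaStd, 1)
  expect_equal(fit@beta, 2)

  set.seed(64)
  xr <- rnorm(500); yr <- rnorm(500)
  nullFit <- simpleRegression(yr, xr)
  expect_lt(abs(nullFit@adjR2), 0.02)

  # closed-form adjusted R2 on arbitrary fits
  for (i in 1:10) {
    xi <- rnorm(15); yi <- 0.5 * xi + rnorm(15)
    f <- simpleRegression(yi, xi)
    expect_equal(f@adjR2, 1 - (1 - f@r2) * (15 - 1) / (15 - 2),
                 tolerance = 1e-12)
    expect_equal(abs(f@betaStd), sqrt(f@r2), tolerance = 1e-12)
  }
  expect_error(simpleRegression(1:5, rep(2, 5)), "constant")
})

test_that("cohort summary reports mean/sd/n per group", {
  co <- data.frame(subject_id = as.character(1:4),
                   group = c("HC", "HC", "PwPA", "PwPA"),
                   F1 = c(1, 3, 10, 12))
  sm <- cohortSummary(co, "F1")
  expect_equal(sm$mean[sm$group == "HC"], 2)
  expect_equal(sm$sd[sm$group == "PwPA"], sd(c(10, 12)))
  expect_equal(sm$n, c(2L, 2L))
})
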