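test_that("group summaries reproduce hand arithmetic", {
  g <- groupSummary(c(1, 2, 3))
  expect_equal(g@mean, 2)
  expect_equal(g@sem, 1 / sqrt(3))
  z <- groupSummary(c(5, 5, 5, 5), "area", "%")
  expect_equal(z@mean, 5)
  expect_identical(z@sem, 0)
  expect_identical(z@n, 4L)
  expect_message(groupSummary(c(1, 2, NA, 4)), "1 missing")
  expect_error(suppressMessages(groupSummary(c(1, NA))), "2 non-missing")
})

test_that("identical groups give t = 0 and p = 1", {
  a <- new("GroupStats", n = 6L, mean = 3, sem = 0.5)
  tt <- tTestGroups(a, a)
  expect_identical(tt@tStatistic, 0)
  expect_identical(tt@pValue, 1)
})

test_that("printed summaries reproduce the published significance calls", {
  bp <- tTestGroups(new("GroupStats", n = 6L, mean = 500.9, sem = 43.1),
                    new("GroupStats", n = 6L, mean = 140.3, sem = 31.6))
  expect_equal(bp@tStatistic, (500.9 - 140.3) / sqrt(43.1^2 + 31.6^2),
               tolerance = 1e-12)
  expect_equal(bp@tStatistic, 6.748, tolerance = 1e-3)
  expect_identical(bp@df, 10)
  expect_lt(bp@pValue, 0.01)
  expect_identical(bp@source, "summary-stats")
})

test_that("raw-values and summary-stat modes agree to 1e-10", {
  set.seed(5)
  a <- rnorm(8, 10, 2)
  b <- rnorm(6, 7, 3)
  for (v in c("student", "welch")) {
    raw <- tTestGroups(a, b, v)
    summ <- tTestGroups(groupSummary(a), groupSummary(b), v)
    expect_equal(raw@tStatistic, summ@tStatistic, tolerance = 1e-10)
    expect_equal(raw@pValue, summ@pValue, tolerance = 1e-10)
    expect_identical(raw@source, "raw-values")
  }
})

test_that("both variants agree with stats::t.test where they coincide", {
  set.seed(6)
  a <- rnorm(7, 5, 1)
  b <- rnorm(7, 4, 1.5)
  student <- tTestGroups(a, b, "student")
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(student@tStatistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(student@pValue, ref$p.value, tolerance = 1e-10)
  b2 <- rnorm(5, 4, 3)
  welch <- tTestGroups(a, b2, "welch")
  refW <- stats::t.test(a, b2)
  expect_equal(welch@tStatistic, unname(refW$statistic), tolerance = 1e-10)
  expect_equal(welch@df, unname(refW$parameter), tolerance = 1e-10)
  expect_equal(welch@pValue, refW$p.value, tolerance = 1e-10)
})

test_that("swapping groups negates t and preserves p", {
  a <- new("GroupStats", n = 6L, mean = 9.01, sem = 0.98)
  b <- new("GroupStats", n = 6L, mean = 2.78, sem = 0.6)
  ab <- tTestGroups(a, b)
  ba <- tTestGroups(b, a)
  expect_equal(ab@tStatistic, -ba@tStatistic)
  expect_identical(ab@pValue, ba@pValue)
})

test_that("welch and student p values agree under equal variance, equal n", {
  set.seed(7)
  ok <- replicate(20, {
    a <- rnorm(6, 10, 2)
    b <- rnorm(6, 11, 2)
    b <- (b - mean(b)) / stats::sd(b) * stats::sd(a) + mean(b)  # equal s.d.
    ps <- tTestGroups(a, b, "student")@pValue
    pw <- tTestGroups(a, b, "welch")@pValue
    abs(pw - ps) / ps < 0.1
  })
  expect_identical(mean(ok), 1)
  # welch df never exceeds pooled df
  a <- rnorm(6); b <- rnorm(6)
  expect_lte(tTestGroups(a, b, "welch")@df,
             tTestGroups(a, b, "student")@df + 1e-9)
})

test_that("zero-variance degeneracies follow the stated conventions", {
  same <- tTestGroups(c(2, 2, 2), c(2, 2, 2))
  expect_identical(same@pValue, 1)
  expect_warning(diffp <- tTestGroups(c(2, 2, 2), c(3, 3, 3)),
                 "zero variance")
  expect_identical(diffp@pValue, 0)
})

test_that("marker ratios divide group means with propagated error", {
  s100 <- new("GroupStats", n = 6L, mean = 9.0, sem = 1.0)
  th <- new("GroupStats", n = 6L, mean = 0.08, sem = 0.01)
  r <- markerRatio(s100, th)
  expect_equal(r$ratio, 112.5)
  expect_equal(r$se, sqrt((1 / 0.08)^2 + (9 * 0.01 / 0.08^2)^2))
  glu <- new("GroupStats", n = 6L, mean = 2.8, sem = 0.6)
  expect_equal(markerRatio(glu, th)$ratio, 35)
  expect_equal(markerRatio(s100, s100)$ratio, 1)
  bad <- new("GroupStats", n = 6L, mean = 0, sem = 0.1)
  expect_error(markerRatio(s100, bad), "undefined")
})

test_that("group comparison tables carry both groups and the test", {
  df <- data.frame(group = rep(c("a", "b"), each = 4),
                   positive_area_pct = c(9, 10, 8, 9.5, 3, 2.5, 3.2, 2.9))
  out <- compareGroups(df, parameters = "positive_area_pct")
  expect_identical(nrow(out), 1L)
  expect_identical(out$n_a, 4L)
  expect_lt(out$p, 0.01)
  expect_gt(out$mean_a, out$mean_b)
  df$extra1 <- df$extra2 <- df$extra3 <- df$extra4 <- rnorm(8)
  expect_message(compareGroups(df, parameters = c("positive_area_pct",
                                                  "extra1", "extra2",
                                                  "extra3", "extra4")),
                 "multiple-testing")
})
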