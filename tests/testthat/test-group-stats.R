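test_that("the KS normality screen is calibrated and has power", {
  set.seed(201)
  gauss <- rnorm(1000)
  expect_gt(ksNormality(gauss), 0.05)
  unif <- runif(1000, -1, 1)
  unif <- unif / sd(unif)
  expect_lt(ksNormality(unif), 0.05)
  expect_warning(p0 <- ksNormality(rep(2, 20)), "degenerate")
  expect_equal(p0, 0)
  expect_error(ksNormality(c(1, 2, 3)), "at least 5")
})

test_that("the Lilliefors statistic agrees with the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(202)
  for (i in 1:5) {
    x <- rnorm(60) + rexp(60) * (i > 3)
    expect_equal(
      tarsalSSM:::lillieforsStat(x),
      unname(nortest::lillie.test(x)$statistic),
      tolerance = 1e-12
    )
  }
})

toyTable <- function(vals, groups, age = NULL, gender = NULL) {
  n <- length(vals)
  data.frame(
    subject_id = sprintf("s%d", seq_len(n)),
    instance_id = sprintf("i%d", seq_len(n)),
    group = groups, side = "L",
    age = if (is.null(age)) runif(n, 20, 50) else age,
    gender = if (is.null(gender)) sample(c("M", "F"), n, TRUE) else gender,
    b1 = vals, bsd1 = vals
  )
}

test_that("the omnibus ANOVA reproduces the hand-computed toy F-test", {
  # groups {1,2,3}, {2,3,4}, {6,7,8}: SSB = 42 (df 2), SSW = 6 (df 6),
  # F = 21, p = P(F(2,6) > 21)
  tab <- toyTable(
    c(1, 2, 3, 2, 3, 4, 6, 7, 8),
    rep(c("CAI", "CAI_CONTRA", "HEALTHY"), each = 3)
  )
  av <- anovaPerMode(tab)
  omni <- av[av$comparison == "omnibus", ]
  expect_equal(omni$p_raw, pf(21, 2, 6, lower.tail = FALSE), tolerance = 1e-10)

  # pairwise pooled-variance t against the hand formula (MSW = 1, df = 6)
  pw <- av[av$comparison == "CAI vs HEALTHY", ]
  tstat <- (2 - 7) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(pw$p_raw, 2 * pt(-abs(tstat), df = 6), tolerance = 1e-10)
  # Bonferroni: exactly min(1, 3p)
  expect_equal(av$p_adjusted[av$comparison != "omnibus"],
    pmin(1, 3 * av$p_raw[av$comparison != "omnibus"])
  )
})

test_that("ANOVA boundary and degenerate group sizes are contracted", {
  set.seed(203)
  x <- rnorm(10)
  tab <- toyTable(c(x, x), rep(c("CAI", "HEALTHY"), each = 10))
  av <- anovaPerMode(tab)
  expect_equal(av$p_raw[av$comparison == "omnibus"], 1, tolerance = 1e-12)

  small <- toyTable(rnorm(5), c("CAI", "CAI", "CAI", "HEALTHY", "HEALTHY"))
  avs <- anovaPerMode(small)
  expect_true(all(!avs$available))
  expect_true(all(is.na(avs$p_raw)))
})

test_that("ANCOVA matches ANOVA when covariates carry no effect", {
  # with null covariates the two nested-model p-values differ only by
  # the noise the covariates absorb: the mean absolute p difference sits
  # near 0.035 at 50 per group (measured by this simulation oracle), and
  # the significance flags agree almost always
  set.seed(204)
  agree <- 0L
  diffs <- replicate(200, {
    tab <- toyTable(rnorm(150), rep(c("CAI", "CAI_CONTRA", "HEALTHY"), each = 50))
    a <- anovaPerMode(tab)
    p1 <- a$p_raw[a$comparison == "omnibus"]
    p2 <- ancovaPerMode(tab)$p
    agree <<- agree + ((p1 < 0.05) == (p2 < 0.05))
    abs(p1 - p2)
  })
  expect_lt(mean(diffs), 0.05)
  expect_gte(agree / 200, 0.95)
})

test_that("ANCOVA deflates a group effect that is an age confound", {
  set.seed(205)
  hits <- replicate(100, {
    age <- c(runif(26, 18, 32), runif(26, 20, 34), runif(26, 40, 55))
    b <- 0.08 * age + rnorm(78, sd = 0.6)
    tab <- toyTable(b, rep(c("CAI", "CAI_CONTRA", "HEALTHY"), each = 26), age = age)
    a <- anovaPerMode(tab)
    ancovaPerMode(tab)$p > a$p_raw[a$comparison == "omnibus"]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("single-level covariates are dropped with a warning", {
  set.seed(206)
  tab <- toyTable(rnorm(30), rep(c("CAI", "CAI_CONTRA", "HEALTHY"), each = 10),
    gender = rep("F", 30)
  )
  expect_warning(res <- ancovaPerMode(tab), "gender")
  expect_true(is.finite(res$p))
})

test_that("runComparison orchestrates all tests and flags correctly", {
  set.seed(207)
  n <- 26
  vals <- c(rnorm(n, 1.2), rnorm(n, 1.2), rnorm(n, 0))
  tab <- toyTable(vals, rep(c("CAI", "CAI_CONTRA", "HEALTHY"), each = n))
  res <- runComparison(tab, alpha = 0.05)
  expect_s4_class(res, "ComparisonResult")
  fl <- pairwiseFlags(res)
  expect_true(fl[1, "CAI vs HEALTHY"])
  expect_true(fl[1, "CAI_CONTRA vs HEALTHY"])
  expect_false(fl[1, "CAI vs CAI_CONTRA"])
  expect_true(all(res@results$p_adjusted >= res@results$p_raw - 1e-15))
  expect_true(all(res@results$p_raw >= 0 & res@results$p_adjusted <= 1))

  # alpha = 1: every comparison flagged
  res1 <- runComparison(tab, alpha = 1)
  expect_true(all(pairwiseFlags(res1)))
})

test_that("shared subjects trigger the non-independence warning and policy", {
  meta <- syntheticMetadata(nCai = 4L, nHealthy = 4L, nBilateral = 3L, seed = 3L)
  set.seed(208)
  nModes <- 2
  for (k in seq_len(nModes)) {
    meta[[paste0("b", k)]] <- rnorm(nrow(meta))
    meta[[paste0("bsd", k)]] <- meta[[paste0("b", k)]]
  }
  expect_warning(runComparison(meta, alpha = 0.05), "independent")
  r <- runComparison(meta, healthyPolicy = "one-per-subject", warnNonIndependence = FALSE)
  expect_s4_class(r, "ComparisonResult")
})

test_that("comparison results serialise to tidy CSV and JSON", {
  set.seed(209)
  tab <- toyTable(rnorm(30), rep(c("CAI", "CAI_CONTRA", "HEALTHY"), each = 10))
  res <- runComparison(tab)
  csv <- file.path(tempdir(), "stats.csv")
  js <- file.path(tempdir(), "stats.json")
  writeComparison(res, csv, js)
  back <- read.csv(csv)
  expect_equal(
    sort(unique(back$test)),
    c("ancova", "anova", "ks_normality", "pairwise_bonferroni")
  )
  expect_true(all(c("mode", "comparison", "p_raw", "p_adjusted", "significant")
  %in% names(back)))
  expect_true(jsonlite::validate(paste(readLines(js), collapse = "")))
  p <- plotModeBoxplot(tab, 1)
  expect_s3_class(p, "ggplot")
})
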