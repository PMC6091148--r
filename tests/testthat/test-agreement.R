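test_that("Pearson r matches hand computations and handles degenerate cases", {
  res <- pearson_ci(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$r, 0.6, tolerance = 1e-12)

  x <- 1:10
  perfect <- pearson_ci(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$conf_low, 1)
  expect_equal(perfect$conf_high, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)

  expect_error(pearson_ci(1:3, 1:4), "length")
  expect_error(pearson_ci(1:2, 2:3), "at least 3")
  expect_error(pearson_ci(rep(1, 5), 1:5), "variance")
})

test_that("Fisher-z interval matches cor.test and shrinks with n", {
  set.seed(8)
  x <- rnorm(25); y <- x + rnorm(25)
  res <- pearson_ci(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(c(res$conf_low, res$conf_high), as.numeric(ct$conf.int),
               tolerance = 1e-10)

  widths <- sapply(c(10, 40, 160), function(n) {
    # fixed r = 0.8 at increasing n
    xx <- seq_len(n)
    yy <- 0.8 * scale(xx)[, 1] + sqrt(1 - 0.64) * scale(resid(lm(rnorm(n) ~ xx)))[, 1]
    r <- pearson_ci(xx, yy)
    r$conf_high - r$conf_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("ICC equals 1 for identity, penalizes offsets, matches the ANOVA oracle", {
  x <- c(1, 3, 5, 7, 11)
  expect_equal(icc_agreement(x, x)$icc, 1)

  off <- icc_agreement(x, x + 3)
  expect_lt(off$icc, 1)
  expect_equal(pearson_ci(x, x + 3)$r, 1)

  set.seed(13)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    a <- rnorm(n, 10, 3)
    b <- a * runif(1, 0.5, 1.5) + rnorm(n, runif(1, -2, 2), 1)
    expect_equal(icc_agreement(a, b)$icc, oracle_icc(a, b), tolerance = 1e-10)
  }
})

test_that("ICC approaches Pearson r for double-entry symmetric data", {
  set.seed(5)
  x <- rnorm(150); y <- 0.9 * x + rnorm(150, 0, 0.4)
  xs <- c(x, y); ys <- c(y, x)
  expect_equal(icc_agreement(xs, ys)$icc, pearson_ci(xs, ys)$r,
               tolerance = 5e-3)
})

test_that("ICC confidence interval brackets the estimate", {
  set.seed(2)
  a <- rnorm(20); b <- a + rnorm(20, 0.5, 0.7)
  res <- icc_agreement(a, b)
  expect_lte(res$conf_low, res$icc)
  expect_gte(res$conf_high, res$icc)
})

test_that("Bland-Altman bias and limits match hand arithmetic", {
  res <- bland_altman(c(0, 0), c(10, 20))   # differences -10, -20
  expect_equal(res$bias, -15)
  expect_equal(res$sd_diff, sqrt(50), tolerance = 1e-12)
  expect_equal(res$loa_lower, -15 - 1.96 * sqrt(50), tolerance = 1e-12)
  expect_equal(res$loa_upper, -15 + 1.96 * sqrt(50), tolerance = 1e-12)

  x <- c(5, 7, 9)
  same <- bland_altman(x, x)
  expect_equal(c(same$bias, same$loa_lower, same$loa_upper), c(0, 0, 0))

  # translation equivariance: constant shift moves bias, not the LoA width
  set.seed(3)
  mr <- rnorm(12, 100, 20); cta <- rnorm(12, 110, 20)
  b0 <- bland_altman(mr, cta); b5 <- bland_altman(mr + 5, cta)
  expect_equal(b5$bias, b0$bias + 5)
  expect_equal(b5$loa_upper - b5$loa_lower, b0$loa_upper - b0$loa_lower)
})

test_that("weighted kappa matches the contingency-table oracle", {
  r1 <- c(1, 1, 2, 2); r2 <- c(2, 2, 1, 1)
  expect_equal(weighted_kappa(r1, r2)$kappa, oracle_weighted_kappa(r1, r2),
               tolerance = 1e-12)

  expect_equal(weighted_kappa(c(1, 3, 5, 2), c(1, 3, 5, 2))$kappa, 1)

  set.seed(17)
  for (i in 1:25) {
    n <- sample(6:60, 1)
    a <- sample(1:5, n, replace = TRUE)
    b <- pmin(pmax(a + sample(-1:1, n, replace = TRUE), 1), 5)
    expect_equal(weighted_kappa(a, b)$kappa, oracle_weighted_kappa(a, b),
                 tolerance = 1e-10)
  }
  expect_error(weighted_kappa(c(1, 6), c(1, 2)), "1..5")
})

test_that("kappa of independent raters with shared marginals tends to zero", {
  set.seed(23)
  n <- 1e5
  a <- sample(1:5, n, replace = TRUE, prob = c(0.1, 0.2, 0.3, 0.25, 0.15))
  b <- sample(1:5, n, replace = TRUE, prob = c(0.1, 0.2, 0.3, 0.25, 0.15))
  expect_lt(abs(weighted_kappa(a, b)$kappa), 0.02)
})

test_that("coefficients map onto the qualitative interpretation scale", {
  expect_identical(interpret_coefficient(c(0.39, 0.40, 0.59, 0.60, 0.74, 0.75)),
                   c("poor", "fair", "fair", "good", "good", "excellent"))
  expect_identical(interpret_coefficient(0.67), "good")
  expect_identical(interpret_coefficient(0.80), "excellent")
  expect_identical(interpret_coefficient(-0.5), "poor")
  expect_error(interpret_coefficient(NaN), "finite")
})

test_that("agreement_report assembles all estimates with broom methods", {
  set.seed(6)
  cta <- rexp(30, 1 / 100)
  mr <- 0.9 * cta + rnorm(30, -5, 10)
  rep <- agreement_report(mr, cta)
  g <- glance(rep)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n, 30)
  expect_equal(g$r, pearson_ci(cta, mr)$r)
  expect_equal(g$bias, mean(mr - cta))
  expect_true(g$loa_lower <= g$bias && g$bias <= g$loa_upper)
  td <- tidy(rep)
  expect_true(all(c("pearson_r", "icc", "slope", "bias") %in% td$term))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(rep, type = "bland_altman"), "ggplot")
})

test_that("stratified agreement partitions the data and matches pooled", {
  set.seed(7)
  pairs <- tibble::tibble(
    cta_mm3 = rexp(40, 1 / 150),
    mr_mm3 = 0.9 * cta_mm3 + rnorm(40, -10, 15),
    field_strength = rep(c("1.5T", "3T"), 20))
  strat <- stratified_agreement(pairs, by = "field_strength")
  expect_equal(strat$stratum, c("pooled", "1.5T", "3T"))
  expect_equal(sum(strat$n[-1]), strat$n[1])

  one <- stratified_agreement(pairs[pairs$field_strength == "3T", ],
                              by = "field_strength")
  expect_equal(one[one$stratum == "pooled", ]$r, one[one$stratum == "3T", ]$r)

  expect_error(stratified_agreement(pairs, by = "nope"), "unknown")
  # tiny strata reported n-only
  pairs$small <- c("a", rep("b", 39))
  st <- stratified_agreement(pairs, by = "small")
  expect_true(is.na(st$r[st$stratum == "a"]) || !"r" %in% names(st))
})
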