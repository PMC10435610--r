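test_that("impairment classification is strict at Z < -1.5 and keeps NA", {
  expect_identical(classify_impairment(c(-1.6, -1.5, 0.3, NA)),
                   c(TRUE, FALSE, FALSE, NA))
  expect_error(classify_impairment(c(-Inf, 1)), "finite")
})

test_that("change scores are T2 - T1 with per-measure omission", {
  cohort <- data.frame(
    subject_id = c("a", "a", "b", "c", "c"),
    timepoint = c("T1", "T2", "T1", "T1", "T2"),
    ec_fpn = c(0.40, 0.45, 0.39, 0.50, 0.52),
    ef_word_fluency = c(0.1, 0.2, 0.3, 0.4, NA),
    ef_set_shifting = c(-1, 0, 1, -0.5, -0.2))
  cs <- change_scores(cohort)
  expect_identical(cs$subject_id, c("a", "c"))  # b has only T1
  expect_equal(cs$delta_ec_fpn, c(0.05, 0.02))
  expect_identical(is.na(cs$delta_ef_word_fluency), c(FALSE, TRUE))
  expect_equal(cs$delta_ef_set_shifting, c(1, 0.3))
  expect_identical(attr(cs, "n_omitted")[["ef_word_fluency"]], 1L)
})

test_that("paired test handles degenerate and strong-shift cases", {
  x <- rnorm(10)
  res <- paired_change_test(x, x)
  expect_identical(res$p_value, 1)
  expect_identical(res$statistic, 0)

  set.seed(8)
  x1 <- rnorm(30)
  x2 <- x1 + 1 + rnorm(30, sd = sqrt(0.1))
  res2 <- paired_change_test(x1, x2)
  expect_lt(res2$p_value, 0.001)
  expect_identical(res2$n_pairs, 30L)

  expect_error(paired_change_test(1:2, 2:3), "at least 3")
})

test_that("paired-test pipeline holds its type-I error near 0.05", {
  set.seed(1234)
  rejections <- vapply(1:1000, function(i) {
    x1 <- rnorm(30)
    paired_change_test(x1, x1 + rnorm(30))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("covariate screening keeps associated candidates and drops null ones", {
  set.seed(20)
  n <- 100
  y <- rnorm(n)
  x_raw <- rnorm(n)
  # orthogonalized residual: exactly zero sample correlation with y
  x_null <- residuals(lm(x_raw ~ y))
  grp <- rep(c("a", "b"), each = 25)
  y2 <- rnorm(50) + ifelse(grp == "b", 2, 0)  # 2 pooled SDs apart
  scr <- screen_covariates(
    data.frame(y = y, x_null = x_null),
    "y", "x_null", c(x_null = "continuous"))
  expect_false(scr$selected)

  scr2 <- screen_covariates(
    data.frame(y = y2, grp = grp), "y", "grp", c(grp = "binary"))
  expect_true(scr2$selected)

  empty <- screen_covariates(data.frame(y = y), "y", character(), c())
  expect_identical(nrow(empty), 0L)

  expect_warning(
    screen_covariates(data.frame(y = y, one = rep("z", n)), "y",
                      "one", c(one = "binary")),
    "single observed level")
})

test_that("categorical screening uses a 3-group test", {
  set.seed(30)
  g <- rep(c("p", "q", "r"), each = 40)
  y <- rnorm(120) + c(p = 0, q = 0, r = 1.5)[g]
  scr <- screen_covariates(data.frame(y = y, g = g), "y", "g",
                           c(g = "categorical"))
  expect_true(scr$selected)
  expect_true(scr$test %in% c("anova", "kruskal-wallis"))
})

test_that("backward regression recovers a planted effect and drops a null one", {
  set.seed(501)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.5 * x1 + rnorm(n, sd = 0.5)
  # population standardized beta: 0.5 * sd(x1) / sd(y) = 0.5 / sqrt(0.5)
  pop_beta <- 0.5 / sqrt(0.25 + 0.25)
  rr <- backward_regression(y, data.frame(x1 = x1, x2 = x2))
  expect_identical(rr$excluded$predictor, "x2")
  expect_identical(rr$retained$predictor, "x1")
  beta_x1 <- rr$retained$standardized_beta[rr$retained$predictor == "x1"]
  expect_lt(abs(beta_x1 - pop_beta), 0.1)
})

test_that("single significant predictor reduces to plain OLS", {
  set.seed(41)
  x <- rnorm(80); y <- 0.8 * x + rnorm(80)
  rr <- backward_regression(y, data.frame(x = x))
  ref <- lm(y ~ x)
  expect_equal(rr$retained$beta, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_identical(nrow(rr$excluded), 0L)
  expect_equal(rr$adj_r2, summary(ref)$adj.r.squared, tolerance = 1e-12)
  fs <- summary(ref)$fstatistic
  expect_equal(rr$f_stat, unname(fs[1]), tolerance = 1e-12)
  expect_equal(rr$df, unname(fs[2:3]))
})

test_that("backward elimination matches an independent QR-based eliminator", {
  set.seed(61)
  agree <- vapply(1:200, function(i) {
    n <- 100
    X <- matrix(rnorm(n * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(n)
    mine <- backward_regression(y, as.data.frame(X))$retained$predictor
    oracle <- colnames(X)[oracle_backward(y, X)]
    identical(sort(mine), sort(oracle))
  }, logical(1))
  expect_true(all(agree))
})

test_that("null-retention rate matches the independent oracle's rate", {
  set.seed(77)
  runs <- t(vapply(1:300, function(i) {
    n <- 100
    X <- matrix(rnorm(n * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(n)
    c(mine = nrow(backward_regression(y, as.data.frame(X))$retained) > 0,
      oracle = length(oracle_backward(y, X)) > 0)
  }, logical(2)))
  expect_lt(abs(mean(runs[, "mine"]) - mean(runs[, "oracle"])), 0.05)
})

test_that("standardized betas are invariant to affine predictor rescaling", {
  set.seed(55)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.4 * x1 - 0.3 * x2 + rnorm(n, sd = 0.6)
  a <- backward_regression(y, data.frame(x1 = x1, x2 = x2))
  b <- backward_regression(y, data.frame(x1 = x1 * 1000 + 77, x2 = x2))
  expect_equal(a$retained$standardized_beta, b$retained$standardized_beta,
               tolerance = 1e-10)
})

test_that("elimination is monotone and terminates", {
  set.seed(66)
  n <- 60
  X <- as.data.frame(matrix(rnorm(n * 5), ncol = 5))
  names(X) <- paste0("x", 1:5)
  rr <- backward_regression(rnorm(n), X)
  expect_lte(nrow(rr$excluded), 5L)
  expect_true(all(rr$excluded$p_value_at_exclusion >= rr$threshold))
  expect_true(all(rr$retained$p_value < rr$threshold))
  expect_setequal(c(rr$retained$predictor, rr$excluded$predictor), names(X))
})

test_that("categoricals enter reference-coded and exact collinearity errors", {
  set.seed(72)
  n <- 90
  g <- sample(c("frontal", "temporal", "parietal"), n, replace = TRUE)
  y <- rnorm(n) + ifelse(g == "frontal", 1, 0)
  rr <- backward_regression(y, data.frame(loc = g),
                            reference_levels = list(loc = "frontal"))
  all_terms <- c(rr$retained$predictor, rr$excluded$predictor)
  expect_setequal(all_terms, c("loc:temporal", "loc:parietal"))

  x <- rnorm(n)
  expect_error(backward_regression(y, data.frame(a = x, b = 2 * x)),
               "collinearity")
  expect_error(backward_regression(rnorm(3), data.frame(a = rnorm(3),
                                                        b = rnorm(3))),
               "too few")
})

test_that("drop_collinear keeps the first-listed of a correlated pair", {
  set.seed(81)
  x <- rnorm(50)
  d <- data.frame(first = x, second = x + rnorm(50, sd = 0.1),
                  other = rnorm(50))
  expect_message(keep <- drop_collinear(d, c("first", "second", "other")),
                 "dropping 'second'")
  expect_identical(keep, c("first", "other"))
})

test_that("bonferroni threshold divides alpha by m", {
  expect_identical(round(bonferroni_threshold(0.05, 3), 4), 0.0167)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_identical(bonferroni_threshold(0.01, 2), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
  expect_error(bonferroni_threshold(1.5, 3), "alpha")
})
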