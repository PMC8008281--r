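test_that("mixed model reduces to OLS when every subject has one scan", {
  co <- score_cohort(generate_cohort(cohort_config(n_subjects = 60,
                                                   frac_longitudinal = 0,
                                                   seed = 21)))
  r <- fit_lme(co, "wm", "ses_m")
  ols <- lm(wm ~ ses_m + ga_weeks + sex, data = co)
  expect_equal(r$beta, unname(coef(ols)["ses_m"]), tolerance = 1e-4)
  expect_equal(r$ci_hi - r$ci_lo,
               2 * qnorm(0.975) * summary(ols)$coefficients["ses_m", 2],
               tolerance = 0.15)  # same information up to REML/OLS scaling
})

test_that("a planted one-noise-SD SES effect is recovered in sign", {
  hits <- vapply(1:50, function(s) {
    co <- score_cohort(generate_cohort(one_outcome_config(
      beta_ses = 1, sd = 1, n_subjects = 100, seed = 400 + s)))
    fit_lme(co, "y", "ses_m")$beta > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null SES coefficient is covered by the 95% CI at ~95%", {
  cover <- vapply(1:100, function(s) {
    co <- score_cohort(generate_cohort(one_outcome_config(
      beta_ses = 0, n_subjects = 60, seed = 7000 + s)))
    r <- fit_lme(co, "y", "ses_m")
    r$ci_lo <= 0 && r$ci_hi >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("model guards: schema, collinearity, constant outcome", {
  co <- score_cohort(generate_cohort(cohort_config(n_subjects = 20,
                                                   seed = 2)))
  expect_error(fit_lme(co, "nope", "ses_m"), "lacks column")
  co$dup <- co$ses_m
  expect_error(fit_lme(co, "wm", "ses_m", covariates = c("ga_weeks", "sex",
                                                         "dup")),
               "collinear")
  co$flat <- 1
  expect_error(fit_lme(co, "flat", "ses_m"), "constant")
  # two-level factor predictors are recoded 0/1 by level order
  r <- fit_lme(co, "wm", "ses_group")
  expect_true(is.finite(r$beta))
})

test_that("rank-sum exact mode reproduces textbook and enumerated values", {
  w <- wilcoxon_mann_whitney(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(w$rank_sum_x, 3)
  expect_equal(w$p, 1 / 6)
  # rank sums of the two groups always total n(n+1)/2
  expect_equal(w$rank_sum_x + w$rank_sum_y, 10)
  # no-ties exact mode equals the closed-form Wilcoxon distribution
  set.seed(5)
  for (rep in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    w2 <- wilcoxon_mann_whitney(x, y, mode = "exact")
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(w2$p, ref$p.value, tolerance = 1e-12)
  }
  # tied data: enumeration against the independent combn oracle
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  w3 <- wilcoxon_mann_whitney(x, y, mode = "exact")
  expect_equal(w3$p, oracle_ranksum_exact(x, y))
})

test_that("rank-sum normal mode applies midranks and tie correction", {
  set.seed(9)
  x <- round(rnorm(30), 1); y <- round(rnorm(35, 0.4), 1)  # forces ties
  w <- wilcoxon_mann_whitney(x, y, mode = "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  expect_warning(wilcoxon_mann_whitney(rep(1, 4), rep(1, 6)), "identical")
})

test_that("chi-square matches hand-checked tables", {
  edu <- rbind(c(4, 19, 23, 39, 59), c(9, 26, 23, 30, 56))
  r <- chi_square_test(edu)
  expect_equal(r$df, 4)
  expect_gt(r$statistic, 0)
  expect_equal(r$statistic,
               sum((edu - r$expected)^2 / r$expected), tolerance = 1e-12)
  expect_equal(chi_square_test(rbind(c(5, 5), c(5, 5)))$statistic, 0)
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "all-zero")
  expect_error(chi_square_test(rbind(c(0.5, 1), c(1, 2))), "integers")
})

test_that("Spearman correlation handles monotone, tied and constant data", {
  x <- 1:20
  expect_equal(spearman_rho(x, x^3)$rho, 1)
  expect_equal(spearman_rho(x, -sqrt(x))$rho, -1)
  set.seed(4)
  xt <- sample(1:5, 40, replace = TRUE)
  yt <- sample(1:5, 40, replace = TRUE)
  r <- spearman_rho(xt, yt)
  expect_equal(r$rho, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_warning(r0 <- spearman_rho(rep(2, 10), rnorm(10)), "constant")
  expect_true(is.na(r0$rho))
})

test_that("KS normality statistic matches the ECDF-sweep oracle", {
  x <- c(-1.2, -0.3, 0.1, 0.8, 2.0)
  r <- ks_normality(x, lilliefors = FALSE)
  expect_equal(r$D, oracle_ks_D(x, mean(x), sd(x)), tolerance = 1e-12)
  rl <- ks_normality(x)
  expect_equal(rl$D, r$D, tolerance = 1e-12)  # same D, corrected p
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("KS normality is calibrated under the null and powered against
           uniform data", {
  set.seed(31)
  rej_unif <- mean(vapply(1:100, function(i)
    ks_normality(runif(500))$p < 0.05, logical(1)))
  expect_gte(rej_unif, 0.95)
  rej_norm <- mean(vapply(1:100, function(i)
    ks_normality(rnorm(1000))$p < 0.05, logical(1)))
  expect_lte(rej_norm, 0.12)
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               rep(0.05, 5))
  expect_equal(benjamini_hochberg(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  # order invariance; adjustment never decreases a p-value's rank order
  set.seed(2)
  p <- runif(20)
  q <- benjamini_hochberg(p)
  o <- sample(20)
  expect_equal(benjamini_hochberg(p[o]), q[o])
  expect_true(all(q >= p))
  expect_identical(order(q[order(p)]), seq_len(20))  # monotone in p
})

test_that("ICC(A,1) matches the ANOVA oracle and its limits", {
  set.seed(6)
  base <- rnorm(6, 10, 2)
  m <- cbind(base, base)
  expect_equal(icc_agreement(m), 1, tolerance = 1e-9)
  m2 <- cbind(base, base + rnorm(6, 0.5, 0.7))
  expect_equal(icc_agreement(m2), oracle_icc_a1(m2), tolerance = 1e-9)
  noise <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc_agreement(noise)), 0.1)
  expect_warning(icc_bad <- icc_agreement(matrix(1, 6, 2)), "constant")
  expect_true(is.na(icc_bad))
  expect_error(icc_agreement(matrix(1:8, 4, 2)), "at least 5")
})

test_that("growth slopes divide outcome change by GA change", {
  d <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                  ga_weeks = c(28, 36, 30, 34),
                  vol = c(100, 120, 50, 50))
  g <- growth_slopes(d, "vol", group = NULL)
  expect_equal(g$slopes$slope[g$slopes$subject == "a"], 2.5)
  expect_equal(g$slopes$slope[g$slopes$subject == "b"], 0)
  d2 <- d; d2$ga_weeks <- c(28, 28, 30, 34)
  expect_error(growth_slopes(d2, "vol", group = NULL), "strictly exceed")
})

test_that("a one-SD slope difference is detected by the rank-sum test", {
  hits <- vapply(1:200, function(s) {
    set.seed(600 + s)
    n <- 20
    d <- data.frame(
      subject_id = rep(sprintf("s%02d", 1:(2 * n)), each = 2),
      ga_weeks = rep(c(28, 36), 2 * n),
      ses_group = rep(c("low", "high"), each = 2 * n))
    slope <- c(rnorm(n, 2, 1), rnorm(n, 3, 1))  # planted 1-SD difference
    d$vol <- 100 + slope[rep(1:(2 * n), each = 2)] * (d$ga_weeks - 28) +
      rnorm(4 * n, 0, 0.5)
    growth_slopes(d, "vol")$comparison$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})
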