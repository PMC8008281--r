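#' Linear mixed-effects association between SES and a morphometry outcome
#'
#' Fits `outcome ~ predictor + GA + sex (+ distress) + (1 | subject)` by
#' REML, the standard longitudinal-neuroimaging model: fixed effects for
#' the SES predictor, gestational age at scan (weeks) and fetal sex
#' (female 0, male 1), and a per-subject random intercept absorbing
#' intra-subject correlation across repeated scans.  Inference on the
#' predictor coefficient is two-sided Wald: `z = beta / SE`,
#' `CI = beta +/- 1.96 SE`.
#'
#' Rows with missing values in any used column are dropped (complete-case;
#' the count is reported).  A rank-deficient fixed-effects design is an
#' error naming the collinear columns; non-convergence and singular
#' random-effects fits are flagged on the result, never silent.
#'
#' @param data Per-scan table joining morphometry outcomes with cohort
#'   covariates.
#' @param outcome Name of the outcome column.
#' @param predictor Name of the SES predictor column (numeric, or a
#'   two-level factor which is recoded 0/1 by level order, e.g. SES group
#'   low 0 / high 1).
#' @param covariates Adjustment columns (default GA and sex).
#' @param group Subject-identifier column for the random intercept.
#' @param distress_adjust If `TRUE`, add the binary high-distress flag
#'   (column `distress`) as a covariate; incomplete distress visits drop
#'   out by the complete-case rule.
#' @return One-row data frame of class `assoc_result`: `outcome`,
#'   `predictor`, `beta`, `ci_lo`, `ci_hi`, `p`, `n_obs`, `n_subjects`,
#'   `n_dropped`, `converged`, `singular`.
#' @export
fit_lme <- function(data, outcome, predictor,
                    covariates = c("ga_weeks", "sex"),
                    group = "subject_id", distress_adjust = FALSE) {
  if (distress_adjust) covariates <- union(covariates, "distress")
  used <- c(outcome, predictor, covariates, group)
  miss <- setdiff(used, names(data))
  if (length(miss))
    stopf("data lacks column(s): %s", paste(miss, collapse = ", "))
  d <- data[, used, drop = FALSE]
  cc <- complete.cases(d)
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  if (is.factor(d[[predictor]]) || is.character(d[[predictor]])) {
    f <- as.factor(d[[predictor]])
    if (nlevels(droplevels(f)) != 2L)
      stopf("factor predictors must have exactly 2 observed levels")
    d[[predictor]] <- as.numeric(f == levels(f)[2L])
  }
  if (length(unique(d[[outcome]])) < 2L)
    stopf("outcome '%s' is constant", outcome)
  if (length(unique(d[[group]])) < 2L)
    stopf("need at least 2 subjects")

  fixed <- c(predictor, covariates)
  X <- as.matrix(cbind(`(Intercept)` = 1,
                       d[, fixed, drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("singular fixed-effects design; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }

  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(fixed, collapse = " + "),
                                 "+ (1 |", group, ")"))
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = TRUE,
               control = lme4::lmerControl(
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.nRE = "ignore",
                 calc.derivs = FALSE)),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  co <- summary(fit)$coefficients
  beta <- co[predictor, "Estimate"]
  se <- co[predictor, "Std. Error"]
  zc <- qnorm(0.975)
  res <- data.frame(outcome = outcome, predictor = predictor,
                    beta = beta,
                    ci_lo = beta - zc * se, ci_hi = beta + zc * se,
                    p = 2 * pnorm(-abs(beta / se)),
                    n_obs = nrow(d),
                    n_subjects = length(unique(d[[group]])),
                    n_dropped = n_dropped,
                    converged = converged,
                    singular = lme4::isSingular(fit),
                    stringsAsFactors = FALSE)
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum test on midranks.  In exact mode the permutation
#' null is enumerated over all assignments of the pooled values to the two
#' groups (valid with ties); in normal mode the tie-corrected Gaussian
#' approximation with continuity correction is used.  `mode = "auto"`
#' enumerates when the pooled sample has at most 20 observations.  Both
#' groups' rank sums are reported.
#'
#' @param x,y Nonempty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (referring to the rank sum of `x`).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List: `rank_sum_x`, `rank_sum_y`, `p`, `mode`.
#' @export
wilcoxon_mann_whitney <- function(x, y,
                                  alternative = c("two.sided", "less",
                                                  "greater"),
                                  mode = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stopf("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)                      # midranks
  w_x <- sum(rk[seq_len(n1)])
  w_y <- sum(rk) - w_x
  if (length(unique(pooled)) == 1L) {
    warnf("all values identical across both samples; p = 1")
    return(list(rank_sum_x = w_x, rank_sum_y = w_y, p = 1,
                mode = "degenerate"))
  }
  if (mode == "auto") mode <- if (n <= 20L) "exact" else "normal"
  mu <- n1 * (n + 1) / 2
  if (mode == "exact") {
    sums <- combn(n, n1, FUN = function(ix) sum(rk[ix]))
    tol <- 1e-9
    p <- switch(alternative,
                less = mean(sums <= w_x + tol),
                greater = mean(sums >= w_x - tol),
                two.sided = mean(abs(sums - mu) >= abs(w_x - mu) - tol))
  } else {
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    dev <- w_x - mu
    cc <- 0.5 * sign(dev)
    z <- (dev - cc) / sqrt(sig2)
    p <- switch(alternative,
                less = pnorm((dev + 0.5) / sqrt(sig2)),
                greater = pnorm((dev - 0.5) / sqrt(sig2),
                                lower.tail = FALSE),
                two.sided = min(1, 2 * pnorm(-abs(z))))
  }
  list(rank_sum_x = w_x, rank_sum_y = w_y, p = p, mode = mode)
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table of counts (no
#' continuity correction), `df = (r-1)(c-1)`.
#'
#' @param counts Matrix of nonnegative integer counts with no all-zero row
#'   or column.
#' @return List: `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stopf("contingency table has an all-zero row or column")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Spearman rank correlation
#'
#' Spearman's rho (Pearson correlation of midranks) with a two-sided p
#' from the t approximation.
#'
#' @param x,y Paired numeric samples, n >= 3.
#' @return List: `rho`, `p`, `n`.  Constant input yields `rho = NA` with
#'   a warning.
#' @export
spearman_rho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warnf("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Kolmogorov-Smirnov normality test
#'
#' One-sample KS distance between the empirical distribution and a normal
#' with the sample mean and SD.  Because those parameters are estimated
#' from the data, the default p-value uses the Lilliefors correction; the
#' plain KS p-value (valid only for a fully specified normal) is available
#' as `lilliefors = FALSE`.
#'
#' @param x Numeric sample, n >= 5, non-constant.
#' @param lilliefors Use the Lilliefors-corrected p (default `TRUE`).
#' @return List: `D`, `p`, `n`.
#' @export
ks_normality <- function(x, lilliefors = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 5L) stopf("need at least 5 observations")
  if (sd(x) == 0) stopf("constant sample: normality test undefined")
  if (lilliefors) {
    lt <- nortest::lillie.test(x)
    list(D = unname(lt$statistic), p = lt$p.value, n = n)
  } else {
    kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    list(D = unname(kt$statistic), p = kt$p.value, n = n)
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment within one declared family of
#' tests: `q_(i) = min_{j >= i} p_(j) * m / j`, returned in input order.
#'
#' @param pvals Numeric p-values in `[0, 1]` (one family).
#' @return q-values in `[0, 1]`, same order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Intraclass correlation coefficient for absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (ICC(A,1)) from the ANOVA mean squares of an items x raters table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param ratings Numeric matrix, `n >= 5` items (rows) by `k >= 2` raters
#'   (columns), no missing values.
#' @return Scalar ICC; `NA` with a warning when the ratings are constant.
#' @export
icc_agreement <- function(ratings) {
  m <- as.matrix(ratings)
  if (nrow(m) < 5L || ncol(m) < 2L)
    stopf("need at least 5 items and 2 raters")
  if (anyNA(m)) stopf("ratings must be complete")
  if (length(unique(as.vector(m))) == 1L) {
    warnf("constant ratings: ICC undefined")
    return(NA_real_)
  }
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sst <- sum((m - grand)^2)
  mse <- (sst - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Per-subject growth slopes and SES group comparison
#'
#' For subjects with exactly two scans, the growth rate of an outcome is
#' `(value2 - value1) / (GA2 - GA1)` (outcome units per week).  When an
#' SES group column is present the low and high groups' slopes are
#' compared with the rank-sum test.
#'
#' @param data Per-scan table.
#' @param outcome Outcome column name.
#' @param ga Gestational-age column (weeks).
#' @param subject Subject-identifier column.
#' @param group Optional SES group column (`"low"`/`"high"`); `NULL`
#'   skips the comparison.
#' @return List: `slopes` (data frame of subject, slope, and group) and
#'   `comparison` (rank-sum result or `NULL`).
#' @export
growth_slopes <- function(data, outcome, ga = "ga_weeks",
                          subject = "subject_id", group = "ses_group") {
  if (!is.null(group) && !group %in% names(data)) group <- NULL
  cnt <- table(data[[subject]])
  pairs <- names(cnt)[cnt == 2L]
  if (!length(pairs)) stopf("no subjects with exactly 2 scans")
  d <- data[data[[subject]] %in% pairs, ]
  d <- d[order(d[[subject]], d[[ga]]), ]
  i1 <- seq(1L, nrow(d), by = 2L)
  i2 <- i1 + 1L
  dga <- d[[ga]][i2] - d[[ga]][i1]
  if (any(dga <= 0))
    stopf("second-scan GA must strictly exceed first-scan GA")
  slopes <- data.frame(subject = d[[subject]][i1],
                       slope = (d[[outcome]][i2] - d[[outcome]][i1]) / dga,
                       stringsAsFactors = FALSE)
  comparison <- NULL
  if (!is.null(group)) {
    slopes$group <- as.character(d[[group]][i1])
    lo <- slopes$slope[slopes$group == "low"]
    hi <- slopes$slope[slopes$group == "high"]
    if (length(lo) && length(hi))
      comparison <- wilcoxon_mann_whitney(lo, hi, mode = "normal")
  }
  list(slopes = slopes, comparison = comparison)
}
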