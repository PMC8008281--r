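#' Default planted outcome model
#'
#' Per-outcome linear-model parameters used by [generate_cohort()]:
#' intercept, SES slope (per maternal Hollingshead score point), GA slope
#' (per week), sex offset (male - female), and the per-scan noise SD in
#' outcome units.  Slopes mirror the direction and magnitude of published
#' fetal SES-morphometry associations (cortical gray matter decreasing in
#' SES; white matter, cerebellum, brainstem and lobe volumes increasing;
#' gyrification and sulcal depth decreasing), with noise SDs back-derived
#' from the precision (95% CIs) such studies report at n ~ 184 scans.
#' Intercepts place outcome means at typical mid-third-trimester values.
#'
#' @return Data frame with columns `outcome`, `beta0`, `beta_ses`,
#'   `beta_ga`, `beta_sex`, `sd`.
#' @export
default_effect_sizes <- function() {
  es <- read.csv(text = "
outcome,mean,beta_ses,beta_ga,beta_sex,sd
cgm,69.5,-0.11,5.0,1.5,5.0
wm,110.0,0.23,4.5,1.0,8.0
dgm,24.0,0.01,1.2,0.1,0.7
cerebellum,10.7,0.02,0.7,0.1,0.7
brainstem,4.6,0.004,0.25,0.1,0.3
vol_frontal,30.0,0.07,1.5,0.3,4.0
vol_parietal,20.0,0.07,1.0,0.3,3.0
vol_temporal,12.0,0.04,0.6,0.2,2.0
vol_occipital,8.0,0.02,0.4,0.1,1.3
lgi_frontal,1.25,-0.0011,0.03,0,0.055
lgi_parietal,1.40,-0.0024,0.03,0,0.08
lgi_temporal,1.37,-0.0015,0.03,0,0.065
lgi_occipital,1.32,-0.0021,0.03,0,0.075
depth_frontal,1.80,-0.0024,0.12,0,0.21
depth_parietal,2.10,-0.0095,0.12,0,0.29
depth_temporal,1.90,-0.0053,0.12,0,0.23
depth_occipital,1.25,-0.0073,0.12,0,0.22
", strip.white = TRUE)
  # anchor intercepts at cohort-typical covariates: GA 33.6 wk, maternal
  # score 48, P(male) 0.52
  es$beta0 <- es$mean - es$beta_ga * 33.6 - es$beta_ses * 48 -
    es$beta_sex * 0.521
  es$mean <- NULL
  es[, c("outcome", "beta0", "beta_ses", "beta_ga", "beta_sex", "sd")]
}

#' Synthetic cohort configuration
#'
#' Study-scale defaults: 144 subjects of whom 40 contribute a longitudinal
#' pair (184 scans), gestational age 24-39.4 weeks, 52.1% male fetuses,
#' and parental education/occupation level distributions matching a
#' typical two-hospital convenience cohort (education skewed toward
#' college/graduate levels; occupation bimodal between "homemaker or
#' unemployed" and "major business or professional").
#'
#' @param n_subjects Number of fetuses (>= 1).
#' @param frac_longitudinal Fraction scanned twice, in `[0, 1]`.
#' @param ga_range Gestational-age range at scan, weeks (low < high).
#' @param education_probs,occupation_probs Lists with `maternal` and
#'   `paternal` 5-vectors of level probabilities (each summing to 1).
#' @param copula_rho Latent Gaussian correlation between the two parents'
#'   levels (education and occupation each), default 0.5.
#' @param effect_sizes Planted outcome model, as
#'   [default_effect_sizes()].
#' @param noise_sd Multiplier on each outcome's per-scan noise SD.
#' @param subject_sd Random-intercept SD as a multiple of each outcome's
#'   noise SD.
#' @param p_male Probability a fetus is male.
#' @param distress_completion Probability a subject completes the distress
#'   questionnaires.
#' @param seed Integer seed; `NULL` inherits the session RNG stream.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 144,
                          frac_longitudinal = 40 / 144,
                          ga_range = c(24, 39.4),
                          education_probs = list(
                            maternal = c(4, 19, 23, 39, 59) / 144,
                            paternal = c(9, 26, 23, 30, 56) / 144),
                          occupation_probs = list(
                            maternal = c(27, 9, 8, 15, 85) / 144,
                            paternal = c(18, 15, 14, 10, 87) / 144),
                          copula_rho = 0.5,
                          effect_sizes = default_effect_sizes(),
                          noise_sd = 1,
                          subject_sd = 0.7,
                          p_male = 75 / 144,
                          distress_completion = 0.583,
                          seed = NULL) {
  if (!is_count(n_subjects)) stopf("n_subjects must be a positive integer")
  if (frac_longitudinal < 0 || frac_longitudinal > 1)
    stopf("frac_longitudinal must lie in [0, 1]")
  if (length(ga_range) != 2L || ga_range[1L] >= ga_range[2L])
    stopf("ga_range must be (low, high) with low < high")
  for (par in c("maternal", "paternal")) {
    check_prob_vector(education_probs[[par]],
                      paste(par, "education_probs"))
    check_prob_vector(occupation_probs[[par]],
                      paste(par, "occupation_probs"))
  }
  if (abs(copula_rho) >= 1) stopf("copula_rho must lie in (-1, 1)")
  need <- c("outcome", "beta0", "beta_ses", "beta_ga", "beta_sex", "sd")
  if (!all(need %in% names(effect_sizes)))
    stopf("effect_sizes needs columns: %s", paste(need, collapse = ", "))
  if (noise_sd < 0 || subject_sd < 0)
    stopf("noise_sd and subject_sd must be nonnegative")
  structure(list(n_subjects = as.integer(n_subjects),
                 frac_longitudinal = frac_longitudinal,
                 ga_range = ga_range,
                 education_probs = education_probs,
                 occupation_probs = occupation_probs,
                 copula_rho = copula_rho,
                 effect_sizes = effect_sizes,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 p_male = p_male,
                 distress_completion = distress_completion,
                 seed = seed),
            class = "cohort_config")
}

# ordinal level from a latent standard normal via cumulative cut points
latent_to_level <- function(z, probs) {
  cuts <- qnorm(cumsum(probs)[1:4])
  findInterval(z, cuts) + 1L
}

#' Generate a synthetic fetal MRI cohort
#'
#' One row per scan.  Longitudinal subjects contribute two rows with
#' strictly increasing gestational age (first scan early third trimester,
#' second 4.5-9 weeks later).  Parental education and occupation levels are
#' drawn from the configured ordinal distributions with a latent Gaussian
#' copula (`copula_rho`) linking the two parents.  Each configured outcome
#' is generated from the planted linear model
#' `beta0 + beta_ga * GA + beta_sex * sex + beta_ses * maternal_score +
#' subject_intercept + noise`, so downstream estimates can be compared with
#' known truth.  Distress questionnaires are completed by a random subset
#' of subjects (per `distress_completion`); the rest are `NA`.
#'
#' @param config A [cohort_config()].
#' @return Data frame of scans with covariate, SES-level, distress and
#'   outcome columns.  The planted parameters are attached as
#'   `attr(, "ground_truth")`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    n_long <- as.integer(round(config$frac_longitudinal * n))
    lo <- config$ga_range[1L]
    hi <- config$ga_range[2L]

    subj <- sprintf("S%03d", seq_len(n))
    sex <- rbinom(n, 1L, config$p_male)
    rho <- config$copula_rho
    draw_pair <- function(probs) {
      zm <- rnorm(n)
      zf <- rho * zm + sqrt(1 - rho^2) * rnorm(n)
      list(m = latent_to_level(zm, probs$maternal),
           f = latent_to_level(zf, probs$paternal))
    }
    edu <- draw_pair(config$education_probs)
    occ <- draw_pair(config$occupation_probs)
    ses_m <- hollingshead_score(edu$m, occ$m)

    completes <- runif(n) < config$distress_completion
    long <- c(rep(TRUE, n_long), rep(FALSE, n - n_long))

    # longitudinal pairs: first scan early in the window, second 25-55% of
    # the window later (defaults: first ~25.5-30.9 wk, gap ~3.9-8.5 wk)
    rng <- hi - lo
    ga1 <- ifelse(long,
                  runif(n, lo + 0.10 * rng, lo + 0.45 * rng),
                  runif(n, lo, hi))
    ga2 <- pmin(ga1 + runif(n, 0.25 * rng, 0.55 * rng), hi - 1e-3 * rng)

    idx <- c(seq_len(n), which(long))
    tp <- c(rep(1L, n), rep(2L, n_long))
    ga <- c(ga1, ga2[long])[order(idx, tp)]
    idx_o <- sort(idx)
    tp <- tp[order(idx, tp)]

    m <- length(idx_o)
    tab <- data.frame(scan_id = sprintf("%s_T%d", subj[idx_o], tp),
                      subject_id = subj[idx_o],
                      timepoint = tp,
                      ga_weeks = ga,
                      sex = sex[idx_o],
                      edu_m = edu$m[idx_o], occ_m = occ$m[idx_o],
                      edu_f = edu$f[idx_o], occ_f = occ$f[idx_o],
                      stringsAsFactors = FALSE)

    q_na <- rep(NA_real_, m)
    comp <- completes[idx_o]
    tab$ssai <- ifelse(comp, pmax(20, round(rnorm(m, 35, 10))), q_na)
    tab$stai <- ifelse(comp, pmax(20, round(rnorm(m, 35, 9))), q_na)
    tab$pss <- ifelse(comp, pmax(0, round(rnorm(m, 13, 6))), q_na)
    tab$epds <- ifelse(comp, pmax(0, round(rnorm(m, 6, 4))), q_na)

    es <- config$effect_sizes
    for (r in seq_len(nrow(es))) {
      sd_o <- es$sd[r]
      b_subj <- rnorm(n, 0, config$subject_sd * sd_o)
      eps <- rnorm(m, 0, config$noise_sd * sd_o)
      tab[[es$outcome[r]]] <- es$beta0[r] +
        es$beta_ga[r] * tab$ga_weeks +
        es$beta_sex[r] * tab$sex +
        es$beta_ses[r] * ses_m[idx_o] +
        b_subj[idx_o] + eps
    }
    if (all(c("cgm", "wm", "dgm", "cerebellum", "brainstem") %in%
              es$outcome))
      tab$whole_brain <- tab$cgm + tab$wm + tab$dgm + tab$cerebellum +
        tab$brainstem

    attr(tab, "ground_truth") <- list(
      effect_sizes = es,
      ses_predictor = "maternal Hollingshead score",
      noise_sd = config$noise_sd, subject_sd = config$subject_sd,
      n_longitudinal = n_long, seed = config$seed)
    tab
  })
}

#' Write a cohort table and its ground-truth sidecar
#'
#' @param cohort Table from [generate_cohort()].
#' @param path CSV output path; the planted parameters go to
#'   `<path>.truth.json`.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt))
    jsonlite::write_json(gt, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
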