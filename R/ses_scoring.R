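#' Hollingshead two-factor socioeconomic score
#'
#' Combines ordinal education and occupation levels into the two-factor
#' index of social position: `score = 7 * occupation + 4 * education`.
#' Both levels are coded 1 (lowest) to 5 (highest), so the score ranges
#' from 11 (unemployed, no schooling beyond the obligatory minimum) to 55
#' (higher executive with post-college education).
#'
#' @param education Integer vector of education levels in 1..5.
#' @param occupation Integer vector of occupation levels in 1..5.
#'   Homemakers and the unemployed are occupation level 1; there is no
#'   separate "not in labor force" code.
#' @return Integer vector of SES scores in 11..55.  `NA` inputs yield `NA`.
#' @examples
#' hollingshead_score(1, 1) # 11
#' hollingshead_score(5, 5) # 55
#' @export
hollingshead_score <- function(education, occupation) {
  if (length(education) != length(occupation))
    stopf("education and occupation must have equal length")
  chk <- function(x, what) {
    bad <- !is.na(x) & (!is.numeric(x) | x < 1 | x > 5 | x != floor(x))
    if (any(bad))
      stopf("%s levels must be integers in 1..5 (bad: %s)", what,
            paste(unique(x[bad]), collapse = ", "))
  }
  chk(education, "education")
  chk(occupation, "occupation")
  as.integer(7L * occupation + 4L * education)
}

#' Assign a family to the low or high SES group
#'
#' A family is "high" SES when either parent's score is strictly above the
#' threshold (the study median, 51); equality with the threshold maps to
#' "low".  A missing parent is ignored; at least one score must be present.
#'
#' @param maternal_score,paternal_score Numeric vectors of SES scores in
#'   11..55 (`NA` allowed for an absent parent).
#' @param threshold Group cut point (default 51, the cohort median score).
#' @return Factor with levels `c("low", "high")`.
#' @export
assign_ses_group <- function(maternal_score, paternal_score, threshold = 51) {
  n <- max(length(maternal_score), length(paternal_score))
  m <- rep_len(maternal_score, n)
  f <- rep_len(paternal_score, n)
  chk <- function(x) {
    if (any(!is.na(x) & (x < 11 | x > 55)))
      stopf("SES scores must lie in 11..55")
  }
  chk(m); chk(f)
  if (any(is.na(m) & is.na(f)))
    stopf("at least one parental SES score is required per family")
  top <- pmax(m, f, na.rm = TRUE)
  factor(ifelse(top > threshold, "high", "low"), levels = c("low", "high"))
}

#' Default maternal distress thresholds
#'
#' Cut points above which each questionnaire indicates high distress:
#' Spielberger State Anxiety Inventory (SSAI) 40, Spielberger Trait Anxiety
#' Inventory (STAI) 40, Perceived Stress Scale (PSS) 15, Edinburgh Postnatal
#' Depression Scale (EPDS) 10.
#' @export
distress_thresholds <- function() {
  c(ssai = 40, stai = 40, pss = 15, epds = 10)
}

#' Flag high maternal distress
#'
#' A visit is high-distress when at least one completed questionnaire total
#' is strictly greater than its threshold.  Equality with a threshold is not
#' an exceedance.  Visits with no completed questionnaire are flagged `NA`
#' (missing), never 0.
#'
#' @param ssai,stai,pss,epds Questionnaire totals (points); `NA` = not
#'   completed.
#' @param thresholds Named numeric vector as from [distress_thresholds()].
#' @return Integer vector: 1 high distress, 0 low, `NA` if all measures are
#'   missing.
#' @export
flag_high_distress <- function(ssai = NA, stai = NA, pss = NA, epds = NA,
                               thresholds = distress_thresholds()) {
  scores <- cbind(ssai = ssai, stai = stai, pss = pss, epds = epds)
  if (any(scores < 0, na.rm = TRUE))
    stopf("questionnaire totals cannot be negative")
  need <- c("ssai", "stai", "pss", "epds")
  if (!all(need %in% names(thresholds)))
    stopf("thresholds must name ssai, stai, pss and epds")
  exceed <- sweep(scores, 2L, thresholds[need], `>`)
  n_present <- rowSums(!is.na(scores))
  out <- as.integer(rowSums(exceed, na.rm = TRUE) > 0)
  out[n_present == 0L] <- NA_integer_
  out
}

#' Derive SES and distress columns for a cohort table
#'
#' Computes parental Hollingshead scores (`ses_m`, `ses_f`), the family SES
#' group (`ses_group`), and the binary high-distress flag (`distress`) from
#' the raw level and questionnaire columns (`edu_m`, `occ_m`, `edu_f`,
#' `occ_f`, `ssai`, `stai`, `pss`, `epds`).
#'
#' @param cohort Data frame with the raw columns above.
#' @param ses_threshold SES group cut point (default 51).
#' @param thresholds Distress thresholds, as in [flag_high_distress()].
#' @return `cohort` with the derived columns appended (overwritten if
#'   present).
#' @export
score_cohort <- function(cohort, ses_threshold = 51,
                         thresholds = distress_thresholds()) {
  need <- c("edu_m", "occ_m", "edu_f", "occ_f")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stopf("cohort lacks column(s): %s", paste(miss, collapse = ", "))
  cohort$ses_m <- hollingshead_score(cohort$edu_m, cohort$occ_m)
  cohort$ses_f <- hollingshead_score(cohort$edu_f, cohort$occ_f)
  cohort$ses_group <- assign_ses_group(cohort$ses_m, cohort$ses_f,
                                       ses_threshold)
  for (q in c("ssai", "stai", "pss", "epds"))
    if (is.null(cohort[[q]])) cohort[[q]] <- NA_real_
  cohort$distress <- flag_high_distress(cohort$ssai, cohort$stai,
                                        cohort$pss, cohort$epds, thresholds)
  cohort
}
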