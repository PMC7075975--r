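#' Assemble the per-duo analysis table
#'
#' Joins scores, phenotypes and design-group labels into the data frame
#' the analysis functions consume, computing all SD-unit variables
#' against the random reference group: parental BMI z-scores are
#' anchored in REF mean/SD, child BMI z-scores come from an LMS
#' reference estimated on REF duos (sex- and age-month-specific), GRSs
#' are standardised with [standardize_scores()] on REF, and child
#' overweight is flagged at the configured reference percentile.
#'
#' @param scores A `score_set` data frame.
#' @param phenotypes Phenotype table with `duo_id`, `maternal_bmi`,
#'   `paternal_bmi`, `child_bmi`, `child_sex`, `child_age_months`.
#' @param groups [sample_design_groups()] output.
#' @param lms_reference Optional LMS table; default: estimated from the
#'   REF duos by [estimate_lms_reference()].
#' @param overweight_percentile Child overweight cutoff as a reference
#'   percentile on the z-scale (default 0.9).
#' @param adult_cutoff Adult overweight cutoff in kg/m^2 (default 25).
#' @return Data frame with one row per duo carrying `group`, raw BMIs,
#'   `maternal_bmi_z`, `paternal_bmi_z`, `child_bmi_z`,
#'   `child_overweight`, `maternal_overweight` and the five `*_sd` GRS
#'   columns.
#' @export
analysis_frame <- function(scores, phenotypes, groups,
                           lms_reference = NULL,
                           overweight_percentile = 0.9,
                           adult_cutoff = 25) {
  d <- merge(merge(phenotypes, groups, by = "duo_id"), scores, by = "duo_id")
  ref <- d$group == "REF"
  if (sum(ref) < 2L) .stopf("need at least 2 REF duos to anchor SD-units")
  anchor <- function(x) {
    mu <- mean(x[ref], na.rm = TRUE); s <- sd(x[ref], na.rm = TRUE)
    if (!is.finite(s) || s == 0) .stopf("degenerate REF distribution")
    (x - mu) / s
  }
  d$maternal_bmi_z <- anchor(d$maternal_bmi)
  d$paternal_bmi_z <- anchor(d$paternal_bmi)
  if (is.null(lms_reference))
    lms_reference <- estimate_lms_reference(d$child_bmi[ref],
                                            d$child_sex[ref],
                                            d$child_age_months[ref])
  d$child_bmi_z <- child_bmi_zscore(d$child_bmi, d$child_sex,
                                    d$child_age_months, lms_reference)
  d$child_overweight <- overweight_flags(d$child_bmi_z,
                                         ow_rule_child_z(overweight_percentile))
  d$maternal_overweight <- overweight_flags(d$maternal_bmi,
                                            ow_rule_adult(adult_cutoff))
  std <- standardize_scores(scores, reference_ids = d$duo_id[ref])
  sd_cols <- grep("_sd$", names(std), value = TRUE)
  d <- merge(d, std[, c("duo_id", sd_cols)], by = "duo_id")
  d
}
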