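# The study-design analysis layer: linear within-reference models,
# case-cohort and exposure-based-cohort logistic models, derived ratio
# statistics and GRS validity correlations.

.DEFAULT_DETERMINANTS <- c(maternal_bmi_z = "Maternal BMI",
                           paternal_bmi_z = "Paternal BMI",
                           child_sd = "Child GRS",
                           maternal_sd = "Maternal GRS",
                           mat_trans_sd = "Maternal transmitted GRS",
                           pat_trans_sd = "Paternal transmitted GRS",
                           mat_nontrans_sd = "Maternal non-transmitted GRS")

.pick_determinants <- function(data, determinants) {
  if (is.null(determinants)) {
    determinants <- .DEFAULT_DETERMINANTS[names(.DEFAULT_DETERMINANTS) %in%
                                            names(data)]
  } else if (is.null(names(determinants))) {
    determinants <- setNames(determinants, determinants)
  }
  miss <- setdiff(names(determinants), names(data))
  if (length(miss))
    .stopf("determinant column(s) not in data: %s", paste(miss, collapse = ", "))
  determinants
}

#' Linear models of child BMI within the reference group
#'
#' One ordinary least-squares model per determinant with continuous
#' child BMI (SD-units) as the outcome, plus parental-BMI models
#' additionally adjusted for the respective transmitted GRS when those
#' columns are present.
#'
#' @param data Data frame with a `child_bmi_z` outcome column and the
#'   determinant columns (SD-units).
#' @param determinants Named character vector mapping column names to
#'   output labels; default: the standard set of parental BMI and the
#'   five GRS components, restricted to available columns.
#' @return A ModelResult data frame, one row per model.
#' @export
run_linear_ref <- function(data, determinants = NULL) {
  determinants <- .pick_determinants(data, determinants)
  rows <- lapply(names(determinants), function(cc)
    fit_linear(data$child_bmi_z, data[[cc]], determinant = determinants[[cc]]))
  adj <- list(c("maternal_bmi_z", "mat_trans_sd", "Maternal BMI | maternal transmitted GRS"),
              c("paternal_bmi_z", "pat_trans_sd", "Paternal BMI | paternal transmitted GRS"))
  for (a in adj) {
    if (all(c(a[1], a[2]) %in% names(data)) && a[1] %in% names(determinants))
      rows <- c(rows, list(fit_linear(data$child_bmi_z, data[[a[1]]],
                                      covariate = data[[a[2]]],
                                      determinant = a[3])))
  }
  do.call(rbind, rows)
}

#' Case-cohort analysis of child overweight
#'
#' Pools the random reference group with the high-child-BMI case group
#' and fits one unadjusted logistic model per determinant with "selected
#' into the case group" as the outcome, mirroring a case-cohort design
#' where case-group membership stands in for childhood overweight.
#' Parental-BMI determinants are additionally re-fit adjusted for the
#' respective transmitted GRS when available.
#'
#' @param data Data frame with one row per duo, a `group` column
#'   (levels including REF and CH_OW) and determinant columns in
#'   SD-units.  REF and CH_OW rows must be disjoint duos.
#' @param determinants As in [run_linear_ref()].
#' @return A ModelResult data frame.
#' @export
run_case_cohort <- function(data, determinants = NULL) {
  if (anyDuplicated(data$duo_id))
    .stopf("duplicated duo_id across groups")
  data <- data[data$group %in% c("REF", "CH_OW"), , drop = FALSE]
  if (!nrow(data)) .stopf("no REF/CH_OW rows")
  outcome <- data$group == "CH_OW"
  determinants <- .pick_determinants(data, determinants)
  rows <- lapply(names(determinants), function(cc)
    fit_logistic(outcome, data[[cc]], determinant = determinants[[cc]]))
  adj <- list(c("maternal_bmi_z", "mat_trans_sd", "Maternal BMI | maternal transmitted GRS"),
              c("paternal_bmi_z", "pat_trans_sd", "Paternal BMI | paternal transmitted GRS"))
  for (a in adj) {
    if (all(c(a[1], a[2]) %in% names(data)) && a[1] %in% names(determinants))
      rows <- c(rows, list(fit_logistic(outcome, data[[a[1]]],
                                        covariate = data[[a[2]]],
                                        determinant = a[3])))
  }
  do.call(rbind, rows)
}

#' Exposure-based cohort analysis of child overweight
#'
#' Pools the random reference group with the high-maternal-BMI group and
#' models actual child overweight, always adjusting for the group
#' indicator (REF = 0).  Optionally adds the group x determinant
#' interaction, reporting per-group ORs and the interaction p-value.
#' The first output row is the unadjusted group-indicator model itself.
#'
#' @param data Data frame with `duo_id`, `group` (REF / MO_OW), a logical
#'   `child_overweight` column and determinant columns in SD-units.
#' @param determinants As in [run_linear_ref()].
#' @param with_interaction Fit interaction models (default `FALSE`).
#' @return A ModelResult data frame.
#' @export
run_exposure_cohort <- function(data, determinants = NULL,
                                with_interaction = FALSE) {
  if (anyDuplicated(data$duo_id))
    .stopf("duplicated duo_id across groups")
  data <- data[data$group %in% c("REF", "MO_OW"), , drop = FALSE]
  if (!nrow(data)) .stopf("no REF/MO_OW rows")
  if (!"child_overweight" %in% names(data))
    .stopf("data must carry a child_overweight column")
  outcome <- as.logical(data$child_overweight)
  gind <- as.numeric(data$group == "MO_OW")
  determinants <- .pick_determinants(data, determinants)
  rows <- list(fit_logistic(outcome, gind,
                            determinant = "Group indicator (MO_OW)"))
  for (cc in names(determinants)) {
    rows <- c(rows, list(
      fit_logistic(outcome, data[[cc]], covariate = gind,
                   interaction = with_interaction,
                   determinant = determinants[[cc]])))
  }
  do.call(rbind, rows)
}

#' Ratio of two regression effect sizes
#'
#' `round(beta_a / beta_b, 2)`: e.g. the effect of a transmitted GRS on
#' child BMI relative to the effect of the corresponding parental BMI.
#'
#' @param beta_a,beta_b Effect sizes on the same scale; `beta_b != 0`.
#' @return Two-decimal ratio.
#' @export
effect_ratio <- function(beta_a, beta_b) {
  if (any(beta_b == 0)) .stopf("zero denominator effect size")
  round(beta_a / beta_b, 2)
}

#' Ratio of two excess odds ratios
#'
#' `round((or_a - 1) / (or_b - 1), 2)`, the excess-odds-ratio comparison
#' used to relate genetic and phenotypic associations on the OR scale.
#'
#' @param or_a Numerator odds ratio.
#' @param or_b Denominator odds ratio; must exceed 1.
#' @return Two-decimal ratio of excess odds ratios.
#' @export
excess_or_ratio <- function(or_a, or_b) {
  if (any(or_b <= 1)) .stopf("denominator odds ratio must exceed 1")
  round((or_a - 1) / (or_b - 1), 2)
}

#' GRS validity correlations
#'
#' Pearson correlations among the five score components, with the
#' analytic expectations that hold under random mating and HWE:
#' full-vs-full parent-child 0.5, half-score vs the full score containing
#' it `1/sqrt(2)`, non-transmitted vs child 0, transmitted maternal vs
#' child `1/sqrt(2)`.  Pairs whose observed correlation deviates from the
#' expectation by more than `3/sqrt(n) + 0.02` are flagged.  Note that
#' assortative mating legitimately raises the parent-child and
#' between-parent correlations; flags signal departure from the
#' random-mating expectation, not an error per se.
#'
#' @param scores A `score_set` (allele-count columns are used; Pearson
#'   correlations are scale-invariant).
#' @return A `validation_report`: data frame of pairs with `observed`,
#'   `expected`, `flag`; the full correlation matrix is attached as
#'   attribute `correlations`.
#' @export
validation_correlations <- function(scores) {
  n <- nrow(scores)
  if (n < 30L) .stopf("need at least 30 duos for validity correlations")
  comps <- c(child = "child_count", maternal = "maternal_count",
             mat_trans = "mat_trans_count", pat_trans = "pat_trans_count",
             mat_nontrans = "mat_nontrans_count")
  m <- as.matrix(scores[, comps])
  colnames(m) <- names(comps)
  if (any(apply(m, 2, sd) == 0)) .stopf("degenerate score variance")
  cm <- cor(m)
  half <- 1 / sqrt(2)
  pairs <- data.frame(
    a = c("maternal", "mat_trans", "pat_trans", "mat_nontrans",
          "maternal", "maternal"),
    b = c("child", "child", "child", "child", "mat_trans", "mat_nontrans"),
    expected = c(0.5, half, half, 0, half, half),
    stringsAsFactors = FALSE)
  pairs$observed <- cm[cbind(pairs$a, pairs$b)]
  tol <- 3 / sqrt(n) + 0.02
  pairs$flag <- abs(pairs$observed - pairs$expected) > tol
  pairs <- pairs[, c("a", "b", "observed", "expected", "flag")]
  attr(pairs, "correlations") <- cm
  attr(pairs, "tolerance") <- tol
  class(pairs) <- c("validation_report", "data.frame")
  pairs
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> tolerance %.3f\n", attr(x, "tolerance")))
  print.data.frame(cbind(x[1:2],
                         observed = round(x$observed, 3),
                         expected = round(x$expected, 3),
                         flag = x$flag))
  invisible(x)
}
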