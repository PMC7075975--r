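# Overweight flags and construction of the three sampling groups
# (random reference, high-maternal-BMI, high-child-BMI).

#' Overweight flags
#'
#' Thresholds a BMI or z-score vector into overweight indicators.  The
#' comparison is inclusive (`value >= cutoff` is overweight).  Rules:
#' * `ow_rule_adult(cutoff = 25)` - absolute adult BMI cutoff in kg/m^2.
#' * `ow_rule_child_z(percentile = 0.9)` - z-score cutoff at the normal
#'   quantile of the given reference percentile (applied to LMS/internal
#'   z-scores).
#' * `ow_rule_percentile(p, reference)` - empirical percentile of a
#'   reference sample, applied on the measurement scale.
#'
#' @param values Numeric vector (BMI or z-scores, matching the rule).
#' @param rule A rule object from one of the constructors above.
#' @return Logical vector (NA where `values` is NA).
#' @export
overweight_flags <- function(values, rule) {
  if (!inherits(rule, "ow_rule")) .stopf("unknown overweight rule")
  cutoff <- switch(rule$type,
                   absolute = rule$cutoff,
                   zscore = rule$cutoff,
                   percentile = quantile(rule$reference, rule$p, names = FALSE,
                                         na.rm = TRUE),
                   .stopf("unknown overweight rule type '%s'", rule$type))
  values >= cutoff
}

#' @rdname overweight_flags
#' @param cutoff Absolute BMI cutoff (kg/m^2).
#' @export
ow_rule_adult <- function(cutoff = 25) {
  structure(list(type = "absolute", cutoff = cutoff), class = "ow_rule")
}

#' @rdname overweight_flags
#' @param percentile Reference percentile defining child overweight
#'   (default 0.9, i.e. the 90th percentile).
#' @export
ow_rule_child_z <- function(percentile = 0.9) {
  structure(list(type = "zscore", cutoff = qnorm(percentile)),
            class = "ow_rule")
}

#' @rdname overweight_flags
#' @param p Percentile in (0, 1).
#' @param reference Reference sample on the measurement scale.
#' @export
ow_rule_percentile <- function(p, reference) {
  structure(list(type = "percentile", p = p, reference = reference),
            class = "ow_rule")
}

#' Sample the three design groups
#'
#' Selects the sampling groups of a BMI-extremes duo design from a source
#' cohort:
#' * `REF`: a uniform random sample of duos;
#' * `MO_OW`: a random sample among duos whose mother's BMI is at or
#'   above `maternal_bmi_threshold`, excluding REF members;
#' * `CH_OW`: the duos with the highest child BMI z-scores, excluding
#'   REF and MO_OW members (ties broken by `duo_id` order).
#'
#' Selection is deterministic given `seed`.
#'
#' @param phenotypes Data frame with `duo_id` and `maternal_bmi`.
#' @param child_z Child BMI z-scores parallel to `phenotypes` rows.
#' @param n_ref,n_mo_ow,n_ch_ow Requested group sizes.
#' @param maternal_bmi_threshold Eligibility threshold for MO_OW
#'   (default 30 kg/m^2, an obesity-range tail; distinct from the
#'   overweight flag cutoff of 25).
#' @param seed Integer seed.
#' @return Data frame `duo_id`, `group` (factor REF / MO_OW / CH_OW /
#'   unselected).
#' @export
sample_design_groups <- function(phenotypes, child_z, n_ref, n_mo_ow, n_ch_ow,
                                 maternal_bmi_threshold = 30, seed = 1L) {
  n <- nrow(phenotypes)
  if (length(child_z) != n) .stopf("child_z must match phenotype rows")
  if (n_ref + n_mo_ow + n_ch_ow > n)
    .stopf("requested group sizes exceed cohort size")
  .set_substream(seed, "design")
  ids <- phenotypes$duo_id
  group <- rep("unselected", n)

  ref_idx <- sample.int(n, n_ref)
  group[ref_idx] <- "REF"

  elig <- which(group == "unselected" &
                  !is.na(phenotypes$maternal_bmi) &
                  phenotypes$maternal_bmi >= maternal_bmi_threshold)
  if (length(elig) < n_mo_ow)
    .stopf("only %d mothers at or above BMI %.1f available for MO_OW (need %d)",
           length(elig), maternal_bmi_threshold, n_mo_ow)
  group[elig[sample.int(length(elig), n_mo_ow)]] <- "MO_OW"

  pool <- which(group == "unselected" & !is.na(child_z))
  if (length(pool) < n_ch_ow)
    .stopf("only %d duos available for CH_OW (need %d)", length(pool), n_ch_ow)
  ord <- pool[order(-child_z[pool], ids[pool])]
  group[ord[seq_len(n_ch_ow)]] <- "CH_OW"

  data.frame(duo_id = ids,
             group = factor(group,
                            levels = c("REF", "MO_OW", "CH_OW", "unselected")),
             stringsAsFactors = FALSE)
}
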