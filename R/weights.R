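#' Read a variant weight table
#'
#' Reads the variant panel that defines a weighted genetic risk score: one
#' row per variant with its effect allele, other allele and per-allele
#' effect-size weight (e.g. a GWAS panel of BMI-associated SNPs).
#'
#' @param path Path to a tab-separated file with header columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `weight`.
#' @param orient If `TRUE` (default), rows with negative weights are
#'   flipped (alleles swapped, weight negated) so that every weight is
#'   non-negative and the effect allele is always the trait-increasing
#'   allele.  All scoring functions assume this orientation.
#' @return A `weight_table`: a data frame in file order with the columns
#'   above, positions 1-based.
#' @seealso [weighted_grs()], [orient_weights()]
#' @export
read_weights <- function(path, orient = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("variant_id", "chrom", "pos", "effect_allele",
                "other_allele", "weight")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    .stopf("weight table is missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  df <- df[required]
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  if (!is.numeric(df$weight))
    .stopf("non-numeric weight values in '%s'", path)
  as_weight_table(df, orient = orient)
}

#' Construct and validate a weight table
#'
#' @param df Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `weight`.
#' @inheritParams read_weights
#' @return A validated `weight_table`.
#' @export
as_weight_table <- function(df, orient = TRUE) {
  dup <- df$variant_id[duplicated(df$variant_id)]
  if (length(dup))
    .stopf("duplicated variant_id: %s", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(df$weight)))
    .stopf("non-finite weight for variant(s): %s",
           paste(df$variant_id[!is.finite(df$weight)], collapse = ", "))
  same <- df$effect_allele == df$other_allele
  if (any(same))
    .stopf("effect and other allele identical for variant(s): %s",
           paste(df$variant_id[same], collapse = ", "))
  df$pos <- as.integer(df$pos)
  if (orient) df <- orient_weights(df)
  rownames(df) <- NULL
  class(df) <- c("weight_table", "data.frame")
  df
}

#' Orient weights so all are non-negative
#'
#' Flips (effect allele, other allele, sign of weight) wherever the weight
#' is negative, making "effect allele" synonymous with "trait-increasing
#' allele" throughout the package.
#'
#' @param weights A weight table.
#' @return The weight table with all weights `>= 0`.
#' @export
orient_weights <- function(weights) {
  neg <- weights$weight < 0
  if (any(neg)) {
    ea <- weights$effect_allele[neg]
    weights$effect_allele[neg] <- weights$other_allele[neg]
    weights$other_allele[neg] <- ea
    weights$weight[neg] <- -weights$weight[neg]
  }
  weights
}

#' Total allele capacity of a panel
#'
#' Number of effect alleles an individual (or haplotype) can maximally
#' carry over a panel: `max_alleles_per_site * n_variants`.  A 941-variant
#' panel gives a per-individual capacity of 1882 alleles.
#'
#' @param weights A weight table.
#' @param max_alleles_per_site 2 for a diploid genotype score, 1 for a
#'   single-haplotype score.
#' @return Integer capacity.
#' @export
allele_capacity <- function(weights, max_alleles_per_site = 2L) {
  if (!max_alleles_per_site %in% c(1L, 2L))
    .stopf("max_alleles_per_site must be 1 or 2")
  as.integer(max_alleles_per_site) * nrow(weights)
}

#' Write a tabular result to TSV
#'
#' Deterministic column order (as given), tab-separated, header always
#' written.  Numeric columns are rendered with a configurable number of
#' significant digits.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 6).
#' @param allow_empty Allow writing a header-only file when `records` has
#'   zero rows.
#' @export
write_table <- function(records, path, digits = 6L, allow_empty = FALSE) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  if (nrow(records) == 0L && !allow_empty)
    .stopf("refusing to write an empty table (set allow_empty = TRUE)")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  }
  ok <- tryCatch({
    write.table(out, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .stopf("cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path TSV with header columns `duo_id`, `maternal_bmi`,
#'   `paternal_bmi`, `child_bmi`, `child_sex`, `child_age_months`.
#'   Paternal BMI may be empty (reported by the mother and often missing);
#'   rows with non-positive maternal, paternal or child BMI are rejected
#'   with a warning.
#' @return A data frame of typed phenotype records.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  required <- c("duo_id", "maternal_bmi", "paternal_bmi", "child_bmi",
                "child_sex", "child_age_months")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    .stopf("phenotype table is missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  df <- df[required]
  df$duo_id <- as.character(df$duo_id)
  for (cc in c("maternal_bmi", "paternal_bmi", "child_bmi"))
    df[[cc]] <- as.numeric(df[[cc]])
  df$child_sex <- as.character(df$child_sex)
  bad_sex <- !df$child_sex %in% c("F", "M")
  if (any(bad_sex))
    .stopf("child_sex must be 'F' or 'M' (offending duo: %s)",
           df$duo_id[bad_sex][1L])
  df$child_age_months <- as.integer(df$child_age_months)
  bad <- (!is.na(df$maternal_bmi) & df$maternal_bmi <= 0) |
    (!is.na(df$child_bmi) & df$child_bmi <= 0) |
    (!is.na(df$paternal_bmi) & df$paternal_bmi <= 0)
  if (any(bad)) {
    .warnf("rejecting %d row(s) with non-positive BMI", sum(bad))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}
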