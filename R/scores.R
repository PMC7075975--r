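# Weighted genetic risk scores on three scales: raw weighted sums,
# allele counts, and SD-units anchored in a reference group.

#' Weighted genetic risk score from dosages
#'
#' The raw GRS: `sum_j w_j g_j` over non-missing sites, with weights
#' oriented so every `w_j >= 0` (effect allele = trait-increasing
#' allele).
#'
#' @param dosages Numeric `V x n` matrix (or length-`V` vector) of
#'   effect-allele dosages in `[0, 2]`, NA = missing, rows aligned to the
#'   weight table.
#' @param weights A weight table (or bare non-negative numeric vector).
#' @return Data frame with one row per individual: `raw` and
#'   `n_sites_used`.
#' @export
weighted_grs <- function(dosages, weights) {
  w <- if (is.data.frame(weights)) weights$weight else weights
  if (any(w < 0)) .stopf("weights must be oriented non-negative")
  if (!is.matrix(dosages)) dosages <- matrix(dosages, ncol = 1L)
  if (nrow(dosages) != length(w))
    .stopf("dosage rows (%d) do not match panel size (%d)",
           nrow(dosages), length(w))
  n_used <- colSums(!is.na(dosages))
  if (any(n_used == 0L))
    .stopf("individual(s) with all sites missing")
  raw <- colSums(dosages * w, na.rm = TRUE)
  data.frame(raw = raw, n_sites_used = n_used)
}

#' Rescale a raw GRS to an allele count
#'
#' Maps the weighted sum onto the scale "number of effect alleles
#' carried": `rescaled = raw * n_variants / sum(w)`.  An individual with
#' average dosage 1 at every site scores exactly `n_variants`; the
#' maximum is [allele_capacity()] (`2 * n_variants` for a genotype
#' score, `n_variants` for a haplotype score).
#'
#' @param raw Numeric raw score(s).
#' @param weights Weight table or non-negative weight vector for the
#'   sites the raw score was computed over.
#' @param max_alleles_per_site 2 for genotype scores, 1 for haplotype
#'   scores (interpretation only; the linear map is identical).
#' @return Numeric allele-count scale score(s).
#' @export
rescale_to_allele_counts <- function(raw, weights, max_alleles_per_site = 2L) {
  w <- if (is.data.frame(weights)) weights$weight else weights
  if (any(w < 0)) .stopf("weights must be oriented non-negative")
  sw <- sum(w)
  if (sw == 0) .stopf("total weight is zero; cannot rescale")
  if (!max_alleles_per_site %in% c(1L, 2L))
    .stopf("max_alleles_per_site must be 1 or 2")
  raw * length(w) / sw
}

#' Haplotype-component GRSs from transmission calls
#'
#' Builds the maternal transmitted, paternal transmitted and maternal
#' non-transmitted raw scores as weighted sums of the called alleles.
#' Because different duos have different sets of called sites, each score
#' is rescaled by `sum(w_all) / sum(w_called)` so that raw scores remain
#' comparable across duos (a duo with a missing high-weight site is
#' scaled up accordingly).
#'
#' @param calls A [infer_duo_transmission()] result.
#' @param weights Weight table aligned to the call matrices.
#' @param min_call_rate Variants with cross-duo call rate below this are
#'   excluded before scoring (default 0.95).
#' @return Data frame with per-duo raw scores `mat_trans`, `pat_trans`,
#'   `mat_nontrans` and the per-component `n_sites_*` counts, plus an
#'   attribute `variants_used` (logical vector over the panel).
#' @export
haplotype_scores <- function(calls, weights, min_call_rate = 0.95) {
  stopifnot(inherits(calls, "transmission_calls"))
  w_all <- weights$weight
  if (any(w_all < 0)) .stopf("weights must be oriented non-negative")
  if (length(w_all) != nrow(calls$mt))
    .stopf("weight table does not match call matrices")
  keep <- variant_call_rate(calls) >= min_call_rate
  if (!any(keep))
    .stopf("no variant passes the %.0f%% call-rate filter",
           100 * min_call_rate)
  w <- w_all[keep]
  one <- function(mat, comp) {
    m <- mat[keep, , drop = FALSE]
    called_w <- colSums(w * !is.na(m))
    if (any(called_w == 0))
      .stopf("duo(s) with zero called sites for the %s score", comp)
    raw <- colSums(w * m, na.rm = TRUE) * sum(w) / called_w
    list(raw = raw, n = colSums(!is.na(m)))
  }
  mt <- one(calls$mt, "maternal transmitted")
  pt <- one(calls$pt, "paternal transmitted")
  mnt <- one(calls$mnt, "maternal non-transmitted")
  out <- data.frame(duo_id = calls$duo_ids,
                    mat_trans = mt$raw, pat_trans = pt$raw,
                    mat_nontrans = mnt$raw,
                    n_sites_mat_trans = mt$n, n_sites_pat_trans = pt$n,
                    n_sites_mat_nontrans = mnt$n,
                    stringsAsFactors = FALSE)
  attr(out, "variants_used") <- keep
  out
}

#' Assemble the five-score set for a duo collection
#'
#' Computes, per duo, the child and maternal full-genotype GRSs and the
#' three haplotype-component GRSs from transmission calls, on the raw and
#' allele-count scales.  Full scores use the same call-rate-filtered
#' variant set and the same missingness rescaling as the haplotype
#' scores, so the additivity identities (child = maternal transmitted +
#' paternal transmitted, maternal = transmitted + non-transmitted) hold
#' exactly on complete data.
#'
#' @param duos A [duo_genotypes()] collection.
#' @param calls Matching [infer_duo_transmission()] result.
#' @param weights Weight table aligned to the panel.
#' @param min_call_rate Variant call-rate filter (default 0.95).
#' @param hardcall_threshold Dosage hard-call threshold for the full
#'   genotype scores.
#' @return A `score_set` data frame: per duo `child_raw`, `child_count`,
#'   `maternal_raw`, `maternal_count`, `mat_trans_*`, `pat_trans_*`,
#'   `mat_nontrans_*` and `n_sites_*` columns.
#' @export
build_score_set <- function(duos, calls, weights, min_call_rate = 0.95,
                            hardcall_threshold = 0.1) {
  stopifnot(inherits(duos, "duo_genotypes"))
  hap <- haplotype_scores(calls, weights, min_call_rate)
  keep <- attr(hap, "variants_used")
  w <- weights$weight[keep]
  g <- .duo_genotype_matrices(duos, hardcall_threshold)
  full <- function(mat) {
    m <- mat[keep, , drop = FALSE]
    called_w <- colSums(w * !is.na(m))
    if (any(called_w == 0)) .stopf("duo(s) with all filtered sites missing")
    list(raw = colSums(w * m, na.rm = TRUE) * sum(w) / called_w,
         n = colSums(!is.na(m)))
  }
  ch <- full(g$child)
  mo <- full(g$mother)
  to_count <- function(raw) rescale_to_allele_counts(raw, w)
  out <- data.frame(
    duo_id = duos$duo_ids,
    child_raw = ch$raw, child_count = to_count(ch$raw),
    maternal_raw = mo$raw, maternal_count = to_count(mo$raw),
    mat_trans_raw = hap$mat_trans,
    mat_trans_count = rescale_to_allele_counts(hap$mat_trans, w, 1L),
    pat_trans_raw = hap$pat_trans,
    pat_trans_count = rescale_to_allele_counts(hap$pat_trans, w, 1L),
    mat_nontrans_raw = hap$mat_nontrans,
    mat_nontrans_count = rescale_to_allele_counts(hap$mat_nontrans, w, 1L),
    n_sites_child = ch$n, n_sites_maternal = mo$n,
    n_sites_mat_trans = hap$n_sites_mat_trans,
    n_sites_pat_trans = hap$n_sites_pat_trans,
    n_sites_mat_nontrans = hap$n_sites_mat_nontrans,
    stringsAsFactors = FALSE)
  class(out) <- c("score_set", "data.frame")
  attr(out, "variants_used") <- keep
  out
}

#' Score set from simulated truth
#'
#' The same shape as [build_score_set()] but computed from the
#' simulator's true transmissions (no inference, no missingness); useful
#' as ground truth and for large statistical-property simulations.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A `score_set` data frame.
#' @export
truth_score_set <- function(cohort) {
  stopifnot(inherits(cohort, "trio_cohort"))
  ts <- cohort$truth_scores
  w <- cohort$variants$weight
  out <- data.frame(
    duo_id = ts$duo_id,
    child_raw = ts$child,
    child_count = rescale_to_allele_counts(ts$child, w),
    maternal_raw = ts$maternal,
    maternal_count = rescale_to_allele_counts(ts$maternal, w),
    mat_trans_raw = ts$mat_trans,
    mat_trans_count = rescale_to_allele_counts(ts$mat_trans, w, 1L),
    pat_trans_raw = ts$pat_trans,
    pat_trans_count = rescale_to_allele_counts(ts$pat_trans, w, 1L),
    mat_nontrans_raw = ts$mat_nontrans,
    mat_nontrans_count = rescale_to_allele_counts(ts$mat_nontrans, w, 1L),
    n_sites_child = nrow(cohort$variants),
    n_sites_maternal = nrow(cohort$variants),
    n_sites_mat_trans = nrow(cohort$variants),
    n_sites_pat_trans = nrow(cohort$variants),
    n_sites_mat_nontrans = nrow(cohort$variants),
    stringsAsFactors = FALSE)
  class(out) <- c("score_set", "data.frame")
  out
}

#' Standardise scores to SD-units against a reference group
#'
#' Adds `*_sd` columns: `(allele_count - mean_ref) / sd_ref` per score
#' component, where mean and SD are computed over the designated
#' reference duos only (in a selected-sample design, the random reference
#' group anchors the scale).
#'
#' @param scores A `score_set` data frame.
#' @param reference_ids Duo ids defining the reference group (default:
#'   all duos).
#' @return The score set with `child_sd`, `maternal_sd`, `mat_trans_sd`,
#'   `pat_trans_sd`, `mat_nontrans_sd` columns added.
#' @export
standardize_scores <- function(scores, reference_ids = scores$duo_id) {
  ref <- scores$duo_id %in% reference_ids
  if (sum(ref) < 2L) .stopf("reference group must contain at least 2 duos")
  comps <- c("child", "maternal", "mat_trans", "pat_trans", "mat_nontrans")
  for (comp in comps) {
    x <- scores[[paste0(comp, "_count")]]
    mu <- mean(x[ref]); s <- sd(x[ref])
    if (!is.finite(s) || s == 0)
      .stopf("zero variance in reference group for the %s score", comp)
    scores[[paste0(comp, "_sd")]] <- (x - mu) / s
  }
  scores
}
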