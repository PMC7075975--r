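#' Simulation parameters for a synthetic trio cohort
#'
#' Defines the generative model for mother-father-child trios with known
#' allelic transmissions.  Haplotype alleles are drawn independently under
#' Hardy-Weinberg equilibrium; children inherit one parental haplotype per
#' haplotype block; parental BMI (z-scale) loads on the parent's own full
#' genetic score; child BMI z is a linear combination of the transmitted
#' half-scores, an optional maternal-nurture term (the non-transmitted
#' maternal half-score), an optional shared-environment term and residual
#' noise scaled to unit total variance.
#'
#' @param n_trios Number of trios.
#' @param n_variants Panel size (default 941, the size of the adult-BMI
#'   GWAS panel the package emulates).
#' @param allele_freq Effect-allele frequency law: a length-2 numeric
#'   range for `Uniform(lo, hi)` draws (default `c(0.1, 0.9)`), a single
#'   value for a constant frequency, or a length-`n_variants` vector.
#' @param weight_sd Scale of the half-normal per-allele weight draw
#'   (`|N(0, weight_sd^2)|`); weights only set the raw-score scale, the
#'   phenotype model standardises scores internally.  Default 0.02, a
#'   typical per-allele effect magnitude for a polygenic anthropometric
#'   trait.
#' @param beta_transmitted Effect (per SD) of each transmitted half-score
#'   on child BMI z.  Default 0.17, which makes the two transmitted
#'   half-scores jointly explain about 6% of child BMI variance, matching
#'   the variance explained reported for the emulated panel in adults.
#' @param beta_nurture Effect (per SD) of the maternal non-transmitted
#'   half-score on child BMI z (genetic nurture; default 0).
#' @param beta_shared_env Effect (per SD) of a family-level environment
#'   deviate shared between mother and child (default 0).
#' @param spousal_corr Target phenotypic mother-father BMI-z correlation,
#'   achieved by Gaussian-copula rank matching (default 0 = random
#'   mating).
#' @param h2_parent Fraction of parental BMI-z variance explained by the
#'   parent's own full score (default 0.06).
#' @param block_length Variants per haplotype block; blocks are labelled
#'   as chromosomes in the generated panel, so block boundaries are known
#'   to downstream window matching the way chromosome boundaries are in
#'   real data.  Default 50.
#' @param recomb_prob Probability that the transmitted parental haplotype
#'   switches between consecutive blocks (default 0.5 = independent
#'   blocks).
#' @param phase_error_rate Per-site switch-error probability applied to
#'   the observed (phased) mother and child haplotypes (default 0).
#' @param genotype_missing_rate Per-site, per-individual probability that
#'   the observed genotype is missing (default 0).
#' @param seed Master seed; all randomness flows from it through named
#'   substreams.
#' @return A validated `sim_params` object.
#' @export
sim_params <- function(n_trios,
                       n_variants = 941L,
                       allele_freq = c(0.1, 0.9),
                       weight_sd = 0.02,
                       beta_transmitted = 0.17,
                       beta_nurture = 0,
                       beta_shared_env = 0,
                       spousal_corr = 0,
                       h2_parent = 0.06,
                       block_length = 50L,
                       recomb_prob = 0.5,
                       phase_error_rate = 0,
                       genotype_missing_rate = 0,
                       seed = 1L) {
  n_trios <- as.integer(n_trios)
  n_variants <- as.integer(n_variants)
  if (is.na(n_trios) || n_trios < 0L) .stopf("n_trios must be >= 0")
  if (is.na(n_variants) || n_variants < 1L) .stopf("n_variants must be >= 1")
  if (!length(allele_freq) %in% c(1L, 2L, n_variants))
    .stopf("allele_freq must have length 1, 2 or n_variants")
  if (any(allele_freq <= 0 | allele_freq >= 1))
    .stopf("allele frequencies must lie in (0, 1)")
  if (weight_sd <= 0) .stopf("weight_sd must be positive")
  .check_prob(h2_parent, "h2_parent")
  .check_prob(recomb_prob, "recomb_prob")
  .check_prob(phase_error_rate, "phase_error_rate")
  .check_prob(genotype_missing_rate, "genotype_missing_rate")
  if (abs(spousal_corr) > 1) .stopf("spousal_corr must be in [-1, 1]")
  if (block_length < 1L) .stopf("block_length must be >= 1")
  # idealised variance budget (independent components); the exact
  # empirical decomposition is re-checked at simulation time
  sys_var <- 2 * beta_transmitted^2 + beta_nurture^2 + beta_shared_env^2
  if (sys_var > 1)
    .stopf(paste("impossible variance decomposition: systematic child BMI",
                 "variance %.3f exceeds 1"), sys_var)
  if (h2_parent + beta_shared_env^2 > 1)
    .stopf("h2_parent + beta_shared_env^2 must not exceed 1")
  structure(list(n_trios = n_trios, n_variants = n_variants,
                 allele_freq = allele_freq, weight_sd = weight_sd,
                 beta_transmitted = beta_transmitted,
                 beta_nurture = beta_nurture,
                 beta_shared_env = beta_shared_env,
                 spousal_corr = spousal_corr, h2_parent = h2_parent,
                 block_length = as.integer(block_length),
                 recomb_prob = recomb_prob,
                 phase_error_rate = phase_error_rate,
                 genotype_missing_rate = genotype_missing_rate,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  %d trios x %d variants (blocks of %d)\n",
              x$n_trios, x$n_variants, x$block_length))
  cat(sprintf("  beta_transmitted=%.3f nurture=%.3f shared_env=%.3f\n",
              x$beta_transmitted, x$beta_nurture, x$beta_shared_env))
  cat(sprintf("  spousal_corr=%.2f h2_parent=%.2f phase_err=%.3f miss=%.3f seed=%d\n",
              x$spousal_corr, x$h2_parent, x$phase_error_rate,
              x$genotype_missing_rate, x$seed))
  invisible(x)
}

#' Read simulation parameters from a YAML config
#'
#' @param path YAML file whose top-level keys are [sim_params()]
#'   arguments.
#' @return A `sim_params` object.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sim_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(cfg$allele_freq)) cfg$allele_freq <- unlist(cfg$allele_freq)
  do.call(sim_params, cfg)
}
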