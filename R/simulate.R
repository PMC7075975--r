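#' Simulate a trio cohort with known allelic transmissions
#'
#' Generates mother-father-child trios under the model described in
#' [sim_params()]: HWE haplotypes over a weighted variant panel,
#' phenotypic assortative mating by Gaussian-copula rank matching,
#' block-wise Mendelian transmission, polygenic parent and child BMI with
#' configurable transmitted, nurture and shared-environment components,
#' and an observed mother-child duo view (fathers withheld) with optional
#' phasing switch errors and genotype missingness.
#'
#' @param params A [sim_params()] object.
#' @return A `trio_cohort` list with elements `params`, `variants` (the
#'   generated weight panel with a `freq` column), truth haplotypes
#'   (`mother_h1/h2`, `father_h1/h2`, `child_mat`, `child_pat`), block
#'   transmission choices (`mat_choice`, `pat_choice`), `phenotypes`,
#'   `latent` (true z-scales), `truth_scores` (raw truth GRS components)
#'   and `duos` (the observed [duo_genotypes()]).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_trios
  V <- params$n_variants
  seed <- params$seed

  # --- panel: frequencies, weights, alleles, block structure ---
  .set_substream(seed, "panel")
  p <- switch(as.character(length(params$allele_freq)),
              "1" = rep(params$allele_freq, V),
              "2" = runif(V, params$allele_freq[1], params$allele_freq[2]),
              params$allele_freq)
  w <- abs(rnorm(V, 0, params$weight_sd))
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("A", "T"), c("C", "G"))
  pick <- sample.int(nrow(pairs), V, replace = TRUE,
                     prob = c(.22, .22, .22, .22, .06, .06))
  swap <- runif(V) < 0.5
  ea <- ifelse(swap, pairs[pick, 2], pairs[pick, 1])
  oa <- ifelse(swap, pairs[pick, 1], pairs[pick, 2])
  block <- (seq_len(V) - 1L) %/% params$block_length + 1L
  pos_in <- ave(seq_len(V), block, FUN = seq_along)
  variants <- as_weight_table(data.frame(
    variant_id = sprintf("v%05d", seq_len(V)),
    chrom = as.character(block),
    pos = pos_in * 5000L,
    effect_allele = ea, other_allele = oa,
    weight = w, stringsAsFactors = FALSE), orient = FALSE)
  variants$freq <- p

  if (n == 0L) return(.empty_cohort(params, variants))

  # --- parental haplotypes under HWE ---
  .set_substream(seed, "haplotypes")
  draw <- function() matrix(rbinom(V * n, 1L, p), nrow = V)
  mh1 <- draw(); mh2 <- draw(); fh1 <- draw(); fh2 <- draw()

  m_raw <- colSums((mh1 + mh2) * w)
  f_raw <- colSums((fh1 + fh2) * w)

  # --- parental phenotypes and assortative mating ---
  .set_substream(seed, "phenotypes")
  h2 <- params$h2_parent
  bse <- params$beta_shared_env
  env <- rnorm(n)                     # family-level shared environment
  res_load <- sqrt(max(0, 1 - h2 - bse^2))
  mother_z <- sqrt(h2) * .zstd(m_raw) + bse * env + res_load * rnorm(n)
  father_z <- sqrt(h2) * .zstd(f_raw) + res_load * rnorm(n) +
    bse * rnorm(n)                    # father's env is his own household's
  .set_substream(seed, "mating")
  rho <- params$spousal_corr
  u <- rnorm(n)
  v <- rho * u + sqrt(1 - rho^2) * rnorm(n)
  # couple j pairs the rank(u)[j]-th mother (by BMI z) with the
  # rank(v)[j]-th father; mothers keep their original order
  mo_of_couple <- order(mother_z)[rank(u, ties.method = "first")]
  fa_of_couple <- order(father_z)[rank(v, ties.method = "first")]
  fperm <- integer(n)
  fperm[mo_of_couple] <- fa_of_couple
  fh1 <- fh1[, fperm, drop = FALSE]
  fh2 <- fh2[, fperm, drop = FALSE]
  father_z <- father_z[fperm]
  f_raw <- f_raw[fperm]

  # --- block-wise transmission ---
  .set_substream(seed, "transmission")
  nb <- max(block)
  markov_choice <- function() {
    ch <- matrix(1L, nrow = nb, ncol = n)
    ch[1, ] <- 1L + rbinom(n, 1L, 0.5)
    if (nb > 1L) for (b in 2:nb) {
      sw <- rbinom(n, 1L, params$recomb_prob) == 1L
      ch[b, ] <- ifelse(sw, 3L - ch[b - 1L, ], ch[b - 1L, ])
    }
    ch
  }
  mat_choice <- markov_choice()
  pat_choice <- markov_choice()
  pick_hap <- function(h1, h2, choice) {
    out <- h1
    sel <- choice[block, , drop = FALSE] == 2L
    out[sel] <- h2[sel]
    out
  }
  child_mat <- pick_hap(mh1, mh2, mat_choice)
  child_pat <- pick_hap(fh1, fh2, pat_choice)

  mt_raw <- colSums(child_mat * w)
  pt_raw <- colSums(child_pat * w)
  mnt_raw <- m_raw - mt_raw
  c_raw <- mt_raw + pt_raw

  # --- child phenotype; residual variance completes to 1 ---
  .set_substream(seed, "child_phenotypes")
  sys <- params$beta_transmitted * (.zstd(mt_raw) + .zstd(pt_raw)) +
    params$beta_nurture * .zstd(mnt_raw) + bse * env
  sys_var <- if (n > 1) stats::var(sys) else 0
  if (sys_var > 1)
    .stopf("impossible variance decomposition: systematic variance %.3f > 1",
           sys_var)
  child_z <- sys + sqrt(1 - sys_var) * rnorm(n)

  duo_ids <- sprintf("duo%05d", seq_len(n))
  child_sex <- ifelse(rbinom(n, 1L, 0.5) == 1L, "M", "F")
  age <- pmin(96L, pmax(72L, as.integer(round(rnorm(n, 84, 3.6)))))
  phenotypes <- data.frame(
    duo_id = duo_ids,
    maternal_bmi = 23.1 + 3.2 * mother_z,
    paternal_bmi = 25.1 + 3.0 * father_z,
    child_bmi = 15.6 + 1.6 * child_z,
    child_sex = child_sex,
    child_age_months = age,
    stringsAsFactors = FALSE)

  truth_scores <- data.frame(
    duo_id = duo_ids,
    child = c_raw, maternal = m_raw, paternal = f_raw,
    mat_trans = mt_raw, pat_trans = pt_raw, mat_nontrans = mnt_raw,
    stringsAsFactors = FALSE)

  # --- observed duo view: random within-child haplotype order, then
  #     switch errors and genotype missingness ---
  .set_substream(seed, "phase_obs")
  csw <- rbinom(n, 1L, 0.5) == 1L
  ch1 <- child_mat; ch2 <- child_pat
  if (any(csw)) {
    ch1[, csw] <- child_pat[, csw]
    ch2[, csw] <- child_mat[, csw]
  }
  duos <- duo_genotypes(variants, mh1, mh2, ch1, ch2, duo_ids = duo_ids)
  if (params$phase_error_rate > 0)
    duos <- inject_phase_errors(duos, params$phase_error_rate,
                                seed = .substream_seed(seed, "phase_errors"))
  if (params$genotype_missing_rate > 0) {
    .set_substream(seed, "missingness")
    miss_m <- matrix(runif(V * n) < params$genotype_missing_rate, nrow = V)
    miss_c <- matrix(runif(V * n) < params$genotype_missing_rate, nrow = V)
    duos$mother_h1[miss_m] <- NA_integer_
    duos$mother_h2[miss_m] <- NA_integer_
    duos$child_h1[miss_c] <- NA_integer_
    duos$child_h2[miss_c] <- NA_integer_
  }

  structure(list(params = params, variants = variants,
                 mother_h1 = mh1, mother_h2 = mh2,
                 father_h1 = fh1, father_h2 = fh2,
                 child_mat = child_mat, child_pat = child_pat,
                 mat_choice = mat_choice, pat_choice = pat_choice,
                 phenotypes = phenotypes,
                 latent = data.frame(duo_id = duo_ids, mother_z = mother_z,
                                     father_z = father_z, child_z = child_z,
                                     shared_env = env,
                                     stringsAsFactors = FALSE),
                 truth_scores = truth_scores,
                 duos = duos),
            class = "trio_cohort")
}

.empty_cohort <- function(params, variants) {
  V <- nrow(variants)
  e <- matrix(integer(0), nrow = V, ncol = 0)
  ef <- function(...) data.frame(..., stringsAsFactors = FALSE)[0, , drop = FALSE]
  structure(list(params = params, variants = variants,
                 mother_h1 = e, mother_h2 = e, father_h1 = e, father_h2 = e,
                 child_mat = e, child_pat = e,
                 mat_choice = matrix(integer(0), nrow = 0, ncol = 0),
                 pat_choice = matrix(integer(0), nrow = 0, ncol = 0),
                 phenotypes = ef(duo_id = character(), maternal_bmi = numeric(),
                                 paternal_bmi = numeric(), child_bmi = numeric(),
                                 child_sex = character(),
                                 child_age_months = integer()),
                 latent = ef(duo_id = character(), mother_z = numeric(),
                             father_z = numeric(), child_z = numeric(),
                             shared_env = numeric()),
                 truth_scores = ef(duo_id = character(), child = numeric(),
                                   maternal = numeric(), paternal = numeric(),
                                   mat_trans = numeric(), pat_trans = numeric(),
                                   mat_nontrans = numeric()),
                 duos = duo_genotypes(variants, e, e, e, e,
                                      duo_ids = character(0))),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("<trio_cohort> %d trios x %d variants (seed %d)\n",
              ncol(x$mother_h1), nrow(x$variants), x$params$seed))
  invisible(x)
}

#' Inject haplotype switch errors into observed duo genotypes
#'
#' Applies the standard switch-error model of statistical phasing: at each
#' site, independently with probability `rate`, the haplotype assignment
#' of that site and all subsequent sites of the same region (chromosome /
#' haplotype block) is swapped.  Two switches cancel, so a site's final
#' assignment is flipped iff an odd number of switch events occurred at or
#' before it within its region.  Genotypes (`h1 + h2`) are unchanged.
#'
#' @param duos A [duo_genotypes()] object.
#' @param rate Per-site switch probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The duo collection with mother and child haplotypes perturbed
#'   independently.
#' @export
inject_phase_errors <- function(duos, rate, seed = 1L) {
  .check_prob(rate, "rate")
  if (rate == 0) return(duos)
  set.seed(as.integer(seed))
  V <- nrow(duos$variants)
  n <- length(duos$duo_ids)
  rb <- .region_bounds(duos$variants$chrom)
  idx <- seq_len(V)
  swap_pair <- function(h1, h2) {
    ev <- matrix(rbinom(V * n, 1L, rate), nrow = V)
    s <- c(0, cumsum(ev))
    cells <- seq_len(V * n)
    i <- ((cells - 1L) %% V) + 1L
    off <- cells - i
    odd <- (s[off + idx[i] + 1L] - s[off + rb$start[i]]) %% 2L == 1L
    odd <- matrix(odd, nrow = V)
    o1 <- h1
    o1[odd] <- h2[odd]
    h2[odd] <- h1[odd]
    list(o1, h2)
  }
  m <- swap_pair(duos$mother_h1, duos$mother_h2)
  duos$mother_h1 <- m[[1]]; duos$mother_h2 <- m[[2]]
  ch <- swap_pair(duos$child_h1, duos$child_h2)
  duos$child_h1 <- ch[[1]]; duos$child_h2 <- ch[[2]]
  duos
}

#' Export a simulated cohort to disk
#'
#' Writes the observed mother-child data the way a real study would
#' receive it: a phased VCF containing mothers and children only (fathers
#' are withheld, mirroring studies with no paternal genotypes), the
#' phenotype TSV, the weight panel TSV and a truth TSV with the simulated
#' raw score components for validation.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written (`vcf`, `phenotypes`, `weights`,
#'   `truth`).
#' @export
export_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "trio_cohort"))
  if (nrow(cohort$truth_scores) == 0L) .stopf("cannot export an empty cohort")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    .stopf("cannot create output directory '%s'", out_dir)
  paths <- c(vcf = file.path(out_dir, "duos.vcf"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             weights = file.path(out_dir, "weights.tsv"),
             truth = file.path(out_dir, "truth_scores.tsv"))
  .write_phased_vcf(cohort$duos, paths[["vcf"]])
  write_table(cohort$phenotypes, paths[["phenotypes"]])
  wt <- cohort$variants
  class(wt) <- "data.frame"
  write_table(wt[c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "weight")], paths[["weights"]], digits = 10)
  write_table(cohort$truth_scores, paths[["truth"]], digits = 10)
  invisible(paths)
}
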