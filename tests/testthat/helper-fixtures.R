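# Shared fixtures, built in code.

# small weight panel as a plain data frame
make_panel <- function(V = 10L, block = 5L, weights = NULL, seed = 42L) {
  set.seed(seed)
  if (is.null(weights)) weights <- round(abs(rnorm(V, 0, 0.02)), 6)
  as_weight_table(data.frame(
    variant_id = sprintf("v%03d", seq_len(V)),
    chrom = as.character((seq_len(V) - 1L) %/% block + 1L),
    pos = (ave(seq_len(V), (seq_len(V) - 1L) %/% block, FUN = seq_along)) * 100L,
    effect_allele = rep(c("A", "C"), length.out = V),
    other_allele = rep(c("G", "T"), length.out = V),
    weight = weights,
    stringsAsFactors = FALSE))
}

# hand-built duo collection from allele matrices
make_duos <- function(mh1, mh2, ch1, ch2, block = nrow(mh1), ...) {
  V <- nrow(mh1)
  panel <- make_panel(V = V, block = block)
  duo_genotypes(panel, mh1, mh2, ch1, ch2,
                duo_ids = sprintf("d%02d", seq_len(ncol(mh1))), ...)
}

# a small simulated cohort most test files can share
tiny_cohort <- function(n = 60L, V = 100L, seed = 11L, ...) {
  simulate_cohort(sim_params(n_trios = n, n_variants = V, seed = seed, ...))
}

# truth transmission-accuracy of a call set against the simulator
call_accuracy <- function(cohort, calls) {
  called <- !is.na(calls$mt)
  c(mt = mean(calls$mt[called] == cohort$child_mat[called]),
    pt = mean(calls$pt[called] == cohort$child_pat[called]))
}
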