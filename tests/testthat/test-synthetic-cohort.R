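# The trio simulator: determinism, Mendelian structure, sampling laws.

test_that("an empty cohort is valid and simulation is seed-deterministic", {
  co0 <- simulate_cohort(sim_params(n_trios = 0L, n_variants = 20L))
  expect_equal(nrow(co0$phenotypes), 0L)
  expect_equal(ncol(co0$mother_h1), 0L)

  a <- tiny_cohort(n = 40L, V = 60L, seed = 9L)
  b <- tiny_cohort(n = 40L, V = 60L, seed = 9L)
  expect_identical(a$duos$mother_h1, b$duos$mother_h1)
  expect_identical(a$duos$child_h1, b$duos$child_h1)
  expect_identical(a$phenotypes, b$phenotypes)
  d <- tiny_cohort(n = 40L, V = 60L, seed = 10L)
  expect_false(identical(a$duos$mother_h1, d$duos$mother_h1))
})

test_that("named substreams isolate the random components", {
  # toggling phase errors must not shift haplotype or phenotype draws
  a <- tiny_cohort(n = 30L, V = 40L, seed = 2L, phase_error_rate = 0)
  b <- tiny_cohort(n = 30L, V = 40L, seed = 2L, phase_error_rate = 0.2)
  expect_identical(a$mother_h1, b$mother_h1)
  expect_identical(a$child_mat, b$child_mat)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_false(identical(a$duos$mother_h1, b$duos$mother_h1))
})

test_that("empirical allele frequencies follow the binomial sampling law", {
  co <- simulate_cohort(sim_params(n_trios = 20000L, n_variants = 50L,
                                   seed = 21L))
  p <- co$variants$freq
  n_haps <- 4 * 20000
  phat <- (rowSums(co$mother_h1) + rowSums(co$mother_h2) +
             rowSums(co$father_h1) + rowSums(co$father_h2)) / n_haps
  se <- sqrt(p * (1 - p) / n_haps)
  expect_true(all(abs(phat - p) < 4 * se))
  expect_true(mean(abs(phat - p) < 2 * se) > 0.9)
})

test_that("copula rank matching hits the target spousal correlation", {
  co <- simulate_cohort(sim_params(n_trios = 20000L, n_variants = 60L,
                                   spousal_corr = 0.3, seed = 22L))
  r <- cor(co$latent$mother_z, co$latent$father_z)
  expect_equal(r, 0.3, tolerance = 0.02 / 0.3)
  # and the phenotype table inherits it
  r2 <- cor(co$phenotypes$maternal_bmi, co$phenotypes$paternal_bmi)
  expect_equal(r2, 0.3, tolerance = 0.025 / 0.3)
})

test_that("truth obeys Mendelian transmission and score additivity", {
  co <- tiny_cohort(n = 80L, V = 120L, seed = 13L)
  g_m <- co$mother_h1 + co$mother_h2
  g_c <- co$child_mat + co$child_pat
  expect_false(any((g_m == 0L & g_c == 2L) | (g_m == 2L & g_c == 0L)))
  # child haplotypes are block-wise copies of the labelled parental ones
  blocks <- as.integer(co$variants$chrom)
  for (j in c(1L, 40L)) {
    pick <- co$mat_choice[blocks, j]
    expected <- ifelse(pick == 1L, co$mother_h1[, j], co$mother_h2[, j])
    expect_identical(co$child_mat[, j], expected)
  }
  ts <- co$truth_scores
  expect_equal(ts$child, ts$mat_trans + ts$pat_trans)
  expect_equal(ts$maternal, ts$mat_trans + ts$mat_nontrans)
})

test_that("random mating decorrelates maternal and paternal scores", {
  co <- simulate_cohort(sim_params(n_trios = 20000L, n_variants = 100L,
                                   spousal_corr = 0, seed = 23L))
  r <- cor(co$truth_scores$maternal, co$truth_scores$pat_trans)
  expect_lt(abs(r), 3 / sqrt(20000))
})

test_that("transmitted effects drive the child phenotype as configured", {
  co <- simulate_cohort(sim_params(n_trios = 20000L, n_variants = 100L,
                                   beta_transmitted = 0.3, seed = 24L))
  ts <- co$truth_scores
  r <- cor(co$latent$child_z, scale(ts$mat_trans) + scale(ts$pat_trans))
  # corr = beta * sqrt(2) for independent half-scores
  expect_equal(as.numeric(r), 0.3 * sqrt(2), tolerance = 0.05)
  co0 <- simulate_cohort(sim_params(n_trios = 5000L, n_variants = 100L,
                                    beta_transmitted = 0, seed = 25L))
  expect_lt(abs(cor(co0$latent$child_z, co0$truth_scores$child)), 0.05)
})

test_that("an impossible variance budget is rejected before sampling", {
  expect_error(sim_params(n_trios = 10L, beta_transmitted = 0.6,
                          beta_nurture = 0.6),
               "variance decomposition")
  expect_error(sim_params(n_trios = 10L, phase_error_rate = 1.2), "\\[0, 1\\]")
})

test_that("switch errors respect parity and conserve genotypes", {
  co <- tiny_cohort(n = 20L, V = 40L, seed = 3L)
  expect_identical(inject_phase_errors(co$duos, 0), co$duos)

  # forced switches on a 2-site region: site 1 flips once, site 2 twice
  mh1 <- matrix(c(0L, 0L), 2, 1); mh2 <- matrix(c(1L, 1L), 2, 1)
  duos <- make_duos(mh1, mh2, mh1, mh2, block = 2L)
  out <- inject_phase_errors(duos, 1, seed = 1L)
  expect_equal(out$mother_h1[, 1], c(1L, 0L))
  expect_equal(out$mother_h2[, 1], c(0L, 1L))

  noisy <- inject_phase_errors(co$duos, 0.3, seed = 5L)
  expect_identical(noisy$mother_h1 + noisy$mother_h2,
                   co$duos$mother_h1 + co$duos$mother_h2)
  expect_identical(noisy$child_h1 + noisy$child_h2,
                   co$duos$child_h1 + co$duos$child_h2)
})

test_that("genotype missingness is injected at the requested rate", {
  co <- tiny_cohort(n = 200L, V = 200L, seed = 6L,
                    genotype_missing_rate = 0.05)
  miss <- mean(is.na(co$duos$mother_h1))
  expect_equal(miss, 0.05, tolerance = 0.1)
  # both haplotypes of a site go missing together
  expect_identical(is.na(co$duos$mother_h1), is.na(co$duos$mother_h2))
})
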