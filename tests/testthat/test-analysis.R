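# The statistical layer: regression primitives, design analyses,
# derived ratios, group comparisons, validity correlations.

test_that("linear fits match the normal-equations oracle", {
  r <- suppressWarnings(fit_linear(c(1, 3, 5), c(0, 1, 2)))
  expect_equal(r$estimate, 2)
  expect_equal(r$r_squared, 1)
  r2 <- suppressWarnings(fit_linear(1:10, 1:10))
  expect_equal(r2$estimate, 1)
  expect_equal(r2$r_squared, 1)

  set.seed(91)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  fit <- fit_linear(y, x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$estimate, unname(beta[2, 1]), tolerance = 1e-10)
  expect_error(fit_linear(y, rep(1, 20)), "constant")
})

test_that("logistic fits reproduce the cross-product odds ratio", {
  case <- rep(c(TRUE, FALSE), times = c(100, 100))
  expos <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  fit <- fit_logistic(case, expos)
  expect_equal(fit$estimate, (20 * 90) / (80 * 10), tolerance = 1e-8)
  expect_true(fit$ci_low < fit$estimate && fit$estimate < fit$ci_high)

  # permuted null: OR near 1, CI covers 1
  set.seed(92)
  x <- rnorm(400)
  nullfit <- fit_logistic(rep(c(TRUE, FALSE), 200), x)
  expect_true(nullfit$ci_low < 1 && nullfit$ci_high > 1)

  # separation raises, single-class raises
  expect_error(fit_logistic(c(TRUE, TRUE, FALSE, FALSE), c(2, 3, -2, -3)),
               "separation")
  expect_error(fit_logistic(rep(TRUE, 10), rnorm(10)), "single class")
})

test_that("interaction models report per-group ORs and a p-value", {
  set.seed(93)
  n <- 2000L
  g <- rep(0:1, each = n / 2)
  x <- rnorm(n)
  # group-specific slopes 0.8 and 0.2
  eta <- -0.5 + 0.8 * x - 0.6 * x * g + 0.3 * g
  y <- runif(n) < plogis(eta)
  fit <- fit_logistic(y, x, covariate = g, interaction = TRUE)
  expect_equal(log(fit$est_ref), 0.8, tolerance = 0.25)
  expect_equal(log(fit$est_grp), 0.2, tolerance = 0.25)
  expect_lt(fit$p_interaction, 0.01)
  plain <- fit_logistic(y, x, covariate = g)
  expect_true(is.na(plain$p_interaction))
})

test_that("interaction p-values are uniform under homogeneous effects", {
  set.seed(94)
  ps <- replicate(300, {
    n <- 400L
    g <- rep(0:1, each = n / 2)
    x <- rnorm(n)
    y <- runif(n) < plogis(-1 + 0.5 * x + 0.5 * g)
    fit_logistic(y, x, covariate = g, interaction = TRUE)$p_interaction
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("derived ratio statistics match their worked examples", {
  expect_equal(effect_ratio(0.21, 0.28), 0.75)
  expect_equal(effect_ratio(0.10, 0.18), 0.56)
  expect_equal(effect_ratio(0.4, 0.4), 1.0)
  # scale-free in the underlying betas
  expect_equal(effect_ratio(3 * 0.21, 3 * 0.28), effect_ratio(0.21, 0.28))
  expect_error(effect_ratio(1, 0), "zero")

  expect_equal(excess_or_ratio(1.30, 2.01), 0.30)
  expect_equal(excess_or_ratio(1.30, 1.64), 0.47)
  expect_equal(excess_or_ratio(1.0, 2.0), 0)
  expect_error(excess_or_ratio(1.2, 1.0), "exceed 1")
})

test_that("group comparisons use Welch t and pooled-variance z", {
  same <- c(1, 2, 3, 4)
  r <- compare_groups(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  rb <- compare_groups(rep(c(TRUE, FALSE), 10), rep(c(TRUE, FALSE), 15))
  expect_equal(rb$statistic, 0)

  # closed-form Welch oracle
  set.seed(95)
  a <- rnorm(15, 1); b <- rnorm(20, 0.2)
  rw <- compare_groups(a, b)
  tstat <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(rw$statistic, tstat, tolerance = 1e-10)

  # pooled z agrees with the chi-square of prop.test without correction
  xa <- rep(c(TRUE, FALSE), times = c(30, 70))
  xb <- rep(c(TRUE, FALSE), times = c(45, 55))
  rz <- compare_groups(xa, xb)
  pt <- prop.test(c(30, 45), c(100, 100), correct = FALSE)
  expect_equal(rz$statistic^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(rz$p_value, pt$p.value, tolerance = 1e-10)
  expect_error(compare_groups(numeric(0), 1:3), "empty")
})

test_that("design analyses wire outcomes, groups and adjustments", {
  co <- simulate_cohort(sim_params(n_trios = 3000L, n_variants = 120L,
                                   beta_transmitted = 0.25, seed = 96L))
  sc <- standardize_scores(truth_score_set(co))
  groups <- sample_design_groups(co$phenotypes, co$latent$child_z,
                                 n_ref = 400L, n_mo_ow = 250L, n_ch_ow = 500L,
                                 maternal_bmi_threshold = 26, seed = 3L)
  dat <- analysis_frame(truth_score_set(co), co$phenotypes, groups)

  cc <- run_case_cohort(dat)
  expect_s3_class(cc, "data.frame")
  child_or <- cc$estimate[cc$determinant == "Child GRS"]
  expect_gt(child_or, 1)
  expect_lt(cc$p_value[cc$determinant == "Child GRS"], 0.05)
  # adjusted parental-BMI model present
  expect_true(any(grepl("Maternal BMI \\|", cc$determinant)))

  ec <- run_exposure_cohort(dat, with_interaction = TRUE)
  expect_equal(ec$determinant[1], "Group indicator (MO_OW)")
  expect_gt(ec$estimate[1], 1)   # maternal selection raises child overweight
  expect_true(all(!is.na(ec$p_interaction[-1])))
  ec0 <- run_exposure_cohort(dat)
  expect_true(all(is.na(ec0$p_interaction)))

  lr <- run_linear_ref(dat[dat$group == "REF", ])
  expect_true("Maternal transmitted GRS" %in% lr$determinant)
  expect_gt(lr$estimate[lr$determinant == "Child GRS"], 0)

  dup <- rbind(dat, dat[1, ])
  expect_error(run_case_cohort(dup), "duplicated")
})

test_that("validity correlations match their analytic expectations", {
  co <- simulate_cohort(sim_params(n_trios = 8000L, n_variants = 200L,
                                   seed = 97L))
  sc <- truth_score_set(co)
  vr <- validation_correlations(sc)
  expect_false(any(vr$flag))
  expect_equal(vr$observed[vr$a == "maternal" & vr$b == "child"], 0.5,
               tolerance = 0.1)
  # additivity: child correlates perfectly with Mt + Pt
  expect_equal(cor(sc$child_count, sc$mat_trans_count + sc$pat_trans_count),
               1)
  m <- attr(vr, "correlations")
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(1, 5))
  expect_error(validation_correlations(sc[1:10, ]), "at least 30")
})
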