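# Regression primitives returning uniform ModelResult rows.

.model_result <- function(determinant, n, estimate, ci_low, ci_high, p_value,
                          scale, covariates = character(0),
                          r_squared = NA_real_,
                          est_ref = NA_real_, ci_low_ref = NA_real_,
                          ci_high_ref = NA_real_,
                          est_grp = NA_real_, ci_low_grp = NA_real_,
                          ci_high_grp = NA_real_,
                          p_interaction = NA_real_) {
  data.frame(determinant = determinant, n = n, estimate = estimate,
             ci_low = ci_low, ci_high = ci_high, p_value = p_value,
             scale = scale,
             covariates = paste(covariates, collapse = "+"),
             r_squared = r_squared,
             est_ref = est_ref, ci_low_ref = ci_low_ref,
             ci_high_ref = ci_high_ref,
             est_grp = est_grp, ci_low_grp = ci_low_grp,
             ci_high_grp = ci_high_grp,
             p_interaction = p_interaction,
             stringsAsFactors = FALSE)
}

#' Simple linear regression for a continuous outcome
#'
#' Ordinary least squares of `y` on a determinant, optionally with one
#' additional covariate (used to re-estimate phenotype associations
#' controlling for the respective transmitted GRS).  The reported
#' estimate is the determinant's slope with a t-based 95% CI and
#' p-value, plus the model R^2.
#'
#' @param y Outcome (e.g. child BMI in SD-units).
#' @param x Determinant (SD-units).
#' @param covariate Optional single covariate vector.
#' @param determinant Label for the output row.
#' @return A one-row ModelResult data frame (`scale = "linear_beta"`).
#' @export
fit_linear <- function(y, x, covariate = NULL, determinant = "x") {
  dat <- data.frame(y = y, x = x)
  covs <- character(0)
  if (!is.null(covariate)) {
    dat$z <- covariate
    covs <- "covariate"
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 3L) .stopf("need at least 3 complete observations")
  if (sd(dat$x) == 0) .stopf("constant determinant")
  fml <- if (is.null(covariate)) y ~ x else y ~ x + z
  fit <- lm(fml, data = dat)
  sm <- summary(fit)
  est <- coef(fit)[["x"]]
  se <- sm$coefficients["x", "Std. Error"]
  tq <- qt(0.975, fit$df.residual)
  .model_result(determinant, nrow(dat), est, est - tq * se, est + tq * se,
                sm$coefficients["x", "Pr(>|t|)"], "linear_beta", covs,
                r_squared = sm$r.squared)
}

#' Logistic regression for a binary outcome
#'
#' Maximum-likelihood logistic fit reported as an odds ratio per unit of
#' the determinant with a Wald 95% CI.  With `interaction = TRUE` the
#' model adds a `covariate x determinant` term (the covariate then being
#' a 0/1 group indicator) and reports per-group ORs and the interaction
#' p-value.  Complete separation raises an explicit error instead of
#' returning a silently diverged estimate.
#'
#' @param case Logical (or 0/1) outcome vector; both classes must occur.
#' @param x Determinant.
#' @param covariate Optional covariate (for the group-adjusted and
#'   interaction models, the group indicator coded REF = 0).
#' @param interaction Add the `x:covariate` interaction term.
#' @param determinant Label for the output row.
#' @return A one-row ModelResult data frame (`scale = "odds_ratio"`).
#' @export
fit_logistic <- function(case, x, covariate = NULL, interaction = FALSE,
                         determinant = "x") {
  if (interaction && is.null(covariate))
    .stopf("interaction = TRUE requires a covariate (group indicator)")
  dat <- data.frame(case = as.logical(case), x = x)
  covs <- character(0)
  if (!is.null(covariate)) {
    dat$g <- as.numeric(covariate)
    covs <- "group"
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$case)) < 2L)
    .stopf("outcome has a single class; no contrast to estimate")
  if (sd(dat$x) == 0) .stopf("constant determinant")
  fml <- if (is.null(covariate)) case ~ x
         else if (interaction) case ~ x + g + x:g
         else case ~ x + g
  fit <- suppressWarnings(
    glm(fml, family = binomial(), data = dat,
        control = list(maxit = 100L, epsilon = 1e-10)))
  separated <- all(fit$fitted.values < 1e-6 | fit$fitted.values > 1 - 1e-6)
  if (!fit$converged || any(abs(coef(fit)) > 15) || separated)
    .stopf(paste("logistic model did not converge (likely complete",
                 "separation); estimates are not reportable"))
  est <- coef(fit)[["x"]]
  se <- sqrt(vcov(fit)["x", "x"])
  zq <- qnorm(0.975)
  p <- 2 * pnorm(-abs(est / se))
  row <- .model_result(determinant, nrow(dat), exp(est),
                       exp(est - zq * se), exp(est + zq * se), p,
                       "odds_ratio", covs)
  if (interaction) {
    bi <- coef(fit)[["x:g"]]
    sei <- sqrt(vcov(fit)["x:g", "x:g"])
    # per-group slopes: REF = b_x, group = b_x + b_int
    bg <- est + bi
    seg <- sqrt(vcov(fit)["x", "x"] + vcov(fit)["x:g", "x:g"] +
                  2 * vcov(fit)["x", "x:g"])
    row$est_ref <- exp(est)
    row$ci_low_ref <- exp(est - zq * se)
    row$ci_high_ref <- exp(est + zq * se)
    row$est_grp <- exp(bg)
    row$ci_low_grp <- exp(bg - zq * seg)
    row$ci_high_grp <- exp(bg + zq * seg)
    row$p_interaction <- 2 * pnorm(-abs(bi / sei))
    row$covariates <- "group+group:x"
  }
  row
}

#' Two-group comparison
#'
#' Welch's two-sample t-test for continuous variables; a two-proportion
#' z-test with pooled variance for binary (logical) variables.
#'
#' @param values_a,values_b Numeric or logical samples.
#' @return List with `method`, `statistic`, `p_value` and the group
#'   means/proportions.
#' @export
compare_groups <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (!length(values_a) || !length(values_b)) .stopf("empty group")
  binary <- is.logical(values_a) ||
    all(values_a %in% c(0, 1)) && all(values_b %in% c(0, 1))
  if (binary) {
    p1 <- mean(values_a); p2 <- mean(values_b)
    n1 <- length(values_a); n2 <- length(values_b)
    pp <- (sum(values_a) + sum(values_b)) / (n1 + n2)
    z <- if (pp %in% c(0, 1)) 0
         else (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    list(method = "two_proportion_z", statistic = z,
         p_value = 2 * pnorm(-abs(z)), estimate_a = p1, estimate_b = p2)
  } else {
    if (length(values_a) < 2L || length(values_b) < 2L)
      .stopf("continuous comparison needs n >= 2 per group")
    tt <- t.test(values_a, values_b)
    list(method = "welch_t", statistic = unname(tt$statistic),
         p_value = tt$p.value, estimate_a = mean(values_a),
         estimate_b = mean(values_b))
  }
}
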