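# Lambda-Mu-Sigma (LMS) standardisation of child BMI, and internal
# z-scores for parental BMI.

#' LMS z-score
#'
#' The Cole LMS transform: `z = ((x/M)^L - 1) / (L * S)` for `L != 0`,
#' with the continuity limit `z = log(x/M) / S` at `L = 0`.  `M` is the
#' reference median (kg/m^2 for BMI), `S` the coefficient of variation
#' and `L` the Box-Cox power correcting skewness.
#'
#' @param x Measurement (e.g. BMI, kg/m^2), positive.
#' @param L,M,S LMS parameters; `M > 0`, `S > 0`.
#' @return z-score in SD-units.  Strictly increasing in `x`.
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(x <= 0, na.rm = TRUE)) .stopf("x must be positive")
  if (any(M <= 0) || any(S <= 0)) .stopf("M and S must be positive")
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  out <- ((x / M)^L - 1) / (L * S)
  small <- abs(L) <= 1e-8
  out[small] <- log(x[small] / M[small]) / S[small]
  out
}

#' Estimate an LMS reference from a sample
#'
#' Builds a sex- and age-specific LMS reference table from a (large)
#' reference sample by moment matching within sex x age-month bands,
#' with `L` fixed at 1 (no skewness correction): `M` = band mean, `S` =
#' band SD / mean, so the transform reduces to `(x - M) / (M * S)`.
#' Intended for simulated cohorts; measured reference tables (WHO, IOTF)
#' can be supplied in the same format instead.
#'
#' @param bmi,sex,age_months Parallel vectors for the reference sample.
#' @param band_months Width of the age bands in months (default 3).
#' @param min_band_n Bands with fewer observations are merged into the
#'   adjacent band of the same sex (default 10), so sparse tail ages do
#'   not produce unstable parameters.
#' @return An `lms_reference` data frame: `sex`, `age_lo_months`,
#'   `age_hi_months` (half-open bands), `L`, `M`, `S`.
#' @export
estimate_lms_reference <- function(bmi, sex, age_months, band_months = 3L,
                                   min_band_n = 10L) {
  stopifnot(length(bmi) == length(sex), length(bmi) == length(age_months))
  if (any(bmi <= 0, na.rm = TRUE)) .stopf("bmi must be positive")
  band_lo <- (age_months %/% band_months) * band_months
  rows <- lapply(split(seq_along(bmi), sex), function(sx_idx) {
    # greedy forward merge of under-filled bands within this sex
    bands <- sort(unique(band_lo[sx_idx]))
    grp <- integer(length(bands))
    g <- 1L; count <- 0L
    for (k in seq_along(bands)) {
      grp[k] <- g
      count <- count + sum(band_lo[sx_idx] == bands[k])
      if (count >= min_band_n && k < length(bands)) {
        g <- g + 1L; count <- 0L
      }
    }
    if (count > 0L && count < min_band_n && g > 1L)
      grp[grp == g] <- g - 1L           # fold a sparse tail backwards
    lapply(split(seq_along(bands), grp), function(bk) {
      i <- sx_idx[band_lo[sx_idx] %in% bands[bk]]
      if (length(i) < 2L)
        .stopf("age band with fewer than 2 observations; widen band_months")
      m <- mean(bmi[i]); s <- sd(bmi[i])
      if (s == 0) .stopf("degenerate (constant) BMI band")
      data.frame(sex = sex[i][1L], age_lo_months = min(bands[bk]),
                 age_hi_months = max(bands[bk]) + band_months,
                 L = 1, M = m, S = s / m, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  out <- out[order(out$sex, out$age_lo_months), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lms_reference", "data.frame")
  out
}

#' Apply an LMS reference to child BMI
#'
#' @param bmi,sex,age_months Child measurements.
#' @param reference An [estimate_lms_reference()]-shaped table.  Ages are
#'   matched to `[age_lo_months, age_hi_months)` bands; ages outside all
#'   bands are clamped to the nearest band of the same sex.
#' @return Numeric vector of sex- and age-specific BMI z-scores.
#' @export
child_bmi_zscore <- function(bmi, sex, age_months, reference) {
  z <- rep(NA_real_, length(bmi))
  for (sx in unique(sex)) {
    rf <- reference[reference$sex == sx, , drop = FALSE]
    if (nrow(rf) == 0L) .stopf("no LMS reference rows for sex '%s'", sx)
    sel <- which(sex == sx)
    band <- findInterval(age_months[sel], rf$age_lo_months)
    band[band < 1L] <- 1L
    band[band > nrow(rf)] <- nrow(rf)
    z[sel] <- lms_zscore(bmi[sel], rf$L[band], rf$M[band], rf$S[band])
  }
  z
}

#' Internally standardised z-scores
#'
#' `(x - mean) / sd` within each stratum (or overall when `strata` is
#' `NULL`); the standardisation used for parental BMI.
#'
#' @param values Numeric vector.
#' @param strata Optional grouping labels.
#' @return z-scores, NA where `values` is NA.
#' @export
internal_zscore <- function(values, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, length(values))
  out <- rep(NA_real_, length(values))
  for (s in unique(strata)) {
    i <- which(strata == s & !is.na(values))
    if (length(i) < 2L)
      .stopf("stratum '%s' has fewer than 2 non-missing values", s)
    sdv <- sd(values[i])
    if (sdv == 0) .stopf("stratum '%s' is constant", s)
    out[i] <- (values[i] - mean(values[i])) / sdv
  }
  out
}
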