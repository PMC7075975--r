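# Duo phasing: hard calls, Mendelian logic, haplotype resolution, QC.

test_that("dosages convert to best-guess genotypes with round-half-up", {
  expect_equal(best_guess_genotype(1.97), 2L)
  expect_equal(best_guess_genotype(1.5), NA_integer_)
  expect_equal(best_guess_genotype(1.5, threshold = 0.5), 2L)
  expect_equal(best_guess_genotype(c(0.04, NA, 0.92)), c(0L, NA, 1L))
  expect_error(best_guess_genotype(2.1), "\\[0, 2\\]")
  expect_error(best_guess_genotype(1, threshold = 0), "0.5")
})

test_that("genotype-only transmission follows the Mendelian table", {
  grid <- expand.grid(m = c(0L, 1L, 2L, NA), c = c(0L, 1L, 2L, NA))
  res <- infer_site_transmission(grid$m, grid$c)
  pick <- function(m, c) res[which(
    (grid$m %in% m | (is.na(m) & is.na(grid$m))) &
      (grid$c %in% c | (is.na(c) & is.na(grid$c)))), ]
  r <- pick(2L, 1L)   # mother hom-effect, child het
  expect_equal(unlist(r[1:3]), c(maternal_transmitted = 1L,
                                 maternal_non_transmitted = 1L,
                                 paternal_transmitted = 0L))
  expect_equal(as.character(pick(0L, 2L)$call_class), "mendel_error")
  expect_equal(as.character(pick(2L, 0L)$call_class), "mendel_error")
  expect_equal(as.character(pick(1L, 1L)$call_class), "needs_phase")
  expect_equal(as.character(pick(NA, 1L)$call_class), "genotype_missing")
  # mother het, child hom: fully determined
  r <- pick(1L, 0L)
  expect_equal(unlist(r[1:3]), c(maternal_transmitted = 0L,
                                 maternal_non_transmitted = 1L,
                                 paternal_transmitted = 0L))
  r <- pick(1L, 2L)
  expect_equal(unlist(r[1:3]), c(maternal_transmitted = 1L,
                                 maternal_non_transmitted = 0L,
                                 paternal_transmitted = 1L))
  # additivity wherever all three are called
  ok <- !is.na(res$maternal_transmitted)
  expect_equal(res$maternal_transmitted[ok] + res$paternal_transmitted[ok],
               grid$c[ok])
  expect_equal(res$maternal_transmitted[ok] + res$maternal_non_transmitted[ok],
               grid$m[ok])
})

test_that("double heterozygotes resolve by regional haplotype match", {
  mh <- rbind(c(0L, 1L, 0L), c(1L, 0L, 1L))
  ch <- rbind(c(0L, 1L, 0L), c(1L, 1L, 1L))
  r <- resolve_double_het(mh, ch, 2L)
  expect_false(r$tie)
  expect_equal(r$transmitted_child_hap, 1L)
  expect_equal(r$maternal_transmitted, 1L)
  expect_equal(r$maternal_non_transmitted, 0L)
  expect_equal(r$paternal_transmitted, 1L)

  # perfectly symmetric windows tie
  mh <- rbind(c(1L, 1L), c(1L, 0L))
  r <- resolve_double_het(mh, mh, 2L)
  expect_true(r$tie)
  expect_true(is.na(r$maternal_transmitted))

  expect_error(resolve_double_het(rbind(0L, 1L), rbind(c(0L, 1L), c(1L, 0L)), 1L),
               "equal width")
  expect_error(resolve_double_het(rbind(c(1L, 1L), c(1L, 0L)),
                                  rbind(c(1L, 1L), c(1L, 0L)), 1L),
               "heterozygous")
})

test_that("whole-cohort inference agrees with per-site resolution", {
  co <- tiny_cohort(n = 30L, V = 40L, seed = 31L, block_length = 8L,
                    phase_error_rate = 0.05)
  calls <- infer_duo_transmission(co$duos, window = 7L)
  g <- list(m = co$duos$mother_h1 + co$duos$mother_h2,
            c = co$duos$child_h1 + co$duos$child_h2)
  blocks <- as.integer(co$duos$variants$chrom)
  w <- 3L
  checked <- 0L
  for (j in seq_len(30L)) for (i in which(g$m[, j] == 1L & g$c[, j] == 1L)) {
    reg <- which(blocks == blocks[i])
    win <- max(min(reg), i - w):min(max(reg), i + w)
    r <- resolve_double_het(rbind(co$duos$mother_h1[win, j],
                                  co$duos$mother_h2[win, j]),
                            rbind(co$duos$child_h1[win, j],
                                  co$duos$child_h2[win, j]),
                            which(win == i))
    if (r$tie) {
      expect_true(is.na(calls$mt[i, j]))
      expect_equal(CALL_CLASSES[calls$call_class[i, j]], "tie_missing")
    } else {
      expect_equal(calls$mt[i, j], r$maternal_transmitted)
      expect_equal(calls$pt[i, j], r$paternal_transmitted)
    }
    checked <- checked + 1L
  }
  expect_gt(checked, 50L)
})

test_that("inference reproduces truth exactly without phase errors", {
  co <- simulate_cohort(sim_params(n_trios = 120L, n_variants = 941L,
                                   seed = 33L))
  calls <- infer_duo_transmission(co$duos)
  acc <- call_accuracy(co, calls)
  expect_equal(unname(acc), c(1, 1))
  # additivity invariant over every inferred duo
  g <- list(m = co$duos$mother_h1 + co$duos$mother_h2,
            c = co$duos$child_h1 + co$duos$child_h2)
  ok <- !is.na(calls$mt)
  expect_true(all((calls$mt + calls$pt)[ok] == g$c[ok]))
  expect_true(all((calls$mt + calls$mnt)[ok] == g$m[ok]))
  expect_equal(calls$qc$mendel_error_count, rep(0L, 120L))
  expect_true(all(calls$qc$relatedness_verdict == "consistent_duo"))
})

test_that("site accuracy degrades monotonically with switch-error rate", {
  accs <- vapply(c(0, 0.01, 0.05), function(rate) {
    co <- simulate_cohort(sim_params(n_trios = 150L, n_variants = 941L,
                                     phase_error_rate = rate, seed = 34L))
    calls <- infer_duo_transmission(co$duos)
    call_accuracy(co, calls)[["mt"]]
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_lt(accs[3], accs[1])
})

test_that("Mendelian errors and missing genotypes are handled per site", {
  co <- tiny_cohort(n = 5L, V = 120L, seed = 35L)
  duos <- co$duos
  # corrupt one site of duo 1 into an opposite-homozygote pair
  duos$mother_h1[7, 1] <- 0L; duos$mother_h2[7, 1] <- 0L
  duos$child_h1[7, 1] <- 1L; duos$child_h2[7, 1] <- 1L
  duos$mother_h1[9, 2] <- NA; duos$mother_h2[9, 2] <- NA
  calls <- infer_duo_transmission(duos)
  expect_equal(CALL_CLASSES[calls$call_class[7, 1]], "mendel_error")
  expect_true(is.na(calls$mt[7, 1]))
  expect_equal(calls$qc$mendel_error_count[1], 1L)
  expect_equal(CALL_CLASSES[calls$call_class[9, 2]], "genotype_missing")

  duos$mother_h1[] <- NA; duos$mother_h2[] <- NA
  expect_error(infer_duo_transmission(duos), "missing")
})

test_that("unphased focal sites cannot be haplotype-resolved", {
  co <- tiny_cohort(n = 20L, V = 60L, seed = 36L)
  duos <- co$duos
  V <- nrow(duos$variants); n <- length(duos$duo_ids)
  duos$phase_known_mother <- matrix(TRUE, V, n)
  duos$phase_known_child <- matrix(TRUE, V, n)
  g <- list(m = duos$mother_h1 + duos$mother_h2,
            c = duos$child_h1 + duos$child_h2)
  dh <- which(g$m == 1L & g$c == 1L)[1]
  duos$phase_known_child[dh] <- FALSE
  calls <- infer_duo_transmission(duos)
  expect_equal(CALL_CLASSES[calls$call_class[dh]], "tie_missing")
})

test_that("opposite homozygotes separate true duos from unrelated pairs", {
  co <- simulate_cohort(sim_params(n_trios = 30L, n_variants = 800L,
                                   allele_freq = 0.5, seed = 37L))
  qc <- check_duo_relatedness(co$duos)
  expect_true(all(qc$opposite_homozygote_rate == 0))
  expect_true(all(qc$relatedness_verdict == "consistent_duo"))

  # unrelated "duos": pair mothers with another family's child
  fake <- co$duos
  shift <- c(2:30, 1)
  fake$child_h1 <- fake$child_h1[, shift]
  fake$child_h2 <- fake$child_h2[, shift]
  qc2 <- check_duo_relatedness(fake)
  # HWE oracle at MAF 0.5: P(opposite homozygotes) = 2 * 0.25 * 0.25
  se <- sqrt(0.125 * 0.875 / 800)
  expect_true(all(abs(qc2$opposite_homozygote_rate - 0.125) < 4 * se))
  expect_true(all(qc2$relatedness_verdict == "inconsistent"))

  # threshold 0 flags even a single discordant site
  one <- co$duos
  one$mother_h1[1, 1] <- 0L; one$mother_h2[1, 1] <- 0L
  one$child_h1[1, 1] <- 1L; one$child_h2[1, 1] <- 1L
  qc3 <- check_duo_relatedness(one, rate_threshold = 0)
  expect_equal(qc3$relatedness_verdict[1], "inconsistent")

  small <- tiny_cohort(n = 3L, V = 50L, seed = 38L)
  expect_error(check_duo_relatedness(small$duos), "larger")
})

test_that("call-rate filtering tracks per-variant completeness", {
  co <- tiny_cohort(n = 40L, V = 60L, seed = 39L)
  duos <- co$duos
  duos$mother_h1[5, 1:10] <- NA; duos$mother_h2[5, 1:10] <- NA
  calls <- infer_duo_transmission(duos)
  cr <- variant_call_rate(calls)
  expect_lte(cr[5], 30 / 40)
  expect_true(all(cr >= 0 & cr <= 1))
})
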