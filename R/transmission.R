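# Duo phasing: assigning parent-of-origin to child alleles from
# mother-child genotypes plus phased haplotypes.

#' Call classes of per-site transmission inference
#'
#' `unambiguous`: mother or child homozygous, transmission follows from
#' Mendelian logic alone.  `phase_resolved`: double heterozygote resolved
#' by regional haplotype matching.  `tie_missing`: double heterozygote
#' whose haplotype match was a tie (or unphased at the focal site); left
#' missing by the default policy.  `mendel_error`: opposite-homozygote
#' mother-child pair, impossible under transmission.  `genotype_missing`:
#' either genotype missing.  `needs_phase` only appears in the output of
#' [infer_site_transmission()], before haplotype resolution.
#'
#' @export
CALL_CLASSES <- c("unambiguous", "phase_resolved", "tie_missing",
                  "mendel_error", "genotype_missing", "needs_phase")

#' Convert dosages to best-guess genotypes
#'
#' Rounds an imputed effect-allele dosage to the nearest hard genotype
#' when it is close enough, otherwise returns missing.  Exact half-way
#' dosages round up (round-half-up), so `1.5` with `threshold = 0.5`
#' gives `2`.
#'
#' @param dosage Numeric vector of dosages in `[0, 2]` (NA allowed).
#' @param threshold Maximum allowed distance from the nearest integer, in
#'   `(0, 0.5]`; default 0.1.
#' @return Integer vector in `{0, 1, 2, NA}`.
#' @export
best_guess_genotype <- function(dosage, threshold = 0.1) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 0.5)
    .stopf("threshold must be in (0, 0.5]")
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    .stopf("dosages must lie in [0, 2]")
  r <- floor(dosage + 0.5)            # round half up
  out <- ifelse(abs(dosage - r) <= threshold, r, NA_real_)
  as.integer(out)
}

#' Per-site transmission from mother and child genotypes alone
#'
#' Applies the Mendelian bookkeeping that determines allelic transmission
#' wherever mother or child (or both) are homozygous.  Double
#' heterozygotes cannot be resolved from genotypes and are flagged
#' `needs_phase`; impossible combinations (opposite homozygotes) are
#' `mendel_error`; any missing genotype gives `genotype_missing`.
#'
#' @param mother_g,child_g Integer vectors of genotypes in
#'   `{0, 1, 2, NA}` (effect-allele counts).
#' @return A data frame with columns `maternal_transmitted`,
#'   `maternal_non_transmitted`, `paternal_transmitted` (0/1/NA) and
#'   `call_class`.
#' @export
infer_site_transmission <- function(mother_g, child_g) {
  if (length(mother_g) != length(child_g))
    .stopf("mother_g and child_g must have equal length")
  bad <- function(g) any(!g %in% c(0L, 1L, 2L, NA))
  if (bad(mother_g) || bad(child_g))
    .stopf("genotypes must lie in {0, 1, 2, NA}")
  n <- length(mother_g)
  mt <- mnt <- pt <- rep(NA_integer_, n)
  cls <- rep("genotype_missing", n)
  ok <- !is.na(mother_g) & !is.na(child_g)

  mendel <- ok & ((mother_g == 0L & child_g == 2L) |
                    (mother_g == 2L & child_g == 0L))
  cls[mendel] <- "mendel_error"

  i <- ok & !mendel & mother_g == 2L
  mt[i] <- 1L; mnt[i] <- 1L; pt[i] <- child_g[i] - 1L; cls[i] <- "unambiguous"
  i <- ok & !mendel & mother_g == 0L
  mt[i] <- 0L; mnt[i] <- 0L; pt[i] <- child_g[i]; cls[i] <- "unambiguous"
  i <- ok & mother_g == 1L & child_g == 0L
  mt[i] <- 0L; mnt[i] <- 1L; pt[i] <- 0L; cls[i] <- "unambiguous"
  i <- ok & mother_g == 1L & child_g == 2L
  mt[i] <- 1L; mnt[i] <- 0L; pt[i] <- 1L; cls[i] <- "unambiguous"
  i <- ok & mother_g == 1L & child_g == 1L
  cls[i] <- "needs_phase"

  data.frame(maternal_transmitted = mt, maternal_non_transmitted = mnt,
             paternal_transmitted = pt,
             call_class = factor(cls, levels = CALL_CLASSES),
             stringsAsFactors = FALSE)
}

#' Resolve a double heterozygote by regional haplotype matching
#'
#' At a site where both mother and child are heterozygous, compares each
#' child haplotype with each maternal haplotype over a window of
#' surrounding sites and declares the child haplotype whose best maternal
#' match strictly exceeds the other's to be the maternally transmitted
#' one.  Equal best scores are a tie.
#'
#' @param mother_haps,child_haps Two haplotype windows per individual: a
#'   `2 x W` matrix (rows = haplotypes) of 0/1/NA alleles.
#' @param focal_index Position of the variant of interest within the
#'   window (1-based).  The mother must be heterozygous there.
#' @return A list with `transmitted_child_hap` (1 or 2, NA on tie),
#'   `tie`, and the resulting focal calls `maternal_transmitted`,
#'   `maternal_non_transmitted` (the focal allele of the maternal
#'   haplotype *not* matched by the transmitted child haplotype) and
#'   `paternal_transmitted` (NA on tie).
#' @export
resolve_double_het <- function(mother_haps, child_haps, focal_index) {
  mh <- as.matrix(mother_haps); ch <- as.matrix(child_haps)
  if (nrow(mh) != 2L || nrow(ch) != 2L || ncol(mh) != ncol(ch))
    .stopf("haplotype windows must be 2 x W matrices of equal width")
  W <- ncol(mh)
  if (focal_index < 1L || focal_index > W)
    .stopf("focal_index outside window")
  if (is.na(mh[1, focal_index]) || is.na(mh[2, focal_index]) ||
      mh[1, focal_index] + mh[2, focal_index] != 1L)
    .stopf("mother must be heterozygous at the focal site")
  score <- function(a, b) sum(a == b, na.rm = TRUE)
  s <- matrix(c(score(ch[1, ], mh[1, ]), score(ch[1, ], mh[2, ]),
                score(ch[2, ], mh[1, ]), score(ch[2, ], mh[2, ])),
              nrow = 2, byrow = TRUE)
  best <- apply(s, 1, max)
  if (best[1] == best[2])
    return(list(transmitted_child_hap = NA_integer_, tie = TRUE,
                maternal_transmitted = NA_integer_,
                maternal_non_transmitted = NA_integer_,
                paternal_transmitted = NA_integer_))
  tch <- if (best[1] > best[2]) 1L else 2L
  mt <- ch[tch, focal_index]
  # matched maternal haplotype; prefer the one agreeing at the focal site
  mm <- if (s[tch, 1] == s[tch, 2]) {
    if (!is.na(mt) && mh[2, focal_index] == mt) 2L else 1L
  } else which.max(s[tch, ])
  list(transmitted_child_hap = tch, tie = FALSE,
       maternal_transmitted = mt,
       maternal_non_transmitted = mh[3L - mm, focal_index],
       paternal_transmitted = ch[3L - tch, focal_index])
}

#' Infer allelic transmission for a duo collection
#'
#' Runs the full duo-phasing procedure for every mother-child pair: hard
#' genotypes (from dosages if present), Mendelian per-site calls, and
#' window-based haplotype matching for double heterozygotes, with windows
#' truncated at region (chromosome) boundaries.  Ties and Mendelian
#' errors yield missing calls at that site; per-duo QC summarises call
#' counts, Mendelian inconsistencies and the opposite-homozygote
#' relatedness check.
#'
#' @param duos A [duo_genotypes()] collection.
#' @param window Haplotype-matching window width in sites (centred on the
#'   focal variant, truncated at region edges); default 51.
#' @param hardcall_threshold Dosage threshold for
#'   [best_guess_genotype()]; default 0.1.
#' @param tie_policy `"missing"` (default) leaves tied double
#'   heterozygotes uncalled.  `"minor_paternal"` is a deliberately naive
#'   contrast that assigns the minor allele paternally at ties; it is the
#'   mechanism behind the known low-frequency assignment bias of
#'   duo-based inference and exists for [quantify_transmission_bias()].
#' @param relatedness_threshold Opposite-homozygote rate above which a
#'   duo is flagged `inconsistent` (default 0.01).
#' @return An object of class `transmission_calls`: list with `mt`,
#'   `mnt`, `pt` (`V x n` 0/1/NA matrices), `call_class` (`V x n` factor
#'   codes as integer matrix with levels in `CALL_CLASSES`), `duo_ids`,
#'   `variants`, and `qc` (one row per duo: `n_variants_called`,
#'   `mendel_error_count`, `opposite_homozygote_rate`,
#'   `relatedness_verdict`).
#' @export
infer_duo_transmission <- function(duos, window = 51L,
                                   hardcall_threshold = 0.1,
                                   tie_policy = c("missing", "minor_paternal"),
                                   relatedness_threshold = 0.01) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(duos, "duo_genotypes"))
  V <- nrow(duos$variants)
  n <- length(duos$duo_ids)
  if (n == 0L) .stopf("no duos to infer")

  # process duos in column chunks so per-site temporaries stay bounded
  # on large cohorts; results are stitched into preallocated matrices
  mt <- mnt <- pt <- matrix(NA_integer_, V, n)
  cls <- matrix(0L, V, n)
  co_called <- integer(n)
  chunk <- max(1L, min(n, as.integer(8e6 %/% V)))
  minor <- NULL
  if (tie_policy == "minor_paternal") {
    gm_all <- .duo_genotype_matrices(duos, hardcall_threshold)$mother
    minor <- ifelse(rowMeans(gm_all, na.rm = TRUE) / 2 <= 0.5, 1L, 0L)
    rm(gm_all)
  }
  for (lo in seq(1L, n, by = chunk)) {
    cols <- lo:min(n, lo + chunk - 1L)
    sub <- .subset_duos(duos, cols)
    g <- .duo_genotype_matrices(sub, hardcall_threshold)
    site <- infer_site_transmission(as.integer(g$mother), as.integer(g$child))
    mt_k <- matrix(site$maternal_transmitted, nrow = V)
    mnt_k <- matrix(site$maternal_non_transmitted, nrow = V)
    pt_k <- matrix(site$paternal_transmitted, nrow = V)
    cls_k <- matrix(as.integer(site$call_class), nrow = V)
    rm(site)
    needs <- which(cls_k == match("needs_phase", CALL_CLASSES))
    if (length(needs)) {
      res <- .resolve_double_hets(sub, needs, window)
      tie <- res$tie
      cls_k[needs] <- ifelse(tie, match("tie_missing", CALL_CLASSES),
                             match("phase_resolved", CALL_CLASSES))
      mt_k[needs] <- res$mt
      mnt_k[needs] <- ifelse(is.na(res$mt), NA_integer_, 1L - res$mt)
      pt_k[needs] <- res$pt
      if (tie_policy == "minor_paternal" && any(tie)) {
        # naive contrast: at ties, hand the minor allele to the father
        i <- ((needs[tie] - 1L) %% V) + 1L
        pt_k[needs[tie]] <- minor[i]
        mt_k[needs[tie]] <- 1L - minor[i]
        mnt_k[needs[tie]] <- minor[i]
        cls_k[needs[tie]] <- match("phase_resolved", CALL_CLASSES)
      }
    }
    mt[, cols] <- mt_k; mnt[, cols] <- mnt_k; pt[, cols] <- pt_k
    cls[, cols] <- cls_k
    co_called[cols] <- colSums(!is.na(g$mother) & !is.na(g$child))
  }
  if (all(co_called == 0L)) .stopf("all genotypes missing")

  opp <- colSums(cls == match("mendel_error", CALL_CLASSES))
  qc <- data.frame(
    duo_id = duos$duo_ids,
    n_variants_called = colSums(!is.na(mt)),
    mendel_error_count = opp,
    n_co_called = co_called,
    opposite_homozygote_rate = ifelse(co_called > 0, opp / co_called, NA_real_),
    stringsAsFactors = FALSE)
  qc$relatedness_verdict <- ifelse(
    !is.na(qc$opposite_homozygote_rate) &
      qc$opposite_homozygote_rate < relatedness_threshold,
    "consistent_duo", "inconsistent")

  structure(list(mt = mt, mnt = mnt, pt = pt, call_class = cls,
                 duo_ids = duos$duo_ids, variants = duos$variants, qc = qc),
            class = "transmission_calls")
}

# Vectorised double-heterozygote resolution over a duo collection.
# 'cells' are linear indices into the V x n genotype matrices.
.resolve_double_hets <- function(duos, cells, window) {
  V <- nrow(duos$variants)
  w <- max(0L, (as.integer(window) - 1L) %/% 2L)
  rb <- .region_bounds(duos$variants$chrom)
  idx <- seq_len(V)
  lo <- pmax(idx - w, rb$start)
  hi <- pmin(idx + w, rb$end)

  mask <- NULL
  if (!is.null(duos$phase_known_mother) || !is.null(duos$phase_known_child)) {
    mask <- if (is.null(duos$phase_known_mother)) duos$phase_known_child
            else if (is.null(duos$phase_known_child)) duos$phase_known_mother
            else duos$phase_known_mother & duos$phase_known_child
  }
  s11 <- .window_match(duos$child_h1, duos$mother_h1, cells, lo, hi, mask)
  s12 <- .window_match(duos$child_h1, duos$mother_h2, cells, lo, hi, mask)
  s21 <- .window_match(duos$child_h2, duos$mother_h1, cells, lo, hi, mask)
  s22 <- .window_match(duos$child_h2, duos$mother_h2, cells, lo, hi, mask)
  b1 <- pmax(s11, s12)
  b2 <- pmax(s21, s22)

  # focal haplotype alleles must be phased and consistent with the
  # heterozygous genotype, else the site is unresolvable
  c1 <- duos$child_h1[cells]
  c2 <- duos$child_h2[cells]
  focal_ok <- !is.na(c1) & !is.na(c2) & (c1 + c2 == 1L)
  if (!is.null(mask)) focal_ok <- focal_ok & mask[cells]

  tie <- b1 == b2 | !focal_ok
  mt <- ifelse(tie, NA_integer_, ifelse(b1 > b2, c1, c2))
  pt <- ifelse(tie, NA_integer_, ifelse(b1 > b2, c2, c1))
  list(mt = as.integer(mt), pt = as.integer(pt), tie = tie)
}

#' @export
print.transmission_calls <- function(x, ...) {
  tab <- table(factor(CALL_CLASSES[x$call_class], levels = CALL_CLASSES))
  cat(sprintf("<transmission_calls> %d duos x %d variants\n",
              length(x$duo_ids), nrow(x$variants)))
  print(tab[tab > 0 | names(tab) != "needs_phase"])
  invisible(x)
}

#' Per-variant call rate of a transmission call set
#'
#' Fraction of duos with a complete (non-missing) transmission call at
#' each variant.  Variants below a call-rate threshold are excluded from
#' score construction (mirroring a genotype call-rate filter).
#'
#' @param calls A [infer_duo_transmission()] result.
#' @return Numeric vector of per-variant call rates in panel order.
#' @export
variant_call_rate <- function(calls) {
  stopifnot(inherits(calls, "transmission_calls"))
  rowMeans(!is.na(calls$mt))
}

#' Duo relatedness check via opposite homozygotes
#'
#' A true mother-child pair can never be opposite homozygotes at a
#' correctly genotyped site, so the rate of opposite-homozygote sites
#' over co-called sites discriminates true duos from unrelated pairs
#' (for unrelated pairs under HWE the expected per-site rate is
#' `2 p^2 q^2`, e.g. 0.125 at MAF 0.5).
#'
#' @param duos A [duo_genotypes()] collection.
#' @param rate_threshold Verdict threshold; `consistent_duo` iff the rate
#'   is strictly below it (default 0.01).
#' @param min_sites Minimum co-called sites required per duo (default
#'   100).
#' @return Data frame with `duo_id`, `n_co_called`,
#'   `opposite_homozygote_count`, `opposite_homozygote_rate`,
#'   `relatedness_verdict`.
#' @export
check_duo_relatedness <- function(duos, rate_threshold = 0.01,
                                  min_sites = 100L) {
  stopifnot(inherits(duos, "duo_genotypes"))
  g <- .duo_genotype_matrices(duos)
  co <- !is.na(g$mother) & !is.na(g$child)
  opp <- co & ((g$mother == 0L & g$child == 2L) |
                 (g$mother == 2L & g$child == 0L))
  n_co <- colSums(co)
  if (any(n_co < min_sites))
    .stopf(paste("duo(s) with fewer than %d co-called sites (first: %s);",
                 "use a larger variant panel"),
           min_sites, duos$duo_ids[which(n_co < min_sites)[1]])
  rate <- colSums(opp) / n_co
  data.frame(duo_id = duos$duo_ids,
             n_co_called = n_co,
             opposite_homozygote_count = colSums(opp),
             opposite_homozygote_rate = rate,
             relatedness_verdict = ifelse(rate < rate_threshold,
                                          "consistent_duo", "inconsistent"),
             stringsAsFactors = FALSE)
}
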