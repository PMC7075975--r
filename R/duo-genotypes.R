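#' Phased genotypes for a collection of mother-child duos
#'
#' Container for haplotype-coded genotypes over a variant panel.  Alleles
#' are coded `1` = effect allele, `0` = other allele, `NA` = missing, and
#' stored as `V x n` integer matrices (variants in panel order by row, one
#' column per duo).  The two haplotypes of an individual are `h1`/`h2`;
#' their order is the (statistically) phased order and carries no
#' parent-of-origin meaning by itself.
#'
#' @param variants Weight table (or any data frame with `variant_id` and
#'   `chrom`) defining row order and haplotype regions.
#' @param mother_h1,mother_h2,child_h1,child_h2 Integer `V x n` matrices
#'   of 0/1/NA alleles.
#' @param duo_ids Character vector of duo identifiers (length `n`).
#' @param mother_ids,child_ids Sample identifiers; default derived from
#'   `duo_ids`.
#' @param phase_known_mother,phase_known_child Optional logical `V x n`
#'   matrices; `FALSE` marks sites whose within-individual haplotype
#'   assignment is not phased (genotype still usable).  `NULL` means
#'   phased everywhere.
#' @param mother_ds,child_ds Optional numeric `V x n` dosage matrices in
#'   `[0, 2]` (effect-allele dosage).
#' @return An object of class `duo_genotypes`.
#' @export
duo_genotypes <- function(variants, mother_h1, mother_h2, child_h1, child_h2,
                          duo_ids,
                          mother_ids = paste0("M_", duo_ids),
                          child_ids = paste0("C_", duo_ids),
                          phase_known_mother = NULL,
                          phase_known_child = NULL,
                          mother_ds = NULL, child_ds = NULL) {
  V <- nrow(variants)
  n <- length(duo_ids)
  mats <- list(mother_h1 = mother_h1, mother_h2 = mother_h2,
               child_h1 = child_h1, child_h2 = child_h2)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || nrow(m) != V || ncol(m) != n)
      .stopf("'%s' must be a %d x %d matrix", nm, V, n)
    if (any(!m %in% c(0L, 1L, NA)))
      .stopf("'%s' contains alleles outside {0, 1, NA}", nm)
  }
  for (nm in c("phase_known_mother", "phase_known_child")) {
    m <- get(nm)
    if (!is.null(m) && (!is.logical(m) || nrow(m) != V || ncol(m) != n))
      .stopf("'%s' must be NULL or a logical %d x %d matrix", nm, V, n)
  }
  for (nm in c("mother_ds", "child_ds")) {
    m <- get(nm)
    if (!is.null(m)) {
      if (!is.matrix(m) || nrow(m) != V || ncol(m) != n)
        .stopf("'%s' must be NULL or a %d x %d matrix", nm, V, n)
      if (any(m < 0 | m > 2, na.rm = TRUE))
        .stopf("'%s' has dosages outside [0, 2]", nm)
    }
  }
  structure(list(variants = variants,
                 mother_h1 = mother_h1, mother_h2 = mother_h2,
                 child_h1 = child_h1, child_h2 = child_h2,
                 duo_ids = as.character(duo_ids),
                 mother_ids = as.character(mother_ids),
                 child_ids = as.character(child_ids),
                 phase_known_mother = phase_known_mother,
                 phase_known_child = phase_known_child,
                 mother_ds = mother_ds, child_ds = child_ds),
            class = "duo_genotypes")
}

#' @export
print.duo_genotypes <- function(x, ...) {
  cat(sprintf("<duo_genotypes> %d duos x %d panel variants\n",
              length(x$duo_ids), nrow(x$variants)))
  miss <- mean(is.na(x$mother_h1)) + mean(is.na(x$child_h1))
  cat(sprintf("  regions: %d; missing allele fraction: %.3f\n",
              length(rle(as.character(x$variants$chrom))$lengths), miss / 2))
  invisible(x)
}

#' Number of duos / variants in a duo_genotypes object
#' @param duos A `duo_genotypes` object.
#' @return Integer count.
#' @export
n_duos <- function(duos) length(duos$duo_ids)

#' @rdname n_duos
#' @export
n_panel_variants <- function(duos) nrow(duos$variants)

# Column subset of a duo collection (internal; keeps shared matrices
# unchanged when all columns are selected).
.subset_duos <- function(duos, cols) {
  if (length(cols) == length(duos$duo_ids) && all(cols == seq_along(cols)))
    return(duos)
  take <- function(m) if (is.null(m)) NULL else m[, cols, drop = FALSE]
  duos$mother_h1 <- take(duos$mother_h1)
  duos$mother_h2 <- take(duos$mother_h2)
  duos$child_h1 <- take(duos$child_h1)
  duos$child_h2 <- take(duos$child_h2)
  duos$phase_known_mother <- take(duos$phase_known_mother)
  duos$phase_known_child <- take(duos$phase_known_child)
  duos$mother_ds <- take(duos$mother_ds)
  duos$child_ds <- take(duos$child_ds)
  duos$duo_ids <- duos$duo_ids[cols]
  duos$mother_ids <- duos$mother_ids[cols]
  duos$child_ids <- duos$child_ids[cols]
  duos
}

# Hard genotype matrices (0/1/2/NA).  When dosages are present they take
# precedence, thresholded by best_guess_genotype(); otherwise the two
# haplotype alleles are summed.
.duo_genotype_matrices <- function(duos, hardcall_threshold = 0.1) {
  mg <- if (!is.null(duos$mother_ds)) {
    matrix(best_guess_genotype(duos$mother_ds, hardcall_threshold),
           nrow = nrow(duos$variants))
  } else duos$mother_h1 + duos$mother_h2
  cg <- if (!is.null(duos$child_ds)) {
    matrix(best_guess_genotype(duos$child_ds, hardcall_threshold),
           nrow = nrow(duos$variants))
  } else duos$child_h1 + duos$child_h2
  list(mother = mg, child = cg)
}
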