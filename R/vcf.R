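#' Read phased duo genotypes from a VCF
#'
#' Reads a VCF 4.x file, restricts it to the variants of a weight panel,
#' recodes alleles so that `1` = effect allele, and assembles a
#' [duo_genotypes()] collection for the given mother/child sample pairs.
#'
#' Phased entries use the `|` separator; unphased entries (`/`) keep their
#' genotype but are marked `phase_known = FALSE` and are ignored by
#' haplotype matching.  Panel variants absent from the VCF are retained
#' with all alleles missing.  Records whose REF/ALT pair does not match
#' the panel's allele pair are dropped with a warning (no strand flipping
#' is attempted; strand-ambiguous A/T and C/G variants are matched by
#' allele identity only and reported via a message).  Multiallelic
#' records are dropped with a warning.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param panel A [read_weights()] weight table.
#' @param mother_ids,child_ids Paired sample identifiers; duo `i` is
#'   `mother_ids[i]` + `child_ids[i]`.  All must be present in the VCF.
#' @param duo_ids Optional duo labels, default `child_ids`.
#' @return A [duo_genotypes()] object with dosages attached when the VCF
#'   carries a `DS` FORMAT field.
#' @export
read_phased_vcf <- function(path, panel, mother_ids, child_ids,
                            duo_ids = child_ids) {
  if (length(mother_ids) != length(child_ids))
    .stopf("mother_ids and child_ids must be paired (equal length)")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    .warnf("dropping %d multiallelic VCF record(s)", sum(multi))

  hit <- match(panel$variant_id, fix[, "ID"])
  hit[!is.na(hit) & multi[hit]] <- NA

  # allele harmonisation against the panel
  flip <- rep(NA, nrow(panel))   # TRUE: VCF REF is the effect allele
  ok <- !is.na(hit)
  ref <- fix[hit[ok], "REF"]; alt <- fix[hit[ok], "ALT"]
  ea <- panel$effect_allele[ok]; oa <- panel$other_allele[ok]
  straight <- ref == oa & alt == ea
  flipped <- ref == ea & alt == oa
  flip[ok] <- ifelse(straight, FALSE, ifelse(flipped, TRUE, NA))
  mismatch <- ok & is.na(flip)
  if (any(mismatch)) {
    .warnf("dropping %d panel variant(s) whose VCF alleles do not match: %s",
           sum(mismatch),
           paste(utils::head(panel$variant_id[mismatch], 5), collapse = ", "))
    hit[mismatch] <- NA
  }
  pair <- paste0(pmin(ea, oa), pmax(ea, oa))
  n_ambig <- sum(!is.na(flip[ok]) & pair %in% c("AT", "CG"))
  if (n_ambig > 0)
    message(sprintf(
      "%d strand-ambiguous (A/T or C/G) variant(s) matched by allele identity",
      n_ambig))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  need <- unique(c(mother_ids, child_ids))
  absent <- setdiff(need, samples)
  if (length(absent))
    .stopf("sample id(s) not in VCF: %s", paste(absent, collapse = ", "))

  has_ds <- nrow(vcf@gt) > 0 &&
    "DS" %in% strsplit(vcf@gt[1, "FORMAT"], ":", fixed = TRUE)[[1]]
  ds <- if (has_ds) vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
        else NULL

  V <- nrow(panel)
  decode <- function(ids) {
    g <- gt[, ids, drop = FALSE]
    a1 <- substr(g, 1L, 1L); sep <- substr(g, 2L, 2L); a2 <- substr(g, 3L, 3L)
    a1 <- suppressWarnings(as.integer(a1))
    a2 <- suppressWarnings(as.integer(a2))
    phased <- sep == "|"
    phased[is.na(phased)] <- FALSE
    # re-index to panel rows (NA rows for absent variants)
    take <- function(m) {
      out <- matrix(m[hit, , drop = FALSE], nrow = V)
      out
    }
    h1 <- take(matrix(a1, nrow = nrow(gt)))
    h2 <- take(matrix(a2, nrow = nrow(gt)))
    pk <- take(matrix(phased, nrow = nrow(gt)))
    pk[is.na(pk)] <- FALSE
    # recode so 1 = effect allele
    fl <- which(!is.na(hit) & flip)
    if (length(fl)) {
      h1[fl, ] <- 1L - h1[fl, ]
      h2[fl, ] <- 1L - h2[fl, ]
    }
    d <- NULL
    if (!is.null(ds)) {
      d <- take(ds[, ids, drop = FALSE])
      if (length(fl)) d[fl, ] <- 2 - d[fl, ]
    }
    list(h1 = h1, h2 = h2, pk = matrix(as.logical(pk), nrow = V), ds = d)
  }
  mo <- decode(mother_ids)
  ch <- decode(child_ids)
  duo_genotypes(panel, mo$h1, mo$h2, ch$h1, ch$h2,
                duo_ids = duo_ids, mother_ids = mother_ids,
                child_ids = child_ids,
                phase_known_mother = mo$pk, phase_known_child = ch$pk,
                mother_ds = mo$ds, child_ds = ch$ds)
}

# Write a minimal phased VCF (GT only) for mothers + children of a
# duo_genotypes object.  REF = other allele, ALT = effect allele, so the
# allele codes are written unchanged.
.write_phased_vcf <- function(duos, path) {
  v <- duos$variants
  enc <- function(h1, h2, pk) {
    a1 <- ifelse(is.na(h1), ".", as.character(h1))
    a2 <- ifelse(is.na(h2), ".", as.character(h2))
    sep <- if (is.null(pk)) "|" else ifelse(pk, "|", "/")
    matrix(paste0(a1, sep, a2), nrow = nrow(v))
  }
  gm <- enc(duos$mother_h1, duos$mother_h2, duos$phase_known_mother)
  gc_ <- enc(duos$child_h1, duos$child_h2, duos$phase_known_child)
  header <- c("##fileformat=VCFv4.2",
              "##source=duogrs",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", duos$mother_ids, duos$child_ids),
                    collapse = "\t"))
  cols <- c(list(v$chrom, v$pos, v$variant_id, v$other_allele,
                 v$effect_allele, ".", "PASS", ".", "GT"),
            lapply(seq_len(ncol(gm)), function(j) gm[, j]),
            lapply(seq_len(ncol(gc_)), function(j) gc_[, j]))
  body <- do.call(paste, c(cols, sep = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
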