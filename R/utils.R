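# Internal helpers shared across modules.

# Deterministic named substreams derived from one master seed.  Each
# stochastic component of the simulator seeds its own stream, so toggling
# e.g. phase errors does not shift the haplotype draws.
.SUBSTREAMS <- c(panel = 1L, haplotypes = 2L, mating = 3L, transmission = 4L,
                 phenotypes = 5L, phase_obs = 6L, phase_errors = 7L,
                 missingness = 8L, design = 9L, child_phenotypes = 10L)

.substream_seed <- function(seed, name) {
  k <- .SUBSTREAMS[[name]]
  as.integer((as.double(seed) %% 2111038) * 1000L + k * 101L)
}

.set_substream <- function(seed, name) set.seed(.substream_seed(seed, name))

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stopf("'%s' must be a single value in [0, 1]", name)
  invisible(x)
}

# Standardise to mean 0 / sd 1; degenerate vectors map to zeros so that
# tiny simulated cohorts do not fall over before validation catches them.
.zstd <- function(x) {
  if (length(x) < 2L) return(rep(0, length(x)))
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# First/last panel index of the haplotype region (chromosome) each variant
# belongs to.  Regions are maximal runs of equal 'chrom' labels in panel
# order; windows for haplotype matching never cross them.
.region_bounds <- function(chrom) {
  r <- rle(as.character(chrom))
  id <- rep(seq_along(r$lengths), r$lengths)
  idx <- seq_along(id)
  list(start = ave(idx, id, FUN = min), end = ave(idx, id, FUN = max),
       id = id)
}

# Windowed agreement counts between a child and a mother haplotype at
# selected matrix cells, windows truncated at region edges.  'ch'/'mh' are
# V x n matrices, 'cells' linear indices into them, lo/hi per-site window
# bounds (length V).  Uses one global cumsum; within-column differences are
# exact because both endpoints share the column carry.
.window_match <- function(ch, mh, cells, lo, hi, mask = NULL) {
  a <- ch == mh
  a[is.na(a)] <- FALSE
  if (!is.null(mask)) a <- a & mask
  s <- c(0, cumsum(a))
  V <- nrow(ch)
  i <- ((cells - 1L) %% V) + 1L
  off <- cells - i
  s[off + hi[i] + 1L] - s[off + lo[i]]
}
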