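# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals. Reported table percentages
# use half-up rounding (0.005 -> 0.01), unlike base round()'s round-half-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Coverage-weighted mean methylation; sites with zero coverage contribute
# nothing. Returns NA_real_ when total weight is zero.
weighted_meth <- function(meth, cov) {
  keep <- !is.na(meth) & cov > 0
  tot <- sum(cov[keep])
  if (tot == 0) return(NA_real_)
  sum(meth[keep] * cov[keep]) / tot
}

# Convert a 0-based half-open interval tibble (chrom, start, end) to GRanges.
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# Convert 0-based point positions (chrom, pos) to width-1 GRanges.
points_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$pos + 1L, width = 1L)
  )
}

# Validate a sites tibble is sorted by (chrom, pos); chrom order is the order
# of first appearance, which read_methcounts()/sort_sites() guarantee.
assert_sorted_sites <- function(sites, arg = "sites") {
  if (nrow(sites) < 2) return(invisible(sites))
  ok <- all(unlist(lapply(
    split(sites$pos, factor(sites$chrom, levels = unique(sites$chrom))),
    function(p) !is.unsorted(p)
  )))
  if (!ok) {
    abort(sprintf("`%s` must be sorted by (chrom, pos); see sort_sites().", arg))
  }
  invisible(sites)
}

# Canonical site ordering: chromosomes alphabetically, positions ascending.
sort_sites <- function(sites) {
  dplyr::arrange(sites, .data$chrom, .data$pos)
}

# Derive a stream-specific RNG seed from a master seed; keeps results for
# different stages independent while everything flows from one integer.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  x
}
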