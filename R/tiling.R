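#' Analysis configuration
#'
#' Bundles the thresholds used across the pipeline: tile width in bp, the
#' absolute methylation-difference threshold for calling a differentially
#' methylated region (DMR), the log2 fold-change threshold splitting genes
#' into high/low differential-expression classes, the number of resampling
#' draws for the depletion test, and the RNG seed.
#'
#' @param tile_width Tile width in bp; default 1000.
#' @param dmr_threshold Absolute methylation difference above which a tile is
#'   called a DMR (strict inequality); default 0.2.
#' @param logfc_threshold Absolute log2 fold-change above which a gene is
#'   classed as highly differentially expressed (strict); default 1.
#' @param n_resample_draws Number of random background draws in the depletion
#'   test; default 100.
#' @param rng_seed Integer seed governing all randomized steps.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(tile_width = 1000L, dmr_threshold = 0.2,
                            logfc_threshold = 1.0, n_resample_draws = 100L,
                            rng_seed = 1L) {
  if (tile_width <= 0) abort("`tile_width` must be positive.")
  if (dmr_threshold <= 0 || dmr_threshold >= 1) {
    abort("`dmr_threshold` must lie in (0, 1).")
  }
  if (n_resample_draws < 1) abort("`n_resample_draws` must be >= 1.")
  structure(
    list(
      tile_width = as.integer(tile_width), dmr_threshold = dmr_threshold,
      logfc_threshold = logfc_threshold,
      n_resample_draws = as.integer(n_resample_draws),
      rng_seed = as.integer(rng_seed)
    ),
    class = "analysis_config"
  )
}

#' Genome-wide fixed-width tile grid
#'
#' Per chromosome, non-overlapping tiles `[0, w)`, `[w, 2w)`, ... with the
#' final tile truncated at the chromosome end, so each chromosome yields
#' `ceiling(length / w)` tiles.
#'
#' @param chrom_sizes Named vector (or two-column tibble) of chromosome
#'   lengths in bp.
#' @param config An [analysis_config()]; only `tile_width` is used.
#' @return Tile tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `tile_id`, `origin = "grid"`, `source_snp = NA`.
#' @examples
#' make_grid_tiles(c(chrTest = 2500), analysis_config())
#' @export
make_grid_tiles <- function(chrom_sizes, config = analysis_config()) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (length(chrom_sizes) == 0) abort("`chrom_sizes` is empty.")
  w <- config$tile_width
  purrr::imap(chrom_sizes, function(len, chrom) {
    starts <- seq.int(0L, len - 1L, by = w)
    tibble(
      chrom = chrom, start = starts, end = pmin(starts + w, as.integer(len))
    )
  }) |>
    bind_rows() |>
    mutate(
      tile_id = paste0(.data$chrom, ":", .data$start, "-", .data$end),
      origin = "grid", source_snp = NA_character_
    )
}

#' SNP-centred tiles
#'
#' One tile of width `w` centred on each SNP: `[p - w/2, p + w/2)`, clipped
#' at position 0 and at the chromosome end. For even `w` the centre base is
#' the first base of the right half. Overlapping or duplicate-position tiles
#' are all retained — each locus is its own unit of analysis.
#'
#' @param snps Tibble with `chrom`, `pos` (0-based) and optionally `id`.
#' @param chrom_sizes Named vector (or tibble) of chromosome lengths.
#' @param config An [analysis_config()]; only `tile_width` is used.
#' @return Tile tibble with `origin = "snp_centred"` and `source_snp` set.
#' @export
make_snp_tiles <- function(snps, chrom_sizes, config = analysis_config()) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (any(snps$pos < 0)) abort("SNP positions must be >= 0.")
  missing_chrom <- setdiff(unique(snps$chrom), names(chrom_sizes))
  if (length(missing_chrom) > 0) {
    bad <- snps[snps$chrom %in% missing_chrom, ]
    id <- bad[["id"]] %||% paste0(bad$chrom, ":", bad$pos)
    abort(sprintf(
      "SNP %s lies on a chromosome absent from `chrom_sizes` (%s).",
      id[1], bad$chrom[1]
    ))
  }
  w <- config$tile_width
  half <- w %/% 2L
  len <- unname(chrom_sizes[snps$chrom])
  start <- pmax(snps$pos - half, 0L)
  end <- pmin(snps$pos - half + w, as.integer(len))
  id <- snps[["id"]] %||% paste0("snp_", seq_len(nrow(snps)))
  tibble(
    chrom = snps$chrom, start = as.integer(start), end = as.integer(end),
    tile_id = paste0(id, "|", snps$chrom, ":", start, "-", end),
    origin = "snp_centred", source_snp = id
  )
}

#' Regional methylation over tiles
#'
#' The regional statistic of bisulfite analysis: per tile, the
#' coverage-weighted mean methylation over the symmetric CpGs whose anchor
#' position falls inside `[start, end)` — i.e. total methylated reads over
#' total reads. Tiles containing no covered CpG are reported with missing
#' methylation rather than dropped, because "tile with data" bookkeeping is
#' the denominator of every downstream percentage. An unweighted per-CpG
#' mean is available with `weighted = FALSE`.
#'
#' @param tiles Tile tibble from [make_grid_tiles()] or [make_snp_tiles()].
#' @param sites Symmetric-merged CpG site tibble, sorted by `(chrom, pos)`.
#' @param weighted Weight each CpG by its read coverage? Default `TRUE`.
#' @return Tibble: tile columns plus `mean_meth` (`NA` iff no covered CpG),
#'   `n_cpgs_covered`, `total_reads`.
#' @export
region_methylation <- function(tiles, sites, weighted = TRUE) {
  assert_sorted_sites(sites)
  check_flag(weighted, "weighted")
  covered <- sites[!is.na(sites$meth) & sites$cov > 0, ]
  out <- tiles
  out$mean_meth <- NA_real_
  out$n_cpgs_covered <- 0L
  out$total_reads <- 0L
  if (nrow(covered) > 0 && nrow(tiles) > 0) {
    hits <- GenomicRanges::findOverlaps(
      points_to_granges(covered), intervals_to_granges(tiles)
    )
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    w <- if (weighted) covered$cov[q] else rep(1, length(q))
    num <- tapply(covered$meth[q] * w, s, sum)
    den <- tapply(w, s, sum)
    reads <- tapply(covered$cov[q], s, sum)
    n <- tapply(rep(1L, length(q)), s, sum)
    idx <- as.integer(names(num))
    out$mean_meth[idx] <- unname(num / den)
    out$n_cpgs_covered[idx] <- as.integer(unname(n))
    out$total_reads[idx] <- as.integer(unname(reads))
  }
  out
}
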