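#' Call differentially methylated tiles between two conditions
#'
#' A tile is a DMR when the absolute difference between its regional
#' methylation in the reference and test conditions exceeds
#' `config$dmr_threshold` (strict inequality, default `> 0.2`). Calls exist
#' only for tiles with data — at least one covered CpG — in *both*
#' conditions; tiles present in one collection only, or with missing
#' methylation in either, are excluded with a reported count.
#'
#' The sign convention is `delta = meth_ref - meth_test`: with activated B
#' cells as reference and an EBV-transformed line as test, hypomethylation
#' in the test condition appears as positive `delta`
#' (`direction = "hypo_in_test"`).
#'
#' @param meth_ref,meth_test Tile methylation tibbles from
#'   [region_methylation()], matched by `tile_id`.
#' @param config An [analysis_config()]; uses `dmr_threshold`.
#' @return Tibble with tile columns and `meth_ref`, `meth_test`, `delta`,
#'   `is_dmr`, `direction` (`"hypo_in_test"`, `"hyper_in_test"`, `"none"`).
#' @export
call_dmrs <- function(meth_ref, meth_test, config = analysis_config()) {
  thr <- config$dmr_threshold
  ref <- meth_ref[, c("tile_id", "chrom", "start", "end", "origin",
                      "source_snp", "mean_meth")]
  tst <- meth_test[, c("tile_id", "mean_meth")]
  joined <- inner_join(
    rename(ref, meth_ref = "mean_meth"),
    rename(tst, meth_test = "mean_meth"),
    by = "tile_id"
  )
  n_unmatched <- nrow(meth_ref) + nrow(meth_test) - 2 * nrow(joined)
  calls <- joined |>
    filter(!is.na(.data$meth_ref), !is.na(.data$meth_test)) |>
    mutate(
      delta = .data$meth_ref - .data$meth_test,
      is_dmr = abs(.data$delta) > thr,
      direction = dplyr::case_when(
        .data$delta > thr ~ "hypo_in_test",
        .data$delta < -thr ~ "hyper_in_test",
        TRUE ~ "none"
      )
    )
  n_excluded <- n_unmatched + (nrow(joined) - nrow(calls))
  if (n_excluded > 0) {
    inform(sprintf(
      "%d tile(s) lacked data in one or both conditions and were excluded.",
      n_excluded
    ))
  }
  calls
}

#' Summarise DMR calls for a locus set
#'
#' The bookkeeping behind every reported DMR percentage: input locus count,
#' tiles with data in both conditions (the denominator), DMR count, and the
#' percentage `100 * n_dmr / n_with_data` rounded half-up to two decimals,
#' with directional hypo/hyper counts.
#'
#' @param calls DMR call tibble from [call_dmrs()].
#' @param n_loci Number of input loci/tiles the calls were derived from;
#'   defaults to the number of calls.
#' @return One-row tibble: `n_loci`, `n_with_data`, `n_dmr`, `n_hypo`,
#'   `n_hyper`, `pct_dmr` (`NA` when no tile has data).
#' @examples
#' summarize_dmrs(
#'   tibble::tibble(is_dmr = rep(c(TRUE, FALSE), c(6, 28)), delta = 0.5),
#'   n_loci = 35
#' )
#' @export
summarize_dmrs <- function(calls, n_loci = nrow(calls)) {
  n_with_data <- nrow(calls)
  if (n_loci < n_with_data) {
    abort("`n_loci` cannot be smaller than the number of calls.")
  }
  n_dmr <- sum(calls$is_dmr)
  n_hypo <- sum(calls$is_dmr & calls$delta > 0)
  n_hyper <- sum(calls$is_dmr & calls$delta < 0)
  pct <- if (n_with_data == 0) NA_real_ else {
    round_half_up(100 * n_dmr / n_with_data, 2)
  }
  tibble(
    n_loci = as.integer(n_loci), n_with_data = as.integer(n_with_data),
    n_dmr = as.integer(n_dmr), n_hypo = as.integer(n_hypo),
    n_hyper = as.integer(n_hyper), pct_dmr = pct
  )
}

#' Distribution of tile methylation across a methylome
#'
#' Histogram of regional methylation over tiles with data, plus the
#' five-number-style summary (median, quartiles, IQR, extremes) used to
#' compare methylomes between conditions.
#'
#' @param meth Tile methylation tibble from [region_methylation()].
#' @param breaks Histogram bin boundaries on `[0, 1]`; default 20 equal bins.
#' @return List of class `"meth_distribution"` with `histogram` (tibble:
#'   `bin_start`, `bin_end`, `count`) and `summary` (one-row tibble).
#' @export
genome_methylation_distribution <- function(meth,
                                            breaks = seq(0, 1, by = 0.05)) {
  m <- meth$mean_meth[!is.na(meth$mean_meth)]
  if (length(m) == 0) {
    out <- list(
      histogram = tibble(
        bin_start = utils::head(breaks, -1), bin_end = breaks[-1],
        count = 0L
      ),
      summary = tibble(
        n = 0L, minimum = NA_real_, first_quartile = NA_real_,
        median = NA_real_, third_quartile = NA_real_, maximum = NA_real_,
        iqr = NA_real_
      )
    )
    return(structure(out, class = "meth_distribution"))
  }
  bins <- cut(m, breaks = breaks, include.lowest = TRUE, right = FALSE)
  counts <- as.integer(table(bins))
  q <- unname(quantile(m, c(0, 0.25, 0.5, 0.75, 1)))
  out <- list(
    histogram = tibble(
      bin_start = utils::head(breaks, -1), bin_end = breaks[-1],
      count = counts
    ),
    summary = tibble(
      n = length(m), minimum = q[1], first_quartile = q[2], median = q[3],
      third_quartile = q[4], maximum = q[5], iqr = q[4] - q[2]
    )
  )
  structure(out, class = "meth_distribution")
}

#' @export
print.meth_distribution <- function(x, ...) {
  cat("Tile methylation distribution\n")
  print(x$summary)
  invisible(x)
}

#' @export
glance.meth_distribution <- function(x, ...) x$summary

#' Reciprocal overlap of two DMR sets
#'
#' For DMR call sets on the same tile grid, the percentage of each set's DMR
#' tiles that are also DMRs in the other set (matched by `tile_id`).
#'
#' @param calls_a,calls_b DMR call tibbles from [call_dmrs()].
#' @return One-row tibble: `n_dmr_a`, `n_dmr_b`, `n_shared`, `pct_a_in_b`,
#'   `pct_b_in_a` (a percentage is `NA` when its set has zero DMRs).
#' @export
dmr_overlap <- function(calls_a, calls_b) {
  a <- calls_a$tile_id[calls_a$is_dmr]
  b <- calls_b$tile_id[calls_b$is_dmr]
  shared <- length(intersect(a, b))
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 2)
  }
  tibble(
    n_dmr_a = length(a), n_dmr_b = length(b), n_shared = shared,
    pct_a_in_b = pct(shared, length(a)), pct_b_in_a = pct(shared, length(b))
  )
}
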