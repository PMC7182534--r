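#' Classify genes by differential-expression magnitude
#'
#' Splits genes into high/low differential-expression classes on the
#' absolute log2 fold-change: `de_class = "high"` when
#' `|logfc| > config$logfc_threshold` (strict; default 1, i.e. at least a
#' single log-fold change), `"low"` otherwise. Records with missing `logfc`
#' are excluded with a reported count.
#'
#' @param records Tibble with `gene` and `logfc` (log2 fold-change,
#'   test vs reference; positive means higher in the test condition).
#' @param config An [analysis_config()]; uses `logfc_threshold`.
#' @return `records` (minus missing-`logfc` rows) with a `de_class` column.
#' @seealso [summarize_expression_classes()] for the class bookkeeping.
#' @export
classify_expression <- function(records, config = analysis_config()) {
  thr <- config$logfc_threshold
  missing <- is.na(records$logfc) | !is.finite(records$logfc)
  if (any(missing)) {
    inform(sprintf("Excluded %d record(s) with missing logFC.", sum(missing)))
  }
  out <- records[!missing, , drop = FALSE]
  out$de_class <- ifelse(abs(out$logfc) > thr, "high", "low")
  out
}

#' Expression-class bookkeeping
#'
#' Counts per differential-expression class with the up/down split of the
#' high class and the percentage of genes showing at least the threshold
#' fold-change (half-up, two decimals).
#'
#' @param classified Output of [classify_expression()].
#' @return One-row tibble: `n_genes`, `n_high`, `n_low`, `n_up`, `n_down`,
#'   `pct_high`.
#' @export
summarize_expression_classes <- function(classified) {
  n <- nrow(classified)
  n_high <- sum(classified$de_class == "high")
  tibble(
    n_genes = n, n_high = n_high, n_low = n - n_high,
    n_up = sum(classified$de_class == "high" & classified$logfc > 0),
    n_down = sum(classified$de_class == "high" & classified$logfc < 0),
    pct_high = if (n == 0) NA_real_ else round_half_up(100 * n_high / n, 2)
  )
}

#' Correlate methylation difference with expression change
#'
#' Per annotation class, the correlation between the per-annotation
#' methylation difference and the proximal gene's log2 fold-change. Pearson
#' by default (`method = "spearman"` available). Classes with fewer than 3
#' complete rows or zero variance in either variable get a missing
#' coefficient.
#'
#' @param rows Tibble with `klass`, `delta_meth` and `logfc` (one row per
#'   annotation interval, carrying its assigned gene's logFC).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble per class: `klass`, `n`, `r`.
#' @export
correlate_meth_expression <- function(rows,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  rows |>
    filter(is.finite(.data$delta_meth), is.finite(.data$logfc)) |>
    group_by(.data$klass) |>
    summarise(
      n = n(),
      r = if (n() < 3 ||
              stats::sd(.data$delta_meth) == 0 ||
              stats::sd(.data$logfc) == 0) NA_real_ else {
        cor(.data$delta_meth, .data$logfc, method = method)
      },
      .groups = "drop"
    )
}

#' DMR rate by differential-expression class
#'
#' Per annotation class, the 2 x 2 table of differential-expression class
#' (high/low) against DMR status of the annotation interval, the DMR rate in
#' each expression class (half-up percentages), and the Pearson chi-square
#' test of association. Classes with no rows are skipped with a warning.
#'
#' @param rows Tibble with `klass`, `de_class` and `is_dmr` per annotation
#'   interval.
#' @return Tibble per class: counts, `pct_dmr_low`, `pct_dmr_high`,
#'   `statistic`, `p`.
#' @export
dmr_rate_by_de_class <- function(rows) {
  classes <- unique(rows$klass)
  out <- purrr::map(classes, function(cl) {
    r <- rows[rows$klass == cl & !is.na(rows$is_dmr), ]
    if (nrow(r) == 0) {
      warn(sprintf("Annotation class '%s' has no rows; skipped.", cl))
      return(NULL)
    }
    n_low <- sum(r$de_class == "low")
    n_high <- sum(r$de_class == "high")
    dmr_low <- sum(r$de_class == "low" & r$is_dmr)
    dmr_high <- sum(r$de_class == "high" & r$is_dmr)
    m <- rbind(low = c(dmr_low, n_low - dmr_low),
               high = c(dmr_high, n_high - dmr_high))
    test_ok <- n_low > 0 && n_high > 0 && sum(m[, 1]) > 0 && sum(m[, 2]) > 0
    ct <- if (test_ok) suppressWarnings(chisq.test(m, correct = FALSE)) else {
      NULL
    }
    tibble(
      klass = cl, n_low = n_low, n_dmr_low = dmr_low,
      pct_dmr_low = if (n_low > 0) round_half_up(100 * dmr_low / n_low, 2)
                    else NA_real_,
      n_high = n_high, n_dmr_high = dmr_high,
      pct_dmr_high = if (n_high > 0) round_half_up(100 * dmr_high / n_high, 2)
                     else NA_real_,
      statistic = if (is.null(ct)) NA_real_ else unname(ct$statistic),
      p = if (is.null(ct)) NA_real_ else ct$p.value
    )
  })
  bind_rows(out)
}

#' Read a gene-level expression table
#'
#' Two-column TSV: gene label and log2 fold-change (optionally with a
#' header row `gene logfc`).
#'
#' @param path Path to the TSV.
#' @return Tibble `gene`, `logfc`.
#' @export
read_expression_table <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("^gene\\b", first, ignore.case = TRUE)
  readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("gene", "logfc"),
    skip = 0,
    col_types = readr::cols(
      gene = readr::col_character(), logfc = readr::col_double()
    ),
    progress = FALSE
  )
}
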