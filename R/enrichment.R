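#' Resampling test for DMR depletion in a locus set
#'
#' Tests whether a query locus set contains fewer DMRs than expected from a
#' background SNP catalogue. Each of `config$n_resample_draws` draws samples
#' `n_query` background tiles without replacement (a pseudo locus set) and
#' counts its DMRs; the empirical p-value for depletion is the add-one
#' lower-tail estimate
#' `(1 + #\{draws <= observed\}) / (1 + n_draws)`, which is never exactly 0
#' with finitely many draws. Draws are deterministic for a fixed
#' `config$rng_seed`.
#'
#' @param observed_dmr Observed DMR count in the query set.
#' @param n_query Number of query tiles with data (the draw size).
#' @param background_calls DMR call tibble for the background catalogue
#'   (one row per background tile with data).
#' @param config An [analysis_config()]; uses `n_resample_draws`, `rng_seed`.
#' @param alternative `"less"` (depletion, the default) or `"greater"`.
#' @return Object of class `"depletion_result"`: a list with `observed_dmr`,
#'   `n_query`, `n_draws`, `seed`, `alternative`, `draws` (integer vector),
#'   `min_draw`, `max_draw`, `empirical_p`.
#' @export
resample_depletion <- function(observed_dmr, n_query, background_calls,
                               config = analysis_config(),
                               alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  n_bg <- nrow(background_calls)
  if (n_bg < n_query) {
    abort(sprintf(
      "Background has %d tiles with data but the query needs %d.",
      n_bg, n_query
    ))
  }
  is_dmr <- background_calls$is_dmr
  n_draws <- config$n_resample_draws
  draws <- withr::with_seed(config$rng_seed, {
    vapply(
      seq_len(n_draws),
      function(i) sum(is_dmr[sample.int(n_bg, n_query)]),
      integer(1)
    )
  })
  k <- if (alternative == "less") sum(draws <= observed_dmr) else {
    sum(draws >= observed_dmr)
  }
  structure(
    list(
      observed_dmr = as.integer(observed_dmr), n_query = as.integer(n_query),
      n_draws = n_draws, seed = config$rng_seed, alternative = alternative,
      draws = draws, min_draw = min(draws), max_draw = max(draws),
      empirical_p = (1 + k) / (1 + n_draws)
    ),
    class = "depletion_result"
  )
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Locus-set depletion test (%s tail)\n",
      "  observed DMRs: %d of %d query tiles (%.2f%%)\n",
      "  %d background draws: min %d, max %d\n",
      "  empirical p = %.4g\n"
    ),
    if (x$alternative == "less") "lower" else "upper",
    x$observed_dmr, x$n_query, 100 * x$observed_dmr / x$n_query,
    x$n_draws, x$min_draw, x$max_draw, x$empirical_p
  ))
  invisible(x)
}

#' @rdname resample_depletion
#' @param x A `depletion_result`.
#' @param ... Unused.
#' @export
tidy.depletion_result <- function(x, ...) {
  tibble(draw = seq_along(x$draws), n_dmr = x$draws)
}

#' @rdname resample_depletion
#' @export
glance.depletion_result <- function(x, ...) {
  tibble(
    observed_dmr = x$observed_dmr, n_query = x$n_query, n_draws = x$n_draws,
    min_draw = x$min_draw, max_draw = x$max_draw,
    mean_draw = mean(x$draws), empirical_p = x$empirical_p,
    alternative = x$alternative, seed = x$seed
  )
}

#' Serialize a depletion result as JSON
#'
#' @param x A `depletion_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depletion_json <- function(x, path) {
  jsonlite::write_json(
    list(
      observed = x$observed_dmr, n_query = x$n_query, n_draws = x$n_draws,
      seed = x$seed, alternative = x$alternative, min = x$min_draw,
      max = x$max_draw, empirical_p = x$empirical_p, draws = x$draws
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Lower tail of the binomial distribution
#'
#' `P(X <= k)` for `X ~ Binomial(n, p)`, computed by summing exact terms in
#' log space, for threshold-adjustment arguments of the form "even if a
#' fraction p of loci were DMRs, observing k or fewer out of n would have
#' probability ...".
#'
#' @param n Number of trials.
#' @param k Number of successes (0 <= k <= n).
#' @param p Success probability.
#' @return `P(X <= k)`.
#' @examples
#' binomial_lower_tail(10, 0, 0.5) # 2^-10
#' @export
binomial_lower_tail <- function(n, k, p) {
  if (length(n) != 1 || length(k) != 1 || length(p) != 1 ||
      is.na(n) || is.na(k) || is.na(p) ||
      n < 0 || k < 0 || k > n || p < 0 || p > 1 ||
      n != floor(n) || k != floor(k)) {
    abort("Require integers 0 <= k <= n and probability 0 <= p <= 1.")
  }
  if (p == 0) return(1)
  if (p == 1) return(if (k >= n) 1 else 0)
  i <- 0:k
  log_terms <- lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)
  m <- max(log_terms)
  min(1, exp(m + log(sum(exp(log_terms - m)))))
}
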