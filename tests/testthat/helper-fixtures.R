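# Fixture builders used across test files. All are seeded by the caller.

# Random covered symmetric-site table on one chromosome, sorted.
random_sites <- function(n, chrom = "chr1", max_pos = 10000,
                         cov_lambda = 10) {
  pos <- sort(sample.int(max_pos, n))
  cov <- rpois(n, cov_lambda) + 1L
  tibble::tibble(
    chrom = chrom, pos = pos, strand = "+", context = "CpG",
    meth = round(runif(n), 3), cov = cov
  )
}

# Random strand-split site table: dyads at (p, +) and (p+1, -), some with
# a missing partner, never colliding between dyads.
random_strand_split_sites <- function(n_dyads, chrom = "chr1") {
  anchors <- sort(sample.int(50000, n_dyads)) * 3L
  rows <- lapply(seq_len(n_dyads), function(i) {
    keep_plus <- runif(1) < 0.9
    keep_minus <- runif(1) < 0.9
    if (!keep_plus && !keep_minus) keep_plus <- TRUE
    out <- list()
    if (keep_plus) {
      out$p <- tibble::tibble(
        chrom = chrom, pos = anchors[i], strand = "+", context = "CpG",
        meth = round(runif(1), 3), cov = rpois(1, 6)
      )
    }
    if (keep_minus) {
      out$m <- tibble::tibble(
        chrom = chrom, pos = anchors[i] + 1L, strand = "-", context = "CpG",
        meth = round(runif(1), 3), cov = rpois(1, 6)
      )
    }
    dplyr::bind_rows(out)
  })
  s <- dplyr::bind_rows(rows)
  s$meth[s$cov == 0] <- NA_real_
  dplyr::arrange(s, chrom, pos)
}

# Random annotation track (possibly overlapping within and across classes).
random_track <- function(chrom = "chr1", span = 50000, n_per_class = 8) {
  make <- function(klass) {
    start <- sample.int(span - 2000, n_per_class)
    tibble::tibble(
      chrom = chrom, start = start,
      end = start + sample(200:2000, n_per_class, replace = TRUE),
      klass = klass
    )
  }
  dplyr::bind_rows(make("promoter"), make("exon"), make("intron"))
}

# Independent brute-force class assignment: per-locus membership scan with
# promoter > exon > intron > intergenic precedence.
brute_assign <- function(pos_chrom, pos, track) {
  vapply(seq_along(pos), function(i) {
    for (cl in c("promoter", "exon", "intron")) {
      t <- track[track$klass == cl & track$chrom == pos_chrom[i], ]
      if (nrow(t) > 0 && any(pos[i] >= t$start & pos[i] < t$end)) return(cl)
    }
    "intergenic"
  }, character(1))
}

# Brute-force bp gap between a point and an interval (0 when inside).
brute_gap <- function(pos, start, end) {
  pmax(0L, start - pos, pos - (end - 1L))
}

# Pearson chi-square by the textbook formula on a counts matrix.
brute_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Build a tiny synthetic study (methylome + tiles + calls) shared by
# annotation/pipeline tests; cached per session to keep the suite fast.
tiny_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    p <- synth_params("crisp", chrom_sizes = c(chrS1 = 2e5, chrS2 = 2e5),
                      seed = 404)
    meth <- generate_methylomes(p)
    sites <- lapply(meth$conditions, function(reps)
      merge_symmetric(merge_replicates(reps)))
    cfg <- analysis_config(rng_seed = 404)
    tiles <- make_grid_tiles(p$chrom_sizes, cfg)
    tm <- lapply(sites, function(s) region_methylation(tiles, s))
    calls <- suppressMessages(call_dmrs(tm$reference, tm$test, cfg))
    cache <<- list(params = p, truth = meth$truth, sites = sites,
                   tiles = tiles, tile_meth = tm, calls = calls, cfg = cfg)
    cache
  }
})
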