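test_that("read_methcounts maps fields, filters context, and validates", {
  f <- withr::local_tempfile()
  writeLines(c(
    "chr1\t100\t+\tCpG\t0.75\t4",
    "chr1\t102\t+\tCHH\t0.1\t3",
    "chr1\t105\t-\tCpGx\t1\t2",
    "chr2\t7\t+\tCpG\t0\t0",
    "chr1\t300\t+\tCCG\t0.2\t5"
  ), f)
  expect_message(sites <- read_methcounts(f), "2 non-CpG")
  expect_equal(nrow(sites), 3)
  expect_equal(sites$pos, c(100L, 105L, 7L))
  expect_equal(sites$chrom, c("chr1", "chr1", "chr2"))
  first <- sites[1, ]
  expect_equal(first$meth, 0.75)
  expect_equal(first$cov, 4L)
  expect_equal(first$strand, "+")
  # zero-coverage row retained with missing methylation, not 0
  expect_true(is.na(sites$meth[sites$cov == 0]))
  expect_equal(nrow(suppressMessages(read_methcounts(f, drop_uncovered = TRUE))), 2)
})

test_that("read_methcounts names the offending line on malformed input", {
  cases <- list(
    list(rows = c("chr1\t10\t+\tCpG\t0.5\t4", "chr1\tabc\t+\tCpG\t0.5\t4"),
         msg = "line 2.*pos"),
    list(rows = c("chr1\t10\t+\tCpG\tnotnum\t4"), msg = "line 1.*meth"),
    list(rows = c("chr1\t10\t+\tCpG\t0.5"), msg = "line 1"),
    list(rows = c("chr1\t10\t+\tCpG\t1.5\t4"), msg = "line 1.*outside")
  )
  for (case in cases) {
    f <- withr::local_tempfile()
    writeLines(case$rows, f)
    expect_error(read_methcounts(f), case$msg)
  }
})

test_that("merge_symmetric pools dyads by coverage and passes singletons", {
  s <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 101L, 200L, 301L, 400L, 401L),
    strand = c("+", "-", "+", "-", "+", "-"),
    context = "CpG",
    meth = c(0.5, 1.0, 0.3, 0.8, NA, 0.2),
    cov = c(4L, 2L, 5L, 3L, 0L, 3L)
  )
  out <- merge_symmetric(s)
  expect_equal(nrow(out), 4)
  # paired dyad: coverage-weighted mean
  expect_equal(out$meth[out$pos == 100], 2 / 3)
  expect_equal(out$cov[out$pos == 100], 6L)
  # unpaired sites unchanged
  expect_equal(out$meth[out$pos == 200], 0.3)
  expect_equal(out$meth[out$pos == 301], 0.8)
  # zero-coverage plus strand contributes zero weight
  expect_equal(out$meth[out$pos == 400], 0.2)
  expect_equal(out$cov[out$pos == 400], 3L)
})

test_that("merge_symmetric conserves coverage and is idempotent", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      s <- random_strand_split_sites(40)
    })
    once <- merge_symmetric(s)
    expect_equal(sum(once$cov), sum(s$cov))
    expect_equal(merge_symmetric(once), once)
  }
})

test_that("merge_symmetric never merges minus sites farther than p + 1", {
  s <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 103L), strand = c("+", "-"),
    context = "CpG", meth = c(0.5, 1), cov = c(2L, 2L)
  )
  expect_equal(nrow(merge_symmetric(s)), 2)
  # same offset on different chromosomes must not pair either
  s2 <- tibble::tibble(
    chrom = c("chr1", "chr2"), pos = c(100L, 101L), strand = c("+", "-"),
    context = "CpG", meth = c(0.5, 1), cov = c(2L, 2L)
  )
  expect_equal(nrow(merge_symmetric(s2)), 2)
})

test_that("merge_symmetric rejects duplicate sites", {
  s <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 100L), strand = "+", context = "CpG",
    meth = 0.5, cov = 2L
  )
  expect_error(merge_symmetric(s), "Duplicate")
})

test_that("merge_replicates pools by coverage with union semantics", {
  site <- function(pos, meth, cov) tibble::tibble(
    chrom = "chr1", pos = pos, strand = "+", context = "CpG",
    meth = meth, cov = cov
  )
  # identical replicates: same mean, summed coverage
  r <- merge_replicates(list(site(10L, 0.6, 2L), site(10L, 0.6, 2L),
                             site(10L, 0.6, 2L)))
  expect_equal(r$meth, 0.6)
  expect_equal(r$cov, 6L)
  # weighted mean
  r2 <- merge_replicates(list(site(10L, 1.0, 1L), site(10L, 0.0, 3L)))
  expect_equal(r2$meth, 0.25)
  expect_equal(r2$cov, 4L)
  # site in one replicate only passes through
  r3 <- merge_replicates(list(site(10L, 0.5, 2L), site(20L, 0.9, 4L),
                              site(30L, 0.1, 1L)))
  expect_equal(nrow(r3), 3)
  expect_equal(r3$meth[r3$pos == 20], 0.9)
  # single replicate is the identity
  one <- site(c(10L, 20L), c(0.2, 0.4), c(3L, 5L))
  expect_equal(merge_replicates(list(one)), one)
  expect_error(merge_replicates(list()), "non-empty")
})

test_that("apply_chrom_filter drops excluded chromosomes exactly", {
  x <- tibble::tibble(chrom = c("chr1", "chrX", "chrY", "1"), pos = 1:4)
  out <- apply_chrom_filter(x)
  expect_equal(out$chrom, c("chr1", "1"))
  expect_equal(apply_chrom_filter(x, character()), x)
  expect_warning(apply_chrom_filter(x, unique(x$chrom)), "empty")
  # no silent prefix harmonization: "X" is not "chrX"
  expect_true("1" %in% apply_chrom_filter(x, "chr1")$chrom)
})

test_that("normalize_chroms harmonizes the chr prefix only when asked", {
  x <- tibble::tibble(chrom = c("1", "chr2"))
  expect_equal(normalize_chroms(x, "add")$chrom, c("chr1", "chr2"))
  expect_equal(normalize_chroms(x, "strip")$chrom, c("1", "2"))
})

test_that("write + read round-trips a site table", {
  withr::with_seed(9, {
    s <- random_strand_split_sites(30)
  })
  f <- withr::local_tempfile()
  write_methcounts(s, f)
  back <- read_methcounts(f)
  expect_equal(back$pos, s$pos)
  expect_equal(back$cov, s$cov)
  expect_equal(back$meth, s$meth)
  expect_equal(back$strand, s$strand)
})

test_that("BED reader tolerates track lines and keeps 0-based coordinates", {
  f <- withr::local_tempfile()
  writeLines(c(
    "track name=test", "# comment",
    "chr1\t0\t1000\tregion1\t0\t+",
    "chr2\t500\t600\tregion2\t0\t-"
  ), f)
  bed <- read_bed(f)
  expect_equal(nrow(bed), 2)
  expect_equal(bed$start, c(0L, 500L))
  expect_equal(bed$name[1], "region1")
  f2 <- withr::local_tempfile()
  writeLines("chr1\t100\t100", f2)
  expect_error(read_bed(f2), "end <= start")
})
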