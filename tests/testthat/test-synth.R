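test_that("generation is byte-deterministic for a fixed seed", {
  p <- synth_params("crisp", chrom_sizes = c(chrS1 = 5e4), seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic_dataset(generate_synthetic_dataset(p), d1)
  write_synthetic_dataset(generate_synthetic_dataset(p), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  p2 <- synth_params("crisp", chrom_sizes = c(chrS1 = 5e4), seed = 78)
  m1 <- generate_methylomes(p)$conditions$test[[1]]
  m2 <- generate_methylomes(p2)$conditions$test[[1]]
  expect_false(identical(m1, m2))
})

test_that("planted blocks cover the requested genome fraction", {
  p <- synth_params("crisp", chrom_sizes = c(chrS1 = 5e5, chrS2 = 5e5),
                    seed = 5)
  blocks <- generate_methylomes(p)$truth$blocks
  covered <- sum(blocks$end - blocks$start)
  expect_equal(covered / sum(p$chrom_sizes), p$block_fraction,
               tolerance = 0.02)
  # non-overlapping within each chromosome
  for (cn in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == cn, ]
    b <- b[order(b$start), ]
    expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  # infeasible packing errors out
  expect_error(
    generate_methylomes(synth_params(
      chrom_sizes = c(c1 = 3e4), block_fraction = 0.99,
      block_length = 1.6e4, seed = 1
    )),
    "pack"
  )
})

test_that("null generation (f = 0) yields only a false-positive DMR rate", {
  p <- synth_params("crisp", chrom_sizes = c(chrS1 = 3e5),
                    block_fraction = 0, seed = 12)
  meth <- generate_methylomes(p)
  expect_equal(nrow(meth$truth$blocks), 0)
  sites <- lapply(meth$conditions, function(reps)
    merge_symmetric(merge_replicates(reps)))
  tiles <- make_grid_tiles(p$chrom_sizes)
  tm <- lapply(sites, function(s) region_methylation(tiles, s))
  s <- summarize_dmrs(call_dmrs(tm$reference, tm$test))
  expect_lt(s$pct_dmr, 2)
})

test_that("observed coverage matches the Poisson depth across replicates", {
  p <- synth_params("crisp", chrom_sizes = c(chrS1 = 2e5), seed = 31)
  meth <- generate_methylomes(p)
  expect_length(meth$conditions$reference, p$n_replicates)
  pooled <- merge_symmetric(merge_replicates(meth$conditions$reference))
  expect_equal(mean(pooled$cov), p$coverage_lambda, tolerance = 0.05)
  # strand-split emission: raw replicates carry both strands
  raw <- meth$conditions$reference[[1]]
  expect_setequal(unique(raw$strand), c("+", "-"))
})

test_that("locus-set depletion follows the rejection-sampling law", {
  # rho = 0: no depleted locus inside any block
  p0 <- synth_params("crisp", chrom_sizes = c(chrS1 = 5e5),
                     depletion_rho = 0, n_query = 200, seed = 3)
  m0 <- generate_methylomes(p0)
  ls0 <- generate_locus_sets(p0, m0$truth)
  expect_false(any(ls0$depleted$in_block))
  # rho = 0.3, f = 0.4: inside-block fraction ~ 0.12 / 0.72
  p1 <- synth_params("crisp", chrom_sizes = c(chrS1 = 1e6),
                     block_fraction = 0.4, depletion_rho = 0.3,
                     n_query = 3000, n_background = 100, seed = 3)
  m1 <- generate_methylomes(p1)
  ls1 <- generate_locus_sets(p1, m1$truth)
  expect_equal(mean(ls1$depleted$in_block), 0.12 / 0.72, tolerance = 0.12)
  # background is uniform: inside-block fraction ~ f
  p2 <- synth_params("crisp", chrom_sizes = c(chrS1 = 1e6),
                     block_fraction = 0.4, n_background = 3000, seed = 3)
  m2 <- generate_methylomes(p2)
  ls2 <- generate_locus_sets(p2, m2$truth)
  expect_equal(mean(ls2$background$in_block), 0.4, tolerance = 0.12)
})

test_that("expression generator obeys its closed-form correlation", {
  # many genes on a large layout; no methylome needed, blocks are supplied
  p <- synth_params(
    chrom_sizes = c(chrL = 2.1e7), gene_spacing = 10000,
    expr_slope = 0.5, expr_noise = 0.1, block_fraction = 0.4,
    block_length = 20000, seed = 9
  )
  blocks <- withr::with_seed(9, {
    starts <- seq(0L, 2.05e7, by = 50000L)
    tibble::tibble(chrom = "chrL", start = starts, end = starts + 20000L)
  })
  anno <- generate_annotations_and_expression(p, list(blocks = blocks))
  expect_gt(nrow(anno$genes), 2000)
  joined <- dplyr::inner_join(anno$expression, anno$gene_truth, by = "gene")
  r_obs <- cor(joined$delta_true, joined$logfc)
  a <- p$expr_slope
  v <- stats::var(joined$delta_true)
  r_expected <- a * sqrt(v) / sqrt(a^2 * v + p$expr_noise^2)
  expect_equal(r_obs, r_expected, tolerance = 0.05)
  # sigma = 0 gives exact linearity
  p_exact <- synth_params(chrom_sizes = c(chrL = 2e6), expr_noise = 1e-12,
                          expr_slope = 1, seed = 2)
  a2 <- generate_annotations_and_expression(p_exact, list(blocks = blocks))
  j2 <- dplyr::inner_join(a2$expression, a2$gene_truth, by = "gene")
  expect_equal(j2$logfc, j2$delta_true, tolerance = 1e-9)
  # zero slope centres the correlation on zero
  p_null <- synth_params(chrom_sizes = c(chrL = 2.1e7),
                         gene_spacing = 10000, expr_slope = 0,
                         expr_noise = 0.5, seed = 10)
  a3 <- generate_annotations_and_expression(p_null, list(blocks = blocks))
  j3 <- dplyr::inner_join(a3$expression, a3$gene_truth, by = "gene")
  expect_lt(abs(cor(j3$delta_true, j3$logfc)), 0.06)
})

test_that("promoters in the gene layout are exempt from the planted shift", {
  st <- tiny_study()
  anno <- generate_annotations_and_expression(st$params, st$truth)
  # sites inside promoters show no shift between conditions even in blocks
  prom_in_block <- dplyr::inner_join(
    anno$promoters, st$truth$blocks,
    by = "chrom", suffix = c("", "_blk"), relationship = "many-to-many"
  )
  prom_in_block <- prom_in_block[
    prom_in_block$start >= prom_in_block$start_blk &
      prom_in_block$end <= prom_in_block$end_blk,
  ]
  expect_gt(nrow(prom_in_block), 0)
  pts <- function(sites, iv) {
    keep <- sites$chrom == iv$chrom & sites$pos >= iv$start &
      sites$pos < iv$end & sites$cov > 0
    sum(sites$meth[keep] * sites$cov[keep]) / sum(sites$cov[keep])
  }
  iv <- prom_in_block[1, ]
  m_ref <- pts(st$sites$reference, iv)
  m_test <- pts(st$sites$test, iv)
  expect_lt(abs(m_ref - m_test), st$params$block_shift / 2)
})
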