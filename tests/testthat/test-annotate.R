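test_that("assignment follows promoter > exon > intron precedence", {
  track <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 150L, 150L, 400L),
    end = c(200L, 300L, 350L, 500L),
    klass = c("promoter", "exon", "intron", "intron")
  )
  loci <- tibble::tibble(chrom = "chr1",
                         pos = c(160L, 250L, 320L, 450L, 900L))
  a <- assign_annotation(loci, track)
  expect_equal(a$klass,
               c("promoter", "exon", "intron", "intron", "intergenic"))
  # configurable precedence flips the promoter/exon call
  a2 <- assign_annotation(loci, track,
                          precedence = c("exon", "intron", "promoter"))
  expect_equal(a2$klass[1], "exon")
  # tiles are assigned by midpoint
  tiles <- tibble::tibble(chrom = "chr1", start = 0L, end = 320L,
                          tile_id = "t1")
  expect_equal(assign_annotation(tiles, track)$klass, "promoter")
})

test_that("assignment matches a brute-force membership scan and partitions", {
  for (seed in 1:30) {
    withr::with_seed(seed, {
      track <- random_track()
      loci <- tibble::tibble(
        chrom = "chr1", pos = sample.int(50000, 60)
      )
      shuffled_track <- track[sample.int(nrow(track)), ]
    })
    a <- assign_annotation(loci, track)
    expect_equal(a$klass, brute_assign(loci$chrom, loci$pos, track))
    # shuffling track interval order never changes an assignment
    expect_equal(assign_annotation(loci, shuffled_track)$klass, a$klass)
    # classes partition loci
    expect_equal(sum(table(a$klass)), nrow(loci))
  }
})

test_that("closest_gene minimizes the bp gap with seeded tie-breaking", {
  genes <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 5000L), end = c(2000L, 6000L),
    gene = c("A", "B")
  )
  # containment: distance 0
  inside <- closest_gene(tibble::tibble(chrom = "chr1", pos = 1500L), genes)
  expect_equal(inside$gene, "A")
  expect_equal(inside$gene_distance, 0L)
  # strictly closer gene wins
  near_b <- closest_gene(tibble::tibble(chrom = "chr1", pos = 4800L), genes)
  expect_equal(near_b$gene, "B")
  # exact tie: stable under a fixed seed, can differ across seeds
  genes$start[2] <- 5001L; genes$end[2] <- 6001L
  tie <- tibble::tibble(chrom = "chr1", pos = 3500L) # gap 1501 to both
  picks <- vapply(1:20, function(s) closest_gene(tie, genes, seed = s)$gene,
                  character(1))
  expect_true(all(picks %in% c("A", "B")))
  expect_equal(sort(unique(picks)), c("A", "B"))
  expect_identical(closest_gene(tie, genes, seed = 4)$gene,
                   closest_gene(tie, genes, seed = 4)$gene)
  # no gene on the chromosome: missing result
  off <- closest_gene(tibble::tibble(chrom = "chr9", pos = 10L), genes)
  expect_true(is.na(off$gene))
})

test_that("closest_gene matches an exhaustive distance scan", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      genes <- tibble::tibble(
        chrom = "chr1", start = sort(sample.int(99000, 50)),
        gene = paste0("g", 1:50)
      )
      genes$end <- genes$start + sample(100:900, 50, replace = TRUE)
      loci <- tibble::tibble(chrom = "chr1", pos = sample.int(100000, 40))
    })
    got <- closest_gene(loci, genes, seed = 1)
    for (i in seq_len(nrow(loci))) {
      gaps <- brute_gap(loci$pos[i], genes$start, genes$end)
      expect_equal(got$gene_distance[i], min(gaps))
      expect_true(got$gene[i] %in% genes$gene[gaps == min(gaps)])
    }
  }
})

test_that("chi-square test matches the textbook Pearson formula", {
  m <- rbind(a = c(12, 5), b = c(3, 14))
  res <- annotation_distribution_test(
    c(x = 12, y = 5), c(x = 3, y = 14)
  )
  expect_equal(res$statistic, brute_chisq(m), tolerance = 1e-9)
  expect_equal(res$df, 1)
  # identical proportions: statistic 0, p 1
  same <- annotation_distribution_test(c(x = 10, y = 10), c(x = 10, y = 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # 2 x 4 table: df = 3, statistic matches the formula
  ca <- c(promoter = 30, exon = 45, intron = 80, intergenic = 120)
  cb <- c(promoter = 60, exon = 40, intron = 70, intergenic = 140)
  r4 <- annotation_distribution_test(ca, cb)
  expect_equal(r4$df, 3)
  expect_equal(r4$statistic, brute_chisq(rbind(ca, cb)), tolerance = 1e-9)
  expect_error(annotation_distribution_test(c(x = 0, y = 5), c(x = 0, y = 3)),
               "zero marginal")
})

test_that("Monte-Carlo Fisher test is seeded and returns p in (0, 1]", {
  ca <- c(promoter = 8, exon = 12, intron = 25, intergenic = 55)
  cb <- c(promoter = 20, exon = 15, intron = 20, intergenic = 45)
  r1 <- annotation_distribution_test(ca, cb, method = "fisher_mc",
                                     n_tables = 2000, seed = 5)
  r2 <- annotation_distribution_test(ca, cb, method = "fisher_mc",
                                     n_tables = 2000, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)
  expect_lte(r1$p, 1)
  g <- glance(r1)
  expect_equal(g$method, "fisher_mc")
  expect_equal(sum(tidy(r1)$count), sum(ca) + sum(cb))
})

test_that("annotation track merges overlapping intervals within a class", {
  tr <- annotation_track(
    promoters = tibble::tibble(chrom = "chr1", start = c(0L, 50L),
                               end = c(100L, 200L)),
    exons = tibble::tibble(chrom = "chr1", start = 300L, end = 400L)
  )
  pr <- tr[tr$klass == "promoter", ]
  expect_equal(nrow(pr), 1)
  expect_equal(c(pr$start, pr$end), c(0L, 200L))
})

test_that("per-class profile separates shift-exempt promoters", {
  st <- tiny_study()
  anno <- generate_annotations_and_expression(st$params, st$truth)
  assignments <- assign_annotation(st$tiles, anno$track)
  meth_long <- dplyr::bind_rows(lapply(names(st$tile_meth), function(cn) {
    tibble::tibble(tile_id = st$tile_meth[[cn]]$tile_id, condition = cn,
                   mean_meth = st$tile_meth[[cn]]$mean_meth)
  }))
  prof <- annotation_methylation_profile(assignments, meth_long,
                                         calls = st$calls)
  rates <- prof$dmr_rates
  f <- st$params$block_fraction
  # promoters are exempt from the planted shift; other classes track the
  # planted block fraction
  expect_lt(rates$dmr_fraction[rates$klass == "promoter"], 0.05)
  expect_gt(rates$dmr_fraction[rates$klass == "intergenic"], f - 0.15)
  expect_lt(rates$dmr_fraction[rates$klass == "intergenic"], f + 0.15)
  # profile covers both conditions for every class present
  expect_true(all(table(prof$profile$klass) == 2))
  # identical methylation across classes gives identical summaries
  flat <- tibble::tibble(tile_id = c("a", "b", "c", "d"),
                         klass = c("exon", "intron", "exon", "intron"))
  fm <- tibble::tibble(tile_id = c("a", "b", "c", "d"), condition = "x",
                       mean_meth = 0.5)
  pf <- annotation_methylation_profile(flat, fm)$profile
  expect_equal(pf$median, rep(0.5, 2))
  expect_equal(pf$iqr, rep(0, 2))
})
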