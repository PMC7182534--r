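#' Parameters for the synthetic methylome generator
#'
#' The generator emulates the data regime of an EBV-transformation
#' methylome study: a highly methylated baseline (per-CpG Beta draws with
#' mean ~0.85), large hypomethylated blocks covering a genome fraction `f`
#' in the test condition only (methylation reduced by `d` inside blocks,
#' floored at 0), shallow Poisson read coverage split across strands and
#' biological replicates, locus sets with a controlled propensity `rho` to
#' fall inside blocks, a gene layout whose promoters are exempt from the
#' block shift, and expression log fold-changes weakly coupled to gene-level
#' methylation change.
#'
#' Two presets bundle the study conditions: `"paperlike"` (block fraction
#' 0.46, shift 0.25, mean coverage 6x — the shallow, noisy regime) and
#' `"crisp"` (shift 0.4, coverage 20x — a high-signal regime for fast
#' deterministic recovery tests).
#'
#' @param preset `"paperlike"` (default) or `"crisp"`.
#' @param chrom_sizes Named vector of chromosome lengths; default two
#'   500-kb chromosomes.
#' @param cpg_spacing Mean bp between symmetric CpGs (exponential spacing);
#'   default 100.
#' @param baseline_shape1,baseline_shape2 Beta shape parameters of the
#'   per-CpG baseline methylation; defaults (8.5, 1.5) give mean 0.85.
#' @param block_fraction Genome fraction inside hypomethylated blocks.
#' @param block_shift Methylation decrease inside blocks (test condition).
#' @param block_length Length of each planted block in bp; default 20000.
#' @param coverage_lambda Mean total read depth per condition; default 6.
#' @param n_replicates Biological replicates per condition (coverage is
#'   split evenly across them); default 3.
#' @param depletion_rho Relative propensity of the depleted locus set to
#'   fall inside blocks (1 = null, 0 = fully depleted).
#' @param n_background,n_query Sizes of the background catalogue and the
#'   depleted query locus set.
#' @param expr_slope,expr_noise Slope linking logFC to true gene-level
#'   methylation difference, and the s.d. of the Gaussian noise around it.
#' @param gene_spacing bp between consecutive gene starts; default 50000.
#' @param exempt_promoters Exempt promoter intervals from the block shift?
#'   Default `TRUE`.
#' @param tile_width Tile width the gene layout aligns to; default 1000.
#' @param seed Master seed; every generator draws from streams derived
#'   from it.
#' @return List of class `"synth_params"`.
#' @export
synth_params <- function(preset = c("paperlike", "crisp"),
                         chrom_sizes = c(chrS1 = 5e5, chrS2 = 5e5),
                         cpg_spacing = 100,
                         baseline_shape1 = 8.5, baseline_shape2 = 1.5,
                         block_fraction = 0.46,
                         block_shift = NULL,
                         block_length = 20000,
                         coverage_lambda = NULL,
                         n_replicates = 3L,
                         depletion_rho = 1,
                         n_background = 1000L, n_query = 50L,
                         expr_slope = 2, expr_noise = 0.5,
                         gene_spacing = 50000,
                         exempt_promoters = TRUE,
                         tile_width = 1000L,
                         seed = 1L) {
  preset <- match.arg(preset)
  block_shift <- block_shift %||% switch(preset, paperlike = 0.25, crisp = 0.4)
  coverage_lambda <- coverage_lambda %||% switch(preset, paperlike = 6, crisp = 20)
  p <- list(
    preset = preset, chrom_sizes = as_chrom_sizes(chrom_sizes),
    cpg_spacing = cpg_spacing,
    baseline_shape1 = baseline_shape1, baseline_shape2 = baseline_shape2,
    block_fraction = block_fraction, block_shift = block_shift,
    block_length = block_length, coverage_lambda = coverage_lambda,
    n_replicates = as.integer(n_replicates),
    depletion_rho = depletion_rho,
    n_background = as.integer(n_background), n_query = as.integer(n_query),
    expr_slope = expr_slope, expr_noise = expr_noise,
    gene_spacing = gene_spacing, exempt_promoters = exempt_promoters,
    tile_width = as.integer(tile_width), seed = as.integer(seed)
  )
  if (p$block_fraction < 0 || p$block_fraction > 1) {
    abort("`block_fraction` must lie in [0, 1].")
  }
  if (p$block_shift <= 0 || p$block_shift >= 1) {
    abort("`block_shift` must lie in (0, 1).")
  }
  if (p$depletion_rho < 0) abort("`depletion_rho` must be >= 0.")
  structure(p, class = "synth_params")
}

# Deterministic gene layout shared by the methylome generator (promoter
# exemption) and the annotation generator. Genes sit at multiples of
# `gene_spacing`; each has a 1-tile promoter aligned to the tile grid,
# followed by 4 exons (500 bp) alternating with 3 introns (2 kb).
synth_gene_layout <- function(params) {
  w <- params$tile_width
  exon_len <- 500L
  intron_len <- 2000L
  n_exons <- 4L
  body_len <- n_exons * exon_len + (n_exons - 1L) * intron_len
  footprint <- w + body_len
  layouts <- purrr::imap(params$chrom_sizes, function(len, chrom) {
    starts <- seq(0, len - footprint, by = params$gene_spacing)
    starts <- as.integer(round(starts / w) * w)
    purrr::map(seq_along(starts), function(i) {
      g <- starts[i]
      gene <- sprintf("%s_g%03d", chrom, i)
      exon_starts <- g + w + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
      intron_starts <- exon_starts[-n_exons] + exon_len
      list(
        promoters = tibble(chrom = chrom, start = g, end = g + w, gene = gene),
        exons = tibble(chrom = chrom, start = exon_starts,
                       end = exon_starts + exon_len, gene = gene),
        introns = tibble(chrom = chrom, start = intron_starts,
                         end = intron_starts + intron_len, gene = gene),
        genes = tibble(chrom = chrom, start = g + w,
                       end = g + footprint, gene = gene)
      )
    })
  })
  flat <- purrr::flatten(layouts)
  list(
    promoters = bind_rows(purrr::map(flat, "promoters")),
    exons = bind_rows(purrr::map(flat, "exons")),
    introns = bind_rows(purrr::map(flat, "introns")),
    genes = bind_rows(purrr::map(flat, "genes"))
  )
}

# Are 0-based point positions inside any of the given intervals?
points_in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0 || length(pos) == 0) {
    return(rep(FALSE, length(pos)))
  }
  IRanges::overlapsAny(
    points_to_granges(tibble(chrom = chrom, pos = pos)),
    intervals_to_granges(intervals)
  )
}

#' Generate per-condition synthetic methylomes with planted blocks
#'
#' Symmetric CpG positions are laid down with exponential spacing; each CpG
#' gets a true baseline methylation from a Beta distribution shared between
#' conditions. Inside planted blocks (placed uniformly without overlap to a
#' total genome fraction `block_fraction`), the test condition's true
#' methylation is reduced by `block_shift` (floored at 0); promoter
#' intervals are exempt when `exempt_promoters` is set. Observed data are
#' strand-split — each dyad is emitted as a `+` row at `p` and a `-` row at
#' `p + 1` with independent Poisson coverage and Binomial methylated-read
#' counts — so the reader-side symmetric merge is exercised. Output is
#' byte-deterministic for a fixed seed.
#'
#' @param params A [synth_params()] object.
#' @return List with `conditions` (named list `reference`/`test`, each a
#'   list of replicate site tibbles) and `truth` (planted `blocks`,
#'   exempted `promoters`, per-site truth is not retained).
#' @export
generate_methylomes <- function(params) {
  layout <- synth_gene_layout(params)
  promoters <- if (params$exempt_promoters) layout$promoters else {
    tibble(chrom = character(), start = integer(), end = integer())
  }
  withr::with_seed(derive_seed(params$seed, 1L), {
    blocks <- place_blocks(params)
    per_chrom <- purrr::imap(params$chrom_sizes, function(len, chrom) {
      n_guess <- ceiling(1.3 * len / params$cpg_spacing) + 50
      gaps <- pmax(2, round(rexp(n_guess, 1 / params$cpg_spacing)))
      pos <- cumsum(gaps)
      pos <- pos[pos < len - 1]
      m_true <- rbeta(length(pos), params$baseline_shape1,
                      params$baseline_shape2)
      in_block <- points_in_intervals(chrom, pos, blocks)
      in_prom <- points_in_intervals(chrom, pos, promoters)
      shifted <- in_block & !in_prom
      m_test <- ifelse(shifted, pmax(0, m_true - params$block_shift), m_true)
      list(chrom = chrom, pos = as.integer(pos),
           m = list(reference = m_true, test = m_test))
    })
    lam <- params$coverage_lambda / (2 * params$n_replicates)
    conditions <- purrr::map(
      setNames(c("reference", "test"), c("reference", "test")),
      function(cond) {
        purrr::map(seq_len(params$n_replicates), function(rep_i) {
          bind_rows(purrr::map(per_chrom, function(pc) {
            observe_strand_split(pc$chrom, pc$pos, pc$m[[cond]], lam)
          }))
        })
      }
    )
    list(
      conditions = conditions,
      truth = list(blocks = blocks, promoters_exempt = promoters,
                   params = params)
    )
  })
}

# Place non-overlapping fixed-length blocks totalling fraction f of the
# genome. The block count is set globally (round(f * L / block_length)) and
# apportioned to chromosomes by largest remainder, so the planted fraction
# is not distorted by per-chromosome rounding; within a chromosome, blocks
# fall uniformly over the free space.
place_blocks <- function(params) {
  bl <- as.integer(params$block_length)
  sizes <- params$chrom_sizes
  total_blocks <- round(params$block_fraction * sum(sizes) / bl)
  if (total_blocks == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  quota <- params$block_fraction * sizes / bl
  n_per <- floor(quota)
  rest <- total_blocks - sum(n_per)
  if (rest > 0) {
    extra <- order(quota - n_per, decreasing = TRUE)[seq_len(rest)]
    n_per[extra] <- n_per[extra] + 1
  }
  infeasible <- which(n_per * bl > sizes)
  if (length(infeasible) > 0) {
    i <- infeasible[1]
    abort(sprintf(
      "Cannot pack %d blocks of %d bp into %s (%d bp).",
      n_per[i], bl, names(sizes)[i], as.integer(sizes[i])
    ))
  }
  purrr::imap(setNames(as.integer(n_per), names(sizes)), function(n_blocks, chrom) {
    if (n_blocks == 0) {
      return(tibble(chrom = character(), start = integer(), end = integer()))
    }
    free <- sizes[[chrom]] - n_blocks * bl
    cuts <- sort(runif(n_blocks, 0, free))
    starts <- as.integer(floor(cuts)) + (seq_len(n_blocks) - 1L) * bl
    tibble(chrom = chrom, start = starts, end = starts + bl)
  }) |> bind_rows()
}

# Observe one condition at given true methylation: strand-split Poisson
# coverage, Binomial methylated reads.
observe_strand_split <- function(chrom, pos, m_true, lam_per_strand) {
  n <- length(pos)
  cov_p <- rpois(n, lam_per_strand)
  cov_m <- rpois(n, lam_per_strand)
  k_p <- rbinom(n, cov_p, m_true)
  k_m <- rbinom(n, cov_m, m_true)
  out <- tibble(
    chrom = rep(chrom, 2L * n),
    pos = c(pos, pos + 1L),
    strand = rep(c("+", "-"), each = n),
    context = "CpG",
    meth = c(ifelse(cov_p > 0, k_p / cov_p, NA_real_),
             ifelse(cov_m > 0, k_m / cov_m, NA_real_)),
    cov = c(cov_p, cov_m)
  )
  sort_sites(out)
}

#' Generate background and depleted locus sets
#'
#' Background loci are uniform over the genome. Depleted-set loci are drawn
#' by rejection: a uniform proposal inside a planted block is accepted with
#' probability `depletion_rho`, outside always — so the expected
#' inside-block fraction is `rho * f / (rho * f + 1 - f)` and `rho = 1`
#' reproduces the background law (the calibration null).
#'
#' @param params A [synth_params()] object.
#' @param truth Truth list from [generate_methylomes()] (for the block
#'   intervals).
#' @return List of tibbles `background` and `depleted` (`chrom`, `pos`,
#'   `id`, `in_block`).
#' @export
generate_locus_sets <- function(params, truth) {
  blocks <- truth$blocks
  sizes <- params$chrom_sizes
  draw_uniform <- function(n) {
    chrom <- sample(names(sizes), n, replace = TRUE,
                    prob = sizes / sum(sizes))
    pos <- as.integer(floor(runif(n, 0, unname(sizes[chrom]))))
    tibble(chrom = chrom, pos = pos)
  }
  withr::with_seed(derive_seed(params$seed, 2L), {
    bg <- draw_uniform(params$n_background)
    bg$id <- sprintf("bg_%05d", seq_len(nrow(bg)))
    bg$in_block <- points_in_intervals(bg$chrom, bg$pos, blocks)
    kept <- list()
    n_kept <- 0
    for (iter in seq_len(2000L)) {
      prop <- draw_uniform(params$n_query)
      inb <- points_in_intervals(prop$chrom, prop$pos, blocks)
      accept <- ifelse(inb, runif(nrow(prop)) < params$depletion_rho, TRUE)
      if (any(accept)) {
        keep <- prop[accept, ]
        keep$in_block <- inb[accept]
        kept[[length(kept) + 1]] <- keep
        n_kept <- n_kept + sum(accept)
      }
      if (n_kept >= params$n_query) break
    }
    if (n_kept < params$n_query) {
      abort("Could not generate the requested depleted locus set.")
    }
    depleted <- bind_rows(kept)[seq_len(params$n_query), ]
    depleted$id <- sprintf("dep_%05d", seq_len(nrow(depleted)))
    list(
      background = bg[, c("chrom", "pos", "id", "in_block")],
      depleted = depleted[, c("chrom", "pos", "id", "in_block")]
    )
  })
}

#' Generate the annotation track, gene models and expression table
#'
#' Genes tile part of each chromosome on a deterministic layout (the same
#' layout whose promoters the methylome generator exempts from the block
#' shift): a 1-tile promoter upstream of the TSS, then exons alternating
#' with introns. Each gene's log2 fold-change is
#' `expr_slope * delta_true + Normal(0, expr_noise)`, where `delta_true` is
#' the gene's expected methylation decrease — `block_shift` times the
#' fraction of its body inside planted blocks. Promoter methylation carries
#' no signal (exempt from the shift), so correlation with logFC is present
#' at exons/introns but absent at promoters, by construction.
#'
#' @param params A [synth_params()] object.
#' @param truth Truth list from [generate_methylomes()].
#' @return List: `track` (long annotation track), `promoters`, `exons`,
#'   `introns`, `genes` (labelled interval tibbles), `expression`
#'   (`gene`, `logfc`), `gene_truth` (`gene`, `frac_in_block`,
#'   `delta_true`).
#' @export
generate_annotations_and_expression <- function(params, truth) {
  layout <- synth_gene_layout(params)
  blocks_gr <- intervals_to_granges(truth$blocks)
  genes_gr <- intervals_to_granges(layout$genes)
  ov <- GenomicRanges::intersect(
    genes_gr, GenomicRanges::reduce(blocks_gr)
  )
  hits <- GenomicRanges::findOverlaps(genes_gr, ov)
  ov_width <- tapply(
    GenomicRanges::width(IRanges::pintersect(
      genes_gr[S4Vectors::queryHits(hits)], ov[S4Vectors::subjectHits(hits)]
    )),
    S4Vectors::queryHits(hits), sum
  )
  frac <- rep(0, nrow(layout$genes))
  frac[as.integer(names(ov_width))] <-
    unname(ov_width) / GenomicRanges::width(genes_gr)[as.integer(names(ov_width))]
  delta_true <- params$block_shift * frac
  withr::with_seed(derive_seed(params$seed, 3L), {
    logfc <- params$expr_slope * delta_true +
      rnorm(length(delta_true), 0, params$expr_noise)
  })
  list(
    track = annotation_track(
      promoters = layout$promoters, exons = layout$exons,
      introns = layout$introns
    ),
    promoters = layout$promoters, exons = layout$exons,
    introns = layout$introns, genes = layout$genes,
    expression = tibble(gene = layout$genes$gene, logfc = logfc),
    gene_truth = tibble(
      gene = layout$genes$gene, frac_in_block = frac, delta_true = delta_true
    )
  )
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running all three generators off one seed.
#'
#' @param params A [synth_params()] object.
#' @return List with `methylomes`, `locus_sets`, `annotations`, `truth`.
#' @export
generate_synthetic_dataset <- function(params = synth_params()) {
  meth <- generate_methylomes(params)
  loci <- generate_locus_sets(params, meth$truth)
  anno <- generate_annotations_and_expression(params, meth$truth)
  list(
    methylomes = meth$conditions, locus_sets = loci, annotations = anno,
    truth = meth$truth
  )
}

#' Write a synthetic dataset to disk in pipeline input formats
#'
#' Emits methylation call TSVs per condition/replicate, locus-set and block
#' BED files, a `chrom.sizes` table, gene-model and annotation BEDs, the
#' expression TSV, and a truth JSON. These are exactly the formats
#' [run_pipeline()] consumes.
#'
#' @param dataset Output of [generate_synthetic_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  for (cond in names(dataset$methylomes)) {
    reps <- dataset$methylomes[[cond]]
    for (i in seq_along(reps)) {
      write_methcounts(reps[[i]], fp(sprintf("%s_rep%d.meth", cond, i)))
    }
  }
  sizes <- dataset$truth$params$chrom_sizes
  readr::write_lines(
    paste(names(sizes), as.integer(sizes), sep = "\t"), fp("chrom.sizes")
  )
  loci_bed <- function(x) {
    tibble(chrom = x$chrom, start = x$pos, end = x$pos + 1L, name = x$id)
  }
  write_bed(loci_bed(dataset$locus_sets$background), fp("background.bed"))
  write_bed(loci_bed(dataset$locus_sets$depleted), fp("depleted.bed"))
  write_bed(dataset$truth$blocks, fp("truth_blocks.bed"))
  anno <- dataset$annotations
  write_bed(
    mutate(anno$track, name = .data$klass), fp("annotations.bed")
  )
  write_bed(rename(anno$genes, name = "gene"), fp("genes.bed"))
  readr::write_tsv(anno$expression, fp("expression.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(
      seed = dataset$truth$params$seed,
      block_fraction = dataset$truth$params$block_fraction,
      block_shift = dataset$truth$params$block_shift,
      n_blocks = nrow(dataset$truth$blocks),
      gene_truth = dataset$annotations$gene_truth
    ),
    fp("truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
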