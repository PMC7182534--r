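#' Pipeline run configuration
#'
#' Collects file paths and analysis settings for [run_pipeline()]. All
#' referenced files are checked for existence at validation time. A
#' configuration can also be loaded from a YAML document with
#' [read_run_config()].
#'
#' @param methylomes Named list with entries `reference` and `test`, each a
#'   character vector of per-replicate methylation call file paths.
#' @param chrom_sizes Path to a `chrom.sizes` table.
#' @param locus_sets Named list of BED paths, one per query locus set.
#' @param background Path to the background SNP catalogue BED.
#' @param annotations Path to a BED with annotation class
#'   (promoter/exon/intron) in the name column; optional.
#' @param genes Path to a BED of gene intervals with gene label in the name
#'   column; optional.
#' @param expression Path to a gene/logFC TSV; optional.
#' @param config An [analysis_config()].
#' @param excluded_chroms Chromosomes dropped everywhere; default
#'   `c("chrX", "chrY", "chrM")`.
#' @param out_dir Output directory; `NULL` to keep results in memory only.
#' @return List of class `"run_config"`.
#' @export
pipeline_config <- function(methylomes, chrom_sizes, locus_sets = list(),
                            background = NULL, annotations = NULL,
                            genes = NULL, expression = NULL,
                            config = analysis_config(),
                            excluded_chroms = c("chrX", "chrY", "chrM"),
                            out_dir = NULL) {
  if (!all(c("reference", "test") %in% names(methylomes))) {
    abort("`methylomes` needs named entries `reference` and `test`.")
  }
  paths <- c(
    unlist(methylomes), chrom_sizes, unlist(locus_sets), background,
    annotations, genes, expression
  )
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("Input file not found: %s", missing[1]))
  }
  structure(
    list(
      methylomes = methylomes, chrom_sizes = chrom_sizes,
      locus_sets = locus_sets, background = background,
      annotations = annotations, genes = genes, expression = expression,
      config = config, excluded_chroms = excluded_chroms, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Expects the same fields as [pipeline_config()]; entries under `config`
#' are passed to [analysis_config()].
#'
#' @param path Path to a YAML file.
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Reading YAML configs requires the 'yaml' package.")
  }
  y <- yaml::read_yaml(path)
  cfg <- do.call(analysis_config, y$config %||% list())
  pipeline_config(
    methylomes = y$methylomes, chrom_sizes = y$chrom_sizes,
    locus_sets = y$locus_sets %||% list(), background = y$background,
    annotations = y$annotations, genes = y$genes, expression = y$expression,
    config = cfg,
    excluded_chroms = y$excluded_chroms %||% c("chrX", "chrY", "chrM"),
    out_dir = y$out_dir
  )
}

# Run one pipeline stage; failures abort naming the stage, outputs written
# so far are retained.
run_stage <- function(stage, expr) {
  tryCatch(
    expr,
    error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    }
  )
}

#' Run the full tile-methylation analysis
#'
#' End-to-end orchestration: (1) read, replicate-pool and symmetric-merge
#' each condition's methylome and compute genome-wide tile methylation; (2)
#' call DMRs genome-wide and per query locus set with table-style
#' summaries; (3) test each locus set for DMR depletion against the
#' background catalogue by resampling; (4) assign tiles to annotation
#' classes and profile methylation and DMR rates per class; (5) summarise
#' the genome-wide methylation distribution per condition; (6) integrate
#' expression log fold-changes with per-annotation methylation differences.
#' Stage 6 is skipped with a warning when no expression table is
#' configured. Every emitted summary is stamped with the seed and a config
#' hash; reported percentages are recomputable from the reported counts.
#'
#' @param rc A [pipeline_config()] object.
#' @return List of class `"methtiler_report"` with one element per stage.
#' @export
run_pipeline <- function(rc) {
  cfg <- rc$config
  sizes <- run_stage("inputs", {
    s <- read_chrom_sizes(rc$chrom_sizes)
    s[!names(s) %in% rc$excluded_chroms]
  })

  sites <- run_stage("methylomes", {
    purrr::map(rc$methylomes, function(paths) {
      reps <- purrr::map(paths, read_methcounts)
      pooled <- merge_replicates(reps)
      apply_chrom_filter(merge_symmetric(pooled), rc$excluded_chroms)
    })
  })

  tiles <- make_grid_tiles(sizes, cfg)
  tile_meth <- run_stage("tile_methylation", {
    purrr::map(sites, function(s) region_methylation(tiles, s))
  })

  genome <- run_stage("genome_dmrs", {
    calls <- call_dmrs(tile_meth$reference, tile_meth$test, cfg)
    list(
      calls = calls,
      summary = summarize_dmrs(calls, n_loci = nrow(tiles)),
      distribution = purrr::map(tile_meth, genome_methylation_distribution)
    )
  })

  locus <- run_stage("locus_sets", {
    bg <- NULL
    if (!is.null(rc$background)) {
      bg_loci <- bed_to_loci(read_bed(rc$background), rc$excluded_chroms)
      bg <- locus_set_calls(bg_loci, sizes, sites, cfg)
    }
    sets <- purrr::imap(rc$locus_sets, function(path, nm) {
      loci <- bed_to_loci(read_bed(path), rc$excluded_chroms)
      res <- locus_set_calls(loci, sizes, sites, cfg)
      depletion <- NULL
      if (!is.null(bg) && res$summary$n_with_data > 0 &&
          nrow(bg$calls) >= res$summary$n_with_data) {
        depletion <- resample_depletion(
          observed_dmr = res$summary$n_dmr,
          n_query = res$summary$n_with_data,
          background_calls = bg$calls, config = cfg
        )
      }
      list(loci = loci, calls = res$calls, summary = res$summary,
           depletion = depletion)
    })
    list(background = bg, sets = sets)
  })

  annotation <- NULL
  if (!is.null(rc$annotations)) {
    annotation <- run_stage("annotation", {
      bed <- read_bed(rc$annotations)
      track <- tibble(
        chrom = bed$chrom, start = bed$start, end = bed$end,
        klass = bed$name
      )
      track <- apply_chrom_filter(track, rc$excluded_chroms)
      assignments <- assign_annotation(tiles, track)
      meth_long <- bind_rows(purrr::imap(
        tile_meth,
        function(m, cond) {
          tibble(tile_id = m$tile_id, condition = cond,
                 mean_meth = m$mean_meth)
        }
      ))
      profile <- annotation_methylation_profile(
        assignments, meth_long, calls = genome$calls
      )
      class_counts <- purrr::map(locus$sets, function(s) {
        a <- assign_annotation(s$loci, track)
        table(factor(a$klass, levels = c(
          "promoter", "exon", "intron", "intergenic"
        )))
      })
      bg_counts <- NULL
      dist_tests <- NULL
      if (!is.null(locus$background)) {
        a <- assign_annotation(
          bed_to_loci(read_bed(rc$background), rc$excluded_chroms), track
        )
        bg_counts <- table(factor(a$klass, levels = c(
          "promoter", "exon", "intron", "intergenic"
        )))
        dist_tests <- purrr::map(class_counts, function(cc) {
          keep <- (cc + bg_counts) > 0
          annotation_distribution_test(
            setNames(as.integer(cc[keep]), names(cc)[keep]),
            setNames(as.integer(bg_counts[keep]), names(bg_counts)[keep])
          )
        })
      }
      list(track = track, assignments = assignments, profile = profile,
           class_counts = class_counts, background_counts = bg_counts,
           distribution_tests = dist_tests)
    })
  }

  expression <- NULL
  if (is.null(rc$expression) || is.null(rc$genes) ||
      is.null(rc$annotations)) {
    warn("No expression table (or genes/annotations) configured; expression integration skipped.")
  } else {
    expression <- run_stage("expression", {
      expr <- classify_expression(read_expression_table(rc$expression), cfg)
      genes <- read_bed(rc$genes) |> rename(gene = "name")
      rows <- integrate_expression_methylation(
        annotation$track, genes, sites$reference, sites$test, expr, cfg
      )
      list(
        rows = rows,
        class_summary = summarize_expression_classes(expr),
        correlations = correlate_meth_expression(rows),
        dmr_rates = dmr_rate_by_de_class(rows)
      )
    })
  }

  report <- structure(
    list(
      tiles = tiles, tile_methylation = tile_meth, genome = genome,
      locus_sets = locus, annotation = annotation, expression = expression,
      seed = cfg$rng_seed, config = cfg,
      config_hash = rlang::hash(rc[setdiff(names(rc), "out_dir")])
    ),
    class = "methtiler_report"
  )
  if (!is.null(rc$out_dir)) write_report(report, rc$out_dir)
  report
}

# BED intervals -> point loci (midpoints; width-1 BED rows are SNPs).
bed_to_loci <- function(bed, excluded_chroms) {
  loci <- tibble(
    chrom = bed$chrom,
    pos = bed$start + (bed$end - bed$start) %/% 2L,
    id = bed[["name"]] %||% paste0(bed$chrom, ":", bed$start)
  )
  apply_chrom_filter(loci, excluded_chroms)
}

# SNP-centred tiles + per-condition methylation + DMR calls for one locus
# set.
locus_set_calls <- function(loci, sizes, sites, cfg) {
  tiles <- make_snp_tiles(loci[loci$chrom %in% names(sizes), ], sizes, cfg)
  meth <- purrr::map(sites, function(s) region_methylation(tiles, s))
  calls <- call_dmrs(meth$reference, meth$test, cfg)
  list(calls = calls, summary = summarize_dmrs(calls, n_loci = nrow(loci)))
}

#' Join per-annotation methylation differences with expression
#'
#' For each annotation interval: regional methylation in both conditions,
#' the difference (reference minus test), DMR status at the configured
#' threshold, the closest gene (interval midpoint; ties seeded-random), and
#' that gene's logFC and differential-expression class.
#'
#' @param track Long annotation track (`chrom`, `start`, `end`, `klass`).
#' @param genes Gene interval tibble (`chrom`, `start`, `end`, `gene`).
#' @param sites_ref,sites_test Symmetric-merged site tibbles.
#' @param expression Classified expression tibble from
#'   [classify_expression()].
#' @param config An [analysis_config()].
#' @return Tibble: one row per annotation interval with data and a matched
#'   gene, columns `klass`, `delta_meth`, `is_dmr`, `gene`, `logfc`,
#'   `de_class`.
#' @export
integrate_expression_methylation <- function(track, genes, sites_ref,
                                             sites_test, expression,
                                             config = analysis_config()) {
  anno_tiles <- track |>
    mutate(
      tile_id = paste0(.data$klass, "_", dplyr::row_number()),
      origin = "annotation", source_snp = NA_character_
    )
  m_ref <- region_methylation(anno_tiles, sites_ref)
  m_test <- region_methylation(anno_tiles, sites_test)
  rows <- call_dmrs(m_ref, m_test, config) |>
    rename(delta_meth = "delta") |>
    inner_join(anno_tiles[, c("tile_id", "klass")], by = "tile_id")
  rows <- closest_gene(rows, genes, seed = config$rng_seed)
  rows |>
    inner_join(expression[, c("gene", "logfc", "de_class")], by = "gene") |>
    select("tile_id", "klass", "chrom", "start", "end", "delta_meth",
           "is_dmr", "gene", "logfc", "de_class")
}

#' @export
print.methtiler_report <- function(x, ...) {
  cat("methtiler pipeline report\n")
  cat(sprintf("  seed %d, config hash %s\n", x$seed, x$config_hash))
  cat(sprintf("  grid tiles: %d; genome-wide DMRs: %d of %d tiles with data (%.2f%%)\n",
              nrow(x$tiles), x$genome$summary$n_dmr,
              x$genome$summary$n_with_data, x$genome$summary$pct_dmr))
  for (nm in names(x$locus_sets$sets)) {
    s <- x$locus_sets$sets[[nm]]
    p <- if (is.null(s$depletion)) NA_real_ else s$depletion$empirical_p
    cat(sprintf("  locus set %s: %d/%d DMRs (%.2f%%), depletion p = %.4g\n",
                nm, s$summary$n_dmr, s$summary$n_with_data,
                s$summary$pct_dmr, p))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' TSV summaries plus JSON for depletion results, mirroring the layout of
#' the analysis tables; every file carries the seed and config hash in a
#' companion `run_info.json`.
#'
#' @param report A `"methtiler_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  jsonlite::write_json(
    list(seed = report$seed, config_hash = report$config_hash),
    fp("run_info.json"), auto_unbox = TRUE
  )
  readr::write_tsv(report$genome$summary, fp("genome_dmr_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    report$genome$calls |> select(-"origin", -"source_snp"),
    fp("genome_dmr_calls.tsv"), progress = FALSE
  )
  set_summaries <- purrr::imap(
    report$locus_sets$sets,
    function(s, nm) mutate(s$summary, locus_set = nm, .before = 1)
  )
  if (length(set_summaries) > 0) {
    readr::write_tsv(bind_rows(set_summaries), fp("locus_set_summaries.tsv"),
                     progress = FALSE)
  }
  for (nm in names(report$locus_sets$sets)) {
    d <- report$locus_sets$sets[[nm]]$depletion
    if (!is.null(d)) {
      write_depletion_json(d, fp(sprintf("depletion_%s.json", nm)))
    }
  }
  if (!is.null(report$annotation)) {
    readr::write_tsv(report$annotation$profile$profile,
                     fp("annotation_profile.tsv"), progress = FALSE)
    if (!is.null(report$annotation$profile$dmr_rates)) {
      readr::write_tsv(report$annotation$profile$dmr_rates,
                       fp("annotation_dmr_rates.tsv"), progress = FALSE)
    }
  }
  if (!is.null(report$expression)) {
    readr::write_tsv(report$expression$class_summary,
                     fp("expression_classes.tsv"), progress = FALSE)
    readr::write_tsv(report$expression$correlations,
                     fp("expression_correlations.tsv"), progress = FALSE)
    readr::write_tsv(report$expression$dmr_rates,
                     fp("expression_dmr_rates.tsv"), progress = FALSE)
  }
  invisible(dir)
}
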