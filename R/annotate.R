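#' Build an annotation track
#'
#' Combines promoter, exon and intron interval tables into the single long
#' track used by [assign_annotation()]. Intervals are merged (unioned)
#' within each class, so downstream assignment is independent of how the
#' input intervals were split or ordered. Intergenic is implicit: the
#' complement of the union of all three classes.
#'
#' @param promoters,exons,introns Interval tibbles (`chrom`, `start`, `end`,
#'   0-based half-open); any may be `NULL`.
#' @return Tibble `chrom`, `start`, `end`, `klass` with merged,
#'   non-overlapping intervals within each class.
#' @export
annotation_track <- function(promoters = NULL, exons = NULL, introns = NULL) {
  parts <- list(promoter = promoters, exon = exons, intron = introns)
  purrr::imap(purrr::compact(parts), function(x, klass) {
    gr <- GenomicRanges::reduce(intervals_to_granges(x))
    tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      klass = klass
    )
  }) |> bind_rows()
}

#' Assign loci to annotation classes
#'
#' Each locus receives exactly one class — promoter, exon, intron or
#' intergenic — by precedence: a locus inside both a promoter and an exon is
#' a promoter locus. Point loci (`pos`) are used as-is; interval loci
#' (tiles) are represented by their midpoint. Precedence is configurable;
#' the default puts the regulatory class first.
#'
#' @param loci Tibble with `chrom` and either `pos` or `start`/`end`.
#' @param track Long annotation track from [annotation_track()].
#' @param precedence Class order, highest priority first.
#' @return `loci` with a `klass` column added.
#' @export
assign_annotation <- function(loci, track,
                              precedence = c("promoter", "exon", "intron")) {
  pts <- annotation_points(loci)
  pts_gr <- points_to_granges(pts)
  klass <- rep("intergenic", nrow(pts))
  unassigned <- rep(TRUE, nrow(pts))
  for (cl in precedence) {
    cl_track <- track[track$klass == cl, , drop = FALSE]
    if (nrow(cl_track) == 0) next
    hit <- IRanges::overlapsAny(pts_gr, intervals_to_granges(cl_track))
    take <- hit & unassigned
    klass[take] <- cl
    unassigned <- unassigned & !take
  }
  loci$klass <- klass
  loci
}

# Midpoint representation of loci: points pass through, intervals are
# reduced to start + floor(width/2).
annotation_points <- function(loci) {
  if ("pos" %in% names(loci)) {
    tibble(chrom = loci$chrom, pos = loci$pos)
  } else if (all(c("start", "end") %in% names(loci))) {
    tibble(
      chrom = loci$chrom,
      pos = loci$start + (loci$end - loci$start) %/% 2L
    )
  } else {
    abort("`loci` needs a `pos` column or `start`/`end` columns.")
  }
}

#' Closest gene to each locus
#'
#' For each locus (point or interval midpoint), the gene minimizing the bp
#' gap — 0 when the locus overlaps the gene; upstream and downstream are not
#' distinguished. Exact distance ties are broken by a seeded uniform random
#' choice, so results are deterministic under a fixed seed. Loci on
#' chromosomes with no gene get `NA`.
#'
#' @param loci Tibble with `chrom` and `pos` (or `start`/`end`).
#' @param genes Tibble with `chrom`, `start`, `end`, `gene`.
#' @param seed Integer seed for tie-breaking.
#' @return `loci` with `gene` (label) and `gene_distance` (bp) columns.
#' @export
closest_gene <- function(loci, genes, seed = 1L) {
  pts <- annotation_points(loci)
  pts_gr <- points_to_granges(pts)
  genes_gr <- intervals_to_granges(genes)
  # nearest(select = "all") does not report ties that straddle the query
  # (one gene upstream, one downstream), so the candidate set is rebuilt:
  # take the nearest-gene radius per locus, collect every gene within it,
  # and resolve on the exact bp gap (adjacency counts 1, the bedtools
  # convention; 0 only on overlap)
  dtn <- suppressWarnings(GenomicRanges::distanceToNearest(pts_gr, genes_gr))
  qn <- S4Vectors::queryHits(dtn)
  radius <- S4Vectors::mcols(dtn)$distance + 1L
  expanded <- GenomicRanges::GRanges(
    seqnames = pts$chrom[qn],
    ranges = IRanges::IRanges(
      start = pmax(1L, pts$pos[qn] + 1L - radius),
      end = pts$pos[qn] + 1L + radius
    )
  )
  hits <- GenomicRanges::findOverlaps(expanded, genes_gr)
  q <- qn[S4Vectors::queryHits(hits)]
  s <- S4Vectors::subjectHits(hits)
  d <- pmax(0L, genes$start[s] - pts$pos[q],
            pts$pos[q] - (genes$end[s] - 1L))
  gene <- rep(NA_character_, nrow(pts))
  dist <- rep(NA_integer_, nrow(pts))
  withr::with_seed(seed, {
    for (grp in split(seq_along(q), q)) {
      i <- q[grp[1]]
      grp <- grp[d[grp] == min(d[grp])]
      pick <- if (length(grp) == 1) grp else grp[sample.int(length(grp), 1)]
      gene[i] <- genes$gene[s[pick]]
      dist[i] <- d[pick]
    }
  })
  loci$gene <- gene
  loci$gene_distance <- dist
  loci
}

#' Compare annotation-class distributions between two locus lists
#'
#' Tests whether two locus lists distribute differently over annotation
#' classes, from their class counts. `"chi_square"` is the Pearson test
#' without continuity correction on the 2 x k table
#' (df = k - 1); `"fisher_mc"` is Fisher's exact test with Monte-Carlo
#' p-value estimation (seeded table resampling holding margins fixed),
#' which keeps memory bounded for tables larger than 2 x 2.
#'
#' @param counts_a,counts_b Named non-negative count vectors over the same
#'   classes.
#' @param method `"chi_square"` or `"fisher_mc"`.
#' @param n_tables Monte-Carlo tables for `"fisher_mc"`; default 1e5.
#' @param seed Seed for the Monte-Carlo method.
#' @return Object of class `"contingency_result"`: `table`, `statistic`,
#'   `df`, `p`, `method`.
#' @export
annotation_distribution_test <- function(counts_a, counts_b,
                                         method = c("chi_square", "fisher_mc"),
                                         n_tables = 1e5, seed = 1L) {
  method <- match.arg(method)
  classes <- union(names(counts_a), names(counts_b))
  if (is.null(names(counts_a)) || is.null(names(counts_b))) {
    abort("`counts_a` and `counts_b` must be named count vectors.")
  }
  m <- rbind(
    a = counts_a[classes],
    b = counts_b[classes]
  )
  m[is.na(m)] <- 0
  colnames(m) <- classes
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Contingency table has a zero marginal.")
  }
  if (method == "chi_square") {
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    res <- list(
      table = m, statistic = unname(ct$statistic),
      df = unname(ct$parameter), p = ct$p.value, method = method
    )
  } else {
    ft <- withr::with_seed(
      seed,
      fisher.test(m, simulate.p.value = ncol(m) > 2, B = as.integer(n_tables))
    )
    res <- list(
      table = m, statistic = NA_real_, df = NA_real_, p = ft$p.value,
      method = method
    )
  }
  structure(res, class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Annotation distribution test (%s)\n", x$method))
  print(x$table)
  if (x$method == "chi_square") {
    cat(sprintf("chi-square = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p))
  } else {
    cat(sprintf("p = %.4g\n", x$p))
  }
  invisible(x)
}

#' @rdname annotation_distribution_test
#' @param x A `contingency_result`.
#' @param ... Unused.
#' @export
tidy.contingency_result <- function(x, ...) {
  as_tibble(as.data.frame.table(x$table, responseName = "count")) |>
    rename(list = "Var1", klass = "Var2")
}

#' @rdname annotation_distribution_test
#' @export
glance.contingency_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p = x$p, method = x$method)
}

#' Per-class methylation profile
#'
#' Summarises regional methylation by annotation class and condition
#' (median, quartiles, IQR), and — when DMR calls are supplied — the
#' per-class DMR fraction, quantifying observations such as promoters being
#' largely exempt from genome-wide hypomethylation.
#'
#' @param assignments Tibble with `tile_id` and `klass` (from
#'   [assign_annotation()] applied to tiles).
#' @param meth Long tibble with `tile_id`, `condition`, `mean_meth`.
#' @param calls Optional DMR call tibble (`tile_id`, `is_dmr`).
#' @return List of class `"annotation_profile"`: `profile` (tibble per
#'   class x condition) and `dmr_rates` (tibble per class, or `NULL`).
#' @export
annotation_methylation_profile <- function(assignments, meth, calls = NULL) {
  prof <- inner_join(
    assignments[, c("tile_id", "klass")], meth, by = "tile_id"
  ) |>
    filter(!is.na(.data$mean_meth)) |>
    group_by(.data$klass, .data$condition) |>
    summarise(
      n = n(),
      minimum = min(.data$mean_meth),
      first_quartile = unname(quantile(.data$mean_meth, 0.25)),
      median = median(.data$mean_meth),
      third_quartile = unname(quantile(.data$mean_meth, 0.75)),
      maximum = max(.data$mean_meth),
      .groups = "drop"
    ) |>
    mutate(iqr = .data$third_quartile - .data$first_quartile)
  rates <- NULL
  if (!is.null(calls)) {
    rates <- inner_join(
      assignments[, c("tile_id", "klass")],
      calls[, c("tile_id", "is_dmr")],
      by = "tile_id"
    ) |>
      group_by(.data$klass) |>
      summarise(
        n_with_data = n(), n_dmr = sum(.data$is_dmr),
        dmr_fraction = sum(.data$is_dmr) / n(),
        .groups = "drop"
      )
  }
  structure(list(profile = prof, dmr_rates = rates),
            class = "annotation_profile")
}

#' @export
print.annotation_profile <- function(x, ...) {
  cat("Methylation by annotation class\n")
  print(x$profile)
  if (!is.null(x$dmr_rates)) {
    cat("\nDMR rates by class\n")
    print(x$dmr_rates)
  }
  invisible(x)
}
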