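#' Read a CpG-level methylation call table
#'
#' Parses the six-column per-cytosine text format produced by post-alignment
#' methylation callers: `chrom`, `pos` (0-based), `strand`, `context`,
#' `meth` (methylation fraction) and `cov` (read coverage), whitespace
#' separated, no header. Only CpG-context rows are retained; the number of
#' dropped non-CpG rows is reported. Rows with zero coverage are kept — they
#' mark assayed-but-uncovered CpGs — but their methylation fraction is stored
#' as `NA` so it can never contribute weight downstream. Set `drop_uncovered
#' = TRUE` to discard them instead.
#'
#' @param path Path to the methylation call file.
#' @param drop_uncovered Drop rows with `cov == 0`? Default `FALSE`.
#' @return A tibble with columns `chrom`, `pos` (integer, 0-based), `strand`,
#'   `context`, `meth` (double in `[0, 1]`, `NA` when `cov == 0`) and `cov`
#'   (integer), sorted by `(chrom, pos)`.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t100\t+\tCpG\t0.75\t4", "chr1\t102\t+\tCHH\t0\t3"), f)
#' read_methcounts(f)
#' @export
read_methcounts <- function(path, drop_uncovered = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), meth = double(), cov = integer()
    ))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) < 6)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed row at line %d: expected >= 6 whitespace-separated fields.",
      bad[1]
    ))
  }
  pull <- function(i) vapply(fields, `[[`, character(1), i)
  pos_c <- pull(2); meth_c <- pull(5); cov_c <- pull(6)
  pos <- suppressWarnings(as.integer(pos_c))
  meth <- suppressWarnings(as.double(meth_c))
  cov <- suppressWarnings(as.integer(cov_c))
  for (col in list(list(pos, "pos"), list(meth, "meth"), list(cov, "cov"))) {
    if (anyNA(col[[1]])) {
      abort(sprintf(
        "Malformed row at line %d: non-numeric %s field.",
        which(is.na(col[[1]]))[1], col[[2]]
      ))
    }
  }
  out <- tibble(
    chrom = pull(1), pos = pos, strand = pull(3),
    context = pull(4), meth = meth, cov = cov
  )
  bad_meth <- which(out$cov > 0 & (out$meth < 0 | out$meth > 1))
  if (length(bad_meth) > 0) {
    abort(sprintf(
      "Invalid methylation fraction at line %d: %g is outside [0, 1].",
      bad_meth[1], out$meth[bad_meth[1]]
    ))
  }
  if (any(out$pos < 0)) {
    abort(sprintf("Negative position at line %d.", which(out$pos < 0)[1]))
  }
  is_cpg <- grepl("cpg", out$context, ignore.case = TRUE)
  n_dropped <- sum(!is_cpg)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d non-CpG-context row(s).", n_dropped))
  }
  out <- out[is_cpg, ]
  if (drop_uncovered) out <- out[out$cov > 0, ]
  out$meth[out$cov == 0] <- NA_real_
  sort_sites(out)
}

#' Write a CpG site table to methylation-call text format
#'
#' Inverse of [read_methcounts()]. Zero-coverage sites (methylation `NA`) are
#' written with a methylation field of 0, the convention of the callers this
#' format comes from; reading the file back restores the `NA` marker.
#'
#' @param sites Tibble of CpG sites as returned by [read_methcounts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methcounts <- function(sites, path) {
  meth <- ifelse(is.na(sites$meth), 0, sites$meth)
  lines <- paste(
    sites$chrom, sites$pos, sites$strand,
    sites[["context"]] %||% "CpG",
    formatC(meth, format = "g", digits = 15), sites$cov,
    sep = "\t"
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Merge symmetric CpG dyads across strands
#'
#' A CpG on the plus strand at position `p` and its reverse-complement
#' partner on the minus strand at `p + 1` report methylation of the same
#' dyad. This pools them into one symmetric site anchored at `p`
#' (plus-strand coordinate) with summed coverage and coverage-weighted
#' methylation. Unpaired sites pass through unchanged, so total read count
#' is conserved and the operation is idempotent. Merging is keyed strictly
#' on (`+` at `p`, `-` at `p + 1`) on the same chromosome.
#'
#' @param sites Tibble of CpG sites sorted by `(chrom, pos)`.
#' @return Tibble of symmetric sites sorted by `(chrom, pos)`; merged sites
#'   carry strand `"+"`.
#' @examples
#' s <- tibble::tibble(
#'   chrom = "chr1", pos = c(100L, 101L), strand = c("+", "-"),
#'   context = "CpG", meth = c(0.5, 1), cov = c(4L, 2L)
#' )
#' merge_symmetric(s)
#' @export
merge_symmetric <- function(sites) {
  assert_sorted_sites(sites)
  key <- paste(sites$chrom, sites$pos, sites$strand)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    abort(sprintf("Duplicate site (chrom pos strand): %s", d))
  }
  plus <- sites[sites$strand == "+", ]
  minus <- sites[sites$strand == "-", ]
  other <- sites[!sites$strand %in% c("+", "-"), ]
  m_idx <- match(paste(minus$chrom, minus$pos - 1L), paste(plus$chrom, plus$pos))
  paired_minus <- !is.na(m_idx)
  pi <- m_idx[paired_minus]
  mi <- which(paired_minus)
  cov_p <- plus$cov[pi]
  cov_m <- minus$cov[mi]
  tot <- cov_p + cov_m
  wm <- ifelse(
    tot == 0, NA_real_,
    (ifelse(cov_p > 0, plus$meth[pi] * cov_p, 0) +
       ifelse(cov_m > 0, minus$meth[mi] * cov_m, 0)) / pmax(tot, 1L)
  )
  merged <- plus[pi, ]
  merged$meth <- wm
  merged$cov <- tot
  unpaired_plus <- plus[-pi, , drop = FALSE]
  if (length(pi) == 0) unpaired_plus <- plus
  unpaired_minus <- minus[!paired_minus, , drop = FALSE]
  sort_sites(bind_rows(merged, unpaired_plus, unpaired_minus, other))
}

#' Pool biological replicates of a methylome
#'
#' Combines per-replicate CpG site tables within one condition: per genomic
#' site (chrom, pos, strand), coverage is summed and methylation is the
#' coverage-weighted mean across replicates. Sites present in only some
#' replicates are kept with the available data (union semantics).
#'
#' @param replicates List of one or more CpG site tibbles.
#' @return One pooled site tibble, sorted by `(chrom, pos)`.
#' @export
merge_replicates <- function(replicates) {
  if (!is.list(replicates) || length(replicates) == 0 || is_tibble(replicates)) {
    abort("`replicates` must be a non-empty list of site tibbles.")
  }
  if (length(replicates) == 1) return(sort_sites(replicates[[1]]))
  all <- bind_rows(replicates)
  out <- all |>
    group_by(.data$chrom, .data$pos, .data$strand) |>
    summarise(
      context = .data$context[1],
      meth = weighted_meth(.data$meth, .data$cov),
      cov = sum(.data$cov),
      .groups = "drop"
    )
  sort_sites(out)[, c("chrom", "pos", "strand", "context", "meth", "cov")]
}

#' Drop records on excluded chromosomes
#'
#' Filters any table carrying a `chrom` column. The default exclusion set
#' removes sex, mitochondrial, and other haploid chromosomes, which are
#' excluded from diploid methylation comparisons. Matching is exact string
#' match — no `"chr"` prefix is silently added or stripped (see
#' [normalize_chroms()] for explicit harmonization).
#'
#' @param x Tibble with a `chrom` column (sites, intervals, tiles, loci).
#' @param excluded Character vector of chromosome names to drop.
#' @return `x` without rows on excluded chromosomes.
#' @export
apply_chrom_filter <- function(x, excluded = c("chrX", "chrY", "chrM")) {
  out <- x[!x$chrom %in% excluded, , drop = FALSE]
  if (nrow(out) == 0 && nrow(x) > 0) {
    warn("All records fell on excluded chromosomes; result is empty.")
  }
  out
}

#' Harmonize the "chr" prefix of chromosome names
#'
#' Explicit opt-in renaming; nothing in the package renames chromosomes
#' automatically, because silent renaming causes cross-file mismatches.
#'
#' @param x Tibble with a `chrom` column.
#' @param style `"add"` to ensure a leading `"chr"`, `"strip"` to remove it.
#' @return `x` with rewritten chromosome names.
#' @export
normalize_chroms <- function(x, style = c("add", "strip")) {
  style <- match.arg(style)
  if (style == "add") {
    no_pref <- !startsWith(x$chrom, "chr")
    x$chrom[no_pref] <- paste0("chr", x$chrom[no_pref])
  } else {
    x$chrom <- sub("^chr", "", x$chrom)
  }
  x
}

#' Read a BED interval file
#'
#' BED3/BED6; coordinates stay 0-based half-open. Track definition lines,
#' browser lines and `#` comments are tolerated and skipped.
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t| +")
  nf <- min(lengths(fields))
  pull <- function(i) vapply(fields, `[[`, character(1), i)
  out <- tibble(
    chrom = pull(1),
    start = as.integer(pull(2)),
    end = as.integer(pull(3))
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    abort("Malformed BED: non-numeric start/end.")
  }
  if (any(out$end <= out$start)) {
    abort("Malformed BED: interval with end <= start.")
  }
  if (nf >= 4) out$name <- pull(4)
  if (nf >= 5) out$score <- suppressWarnings(as.double(pull(5)))
  if (nf >= 6) out$strand <- pull(6)
  out
}

#' Write intervals as BED
#'
#' Emits BED3 or, when a `name` column (e.g. `tile_id`) is present, BED6
#' with score 0 and strand `"."` unless the table provides them.
#'
#' @param x Interval tibble with `chrom`, `start`, `end` and optionally
#'   `name`/`tile_id`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  nm <- x[["name"]] %||% x[["tile_id"]]
  if (is.null(nm)) {
    lines <- paste(x$chrom, x$start, x$end, sep = "\t")
  } else {
    lines <- paste(
      x$chrom, x$start, x$end, nm,
      x[["score"]] %||% rep(0, nrow(x)), x[["strand"]] %||% rep(".", nrow(x)),
      sep = "\t"
    )
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a chromosome sizes table
#'
#' Two-column whitespace-separated text (chromosome name, length in bp), the
#' usual `chrom.sizes` convention.
#'
#' @param path Path to the file.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(
    path, col_names = c("chrom", "size"),
    col_types = readr::cols(chrom = "c", size = "d"), progress = FALSE
  )
  setNames(as.integer(x$size), x$chrom)
}

# Accept chrom sizes as a named vector or a two-column tibble.
as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(chrom_sizes[[2]], chrom_sizes[[1]])
  }
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0)) {
    abort("`chrom_sizes` must be a named vector of positive lengths.")
  }
  chrom_sizes
}
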