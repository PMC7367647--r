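## Per-bin raw coverage for one sample: counting reads from an alignment
## file, loading/writing count tables, optional GC correction, and QC.

new_coverage_profile <- function(sample_id, grid, counts, discarded = 0,
                                 metadata = list()) {
  stopifnot(length(counts) == grid$n_bins, all(counts >= 0))
  structure(list(sample_id = sample_id, grid = grid,
                 counts = as.numeric(counts),
                 total_reads = sum(counts), discarded = discarded,
                 metadata = metadata),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %s reads in %d bins (%d discarded)\n",
              x$sample_id, format(x$total_reads, big.mark = ","),
              x$grid$n_bins, x$discarded))
  invisible(x)
}

#' Relative coverage of a profile
#'
#' Per-bin read count divided by the total usable reads; sums to 1 and is
#' invariant under uniform depth scaling, so samples sequenced to different
#' depths are directly comparable. This is the coverage unit entering the
#' Z-score transform.
#'
#' @param profile a `coverage_profile`.
#' @return numeric vector, one value per bin.
#' @export
relative_coverage <- function(profile) {
  if (profile$total_reads == 0) return(rep(0, length(profile$counts)))
  profile$counts / profile$total_reads
}

#' Count aligned reads per bin
#'
#' Assigns each passing read to exactly one bin by the leftmost mapped
#' coordinate; for paired data only the first mate is counted, so a
#' fragment contributes once. Reads on chromosomes absent from the grid are
#' discarded and the discard count logged on the profile.
#'
#' @param alignment_source path to a coordinate-sorted BAM (or SAM, which
#'   is converted on the fly).
#' @param grid a `bin_grid`; its chromosomes must all be present in the
#'   alignment header with matching lengths.
#' @param min_mapq minimum mapping quality (default 30).
#' @param dedup drop duplicate-flagged reads (default `TRUE`).
#' @param proper_pair keep only proper pairs (default `TRUE`; ignored for
#'   unpaired data).
#' @param sample_id profile label; defaults to the file base name.
#' @return a `coverage_profile`.
#' @export
count_reads_per_bin <- function(alignment_source, grid, min_mapq = 30,
                                dedup = TRUE, proper_pair = TRUE,
                                sample_id = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  if (!file.exists(alignment_source))
    stop("alignment file not found: ", alignment_source)
  if (is.null(sample_id))
    sample_id <- sub("\\.(bam|sam)$", "", basename(alignment_source))
  bam <- alignment_source
  if (grepl("\\.sam$", alignment_source, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignment_source,
                            destination = tempfile("cinscreen_"),
                            overwrite = TRUE, indexDestination = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  want <- grid$build$chromosomes
  missing_chr <- setdiff(names(want), names(hdr))
  if (length(missing_chr) > 0)
    stop("alignment header lacks grid chromosomes: ",
         paste(missing_chr, collapse = ", "))
  shared <- intersect(names(want), names(hdr))
  mism <- shared[hdr[shared] != want[shared]]
  if (length(mism) > 0)
    stop("chromosome length mismatch between grid and alignment header: ",
         paste(mism, collapse = ", "))

  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (dedup) FALSE else NA,
    isProperPair = if (proper_pair) TRUE else NA,
    isSecondMateRead = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq,
                                   what = c("rname", "pos"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  rname <- as.character(res$rname)
  pos <- res$pos
  keep <- !is.na(pos) & rname %in% names(want)
  discarded <- sum(!keep)
  rname <- rname[keep]; pos <- pos[keep]

  counts <- numeric(grid$n_bins)
  if (length(pos) > 0) {
    ord <- bin_ordinal(grid, rname, pos - 1)  # 1-based BAM pos -> 0-based
    tab <- tabulate(ord, nbins = grid$n_bins)
    counts <- as.numeric(tab)
  }
  if (discarded > 0)
    message(sprintf("count_reads_per_bin: %d reads discarded (off-grid)",
                    discarded))
  new_coverage_profile(sample_id, grid, counts, discarded = discarded,
                       metadata = list(min_mapq = min_mapq, dedup = dedup,
                                       proper_pair = proper_pair,
                                       source = alignment_source))
}

## Global bin ordinal for 0-based positions; vectorized.
bin_ordinal <- function(grid, chrom, pos0) {
  b <- grid$bins
  chroms <- names(grid$build$chromosomes)
  offsets <- c(0, cumsum(tabulate(match(b$chrom, chroms),
                                  nbins = length(chroms))))
  names(offsets) <- c(chroms, "_end")
  within <- floor(pos0 / grid$bin_size) + 1L
  as.integer(offsets[chrom] + within)
}

#' Write / read a per-bin count table
#'
#' TSV dialect: header `chrom  start  end  count`, one row per bin in grid
#' order, 0-based half-open coordinates. `load_counts_table()` requires the
#' table to match the grid exactly (every bin present once) so the
#' round-trip is lossless.
#'
#' @param profile a `coverage_profile`.
#' @param path TSV path.
#' @return `write_counts_table`: `path` invisibly; `load_counts_table`: a
#'   `coverage_profile`.
#' @export
write_counts_table <- function(profile, path) {
  df <- cbind(fmt_bins(profile$grid$bins), count = profile$counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## plain-integer coordinate rendering for TSV output
fmt_bins <- function(bins) {
  bins$start <- sprintf("%.0f", bins$start)
  bins$end <- sprintf("%.0f", bins$end)
  bins
}

#' @rdname write_counts_table
#' @param grid the `bin_grid` the table must match.
#' @param sample_id profile label; defaults to the file base name.
#' @export
load_counts_table <- function(path, grid, sample_id = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(df)))
    stop("counts table must have columns chrom, start, end, count")
  key <- sprintf("%s:%.0f-%.0f", df$chrom, df$start, df$end)
  gkey <- sprintf("%s:%.0f-%.0f", grid$bins$chrom, grid$bins$start,
                  grid$bins$end)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate bin row in counts table: ", dup)
  }
  missing_bins <- setdiff(gkey, key)
  if (length(missing_bins) > 0)
    stop("counts table missing bin: ", missing_bins[1])
  extra <- setdiff(key, gkey)
  if (length(extra) > 0)
    stop("counts table row not on grid: ", extra[1])
  counts <- df$count[match(gkey, key)]
  if (any(counts < 0) || any(is.na(counts)))
    stop("counts must be non-negative numbers")
  new_coverage_profile(sample_id, grid, counts,
                       metadata = list(source = path))
}

#' GC-bias correction (off by default)
#'
#' When enabled, each bin count is divided by a lowess-smoothed trend of
#' coverage versus GC fraction and rescaled to preserve the total; the
#' default workflow applies no GC correction.
#'
#' @param profile a `coverage_profile`.
#' @param gc_per_bin GC fraction per bin, in `[0, 1]`, same length as the
#'   grid.
#' @param enabled apply the correction (default `FALSE`, identity).
#' @return a `coverage_profile`.
#' @export
gc_correct <- function(profile, gc_per_bin, enabled = FALSE) {
  if (!enabled) return(profile)
  if (length(gc_per_bin) != length(profile$counts))
    stop("gc_per_bin length must equal the number of bins")
  if (any(gc_per_bin < 0 | gc_per_bin > 1, na.rm = TRUE))
    stop("gc_per_bin values must lie in [0, 1]")
  counts <- profile$counts
  use <- !is.na(gc_per_bin) & counts >= 0
  trend <- if (length(unique(gc_per_bin[use])) < 2) {
    rep(mean(counts[use]), length(counts))  # flat GC: constant trend
  } else {
    fit <- lowess(gc_per_bin[use], counts[use], f = 0.3)
    approx(fit$x, fit$y, xout = gc_per_bin, rule = 2)$y
  }
  trend[trend <= 0] <- median(trend[trend > 0])
  corrected <- counts / trend
  corrected <- corrected * (sum(counts) / sum(corrected))
  out <- new_coverage_profile(profile$sample_id, profile$grid, corrected,
                              discarded = profile$discarded,
                              metadata = c(profile$metadata,
                                           list(gc_corrected = TRUE)))
  out
}

#' QC a coverage profile
#'
#' @param profile a `coverage_profile`.
#' @param min_reads minimum total usable reads (default 10 million paired
#'   reads, the depth floor at which 200 kb bin Z-scores are calibrated).
#' @return list of class `qc_report`: `total_reads`, `pass_min_reads`,
#'   `fraction_nonzero_bins`, `flags`.
#' @export
qc_profile <- function(profile, min_reads = 1e7) {
  total <- profile$total_reads
  flags <- character(0)
  if (total == 0) flags <- c(flags, "empty")
  pass <- total >= min_reads
  if (!pass && total > 0) flags <- c(flags, "low_reads")
  frac_nonzero <- mean(profile$counts > 0)
  if (total > 0 && frac_nonzero < 0.5) flags <- c(flags, "sparse_bins")
  structure(list(sample_id = profile$sample_id, total_reads = total,
                 pass_min_reads = pass,
                 fraction_nonzero_bins = frac_nonzero, flags = flags),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %s reads, %s (nonzero bins: %.1f%%)%s\n",
              x$sample_id, format(x$total_reads, big.mark = ","),
              if (x$pass_min_reads) "PASS" else "FAIL",
              100 * x$fraction_nonzero_bins,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
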