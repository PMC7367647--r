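## Genome coordinate frame: builds, intervals, and the 200 kb bin grid.
## Conventions (used everywhere in the package): 0-based, half-open
## intervals [start, end); global bin ordinals are 1-based and contiguous
## in chromosome order.

#' hg19 chromosome lengths
#'
#' Canonical hg19 (GRCh37) chromosome sizes in bp, packaged as data so no
#' network access is ever needed.
#'
#' @param include_sex include chrX and chrY (default `FALSE`; screening is
#'   autosome-based because mixed-sex control panels would create
#'   sex-linked artifacts).
#' @return named integer-ish numeric vector of chromosome lengths.
#' @export
hg19_chrom_sizes <- function(include_sex = FALSE) {
  sizes <- c(
    chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566)
  if (include_sex) sizes <- c(sizes, chrX = 155270560, chrY = 59373566)
  sizes
}

#' Construct a genome build
#'
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param name build identifier.
#' @return object of class `genome_build`.
#' @export
genome_build <- function(chromosomes, name = "custom") {
  if (length(chromosomes) == 0)
    stop("genome build must contain at least one chromosome")
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop("chromosome names must be present and unique")
  if (any(chromosomes <= 0)) stop("chromosome lengths must be > 0")
  structure(list(name = name, chromosomes = chromosomes),
            class = "genome_build")
}

#' The hg19 genome build
#'
#' @inheritParams hg19_chrom_sizes
#' @return `genome_build` with chr1..chr22 (+X/Y if requested).
#' @export
hg19_build <- function(include_sex = FALSE) {
  genome_build(hg19_chrom_sizes(include_sex), name = "hg19")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build> %s: %d chromosomes, %.2f Gb\n", x$name,
              length(x$chromosomes), sum(x$chromosomes) / 1e9))
  invisible(x)
}

#' Construct a genomic interval
#'
#' Coordinates are 0-based, half-open: `[start, end)`.
#'
#' @param chrom chromosome name.
#' @param start,end interval bounds in bp, `0 <= start < end`.
#' @return one-row data.frame with columns chrom/start/end.
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start < 0) || any(start >= end))
    stop("invalid interval: need 0 <= start < end")
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}

#' Tile a genome into fixed-width bins
#'
#' Bins tile each chromosome left to right without overlap; every bin has
#' width `bin_size` except possibly the last per chromosome, which is
#' truncated at the chromosome end.
#'
#' @param build a `genome_build`.
#' @param bin_size bin width in bp (default 200 kb, the resolution at which
#'   low-pass cfDNA coverage is profiled).
#' @return object of class `bin_grid` with a `bins` data.frame
#'   (chrom/start/end, one row per bin in genome order).
#' @export
make_bin_grid <- function(build, bin_size = 2e5) {
  if (!inherits(build, "genome_build")) stop("build must be a genome_build")
  if (length(build$chromosomes) == 0) stop("empty genome build")
  if (bin_size <= 0) stop("bin_size must be > 0")
  pieces <- lapply(names(build$chromosomes), function(ch) {
    len <- build$chromosomes[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len), stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  structure(list(build = build, bin_size = bin_size, bins = bins,
                 n_bins = nrow(bins)),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %s, %d bins of %s bp across %d chromosomes\n",
              x$build$name, x$n_bins, format(x$bin_size, big.mark = ","),
              length(x$build$chromosomes)))
  invisible(x)
}

#' @export
length.bin_grid <- function(x) x$n_bins

## Grid identity used by every stage that combines objects: two grids are
## compatible when build name, bin size and the chromosome tiling agree.
same_grid <- function(a, b) {
  identical(a$build$name, b$build$name) &&
    identical(a$bin_size, b$bin_size) &&
    identical(a$build$chromosomes, b$build$chromosomes)
}

check_same_grid <- function(a, b, what = "objects") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch: %s were made on different bin grids", what))
  invisible(TRUE)
}

#' Bins overlapping an interval (midpoint rule)
#'
#' A bin belongs to an interval when its midpoint lies in `[start, end)`.
#' The midpoint rule guarantees a bin can never be counted by two
#' non-overlapping intervals even when interval boundaries are not
#' bin-aligned.
#'
#' @param grid a `bin_grid`.
#' @param interval one-row data.frame (chrom/start/end) as returned by
#'   [genomic_interval()].
#' @return integer vector of global bin ordinals (possibly empty).
#' @export
bins_in_interval <- function(grid, interval) {
  stopifnot(inherits(grid, "bin_grid"))
  ch <- as.character(interval$chrom[1])
  if (!ch %in% names(grid$build$chromosomes))
    stop(sprintf("unknown chromosome '%s' for grid build %s", ch,
                 grid$build$name))
  b <- grid$bins
  mid <- (b$start + b$end) / 2
  which(b$chrom == ch & mid >= interval$start[1] & mid < interval$end[1])
}
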