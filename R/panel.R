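## The screening panel: recurrently altered chromosomal segments in the
## circulating liver-cancer genome. The packaged default holds the 29
## segments (arm-level gains/losses plus focal TERT and CCND1
## amplifications) against which every sample is screened.

panel_columns <- c("name", "chrom", "loc.start", "loc.end", "direction",
                   "key_genes", "frequency", "seg_mean", "logP")

#' Load a screening panel of chromosomal segments
#'
#' A panel is a TSV with columns `name, chrom, loc.start, loc.end,
#' direction, key_genes, frequency, seg_mean, logP` (0-based half-open
#' coordinates). `direction` is `gain` or `loss` and must agree with the
#' `+`/`-` suffix of the segment name. The packaged default
#' (`source = "default"`) is the 29-segment liver-cancer panel; `frequency`
#' is the fraction of discovery-cohort cancers carrying the alteration,
#' `seg_mean` the discovery segment mean, and `logP` the discovery log10
#' p-value (floored at -100).
#'
#' @param source `"default"` for the packaged panel, or a path to a panel
#'   TSV. An empty file (header only) yields an empty panel.
#' @return data.frame of class `cin_panel`, one row per segment.
#' @export
load_panel <- function(source = "default") {
  path <- if (identical(source, "default")) {
    system.file("extdata", "liver_cin_panel.tsv", package = "cinscreen",
                mustWork = TRUE)
  } else source
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  missing_cols <- setdiff(panel_columns, names(df))
  if (length(missing_cols) > 0)
    stop("panel file missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(df) > 0) {
    for (col in c("loc.start", "loc.end", "frequency", "seg_mean", "logP")) {
      val <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(val) & nzchar(df[[col]]))
      if (length(bad) > 0)
        stop(sprintf("malformed panel row at line %d: non-numeric '%s'",
                     bad[1] + 1L, col))
      df[[col]] <- val
    }
    bad <- which(!(df$loc.start >= 0 & df$loc.start < df$loc.end))
    if (length(bad) > 0)
      stop(sprintf("malformed panel row at line %d: need 0 <= start < end",
                   bad[1] + 1L))
    bad <- which(!df$direction %in% c("gain", "loss"))
    if (length(bad) > 0)
      stop(sprintf("malformed panel row at line %d: direction must be gain/loss",
                   bad[1] + 1L))
    suffix <- ifelse(grepl("\\+$", df$name), "gain",
                     ifelse(grepl("-$", df$name), "loss", NA))
    bad <- which(!is.na(suffix) & suffix != df$direction)
    if (length(bad) > 0)
      stop(sprintf("malformed panel row at line %d: name suffix contradicts direction",
                   bad[1] + 1L))
    if (anyDuplicated(df$name))
      stop("panel segment names must be unique")
    bad <- which(df$frequency < 0 | df$frequency > 1)
    if (length(bad) > 0)
      stop(sprintf("malformed panel row at line %d: frequency outside [0,1]",
                   bad[1] + 1L))
  }
  class(df) <- c("cin_panel", "data.frame")
  df
}

#' @export
print.cin_panel <- function(x, ...) {
  cat(sprintf("<cin_panel> %d segments (%d gains, %d losses)\n", nrow(x),
              sum(x$direction == "gain"), sum(x$direction == "loss")))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}

#' Export a panel as BED6
#'
#' Writes segment name in column 4, 0 in column 5, and the direction as
#' `+` (gain) / `-` (loss) in column 6.
#'
#' @param panel a `cin_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  bed <- data.frame(panel$chrom, sprintf("%.0f", panel$`loc.start`),
                    sprintf("%.0f", panel$`loc.end`), panel$name,
                    0L, ifelse(panel$direction == "gain", "+", "-"))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

panel_interval <- function(panel, i) {
  genomic_interval(panel$chrom[i], panel$`loc.start`[i], panel$`loc.end`[i])
}
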