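## Reference-panel construction and the per-bin Z-score transform:
##   z_b = (coverage_b - mean_b(controls)) / sd_b(controls)
## with coverage in relative units so sequencing depth cancels between a
## sample and the controls.

#' Build a control reference panel
#'
#' Computes per-bin mean and sample standard deviation (n-1 denominator) of
#' relative coverage across healthy-control profiles. Bins whose control
#' standard deviation is zero, or whose control mean falls below 10% of the
#' genome-wide median bin mean (centromeric/telomeric dropouts that would
#' otherwise yield infinite Z), are masked and excluded from all downstream
#' statistics.
#'
#' @param controls list of `coverage_profile`s (>= 2), all on one grid.
#' @return object of class `reference_panel` with fields `grid`,
#'   `n_controls`, `mean_per_bin`, `stdev_per_bin`, `mask` (TRUE = usable).
#' @export
build_reference <- function(controls) {
  if (length(controls) < 2)
    stop("need at least 2 control profiles to build a reference panel")
  grid <- controls[[1]]$grid
  for (p in controls) check_same_grid(grid, p$grid, "control profiles")
  mat <- vapply(controls, relative_coverage, numeric(grid$n_bins))
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, sd)
  med <- median(mu)
  mask <- sdv > 0 & mu >= 0.1 * med
  if (!any(mask))
    warning("reference panel degenerate: every bin is masked ",
            "(controls identical or empty)")
  n_masked <- sum(!mask)
  if (n_masked > 0)
    message(sprintf("build_reference: masked %d/%d bins (sd==0: %d, low mean: %d)",
                    n_masked, grid$n_bins, sum(sdv == 0),
                    sum(sdv > 0 & mu < 0.1 * med)))
  structure(list(grid = grid, n_controls = length(controls),
                 mean_per_bin = mu, stdev_per_bin = sdv, mask = mask),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d controls, %d/%d usable bins on %s\n",
              x$n_controls, sum(x$mask), x$grid$n_bins, x$grid$build$name))
  invisible(x)
}

#' Normalize a sample against a reference panel
#'
#' Per-bin Z-score: `z = (relative_coverage - mean_controls) / sd_controls`
#' on usable bins; masked bins carry `NA`.
#'
#' @param profile a `coverage_profile`.
#' @param reference a `reference_panel` built on the same grid.
#' @return object of class `normalized_profile` with `z_per_bin` (NA on
#'   masked bins) and the panel's `mask`.
#' @export
normalize <- function(profile, reference) {
  stopifnot(inherits(profile, "coverage_profile"),
            inherits(reference, "reference_panel"))
  check_same_grid(profile$grid, reference$grid, "profile and reference")
  rc <- relative_coverage(profile)
  z <- (rc - reference$mean_per_bin) / reference$stdev_per_bin
  z[!reference$mask] <- NA_real_
  if (any(!is.finite(z[reference$mask])))
    stop("non-finite z-scores on unmasked bins; reference panel is invalid")
  structure(list(sample_id = profile$sample_id, grid = profile$grid,
                 z_per_bin = z, mask = reference$mask),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  zu <- x$z_per_bin[x$mask]
  cat(sprintf("<normalized_profile> %s: %d usable bins, mean z %.3f, sd %.3f\n",
              x$sample_id, sum(x$mask), mean(zu), sd(zu)))
  invisible(x)
}

#' Serialize / load a reference panel
#'
#' TSV of chrom/start/end/mean/stdev/mask preceded by a single `#`-prefixed
#' JSON header (build, bin size, bin count, number of controls, coverage
#' unit) so a loaded panel can be validated against a grid.
#'
#' @param reference a `reference_panel`.
#' @param path file path.
#' @return `write_reference`: `path` invisibly; `read_reference`: a
#'   `reference_panel`.
#' @export
write_reference <- function(reference, path) {
  hdr <- jsonlite::toJSON(list(
    build = reference$grid$build$name, bin_size = reference$grid$bin_size,
    n_bins = reference$grid$n_bins, n_controls = reference$n_controls,
    unit = "relative_coverage"), auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  df <- cbind(fmt_bins(reference$grid$bins), mean = reference$mean_per_bin,
              stdev = reference$stdev_per_bin,
              mask = as.integer(reference$mask))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @param grid the `bin_grid` the panel must match.
#' @export
read_reference <- function(path, grid) {
  lines <- readLines(path, n = 1)
  if (!startsWith(lines[1], "#"))
    stop("reference panel file lacks its JSON header line")
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  if (!identical(hdr$build, grid$build$name) ||
      hdr$bin_size != grid$bin_size || hdr$n_bins != grid$n_bins)
    stop("reference panel was built on a different grid (",
         hdr$build, ", ", hdr$bin_size, " bp, ", hdr$n_bins, " bins)")
  df <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  if (nrow(df) != grid$n_bins) stop("reference panel row count mismatch")
  structure(list(grid = grid, n_controls = hdr$n_controls,
                 mean_per_bin = df$mean, stdev_per_bin = df$stdev,
                 mask = df$mask == 1),
            class = "reference_panel")
}
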