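## Panel scoring and the screening call.
##
## Segment-level statistic: with each bin Z approximately N(0,1) under the
## null, the mean of n bin Z-scores has standard deviation 1/sqrt(n), so
## the Stouffer-aggregated z = seg_mean * sqrt(n_bins) is again a proper
## standard-normal statistic; the single cutoff 2.702 is applied to it for
## every segment regardless of length.

#' Aggregate bin Z-scores over an interval
#'
#' `seg_mean` is the mean bin Z over the interval's unmasked bins (midpoint
#' membership rule) and `z = seg_mean * sqrt(n_bins)` (Stouffer
#' aggregation).
#'
#' @param nprofile a `normalized_profile`.
#' @param interval one-row chrom/start/end data.frame.
#' @return list of class `segment_z`: `n_bins`, `seg_mean`, `z`,
#'   `callable`. When the interval covers no unmasked bin the result is an
#'   explicit uncallable sentinel (`callable = FALSE`, `z = NA`), never a
#'   silent zero.
#' @export
segment_z <- function(nprofile, interval) {
  stopifnot(inherits(nprofile, "normalized_profile"))
  ix <- bins_in_interval(nprofile$grid, interval)
  ix <- ix[nprofile$mask[ix]]
  if (length(ix) == 0) {
    return(structure(list(n_bins = 0L, seg_mean = NA_real_, z = NA_real_,
                          callable = FALSE), class = "segment_z"))
  }
  m <- mean(nprofile$z_per_bin[ix])
  structure(list(n_bins = length(ix), seg_mean = m,
                 z = m * sqrt(length(ix)), callable = TRUE),
            class = "segment_z")
}

#' Score a sample against a segment panel
#'
#' Computes the aggregated Z for every panel segment and calls each segment
#' altered at the cutoff. In `absolute` mode (default, matching the
#' two-sided convention `z >= 2.702` or `z <= -2.702`) a segment is altered
#' when `|z| >= cutoff`; in `matched` mode a gain segment requires
#' `z >= cutoff` and a loss segment `z <= -cutoff`. The cutoff comparison
#' is inclusive. Segments with no callable bins are excluded from the count
#' and listed in `uncallable`.
#'
#' @param nprofile a `normalized_profile`.
#' @param panel a `cin_panel` (default: the packaged 29-segment panel).
#' @param cutoff Z cutoff (default 2.702, the ROC-optimized value).
#' @param direction_mode `"absolute"` or `"matched"`.
#' @return object of class `panel_score`: per-segment table (`name, chrom,
#'   loc.start, loc.end, direction, n_bins, seg_mean, z, altered`),
#'   `altered_count`, `category` (one of `">=3", "2", "1", "0"`),
#'   `uncallable`.
#' @export
score_panel <- function(nprofile, panel = load_panel(), cutoff = 2.702,
                        direction_mode = c("absolute", "matched")) {
  direction_mode <- match.arg(direction_mode)
  stopifnot(inherits(nprofile, "normalized_profile"), nrow(panel) >= 0)
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    sz <- segment_z(nprofile, panel_interval(panel, i))
    data.frame(name = panel$name[i], chrom = panel$chrom[i],
               loc.start = panel$`loc.start`[i], loc.end = panel$`loc.end`[i],
               direction = panel$direction[i], n_bins = sz$n_bins,
               seg_mean = sz$seg_mean, z = sz$z, callable = sz$callable,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), chrom = character(), loc.start = numeric(),
               loc.end = numeric(), direction = character(),
               n_bins = integer(), seg_mean = numeric(), z = numeric(),
               callable = logical())
  tab$altered <- FALSE
  cal <- tab$callable
  if (any(cal)) {
    tab$altered[cal] <- if (direction_mode == "absolute") {
      abs(tab$z[cal]) >= cutoff
    } else {
      ifelse(tab$direction[cal] == "gain", tab$z[cal] >= cutoff,
             tab$z[cal] <= -cutoff)
    }
  }
  count <- sum(tab$altered)
  category <- if (count >= 3) ">=3" else as.character(count)
  structure(list(sample_id = nprofile$sample_id, table = tab,
                 altered_count = count, category = category,
                 cutoff = cutoff, direction_mode = direction_mode,
                 uncallable = tab$name[!tab$callable]),
            class = "panel_score")
}

#' @export
print.panel_score <- function(x, ...) {
  cat(sprintf("<panel_score> %s: %d/%d segments altered (category %s, cutoff %.3f, %s mode)\n",
              x$sample_id, x$altered_count, nrow(x$table), x$category,
              x$cutoff, x$direction_mode))
  invisible(x)
}

#' Positive/negative screening call
#'
#' A sample screens positive when at least one panel segment is altered;
#' negative when none is.
#'
#' @param score a `panel_score`.
#' @return list of class `screening_call`: `sample_id`, `positive`,
#'   `altered_count`, `category`, `cutoff_used`.
#' @export
screen <- function(score) {
  stopifnot(inherits(score, "panel_score"))
  structure(list(sample_id = score$sample_id,
                 positive = score$altered_count >= 1,
                 altered_count = score$altered_count,
                 category = score$category, cutoff_used = score$cutoff),
            class = "screening_call")
}

#' @export
print.screening_call <- function(x, ...) {
  cat(sprintf("<screening_call> %s: %s (%d altered segments, cutoff %.3f)\n",
              x$sample_id, if (x$positive) "POSITIVE" else "negative",
              x$altered_count, x$cutoff_used))
  invisible(x)
}

#' Track panel-segment Z across longitudinal samples
#'
#' For serially collected samples of one patient (e.g. pre-surgery and
#' follow-ups), returns each segment's Z trajectory in time order with
#' per-timepoint altered flags and screening calls; no interpolation
#' between timepoints.
#'
#' @param scores time-ordered list of `panel_score`s computed on the same
#'   panel with the same cutoff.
#' @param timepoints optional labels (default `1..n`).
#' @return data.frame with columns `timepoint, sample_id, segment, z,
#'   altered, sample_positive`.
#' @export
track_longitudinal <- function(scores, timepoints = seq_along(scores)) {
  stopifnot(length(scores) >= 1, length(timepoints) == length(scores))
  ref_names <- scores[[1]]$table$name
  for (s in scores) {
    stopifnot(inherits(s, "panel_score"))
    if (!identical(s$table$name, ref_names))
      stop("track_longitudinal: scores come from different panels")
  }
  do.call(rbind, lapply(seq_along(scores), function(k) {
    s <- scores[[k]]
    data.frame(timepoint = timepoints[k], sample_id = s$sample_id,
               segment = s$table$name, z = s$table$z,
               altered = s$table$altered,
               sample_positive = s$altered_count >= 1,
               stringsAsFactors = FALSE)
  }))
}

#' Write a panel score as TSV (+ screening line)
#'
#' @param score a `panel_score`.
#' @param path TSV path for the per-segment table; a companion
#'   `<path>.screen.json` holds the screening call.
#' @return `path`, invisibly.
#' @export
write_score <- function(score, path) {
  write.table(score$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  call <- screen(score)
  jsonlite::write_json(list(sample_id = call$sample_id,
                            positive = call$positive,
                            altered_count = call$altered_count,
                            category = call$category,
                            cutoff = call$cutoff_used),
                       paste0(path, ".screen.json"), auto_unbox = TRUE)
  invisible(path)
}
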