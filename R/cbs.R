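## Circular binary segmentation (CBS) of per-chromosome Z-score vectors.
##
## Candidate change-points are the endpoints of the circular arc maximizing
## the two-sample t statistic between arc and complement; the split is
## accepted when its permutation p-value falls below alpha, and accepted
## parts are segmented recursively. Implemented from scratch with the
## exhaustive arc scan and permutation loop in C++.

#' CBS parameters
#'
#' @param alpha significance level for accepting a split (default 0.05).
#' @param n_perm permutations per split test (default 10000).
#' @param min_width minimum bins per segment part (default 2).
#' @param seed RNG seed recorded in results; `NULL` leaves the RNG state
#'   untouched.
#' @param max_depth recursion cap (default 20).
#' @param early_stop stop a permutation run as soon as the split can no
#'   longer reach `alpha` (default `TRUE`; decisions are unchanged, only
#'   non-significant p-values become sequential estimates).
#' @return list of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 0.05, n_perm = 10000, min_width = 2,
                       seed = NULL, max_depth = 20, early_stop = TRUE) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100, min_width >= 2,
            max_depth >= 1)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), seed = seed,
                 max_depth = as.integer(max_depth),
                 early_stop = isTRUE(early_stop)),
            class = "cbs_params")
}

#' Maximal circular t statistic
#'
#' Scans every circular arc `(i, j]` (0-based cut positions, arc =
#' positions `i+1..j`) with both arc and complement at least `min_width`
#' long, and returns the arc maximizing the absolute pooled two-sample t
#' statistic between arc and complement. Ties are broken by the smallest
#' `i`, then smallest `j`.
#'
#' @param values numeric vector (one chromosome of bin Z-scores).
#' @param min_width minimum points per part (default 2).
#' @return list `(i, j, t)`; all `NA` when the vector is too short for any
#'   split ("no split possible").
#' @export
max_circular_t <- function(values, min_width = 2) {
  stopifnot(is.numeric(values), min_width >= 2)
  res <- cpp_max_circular_t(as.numeric(values), as.integer(min_width))
  list(i = res$i, j = res$j, t = res$t)
}

#' Permutation p-value for a CBS split
#'
#' Permutes the vector and recomputes the maximal |t| each time;
#' `p = (1 + #\{max |t*| >= observed\}) / (n_perm + 1)`. Deterministic for
#' a fixed RNG seed (`set.seed()` before the call).
#'
#' @param values the vector that produced `observed_t`.
#' @param observed_t statistic from [max_circular_t()] on `values`.
#' @param n_perm number of permutations (default 1000).
#' @param min_width as in [max_circular_t()].
#' @param early_stop_alpha if positive, permutation halts once the p-value
#'   is guaranteed to be at least this level (default 0 = run all
#'   permutations).
#' @return the p-value.
#' @export
permutation_p <- function(values, observed_t, n_perm = 1000, min_width = 2,
                          early_stop_alpha = 0) {
  stopifnot(n_perm >= 1)
  res <- cpp_permutation_p(as.numeric(values), abs(observed_t),
                           as.integer(n_perm), as.integer(min_width),
                           early_stop_alpha)
  res$p
}

## One recursive CBS pass over a numeric vector. Returns a data.frame of
## (start_idx, end_idx, logP) with 1-based inclusive indices into `values`.
cbs_core <- function(values, params, depth = 0) {
  n <- length(values)
  leaf <- function(logP = 0) data.frame(start_idx = 1L, end_idx = n,
                                        logP = logP)
  if (n < 2 * params$min_width || depth >= params$max_depth) return(leaf())
  best <- cpp_max_circular_t(values, params$min_width)
  if (is.na(best$t) || best$t == 0) return(leaf())
  p <- cpp_permutation_p(values, abs(best$t), params$n_perm,
                         params$min_width,
                         if (params$early_stop) params$alpha else 0)$p
  if (p >= params$alpha) return(leaf())
  logP <- max(log10(p), log10(1 / (params$n_perm + 1)))
  i <- best$i; j <- best$j
  cuts <- unique(c(i, j))
  cuts <- cuts[cuts > 0 & cuts < n]
  if (length(cuts) == 0) return(leaf())
  bounds <- c(0, sort(cuts), n)
  parts <- list()
  for (k in seq_len(length(bounds) - 1)) {
    lo <- bounds[k] + 1L; hi <- bounds[k + 1]
    sub <- cbs_core(values[lo:hi], params, depth + 1)
    sub$start_idx <- sub$start_idx + lo - 1L
    sub$end_idx <- sub$end_idx + lo - 1L
    sub$logP[sub$logP == 0] <- logP  # children inherit the accepting split's p
    parts[[k]] <- sub
  }
  out <- do.call(rbind, parts)
  ## never emit adjacent segments with identical post-hoc means
  merge_equal_mean_runs(out, values)
}

merge_equal_mean_runs <- function(segs, values) {
  if (nrow(segs) <= 1) return(segs)
  means <- mapply(function(a, b) mean(values[a:b]),
                  segs$start_idx, segs$end_idx)
  keep <- c(TRUE, abs(diff(means)) > 1e-12)
  if (all(keep)) return(segs)
  grp <- cumsum(keep)
  merged <- do.call(rbind, lapply(split(seq_len(nrow(segs)), grp), function(ix) {
    data.frame(start_idx = segs$start_idx[ix[1]],
               end_idx = segs$end_idx[ix[length(ix)]],
               logP = min(segs$logP[ix]))
  }))
  rownames(merged) <- NULL
  merged
}

#' Segment one chromosome of Z-scores
#'
#' Recursive circular binary segmentation: at each level the maximal-t arc
#' is tested by permutation and, if `p < alpha`, its (at most two) cut
#' points split the vector; parts are segmented recursively until no
#' significant split remains or segments reach `min_width`.
#'
#' @param values finite numeric vector of bin Z-scores for one chromosome.
#' @param params a [cbs_params()] object.
#' @return data.frame with one row per segment: `start_idx`, `end_idx`
#'   (1-based inclusive bin indices into `values`), `n_bins`, `seg_mean`,
#'   `z_segment` (= seg_mean * sqrt(n_bins)), `logP` (log10 permutation p
#'   of the accepting split, 0 for an unsplit root, floored at
#'   `log10(1/(n_perm+1))`).
#' @export
cbs_segment <- function(values, params = cbs_params()) {
  stopifnot(is.numeric(values), all(is.finite(values)),
            inherits(params, "cbs_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  segs <- cbs_core(values, params)
  segs$n_bins <- segs$end_idx - segs$start_idx + 1L
  segs$seg_mean <- mapply(function(a, b) mean(values[a:b]),
                          segs$start_idx, segs$end_idx)
  segs$z_segment <- segs$seg_mean * sqrt(segs$n_bins)
  segs[, c("start_idx", "end_idx", "n_bins", "seg_mean", "z_segment", "logP")]
}

#' Segment a normalized genome profile
#'
#' Runs [cbs_segment()] chromosome by chromosome on the unmasked bins of a
#' normalized profile. Masked bins are skipped (not interpolated); segment
#' bp coordinates snap to the outer boundaries of their terminal bins.
#'
#' @param nprofile a `normalized_profile`.
#' @param params a [cbs_params()]; its `seed` (if any) is set once before
#'   the first chromosome.
#' @return object of class `segmentation_result`: `sample_id`, `params`,
#'   and `segments`, a data.frame with columns `chrom, loc.start, loc.end,
#'   n_bins, seg_mean, z_segment, logP`.
#' @export
segment_genome <- function(nprofile, params = cbs_params()) {
  stopifnot(inherits(nprofile, "normalized_profile"))
  if (!is.null(params$seed)) set.seed(params$seed)
  params_noseed <- params; params_noseed$seed <- NULL
  bins <- nprofile$grid$bins
  out <- list()
  for (ch in names(nprofile$grid$build$chromosomes)) {
    idx <- which(bins$chrom == ch & nprofile$mask)
    if (length(idx) == 0) next
    z <- nprofile$z_per_bin[idx]
    segs <- cbs_segment(z, params_noseed)
    segs$chrom <- ch
    segs$loc.start <- bins$start[idx[segs$start_idx]]
    segs$loc.end <- bins$end[idx[segs$end_idx]]
    out[[ch]] <- segs[, c("chrom", "loc.start", "loc.end", "n_bins",
                          "seg_mean", "z_segment", "logP")]
  }
  segments <- do.call(rbind, out)
  rownames(segments) <- NULL
  structure(list(sample_id = nprofile$sample_id, params = params,
                 segments = segments),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s: %d segments on %d chromosomes\n",
              x$sample_id, nrow(x$segments), length(unique(x$segments$chrom))))
  invisible(x)
}

#' Segment table in SEG layout
#'
#' @param result a `segmentation_result`.
#' @return data.frame with columns `sample, chrom, loc.start, loc.end,
#'   num.bins, seg.mean, z, logP`.
#' @export
segment_table <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  s <- result$segments
  data.frame(sample = result$sample_id, chrom = s$chrom,
             loc.start = s$loc.start, loc.end = s$loc.end,
             num.bins = s$n_bins, seg.mean = s$seg_mean, z = s$z_segment,
             logP = s$logP, stringsAsFactors = FALSE)
}

#' Write / read a SEG-style segment table
#'
#' @param result a `segmentation_result`.
#' @param path TSV path.
#' @return `write_seg`: `path` invisibly; `read_seg`: the table as a
#'   data.frame.
#' @export
write_seg <- function(result, path) {
  tab <- segment_table(result)
  tab$loc.start <- sprintf("%.0f", tab$loc.start)
  tab$loc.end <- sprintf("%.0f", tab$loc.end)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
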