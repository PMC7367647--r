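## Cohort-level evaluation: sensitivity/specificity, ROC/AUC with cutoff
## optimization, exact Fisher 2x2 association tests, covariate
## cross-tabulations, and combined-marker positivity.

#' Assemble a labeled cohort
#'
#' @param sample_id unique sample labels.
#' @param label `"cancer"` / `"control"` per sample.
#' @param positive logical screening outcome per sample.
#' @param altered_count optional altered-segment counts (for category
#'   cross-tabulation).
#' @param statistic optional continuous per-sample statistic for ROC (the
#'   conventional choice is the maximum absolute panel-segment Z).
#' @return data.frame of class `labeled_cohort`.
#' @export
labeled_cohort <- function(sample_id, label, positive,
                           altered_count = NULL, statistic = NULL) {
  stopifnot(!anyDuplicated(sample_id), all(label %in% c("cancer", "control")),
            length(label) == length(sample_id),
            length(positive) == length(sample_id))
  df <- data.frame(sample_id = as.character(sample_id),
                   label = as.character(label),
                   positive = as.logical(positive),
                   stringsAsFactors = FALSE)
  if (!is.null(altered_count)) df$altered_count <- altered_count
  if (!is.null(statistic)) df$statistic <- statistic
  class(df) <- c("labeled_cohort", "data.frame")
  df
}

#' Expand per-category counts into a cohort block
#'
#' Utility for published-table arithmetic: given counts of samples with
#' `>=3`, `2`, `1` and `0` altered segments, builds per-sample rows with a
#' representative altered count per category so the positivity logic can be
#' applied (`positive` iff altered count >= 1).
#'
#' @param ge3,two,one,zero sample counts per category.
#' @param label `"cancer"` or `"control"` for the whole block.
#' @param prefix sample-id prefix.
#' @return a `labeled_cohort`.
#' @export
cohort_from_category_counts <- function(ge3, two, one, zero, label,
                                        prefix = label) {
  counts <- rep(c(3L, 2L, 1L, 0L), times = c(ge3, two, one, zero))
  n <- length(counts)
  labeled_cohort(sprintf("%s_%03d", prefix, seq_len(n)),
                 rep(label, n), positive = counts >= 1,
                 altered_count = counts)
}

#' Sensitivity and specificity of a screening cohort
#'
#' @param cohort a `labeled_cohort` containing both labels.
#' @return list: `sensitivity`, `specificity` (fractions), the exact
#'   integer ratios (`tp`, `fn`, `tn`, `fp`, `n_cancer`, `n_control`), and
#'   percentage renderings.
#' @export
confusion_rates <- function(cohort) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  if (length(unique(cohort$label)) < 2)
    stop("confusion_rates needs both cancer and control samples")
  ca <- cohort$label == "cancer"
  tp <- sum(cohort$positive[ca]); fn <- sum(!cohort$positive[ca])
  tn <- sum(!cohort$positive[!ca]); fp <- sum(cohort$positive[!ca])
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fn = fn, tn = tn, fp = fp,
       n_cancer = tp + fn, n_control = tn + fp,
       sensitivity_pct = 100 * tp / (tp + fn),
       specificity_pct = 100 * tn / (tn + fp))
}

#' ROC curve and AUC for a continuous screening statistic
#'
#' Sweeps cutoffs over the observed statistic values (a sample is called
#' positive when `statistic >= cutoff`; tied values are grouped), and
#' computes the AUC by the trapezoid rule — which equals the
#' pairwise-concordance (Mann-Whitney) probability, ties counted 1/2.
#'
#' @param cohort a `labeled_cohort` with a `statistic` column.
#' @return list of class `roc_curve`: `points` (data.frame `cutoff, tpr,
#'   fpr` ordered by decreasing cutoff) and `auc`.
#' @export
roc_auc <- function(cohort) {
  stopifnot(inherits(cohort, "labeled_cohort"),
            "statistic" %in% names(cohort))
  if (length(unique(cohort$label)) < 2)
    stop("roc_auc needs both cancer and control samples")
  stat <- cohort$statistic
  truth <- cohort$label == "cancer"
  if (length(unique(stat)) == 1)
    warning("constant statistic: ROC is degenerate, AUC = 0.5")
  cutoffs <- c(sort(unique(stat), decreasing = TRUE), Inf)
  cutoffs <- sort(unique(cutoffs), decreasing = TRUE)
  pts <- do.call(rbind, lapply(cutoffs, function(ct) {
    pos <- stat >= ct
    data.frame(cutoff = ct, tpr = sum(pos & truth) / sum(truth),
               fpr = sum(pos & !truth) / sum(!truth))
  }))
  pts <- pts[order(-pts$cutoff), ]
  rownames(pts) <- NULL
  ## trapezoid over the (fpr, tpr) path from (0,0) to (1,1)
  fpr <- c(pts$fpr, 1); tpr <- c(pts$tpr, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d cutoffs, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Maximizes `J = TPR - FPR`; ties resolve to the smaller cutoff (more
#' sensitive operating point at equal J).
#'
#' @param curve a `roc_curve`.
#' @return the cutoff value.
#' @export
optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"), nrow(curve$points) >= 2)
  pts <- curve$points
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  min(pts$cutoff[best])
}

#' Exact Fisher test of a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric point probabilities no
#' larger than the observed table's; odds ratio by conditional maximum
#' likelihood with an exact 95% confidence interval (tables with a zero
#' cell yield one-sided open intervals).
#'
#' @param table 2x2 matrix of non-negative integer counts; both margins
#'   must be positive.
#' @return list of class `fisher_result`: `table`, `p_two_sided`,
#'   `or_cmle`, `ci95` (length-2, possibly 0 or Inf at the ends).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("table must hold non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("fisher_exact_2x2: empty margin")
  ft <- fisher.test(table, conf.level = 0.95)
  structure(list(table = table, p_two_sided = ft$p.value,
                 or_cmle = unname(ft$estimate),
                 ci95 = as.numeric(ft$conf.int)),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("<fisher_result> OR = %.3f [%.3f, %.3f], p = %.4g\n",
              x$or_cmle, x$ci95[1], x$ci95[2], x$p_two_sided))
  invisible(x)
}

#' Cross-tabulate screening categories by a covariate
#'
#' Builds table rows in the published layout: for each covariate level the
#' counts of samples with `>=3`, `2`, `1`, `0` altered segments and the
#' percent positive. Missing covariate values are tabulated as an `"NA"`
#' row and excluded from any test. When `test_level` is given, a collapsed
#' 2x2 exact Fisher test of positivity (that level vs all other non-NA
#' levels) is attached.
#'
#' @param cohort a `labeled_cohort` with an `altered_count` column.
#' @param covariate vector of covariate values (may contain `NA`), same
#'   length and order as the cohort.
#' @param test_level optional covariate level to compare against the rest.
#' @return list of class `crosstab`: `rows` (data.frame `level, ge3, two,
#'   one, zero, n, pct_positive`) and `fisher` (a `fisher_result` or
#'   `NULL`).
#' @export
crosstab_by_group <- function(cohort, covariate, test_level = NULL) {
  stopifnot(inherits(cohort, "labeled_cohort"),
            "altered_count" %in% names(cohort),
            length(covariate) == nrow(cohort))
  lev <- as.character(covariate)
  lev[is.na(covariate)] <- "NA"
  levels_order <- c(setdiff(unique(lev), "NA"),
                    if ("NA" %in% lev) "NA")
  rows <- do.call(rbind, lapply(levels_order, function(lv) {
    ac <- cohort$altered_count[lev == lv]
    data.frame(level = lv, ge3 = sum(ac >= 3), two = sum(ac == 2),
               one = sum(ac == 1), zero = sum(ac == 0), n = length(ac),
               pct_positive = 100 * mean(ac >= 1), stringsAsFactors = FALSE)
  }))
  fisher <- NULL
  if (!is.null(test_level)) {
    ok <- lev != "NA"
    if (!test_level %in% lev[ok]) stop("test_level not present: ", test_level)
    in_lv <- lev[ok] == test_level
    pos <- cohort$altered_count[ok] >= 1
    tab <- matrix(c(sum(in_lv & pos), sum(in_lv & !pos),
                    sum(!in_lv & pos), sum(!in_lv & !pos)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c(test_level, "other"),
                                  c("positive", "negative")))
    fisher <- fisher_exact_2x2(tab)
  }
  structure(list(rows = rows, fisher = fisher), class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  print.data.frame(x$rows)
  if (!is.null(x$fisher)) print(x$fisher)
  invisible(x)
}

#' Combined positivity of two screening tests
#'
#' A sample is combined-positive when either test is positive (logical OR),
#' the rule under which adding the cfDNA screen to a serum marker raises
#' detection sensitivity.
#'
#' @param call_a,call_b logical vectors (or scalars) of per-sample calls.
#' @return logical vector of combined calls.
#' @export
combine_tests <- function(call_a, call_b) {
  stopifnot(length(call_a) == length(call_b))
  as.logical(call_a) | as.logical(call_b)
}
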