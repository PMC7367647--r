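## Seeded cfDNA simulator with known copy-number truth.
##
## Coverage model: a tumor fraction tf mixes tumor-derived fragments into a
## diploid background, so a region at tumor copy number c has expected
## relative coverage proportional to 1 + tf * (c/2 - 1). Counts are drawn
## negative-binomially (variance = mu + mu^2/dispersion) because real
## cfDNA bin counts are overdispersed relative to Poisson; dispersion = Inf
## selects the exact multinomial limit used for oracle arithmetic.

#' Simulation parameters
#'
#' @param grid a `bin_grid`.
#' @param depth total fragments per sample (default 1e7, the calibrated
#'   sequencing depth floor).
#' @param tumor_fraction fraction of plasma DNA of tumor origin, in
#'   `[0, 1]` (default 0 = healthy control).
#' @param events data.frame of non-overlapping copy-number events with
#'   columns `chrom, start, end, copy_number` (2 = neutral); `NULL` for
#'   none.
#' @param dispersion negative-binomial dispersion (default 50); `Inf`
#'   draws multinomial counts.
#' @param gc_bias optional per-bin multiplicative bias vector.
#' @param baseline optional per-bin baseline weights (default uniform;
#'   emulates mappability structure when supplied).
#' @param seed RNG seed applied by [simulate_profile()].
#' @return list of class `sim_params`.
#' @export
sim_params <- function(grid, depth = 1e7, tumor_fraction = 0, events = NULL,
                       dispersion = 50, gc_bias = NULL, baseline = NULL,
                       seed = NULL) {
  stopifnot(inherits(grid, "bin_grid"), depth > 0,
            tumor_fraction >= 0, tumor_fraction <= 1, dispersion > 0)
  if (!is.null(events) && nrow(events) > 0) {
    stopifnot(all(c("chrom", "start", "end", "copy_number") %in% names(events)),
              all(events$copy_number >= 0))
    ## events must not overlap within one truth set
    ev <- events[order(events$chrom, events$start), ]
    same <- ev$chrom[-1] == ev$chrom[-nrow(ev)]
    if (any(same & ev$start[-1] < ev$end[-nrow(ev)]))
      stop("simulated copy-number events overlap")
  }
  if (!is.null(gc_bias)) stopifnot(length(gc_bias) == grid$n_bins,
                                   all(gc_bias >= 0))
  if (!is.null(baseline)) stopifnot(length(baseline) == grid$n_bins,
                                    all(baseline >= 0))
  structure(list(grid = grid, depth = depth,
                 tumor_fraction = tumor_fraction, events = events,
                 dispersion = dispersion, gc_bias = gc_bias,
                 baseline = baseline, seed = seed),
            class = "sim_params")
}

#' Expected relative-coverage profile under the admixture model
#'
#' Bin weight is `baseline * (1 + tf * (c/2 - 1)) * gc_bias`, normalized to
#' sum to 1; `c` is the tumor copy number covering the bin midpoint (2
#' outside events).
#'
#' @param params a [sim_params()].
#' @return list of class `sim_truth`: `expected` (per-bin weights, sum 1),
#'   `copy_state` (per-bin tumor copy number), `params`.
#' @export
expected_profile <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  grid <- params$grid
  copy_state <- rep(2, grid$n_bins)
  ev <- params$events
  if (!is.null(ev) && nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      ix <- bins_in_interval(grid, genomic_interval(ev$chrom[i], ev$start[i],
                                                    ev$end[i]))
      copy_state[ix] <- ev$copy_number[i]
    }
  }
  w <- if (is.null(params$baseline)) rep(1, grid$n_bins) else params$baseline
  w <- w * (1 + params$tumor_fraction * (copy_state / 2 - 1))
  if (!is.null(params$gc_bias)) w <- w * params$gc_bias
  if (all(w == 0)) stop("expected profile is identically zero")
  structure(list(expected = w / sum(w), copy_state = copy_state,
                 params = params),
            class = "sim_truth")
}

#' Simulate one cfDNA coverage profile
#'
#' Draws per-bin counts with mean `depth * expected_weight`:
#' negative-binomial at finite dispersion, multinomial (conditioned on the
#' exact total) when `dispersion = Inf`. Fully reproducible for a fixed
#' seed.
#'
#' @param params a [sim_params()].
#' @param sample_id profile label.
#' @return list with elements `profile` (a `coverage_profile`) and `truth`
#'   (a `sim_truth`).
#' @export
simulate_profile <- function(params, sample_id = "sim") {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  truth <- expected_profile(params)
  mu <- params$depth * truth$expected
  counts <- if (is.infinite(params$dispersion)) {
    as.numeric(rmultinom(1, size = round(params$depth),
                         prob = truth$expected))
  } else {
    rnbinom(length(mu), mu = mu, size = params$dispersion)
  }
  prof <- new_coverage_profile(sample_id, params$grid, counts,
                               metadata = list(simulated = TRUE,
                                               tumor_fraction = params$tumor_fraction,
                                               dispersion = params$dispersion,
                                               seed = params$seed))
  list(profile = prof, truth = truth)
}

#' Events data.frame from a screening panel
#'
#' Maps panel segments to copy-number events: gains to `copy_gain` (default
#' 3) and losses to `copy_loss` (default 1).
#'
#' @param panel a `cin_panel` (or subset).
#' @param copy_gain,copy_loss copy numbers assigned to gain/loss segments.
#' @return data.frame `chrom, start, end, copy_number, name`.
#' @export
panel_events <- function(panel, copy_gain = 3, copy_loss = 1) {
  data.frame(chrom = panel$chrom, start = panel$`loc.start`,
             end = panel$`loc.end`,
             copy_number = ifelse(panel$direction == "gain", copy_gain,
                                  copy_loss),
             name = panel$name, stringsAsFactors = FALSE)
}

#' Simulate a case/control cohort with known truth
#'
#' Controls are drawn at tumor fraction 0. Each case draws a tumor fraction
#' from `tf_range` (uniform) and, independently per menu segment, carries
#' that segment's event with its `prob`; events drawn onto overlapping
#' coordinates are resolved by menu precedence (earlier rows win).
#'
#' @param n_cases,n_controls cohort sizes (`n_controls >= 2`).
#' @param menu data.frame with columns `chrom, start, end, copy_number,
#'   prob` (and optionally `name`); see [panel_events()]. Default: the
#'   packaged panel with its published per-segment frequencies.
#' @param tf_range tumor-fraction range for cases (default `c(0.05, 0.3)`).
#' @param grid a `bin_grid`.
#' @param depth,dispersion as in [sim_params()].
#' @param seed RNG seed for the whole cohort.
#' @return list of per-sample entries `(profile, truth, label,
#'   tumor_fraction, events)`.
#' @export
simulate_cohort <- function(n_cases, n_controls, menu = NULL,
                            tf_range = c(0.05, 0.3), grid, depth = 1e7,
                            dispersion = 50, seed = NULL) {
  stopifnot(n_controls >= 2, n_cases >= 0, inherits(grid, "bin_grid"))
  if (is.null(menu)) {
    panel <- load_panel()
    menu <- panel_events(panel)
    menu$prob <- panel$frequency
  }
  stopifnot(all(c("chrom", "start", "end", "copy_number", "prob") %in%
                  names(menu)))
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (k in seq_len(n_controls)) {
    sim <- simulate_profile(sim_params(grid, depth = depth,
                                       tumor_fraction = 0,
                                       dispersion = dispersion),
                            sample_id = sprintf("control_%03d", k))
    out[[length(out) + 1]] <- c(sim, list(label = "control",
                                          tumor_fraction = 0,
                                          events = menu[0, ]))
  }
  for (k in seq_len(n_cases)) {
    tf <- runif(1, tf_range[1], tf_range[2])
    drawn <- menu[runif(nrow(menu)) < menu$prob, , drop = FALSE]
    drawn <- drop_overlapping_events(drawn)
    sim <- simulate_profile(sim_params(grid, depth = depth,
                                       tumor_fraction = tf,
                                       events = drawn,
                                       dispersion = dispersion),
                            sample_id = sprintf("case_%03d", k))
    out[[length(out) + 1]] <- c(sim, list(label = "cancer",
                                          tumor_fraction = tf,
                                          events = drawn))
  }
  out
}

## Precedence rule: earlier menu rows win; later rows overlapping an
## already-kept event are dropped.
drop_overlapping_events <- function(events) {
  if (nrow(events) <= 1) return(events)
  keep <- rep(TRUE, nrow(events))
  for (i in seq_len(nrow(events))[-1]) {
    prior <- which(keep[seq_len(i - 1)])
    for (p in prior) {
      if (events$chrom[i] == events$chrom[p] &&
          events$start[i] < events$end[p] &&
          events$end[i] > events$start[p]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  events[keep, , drop = FALSE]
}
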