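# A one-bin custom panel makes the cutoff arithmetic exact: seg_mean of a
# single bin is the bin z itself and z = seg_mean * sqrt(1).
one_bin_panel <- function(chrom = "c1", start = 0, end = 2e5,
                          name = "seg+", direction = "gain") {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("name", "chrom", "loc.start", "loc.end", "direction",
                       "key_genes", "frequency", "seg_mean", "logP"),
                     collapse = "\t"),
               sprintf("%s\t%s\t%.0f\t%.0f\t%s\t\t0.5\t1\t-5", name, chrom,
                       start, end, direction)), path)
  load_panel(path)
}

test_that("segment z is Stouffer-aggregated over unmasked bins", {
  g <- make_bin_grid(genome_build(c(c1 = 100 * 2e5)), 2e5)
  all0 <- segment_z(nprofile_from_z(rep(0, 100), g),
                    genomic_interval("c1", 0, 100 * 2e5))
  expect_equal(all0$seg_mean, 0)
  expect_equal(all0$z, 0)

  half <- segment_z(nprofile_from_z(rep(0.5, 100), g),
                    genomic_interval("c1", 0, 100 * 2e5))
  expect_equal(half$n_bins, 100)
  expect_equal(half$seg_mean, 0.5)
  expect_equal(half$z, 5)

  # fully masked interval is an explicit uncallable sentinel
  un <- segment_z(nprofile_from_z(rep(1, 100), g, mask = rep(FALSE, 100)),
                  genomic_interval("c1", 0, 100 * 2e5))
  expect_false(un$callable)
  expect_true(is.na(un$z))
})

test_that("segment z of Gaussian-null bins is standard normal", {
  set.seed(55)
  g <- make_bin_grid(genome_build(c(c1 = 50 * 2e5)), 2e5)
  iv <- genomic_interval("c1", 0, 50 * 2e5)
  zz <- vapply(1:1000, function(r) {
    segment_z(nprofile_from_z(rnorm(50), g), iv)$z
  }, numeric(1))
  expect_lt(abs(mean(zz)), 0.1)
  expect_gt(sd(zz), 0.9)
  expect_lt(sd(zz), 1.1)
})

test_that("panel scoring applies the inclusive 2.702 cutoff per mode", {
  hg <- make_bin_grid(hg19_build(), 2e5)
  zero <- score_panel(nprofile_from_z(rep(0, hg$n_bins), hg))
  expect_equal(zero$altered_count, 0)
  expect_equal(zero$category, "0")
  expect_false(screen(zero)$positive)

  g <- toy_grid(1e6)
  pan <- one_bin_panel()
  z <- rep(0, 5); z[1] <- 2.702
  at_cut <- score_panel(nprofile_from_z(z, g), pan)
  expect_true(at_cut$table$altered[1])  # >= is inclusive
  expect_equal(at_cut$altered_count, 1)
  expect_true(screen(at_cut)$positive)

  below <- score_panel(nprofile_from_z(replace(rep(0, 5), 1, 2.701), g), pan)
  expect_false(screen(below)$positive)

  # matched mode requires the sign to agree with the panel direction
  zneg <- replace(rep(0, 5), 1, -5)
  abs_mode <- score_panel(nprofile_from_z(zneg, g), pan,
                          direction_mode = "absolute")
  expect_true(abs_mode$table$altered[1])
  matched <- score_panel(nprofile_from_z(zneg, g), pan,
                         direction_mode = "matched")
  expect_false(matched$table$altered[1])
})

test_that("altered counts, categories, and screening agree", {
  hg <- make_bin_grid(hg19_build(), 2e5)
  panel <- load_panel()
  # drive exactly 11 panel segments over the cutoff
  z <- rep(0, hg$n_bins)
  for (i in 1:11) {
    ix <- bins_in_interval(hg, panel_interval(panel, i))
    z[ix] <- 6 / sqrt(length(ix))
  }
  sc <- score_panel(nprofile_from_z(z, hg), panel)
  expect_equal(sc$altered_count, 11)
  expect_equal(sc$category, ">=3")
  expect_true(screen(sc)$positive)
  expect_equal(sort(sc$table$name[sc$table$altered]), sort(panel$name[1:11]))

  # one segment altered -> category "1", still positive
  z1 <- rep(0, hg$n_bins)
  ix <- bins_in_interval(hg, panel_interval(panel, 7))
  z1[ix] <- 4 / sqrt(length(ix))
  sc1 <- score_panel(nprofile_from_z(z1, hg), panel)
  expect_equal(sc1$category, "1")
  expect_true(screen(sc1)$positive)
})

test_that("scoring is invariant to panel row order and lists uncallables", {
  hg <- make_bin_grid(hg19_build(), 2e5)
  panel <- load_panel()
  set.seed(10)
  z <- rnorm(hg$n_bins) + 0.2
  sc <- score_panel(nprofile_from_z(z, hg), panel)
  shuf <- panel[sample(nrow(panel)), ]
  class(shuf) <- class(panel)
  sc2 <- score_panel(nprofile_from_z(z, hg), shuf)
  expect_equal(sc2$altered_count, sc$altered_count)
  expect_equal(sort(sc2$table$name[sc2$table$altered]),
               sort(sc$table$name[sc$table$altered]))

  # masking every bin of one segment excludes it without silent zeros
  mask <- rep(TRUE, hg$n_bins)
  mask[bins_in_interval(hg, panel_interval(panel, which(panel$name == "TERT+")))] <- FALSE
  scm <- score_panel(nprofile_from_z(z, hg, mask = mask), panel)
  expect_equal(scm$uncallable, "TERT+")
  expect_false("TERT+" %in% scm$table$name[scm$table$altered])
})

test_that("detected segment strength grows with tumor fraction", {
  set.seed(123)
  build <- genome_build(hg19_chrom_sizes()["chr8"], name = "hg19")
  g <- make_bin_grid(build, 2e5)
  panel <- load_panel(); panel <- panel[panel$name == "8q+", ]
  class(panel) <- c("cin_panel", "data.frame")
  ref <- build_reference(simulate_controls(15, g, depth = 1e6))
  mean_abs_z <- vapply(c(0.05, 0.1, 0.2, 0.3), function(tf) {
    zs <- vapply(1:4, function(r) {
      sim <- simulate_profile(sim_params(g, depth = 1e6, tumor_fraction = tf,
                                         events = panel_events(panel)))
      abs(score_panel(normalize(sim$profile, ref), panel)$table$z)
    }, numeric(1))
    mean(zs)
  }, numeric(1))
  expect_true(all(diff(mean_abs_z) > 0))
})

test_that("longitudinal tracking orders timepoints and flags calls", {
  g <- toy_grid(1e6)
  pan <- one_bin_panel(name = "8q+", direction = "gain")
  series <- c(6.63, 2.46, 6.58, 11.8)  # pre-op, post-op, relapse, progression
  scores <- lapply(seq_along(series), function(k) {
    score_panel(nprofile_from_z(replace(rep(0, 5), 1, series[k]), g), pan)
  })
  traj <- track_longitudinal(scores, timepoints = c(0, 10, 40, 70))
  expect_equal(traj$z, series, tolerance = 1e-12)
  expect_equal(traj$altered, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(traj$sample_positive, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(traj$timepoint, c(0, 10, 40, 70))

  single <- track_longitudinal(scores[1])
  expect_equal(nrow(single), 1)

  low <- lapply(1:3, function(k) {
    score_panel(nprofile_from_z(replace(rep(0, 5), 1, 0.5), g), pan)
  })
  expect_false(any(track_longitudinal(low)$altered))

  other <- score_panel(nprofile_from_z(rep(0, 5), g), one_bin_panel(name = "x+"))
  expect_error(track_longitudinal(list(scores[[1]], other)),
               "different panels")
})
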