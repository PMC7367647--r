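# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code at test time; no binary fixtures.

toy_build <- function(len = 1e6, name = "toy") {
  genome_build(c(c1 = len), name = name)
}

toy_grid <- function(len = 1e6, bin_size = 2e5, name = "toy") {
  make_bin_grid(toy_build(len, name), bin_size)
}

# Coverage profile straight from a count vector.
profile_from_counts <- function(counts, grid, sample_id = "s") {
  path <- tempfile(fileext = ".tsv")
  df <- cbind(grid$bins, count = counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_counts_table(path, grid, sample_id = sample_id)
}

# Hand-built normalized profile (z vector + mask) for scoring tests.
nprofile_from_z <- function(z, grid, mask = rep(TRUE, length(z)),
                            sample_id = "s") {
  stopifnot(length(z) == grid$n_bins)
  z[!mask] <- NA_real_
  structure(list(sample_id = sample_id, grid = grid, z_per_bin = z,
                 mask = mask),
            class = "normalized_profile")
}

# Minimal SAM writer: paired, proper-pair, first-mate reads at given
# 1-based positions. Converted to BAM inside count_reads_per_bin().
write_sam_fixture <- function(path, chrom_sizes, chroms, positions,
                              mapq = 60) {
  n <- length(positions)
  if (length(mapq) == 1) mapq <- rep(mapq, n)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes), chrom_sizes))
  ord <- order(match(chroms, names(chrom_sizes)), positions)
  reads <- sprintf("r%04d\t99\t%s\t%d\t%d\t10M\t=\t%d\t150\t%s\t%s",
                   seq_len(n), chroms[ord], positions[ord], mapq[ord],
                   positions[ord] + 100, strrep("A", 10), strrep("I", 10))
  writeLines(c(hdr, reads), path)
  path
}

# Independent exhaustive oracle for the maximal circular-arc two-sample t.
# Plain double loop; statistics computed directly from the two groups.
oracle_max_circular_t <- function(x, min_width = 2) {
  n <- length(x)
  best <- list(i = NA, j = NA, t = NA)
  best_abs <- -1
  for (i in 0:(n - 1)) {
    # cut n coincides with cut 0 circularly; j stops at n-1 so each
    # partition is scored once
    for (j in (i + min_width):min(i + n - min_width, n - 1)) {
      if (j > n - 1 || j < i + min_width) next
      arc <- x[(i + 1):j]
      comp <- x[-((i + 1):j)]
      k <- length(arc); m <- length(comp)
      pooled <- (sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)) /
        (n - 2)
      pooled <- max(pooled, 1e-24)
      dd <- mean(arc) - mean(comp)
      tt <- dd / sqrt(pooled * (1 / k + 1 / m))
      if (abs(dd) <= 1e-9 * max(abs(mean(arc)), abs(mean(comp)))) tt <- 0
      if (abs(tt) > best_abs) {
        best_abs <- abs(tt)
        best <- list(i = i, j = j, t = tt)
      }
    }
  }
  best
}

# Exhaustive two-sided Fisher p over the hypergeometric support.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Pairwise-concordance (Mann-Whitney) AUC oracle, ties counted 1/2.
oracle_auc <- function(stat, is_cancer) {
  ca <- stat[is_cancer]; co <- stat[!is_cancer]
  pairs <- outer(ca, co, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# Simulated NB control cohort on a grid (uniform baseline).
simulate_controls <- function(n, grid, depth = 2e6, dispersion = 50) {
  lapply(seq_len(n), function(k) {
    simulate_profile(sim_params(grid, depth = depth, dispersion = dispersion),
                     sample_id = sprintf("ctrl%02d", k))$profile
  })
}
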