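# Independent oracles used across tests; each re-derives a quantity by the
# most transparent route available (brute force, enumeration, hand formula)
# so that it shares no code with the implementation it checks.

# Brute-force run scan: all maximal runs of TRUE of length >= min_len.
brute_runs <- function(mask, min_len) {
  starts <- integer(); ends <- integer()
  i <- 1L; n <- length(mask)
  while (i <= n) {
    if (isTRUE(mask[i])) {
      j <- i
      while (j < n && isTRUE(mask[j + 1L])) j <- j + 1L
      if (j - i + 1L >= min_len) {
        starts <- c(starts, i); ends <- c(ends, j)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends)
}

# Exact two-sided Mann-Whitney p by full enumeration of label assignments.
# U for a subset = rank sum of the subset minus n_a(n_a+1)/2; two-sided p
# doubles the smaller tail, capped at 1.
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  u_all <- colSums(matrix(r[idx], nrow = n_a)) - n_a * (n_a + 1) / 2
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Hand evaluation of the Pearson chi-square statistic on a 2x2 table.
hand_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# A small panel configuration for fast tests.
small_config <- function(seed = 1L, ...) {
  panel_config(
    n_species_per_class = c(psychro = 2, meso = 3, thermo = 2, hyper = 3),
    proteome_size_by_class = c(psychro = 40, meso = 60, thermo = 50, hyper = 30),
    mean_protein_length = 200,
    seed = seed, ...)
}

random_track <- function(n) stats::runif(n)
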