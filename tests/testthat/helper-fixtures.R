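# Shared fixtures and small independent oracles, built in code.

# Hamming distance between two equal-length strings.
str_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Brute-force enumeration of the exact two-sided rank-sum p-value: loops over
# every size-n1 subset of ranks (independent of the DP implementation).
enumerate_ranksum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  all_w <- apply(utils::combn(n, n1), 2, sum)
  pl <- mean(all_w <= w_obs)
  pg <- mean(all_w >= w_obs)
  min(1, 2 * min(pl, pg))
}

# Brute-force classification oracle: join calls and truth position by
# position.
classify_oracle <- function(calls, truth) {
  ck <- paste(calls$genome_id, calls$position)
  tk <- paste(truth$genome_id, truth$position)
  m <- mm <- fp <- 0L
  for (i in seq_len(nrow(calls))) {
    j <- which(tk == ck[i])
    if (length(j) == 0) fp <- fp + 1L
    else if (truth$alt[j] == calls$alt[i]) m <- m + 1L
    else mm <- mm + 1L
  }
  fn <- sum(!tk %in% ck)
  list(match = m, mismatch = mm, false_positive = fp, false_negative = fn)
}

# Build a sim_reads-like data frame by hand (for pileup unit tests).
manual_reads <- function(genome_id, start, seq, strand = "+",
                         qual_char = "H") {
  n <- length(start)
  data.frame(
    name = sprintf("r%d:%s:%d:%s", seq_len(n), genome_id, start, strand),
    genome_id = genome_id, start = start, strand = strand,
    mate = 1L, seq = seq,
    qual = vapply(nchar(seq), function(L)
      paste(rep(qual_char, L), collapse = ""), character(1)),
    stringsAsFactors = FALSE)
}

# Reduced cohort for fast structural tests.
mini_cohort_config <- function(...) {
  sp <- data.frame(
    species_id = c("spA", "spB", "spC", "spD", "spE", "spF"),
    genome_size = c(250000L, 300000L, 200000L, 280000L, 220000L, 260000L),
    enriched = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  cohort_config(species = sp, strain_divergence = 40,
                genes_per_species = 30, n_cyclic_genes = 2, ...)
}

# The documented default cohort, simulated once per test run.
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(seed = 1)
    cache
  }
})
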