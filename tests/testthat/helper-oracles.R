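# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition, never via the package's own
# code path.

# Benjamini-Hochberg step-up, straight from the definition: sort ascending,
# adj for the i-th order statistic is min over j >= i of m * p_(j) / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive substring scan: first reference (in file order) whose sequence
# contains the read's first seed_len bases.
match_brute <- function(seq, reference, seed_len = 20L) {
  if (nchar(seq) < seed_len) return(NA_character_)
  seed <- substr(seq, 1L, seed_len)
  for (id in names(reference)) {
    if (grepl(seed, reference[[id]], fixed = TRUE)) return(id)
  }
  NA_character_
}

# Enumerate every (position, overlap) adapter candidate and take the
# leftmost one qualifying on overlap and mismatch rate.
trim_pos_brute <- function(seq, adapter, min_overlap = 3L,
                           max_error_rate = 0.1) {
  L <- nchar(seq)
  A <- nchar(adapter)
  for (p in seq_len(L)) {
    o <- min(A, L - p + 1L)
    if (o < min_overlap) next
    mism <- sum(strsplit(substr(seq, p, p + o - 1L), "")[[1]] !=
                  strsplit(substr(adapter, 1L, o), "")[[1]])
    if (mism / o <= max_error_rate) return(p)
  }
  NA_integer_
}

# Pooled-variance two-sample t-test (equal variances), the classical
# closed form, as an oracle for the unmoderated limit of the pipeline.
pooled_t_oracle <- function(y1, y2) {
  n1 <- length(y1)
  n2 <- length(y2)
  sp2 <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) / (n1 + n2 - 2)
  t <- (mean(y2) - mean(y1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n1 + n2 - 2))
}

# A small, fast study configuration for tests that need the whole chain
# but not the default read depth.
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_mirna = 12L, n_de = 2L, n_de_up = 1L,
             lib_size_mean = 2000L, n_mrna = 300L, targets_per_mirna = 15L,
             n_gene_sets = 10L, set_size_range = c(8L, 15L),
             n_enriched_sets = 2L, ...)
}

random_read <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
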