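# Independent oracles used to validate the package's own implementations.
# These are deliberately written as plain, slow enumerations with their own
# arithmetic so they share no code path with the functions under test.

# Read-by-read fractional assignment: tally unique reads per gene in a first
# explicit pass, then walk every read again distributing its unit mass.
oracle_fractional <- function(alignments) {
  hits <- strsplit(as.character(alignments$genes), ",", fixed = TRUE)
  uniq <- list()
  for (h in hits) {
    if (length(h) == 1) {
      uniq[[h]] <- (if (is.null(uniq[[h]])) 0 else uniq[[h]]) + 1
    }
  }
  out <- list()
  add <- function(g, x) {
    x <- unname(x)
    out[[g]] <<- (if (is.null(out[[g]])) 0 else out[[g]]) + x
  }
  for (h in hits) {
    if (length(h) == 1) {
      add(h, 1)
    } else {
      u <- vapply(h, function(g) if (is.null(uniq[[g]])) 0 else uniq[[g]], 0)
      if (sum(u) == 0) {
        for (g in h) add(g, 1 / length(h))
      } else {
        for (i in seq_along(h)) add(h[i], u[i] / sum(u))
      }
    }
  }
  unlist(out)
}

# NB log pmf from first principles (gamma functions), avoiding dnbinom.
oracle_nb_lpmf <- function(x, mean, size) {
  if (is.infinite(size)) return(x * log(mean) - mean - lgamma(x + 1))
  lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
    size * (log(size) - log(size + mean)) + x * (log(mean) - log(size + mean))
}

# Exhaustive conditional exact test for two group sums.
oracle_exact_p <- function(ka, kb, sf_a, sf_b, alpha) {
  total <- ka + kb
  mu <- total / (sum(sf_a) + sum(sf_b))
  mom <- function(sf) {
    m <- mu * sum(sf)
    v <- mu * sum(sf) + alpha * mu^2 * sum(sf^2)
    size <- if (v > m) m^2 / (v - m) else Inf
    c(m, size)
  }
  A <- mom(sf_a); B <- mom(sf_b)
  lp <- vapply(0:total, function(x) {
    oracle_nb_lpmf(x, A[1], A[2]) + oracle_nb_lpmf(total - x, B[1], B[2])
  }, 0)
  lobs <- oracle_nb_lpmf(ka, A[1], A[2]) + oracle_nb_lpmf(kb, B[1], B[2])
  pr <- exp(lp - max(lp))
  min(1, sum(pr[lp <= lobs + 1e-7]) / sum(pr))
}

# Hypergeometric upper tail P(X >= k) by explicit binomial-coefficient sums.
oracle_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# One-sided exact Wilcoxon p by enumerating every label assignment.
oracle_wilcoxon_greater <- function(treated, control) {
  vals <- c(treated, control)
  n <- length(treated)
  ranks <- rank(vals)
  w_obs <- sum(ranks[seq_len(n)])
  combos <- utils::combn(length(vals), n)
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx]))
  mean(w_all >= w_obs)
}

# Tiny two-block expression matrix with noiseless orthogonal profiles.
block_matrix <- function(n_a = 6, n_b = 6, n_samples = 8) {
  pa <- rep(c(5, 0), each = n_samples / 2)
  pb <- rep(c(0, 5), each = n_samples / 2)
  m <- rbind(matrix(pa, n_a, n_samples, byrow = TRUE),
             matrix(pb, n_b, n_samples, byrow = TRUE))
  rownames(m) <- c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b)))
  colnames(m) <- paste0("s", seq_len(n_samples))
  m
}

# Write a counts + metadata fixture pair to temp files.
write_counts_fixture <- function(counts_df, meta_df) {
  cf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  utils::write.table(counts_df, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(meta_df, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  list(counts = cf, meta = mf)
}

default_meta <- function(sample_ids, stage = "E10.5", domain = "AoV") {
  data.frame(sample_id = sample_ids, stage = stage, domain = domain,
             replicate = seq_along(sample_ids), stringsAsFactors = FALSE)
}
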