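# Independent oracles and small fixtures used across the suite.

# Adjusted Rand index between two partitions
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Exact signed-rank p by full enumeration of the 2^n sign assignments
enum_signed_rank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% r
  p_ge <- mean(Vs >= V - 1e-12)
  p_le <- mean(Vs <= V + 1e-12)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# Brute-force silhouette widths
brute_silhouette <- function(X, cl) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  vapply(seq_len(n), function(i) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0) return(0)
    a <- mean(vapply(own, d, numeric(1), i = i))
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g)
      mean(vapply(which(cl == g), d, numeric(1), i = i)), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Two columns with an exact sample correlation r (Gram-Schmidt)
exact_cor_pair <- function(r, n = 24) {
  u <- scale(seq_len(n))[, 1]
  v <- scale(resid(lm(rnorm(n) ~ u)))[, 1]
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  cbind(x = u, y = r * u + sqrt(1 - r^2) * v)
}

# One-factor blocks with planted loadings and equicorrelated block factors;
# returns a change-table-like data.frame plus the block structure
one_factor_cohort <- function(n, n_blocks, mvs_per_block, loading,
                              factor_r = 0.3, seed = 1) {
  set.seed(seed)
  G <- rnorm(n)
  f <- sapply(seq_len(n_blocks), function(b)
    sqrt(factor_r) * G + sqrt(1 - factor_r) * rnorm(n))
  X <- do.call(cbind, lapply(seq_len(n_blocks), function(b)
    sapply(seq_len(mvs_per_block), function(j)
      loading * f[, b] + sqrt(1 - loading^2) * rnorm(n))))
  colnames(X) <- paste0("T", seq_len(ncol(X)))
  blocks <- data.frame(trait = colnames(X),
                       block_id = rep(seq_len(n_blocks),
                                      each = mvs_per_block),
                       stringsAsFactors = FALSE)
  delta <- data.frame(subject_id = sprintf("S%04d", seq_len(n)), X,
                      stringsAsFactors = FALSE, check.names = FALSE)
  list(delta = delta, blocks = blocks)
}

# Small default cohort change table, memoised per seed
small_cohort <- local({
  cache <- list()
  function(seed = 1, n = 883) {
    key <- paste(seed, n)
    if (is.null(cache[[key]])) {
      coh <- generate_cohort(default_cohort_config(n_subjects = n),
                             seed = seed)
      cache[[key]] <<- list(cohort = coh,
                            delta = compute_changes(coh$baseline,
                                                    coh$chronic))
    }
    cache[[key]]
  }
})
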