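# In-code fixtures shared across test files.

# Minimal feature table: p features named with a class prefix, optional
# planted effect d on the first feature.
tiny_table <- function(n = 40, p = 4, d = 0, seed = 1, prefix = "glcm") {
  withr::with_seed(seed, {
    labels <- rep(c(1L, 0L), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[labels == 1, 1] <- X[labels == 1, 1] + d
    colnames(X) <- paste0(prefix, "_f", sprintf("%02d", seq_len(p)))
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("S%03d", seq_len(n)), label = labels),
      tibble::as_tibble(as.data.frame(X)))
  })
}

# Brute-force AUC by pair counting (ties count one half).
auc_bruteforce <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  }
  tot / (length(x) * length(y))
}

# Exhaustive Youden sweep over all unique-midpoint cutoffs.
youden_bruteforce <- function(scores, labels) {
  u <- sort(unique(scores))
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf
  for (c in cuts) {
    sens <- sum(scores >= c & labels == 1) / sum(labels == 1)
    spec <- sum(scores < c & labels == 0) / sum(labels == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Exhaustive 3-vs-3 permutation p for the |mean difference| statistic.
perm_p_exhaustive_3v3 <- function(values) {
  obs <- abs(mean(values[4:6]) - mean(values[1:3]))
  comb <- utils::combn(6, 3)
  mean(apply(comb, 2, function(ix) {
    abs(mean(values[ix]) - mean(values[-ix]))
  }) >= obs - 1e-12)
}
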