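# Independent brute-force oracles. Deliberately naive: explicit ranking,
# enumeration and hand-rolled formulas, sharing no code with the package.

# average ranks by explicit position averaging
rank_oracle <- function(v) {
  s <- sort(v)
  vapply(v, function(x) mean(which(s == x)), numeric(1))
}

pearson_oracle <- function(a, b) {
  ca <- a - mean(a)
  cb <- b - mean(b)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

spearman_oracle <- function(x, y) pearson_oracle(rank_oracle(x), rank_oracle(y))

# BH step-up by the textbook rule
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-sided Fisher exact p by full hypergeometric enumeration of tables
# with the observed margins
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(r1 + r2, c1)
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumeration of all group-A rank subsets
ranksum_exact_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank_oracle(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(n + m, n)
  w_all <- colSums(matrix(r[combos], nrow = n))
  p_lo <- mean(w_all <= w_obs + 1e-9)
  p_hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# log-rank chi-square from the O - E table walked event time by event time
logrank_oracle <- function(time, event, group) {
  g1 <- unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# least-squares branch lengths for a fixed 4-taxon unrooted topology
# ((a,b),(c,d)); returns list(rss, lengths) or NULL if any length < 0
nj4_ls_fit <- function(dm, a, b, c, d) {
  # unknowns: la, lb, lc, ld, internal e
  labs <- c(a, b, c, d)
  pairs <- utils::combn(4, 2)
  A <- matrix(0, ncol(pairs), 5)
  y <- numeric(ncol(pairs))
  uses_internal <- function(i, j) (i <= 2) != (j <= 2)  # across the split
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    A[k, i] <- 1; A[k, j] <- 1
    if (uses_internal(i, j)) A[k, 5] <- 1
    y[k] <- dm[labs[i], labs[j]]
  }
  beta <- solve(t(A) %*% A, t(A) %*% y)
  rss <- sum((A %*% beta - y)^2)
  list(rss = rss, lengths = stats::setNames(as.numeric(beta),
                                            c(labs, "internal")))
}

# brute-force 4-taxon tree: least squares over all three unrooted topologies
nj4_oracle <- function(dm) {
  labs <- rownames(dm)
  tops <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  fits <- lapply(tops, function(tp) {
    f <- nj4_ls_fit(dm, labs[tp[1]], labs[tp[2]], labs[tp[3]], labs[tp[4]])
    f$split <- sort(c(labs[tp[1]], labs[tp[2]]))
    f
  })
  fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
}

# sample SD by the definition
sd_oracle <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))

# per-mutation enumeration oracle for the immunoediting expectation
editing_oracle <- function(sample_df, p_by_context) {
  ns <- sample_df[sample_df$class != "silent", ]
  ns <- ns[!duplicated(paste(ns$chrom, ns$pos, ns$ref, ns$alt)), ]
  expected <- sum(vapply(ns$context, function(cx) p_by_context[[cx]], numeric(1)))
  observed <- sum(ns$n_neoantigens > 0)
  list(observed = observed, expected = expected, ratio = observed / expected)
}
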