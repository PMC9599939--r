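# Independent oracles used by the test suite. These deliberately use naive
# brute-force implementations distinct from the package's code paths.

# all permutations of 1:n, built iteratively (independent of the package's
# recursive generator)
oracle_perms <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    out <- do.call(rbind, lapply(seq_len(k), function(pos) {
      cbind(out[, seq_len(pos - 1L), drop = FALSE], k,
            out[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    }))
  }
  out
}

# exhaustive two-sided Spearman permutation p-value via stats::cor on every
# permutation of y
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  P <- oracle_perms(n)
  obs <- abs(cor(rank(x), rank(y)))
  rhos <- apply(P, 1L, function(idx) cor(rank(x), rank(y)[idx]))
  mean(abs(rhos) >= obs - 1e-12)
}

# exhaustive best split by looping stats::t.test over all admissible cuts
oracle_best_split <- function(x, min_probes = 3L) {
  n <- length(x)
  best <- -Inf
  best_i <- NA_integer_
  for (i in seq_len(n - 1L)) {
    if (i < min_probes || (n - i) < min_probes) next
    a <- x[seq_len(i)]
    b <- x[(i + 1L):n]
    tt <- abs(stats::t.test(a, b, var.equal = TRUE)$statistic)
    if (tt > best) {
      best <- tt
      best_i <- i
    }
  }
  list(stat = unname(best), index = best_i)
}

# two-sided Fisher exact p by enumerating the hypergeometric support
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  sum(probs[probs <= stats::dhyper(a, c1, n - c1, r1) * (1 + 1e-7)])
}

# hand-computed log-rank chi-square: sum over distinct event times of
# (O - E) with hypergeometric variance
oracle_logrank_chisq <- function(months, event, group) {
  g1 <- unique(group)[1]
  times <- sort(unique(months[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- months >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(months == t & event == 1)
    d1 <- sum(months == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small LRR/BAF profile with exactly known states and near-zero noise
make_profile <- function(n = 60L, lrr = rep(0, n), baf_center = rep(0.5, n),
                         genotype = rep("AB", n), noise = 1e-3, seed = 1L) {
  set.seed(seed)
  data.frame(
    snp_id = sprintf("s%03d", seq_len(n)),
    chrom = "chr8",
    pos = seq(1000L, by = 1000L, length.out = n),
    genotype = genotype,
    lrr = lrr + rnorm(n, 0, noise),
    baf = pmin(1, pmax(0, baf_center + rnorm(n, 0, noise))),
    stringsAsFactors = FALSE
  )
}
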