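test_that("spearman handles perfect monotone pairs and transform invariance", {
  expect_equal(spearman(1:5, c(2, 4, 6, 8, 10))$rho, 1.0)
  expect_equal(spearman(1:5, 5:1)$rho, -1.0)
  set.seed(41)
  x <- rnorm(12)
  y <- rnorm(12)
  a <- spearman(x, y)
  expect_equal(spearman(y, x)$rho, a$rho)              # symmetry
  expect_equal(spearman(exp(x), y^3)$rho,
               spearman(x, y)$rho * sign(1))           # rank invariance (y^3 monotone)
  expect_equal(spearman(exp(x), y)$p, a$p)
})

test_that("exact permutation p matches brute-force enumeration at n = 7", {
  set.seed(43)
  for (i in 1:3) {
    x <- rnorm(7)
    y <- rnorm(7)
    ours <- spearman(x, y)
    expect_equal(ours$method, "exact")
    expect_equal(ours$p, oracle_spearman_p(x, y), tolerance = 1e-12)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(ours$rho, unname(ct$estimate))
    expect_equal(ours$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("pairs below five complete cases are skipped, not raised", {
  s <- spearman(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_true(s$skipped)
  expect_true(is.na(s$p))
  s2 <- spearman(c(1, 2, 3, NA, 5, 6), c(1, NA, 3, 4, 5, 6))
  expect_equal(s2$n, 4L)
  expect_true(s2$skipped)
})

test_that("the Bonferroni family covers attempted comparisons", {
  set.seed(47)
  lrr <- matrix(rnorm(30 * 123), 30, 123,
                dimnames = list(sprintf("c%02d", 1:30),
                                sprintf("s%03d", 1:123)))
  fc <- matrix(rnorm(30 * 11), 30, 11,
               dimnames = list(rownames(lrr), sprintf("p%02d", 1:11)))
  res <- correlate_snp_vs_expression(lrr, fc, colnames(lrr))
  expect_equal(res$plan$m, 1353L)
  expect_equal(res$plan$bonferroni_threshold, 0.05 / 1353)
  # threshold nesting: a Bonferroni hit is always a nominal hit
  expect_true(all(!res$results$bonferroni | res$results$nominal))
  # conservation: one row per pair passing the >= 5-case rule
  expect_equal(nrow(res$results), 1353L)
  expect_error(correlate_snp_vs_expression(lrr, fc, character(0)), "empty")
})

test_that("pairs with fewer than five complete cases are absent", {
  set.seed(53)
  lrr <- matrix(rnorm(10 * 2), 10, 2,
                dimnames = list(sprintf("c%02d", 1:10), c("sA", "sB")))
  lrr[1:6, "sB"] <- NA  # only 4 complete cases for sB
  fc <- matrix(rnorm(10), 10, 1, dimnames = list(rownames(lrr), "pA"))
  res <- correlate_snp_vs_expression(lrr, fc, c("sA", "sB"))
  expect_equal(res$results$id1, "sA")
  expect_equal(res$plan$m, 2L)  # the skipped pair still counts in the family
})

test_that("correlation direction follows the sign of rho", {
  expect_equal(classify_direction(c(0.83, -0.881, 0)),
               c("positive", "negative", "undirected"))
})

test_that("planted couplings are recovered and intersected across analyses", {
  set.seed(59)
  n <- 30
  z <- rnorm(n)
  cases <- sprintf("c%02d", 1:n)
  lrr <- cbind(sA = z, sB = rnorm(n), sC = rnorm(n))
  rownames(lrr) <- cases
  probe <- cbind(pA = 2^z, pB = 2^rnorm(n))  # sA coupled to pA, noise off
  rownames(probe) <- cases
  mir <- cbind(mA = 2^(-z), mB = 2^rnorm(n)) # sA anti-coupled to mA
  rownames(mir) <- cases

  r1 <- correlate_snp_vs_expression(lrr, probe, colnames(lrr))
  pair <- r1$results[r1$results$id1 == "sA" & r1$results$id2 == "pA", ]
  expect_equal(pair$rho, 1.0)
  expect_true(pair$nominal)

  r2 <- correlate_snp_vs_mirna(lrr, mir, colnames(lrr))
  dual <- find_dual_correlated_snps(r1$results, r2$results)
  expect_true("sA" %in% dual$snp_id)
  expect_equal(dual$rho[dual$analysis == "mirna" & dual$snp_id == "sA" &
                          dual$partner == "mA"], -1.0)
  # a SNP significant in only one analysis is excluded
  only_mrna <- r1$results[r1$results$id1 == "sA", ]
  none <- r2$results[0, ]
  expect_equal(nrow(find_dual_correlated_snps(only_mrna, none)), 0L)
  expect_equal(nrow(find_dual_correlated_snps(r1$results[0, ], none)), 0L)
})

test_that("expression-miRNA correlation handles identical and reversed pairs", {
  v <- c(0.5, 1, 2, 4, 8, 16)
  cases <- sprintf("c%d", 1:6)
  probe <- matrix(v, 6, 1, dimnames = list(cases, "pA"))
  mir <- cbind(mSame = v, mAnti = rev(v))
  rownames(mir) <- cases
  res <- correlate_expression_vs_mirna(probe, mir)
  expect_equal(res$results$rho[res$results$mir_id == "mSame"], 1.0)
  expect_equal(res$results$rho[res$results$mir_id == "mAnti"], -1.0)
})

test_that("group comparison by alteration status recovers planted shifts", {
  cases <- sprintf("c%02d", 1:20)
  altered <- data.frame(case_id = cases, altered = rep(c(TRUE, FALSE), 10))
  fc <- rbind(
    data.frame(case_id = cases, probe_id = "pA",
               fc = ifelse(rep(c(TRUE, FALSE), 10), 8, 1)),
    data.frame(case_id = cases, probe_id = "pB", fc = 2)
  )
  cmp <- compare_groups_by_alteration(fc, altered)
  expect_equal(nrow(cmp), 2L)  # one row per probe
  expect_equal(cmp$ratio[cmp$probe_id == "pA"], 8)
  expect_equal(cmp$ratio[cmp$probe_id == "pB"], 1)
  all_alt <- data.frame(case_id = cases, altered = TRUE)
  expect_error(compare_groups_by_alteration(fc, all_alt), "non-empty")
})
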