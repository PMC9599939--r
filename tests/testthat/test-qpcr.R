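test_that("the ddCt arithmetic is forced by the formula", {
  r <- compute_fold_change(c(25, 25, 25), c(20, 20, 20),
                           c(24, 24, 24), c(20, 20, 20))
  expect_equal(r$ddct, 1)
  expect_equal(r$fc, 0.5)
  expect_equal(r$category, "under")

  # equal delta-Cts give FC 1; ddCt of -1 gives FC 2
  r1 <- compute_fold_change(c(24, 24, 24), c(20, 20, 20),
                            c(24, 24, 24), c(20, 20, 20))
  expect_equal(r1$fc, 1)
  r2 <- compute_fold_change(c(23, 23, 23), c(20, 20, 20),
                            c(24, 24, 24), c(20, 20, 20))
  expect_equal(r2$fc, 2)

  # missing replicates tolerated, empty triplicate fatal
  r3 <- compute_fold_change(c(25, NA, NA), c(20, 20, 20),
                            c(24, 24, 24), c(20, 20, 20))
  expect_equal(r3$fc, 0.5)
  expect_error(compute_fold_change(c(NA, NA, NA), c(20, 20, 20),
                                   c(24, 24, 24), c(20, 20, 20)),
               "empty Ct triplicate")
  expect_warning(compute_fold_change(c(24, 26, 25), c(20, 20, 20),
                                     c(24, 24, 24), c(20, 20, 20)),
                 "replicate spread")
})

test_that("reciprocal symmetry: fc(ddct) * fc(-ddct) = 1", {
  for (shift in c(-3, -1.5, -0.25, 0, 0.25, 1.5, 3)) {
    up <- compute_fold_change(rep(24 + shift, 3), rep(20, 3),
                              rep(24, 3), rep(20, 3))
    down <- compute_fold_change(rep(24 - shift, 3), rep(20, 3),
                                rep(24, 3), rep(20, 3))
    expect_equal(up$fc * down$fc, 1)
  }
})

test_that("expression categories use closed abnormal cutoffs", {
  expect_equal(classify_expression(0.36), "under")
  expect_equal(classify_expression(2.77), "over")
  expect_equal(classify_expression(1.05), "normal")
  expect_equal(classify_expression(c(0.5, 2.0)), c("under", "over"))
  expect_equal(classify_expression(c(0.5001, 1.9999)), c("normal", "normal"))
  expect_error(classify_expression(0), "positive")

  # monotone non-decreasing with exactly two cut points
  grid <- sort(c(seq(0.01, 4, by = 0.01), 0.5, 2))
  ord <- c(under = 1, normal = 2, over = 3)[classify_expression(grid)]
  expect_true(all(diff(ord) >= 0))
  expect_equal(sum(diff(ord) > 0), 2L)
})

test_that("case-average expression is the arithmetic mean of probe FCs", {
  expect_equal(case_average_expression(c(0.5, 2.0)),
               list(mean_fc = 1.25, category = "normal"))
  expect_equal(case_average_expression(rep(1, 11))$mean_fc, 1)
  expect_equal(case_average_expression(c(NA, 3, 5))$mean_fc, 4)
  expect_error(case_average_expression(NA_real_), "no probes")
})

test_that("probe frequency distribution applies the <5-case exclusion", {
  tab <- rbind(
    data.frame(case_id = sprintf("c%02d", 1:10), probe_id = "pA", fc = 3),
    data.frame(case_id = sprintf("c%02d", 1:4), probe_id = "pB", fc = 1)
  )
  freq <- probe_frequency_distribution(tab)
  expect_equal(freq$probe_id, "pA")
  expect_equal(freq$freq_over, 1)
  expect_equal(freq$freq_over + freq$freq_normal + freq$freq_under, 1,
               tolerance = 1e-12)
  expect_equal(freq$median_fc, 3)
  expect_error(probe_frequency_distribution(tab[0, ]), "empty")
})

test_that("fold_change_table pairs tissues and reports missing assays", {
  cfg <- synthetic_config(ct_sd = 0.05, seed = 8)
  ct <- generate_expression_assays("k1", c(pA = 0.5, pB = -1), cfg)
  fc <- fold_change_table(ct)
  expect_equal(nrow(fc), 2L)
  expect_equal(sort(fc$probe_id), c("pA", "pB"))
  expect_equal(fc$fc[fc$probe_id == "pA"], 2^0.5, tolerance = 0.2)

  broken <- ct[!(ct$tissue == "normal" & ct$probe_id == "pA"), ]
  expect_error(fold_change_table(broken), "paired-assay")
})
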