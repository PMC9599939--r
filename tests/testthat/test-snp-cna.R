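test_that("CN classification honors the printed boundary semantics", {
  expect_equal(classify_segment_cn(1.0), "high_gain")
  expect_equal(classify_segment_cn(0.2), "neutral")   # gain is strict
  expect_equal(classify_segment_cn(-0.2), "neutral")  # loss is strict
  expect_equal(classify_segment_cn(-0.5), "loss")
  expect_equal(classify_segment_cn(-1.0), "big_loss")
  expect_equal(classify_segment_cn(c(0.21, 0.99, -0.21, -0.99)),
               c("gain", "gain", "loss", "loss"))
  expect_error(classify_segment_cn(NaN), "finite")

  # total, piecewise-constant and monotone in mean LRR
  grid <- seq(-2, 2, by = 0.01)
  ord <- c(big_loss = 1, loss = 2, neutral = 3, gain = 4, high_gain = 5)
  expect_true(all(diff(ord[classify_segment_cn(grid)]) >= 0))
})

test_that("BAF classification restricts AI/LOH to informative het SNPs", {
  expect_equal(classify_snp_baf(0.30, "AB"), "AI")
  expect_equal(classify_snp_baf(0.90, "AB"), "LOH")
  expect_equal(classify_snp_baf(0.95, "AA"), "not_informative")
  expect_equal(classify_snp_baf(0.5, "AB"), "normal")
  # AI bands closed, LOH strict
  expect_equal(classify_snp_baf(c(0.20, 0.45, 0.55, 0.80), rep("AB", 4)),
               rep("AI", 4))
  expect_equal(classify_snp_baf(c(0.199, 0.801), c("AB", "AB")),
               c("LOH", "LOH"))
  expect_equal(classify_snp_baf(c(0.46, 0.54), c("AB", "AB")),
               c("normal", "normal"))
  expect_equal(classify_snp_baf(0.3, NA_character_), "not_informative")
  expect_error(classify_snp_baf(1.2, "AB"), "\\[0, 1\\]")
})

test_that("segmentation tiles the profile and finds no spurious splits", {
  set.seed(21)
  pos <- sort(sample(2e6, 30))
  expect_equal(nrow(segment_lrr(pos, rnorm(30, 0, 0.05))), 1L)

  # tiling/disjointness on noisy multi-step profiles
  for (s in 1:5) {
    set.seed(100 + s)
    x <- c(rnorm(40, 0, 0.1), rnorm(40, -0.7, 0.1), rnorm(40, 0.6, 0.1))
    pos <- sort(sample(2e6, 120))
    segs <- segment_lrr(pos, x)
    expect_equal(segs$start[1], 1L)
    expect_equal(segs$end[nrow(segs)], 120L)
    if (nrow(segs) > 1L) {
      expect_equal(segs$start[-1], segs$end[-nrow(segs)] + 1L)
    }
    expect_true(all(segs$n_probes >= 3))
  }
  expect_error(segment_lrr(c(1, 2, 3), c(NA, NA, 0.1)), "min_probes")
})

test_that("segmentation recovers a planted step boundary", {
  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    x <- c(rnorm(50, 0, 0.05), rnorm(50, 1.3, 0.05))
    pos <- sort(sample(2e6, 100))
    segs <- segment_lrr(pos, x)
    nrow(segs) == 2L && abs(segs$end[1] - 50L) <= 2L
  }, logical(1))
  expect_true(all(hits))
})

test_that("the first split matches exhaustive search on short profiles", {
  for (s in 1:20) {
    set.seed(300 + s)
    n <- sample(8:20, 1)
    x <- rnorm(n) + rep(c(0, sample(c(0, 1, -1.2), 1)),
                        c(floor(n / 2), ceiling(n / 2)))
    ours <- cnaexpr:::.best_split(x, 3L)
    oracle <- oracle_best_split(x, 3L)
    expect_equal(ours$index, oracle$index)
    expect_equal(ours$stat, oracle$stat, tolerance = 1e-10)
  }
})

test_that("probe gaps beyond the max spacing force segment boundaries", {
  set.seed(31)
  pos <- c(seq(1e4, by = 1e3, length.out = 50),
           seq(3e6, by = 1e3, length.out = 50))  # ~3 Mb gap
  x <- rnorm(100, 0, 0.05)  # no signal at all
  segs <- segment_lrr(pos, x)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$end[1], 50L)
})

test_that("composite case categories come out of planted profiles", {
  params <- segmentation_params()
  # all neutral / balanced
  p <- make_profile(seed = 1)
  expect_equal(call_case_alterations(p)$category, "not observed")

  # gain segment with AI
  p <- make_profile(n = 80,
                    lrr = rep(c(0, 0.58, 0), c(25, 30, 25)),
                    baf_center = rep(c(0.5, 0.30, 0.5), c(25, 30, 25)),
                    noise = 0.02, seed = 2)
  res <- call_case_alterations(p)
  expect_equal(res$category, "Allelic Imbalance, CN Gain")

  # loss segment whose het BAFs sit above 0.8
  p <- make_profile(n = 80,
                    lrr = rep(c(0, -0.7, 0), c(25, 30, 25)),
                    baf_center = rep(c(0.5, 0.92, 0.5), c(25, 30, 25)),
                    noise = 0.02, seed = 3)
  expect_equal(call_case_alterations(p)$category, "CN Loss, LOH")
})

test_that("LOH takes precedence over AI at the het-fraction rule", {
  # half the informative SNPs in the LOH band, half in the AI band
  p <- make_profile(n = 40, lrr = rep(0, 40),
                    baf_center = rep(c(0.9, 0.3), each = 20),
                    noise = 1e-4, seed = 4)
  res <- call_case_alterations(p, min_het_fraction = 0.5)
  expect_equal(res$segments$allelic_state, "LOH")

  # homozygous-only segment is indeterminate, not LOH
  p <- make_profile(n = 40, genotype = rep("AA", 40),
                    baf_center = rep(0.0, 40), noise = 1e-4, seed = 5)
  expect_equal(call_case_alterations(p)$segments$allelic_state,
               "indeterminate")
})

test_that("cohort alteration summary counts the composite groups", {
  cats <- c("Allelic Imbalance", "CN Gain", "CN Loss, LOH",
            "Allelic Imbalance, CN Gain, CN Loss", "not observed")
  s <- summarize_cohort_alterations(cats)
  expect_equal(s$n_altered, 4L)
  expect_equal(s$loss_loh_no_gain, 1L)
  expect_equal(s$gain_no_loss_loh, 1L)
  expect_equal(s$ai_only, 1L)
  expect_equal(s$mixed_gain_loss, 1L)
  expect_equal(summarize_cohort_alterations(rep("not observed", 5))$pct_altered, 0)
  expect_error(summarize_cohort_alterations(character(0)), "empty")
  expect_error(parse_category("CN Something"), "unknown")
})

test_that("per-SNP CNA membership feeds the correlation subset", {
  p <- make_profile(n = 60, lrr = rep(c(0, -0.7), c(30, 30)), noise = 0.02,
                    seed = 6)
  p2 <- make_profile(n = 60, lrr = rep(0, 60), noise = 0.02, seed = 7)
  profiles <- rbind(cbind(case_id = "c1", p, stringsAsFactors = FALSE),
                    cbind(case_id = "c2", p2, stringsAsFactors = FALSE))
  calls <- call_cohort_alterations(profiles)
  subset1 <- cna_snp_subset(calls$snp_calls, min_cases = 1)
  expect_setequal(subset1, sprintf("s%03d", 31:60))
  expect_length(cna_snp_subset(calls$snp_calls, min_cases = 2), 0L)
})
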