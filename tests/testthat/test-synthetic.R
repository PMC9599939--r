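test_that("SNP map stays inside the gene span, is ordered, and is deterministic", {
  cfg <- synthetic_config(seed = 42)
  m <- generate_snp_map(cfg)
  expect_equal(nrow(m), 888L)
  expect_true(all(m$pos >= 2935353 & m$pos <= 4994806))
  expect_true(all(diff(m$pos) > 0))
  expect_true(all(m$intron >= 1 & m$intron <= 69))
  expect_true(all(m$allele_a != m$allele_b))
  expect_identical(m, generate_snp_map(cfg))

  tiny <- generate_snp_map(synthetic_config(n_snps = 3, seed = 42))
  expect_equal(nrow(tiny), 3L)
  expect_true(all(diff(tiny$pos) > 0))

  expect_error(synthetic_config(n_snps = 0), "n_snps")
  expect_error(synthetic_config(het_fraction = 1.2), "het_fraction")
  expect_error(synthetic_config(gene_span = c(10, 5)), "gene_span")
})

test_that("case profiles realize planted LRR states inside their CN windows", {
  cfg <- synthetic_config(n_snps = 60, noise_sd_lrr = 0.01, seed = 7)
  m <- generate_snp_map(cfg)
  p0 <- generate_case_profile(m, NULL, cfg, case_seed = 7)
  expect_true(all(abs(p0$lrr) < 0.05))

  # Monte-Carlo separability at the maximum noise the generator promises:
  # segment means of a planted gain must land in the (0.2, 1.0) window
  cfg <- synthetic_config(n_snps = 60, noise_sd_lrr = 0.15, seed = 7)
  scen <- data.frame(start = 21L, end = 50L, cn_state = "gain",
                     allelic_state = "normal")
  means <- vapply(seq_len(1000), function(s) {
    p <- generate_case_profile(m, scen, cfg, case_seed = 10000 + s)
    mean(p$lrr[21:50])
  }, numeric(1))
  expect_gte(mean(means > 0.2 & means < 1.0), 0.99)
})

test_that("planted LOH pushes heterozygous BAF outside the 0.2-0.8 band", {
  cfg <- synthetic_config(n_snps = 80, baf_sd = 0.05, het_fraction = 0.5,
                          seed = 11)
  m <- generate_snp_map(cfg)
  scen <- data.frame(start = 1L, end = 80L, cn_state = "neutral",
                     allelic_state = "LOH")
  prop <- vapply(seq_len(200), function(s) {
    p <- generate_case_profile(m, scen, cfg, case_seed = 20000 + s)
    het <- p$genotype == "AB"
    mean(p$baf[het] < 0.2 | p$baf[het] > 0.8)
  }, numeric(1))
  expect_gte(mean(prop), 0.90)
})

test_that("scenario validation rejects overlap and out-of-range segments", {
  cfg <- synthetic_config(n_snps = 50, seed = 1)
  m <- generate_snp_map(cfg)
  overlap <- data.frame(start = c(1L, 20L), end = c(25L, 40L),
                        cn_state = c("gain", "loss"),
                        allelic_state = c("normal", "normal"))
  expect_error(generate_case_profile(m, overlap, cfg), "overlap")
  oob <- data.frame(start = 10L, end = 60L, cn_state = "gain",
                    allelic_state = "normal")
  expect_error(generate_case_profile(m, oob, cfg), "n_snps")
})

test_that("Ct assays realize planted shifts through the 2^-ddCt pipeline", {
  cfg <- synthetic_config(ct_sd = 1e-6, seed = 3)
  ct <- generate_expression_assays("caseA", c(p1 = 0, p2 = 1, p3 = -2), cfg)
  fc <- fold_change_table(ct)
  fc <- fc[match(c("p1", "p2", "p3"), fc$probe_id), ]
  expect_equal(fc$fc, c(1, 2, 0.25), tolerance = 1e-4)
  # planted shift of -1 ddCt cycle is a planted log2 FC of +1, i.e. FC 2
  expect_equal(fc$ddct[2], -1, tolerance = 1e-4)
  expect_error(generate_expression_assays("c", c(p1 = NaN), cfg), "finite")
})

test_that("survival generator honors censoring, determinism and the null", {
  g <- rep(c("low", "high"), each = 30)
  s0 <- generate_survival(g, censor_rate = 0, seed = 5)
  expect_true(all(s0$event == 1))
  expect_identical(s0, generate_survival(g, censor_rate = 0, seed = 5))
  expect_error(generate_survival(g, hazard_ratio = -1), "hazard_ratio")
  expect_error(generate_survival(g, censor_rate = 1), "censor_rate")

  # under HR = 1 the log-rank p-value is uniform (KS test, alpha = 0.01)
  pvals <- vapply(seq_len(500), function(i) {
    s <- generate_survival(g, hazard_ratio = 1, censor_rate = 0,
                           seed = 30000 + i)
    km_logrank(s$months, s$event, s$group)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("planted truth is complete and internally consistent", {
  cfg <- synthetic_config(n_cases = 12, n_snps = 120, seed = 9)
  cohort <- generate_cohort(cfg, n_couplings = 4)
  tr <- cohort$truth
  expect_length(tr$scenarios, 12L)
  for (s in tr$scenarios) {
    if (nrow(s) == 0L) next
    expect_true(all(s$start >= 1 & s$end <= 120 & s$start <= s$end))
    s <- s[order(s$start), ]
    if (nrow(s) > 1L) expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  }
  expect_true(all(tr$couplings$snp_id %in% cohort$snp_map$snp_id))
  expect_true(all(tr$couplings$probe_id %in% colnames(tr$probe_log2fc)))
  expect_equal(dim(tr$probe_log2fc), c(12L, 11L))
  # identical config + seed reproduces the cohort bitwise
  cohort2 <- generate_cohort(cfg, n_couplings = 4)
  expect_identical(cohort, cohort2)
})

test_that("a noise-free planted coupling yields a perfectly monotone pair", {
  cfg <- synthetic_config(n_cases = 30, n_snps = 40, noise_sd_lrr = 1e-6,
                          ct_sd = 1e-9, seed = 13)
  m <- generate_snp_map(cfg)
  set.seed(13)
  lrr <- rnorm(30)
  fc_log2 <- 1.5 * lrr  # exact monotone coupling, noise off
  sp <- spearman(lrr, 2^fc_log2)
  expect_equal(sp$rho, 1.0)
})
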