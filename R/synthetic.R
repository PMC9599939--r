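#' Configuration of the synthetic-cohort generator
#'
#' The generator emulates the study conditions of a paired tumor/normal
#' SNP-array + qPCR + miRNA-array cohort on a single two-megabase gene:
#' 888 intronic SNPs on one chromosome, piecewise-constant tumor LRR with
#' Gaussian noise, BAF mixtures around 0, 0.5 and 1 shifted by planted
#' AI/LOH, triplicate Ct values with replicate noise, planted monotone
#' SNP-to-expression couplings, and exponential survival with
#' group-dependent hazards.
#'
#' @param n_cases number of tumor/normal pairs (default 56).
#' @param n_snps number of SNP markers (default 888).
#' @param gene_span base-pair span of the gene (default the 2 Mb region
#'   chr8:2,935,353-4,994,806).
#' @param chrom chromosome label (default `"chr8"`).
#' @param n_exons number of exons; intron indices run 1..(n_exons-1)
#'   (default 70).
#' @param noise_sd_lrr standard deviation of the Gaussian LRR noise
#'   (default 0.1).
#' @param baf_sd standard deviation of BAF noise around cluster centers
#'   (default 0.04).
#' @param het_fraction probability that a SNP is germline-heterozygous
#'   (default 0.27, the array's mean heterozygosity).
#' @param ct_sd triplicate Ct replicate noise in cycles (default 0.1).
#' @param state_means named numeric vector of per-state LRR means.
#' @param seed integer seed from which all generator randomness flows.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 56L, n_snps = 888L,
                             gene_span = c(2935353L, 4994806L),
                             chrom = "chr8", n_exons = 70L,
                             noise_sd_lrr = 0.1, baf_sd = 0.04,
                             het_fraction = 0.27, ct_sd = 0.1,
                             state_means = c(neutral = 0, gain = 0.58,
                                             high_gain = 1.3, loss = -0.7,
                                             big_loss = -1.5),
                             seed = 1L) {
  if (n_snps < 3L) stop("invalid config: n_snps must be >= 3")
  if (n_cases < 1L) stop("invalid config: n_cases must be >= 1")
  if (!(noise_sd_lrr > 0)) stop("invalid config: noise_sd_lrr must be > 0")
  if (!(het_fraction > 0 && het_fraction < 1)) {
    stop("invalid config: het_fraction must be in (0, 1)")
  }
  if (!(gene_span[1] < gene_span[2])) {
    stop("invalid config: gene_span start must be < end")
  }
  need <- c("neutral", "gain", "high_gain", "loss", "big_loss")
  if (!all(need %in% names(state_means))) {
    stop("state_means must name all of: ", paste(need, collapse = ", "))
  }
  structure(list(n_cases = as.integer(n_cases), n_snps = as.integer(n_snps),
                 gene_span = as.integer(gene_span), chrom = chrom,
                 n_exons = as.integer(n_exons), noise_sd_lrr = noise_sd_lrr,
                 baf_sd = baf_sd, het_fraction = het_fraction, ct_sd = ct_sd,
                 state_means = state_means, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate the SNP annotation table
#'
#' Markers with strictly increasing positions inside the gene span, each
#' assigned an intron index (1..n_exons-1, increasing along the gene) and
#' a pair of alleles. Deterministic for a fixed config seed.
#'
#' @param config a [synthetic_config()] object.
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `intron`,
#'   `allele_a`, `allele_b`.
#' @export
generate_snp_map <- function(config = synthetic_config()) {
  set.seed(config$seed)
  span <- config$gene_span
  pos <- sort(sample(seq(span[1], span[2]), config$n_snps))
  intron <- pmin(config$n_exons - 1L,
                 1L + floor((pos - span[1]) / (span[2] - span[1] + 1) *
                              (config$n_exons - 1L)))
  nts <- c("A", "C", "G", "T")
  allele_a <- sample(nts, config$n_snps, replace = TRUE)
  allele_b <- vapply(allele_a, function(a) sample(setdiff(nts, a), 1L),
                     character(1), USE.NAMES = FALSE)
  data.frame(
    snp_id = sprintf("snp%04d", seq_len(config$n_snps)),
    chrom = config$chrom,
    pos = pos,
    intron = as.integer(intron),
    allele_a = allele_a,
    allele_b = allele_b,
    stringsAsFactors = FALSE
  )
}

.check_scenario <- function(scenario, n_snps) {
  if (is.null(scenario) || nrow(scenario) == 0L) return(invisible(NULL))
  req <- c("start", "end", "cn_state", "allelic_state")
  if (!all(req %in% names(scenario))) {
    stop("scenario needs columns: ", paste(req, collapse = ", "))
  }
  if (any(scenario$start < 1L | scenario$end > n_snps |
          scenario$start > scenario$end)) {
    stop("scenario segments must satisfy 1 <= start <= end <= n_snps")
  }
  s <- scenario[order(scenario$start), , drop = FALSE]
  if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)])) {
    stop("scenario segments overlap")
  }
  invisible(NULL)
}

#' Generate one case's tumor LRR/BAF profile from planted segments
#'
#' Tumor LRR is the per-state mean plus Gaussian noise; SNPs outside every
#' planted segment are copy-neutral and allelically balanced. Germline
#' genotypes are heterozygous with probability `het_fraction`. For
#' heterozygous SNPs the tumor BAF is centered at 0.5 (balanced), shifted
#' mirrored-symmetrically into the AI bands, or pushed outside \[0.2, 0.8\]
#' for LOH; homozygous SNPs cluster near 0 or 1 regardless of state.
#'
#' @param snp_map output of [generate_snp_map()].
#' @param scenario data.frame of planted segments with columns `start`,
#'   `end` (1-based inclusive SNP indices), `cn_state`, `allelic_state`;
#'   NULL or zero rows plants nothing.
#' @param config a [synthetic_config()] object.
#' @param case_seed seed for this case's randomness (default derived from
#'   the config seed).
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `genotype`,
#'   `lrr`, `baf`.
#' @export
generate_case_profile <- function(snp_map, scenario = NULL,
                                  config = synthetic_config(),
                                  case_seed = config$seed + 1L) {
  n <- nrow(snp_map)
  .check_scenario(scenario, n)
  set.seed(case_seed)

  cn_state <- rep("neutral", n)
  al_state <- rep("normal", n)
  if (!is.null(scenario) && nrow(scenario) > 0L) {
    for (k in seq_len(nrow(scenario))) {
      idx <- scenario$start[k]:scenario$end[k]
      cn_state[idx] <- scenario$cn_state[k]
      al_state[idx] <- scenario$allelic_state[k]
    }
  }

  lrr <- config$state_means[cn_state] +
    rnorm(n, 0, config$noise_sd_lrr)

  het <- runif(n) < config$het_fraction
  genotype <- ifelse(het, "AB", ifelse(runif(n) < 0.5, "AA", "BB"))

  baf <- numeric(n)
  hom <- !het
  # homozygous clusters near 0 / 1
  baf[hom] <- ifelse(genotype[hom] == "AA", 0, 1) +
    ifelse(genotype[hom] == "AA", 1, -1) * abs(rnorm(sum(hom), 0, config$baf_sd / 2))
  # heterozygous centers by allelic state, mirrored around 0.5
  hb <- which(het)
  side <- sample(c(-1, 1), length(hb), replace = TRUE)
  center <- numeric(length(hb))
  st <- al_state[hb]
  center[st == "normal"] <- 0.5
  center[st == "AI"] <- 0.5 + side[st == "AI"] * runif(sum(st == "AI"), 0.18, 0.22)
  center[st == "LOH"] <- 0.5 + side[st == "LOH"] * runif(sum(st == "LOH"), 0.40, 0.44)
  baf[hb] <- center + rnorm(length(hb), 0, config$baf_sd)
  baf <- pmin(1, pmax(0, baf))

  data.frame(
    snp_id = snp_map$snp_id,
    chrom = snp_map$chrom,
    pos = snp_map$pos,
    genotype = genotype,
    lrr = as.numeric(lrr),
    baf = baf,
    stringsAsFactors = FALSE
  )
}

#' Plant per-case alteration scenarios emulating the study's cohort mix
#'
#' Each case draws a composite alteration pattern with probabilities
#' matching the reference cohort (30% no alteration, 36% loss with LOH/AI,
#' 16% gain with AI, 11% AI only, 7% mixed gain and loss) and receives
#' planted segments of at least `min_len` SNPs.
#'
#' @param config a [synthetic_config()] object.
#' @param min_len minimum planted segment length in SNPs (default 30).
#' @return named list of scenario data.frames, one per case id.
#' @export
random_scenarios <- function(config = synthetic_config(), min_len = 30L) {
  set.seed(config$seed + 500L)
  n <- config$n_snps
  min_len <- max(3L, min(min_len, floor(n / 4)))
  kinds <- sample(c("none", "loss", "gain", "ai_only", "mixed"),
                  config$n_cases, replace = TRUE,
                  prob = c(0.30, 0.36, 0.16, 0.11, 0.07))
  span <- function() {
    len <- sample(min_len:max(min_len, floor(n / 2)), 1L)
    start <- sample(seq_len(n - len + 1L), 1L)
    c(start, start + len - 1L)
  }
  scen <- lapply(kinds, function(kind) {
    if (kind == "none") {
      return(data.frame(start = integer(), end = integer(),
                        cn_state = character(), allelic_state = character(),
                        stringsAsFactors = FALSE))
    }
    if (kind == "loss") {
      s <- span()
      al <- sample(c("LOH", "AI"), 1L, prob = c(0.25, 0.75))
      return(data.frame(start = s[1], end = s[2],
                        cn_state = sample(c("loss", "big_loss"), 1L,
                                          prob = c(0.85, 0.15)),
                        allelic_state = al, stringsAsFactors = FALSE))
    }
    if (kind == "gain") {
      s <- span()
      return(data.frame(start = s[1], end = s[2],
                        cn_state = sample(c("gain", "high_gain"), 1L,
                                          prob = c(0.85, 0.15)),
                        allelic_state = sample(c("AI", "normal"), 1L,
                                               prob = c(0.8, 0.2)),
                        stringsAsFactors = FALSE))
    }
    if (kind == "ai_only") {
      # copy-neutral AI leaves no LRR change-point, so it is planted at the
      # only granularity at which it is recoverable: the whole gene
      return(data.frame(start = 1L, end = n, cn_state = "neutral",
                        allelic_state = "AI", stringsAsFactors = FALSE))
    }
    # mixed: one gain and one loss segment in the two halves
    half <- floor(n / 2)
    len1 <- sample(min_len:max(min_len, half - 2L), 1L)
    st1 <- sample(seq_len(max(1L, half - len1)), 1L)
    len2 <- sample(min_len:max(min_len, half - 2L), 1L)
    st2 <- half + sample(seq_len(max(1L, n - half - len2)), 1L)
    data.frame(start = c(st1, st2), end = c(st1 + len1 - 1L, st2 + len2 - 1L),
               cn_state = c("gain", "loss"),
               allelic_state = c("AI", sample(c("AI", "LOH"), 1L)),
               stringsAsFactors = FALSE)
  })
  names(scen) <- sprintf("case%03d", seq_len(config$n_cases))
  scen
}

#' Generate triplicate Ct assays realizing planted expression fold changes
#'
#' For each probe the true tumor/normal log2 fold change is realized
#' through the Ct arithmetic: the tumor's delta-Ct is shifted by
#' `-log2fc` cycles relative to the normal's, so the 2^-ddCt pipeline
#' recovers `2^log2fc` up to triplicate noise.
#'
#' @param case_id case identifier.
#' @param probe_log2fc named numeric vector of planted per-probe log2 fold
#'   changes.
#' @param config a [synthetic_config()] object.
#' @param case_seed per-case seed.
#' @param base_target_ct,base_ref_ct baseline mean Ct of the target gene
#'   and the reference gene in normal tissue (cycles).
#' @return data.frame in the long Ct dialect: `case_id`, `probe_id`,
#'   `tissue`, `target`, `rep1`, `rep2`, `rep3`.
#' @export
generate_expression_assays <- function(case_id, probe_log2fc,
                                       config = synthetic_config(),
                                       case_seed = config$seed + 2L,
                                       base_target_ct = 26,
                                       base_ref_ct = 18) {
  if (any(!is.finite(probe_log2fc))) stop("planted shifts must be finite")
  set.seed(case_seed)
  probes <- names(probe_log2fc)
  if (is.null(probes)) stop("probe_log2fc must be named by probe id")
  rows <- lapply(probes, function(p) {
    dct_normal <- base_target_ct - base_ref_ct
    dct_tumor <- dct_normal - probe_log2fc[[p]]
    tri <- function(m) m + rnorm(3L, 0, config$ct_sd)
    rbind(
      data.frame(case_id = case_id, probe_id = p, tissue = "tumor",
                 target = "target",
                 t(setNames(tri(base_ref_ct + dct_tumor),
                            c("rep1", "rep2", "rep3")))),
      data.frame(case_id = case_id, probe_id = p, tissue = "tumor",
                 target = "reference",
                 t(setNames(tri(base_ref_ct), c("rep1", "rep2", "rep3")))),
      data.frame(case_id = case_id, probe_id = p, tissue = "normal",
                 target = "target",
                 t(setNames(tri(base_ref_ct + dct_normal),
                            c("rep1", "rep2", "rep3")))),
      data.frame(case_id = case_id, probe_id = p, tissue = "normal",
                 target = "reference",
                 t(setNames(tri(base_ref_ct), c("rep1", "rep2", "rep3"))))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate exponential survival records with group-dependent hazards
#'
#' Event times are exponential with baseline hazard `hazard` per month for
#' the `low` group and `hazard * hazard_ratio` for the `high` group.
#' Censoring times are independent exponentials scaled so the expected
#' censored fraction equals `censor_rate`; `censor_rate = 0` observes every
#' event.
#'
#' @param group character/factor vector of `"low"`/`"high"` group labels.
#' @param hazard baseline hazard per month (default 0.03, median survival
#'   about 23 months).
#' @param hazard_ratio hazard multiplier for the `high` group (must be > 0).
#' @param censor_rate expected fraction censored, in \[0, 1).
#' @param seed RNG seed.
#' @return data.frame with `case_id`, `months`, `event`, `group`.
#' @export
generate_survival <- function(group, hazard = 0.03, hazard_ratio = 1,
                              censor_rate = 0, seed = 1L) {
  if (!(hazard_ratio > 0)) stop("invalid config: hazard_ratio must be > 0")
  if (!(censor_rate >= 0 && censor_rate < 1)) {
    stop("invalid config: censor_rate must be in [0, 1)")
  }
  set.seed(seed)
  n <- length(group)
  rate <- hazard * ifelse(group == "high", hazard_ratio, 1)
  tevent <- rexp(n, rate)
  if (censor_rate > 0) {
    crate <- rate * censor_rate / (1 - censor_rate)
    tcens <- rexp(n, crate)
    months <- pmin(tevent, tcens)
    event <- as.integer(tevent <= tcens)
  } else {
    months <- tevent
    event <- rep(1L, n)
  }
  data.frame(case_id = if (!is.null(names(group))) names(group) else
               sprintf("case%03d", seq_len(n)),
             months = months, event = event,
             group = as.character(group), stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort with planted ground truth
#'
#' Orchestrates the per-stage generators into one cohort: SNP map, per-case
#' tumor LRR/BAF profiles with planted segments, triplicate Ct tables for
#' the exon-boundary probes, a miRNA fold-change table with detection
#' flags, a clinical table with exponential survival, and a `truth` record
#' holding every planted segment, expression shift, SNP-probe coupling and
#' the survival hazard ratio.
#'
#' Couplings tie a probe's log2 fold change to the case's mean LRR at a
#' planted-segment SNP (monotone, slope `coupling_strength`), so the
#' correlation stage has recoverable signal.
#'
#' @param config a [synthetic_config()] object.
#' @param n_probes number of exon-boundary probes (default 11).
#' @param mir_ids miRNA identifiers (default the packaged 22-miR target
#'   list).
#' @param n_couplings number of planted SNP-probe couplings (default 6).
#' @param coupling_strength log2-FC change per unit LRR (default 2).
#' @param hazard_ratio planted hazard ratio of the high-FC group
#'   (default 1).
#' @param censor_rate expected censored fraction (default 0.05).
#' @return list with `snp_map`, `profiles`, `ct`, `mir`, `clinical`,
#'   `truth`.
#' @export
generate_cohort <- function(config = synthetic_config(), n_probes = 11L,
                            mir_ids = NULL, n_couplings = 6L,
                            coupling_strength = 2, hazard_ratio = 1,
                            censor_rate = 0.05) {
  snp_map <- generate_snp_map(config)
  scenarios <- random_scenarios(config)
  case_ids <- names(scenarios)

  profiles <- do.call(rbind, lapply(seq_along(case_ids), function(i) {
    p <- generate_case_profile(snp_map, scenarios[[i]], config,
                               case_seed = config$seed + 1000L + i)
    cbind(case_id = case_ids[i], p, stringsAsFactors = FALSE)
  }))

  probe_ids <- sprintf("exon %d-%d", seq_len(n_probes), seq_len(n_probes) + 1L)
  if (is.null(mir_ids)) mir_ids <- target_mirs()

  # planted expression structure
  set.seed(config$seed + 2000L)
  case_effect <- rnorm(config$n_cases, 0.4, 1.2)   # broad per-case FC spread
  probe_effect <- rnorm(n_probes, 0, 0.6)
  altered_cases <- vapply(scenarios, function(s) nrow(s) > 0L, logical(1))
  snps_in_segments <- unique(unlist(lapply(scenarios[altered_cases], function(s) {
    unlist(mapply(seq, s$start, s$end, SIMPLIFY = FALSE))
  })))
  couplings <- data.frame(snp_id = character(), probe_id = character(),
                          sign = numeric(), stringsAsFactors = FALSE)
  if (n_couplings > 0L && length(snps_in_segments) > 0L) {
    cs <- sample(snps_in_segments, min(n_couplings, length(snps_in_segments)))
    couplings <- data.frame(
      snp_id = snp_map$snp_id[cs],
      probe_id = sample(probe_ids, length(cs), replace = TRUE),
      sign = sample(c(1, -1), length(cs), replace = TRUE, prob = c(0.8, 0.2)),
      stringsAsFactors = FALSE
    )
  }

  lrr_mat <- lrr_matrix(profiles)
  probe_log2fc <- outer(case_effect, probe_effect, `+`)
  dimnames(probe_log2fc) <- list(case_ids, probe_ids)
  for (k in seq_len(nrow(couplings))) {
    probe_log2fc[, couplings$probe_id[k]] <-
      probe_log2fc[, couplings$probe_id[k]] +
      couplings$sign[k] * coupling_strength * lrr_mat[, couplings$snp_id[k]]
  }

  ct <- do.call(rbind, lapply(seq_along(case_ids), function(i) {
    generate_expression_assays(case_ids[i], probe_log2fc[i, ], config,
                               case_seed = config$seed + 3000L + i)
  }))

  # miRNA: mostly-overexpressed cohort, detection filter at work
  set.seed(config$seed + 4000L)
  mir_case_effect <- rnorm(config$n_cases, 1.3, 1.1)
  mir_effect <- rnorm(length(mir_ids), 0, 0.8)
  mir <- do.call(rbind, lapply(seq_along(case_ids), function(i) {
    l2 <- mir_case_effect[i] + mir_effect + rnorm(length(mir_ids), 0, 0.5)
    data.frame(case_id = case_ids[i], mir_id = mir_ids,
               tumor_detected = runif(length(mir_ids)) < 0.95,
               normal_detected = runif(length(mir_ids)) < 0.95,
               fc = 2^l2, stringsAsFactors = FALSE)
  }))
  mir$fc[!(mir$tumor_detected & mir$normal_detected)] <- NA_real_

  # clinical: survival grouped by planted case-level expression
  group <- setNames(ifelse(2^case_effect >= 1, "high", "low"), case_ids)
  surv <- generate_survival(group, hazard_ratio = hazard_ratio,
                            censor_rate = censor_rate,
                            seed = config$seed + 5000L)
  set.seed(config$seed + 6000L)
  clinical <- data.frame(
    case_id = case_ids,
    months = surv$months,
    event = surv$event,
    family_history = as.integer(runif(config$n_cases) < 17 / 56),
    lymph_node = as.integer(runif(config$n_cases) < 31 / 56),
    stringsAsFactors = FALSE
  )

  truth <- list(scenarios = scenarios, probe_log2fc = probe_log2fc,
                couplings = couplings, hazard_ratio = hazard_ratio,
                group = group)
  list(snp_map = snp_map, profiles = profiles, ct = ct, mir = mir,
       clinical = clinical, truth = truth)
}

#' Tumor LRR matrix (cases x SNPs) from a long profile table
#'
#' @param profiles long data.frame with `case_id`, `snp_id`, `lrr`.
#' @return numeric matrix with case ids as rows and SNP ids as columns.
#' @export
lrr_matrix <- function(profiles) {
  cases <- unique(profiles$case_id)
  snps <- unique(profiles$snp_id)
  m <- matrix(NA_real_, length(cases), length(snps),
              dimnames = list(cases, snps))
  m[cbind(match(profiles$case_id, cases), match(profiles$snp_id, snps))] <-
    profiles$lrr
  m
}
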