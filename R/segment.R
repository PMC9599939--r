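#' Segmentation parameters
#'
#' Controls the recursive binary segmentation of the tumor LRR profile:
#' a candidate change-point is accepted when its permutation p-value falls
#' below `significance_threshold` and both children retain at least
#' `min_probes` SNPs; any inter-SNP gap larger than `max_probe_spacing`
#' base pairs forces a segment boundary regardless of signal.
#'
#' @param significance_threshold permutation p-value below which a split is
#'   accepted (default 5.0e-6).
#' @param max_probe_spacing maximum contiguous probe spacing in base pairs
#'   (default 1e6, i.e. 1000 kbp).
#' @param min_probes minimum number of probes per segment (default 3).
#' @param n_permutations number of label permutations used to estimate the
#'   p-value of the best split (default 10000).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(significance_threshold = 5.0e-6,
                                max_probe_spacing = 1e6,
                                min_probes = 3L,
                                n_permutations = 10000L) {
  if (!(significance_threshold > 0 && significance_threshold < 1)) {
    stop("significance_threshold must be in (0, 1)")
  }
  if (min_probes < 2L) stop("min_probes must be >= 2")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  structure(list(significance_threshold = significance_threshold,
                 max_probe_spacing = max_probe_spacing,
                 min_probes = as.integer(min_probes),
                 n_permutations = as.integer(n_permutations)),
            class = "segmentation_params")
}

# Two-sample t statistic of every admissible split of x into x[1:i] and
# x[(i+1):n]; returns the max |t| and its index, computed in O(n) from
# cumulative sums. A split with zero pooled variance but distinct means is
# treated as infinitely strong.
.best_split <- function(x, min_probes) {
  n <- length(x)
  i <- seq_len(n - 1L)
  ok <- i >= min_probes & (n - i) >= min_probes
  if (!any(ok)) return(list(stat = -Inf, index = NA_integer_))
  cs <- cumsum(x)
  tot <- cs[n]
  ss_tot <- sum(x * x)
  m1 <- cs[i] / i
  m2 <- (tot - cs[i]) / (n - i)
  ss_within <- ss_tot - i * m1^2 - (n - i) * m2^2
  ss_within[ss_within < 0] <- 0  # numeric guard
  pooled_var <- ss_within / (n - 2L)
  se <- sqrt(pooled_var * (1 / i + 1 / (n - i)))
  tstat <- abs(m1 - m2) / se
  tstat[se == 0 & abs(m1 - m2) > 0] <- Inf
  tstat[se == 0 & abs(m1 - m2) == 0] <- 0
  tstat[!ok] <- -Inf
  k <- which.max(tstat)
  list(stat = tstat[k], index = k)
}

# Permutation p-value of the observed max-|t| split statistic, estimated as
# (exceedances)/B with early stopping once the exceedance count can no
# longer come in under the acceptance threshold. The permutation loop runs
# in compiled code (src/perm.cpp) and draws from R's RNG, so it follows
# set.seed().
.split_pvalue <- function(x, observed, params) {
  if (!is.finite(observed)) {
    # infinite statistic (perfect step): no permutation can exceed it
    if (observed > 0) return(0)
    return(1)
  }
  B <- params$n_permutations
  allow <- floor(params$significance_threshold * B)
  res <- .perm_exceed(x, observed, B, allow, params$min_probes)
  res$exceed / res$done
}

.segment_recursive <- function(x, offset, params) {
  n <- length(x)
  if (n < 2L * params$min_probes) {
    return(data.frame(start = offset, end = offset + n - 1L))
  }
  bs <- .best_split(x, params$min_probes)
  if (!is.na(bs$index)) {
    p <- .split_pvalue(x, bs$stat, params)
    if (p < params$significance_threshold) {
      left <- .segment_recursive(x[seq_len(bs$index)], offset, params)
      right <- .segment_recursive(x[(bs$index + 1L):n],
                                  offset + bs$index, params)
      return(rbind(left, right))
    }
  }
  data.frame(start = offset, end = offset + n - 1L)
}

#' Segment a tumor LRR profile into constant-mean runs
#'
#' Recursive binary segmentation: at each step the split maximizing the
#' two-sample t statistic of mean LRR is evaluated against a permutation
#' null, and accepted when its estimated p-value falls below the
#' significance threshold with both children at least `min_probes` long.
#' Probe gaps larger than `max_probe_spacing` force boundaries first. The
#' returned segments tile the SNP index range exactly.
#'
#' @param pos integer/numeric vector of strictly increasing SNP positions
#'   (base pairs).
#' @param lrr numeric vector of tumor log R ratios, same length as `pos`.
#' @param params a [segmentation_params()] object.
#' @return data.frame with one row per segment: `start`, `end` (1-based
#'   inclusive SNP indices), `start_pos`, `end_pos`, `n_probes`,
#'   `mean_lrr`.
#' @export
segment_lrr <- function(pos, lrr, params = segmentation_params()) {
  if (length(pos) != length(lrr)) stop("pos and lrr lengths differ")
  if (any(diff(pos) <= 0)) stop("positions must be strictly increasing")
  finite <- is.finite(lrr)
  if (sum(finite) < params$min_probes) {
    stop("segment_lrr: fewer than min_probes finite LRR values")
  }
  n <- length(lrr)
  # gap-forced chunk boundaries
  gaps <- which(diff(pos) > params$max_probe_spacing)
  chunk_start <- c(1L, gaps + 1L)
  chunk_end <- c(gaps, n)
  segs <- do.call(rbind, lapply(seq_along(chunk_start), function(k) {
    idx <- chunk_start[k]:chunk_end[k]
    .segment_recursive(lrr[idx], chunk_start[k], params)
  }))
  segs$start_pos <- pos[segs$start]
  segs$end_pos <- pos[segs$end]
  segs$n_probes <- segs$end - segs$start + 1L
  segs$mean_lrr <- vapply(seq_len(nrow(segs)), function(k) {
    mean(lrr[segs$start[k]:segs$end[k]], na.rm = TRUE)
  }, numeric(1))
  rownames(segs) <- NULL
  segs[, c("start", "end", "start_pos", "end_pos", "n_probes", "mean_lrr")]
}

#' Call segments, per-SNP states and the composite category for one case
#'
#' Runs [segment_lrr()], assigns each segment a copy-number state from its
#' mean LRR, and an allelic state from the BAF of its informative
#' (germline-heterozygous) SNPs: a segment is called LOH (resp. AI) when at
#' least `min_het_fraction` of its informative SNPs fall in the LOH (resp.
#' AI) bands, LOH taking precedence; segments without informative SNPs are
#' `indeterminate`. Case-level flags are the union over segments and are
#' composed into the canonical label by [category_label()].
#'
#' @param profile data.frame with columns `snp_id`, `pos`, `genotype`,
#'   `lrr`, `baf` for one case.
#' @param params a [segmentation_params()] object.
#' @param thresholds a [cn_thresholds()] object.
#' @param windows a [baf_windows()] object.
#' @param min_het_fraction minimum fraction of informative SNPs in a band
#'   for a segment-level AI/LOH call (default 0.5).
#' @return list with `segments` (annotated data.frame), `snp_calls`
#'   (per-SNP data.frame with `cn_state` and `allelic_call`), and
#'   `category` (composite label string).
#' @export
call_case_alterations <- function(profile,
                                  params = segmentation_params(),
                                  thresholds = cn_thresholds(),
                                  windows = baf_windows(),
                                  min_het_fraction = 0.5) {
  req <- c("snp_id", "pos", "genotype", "lrr", "baf")
  missing_cols <- setdiff(req, names(profile))
  if (length(missing_cols)) {
    stop("profile is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  segs <- segment_lrr(profile$pos, profile$lrr, params)
  segs$cn_state <- classify_segment_cn(segs$mean_lrr, thresholds)
  snp_call <- classify_snp_baf(profile$baf, profile$genotype, windows)

  segs$allelic_state <- vapply(seq_len(nrow(segs)), function(k) {
    calls <- snp_call[segs$start[k]:segs$end[k]]
    inf <- calls[calls != "not_informative"]
    if (length(inf) == 0L) return("indeterminate")
    if (mean(inf == "LOH") >= min_het_fraction) return("LOH")
    if (mean(inf == "AI") >= min_het_fraction) return("AI")
    "normal"
  }, character(1))

  seg_of_snp <- rep(seq_len(nrow(segs)), times = segs$n_probes)
  snp_calls <- data.frame(
    snp_id = profile$snp_id,
    segment = seg_of_snp,
    cn_state = segs$cn_state[seg_of_snp],
    allelic_call = snp_call,
    stringsAsFactors = FALSE
  )

  flags <- c(
    ai = any(segs$allelic_state == "AI"),
    gain = any(segs$cn_state %in% c("gain", "high_gain")),
    loss = any(segs$cn_state %in% c("loss", "big_loss")),
    loh = any(segs$allelic_state == "LOH")
  )
  list(
    segments = segs,
    snp_calls = snp_calls,
    category = unname(category_label(flags[["ai"]], flags[["gain"]],
                                     flags[["loss"]], flags[["loh"]]))
  )
}

#' Call alterations for every case of a cohort
#'
#' @param profiles long data.frame with columns `case_id`, `snp_id`, `pos`,
#'   `genotype`, `lrr`, `baf`.
#' @param ... passed to [call_case_alterations()].
#' @return list with `segments` (all cases, with `case_id`), `snp_calls`,
#'   and `categories` (data.frame `case_id`, `category`).
#' @export
call_cohort_alterations <- function(profiles, ...) {
  cases <- unique(profiles$case_id)
  per_case <- lapply(cases, function(cid) {
    p <- profiles[profiles$case_id == cid, , drop = FALSE]
    p <- p[order(p$pos), , drop = FALSE]
    call_case_alterations(p, ...)
  })
  segs <- do.call(rbind, lapply(seq_along(cases), function(i) {
    s <- per_case[[i]]$segments
    s$case_id <- cases[i]
    s
  }))
  snp_calls <- do.call(rbind, lapply(seq_along(cases), function(i) {
    s <- per_case[[i]]$snp_calls
    s$case_id <- cases[i]
    s
  }))
  categories <- data.frame(
    case_id = cases,
    category = vapply(per_case, `[[`, character(1), "category"),
    stringsAsFactors = FALSE
  )
  list(segments = segs, snp_calls = snp_calls, categories = categories)
}

#' SNPs carrying a copy-number alteration across a cohort
#'
#' A SNP "shows a CNA" in a case when it belongs to a segment whose
#' copy-number state is non-neutral. The correlation stage takes the subset
#' of SNPs altered in at least `min_cases` cases.
#'
#' @param snp_calls the `snp_calls` element of [call_cohort_alterations()].
#' @param min_cases minimum number of cases with a CNA at the SNP
#'   (default 1).
#' @return character vector of SNP ids.
#' @export
cna_snp_subset <- function(snp_calls, min_cases = 1L) {
  altered <- snp_calls$cn_state != "neutral"
  counts <- tapply(altered, snp_calls$snp_id, sum)
  names(counts)[counts >= min_cases]
}
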