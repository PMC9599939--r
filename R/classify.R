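#' Copy-number thresholds on mean segment LRR
#'
#' The LRR windows that map a segment's mean log R ratio to a copy-number
#' state: high gain at `mean LRR >= high_gain_min`, gain strictly above
#' `gain_min`, big loss at `<= big_loss_max`, loss strictly below
#' `loss_max`, and neutral on the closed interval between `loss_max` and
#' `gain_min`. Boundary semantics are exactly as stated: an LRR of 0.2 or
#' -0.2 is neutral.
#'
#' @param high_gain_min lower bound (inclusive) of the high-gain window.
#' @param gain_min lower bound (exclusive) of the gain window.
#' @param loss_max upper bound (exclusive) of the loss window.
#' @param big_loss_max upper bound (inclusive) of the big-loss window.
#' @return an object of class `cn_thresholds`.
#' @export
cn_thresholds <- function(high_gain_min = 1.0, gain_min = 0.2,
                          loss_max = -0.2, big_loss_max = -1.0) {
  if (!(big_loss_max < loss_max && loss_max < 0 && 0 < gain_min &&
        gain_min < high_gain_min)) {
    stop("invalid CN thresholds: need big_loss_max < loss_max < 0 < gain_min < high_gain_min")
  }
  structure(list(high_gain_min = high_gain_min, gain_min = gain_min,
                 loss_max = loss_max, big_loss_max = big_loss_max),
            class = "cn_thresholds")
}

#' BAF windows for allelic-imbalance and LOH classification
#'
#' Bands on the B-allele frequency of germline-heterozygous SNPs: allelic
#' imbalance (AI) on the closed bands \[0.20, 0.45\] and \[0.55, 0.80\],
#' LOH strictly below 0.20 or strictly above 0.80, and balanced ("normal")
#' on the open band (0.45, 0.55).
#'
#' @param ai_inner,ai_outer inner and outer AI band edges (distance from 0
#'   and 1 side handled by mirroring around 0.5).
#' @return an object of class `baf_windows`.
#' @export
baf_windows <- function(ai_inner = 0.45, ai_outer = 0.20) {
  if (!(0 < ai_outer && ai_outer < ai_inner && ai_inner < 0.5)) {
    stop("invalid BAF windows: need 0 < ai_outer < ai_inner < 0.5")
  }
  structure(list(ai_inner = ai_inner, ai_outer = ai_outer),
            class = "baf_windows")
}

#' Classify a segment's mean LRR into a copy-number state
#'
#' @param mean_lrr numeric vector of segment mean log R ratios.
#' @param thresholds a [cn_thresholds()] object.
#' @return character vector with levels `high_gain`, `gain`, `neutral`,
#'   `loss`, `big_loss`.
#' @examples
#' classify_segment_cn(c(1.0, 0.2, -0.5))
#' @export
classify_segment_cn <- function(mean_lrr, thresholds = cn_thresholds()) {
  if (any(!is.finite(mean_lrr))) {
    stop("classify_segment_cn: mean_lrr must be finite")
  }
  out <- rep("neutral", length(mean_lrr))
  out[mean_lrr > thresholds$gain_min] <- "gain"
  out[mean_lrr >= thresholds$high_gain_min] <- "high_gain"
  out[mean_lrr < thresholds$loss_max] <- "loss"
  out[mean_lrr <= thresholds$big_loss_max] <- "big_loss"
  out
}

#' Classify per-SNP BAF into AI / LOH / normal
#'
#' Only germline-heterozygous SNPs are informative for allelic imbalance:
#' a homozygous (or missing) germline genotype yields `not_informative`
#' regardless of the tumor BAF. For heterozygous SNPs the AI bands are
#' closed and the LOH bands strict.
#'
#' @param baf numeric vector of tumor B-allele frequencies in \[0, 1\]
#'   (NA allowed).
#' @param genotype character vector of germline genotypes (`"AA"`, `"AB"`,
#'   `"BB"`, or NA/`"missing"`).
#' @param windows a [baf_windows()] object.
#' @return character vector with levels `AI`, `LOH`, `normal`,
#'   `not_informative`.
#' @examples
#' classify_snp_baf(c(0.30, 0.90, 0.95), c("AB", "AB", "AA"))
#' @export
classify_snp_baf <- function(baf, genotype, windows = baf_windows()) {
  if (length(baf) != length(genotype)) {
    stop("classify_snp_baf: baf and genotype lengths differ")
  }
  bad <- !is.na(baf) & (baf < 0 | baf > 1)
  if (any(bad)) stop("classify_snp_baf: BAF outside [0, 1]")
  out <- rep("not_informative", length(baf))
  het <- !is.na(genotype) & genotype == "AB" & !is.na(baf)
  lo <- windows$ai_outer
  hi <- windows$ai_inner
  b <- baf[het]
  cls <- rep("normal", length(b))
  ai <- (b >= lo & b <= hi) | (b >= 1 - hi & b <= 1 - lo)
  loh <- b < lo | b > 1 - lo
  cls[ai] <- "AI"
  cls[loh] <- "LOH"
  out[het] <- cls
  out
}

# fixed display order of the composite case label
.flag_order <- c("Allelic Imbalance", "CN Gain", "CN Loss", "LOH")

#' Compose the composite case alteration label
#'
#' Flags are joined in the fixed order "Allelic Imbalance, CN Gain,
#' CN Loss, LOH"; a case with no flag set is labelled `"not observed"`.
#'
#' @param ai,gain,loss,loh logical flags (vectorized).
#' @return character vector of canonical labels.
#' @export
category_label <- function(ai, gain, loss, loh) {
  flags <- cbind(ai, gain, loss, loh)
  apply(flags, 1L, function(f) {
    if (!any(f)) "not observed" else paste(.flag_order[f], collapse = ", ")
  })
}

#' Parse a composite alteration label back into flags
#'
#' @param label character vector of labels in the canonical vocabulary.
#' @return data.frame with logical columns `ai`, `gain`, `loss`, `loh`.
#' @export
parse_category <- function(label) {
  known <- c(.flag_order, "not observed")
  parts <- strsplit(label, ", ", fixed = TRUE)
  bad <- vapply(parts, function(p) any(!p %in% known), logical(1))
  if (any(bad)) {
    stop("parse_category: unknown alteration label: ",
         paste(unique(label[bad]), collapse = "; "))
  }
  data.frame(
    ai   = vapply(parts, function(p) "Allelic Imbalance" %in% p, logical(1)),
    gain = vapply(parts, function(p) "CN Gain" %in% p, logical(1)),
    loss = vapply(parts, function(p) "CN Loss" %in% p, logical(1)),
    loh  = vapply(parts, function(p) "LOH" %in% p, logical(1))
  )
}

#' Summarize composite alteration categories over a cohort
#'
#' Reports the case counts behind the alteration taxonomy: how many cases
#' show any somatic alteration, the loss/LOH-without-gain group (and how
#' many of those also show AI), the gain-without-loss/LOH group (and its AI
#' subcount), the AI-only group, and cases mixing gain with loss or LOH.
#'
#' @param categories character vector of composite labels, one per case.
#' @return a list of counts and proportions.
#' @export
summarize_cohort_alterations <- function(categories) {
  if (length(categories) == 0L) {
    stop("summarize_cohort_alterations: empty cohort")
  }
  f <- parse_category(categories)
  altered <- f$ai | f$gain | f$loss | f$loh
  loss_loh <- (f$loss | f$loh) & !f$gain
  gain_only <- f$gain & !(f$loss | f$loh)
  ai_only <- f$ai & !f$gain & !f$loss & !f$loh
  mixed <- f$gain & (f$loss | f$loh)
  list(
    n = length(categories),
    n_altered = sum(altered),
    pct_altered = 100 * mean(altered),
    loss_loh_no_gain = sum(loss_loh),
    loss_loh_no_gain_with_ai = sum(loss_loh & f$ai),
    gain_no_loss_loh = sum(gain_only),
    gain_no_loss_loh_with_ai = sum(gain_only & f$ai),
    ai_only = sum(ai_only),
    mixed_gain_loss = sum(mixed),
    flag_counts = c(ai = sum(f$ai), gain = sum(f$gain),
                    loss = sum(f$loss), loh = sum(f$loh))
  )
}
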