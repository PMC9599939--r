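#' Relative expression by the 2^-ddCt method
#'
#' For each tissue the delta-Ct is the mean of the target-gene Ct
#' triplicate minus the mean of the reference-gene Ct triplicate; the
#' delta-delta-Ct is the tumor delta-Ct minus the normal delta-Ct; and the
#' N-fold change is `2^-ddCt`. Missing replicates are tolerated (the mean
#' runs over available values) but at least one replicate per triplicate is
#' required. A replicate spread above 0.5 cycles triggers a QC warning,
#' not an error.
#'
#' @param target_tumor,ref_tumor,target_normal,ref_normal numeric vectors
#'   of Ct values (cycles), nominally triplicates.
#' @return list with `dct_tumor`, `dct_normal`, `ddct`, `fc`, `category`.
#' @examples
#' compute_fold_change(c(25, 25, 25), c(20, 20, 20),
#'                     c(24, 24, 24), c(20, 20, 20))  # fc = 0.5
#' @export
compute_fold_change <- function(target_tumor, ref_tumor,
                                target_normal, ref_normal) {
  tri <- list(target_tumor = target_tumor, ref_tumor = ref_tumor,
              target_normal = target_normal, ref_normal = ref_normal)
  for (nm in names(tri)) {
    v <- tri[[nm]][!is.na(tri[[nm]])]
    if (length(v) == 0L) stop("empty Ct triplicate: ", nm)
    if (any(v <= 0 | !is.finite(v))) {
      stop("Ct values must be positive and finite: ", nm)
    }
    if (length(v) > 1L && sd(v) > 0.5) {
      warning("replicate spread > 0.5 cycles in ", nm)
    }
  }
  dct_tumor <- mean(target_tumor, na.rm = TRUE) - mean(ref_tumor, na.rm = TRUE)
  dct_normal <- mean(target_normal, na.rm = TRUE) - mean(ref_normal, na.rm = TRUE)
  ddct <- dct_tumor - dct_normal
  fc <- 2^(-ddct)
  list(dct_tumor = dct_tumor, dct_normal = dct_normal, ddct = ddct,
       fc = fc, category = classify_expression(fc))
}

#' Categorize an expression fold change
#'
#' Overexpressed at `fc >= 2.0`, underexpressed at `fc <= 0.5`, and normal
#' on the open interval in between.
#'
#' @param fc positive numeric vector of fold changes.
#' @return character vector with levels `over`, `normal`, `under`.
#' @examples
#' classify_expression(c(0.36, 2.77, 1.05))
#' @export
classify_expression <- function(fc) {
  if (any(!is.finite(fc) | fc <= 0)) {
    stop("classify_expression: fold changes must be positive and finite")
  }
  out <- rep("normal", length(fc))
  out[fc >= 2.0] <- "over"
  out[fc <= 0.5] <- "under"
  out
}

#' Case-level average expression over probes
#'
#' The arithmetic mean of the per-probe fold changes, categorized with the
#' same cutoffs as individual probes.
#'
#' @param fc positive numeric vector of per-probe fold changes (NAs
#'   dropped).
#' @return list with `mean_fc` and `category`.
#' @export
case_average_expression <- function(fc) {
  fc <- fc[!is.na(fc)]
  if (length(fc) == 0L) stop("case_average_expression: no probes with a fold change")
  m <- mean(fc)
  list(mean_fc = m, category = classify_expression(m))
}

#' Fold-change table from a long triplicate-Ct table
#'
#' Pairs tumor and normal assays per (case, probe), applies
#' [compute_fold_change()], and returns one row per pair. Rows missing a
#' tissue or the reference gene raise a paired-assay error.
#'
#' @param ct data.frame in the long Ct dialect (`case_id`, `probe_id`,
#'   `tissue` in tumor/normal, `target` in target/reference, `rep1`,
#'   `rep2`, `rep3`).
#' @return data.frame with `case_id`, `probe_id`, `dct_tumor`,
#'   `dct_normal`, `ddct`, `fc`, `category`.
#' @export
fold_change_table <- function(ct) {
  req <- c("case_id", "probe_id", "tissue", "target", "rep1", "rep2", "rep3")
  miss <- setdiff(req, names(ct))
  if (length(miss)) stop("ct table missing columns: ", paste(miss, collapse = ", "))
  keys <- unique(ct[, c("case_id", "probe_id")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- ct[ct$case_id == keys$case_id[k] & ct$probe_id == keys$probe_id[k], ]
    pick <- function(tissue, target) {
      r <- sub[sub$tissue == tissue & sub$target == target, c("rep1", "rep2", "rep3")]
      if (nrow(r) != 1L) {
        stop("paired-assay error: expected exactly one ", tissue, "/", target,
             " row for case ", keys$case_id[k], " probe ", keys$probe_id[k])
      }
      as.numeric(r[1L, ])
    }
    fcres <- compute_fold_change(pick("tumor", "target"), pick("tumor", "reference"),
                                 pick("normal", "target"), pick("normal", "reference"))
    data.frame(case_id = keys$case_id[k], probe_id = keys$probe_id[k],
               dct_tumor = fcres$dct_tumor, dct_normal = fcres$dct_normal,
               ddct = fcres$ddct, fc = fcres$fc, category = fcres$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-probe frequency distribution of expression categories
#'
#' Probes observed in fewer than `min_cases` cases are excluded (the same
#' fewer-than-five-cases rule the correlation stage applies). Frequencies
#' of over/normal/under sum to one per retained probe; the per-probe
#' median, mean and range of fold changes are reported alongside.
#'
#' @param fc_table data.frame with `case_id`, `probe_id`, `fc`.
#' @param min_cases minimum cases per probe (default 5).
#' @return data.frame with one row per retained probe.
#' @export
probe_frequency_distribution <- function(fc_table, min_cases = 5L) {
  fc_table <- fc_table[!is.na(fc_table$fc), , drop = FALSE]
  if (nrow(fc_table) == 0L) stop("probe_frequency_distribution: empty cohort")
  probes <- split(fc_table, fc_table$probe_id)
  probes <- probes[vapply(probes, nrow, integer(1)) >= min_cases]
  if (length(probes) == 0L) {
    stop("probe_frequency_distribution: no probe retained at min_cases = ",
         min_cases)
  }
  rows <- lapply(names(probes), function(p) {
    fc <- probes[[p]]$fc
    cat3 <- classify_expression(fc)
    data.frame(
      probe_id = p, n = length(fc),
      freq_over = mean(cat3 == "over"),
      freq_normal = mean(cat3 == "normal"),
      freq_under = mean(cat3 == "under"),
      median_fc = median(fc), mean_fc = mean(fc),
      min_fc = min(fc), max_fc = max(fc),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
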