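#' Packaged list of target miRNAs
#'
#' The 22 miRNAs predicted to bind the gene's 3' UTR, shipped as a static
#' text file. Most ids are those reported for the reference cohort; the
#' remainder of the 22 are same-family/cluster placeholders (a synthetic
#' completion), since no numeric result depends on the extra ids.
#'
#' @return character vector of 22 miRNA identifiers.
#' @export
target_mirs <- function() {
  path <- system.file("extdata", "target_mirs.txt", package = "cnaexpr")
  if (path == "") stop("packaged target_mirs.txt not found")
  mirs <- readLines(path)
  mirs <- mirs[nzchar(mirs) & !startsWith(mirs, "#")]
  mirs
}

#' Drop assays without signal in both tissues
#'
#' A miRNA fold change is only defined when both the tumor and the matched
#' normal sample had detectable signal; assays detected in one tissue only
#' are dropped.
#'
#' @param assays data.frame with logical/0-1 columns `tumor_detected` and
#'   `normal_detected`.
#' @return the retained rows.
#' @export
filter_detected <- function(assays) {
  req <- c("tumor_detected", "normal_detected")
  miss <- setdiff(req, names(assays))
  if (length(miss)) stop("assay table missing columns: ", paste(miss, collapse = ", "))
  keep <- as.logical(assays$tumor_detected) & as.logical(assays$normal_detected)
  assays[keep, , drop = FALSE]
}

#' Categorize a miRNA fold change
#'
#' Dysregulated when the fold change is at least 2 (over) or at most 0.5
#' (under); normal otherwise.
#'
#' @param fc positive numeric vector.
#' @return character vector with levels `over`, `normal`, `under`.
#' @export
classify_mir <- function(fc) {
  classify_expression(fc)
}

#' Cohort summary of target-miRNA expression
#'
#' Applies the detection filter, drops miRNAs observed in fewer than
#' `min_cases` cases, then summarizes per miRNA (median and mean fold
#' change over retained cases, with two distinct abnormality labels: by
#' mean and by median) and per case (arithmetic mean fold change over
#' retained miRNAs, categorized with the dysregulation cutoffs). The
#' by-mean abnormal set is the selection rule the correlation stage uses;
#' the by-median set is reported separately.
#'
#' @param assays data.frame with `case_id`, `mir_id`, `tumor_detected`,
#'   `normal_detected`, `fc`.
#' @param min_cases minimum cases per miRNA (default 5).
#' @return list with `per_mir`, `per_case`, `abnormal_mirs_by_mean`,
#'   `abnormal_mirs_by_median`, and case-level counts `n_abnormal`,
#'   `n_over`, `n_under`.
#' @export
mir_cohort_summary <- function(assays, min_cases = 5L) {
  kept <- filter_detected(assays)
  kept <- kept[!is.na(kept$fc), , drop = FALSE]
  if (nrow(kept) == 0L) stop("mir_cohort_summary: no retained assays")
  by_mir <- split(kept, kept$mir_id)
  by_mir <- by_mir[vapply(by_mir, nrow, integer(1)) >= min_cases]
  if (length(by_mir) == 0L) stop("mir_cohort_summary: no miRNA retained")

  per_mir <- do.call(rbind, lapply(names(by_mir), function(m) {
    fc <- by_mir[[m]]$fc
    data.frame(mir_id = m, n = length(fc), mean_fc = mean(fc),
               median_fc = median(fc),
               abnormal_by_mean = mean(fc) >= 2 | mean(fc) <= 0.5,
               abnormal_by_median = median(fc) >= 2 | median(fc) <= 0.5,
               stringsAsFactors = FALSE)
  }))
  rownames(per_mir) <- NULL

  retained_ids <- per_mir$mir_id
  kept <- kept[kept$mir_id %in% retained_ids, , drop = FALSE]
  by_case <- split(kept, kept$case_id)
  per_case <- do.call(rbind, lapply(names(by_case), function(cid) {
    fc <- by_case[[cid]]$fc
    m <- mean(fc)
    data.frame(case_id = cid, n_mirs = length(fc), mean_fc = m,
               category = classify_mir(m), stringsAsFactors = FALSE)
  }))
  rownames(per_case) <- NULL

  list(
    per_mir = per_mir,
    per_case = per_case,
    abnormal_mirs_by_mean = per_mir$mir_id[per_mir$abnormal_by_mean],
    abnormal_mirs_by_median = per_mir$mir_id[per_mir$abnormal_by_median],
    n_abnormal = sum(per_case$category != "normal"),
    n_over = sum(per_case$category == "over"),
    n_under = sum(per_case$category == "under")
  )
}
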