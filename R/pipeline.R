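#' Run the full synthetic-cohort pipeline end to end
#'
#' Chains every stage on one generated cohort: simulation, per-case
#' segmentation and alteration calling, 2^-ddCt expression, miRNA
#' summaries, SNP-expression / SNP-miRNA / expression-miRNA correlation,
#' and survival of the expression-dichotomized groups. Every input and
#' output table is written under `out_dir` in the package's file dialects,
#' and all randomness flows from the config seed, so two runs with the
#' same config are identical.
#'
#' @param config a [synthetic_config()] object.
#' @param out_dir output directory (created if needed).
#' @param seg_params a [segmentation_params()] object.
#' @param min_cases the fewer-than-five-cases exclusion bound (default 5).
#' @param snp_min_cases minimum altered cases for a SNP to enter the
#'   correlation subset (default 1).
#' @param verbose print per-stage in/out counts.
#' @param ... passed to [generate_cohort()].
#' @return (invisibly) a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = tempfile(),
                         seg_params = segmentation_params(),
                         min_cases = 5L, snp_min_cases = 1L,
                         verbose = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  # simulate
  cohort <- generate_cohort(config, ...)
  write_snp_map(cohort$snp_map, file.path(out_dir, "snp_map.tsv"))
  write_lrr_baf(cohort$profiles, file.path(out_dir, "lrr_baf.tsv"))
  write_ct_table(cohort$ct, file.path(out_dir, "ct.csv"))
  write_mir_table(cohort$mir, file.path(out_dir, "mir.csv"))
  write_clinical(cohort$clinical, file.path(out_dir, "clinical.csv"))
  truth_segs <- do.call(rbind, lapply(names(cohort$truth$scenarios), function(cid) {
    s <- cohort$truth$scenarios[[cid]]
    if (nrow(s) == 0L) return(NULL)
    cbind(case_id = cid, s, stringsAsFactors = FALSE)
  }))
  if (!is.null(truth_segs)) {
    write.table(truth_segs, file.path(out_dir, "truth_segments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(cohort$truth$couplings, file.path(out_dir, "truth_couplings.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("simulate: %d cases, %d SNPs", config$n_cases, config$n_snps)

  # call-cna
  calls <- call_cohort_alterations(cohort$profiles, params = seg_params)
  write_segments(calls$segments, file.path(out_dir, "segments.tsv"),
                 chrom = config$chrom)
  write.csv(calls$categories, file.path(out_dir, "categories.csv"),
            row.names = FALSE, quote = TRUE)
  say("call-cna: %d segments, %d/%d cases altered", nrow(calls$segments),
      sum(calls$categories$category != "not observed"),
      nrow(calls$categories))

  # expression
  fc <- fold_change_table(cohort$ct)
  write.csv(fc, file.path(out_dir, "fold_changes.csv"), row.names = FALSE)
  probe_freq <- probe_frequency_distribution(fc, min_cases = min_cases)
  write.csv(probe_freq, file.path(out_dir, "probe_frequencies.csv"),
            row.names = FALSE)
  say("expression: %d (case, probe) fold changes", nrow(fc))

  # mirna
  mir_sum <- mir_cohort_summary(cohort$mir, min_cases = min_cases)
  write.csv(mir_sum$per_mir, file.path(out_dir, "mir_per_mir.csv"),
            row.names = FALSE)
  write.csv(mir_sum$per_case, file.path(out_dir, "mir_per_case.csv"),
            row.names = FALSE)
  say("mirna: %d retained miRNAs, %d abnormal cases",
      nrow(mir_sum$per_mir), mir_sum$n_abnormal)

  # integrate
  lrr_mat <- lrr_matrix(cohort$profiles)
  probe_mat <- fc_matrix(fc, "probe_id")
  mir_mat <- fc_matrix(filter_detected(cohort$mir), "mir_id")
  subset <- cna_snp_subset(calls$snp_calls, min_cases = snp_min_cases)
  mrna_cor <- correlate_snp_vs_expression(lrr_mat, probe_mat, subset,
                                          min_cases = min_cases)
  mir_cor <- correlate_snp_vs_mirna(lrr_mat, mir_mat, subset,
                                    mir_subset = mir_sum$abnormal_mirs_by_mean,
                                    min_cases = min_cases)
  em_cor <- correlate_expression_vs_mirna(probe_mat, mir_mat,
                                          min_cases = min_cases)
  write_results(list(snp_mrna = mrna_cor$results, snp_mir = mir_cor$results,
                     mrna_mir = em_cor$results),
                file.path(out_dir, "correlations.tsv"))
  dual <- find_dual_correlated_snps(mrna_cor$results, mir_cor$results)
  write.table(dual, file.path(out_dir, "dual_correlated_snps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("integrate: %d SNPs in subset, %d + %d + %d correlations",
      length(subset), nrow(mrna_cor$results), nrow(mir_cor$results),
      nrow(em_cor$results))

  # survive
  case_fc <- vapply(split(fc$fc, fc$case_id), mean, numeric(1), na.rm = TRUE)
  clin <- cohort$clinical
  clin$group <- dichotomize_by_fc(case_fc[clin$case_id])
  surv <- list(km = NULL, cox = NULL)
  if (length(unique(clin$group)) == 2L) {
    surv$km <- km_logrank(clin$months, clin$event, clin$group)
    surv$cox <- cox_hr(clin$months, clin$event, clin$group)
    surv_tab <- data.frame(
      group = names(surv$km$n), n = as.vector(surv$km$n),
      median_months = as.vector(surv$km$medians[names(surv$km$n)]),
      logrank_p = surv$km$p, hr = surv$cox$hr,
      hr_lo = surv$cox$ci[1], hr_hi = surv$cox$ci[2]
    )
    write.csv(surv_tab, file.path(out_dir, "survival.csv"), row.names = FALSE)
  }
  say("survive: log-rank p = %s",
      if (is.null(surv$km)) "NA (single group)" else format(surv$km$p))

  invisible(list(cohort = cohort, calls = calls, fc = fc,
                 probe_freq = probe_freq, mir_summary = mir_sum,
                 correlations = list(mrna = mrna_cor, mir = mir_cor,
                                     expr_mir = em_cor),
                 dual = dual, survival = surv, out_dir = out_dir))
}
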