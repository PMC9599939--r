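#' Load the packaged 56-case cohort summary
#'
#' A published ESCC cohort summary: one row per case with the composite
#' somatic-alteration label, the case-average gene-expression fold change
#' (missing for two cases without usable RNA) and the case-average
#' target-miRNA fold change. Used to reproduce the cohort's alteration and
#' expression counts without any array data.
#'
#' @param path override the packaged file (mainly for tests).
#' @return data.frame with `case_id`, `category`, `gene_fc`, `mir_fc`.
#' @export
load_table1_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "escc56_alterations.csv",
                        package = "cnaexpr")
  }
  if (path == "" || !file.exists(path)) stop("packaged cohort summary not found")
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("case_id", "category", "gene_fc", "mir_fc"),
                   "cohort summary")
  if (nrow(df) != 56L) {
    stop("fixture integrity violation: expected 56 rows, got ", nrow(df))
  }
  parse_category(df$category)  # errors on unknown vocabulary
  if (any(!is.na(df$gene_fc) & df$gene_fc <= 0) || any(df$mir_fc <= 0)) {
    stop("fixture integrity violation: non-positive fold change")
  }
  .check_unique_key(df, "case_id", "cohort summary")
  df
}

#' Reproduce the cohort's alteration and expression counts
#'
#' From the packaged 56-case summary alone, recomputes: the altered-case
#' count and percentage; the alteration-group counts (loss/LOH without
#' gain and its AI subcount, gain without loss/LOH and its AI subcount,
#' AI only, gain mixed with loss/LOH); the gene-expression category counts
#' over cases with a fold change; the abnormal-expression percentage
#' within altered and non-altered cases; and the target-miRNA
#' abnormal-case counts.
#'
#' @param fixture output of [load_table1_fixture()] (default: load the
#'   packaged file).
#' @return named list of counts and percentages.
#' @export
reproduce_table1 <- function(fixture = load_table1_fixture()) {
  alt <- summarize_cohort_alterations(fixture$category)
  flags <- parse_category(fixture$category)
  altered <- flags$ai | flags$gain | flags$loss | flags$loh

  gene <- fixture$gene_fc
  has_gene <- !is.na(gene)
  gene_cat <- classify_expression(gene[has_gene])
  gene_abnormal <- has_gene & (gene <= 0.5 | gene >= 2)

  mir_cat <- classify_mir(fixture$mir_fc)

  list(
    n_cases = nrow(fixture),
    n_altered = alt$n_altered,
    pct_altered = alt$pct_altered,
    loss_loh_no_gain = alt$loss_loh_no_gain,
    loss_loh_no_gain_with_ai = alt$loss_loh_no_gain_with_ai,
    gain_no_loss_loh = alt$gain_no_loss_loh,
    gain_no_loss_loh_with_ai = alt$gain_no_loss_loh_with_ai,
    ai_only = alt$ai_only,
    mixed_gain_loss = alt$mixed_gain_loss,
    gene_n = sum(has_gene),
    gene_under = sum(gene_cat == "under"),
    gene_over = sum(gene_cat == "over"),
    gene_abnormal = sum(gene_cat != "normal"),
    pct_gene_abnormal = 100 * mean(gene_cat != "normal"),
    abnormal_in_altered_n = sum(gene_abnormal & altered),
    altered_with_gene_n = sum(altered & has_gene),
    pct_abnormal_in_altered = 100 * sum(gene_abnormal & altered) /
      sum(altered & has_gene),
    abnormal_in_nonaltered_n = sum(gene_abnormal & !altered),
    nonaltered_with_gene_n = sum(!altered & has_gene),
    pct_abnormal_in_nonaltered = 100 * sum(gene_abnormal & !altered) /
      sum(!altered & has_gene),
    mir_abnormal = sum(mir_cat != "normal"),
    mir_over = sum(mir_cat == "over"),
    mir_under = sum(mir_cat == "under")
  )
}
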