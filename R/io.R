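# ---- file dialects -------------------------------------------------------
# All tables are UTF-8 with a header row; genomic coordinates in files are
# 1-based inclusive. TSV for genomic tables, CSV for assay/clinical tables.

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  invisible(df)
}

.check_numeric <- function(df, cols, what) {
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(v))
    if (length(bad)) {
      stop("malformed ", what, ": non-numeric '", col, "' at line(s) ",
           paste(utils::head(bad + 1L, 5L), collapse = ", "))
    }
    df[[col]] <- v
  }
  df
}

.check_unique_key <- function(df, cols, what) {
  key <- do.call(paste, c(df[cols], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("integrity error in ", what, ": duplicated (",
         paste(cols, collapse = ", "), ") keys")
  }
  invisible(df)
}

#' Read / write the SNP annotation table (TSV)
#'
#' Columns: `snp_id`, `chrom`, `pos`, `intron`, `allele_a`, `allele_b`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_snp_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("snp_id", "chrom", "pos", "intron",
                         "allele_a", "allele_b"), "SNP map")
  df <- .check_numeric(df, c("pos", "intron"), "SNP map")
  .check_unique_key(df, "snp_id", "SNP map")
  df
}

#' @rdname read_snp_map
#' @param snp_map data.frame to write.
#' @export
write_snp_map <- function(snp_map, path) {
  write.table(snp_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the long LRR/BAF table (TSV)
#'
#' Columns: `case_id`, `snp_id`, `chrom`, `pos`, `genotype`, `lrr`, `baf`;
#' one row per (case, SNP).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_lrr_baf <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("case_id", "snp_id", "chrom", "pos", "genotype",
                         "lrr", "baf"), "LRR/BAF table")
  df <- .check_numeric(df, c("pos", "lrr", "baf"), "LRR/BAF table")
  .check_unique_key(df, c("case_id", "snp_id"), "LRR/BAF table")
  df
}

#' @rdname read_lrr_baf
#' @param profiles data.frame to write.
#' @export
write_lrr_baf <- function(profiles, path) {
  write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the BED-like segment table (TSV)
#'
#' Columns: `case_id`, `chrom`, `start`, `end` (1-based inclusive genomic
#' positions), `n_probes`, `mean_lrr`, `cn_state`, `allelic_state`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_segments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("case_id", "chrom", "start", "end", "n_probes",
                         "mean_lrr", "cn_state", "allelic_state"),
                   "segment table")
  df <- .check_numeric(df, c("start", "end", "n_probes", "mean_lrr"),
                       "segment table")
  if (any(df$start > df$end)) stop("segment table: start > end")
  df
}

#' @rdname read_segments
#' @param segments annotated segment data.frame (per-case output of
#'   [call_cohort_alterations()]).
#' @param chrom chromosome label for the output rows.
#' @export
write_segments <- function(segments, path, chrom = "chr8") {
  out <- data.frame(
    case_id = segments$case_id, chrom = chrom,
    start = segments$start_pos, end = segments$end_pos,
    n_probes = segments$n_probes, mean_lrr = segments$mean_lrr,
    cn_state = segments$cn_state, allelic_state = segments$allelic_state,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the long triplicate-Ct table (CSV)
#'
#' Columns: `case_id`, `probe_id`, `tissue` (tumor/normal), `target`
#' (target/reference), `rep1`, `rep2`, `rep3`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("case_id", "probe_id", "tissue", "target",
                         "rep1", "rep2", "rep3"), "Ct table")
  df <- .check_numeric(df, c("rep1", "rep2", "rep3"), "Ct table")
  .check_unique_key(df, c("case_id", "probe_id", "tissue", "target"),
                    "Ct table")
  df
}

#' @rdname read_ct_table
#' @param ct data.frame to write.
#' @export
write_ct_table <- function(ct, path) {
  write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the miRNA assay table (CSV)
#'
#' Columns: `case_id`, `mir_id`, `tumor_detected`, `normal_detected`,
#' `fc` (empty when either tissue lacked signal).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_mir_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("case_id", "mir_id", "tumor_detected",
                         "normal_detected", "fc"), "miRNA table")
  df <- .check_numeric(df, "fc", "miRNA table")
  .check_unique_key(df, c("case_id", "mir_id"), "miRNA table")
  df
}

#' @rdname read_mir_table
#' @param mir data.frame to write.
#' @export
write_mir_table <- function(mir, path) {
  write.csv(mir, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the clinical table (CSV)
#'
#' Columns: `case_id`, `months`, `event`, `family_history`, `lymph_node`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("case_id", "months", "event"), "clinical table")
  df <- .check_numeric(df, c("months", "event"), "clinical table")
  .check_unique_key(df, "case_id", "clinical table")
  df
}

#' @rdname read_clinical
#' @param clinical data.frame to write.
#' @export
write_clinical <- function(clinical, path) {
  write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read long-format correlation results (TSV)
#'
#' Columns: `analysis`, `id1`, `id2`, `n`, `rho`, `p`, `nominal`,
#' `bonferroni`, `direction`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .require_columns(df, c("analysis", "id1", "id2", "n", "rho", "p",
                         "nominal", "bonferroni", "direction"),
                   "results table")
  .check_numeric(df, c("n", "rho", "p"), "results table")
}

#' @rdname read_results
#' @param results named list of result data.frames (names become the
#'   `analysis` column).
#' @export
write_results <- function(results, path) {
  out <- do.call(rbind, lapply(names(results), function(a) {
    r <- results[[a]]
    names(r)[1:2] <- c("id1", "id2")
    cbind(analysis = a, r, stringsAsFactors = FALSE)
  }))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
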