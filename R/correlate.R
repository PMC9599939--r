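# ---- Spearman rank correlation with small-sample exact p ----

# all permutations of 1:n as an (n!) x n integer matrix
.perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perm_matrix(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    block <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# exact null distribution of Spearman's rho for sample size n (no ties),
# cached per n
.rho_null <- function(n) {
  key <- paste0("rho_null_", n)
  if (!is.null(.cnaexpr_env[[key]])) return(.cnaexpr_env[[key]])
  P <- .perm_matrix(n)
  S <- rowSums((P - matrix(seq_len(n), nrow(P), n, byrow = TRUE))^2)
  rho <- 1 - 6 * S / (n * (n^2 - 1))
  .cnaexpr_env[[key]] <- rho
  rho
}

#' Spearman rank correlation with a two-sided p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged). The
#' two-sided p-value uses the exact permutation distribution when
#' `n <= exact_limit` and neither vector has ties, and the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom otherwise. Pairs with missing values are deleted pairwise; a
#' pair count below `min_cases` is flagged as skipped rather than raising
#' an error, matching the fewer-than-five-cases exclusion rule.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_cases minimum complete pairs (default 5).
#' @param exact_limit largest n for the exact permutation p (default 9).
#' @return list with `rho`, `p`, `n`, `method` (`exact`/`t-approx`), and
#'   `skipped`.
#' @export
spearman <- function(x, y, min_cases = 5L, exact_limit = 9L) {
  if (length(x) != length(y)) stop("spearman: x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < min_cases) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = NA_character_,
                skipped = TRUE))
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate",
                skipped = TRUE))
  }
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= exact_limit && !ties) {
    null <- .rho_null(n)
    p <- mean(abs(null) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
    method <- "t-approx"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method, skipped = FALSE)
}

#' Direction of a SNP-expression correlation
#'
#' Positive when the copy-number signal and the expression fold change
#' move together (gain with overexpression or loss with underexpression,
#' i.e. rho > 0), negative when rho < 0, and undirected at rho = 0. The
#' copy-number context of the SNP (gain- or loss-dominant) is recorded for
#' reporting only.
#'
#' @param rho numeric vector of correlations.
#' @param cn_context optional character vector recorded alongside.
#' @return character vector `positive`/`negative`/`undirected`.
#' @export
classify_direction <- function(rho, cn_context = NULL) {
  out <- ifelse(rho > 0, "positive", ifelse(rho < 0, "negative", "undirected"))
  if (!is.null(cn_context)) attr(out, "cn_context") <- cn_context
  out
}

# generic pair-correlation engine over the columns of two matrices
.correlate_pairs <- function(x_mat, y_mat, min_cases, alpha, m) {
  threshold <- alpha / m
  rows <- vector("list", ncol(x_mat) * ncol(y_mat))
  k <- 0L
  for (i in seq_len(ncol(x_mat))) {
    for (j in seq_len(ncol(y_mat))) {
      sp <- spearman(x_mat[, i], y_mat[, j], min_cases = min_cases)
      if (sp$skipped) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        id1 = colnames(x_mat)[i], id2 = colnames(y_mat)[j],
        n = sp$n, rho = sp$rho, p = sp$p,
        nominal = sp$p < alpha, bonferroni = sp$p < threshold,
        direction = classify_direction(sp$rho),
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L) {
    return(data.frame(id1 = character(), id2 = character(), n = integer(),
                      rho = numeric(), p = numeric(), nominal = logical(),
                      bonferroni = logical(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Correlate SNP copy-number signal with exon-boundary expression
#'
#' One Spearman correlation per (SNP, probe) pair with at least
#' `min_cases` complete cases, over the SNPs in `snp_subset` (the SNPs
#' flagged as carrying a CNA). The Bonferroni family size is the number of
#' attempted comparisons `|snp_subset| * n_probes`, so excluded pairs still
#' count toward the adjustment.
#'
#' @param lrr_mat cases x SNPs matrix of tumor LRR (from [lrr_matrix()]).
#' @param probe_fc cases x probes matrix of expression fold changes,
#'   aligned on row (case) names.
#' @param snp_subset character vector of SNP ids to test.
#' @param min_cases minimum complete pairs per test (default 5).
#' @param alpha nominal significance level (default 0.05).
#' @return list with `results` (data.frame) and `plan`
#'   (`alpha`, `m`, `bonferroni_threshold`).
#' @export
correlate_snp_vs_expression <- function(lrr_mat, probe_fc, snp_subset,
                                        min_cases = 5L, alpha = 0.05) {
  snp_subset <- intersect(snp_subset, colnames(lrr_mat))
  if (length(snp_subset) == 0L) stop("empty SNP subset")
  common <- intersect(rownames(lrr_mat), rownames(probe_fc))
  x <- lrr_mat[common, snp_subset, drop = FALSE]
  y <- probe_fc[common, , drop = FALSE]
  m <- length(snp_subset) * ncol(probe_fc)
  results <- .correlate_pairs(x, y, min_cases, alpha, m)
  list(results = results,
       plan = list(alpha = alpha, m = m, bonferroni_threshold = alpha / m))
}

#' Correlate SNP copy-number signal with target-miRNA expression
#'
#' Same engine as [correlate_snp_vs_expression()], run against the
#' miRNAs that showed abnormal average expression (fold change >= 2 or
#' <= 0.5), with its own Bonferroni family.
#'
#' @param lrr_mat cases x SNPs matrix of tumor LRR.
#' @param mir_fc cases x miRNAs matrix of miRNA fold changes.
#' @param snp_subset character vector of CNA SNP ids.
#' @param mir_subset character vector of abnormal miRNA ids (default: all
#'   columns of `mir_fc`).
#' @param min_cases,alpha as in [correlate_snp_vs_expression()].
#' @return list with `results` and `plan`.
#' @export
correlate_snp_vs_mirna <- function(lrr_mat, mir_fc, snp_subset,
                                   mir_subset = colnames(mir_fc),
                                   min_cases = 5L, alpha = 0.05) {
  mir_subset <- intersect(mir_subset, colnames(mir_fc))
  if (length(mir_subset) == 0L) stop("empty miRNA subset")
  correlate_snp_vs_expression(lrr_mat, mir_fc[, mir_subset, drop = FALSE],
                              snp_subset, min_cases = min_cases,
                              alpha = alpha)
}

#' Correlate exon-boundary expression with target-miRNA expression
#'
#' @param probe_fc cases x probes matrix of expression fold changes.
#' @param mir_fc cases x miRNAs matrix of miRNA fold changes.
#' @param min_cases,alpha as in [correlate_snp_vs_expression()].
#' @return list with `results` and `plan`.
#' @export
correlate_expression_vs_mirna <- function(probe_fc, mir_fc, min_cases = 5L,
                                          alpha = 0.05) {
  common <- intersect(rownames(probe_fc), rownames(mir_fc))
  x <- probe_fc[common, , drop = FALSE]
  y <- mir_fc[common, , drop = FALSE]
  m <- ncol(x) * ncol(y)
  results <- .correlate_pairs(x, y, min_cases, alpha, m)
  names(results)[names(results) == "id1"] <- "probe_id"
  names(results)[names(results) == "id2"] <- "mir_id"
  list(results = results,
       plan = list(alpha = alpha, m = m, bonferroni_threshold = alpha / m))
}

#' SNPs nominally correlated with both gene and miRNA expression
#'
#' Intersects, on SNP id, the nominally significant rows of the
#' SNP-vs-expression and SNP-vs-miRNA analyses, and reports each SNP with
#' its partner probes and miRNAs, rho and p-values.
#'
#' @param mrna_results `results` data.frame of
#'   [correlate_snp_vs_expression()] (id1 = SNP).
#' @param mir_results `results` data.frame of [correlate_snp_vs_mirna()]
#'   (id1 = SNP).
#' @return data.frame with `snp_id`, `analysis` (`mrna`/`mirna`),
#'   `partner`, `rho`, `p`.
#' @export
find_dual_correlated_snps <- function(mrna_results, mir_results) {
  m1 <- mrna_results[mrna_results$nominal, , drop = FALSE]
  m2 <- mir_results[mir_results$nominal, , drop = FALSE]
  dual <- intersect(unique(m1$id1), unique(m2$id1))
  if (length(dual) == 0L) {
    return(data.frame(snp_id = character(), analysis = character(),
                      partner = character(), rho = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  a <- m1[m1$id1 %in% dual, , drop = FALSE]
  b <- m2[m2$id1 %in% dual, , drop = FALSE]
  out <- rbind(
    data.frame(snp_id = a$id1, analysis = "mrna", partner = a$id2,
               rho = a$rho, p = a$p, stringsAsFactors = FALSE),
    data.frame(snp_id = b$id1, analysis = "mirna", partner = b$id2,
               rho = b$rho, p = b$p, stringsAsFactors = FALSE)
  )
  out[order(out$snp_id, out$analysis, out$partner), , drop = FALSE]
}

#' Group means of expression by somatic-alteration status
#'
#' Per probe (or miRNA): the mean fold change among cases with somatic
#' DNA alterations, among cases without, and their ratio.
#'
#' @param fc_table data.frame with `case_id`, an item id column (`probe_id`
#'   or `mir_id`), and `fc`.
#' @param altered data.frame with `case_id` and logical `altered`.
#' @param item_col name of the item id column (default `"probe_id"`).
#' @return data.frame with one row per item: group means and ratio.
#' @export
compare_groups_by_alteration <- function(fc_table, altered,
                                         item_col = "probe_id") {
  if (!item_col %in% names(fc_table)) {
    stop("fc_table has no column '", item_col, "'")
  }
  status <- setNames(as.logical(altered$altered), altered$case_id)
  fc_table <- fc_table[!is.na(fc_table$fc), , drop = FALSE]
  fc_table$altered <- status[fc_table$case_id]
  if (all(fc_table$altered, na.rm = TRUE) || !any(fc_table$altered, na.rm = TRUE)) {
    stop("both altered and non-altered groups must be non-empty")
  }
  items <- split(fc_table, fc_table[[item_col]])
  rows <- lapply(names(items), function(it) {
    d <- items[[it]]
    m1 <- mean(d$fc[d$altered], na.rm = TRUE)
    m0 <- mean(d$fc[!d$altered], na.rm = TRUE)
    data.frame(item = it, mean_fc_altered = m1, mean_fc_nonaltered = m0,
               ratio = m1 / m0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- item_col
  rownames(out) <- NULL
  out
}

#' Fold-change matrix (cases x items) from a long fold-change table
#'
#' @param fc_table data.frame with `case_id`, an item id column, and `fc`.
#' @param item_col name of the item id column (default `"probe_id"`).
#' @return numeric matrix with case ids as rows.
#' @export
fc_matrix <- function(fc_table, item_col = "probe_id") {
  cases <- unique(fc_table$case_id)
  items <- unique(fc_table[[item_col]])
  m <- matrix(NA_real_, length(cases), length(items),
              dimnames = list(cases, items))
  m[cbind(match(fc_table$case_id, cases),
          match(fc_table[[item_col]], items))] <- fc_table$fc
  m
}
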