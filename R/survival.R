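#' Dichotomize cases by expression fold change
#'
#' `low` below the cutoff, `high` at or above it (the cutoff itself is
#' high, i.e. FC >= 1 is the high-expression group at the default).
#'
#' @param fc positive numeric vector of fold changes.
#' @param cutoff dichotomization cutoff (default 1.0).
#' @return character vector `low`/`high`.
#' @export
dichotomize_by_fc <- function(fc, cutoff = 1.0) {
  if (any(!is.finite(fc) | fc <= 0)) {
    stop("dichotomize_by_fc: fold changes must be positive and finite")
  }
  ifelse(fc < cutoff, "low", "high")
}

#' Kaplan-Meier curves, median survival and the log-rank test
#'
#' Product-limit estimates per group, the per-group median survival (the
#' first time the survival curve drops to 0.5 or below; `NA` when never
#' reached), and the 1-df log-rank chi-square comparing the groups.
#'
#' @param months numeric follow-up times (> 0).
#' @param event 0/1 event indicators (1 = death observed).
#' @param group group labels (exactly two levels required).
#' @return list with `fit` (the `survfit` object), `medians` (named),
#'   `chisq`, `p`, and `n` per group.
#' @export
km_logrank <- function(months, event, group) {
  if (any(months <= 0)) stop("km_logrank: follow-up times must be > 0")
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("km_logrank: need at least two groups")
  }
  d <- data.frame(months = months, event = event, group = group)
  fit <- survival::survfit(survival::Surv(months, event) ~ group, data = d)
  sm <- summary(fit)$table
  medians <- setNames(sm[, "median"], sub("^group=", "", rownames(sm)))
  if (sum(event) == 0L) {
    # no events anywhere: curves never drop, the log-rank test is undefined
    return(list(fit = fit, medians = medians, chisq = NA_real_, p = NA_real_,
                n = setNames(as.vector(table(group)), levels(group))))
  }
  lr <- survival::survdiff(survival::Surv(months, event) ~ group, data = d)
  df <- length(lr$n) - 1L
  p <- pchisq(lr$chisq, df = df, lower.tail = FALSE)
  list(fit = fit, medians = medians, chisq = unname(lr$chisq), p = p,
       n = setNames(as.vector(lr$n), sub("^group=", "", names(lr$n))))
}

#' Hazard ratio from a single-covariate Cox proportional-hazards model
#'
#' Fits the group indicator by partial likelihood with Efron tie handling;
#' the hazard ratio is `exp(coef)` for the `high` group relative to `low`
#' (or the second factor level relative to the first), with a 95% Wald
#' confidence interval. Non-convergence is flagged, not fatal.
#'
#' @param months,event,group as in [km_logrank()].
#' @return list with `hr`, `ci` (length 2), `p` (Wald), `coef`, `se`,
#'   `converged`.
#' @export
cox_hr <- function(months, event, group) {
  group <- as.factor(group)
  if (all(c("low", "high") %in% levels(group))) {
    group <- stats::relevel(group, ref = "low")
  }
  d <- data.frame(months = months, event = event, group = group)
  fit <- tryCatch(
    survival::coxph(survival::Surv(months, event) ~ group, data = d,
                    ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(months, event) ~ group, data = d,
                        ties = "efron"))
      attr(f, "cnaexpr_warning") <- conditionMessage(w)
      f
    }
  )
  s <- summary(fit)
  coef <- unname(s$coefficients[1, "coef"])
  se <- unname(s$coefficients[1, "se(coef)"])
  list(
    hr = exp(coef),
    ci = exp(coef + c(-1, 1) * 1.96 * se),
    p = unname(s$coefficients[1, "Pr(>|z|)"]),
    coef = coef, se = se,
    converged = is.null(attr(fit, "cnaexpr_warning")),
    diagnostics = attr(fit, "cnaexpr_warning")
  )
}

#' Compare somatic-alteration frequency across a binary covariate
#'
#' Builds the 2x2 table of alteration status against the covariate and
#' tests it with the two-sided Fisher exact test; per-level alteration
#' proportions are reported alongside.
#'
#' @param altered logical vector, one per case.
#' @param covariate logical vector (e.g. positive family history), one per
#'   case.
#' @return list with `table` (2x2), `proportions` (altered fraction per
#'   covariate level), and `p`.
#' @export
compare_alteration_frequency <- function(altered, covariate) {
  altered <- as.logical(altered)
  covariate <- as.logical(covariate)
  ok <- !is.na(altered) & !is.na(covariate)
  altered <- altered[ok]
  covariate <- covariate[ok]
  if (length(unique(covariate)) < 2L) {
    stop("compare_alteration_frequency: both covariate levels must be present")
  }
  tab <- table(factor(covariate, levels = c(FALSE, TRUE)),
               factor(altered, levels = c(FALSE, TRUE)),
               dnn = c("covariate", "altered"))
  prop <- c(`FALSE` = mean(altered[!covariate]),
            `TRUE` = mean(altered[covariate]))
  list(table = tab, proportions = prop,
       p = fisher.test(tab, alternative = "two.sided")$p.value)
}
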