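# Cohort comparison stages: paired modality tests on doses and LSF,
# correlation, dose dichotomization, Kaplan-Meier estimation and the
# log-rank test. All tests are two-sided; significance level 0.05.

#' Paired Student t test
#'
#' Classical paired t on the within-case differences, two-sided p value.
#' A zero-variance nonzero difference is flagged degenerate (`t = Inf`).
#'
#' @param x,y Equal-length numeric vectors (length >= 2), paired by case.
#' @return List with `t`, `df`, `p`, `mean_difference`, `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = length(d) - 1,
                p = if (mean(d) == 0) 1 else 0,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = unname(tt$estimate),
       degenerate = FALSE)
}

#' Pearson correlation with t-based p value
#'
#' @param x,y Numeric vectors, length >= 3, non-constant.
#' @return List with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction by default.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param correct Apply the Yates continuity correction.
#' @return List with `chisq`, `df`, `p`.
#' @export
chi2_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("`table` must be 2x2", call. = FALSE)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate margins", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Dichotomize doses at a threshold
#'
#' `"high"` strictly above the threshold, `"low"` at or below it (so a dose
#' exactly at the threshold is low, matching a `> threshold` definition of
#' the high-dose group).
#'
#' @param doses Numeric vector (Gy).
#' @param threshold Positive threshold (Gy), default 200.
#' @return Character vector of `"high"` / `"low"`.
#' @export
dichotomize_by_dose <- function(doses, threshold = 200) {
  .assert_scalar(threshold, "threshold", lo = 1e-12)
  ifelse(doses > threshold, "high", "low")
}

#' Kaplan-Meier estimate
#'
#' Product-limit survival estimate with the restricted mean (over the
#' observed horizon) and its Greenwood-based standard error, and the median
#' survival time (`NA` when the curve never reaches 0.5).
#'
#' @param time Positive event/censoring times (days).
#' @param event 1 = progression observed, 0 = censored.
#' @return List with `time` and `surv` step-function vectors,
#'   `restricted_mean`, `restricted_mean_se`, `median`, and the underlying
#'   `survival::survfit` object as `fit`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop("need at least one record", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tab <- summary(fit, rmean = max(time))$table
  list(time = fit$time, surv = fit$surv,
       restricted_mean = unname(tab[["rmean"]]),
       restricted_mean_se = unname(tab[["se(rmean)"]]),
       median = unname(tab[["median"]]),
       fit = fit)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank statistic with the hypergeometric variance;
#' tied times share a common risk set.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level grouping vector.
#' @return List with `chisq`, `p`, `observed`, `expected` (per group), and
#'   `degenerate` (`TRUE` when there are no events).
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("`group` must have exactly 2 levels", call. = FALSE)
  if (any(table(group) == 0)) stop("both groups must be non-empty", call. = FALSE)
  if (sum(event) == 0)
    return(list(chisq = NA_real_, p = NA_real_, observed = c(0, 0),
                expected = c(0, 0), degenerate = TRUE))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp),
       degenerate = FALSE)
}

#' Full paired-modality and survival comparison report
#'
#' Orchestrates the study's statistical stages on a cohort: per-compartment
#' paired t tests and Pearson correlations of MAA versus microsphere-PET
#' doses, the paired LSF comparison, dose-group dichotomization of the PET
#' tumor dose, and Kaplan-Meier / log-rank PFS analysis by dose group.
#'
#' @param paired_doses `data.frame` with columns `case`, `compartment`,
#'   `dose_maa`, `dose_pet` (Gy) and, on any rows, `lsf_maa`, `lsf_pet`.
#' @param survival_records `data.frame` with columns `case`, `time_days`,
#'   `event`.
#' @param dose_threshold Gy; tumor-dose cut defining the groups.
#' @return List with `paired` (per-compartment test results), `lsf`
#'   (paired LSF test), `groups` (per-case group labels), `km` (per-group
#'   estimates) and `logrank`.
#' @export
run_comparison <- function(paired_doses, survival_records,
                           dose_threshold = 200) {
  need <- c("case", "compartment", "dose_maa", "dose_pet")
  if (!all(need %in% names(paired_doses)))
    stop("`paired_doses` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  paired <- lapply(split(paired_doses, paired_doses$compartment), function(df) {
    df <- df[order(df$case), ]
    res <- list(n = nrow(df),
                t_test = paired_t_test(df$dose_maa, df$dose_pet))
    res$correlation <- tryCatch(pearson_r(df$dose_maa, df$dose_pet),
                                error = function(e) NULL)
    res
  })
  lsf <- NULL
  if (all(c("lsf_maa", "lsf_pet") %in% names(paired_doses))) {
    one <- paired_doses[!duplicated(paired_doses$case), ]
    lsf <- paired_t_test(one$lsf_maa, one$lsf_pet)
  }
  tumor <- paired_doses[paired_doses$compartment == "tumor", ]
  tumor <- tumor[order(tumor$case), ]
  groups <- data.frame(case = tumor$case,
                       group = dichotomize_by_dose(tumor$dose_pet,
                                                   dose_threshold))
  sv <- merge(survival_records, groups, by = "case")
  km <- lapply(split(sv, sv$group), function(df)
    km_estimate(df$time_days, df$event))
  lr <- if (length(unique(sv$group)) == 2)
    logrank_test(sv$time_days, sv$event, sv$group) else NULL
  list(paired = paired, lsf = lsf, groups = groups, km = km, logrank = lr)
}
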