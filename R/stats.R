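#' Complete-case filter with exclusion report
#'
#' A "case" is a subject: subjects lacking a non-missing value at any
#' scheduled visit are excluded entirely (complete-case analysis). The
#' report gives per-arm excluded counts and percentages, the percentage
#' rounded to the nearest integer for reporting (e.g. 4 incomplete out of
#' 127 reports 3%; 5 out of 124 reports 4%).
#'
#' @param panel long data frame with `subject_id`, `arm`, `visit_month` and
#'   the analysis value column.
#' @param value_col name of the value column (default `"utility"`).
#' @param visits scheduled visits; defaults to the visits present.
#' @return list with `data` (retained rows), `excluded` (excluded subject
#'   ids) and `report` (per-arm `n`, `excluded`, `pct`).
#' @export
complete_cases <- function(panel, value_col = "utility", visits = NULL) {
  if (is.null(visits)) visits <- sort(unique(panel$visit_month))
  sched <- panel[panel$visit_month %in% visits, , drop = FALSE]
  ok_visit <- !is.na(sched[[value_col]])
  n_ok <- tapply(ok_visit, sched$subject_id, sum)
  keep_ids <- names(n_ok)[n_ok == length(visits)]
  excl_ids <- setdiff(unique(sched$subject_id), keep_ids)
  arm_of <- sched$arm[!duplicated(sched$subject_id)]
  names(arm_of) <- sched$subject_id[!duplicated(sched$subject_id)]
  arms <- sort(unique(arm_of))
  report <- data.frame(
    arm = arms,
    n = as.integer(table(factor(arm_of, levels = arms))),
    excluded = as.integer(table(factor(arm_of[excl_ids], levels = arms))))
  report$retained <- report$n - report$excluded
  report$pct <- as.integer(round(100 * report$excluded / report$n))
  out <- sched[sched$subject_id %in% keep_ids, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no complete cases remain after filtering; analysis aborted")
  list(data = out, excluded = excl_ids, report = report)
}

#' Per-subject change from baseline
#'
#' `change = value(visit) - value(baseline)` for every follow-up visit;
#' positive change in utilities means improvement.
#'
#' @inheritParams complete_cases
#' @param baseline_month the baseline visit (default 0).
#' @return data frame with `subject_id`, `arm`, `visit_month`, `baseline`
#'   (baseline value) and `change`.
#' @export
change_from_baseline <- function(panel, value_col = "utility",
                                 baseline_month = 0) {
  base <- panel[panel$visit_month == baseline_month, , drop = FALSE]
  fu <- panel[panel$visit_month != baseline_month, , drop = FALSE]
  bl <- stats::setNames(base[[value_col]], base$subject_id)
  data.frame(subject_id = fu$subject_id,
             arm = fu$arm,
             visit_month = fu$visit_month,
             baseline = as.numeric(bl[fu$subject_id]),
             change = fu[[value_col]] - as.numeric(bl[fu$subject_id]),
             stringsAsFactors = FALSE)
}

# Shared closed-form t machinery. stats::t.test is the independent oracle
# in the test suite; this implementation also covers the zero-variance
# degenerate contract (exact verdict rather than an error).
t_result <- function(estimate, se, df, k_tests, family_alpha, degenerate) {
  if (degenerate) {
    p <- if (estimate == 0) 1 else 0
    tstat <- if (estimate == 0) 0 else sign(estimate) * Inf
    ci <- c(estimate, estimate)
  } else {
    tstat <- estimate / se
    p <- 2 * stats::pt(-abs(tstat), df)
    adj_alpha <- family_alpha / k_tests
    q <- stats::qt(1 - adj_alpha / 2, df)
    ci <- estimate + c(-1, 1) * q * se
  }
  adj <- bonferroni(p, k_tests, family_alpha)
  data.frame(estimate = estimate, se = se, t = tstat, df = df, p = p,
             p_adj = adj$p_adj, threshold = adj$threshold,
             ci_lo = ci[1], ci_hi = ci[2], degenerate = degenerate)
}

#' One-sample t-test of mean change against zero (within-group)
#'
#' Two-tailed Student's t-test on one arm's change scores at one visit
#' (equivalent to a paired t of visit vs baseline), with `df = n - 1` and a
#' confidence interval at the Bonferroni-adjusted level. Zero variance is a
#' degenerate case returning the exact verdict (`p = 1` if the mean is 0,
#' else `p = 0`) rather than an error.
#'
#' @param changes numeric vector of change scores (one arm, one visit).
#' @param k_tests number of tests in the family (follow-up visits;
#'   default 3).
#' @param family_alpha family-wise significance level (default 0.05).
#' @return a one-row data frame: `estimate`, `se`, `t`, `df`, `p`, `p_adj`,
#'   `threshold`, `ci_lo`, `ci_hi`, `degenerate`.
#' @export
within_group_test <- function(changes, k_tests = 3, family_alpha = 0.05) {
  changes <- changes[!is.na(changes)]
  n <- length(changes)
  if (n < 2L) stop("need at least 2 observations")
  s <- stats::sd(changes)
  t_result(mean(changes), s / sqrt(n), n - 1L, k_tests, family_alpha,
           degenerate = s == 0)
}

#' Two-sample Student's t-test on change scores (between-group)
#'
#' Classical pooled-variance two-tailed Student's t-test of arm A's vs arm
#' B's change scores at one visit; `estimate = mean(A) - mean(B)`. A Welch
#' (unequal-variance) switch is provided but the pooled form is the
#' default.
#'
#' @param changes_a,changes_b change scores for the two arms.
#' @param welch use the Welch-Satterthwaite form instead of pooled
#'   variance.
#' @inheritParams within_group_test
#' @return a one-row data frame as in [within_group_test()].
#' @export
between_group_test <- function(changes_a, changes_b, k_tests = 3,
                               family_alpha = 0.05, welch = FALSE) {
  a <- changes_a[!is.na(changes_a)]
  b <- changes_b[!is.na(changes_b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need at least 2 observations per arm")
  est <- mean(a) - mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    return(t_result(est, 0, na + nb - 2L, k_tests, family_alpha, TRUE))
  if (welch) {
    se <- sqrt(va / na + vb / nb)
    df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2L
  }
  t_result(est, se, df, k_tests, family_alpha, FALSE)
}

#' Bonferroni correction for the follow-up-visit test family
#'
#' Per-test threshold `family_alpha / k` and adjusted p-values
#' `min(1, k * p)`. With the default family of three follow-up visits at
#' `family_alpha = 0.05` the threshold is 0.0167, conventionally reported
#' as 0.017 at three decimals.
#'
#' @param p numeric vector of raw p-values.
#' @param k number of tests in the family.
#' @param family_alpha family-wise level.
#' @return list with `threshold` and `p_adj`.
#' @export
bonferroni <- function(p, k, family_alpha = 0.05) {
  if (k < 1) stop("k must be >= 1")
  list(threshold = family_alpha / k, p_adj = pmin(1, k * p))
}

#' Repeated-measures ANOVA of utilities over time
#'
#' Classical univariate mixed two-way ANOVA (between factor: arm; within
#' factor: visit; subjects nested in arm) fitted with [stats::aov()] and an
#' `Error(subject)` stratum. Reports F, degrees of freedom and p for the
#' arm main effect (tested against the between-subject stratum) and for the
#' visit and arm-by-visit effects (within-subject stratum). A
#' Greenhouse-Geisser epsilon estimated from the pooled within-arm
#' covariance of the visit-wise values is reported alongside (with
#' GG-corrected p-values for the within-subject effects) but the
#' uncorrected tests are the primary output.
#'
#' @inheritParams complete_cases
#' @return data frame with one row per effect (`arm`, `visit`,
#'   `arm:visit`): `df1`, `df2`, `F`, `p`, and for within-subject effects
#'   `p_gg`; Greenhouse-Geisser epsilon in attribute `"gg_epsilon"`.
#' @export
repeated_measures_anova <- function(panel, value_col = "utility") {
  d <- data.frame(y = panel[[value_col]],
                  arm = factor(panel$arm),
                  visit = factor(panel$visit_month),
                  subject = factor(panel$subject_id))
  if (nlevels(d$arm) < 2L || nlevels(d$visit) < 2L)
    stop("singular design: need two arms and at least two visits")
  fit <- stats::aov(y ~ arm * visit + Error(subject), data = d)
  s <- summary(fit)
  betw <- s[["Error: subject"]][[1L]]
  with_ <- s[["Error: Within"]][[1L]]
  rn <- function(tab) trimws(rownames(tab))
  pick <- function(tab, eff) which(rn(tab) == eff)
  eps <- gg_epsilon(d)
  rows <- list(
    arm = c(tab = 1, i = pick(betw, "arm")),
    visit = c(tab = 2, i = pick(with_, "visit")),
    `arm:visit` = c(tab = 2, i = pick(with_, "arm:visit")))
  out <- do.call(rbind, lapply(names(rows), function(eff) {
    tab <- if (rows[[eff]]["tab"] == 1) betw else with_
    i <- rows[[eff]]["i"]
    resid_i <- pick(tab, "Residuals")
    df1 <- tab[i, "Df"]; df2 <- tab[resid_i, "Df"]
    Fv <- tab[i, "F value"]; p <- tab[i, "Pr(>F)"]
    p_gg <- if (rows[[eff]]["tab"] == 2)
      stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
    else NA_real_
    data.frame(effect = eff, df1 = df1, df2 = df2, F = Fv, p = p,
               p_gg = p_gg)
  }))
  attr(out, "gg_epsilon") <- eps
  out
}

# Greenhouse-Geisser epsilon from the pooled within-arm covariance of the
# subject x visit value matrix.
gg_epsilon <- function(d) {
  k <- nlevels(d$visit)
  wide <- stats::reshape(d[c("subject", "visit", "y")],
                         idvar = "subject", timevar = "visit",
                         direction = "wide")
  arm_of <- d$arm[!duplicated(d$subject)]
  names(arm_of) <- d$subject[!duplicated(d$subject)]
  wide$arm <- arm_of[as.character(wide$subject)]
  Y <- as.matrix(wide[, grep("^y\\.", names(wide)), drop = FALSE])
  S <- matrix(0, k, k)
  tot <- 0
  for (a in levels(d$arm)) {
    Ya <- Y[wide$arm == a, , drop = FALSE]
    if (nrow(Ya) > 1L) {
      S <- S + stats::cov(Ya) * (nrow(Ya) - 1L)
      tot <- tot + nrow(Ya) - 1L
    }
  }
  S <- S / tot
  C <- qr.Q(qr(stats::contr.helmert(k)))
  M <- t(C) %*% S %*% C
  sum(diag(M))^2 / ((k - 1) * sum(M^2))
}

#' Responsiveness statistics: effect size and standardized response mean
#'
#' `ES = mean change / SD of baseline values`;
#' `SRM = mean change / SD of change scores` (sample SDs, n-1 denominator).
#' Zero SD in either denominator yields `NA` for that statistic with a
#' degenerate flag — never a silent infinity.
#'
#' @param changes change scores for one group at one visit.
#' @param baselines baseline values for the same subjects.
#' @param group label for the group (e.g. `"A"`, `"B"`, `"combined"`).
#' @return one-row data frame: `group`, `n`, `mean_change`, `es`, `srm`,
#'   `degenerate`.
#' @export
responsiveness <- function(changes, baselines, group = "combined") {
  ok <- !is.na(changes) & !is.na(baselines)
  changes <- changes[ok]; baselines <- baselines[ok]
  if (length(changes) < 2L) stop("need at least 2 observations")
  mc <- mean(changes)
  sdb <- stats::sd(baselines); sdc <- stats::sd(changes)
  data.frame(group = group, n = length(changes), mean_change = mc,
             es = if (sdb > 0) mc / sdb else NA_real_,
             srm = if (sdc > 0) mc / sdc else NA_real_,
             degenerate = sdb == 0 || sdc == 0)
}

#' Severity-stratified distribution summaries (H&Y boxplot statistics)
#'
#' Per H&Y stage Tukey boxplot statistics of a value (utility or PDQ-39
#' summary index): median and quartiles by linear interpolation
#' (`stats::quantile` type 7 — fixed because boxplot statistics depend on
#' the convention), whiskers at the most extreme observations within
#' 1.5 x IQR of the box, and the observations beyond the whiskers listed as
#' outliers. Empty stages are omitted; stages with fewer than `min_n`
#' observations are flagged low-reliability.
#'
#' @param stage numeric vector of H&Y stages per observation (subject-visit
#'   records from all visits).
#' @param value numeric vector of the measure.
#' @param min_n reliability floor (default 10).
#' @return data frame with one row per observed stage: `hy_stage`, `n`,
#'   `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`, `n_outliers`,
#'   `low_reliability`; the outlier values per stage in attribute
#'   `"outliers"` (a named list).
#' @export
hy_strata <- function(stage, value, min_n = 10L) {
  ok <- !is.na(stage) & !is.na(value)
  stage <- stage[ok]; value <- value[ok]
  if (!all(stage %in% HY_STAGES))
    stop("stages must be drawn from the modified H&Y scale ",
         paste(HY_STAGES, collapse = ", "))
  stages <- sort(unique(stage))
  outliers <- list()
  out <- do.call(rbind, lapply(stages, function(s) {
    v <- value[stage == s]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    outliers[[as.character(s)]] <<- v[v < lo_fence | v > hi_fence]
    data.frame(hy_stage = s, n = length(v), median = q[2], q1 = q[1],
               q3 = q[3], whisker_lo = min(inside), whisker_hi = max(inside),
               n_outliers = sum(v < lo_fence | v > hi_fence),
               low_reliability = length(v) < min_n)
  }))
  attr(out, "outliers") <- outliers
  out
}
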