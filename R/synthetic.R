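#' Specify a two-arm longitudinal PDQ-39 trial design
#'
#' Bundles and validates the parameters of the synthetic trial generator.
#' Defaults emulate a DBS-vs-best-medical-therapy trial in Parkinson's
#' disease with early motor complications: 124 subjects in the stimulation
#' arm (A) and 127 in the medical-therapy arm (B), visits at baseline and 5,
#' 12 and 24 months, mean age 52, baseline Hoehn & Yahr at most 2.5, a
#' between-arm PDQ-39 summary-index treatment effect of 8 points at
#' follow-up, and roughly 3-4% of subjects with an incomplete visit record.
#'
#' @param n_arm_a,n_arm_b subjects per arm (arm A is the intervention-like
#'   arm that improves).
#' @param visits ordered month offsets; first must be baseline (0).
#' @param baseline_si_mean,baseline_si_sd baseline PDQ-39 summary-index mean
#'   and total between-subject SD, in PDQ-39 points.
#' @param arm_effect_si between-arm difference in SI change from baseline at
#'   follow-up visits (points; positive = arm A improves, i.e. its latent SI
#'   drops by this much relative to arm B).
#' @param within_subject_corr correlation of a subject's latent SI across
#'   visits, in `[0, 1)`; realised as the random-intercept variance share.
#' @param subscale_spread_sd SD of the independent noise added to the latent
#'   index to produce each of the eight subscale values (points).
#' @param age_mean,age_sd age distribution (years).
#' @param prop_female proportion of female subjects.
#' @param hy_probs named probability vector over baseline H&Y stages; must
#'   sum to 1. Stages 3-5 default to probability 0 (excluded at enrolment)
#'   but are permitted.
#' @param hy_si_slope PDQ-39 points of latent summary index per H&Y stage:
#'   more severe stages carry worse (higher) baseline severity, so mapped
#'   utilities fall with stage as they do in observed PD data. The
#'   stage-driven share of the subject-level variance is carved out of the
#'   random-intercept variance, keeping the total baseline SD at
#'   `baseline_si_sd`. Set 0 for stage-independent severity.
#' @param missing_case_rate per-subject probability of being an incomplete
#'   case (at least one follow-up visit's subscales withheld).
#' @param seed integer seed governing all randomness of the generator.
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(n_arm_a = 124L, n_arm_b = 127L,
                         visits = c(0, 5, 12, 24),
                         baseline_si_mean = 32, baseline_si_sd = 12,
                         arm_effect_si = 8, within_subject_corr = 0.6,
                         subscale_spread_sd = 8,
                         age_mean = 52, age_sd = 6, prop_female = 0.40,
                         hy_probs = c("0" = 0.02, "1" = 0.15, "1.5" = 0.18,
                                      "2" = 0.40, "2.5" = 0.25),
                         hy_si_slope = 6, missing_case_rate = 9 / 251,
                         seed = 1L) {
  d <- structure(as.list(environment()), class = "trial_design")
  validate_design(d)
  d
}

validate_design <- function(d) {
  stopifnot(d$n_arm_a >= 0, d$n_arm_b >= 0, d$n_arm_a + d$n_arm_b > 0)
  if (length(d$visits) < 2L || d$visits[1] != 0 ||
      any(diff(d$visits) <= 0))
    stop("visits must start at baseline (0) and be strictly increasing")
  if (d$baseline_si_sd <= 0 || d$subscale_spread_sd <= 0 || d$age_sd <= 0)
    stop("all SDs must be > 0")
  if (d$within_subject_corr < 0 || d$within_subject_corr >= 1)
    stop("within_subject_corr must be in [0, 1)")
  for (p in c(d$prop_female, d$missing_case_rate))
    if (p < 0 || p > 1) stop("proportions must be in [0, 1]")
  if (abs(sum(d$hy_probs) - 1) > 1e-9)
    stop("hy_probs must sum to 1")
  if (!all(names(d$hy_probs) %in% as.character(HY_STAGES)))
    stop("hy_probs names must be H&Y stages")
  stages <- as.numeric(names(d$hy_probs))
  mu_hy <- sum(stages * d$hy_probs)
  var_hy <- sum((stages - mu_hy)^2 * d$hy_probs)
  if (d$hy_si_slope^2 * var_hy >
      d$within_subject_corr * d$baseline_si_sd^2)
    stop("hy_si_slope too steep: stage-driven variance exceeds the ",
         "subject-level variance share")
  # Reject scenarios where clipping subscales to [0, 100] would absorb more
  # than half the intended treatment effect (baseline too near a boundary).
  if (d$arm_effect_si > 0) {
    s <- sqrt(d$baseline_si_sd^2 + d$subscale_spread_sd^2)
    realised <- clipnorm_mean(d$baseline_si_mean, s) -
      clipnorm_mean(d$baseline_si_mean - d$arm_effect_si, s)
    if (realised < d$arm_effect_si / 2)
      stop("unusable scenario: truncation at [0, 100] would absorb more ",
           "than half the intended effect (realised ",
           signif(realised, 3), " of ", d$arm_effect_si, " points)")
  }
  invisible(d)
}

# Mean of a N(mu, sd) variable clipped to [0, 100] (closed form).
clipnorm_mean <- function(mu, sd) {
  a <- (0 - mu) / sd
  b <- (100 - mu) / sd
  100 * (1 - stats::pnorm(b)) + mu * (stats::pnorm(b) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(b))
}

#' Generate a synthetic two-arm longitudinal PDQ-39 trial
#'
#' Simulates subject-level latent PDQ-39 summary-index trajectories under a
#' split between a subject random intercept and occasion noise (the
#' intercept's variance share equals `within_subject_corr`), with
#' visit-specific arm means: both arms start at `baseline_si_mean`; at every
#' follow-up visit arm A's latent mean is lower (better) by `arm_effect_si`
#' while arm B stays flat, so the expected between-arm difference in SI
#' change from baseline at the final visit equals `arm_effect_si`. Each of
#' the eight subscale values is the subject-visit latent index plus
#' independent `N(0, subscale_spread_sd)` noise, clipped to `[0, 100]`
#' (clipping, not resampling — a small bias source in extreme scenarios).
#' H&Y stage is sampled at baseline, held fixed, and shifts the subject's
#' latent severity by `hy_si_slope` points per stage (centred at the design's
#' expected stage), so severity-stratified summaries show the worse-HRQoL-
#' with-stage gradient seen in observed PD data. A fraction
#' `missing_case_rate` of subjects is flagged incomplete and has the
#' subscales of one randomly chosen follow-up visit withheld (`NA`),
#' matching subject-level complete-case semantics.
#'
#' Deterministic given the seed; no global RNG state is disturbed.
#'
#' @param design a [trial_design()].
#' @param seed optional override of `design$seed` (useful for replicate
#'   studies).
#' @return a data frame with one row per subject x scheduled visit:
#'   `subject_id`, `arm`, `visit_month`, `age`, `gender`, `hy_stage`, the
#'   eight subscale columns, `si` (mean of the eight), `complete`.
#' @export
generate_trial <- function(design, seed = design$seed) {
  validate_design(design)
  withr::with_seed(as.integer(seed), {
    n <- design$n_arm_a + design$n_arm_b
    k <- length(design$visits)
    arm <- rep(c("A", "B"), c(design$n_arm_a, design$n_arm_b))
    id <- sprintf("%s%03d", arm, c(seq_len(design$n_arm_a),
                                   seq_len(design$n_arm_b)))
    age <- round(stats::rnorm(n, design$age_mean, design$age_sd), 1)
    gender <- ifelse(stats::runif(n) < design$prop_female,
                     "female", "male")
    hy <- sample(as.numeric(names(design$hy_probs)), n, replace = TRUE,
                 prob = design$hy_probs)
    stages <- as.numeric(names(design$hy_probs))
    mu_hy <- sum(stages * design$hy_probs)
    var_hy <- sum((stages - mu_hy)^2 * design$hy_probs)
    var_b <- design$within_subject_corr * design$baseline_si_sd^2
    sd_w <- sqrt(1 - design$within_subject_corr) * design$baseline_si_sd
    # subject intercept = stage-driven severity + residual heterogeneity;
    # the split keeps the total subject-level variance at var_b
    sd_b_resid <- sqrt(var_b - design$hy_si_slope^2 * var_hy)
    b <- design$hy_si_slope * (hy - mu_hy) +
      stats::rnorm(n, 0, sd_b_resid)
    # visit-specific arm means: arm A improves by the full effect at every
    # follow-up visit, arm B stays flat
    shift <- outer(arm == "A", design$visits > 0) * design$arm_effect_si
    latent <- design$baseline_si_mean - shift + b +
      matrix(stats::rnorm(n * k, 0, sd_w), n, k)
    rec <- data.frame(
      subject_id = rep(id, each = k),
      arm = rep(arm, each = k),
      visit_month = rep(design$visits, times = n),
      age = rep(age, each = k),
      gender = rep(gender, each = k),
      hy_stage = rep(hy, each = k),
      stringsAsFactors = FALSE)
    lat_long <- as.vector(t(latent))
    sub <- matrix(stats::rnorm(n * k * 8, lat_long, design$subscale_spread_sd),
                  ncol = 8)
    sub <- pmin(pmax(sub, 0), 100)
    colnames(sub) <- PDQ_SUBSCALES
    rec <- cbind(rec, as.data.frame(sub))
    incomplete <- stats::runif(n) < design$missing_case_rate
    withheld_visit <- design$visits[-1][sample.int(k - 1L, n, replace = TRUE)]
    drop_row <- rep(incomplete, each = k) &
      rec$visit_month == rep(withheld_visit, each = k)
    rec[drop_row, PDQ_SUBSCALES] <- NA_real_
    rec$si <- rowMeans(rec[PDQ_SUBSCALES])
    rec$complete <- rep(!incomplete, each = k)
    rec
  })
}

#' Draw probabilistic ground-truth EQ-5D-3L states for records
#'
#' For each mappable record, draws one level per EQ-5D dimension from the
#' mapping model's predicted probability triple (a random draw, not the
#' argmax), giving a probabilistic ground truth against which the
#' deterministic argmax predictor's accuracy can be measured. Records with
#' withheld subscales (or, for the multinomial family, missing age/gender)
#' get `NA` levels. Deterministic given the seed.
#'
#' @param records data frame of trial records as from [generate_trial()].
#' @param model a `pdq_mapping_model`.
#' @param seed integer seed.
#' @return integer matrix (rows = records, columns = EQ-5D dimensions) of
#'   drawn levels.
#' @export
generate_true_states <- function(records, model, seed) {
  ok <- stats::complete.cases(records[PDQ_SUBSCALES])
  out <- matrix(NA_integer_, nrow(records), length(EQ5D_DIMENSIONS),
                dimnames = list(NULL, EQ5D_DIMENSIONS))
  if (!any(ok)) return(out)
  pred <- predict_states(model, records[ok, , drop = FALSE])
  withr::with_seed(as.integer(seed), {
    for (d in EQ5D_DIMENSIONS) {
      p <- pred$probs[, paste(d, c("p1", "p2", "p3"), sep = "."),
                      drop = FALSE]
      u <- stats::runif(nrow(p))
      out[ok, d] <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])
    }
  })
  out
}

#' Write / read the standard subject-level trial table
#'
#' Plain comma-delimited text with a header row: the interchange format
#' consumed by the pipeline (`subject_id`, `arm`, `visit_month`, `age`,
#' `gender`, `hy_stage`, the eight subscale columns, and any derived
#' columns).
#'
#' @param records data frame of trial records.
#' @param path file path.
#' @return `read_trial_table` returns the data frame; `write_trial_table`
#'   returns `path` invisibly.
#' @export
write_trial_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
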