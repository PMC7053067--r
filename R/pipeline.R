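#' Full trial analysis battery on a utility panel
#'
#' Runs the longitudinal comparison the package exists for: complete-case
#' filtering, per-subject change from baseline, within-arm and between-arm
#' Bonferroni-adjusted Student's t-tests at every follow-up visit,
#' repeated-measures ANOVA of the values over time, and responsiveness
#' statistics (ES, SRM) per arm and combined.
#'
#' @param panel long data frame: `subject_id`, `arm`, `visit_month` and the
#'   value column.
#' @param value_col analysis value column (default `"utility"`).
#' @param family_alpha family-wise significance level (default 0.05; the
#'   per-test Bonferroni threshold divides it by the number of follow-up
#'   visits).
#' @return list with `exclusions` (complete-case report), `within`
#'   (per arm x visit), `between` (per visit), `anova`, `responsiveness`
#'   (per group x visit), and `changes` (per-subject change scores).
#' @export
trial_analysis <- function(panel, value_col = "utility",
                           family_alpha = 0.05) {
  cc <- complete_cases(panel, value_col = value_col)
  ch <- change_from_baseline(cc$data, value_col = value_col)
  fu <- sort(unique(ch$visit_month))
  k <- length(fu)
  arms <- sort(unique(ch$arm))
  within <- do.call(rbind, lapply(fu, function(v) {
    do.call(rbind, lapply(arms, function(a) {
      r <- within_group_test(ch$change[ch$arm == a & ch$visit_month == v],
                             k_tests = k, family_alpha = family_alpha)
      cbind(arm = a, visit_month = v, r)
    }))
  }))
  between <- do.call(rbind, lapply(fu, function(v) {
    r <- between_group_test(
      ch$change[ch$arm == arms[1] & ch$visit_month == v],
      ch$change[ch$arm == arms[2] & ch$visit_month == v],
      k_tests = k, family_alpha = family_alpha)
    cbind(visit_month = v, r)
  }))
  groups <- c(stats::setNames(as.list(arms), arms), list(combined = arms))
  resp <- do.call(rbind, lapply(fu, function(v) {
    do.call(rbind, lapply(names(groups), function(g) {
      sel <- ch$visit_month == v & ch$arm %in% groups[[g]]
      cbind(visit_month = v,
            responsiveness(ch$change[sel], ch$baseline[sel], group = g))
    }))
  }))
  list(exclusions = cc$report,
       within = within,
       between = between,
       anova = repeated_measures_anova(cc$data, value_col = value_col),
       responsiveness = resp,
       changes = ch)
}

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with keys: `data` (path to the subject-level
#' delimited-text table), `granularity` (`"items"` or `"subscales"`),
#' `family` (`"ordinal"`, `"multinomial"` or `"both"`), `coefficients`
#' (named paths per family), `value_sets` (one or more paths),
#' `family_alpha` (default 0.05), and optional `outdir`.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$data)) stop("config: 'data' (input table path) required")
  cfg$granularity <- cfg$granularity %||% "subscales"
  if (!cfg$granularity %in% c("items", "subscales"))
    stop("config: granularity must be 'items' or 'subscales'")
  cfg$family <- cfg$family %||% "both"
  if (!cfg$family %in% c("ordinal", "multinomial", "both"))
    stop("config: family must be 'ordinal', 'multinomial' or 'both'")
  fams <- if (cfg$family == "both") c("ordinal", "multinomial") else cfg$family
  for (f in fams)
    if (is.null(cfg$coefficients[[f]]))
      stop("config: coefficients path for family '", f, "' required")
  if (is.null(cfg$value_sets) || !length(cfg$value_sets))
    stop("config: at least one value set required")
  cfg$family_alpha <- as.numeric(cfg$family_alpha %||% 0.05)
  cfg$families <- fams
  cfg
}

#' Run the full mapping pipeline
#'
#' Ingest -> score -> map (per family) -> tariff (per value set) ->
#' longitudinal analysis, producing one utility panel and one statistics
#' bundle per family x country combination. With an `outdir`, every table
#' is also written as delimited text; partial runs never emit result
#' tables (validation aborts before computation).
#'
#' @param config a config list (see [read_run_config()]) or a YAML path.
#' @return nested list: `data` (scored subject table), and per
#'   `<family>.<country>` a list with `panel` (subject x visit utilities)
#'   and `stats` (the [trial_analysis()] bundle), plus `hy` (H&Y strata
#'   summaries of the utilities and of the observed summary index).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  data <- read_trial_table(cfg$data)
  if (cfg$granularity == "items") data <- score_items_table(data)
  miss <- setdiff(PDQ_SUBSCALES, names(data))
  if (length(miss))
    stop("input table lacks subscale column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(data$si)) data$si <- rowMeans(data[PDQ_SUBSCALES])
  models <- lapply(stats::setNames(cfg$families, cfg$families),
                   function(f) {
    m <- load_mapping_model(cfg$coefficients[[f]])
    if (!identical(m$family, f))
      stop("coefficient file for '", f, "' declares family '", m$family, "'")
    if (f == "multinomial" &&
        (is.null(data$age) || is.null(data$gender)))
      stop("multinomial family requires 'age' and 'gender' columns in the ",
           "input data")
    m
  })
  vsets <- lapply(cfg$value_sets, load_value_set)
  names(vsets) <- vapply(vsets, `[[`, character(1), "country")
  mappable <- stats::complete.cases(data[PDQ_SUBSCALES])
  results <- list(data = data)
  for (f in cfg$families) {
    pred <- predict_states(models[[f]], data[mappable, , drop = FALSE])
    for (cn in names(vsets)) {
      u <- rep(NA_real_, nrow(data))
      u[mappable] <- eq5d_utility(pred$levels, vsets[[cn]])
      panel <- data.frame(subject_id = data$subject_id, arm = data$arm,
                          visit_month = data$visit_month,
                          age = data$age, gender = data$gender,
                          hy_stage = data$hy_stage, utility = u,
                          stringsAsFactors = FALSE)
      key <- paste(f, cn, sep = ".")
      results[[key]] <- list(
        panel = panel,
        stats = trial_analysis(panel, family_alpha = cfg$family_alpha),
        hy = hy_strata(panel$hy_stage, panel$utility))
    }
  }
  results$hy_si <- hy_strata(data$hy_stage, data$si)
  if (!is.null(cfg$outdir)) write_run_artifacts(results, cfg)
  invisible(results)
}

write_run_artifacts <- function(results, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name)
    utils::write.csv(x, file.path(cfg$outdir, paste0(name, ".csv")),
                     row.names = FALSE)
  for (key in setdiff(names(results), c("data", "hy_si"))) {
    st <- results[[key]]$stats
    wr(results[[key]]$panel, paste0(key, "_panel"))
    wr(st$within, paste0(key, "_within"))
    wr(st$between, paste0(key, "_between"))
    wr(st$anova, paste0(key, "_anova"))
    wr(st$responsiveness, paste0(key, "_responsiveness"))
    wr(st$exclusions, paste0(key, "_exclusions"))
    wr(results[[key]]$hy, paste0(key, "_hy_strata"))
  }
  wr(results$hy_si, "pdq39_si_hy_strata")
  invisible(NULL)
}

#' Simulate a trial and write the standard interchange table
#'
#' Generates a synthetic trial from a design (a [trial_design()] or a YAML
#' file whose keys mirror its fields) and writes the subject-level
#' delimited-text table consumed by [run_pipeline()].
#'
#' @param design a `trial_design` or YAML path.
#' @param path output CSV path.
#' @return the generated data frame, invisibly.
#' @export
simulate_trial_file <- function(design, path) {
  if (is.character(design)) {
    cfg <- yaml::read_yaml(design)
    if (!is.null(cfg$hy_probs)) cfg$hy_probs <- unlist(cfg$hy_probs)
    if (!is.null(cfg$visits)) cfg$visits <- as.numeric(unlist(cfg$visits))
    design <- do.call(trial_design, cfg)
  }
  rec <- generate_trial(design)
  write_trial_table(rec, path)
  message(sprintf(
    "simulated %d + %d subjects x %d visits -> %s (%d rows)",
    design$n_arm_a, design$n_arm_b, length(design$visits), path, nrow(rec)))
  invisible(rec)
}
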