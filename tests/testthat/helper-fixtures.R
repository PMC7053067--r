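extdata <- function(f) system.file("extdata", f, package = "pdqmap")

demo_ordinal <- function() load_mapping_model(extdata("demo_ordinal.yaml"))
demo_multinomial <- function() load_mapping_model(extdata("demo_multinomial.yaml"))
uk_value_set <- function() load_value_set(extdata("uk_tto.yaml"))
test_value_set <- function() load_value_set(extdata("test_valueset.yaml"))

# random valid subscale profiles as a data frame
random_profiles <- function(n) {
  m <- matrix(stats::runif(n * 8, 0, 100), n, 8,
              dimnames = list(NULL, PDQ_SUBSCALES))
  as.data.frame(m)
}

# write a temporary ordinal coefficient YAML with given per-dimension
# alpha/beta (same for all five dimensions unless a list is given)
write_ordinal_yaml <- function(alpha, beta) {
  dims <- lapply(EQ5D_DIMENSIONS, function(d)
    list(alpha = alpha, beta = as.list(beta)))
  names(dims) <- EQ5D_DIMENSIONS
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(list(family = "ordinal", label = "tmp",
                        dimensions = dims), path)
  path
}

# small utility panel in long format
make_panel <- function(values, arms, visits = c(0, 5, 12, 24)) {
  n <- nrow(values)
  data.frame(
    subject_id = rep(sprintf("S%03d", seq_len(n)), each = length(visits)),
    arm = rep(arms, each = length(visits)),
    visit_month = rep(visits, times = n),
    utility = as.vector(t(values)))
}

# map a generated trial through a model family and value set to a panel
map_to_panel <- function(rec, model, vs) {
  ok <- stats::complete.cases(rec[PDQ_SUBSCALES])
  u <- rep(NA_real_, nrow(rec))
  u[ok] <- eq5d_utility(predict_states(model, rec[ok, , drop = FALSE])$levels,
                        vs)
  data.frame(subject_id = rec$subject_id, arm = rec$arm,
             visit_month = rec$visit_month, hy_stage = rec$hy_stage,
             utility = u, stringsAsFactors = FALSE)
}
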