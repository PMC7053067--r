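#' Load a mapping-model coefficient file
#'
#' Reads a YAML coefficient file describing one family of EQ-5D-3L
#' response-mapping models (one model per dimension) and validates it
#' strictly. Two families are supported:
#'
#' * `ordinal` — cumulative model with Cauchit (inverse-Cauchy) link per
#'   dimension: cut-points `alpha = c(alpha1, alpha2)` with
#'   `alpha1 < alpha2`, and a slope vector `beta` over a declared subset of
#'   the eight PDQ-39 subscales (units: per PDQ-39 point).
#' * `multinomial` — multinomial logit per dimension with level 1 ("no
#'   problems") as the pivot outcome (linear score fixed at 0); levels 2 and
#'   3 each carry an intercept plus coefficients over the eight subscales,
#'   age in years, and a gender indicator. The file declares the gender
#'   coding (default: 1 = female) and an optional age-centering constant.
#'
#' Validation failures are load-time errors with the offending dimension
#' named; prediction never re-validates.
#'
#' @param path path to the YAML file.
#' @return an object of class `pdq_mapping_model`.
#' @export
load_mapping_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  family <- cfg$family
  if (is.null(family) || !family %in% c("ordinal", "multinomial"))
    stop("mapping file ", path, ": 'family' must be 'ordinal' or 'multinomial'")
  dims <- cfg$dimensions
  if (!setequal(names(dims), EQ5D_DIMENSIONS))
    stop("mapping file ", path, ": dimensions must be exactly {",
         paste(EQ5D_DIMENSIONS, collapse = ", "), "}")
  if (identical(family, "ordinal")) {
    models <- lapply(EQ5D_DIMENSIONS, function(d) {
      b <- dims[[d]]
      alpha <- as.numeric(unlist(b$alpha))
      if (length(alpha) != 2L || anyNA(alpha))
        stop("dimension ", d, ": 'alpha' must be two numeric cut-points")
      if (!(alpha[1] < alpha[2]))
        stop("dimension ", d, ": alpha1 must be < alpha2")
      beta <- unlist(b$beta)
      if (is.null(beta) || !length(beta))
        stop("dimension ", d, ": 'beta' must name at least one subscale")
      bad <- setdiff(names(beta), PDQ_SUBSCALES)
      if (length(bad))
        stop("dimension ", d, ": unknown subscale(s) ",
             paste(bad, collapse = ", "))
      list(alpha = alpha, beta = beta)
    })
  } else {
    covars <- c("intercept", PDQ_SUBSCALES, "age", "female")
    models <- lapply(EQ5D_DIMENSIONS, function(d) {
      b <- dims[[d]]
      expand <- function(lv) {
        co <- unlist(b[[lv]])
        if (is.null(co)) stop("dimension ", d, ": missing '", lv, "' block")
        bad <- setdiff(names(co), covars)
        if (length(bad))
          stop("dimension ", d, " ", lv, ": unknown covariate(s) ",
               paste(bad, collapse = ", "))
        full <- stats::setNames(numeric(length(covars)), covars)
        full[names(co)] <- co
        full
      }
      list(level2 = expand("level2"), level3 = expand("level3"))
    })
  }
  names(models) <- EQ5D_DIMENSIONS
  gc_ <- cfg$gender_coding
  female_code <- if (is.null(gc_$female)) 1 else as.numeric(gc_$female)
  structure(list(family = family,
                 label = cfg$label %||% basename(path),
                 dimensions = models,
                 female_code = female_code,
                 age_center = as.numeric(cfg$age_center %||% 0)),
            class = "pdq_mapping_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pdq_mapping_model <- function(x, ...) {
  cat("EQ-5D-3L response-mapping model set (", x$family, " family): ",
      x$label, "\n", sep = "")
  invisible(x)
}

#' Cauchit cumulative-link probabilities for one dimension
#'
#' For linear predictor `eta = beta'X` over the covered subscale indices,
#' the cumulative probability of "no problems" is
#' `p1 = 0.5 - atan(-alpha1 + eta)/pi` and the cumulative probability of
#' "no or some problems" is `c2 = 0.5 - atan(-alpha2 + eta)/pi`; then
#' `p2 = c2 - p1` and `p3 = 1 - c2`. `atan` is the principal branch in
#' radians. Vectorised over rows of `profile`.
#'
#' @param dim_model one dimension's entry of an ordinal
#'   `pdq_mapping_model` (`list(alpha, beta)`).
#' @param profile named numeric vector of subscale indices, or a data frame
#'   / matrix with subscale columns.
#' @return a numeric matrix with columns `p1`, `p2`, `p3` (rows sum to 1).
#' @export
ordinal_probs <- function(dim_model, profile) {
  X <- profile_matrix(profile, names(dim_model$beta))
  eta <- drop(X %*% dim_model$beta)
  p1 <- 0.5 - atan(-dim_model$alpha[1] + eta) / pi
  c2 <- 0.5 - atan(-dim_model$alpha[2] + eta) / pi
  cbind(p1 = p1, p2 = c2 - p1, p3 = 1 - c2)
}

#' Multinomial-logit probabilities for one dimension
#'
#' Level 1 is the pivot outcome with linear score `s1 = 0`; levels 2 and 3
#' have scores `s2 = beta2'x`, `s3 = beta3'x` where `x` stacks an intercept,
#' the eight subscale indices, age (years, minus any declared centering
#' constant) and the gender indicator. Probabilities are the softmax of
#' `(s1, s2, s3)`, computed with max-subtraction so extreme scores cannot
#' overflow.
#'
#' @param dim_model one dimension's entry of a multinomial
#'   `pdq_mapping_model` (`list(level2, level3)`).
#' @param profile subscale indices as in [ordinal_probs()] (all eight
#'   required).
#' @param age numeric vector of ages in years.
#' @param female numeric/logical indicator, 1 = female under the default
#'   coding.
#' @param age_center centering constant subtracted from age (default 0).
#' @return a numeric matrix with columns `p1`, `p2`, `p3` (rows sum to 1).
#' @export
multinomial_probs <- function(dim_model, profile, age, female,
                              age_center = 0) {
  X <- profile_matrix(profile, PDQ_SUBSCALES)
  if (anyNA(age) || anyNA(female))
    stop("age and gender are required covariates for the multinomial family")
  Z <- cbind(intercept = 1, X, age = as.numeric(age) - age_center,
             female = as.numeric(female))
  s2 <- drop(Z %*% dim_model$level2)
  s3 <- drop(Z %*% dim_model$level3)
  s <- cbind(0, s2, s3)
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  p <- e / rowSums(e)
  colnames(p) <- c("p1", "p2", "p3")
  p
}

# Coerce a profile (named vector, data frame, or matrix) to a row matrix
# with the requested subscale columns; missing covariates are a hard error
# (unmapped-record signal).
profile_matrix <- function(profile, needed) {
  if (is.null(dim(profile))) {
    profile <- matrix(profile, nrow = 1,
                      dimnames = list(NULL, names(profile)))
  } else {
    profile <- as.matrix(profile)
  }
  miss <- setdiff(needed, colnames(profile))
  if (length(miss))
    stop("profile lacks required subscale(s): ", paste(miss, collapse = ", "))
  X <- profile[, needed, drop = FALSE]
  storage.mode(X) <- "double"
  if (anyNA(X))
    stop("profile has missing values in required subscale(s)")
  X
}

#' Assign the maximum-probability level
#'
#' Returns the argmax level of a probability triple (or of each row of a
#' matrix of triples). Exact ties are broken toward the lower, less severe
#' level.
#'
#' @param probs numeric vector `c(p1, p2, p3)` or a matrix with three
#'   columns.
#' @return integer level(s) in `1:3`.
#' @export
assign_level <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (ncol(probs) != 3L) stop("expected probability triples")
  as.integer(max.col(probs, ties.method = "first"))
}

#' Predict EQ-5D-3L states for a table of records
#'
#' Runs one family's five per-dimension models over every row, assigns the
#' maximum-probability level per dimension, and returns both the assigned
#' 5-tuple states and the full 5 x 3 probability table per record (retained
#' for diagnostics). Any record that cannot be mapped in one dimension fails
#' whole (no partial states): missing covariates raise an error.
#'
#' @param model a `pdq_mapping_model` (from [load_mapping_model()]).
#' @param data data frame with the eight subscale columns, plus `age` and
#'   `gender` (or `female`) columns for the multinomial family.
#' @return a list with `levels` (integer matrix, one column per EQ-5D
#'   dimension) and `probs` (numeric matrix with 15 columns
#'   `<dimension>.p1..p3`).
#' @export
predict_states <- function(model, data) {
  stopifnot(inherits(model, "pdq_mapping_model"))
  if (model$family == "multinomial") {
    age <- data[["age"]]
    if (is.null(age)) stop("multinomial family requires an 'age' column")
    fem <- data[["female"]]
    if (is.null(fem)) {
      g <- data[["gender"]]
      if (is.null(g)) stop("multinomial family requires a 'gender' column")
      fem <- as.numeric(g == "female")
      if (model$female_code == 0) fem <- 1 - fem
    }
  }
  lv <- matrix(NA_integer_, nrow(data), length(EQ5D_DIMENSIONS),
               dimnames = list(NULL, EQ5D_DIMENSIONS))
  pr <- NULL
  for (d in EQ5D_DIMENSIONS) {
    p <- if (model$family == "ordinal") {
      ordinal_probs(model$dimensions[[d]], data)
    } else {
      multinomial_probs(model$dimensions[[d]], data, age, fem,
                        model$age_center)
    }
    colnames(p) <- paste(d, c("p1", "p2", "p3"), sep = ".")
    pr <- cbind(pr, p)
    lv[, d] <- assign_level(p)
  }
  list(levels = lv, probs = pr)
}

#' Predict a single EQ-5D-3L state
#'
#' Convenience wrapper around [predict_states()] for one record.
#'
#' @inheritParams predict_states
#' @param profile named numeric vector of the eight subscale indices.
#' @param age,gender scalar covariates for the multinomial family
#'   (`gender` is `"female"`/`"male"`).
#' @return integer vector of 5 levels named by dimension, with the 5 x 3
#'   probability table attached as attribute `"probs"`.
#' @export
predict_state <- function(model, profile, age = NA_real_,
                          gender = NA_character_) {
  df <- as.data.frame(as.list(profile))
  df$age <- age
  df$gender <- gender
  res <- predict_states(model, df)
  structure(stats::setNames(res$levels[1L, ], EQ5D_DIMENSIONS),
            probs = res$probs[1L, ])
}
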