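#' Load an EQ-5D-3L value set (tariff)
#'
#' Reads a YAML value-set file describing the additive tariff structure used
#' by the standard UK time-trade-off value set: a full-health constant of
#' 1.0 (utility of state 11111), an "any dysfunction" constant subtracted
#' once if any dimension is above level 1, per-dimension decrements for
#' levels 2 and 3, and an extreme-level constant subtracted once if any
#' dimension is at level 3 (zero for value sets without such a term).
#'
#' Load-time validation enforces: full-health constant exactly 1.0, all
#' decrements nonnegative, and per-dimension level-3 decrement at least the
#' level-2 decrement (so monotone dominance over the 243-state lattice is
#' guaranteed by construction).
#'
#' @param path path to the YAML file.
#' @return an object of class `pdq_value_set`.
#' @export
load_value_set <- function(path) {
  cfg <- yaml::read_yaml(path)
  fh <- as.numeric(cfg$full_health %||% 1.0)
  if (!identical(fh, 1.0))
    stop("value set ", path, ": full_health constant must be exactly 1.0")
  anyd <- as.numeric(cfg$any_dysfunction %||% 0)
  ext <- as.numeric(cfg$extreme %||% 0)
  dec <- cfg$decrements
  if (!setequal(names(dec), EQ5D_DIMENSIONS))
    stop("value set ", path, ": decrements must cover exactly the five ",
         "canonical EQ-5D dimensions")
  d2 <- vapply(EQ5D_DIMENSIONS, function(d) as.numeric(dec[[d]]$level2),
               numeric(1))
  d3 <- vapply(EQ5D_DIMENSIONS, function(d) as.numeric(dec[[d]]$level3),
               numeric(1))
  if (anyNA(d2) || anyNA(d3))
    stop("value set ", path, ": every dimension needs level2 and level3 ",
         "decrements")
  if (any(c(anyd, ext, d2, d3) < 0))
    stop("value set ", path, ": all decrements must be nonnegative")
  if (any(d3 < d2))
    stop("value set ", path, ": level-3 decrement below level-2 decrement ",
         "for ", paste(EQ5D_DIMENSIONS[d3 < d2], collapse = ", "))
  structure(list(country = cfg$country %||% basename(path),
                 any_dysfunction = anyd, extreme = ext,
                 decrements = rbind(level2 = d2, level3 = d3)),
            class = "pdq_value_set")
}

#' @export
print.pdq_value_set <- function(x, ...) {
  cat("EQ-5D-3L value set:", x$country, "\n")
  cat("  any-dysfunction constant:", x$any_dysfunction,
      " extreme-level constant:", x$extreme, "\n")
  print(x$decrements)
  invisible(x)
}

#' Utility of an EQ-5D-3L state under a value set
#'
#' Computes `u = 1 - anyDysfunction * [any level > 1] - sum of per-dimension
#' decrements - extreme * [any level = 3]`, where the level-1 decrement is
#' zero. Utilities are anchored at 1.0 (full health) and 0.0 (death) and may
#' be negative (states worse than death). Vectorised over rows when `state`
#' is a matrix.
#'
#' @param state integer vector of 5 levels in `1:3` (canonical dimension
#'   order), or a matrix with 5 such columns.
#' @param vs a `pdq_value_set`.
#' @return numeric utility (or vector of utilities), at full floating
#'   precision; rounding is a reporting concern only.
#' @examples
#' \dontrun{
#' uk <- load_value_set(system.file("extdata", "uk_tto.yaml",
#'                                  package = "pdqmap"))
#' eq5d_utility(c(1, 1, 1, 1, 1), uk) # 1.0
#' }
#' @export
eq5d_utility <- function(state, vs) {
  stopifnot(inherits(vs, "pdq_value_set"))
  if (is.null(dim(state))) state <- matrix(state, nrow = 1)
  if (ncol(state) != 5L) stop("a state has exactly five dimension levels")
  if (anyNA(state) || !all(state %in% 1:3))
    stop("invalid state: levels must be in {1, 2, 3}")
  dec <- matrix(0, nrow(state), 5L)
  for (j in 1:5) {
    dec[, j] <- ifelse(state[, j] == 2L, vs$decrements["level2", j],
                       ifelse(state[, j] == 3L, vs$decrements["level3", j], 0))
  }
  u <- 1 -
    vs$any_dysfunction * (rowSums(state > 1L) > 0) -
    rowSums(dec) -
    vs$extreme * (rowSums(state == 3L) > 0)
  as.numeric(u)
}

#' Tabulate utilities of all 243 EQ-5D-3L states
#'
#' Exhaustive enumeration of the 3^5 health states with their utilities
#' under a value set, sorted canonically (state 11111 first, last dimension
#' varying fastest). A validation and diagnostic aid.
#'
#' @param vs a `pdq_value_set`.
#' @return a data frame with the five level columns, a compact `state` label
#'   (e.g. `"21123"`), and `utility`.
#' @export
tabulate_all_states <- function(vs) {
  grid <- expand.grid(anxiety_depression = 1:3, pain_discomfort = 1:3,
                      usual_activities = 1:3, self_care = 1:3,
                      mobility = 1:3)[, EQ5D_DIMENSIONS]
  grid <- grid[do.call(order, grid), , drop = FALSE]
  rownames(grid) <- NULL
  m <- as.matrix(grid)
  data.frame(grid,
             state = apply(m, 1L, paste, collapse = ""),
             utility = eq5d_utility(m, vs))
}
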