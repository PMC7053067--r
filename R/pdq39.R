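#' Score one PDQ-39 subscale
#'
#' Converts the item responses belonging to a single PDQ-39 subscale into the
#' 0-100 subscale index: `100 * sum(items) / (4 * n_items)`, computed over
#' non-missing items. Higher values indicate worse health-related quality of
#' life. Following the instrument's scoring convention, a subscale is
#' scorable only when at least half of its items are answered; otherwise the
#' index is `NA`.
#'
#' @param items integer vector of item responses in `0:4`; `NA` allowed.
#' @return a single numeric index in `[0, 100]`, or `NA_real_` when fewer
#'   than half the items are present.
#' @examples
#' score_subscale(rep(2L, 10)) # mobility all "sometimes" -> 50
#' @export
score_subscale <- function(items) {
  if (length(items) == 0L) stop("subscale has no items")
  present <- !is.na(items)
  vals <- items[present]
  if (length(vals) && (any(vals != floor(vals)) || any(vals < 0 | vals > 4)))
    stop("PDQ-39 item responses must be integers in 0..4")
  if (sum(present) * 2L < length(items)) return(NA_real_)
  100 * sum(vals) / (4 * sum(present))
}

#' Score a full PDQ-39 response set into a subscale profile
#'
#' Applies [score_subscale()] to each of the eight item groups and computes
#' the summary index (SI) as the arithmetic mean of the eight subscale
#' indices. The SI is set only when all eight subscales are scorable; a
#' profile with any unscorable subscale is flagged incomplete.
#'
#' @param items numeric vector of length 39 (item 1..39 in published order),
#'   values in `0:4` or `NA`.
#' @param item_map character vector of length 39 assigning each item to a
#'   subscale key in [PDQ_SUBSCALES]; defaults to the published ordering.
#' @return a list with `subscales` (named numeric vector of 8), `si`
#'   (summary index or `NA`), and `complete` (logical).
#' @export
score_profile <- function(items, item_map = default_item_map()) {
  if (length(items) != 39L) stop("expected 39 PDQ-39 item responses")
  if (length(item_map) != 39L) stop("item_map must assign all 39 items")
  if (!setequal(unique(item_map), PDQ_SUBSCALES))
    stop("item_map must use the eight canonical subscale keys")
  counts <- table(factor(item_map, levels = PDQ_SUBSCALES))
  if (!all(as.integer(counts) == as.integer(PDQ_ITEM_COUNTS[PDQ_SUBSCALES])))
    stop("item_map has wrong item counts per subscale")
  sub <- vapply(PDQ_SUBSCALES,
                function(s) score_subscale(items[item_map == s]),
                numeric(1))
  complete <- !anyNA(sub)
  list(subscales = sub,
       si = if (complete) mean(sub) else NA_real_,
       complete = complete)
}

#' Score an item-level table into a subscale-level table
#'
#' Row-wise [score_profile()] over a data frame of item responses, producing
#' the subscale-level table the mapping stage consumes. Item-level and
#' subscale-level inputs are mutually exclusive per dataset; this is the
#' bridge from the former to the latter.
#'
#' @param data data frame containing the item columns (plus any identifier
#'   columns, which are carried through).
#' @param item_cols character vector of 39 column names, in item order
#'   1..39; defaults to `item1..item39`.
#' @param item_map see [score_profile()].
#' @return `data` with the item columns replaced by the eight subscale
#'   columns, an `si` column, and a `complete` flag.
#' @export
score_items_table <- function(data, item_cols = paste0("item", 1:39),
                              item_map = default_item_map()) {
  missing_cols <- setdiff(item_cols, names(data))
  if (length(missing_cols))
    stop("item columns not found: ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(data[item_cols])
  profs <- apply(m, 1L, score_profile, item_map = item_map)
  sub <- t(vapply(profs, `[[`, numeric(8), "subscales"))
  colnames(sub) <- PDQ_SUBSCALES
  out <- data[setdiff(names(data), item_cols)]
  out <- cbind(out, as.data.frame(sub))
  out$si <- vapply(profs, `[[`, numeric(1), "si")
  out$complete <- vapply(profs, `[[`, logical(1), "complete")
  out
}
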