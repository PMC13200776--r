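# Patient-reported outcome scoring: Facial Disability Index (FDI), System
# Usability Scale (SUS), and plain Likert summaries for the study
# questionnaire.  All items are answered on a 1-5 response format; scores
# are reported as 0-100.

#' Score one FDI subscale
#'
#' The Facial Disability Index has two five-item subscales: physical
#' function (items 1-5) and social/well-being function (items 6-10), each
#' answered 1-5.  The subscale score maps the item sum linearly onto
#' 0-100%: `percent = (sum - 5) * 5`.  One missing item is imputed by the
#' mean of the answered items of the same subscale; more than one missing
#' item is refused.
#'
#' @param items Numeric vector of 5 responses in `[1, 5]`; `NA` allowed
#'   for at most one item.
#' @return Percent in `[0, 100]`.
#' @export
score_fdi_subscale <- function(items) {
  if (length(items) != 5L) {
    stop("an FDI subscale has exactly 5 items", call. = FALSE)
  }
  n_missing <- sum(is.na(items))
  if (n_missing > 1L) {
    stop("insufficient responses: more than one missing item", call. = FALSE)
  }
  answered <- items[!is.na(items)]
  if (any(answered < 1 | answered > 5)) {
    stop("FDI responses must lie in [1, 5]", call. = FALSE)
  }
  if (n_missing == 1L) {
    items[is.na(items)] <- mean(answered)
  }
  (sum(items) - 5) * 5
}

#' Score a full FDI response
#'
#' @param physical_items Items 1-5 (physical function).
#' @param social_items Items 6-10 (social and well-being function).
#' @return Named list with `physical`, `social`, and `total` (mean of the
#'   two subscales), each 0-100.
#' @export
score_fdi <- function(physical_items, social_items) {
  phys <- score_fdi_subscale(physical_items)
  soc <- score_fdi_subscale(social_items)
  list(physical = phys, social = soc, total = (phys + soc) / 2)
}

#' Score the System Usability Scale
#'
#' Ten items on a 1-5 Likert scale.  Positive items (1, 3, 5, 7, 9)
#' contribute `response - 1`; negative items (2, 4, 6, 8, 10) are reversed
#' and contribute `5 - response`.  Each contribution therefore lies in
#' 0-4, with 4 the most favorable response, and the SUS score is 2.5 times
#' the sum of the ten contributions, giving a 0-100 composite.  Missing
#' items are refused (no imputation).
#'
#' @param items Numeric vector of 10 raw responses in `[1, 5]`.
#' @return SUS score in `[0, 100]`.
#' @seealso [sus_from_adjusted()] to score already-reversed 0-4 item
#'   values, [sus_band()] for the usability band.
#' @export
score_sus <- function(items) {
  if (length(items) != 10L || anyNA(items)) {
    stop("incomplete SUS: all 10 items must be answered", call. = FALSE)
  }
  if (any(items < 1 | items > 5)) {
    stop("SUS responses must lie in [1, 5]", call. = FALSE)
  }
  positive <- c(1, 3, 5, 7, 9)
  contrib <- ifelse(seq_along(items) %in% positive, items - 1, 5 - items)
  sus_from_adjusted(contrib)
}

#' SUS score from adjusted (0-4) item values
#'
#' Computes `2.5 * sum(values)` for item contributions that are already on
#' the reversed 0-4 scale, e.g. published per-item means.
#'
#' @param values Numeric vector of 10 values in `[0, 4]`.
#' @return SUS score in `[0, 100]`.
#' @export
sus_from_adjusted <- function(values) {
  if (length(values) != 10L || anyNA(values)) {
    stop("incomplete SUS: 10 adjusted item values are required",
         call. = FALSE)
  }
  if (any(values < 0 | values > 4)) {
    stop("adjusted SUS values must lie in [0, 4]", call. = FALSE)
  }
  2.5 * sum(values)
}

#' Usability band of a SUS score
#'
#' 85-100 "excellent", 70-84 "good", 50-69 "acceptable", below 50 "poor".
#' Band edges belong to the upper band.
#'
#' @param score SUS score in `[0, 100]`.
#' @return One of `"excellent"`, `"good"`, `"acceptable"`, `"poor"`.
#' @export
sus_band <- function(score) {
  if (!is.numeric(score) || length(score) != 1L || !is.finite(score) ||
      score < 0 || score > 100) {
    stop("SUS score must lie in [0, 100]", call. = FALSE)
  }
  if (score >= 85) "excellent"
  else if (score >= 70) "good"
  else if (score >= 50) "acceptable"
  else "poor"
}

#' Summarize a Likert response table
#'
#' Per-item mean and sample standard deviation (n-1 denominator) plus an
#' overall score defined as the mean of the item means.  With a single
#' respondent the SD is reported as 0 and flagged.
#'
#' @param table Numeric matrix or data frame, respondents x items, values
#'   in `[1, 5]`.
#' @return A list of class `likert_summary` with `items` (data frame:
#'   `item`, `mean`, `sd`), `overall_mean`, `overall_sd` (SD of the pooled
#'   responses), `n`, and `single_respondent` flag.
#' @export
summarize_likert <- function(table) {
  m <- as.matrix(table)
  if (length(m) == 0L || nrow(m) == 0L) {
    stop("empty response table", call. = FALSE)
  }
  if (anyNA(m) || any(m < 1 | m > 5)) {
    stop("Likert responses must lie in [1, 5] with no missing values",
         call. = FALSE)
  }
  n <- nrow(m)
  single <- n == 1L
  item_mean <- colMeans(m)
  item_sd <- if (single) rep(0, ncol(m)) else apply(m, 2L, stats::sd)
  items <- data.frame(
    item = if (is.null(colnames(m))) paste0("item_", seq_len(ncol(m)))
           else colnames(m),
    mean = unname(item_mean),
    sd = unname(item_sd),
    stringsAsFactors = FALSE
  )
  structure(list(
    items = items,
    overall_mean = mean(item_mean),
    overall_sd = if (single) 0 else stats::sd(as.vector(m)),
    n = n,
    single_respondent = single
  ), class = "likert_summary")
}

#' @export
print.likert_summary <- function(x, ...) {
  cat(sprintf("Likert summary of %d item(s), n = %d respondent(s)\n",
              nrow(x$items), x$n))
  print(x$items, row.names = FALSE, digits = 3)
  cat(sprintf("Overall score (mean of item means): %.2f (SD %.2f)\n",
              x$overall_mean, x$overall_sd))
  invisible(x)
}
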