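#' Household wealth score from asset indicators
#'
#' The wealth score is the plain sum of binary asset-possession
#' indicators (the indicator set itself is user-supplied, mirroring
#' demographic-and-health-survey style quintile instruments).
#'
#' @param assets data frame or matrix of 0/1 asset indicators, one row per
#'   household.
#' @return integer vector of scores.
#' @export
wealth_score <- function(assets) {
  a <- as.matrix(assets)
  if (any(is.na(a)) || !all(a %in% c(0, 1))) {
    stop("asset indicators must be binary 0/1 with no missing values")
  }
  as.integer(rowSums(a))
}

#' Three-level SES classification of a wealth score
#'
#' Default rule (`"table1"`): score > 9 is high, 6-9 moderate, < 6 low --
#' the non-overlapping partition of the non-negative integers. An
#' alternative reading of the classification text puts 9 in the high class
#' (`rule = "text"`: >= 9 high, 6-8 moderate, < 6 low); the two rules
#' differ only at score 9.
#'
#' @param score non-negative integer wealth score (vectorized).
#' @param rule `"table1"` (default) or `"text"`.
#' @return factor with levels `low`, `moderate`, `high` (monotone
#'   non-decreasing in score).
#' @examples
#' classify_ses(c(5, 9, 10))            # low moderate high
#' classify_ses(9, rule = "text")       # high
#' @export
classify_ses <- function(score, rule = c("table1", "text")) {
  rule <- match.arg(rule)
  if (any(is.na(score)) || any(score < 0)) {
    stop("wealth scores must be non-negative and non-missing")
  }
  hi_cut <- if (rule == "table1") 9 else 8  # score > hi_cut -> high
  cls <- ifelse(score > hi_cut, "high", ifelse(score >= 6, "moderate", "low"))
  factor(cls, levels = c("low", "moderate", "high"))
}
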