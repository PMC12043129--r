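#' Score a concentration vector into quantile categories
#'
#' Bins a vector of biomarker concentrations into `q` ordered categories
#' using its own empirical quantiles as cut points. Category `k` (0-based)
#' collects values above the `k/q` quantile and at or below the `(k+1)/q`
#' quantile: a value equal to a cut point goes to the lower bin. Quantiles
#' use the linear-interpolation definition (R type 7).
#'
#' When the vector has too few distinct values to support `q` bins the
#' duplicated cut points are collapsed and a warning is emitted; the
#' returned object records the collapse so pipelines can log it.
#'
#' @param x numeric vector of concentrations; must be finite and
#'   non-missing (missingness is handled upstream by complete-case
#'   filtering).
#' @param q integer number of quantile categories (>= 2); defaults to 4,
#'   i.e. quartile scoring, the convention for per-quartile mixture effects.
#' @return An object of class `"quantized"`: a list with `scores`
#'   (integers in `0:(q-1)`), `cutpoints` (the `q - 1` interior quantiles,
#'   possibly with duplicates), `q`, `occupancy` (bin counts) and
#'   `collapsed` (TRUE if duplicate cut points were found).
#' @examples
#' quantize(1:8, q = 4)$scores  # 0 0 1 1 2 2 3 3
#' @export
quantize <- function(x, q = 4L) {
  q <- as.integer(q)
  if (q < 2L) stop("q must be at least 2")
  if (length(x) == 0L) stop("empty concentration vector")
  if (anyNA(x) || any(!is.finite(x))) {
    stop("quantize() requires finite, non-missing values; filter upstream")
  }
  cuts <- stats::quantile(x, probs = seq_len(q - 1L) / q, type = 7,
                          names = FALSE)
  collapsed <- anyDuplicated(cuts) > 0L
  if (collapsed) {
    warning("fewer distinct values than quantile bins; bins collapsed")
  }
  # ties at a cut point fall to the lower bin: the score is the number of
  # cut points strictly below x (left-open intervals); duplicated cut
  # points then skip the empty collapsed bins automatically
  scores <- findInterval(x, cuts, left.open = TRUE)
  structure(list(scores = as.integer(scores), cutpoints = cuts, q = q,
                 occupancy = tabulate(scores + 1L, nbins = q),
                 collapsed = collapsed),
            class = "quantized")
}

#' Quantize several exposure columns of a cohort table
#'
#' @param data data frame holding one column per chemical.
#' @param chemicals character vector of column names to score.
#' @param q number of quantile categories per chemical.
#' @return Object of class `"quantized_exposures"`: `scores` (data frame of
#'   integer scores, same column names), `cutpoints` (named list),
#'   `occupancy` (named list), `q`, `collapsed` (named logical).
#' @export
quantize_exposures <- function(data, chemicals, q = 4L) {
  missing_cols <- setdiff(chemicals, names(data))
  if (length(missing_cols)) {
    stop("chemical column(s) not in data: ", paste(missing_cols, collapse = ", "))
  }
  qz <- lapply(chemicals, function(ch) quantize(data[[ch]], q))
  names(qz) <- chemicals
  structure(list(
    scores = as.data.frame(lapply(qz, `[[`, "scores")),
    cutpoints = lapply(qz, `[[`, "cutpoints"),
    occupancy = lapply(qz, `[[`, "occupancy"),
    q = as.integer(q),
    collapsed = vapply(qz, `[[`, logical(1), "collapsed")
  ), class = "quantized_exposures")
}

#' @export
print.quantized_exposures <- function(x, ...) {
  cat("Quantized exposures: ", ncol(x$scores), " chemical(s), q = ", x$q,
      ", n = ", nrow(x$scores), "\n", sep = "")
  for (ch in names(x$cutpoints)) {
    cat("  ", ch, ": cuts [", paste(signif(x$cutpoints[[ch]], 4),
                                    collapse = ", "),
        "], occupancy ", paste(x$occupancy[[ch]], collapse = "/"), "\n",
        sep = "")
  }
  invisible(x)
}

#' Human-biomonitoring reference thresholds for the four metals
#'
#' Default dichotomization thresholds: blood Pb 35 ug/L, blood Hg 0.8 ug/L,
#' blood Cd 0.3 ug/L, urinary As 15 ug/L (GerES IV reference values). A
#' subject is "elevated" at or above the threshold.
#'
#' @param thresholds named numeric vector of thresholds in ug/L.
#' @param direction direction in which a value counts as elevated;
#'   `"gte"` (default, value >= threshold) or `"lte"`.
#' @return Object of class `"reference_thresholds"`.
#' @export
reference_thresholds <- function(thresholds = c(Pb = 35, Hg = 0.8,
                                                Cd = 0.3, As = 15),
                                 direction = "gte") {
  direction <- match.arg(direction, c("gte", "lte"))
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  if (is.null(names(thresholds)) || any(names(thresholds) == "")) {
    stop("thresholds must be named by chemical")
  }
  structure(list(thresholds = thresholds, direction = direction),
            class = "reference_thresholds")
}

#' Dichotomize concentrations against a reference threshold
#'
#' @param x numeric vector of concentrations.
#' @param chemical chemical name, looked up in `thresholds`.
#' @param thresholds a [reference_thresholds()] object.
#' @return List with `indicator` (0/1, 1 = elevated), `threshold`, and
#'   `summary`: a data frame of the two strata with counts and percentages
#'   rounded to one decimal place.
#' @examples
#' d <- dichotomize(c(0.5, 0.9, 1.2), "Hg")
#' d$indicator  # 0 1 1
#' @export
dichotomize <- function(x, chemical, thresholds = reference_thresholds()) {
  if (!inherits(thresholds, "reference_thresholds")) {
    stop("thresholds must be a reference_thresholds object")
  }
  if (!chemical %in% names(thresholds$thresholds)) {
    stop("no reference threshold for chemical: ", chemical)
  }
  thr <- thresholds$thresholds[[chemical]]
  ind <- if (thresholds$direction == "gte") as.integer(x >= thr)
         else as.integer(x <= thr)
  n <- length(x)
  n_hi <- sum(ind)
  op <- if (thresholds$direction == "gte") c(">=", "<") else c("<=", ">")
  summ <- data.frame(
    chemical = chemical,
    stratum = paste(op, thr),
    n = c(n_hi, n - n_hi),
    pct = round(100 * c(n_hi, n - n_hi) / n, 1)
  )
  list(indicator = ind, threshold = thr, summary = summ)
}

#' Percentile summary of a concentration vector
#'
#' Returns P10, P25, median (with a distribution-free 95% CI from the
#' binomial order-statistic method), P75, P95 and the maximum, matching the
#' layout of a descriptive exposure table. Percentiles use the
#' linear-interpolation quantile definition (R type 7).
#'
#' @param x numeric vector, length >= 2 for the CI.
#' @param conf confidence level for the median CI.
#' @return One-row data frame with columns `n`, `p10`, `p25`, `median`,
#'   `median_lo`, `median_hi`, `p75`, `p95`, `max`.
#' @export
summarize_percentiles <- function(x, conf = 0.95) {
  n <- length(x)
  if (n < 1L) stop("empty vector")
  qs <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.95), type = 7,
                        names = FALSE)
  if (n < 2L) {
    warning("n < 2: median confidence interval omitted")
    lo <- hi <- NA_real_
  } else {
    xs <- sort(x)
    alpha <- 1 - conf
    l <- stats::qbinom(alpha / 2, n, 0.5)        # may be 0
    u <- n - l + 1L
    lo <- xs[max(l, 1L)]
    hi <- xs[min(u, n)]
  }
  data.frame(n = n, p10 = qs[1], p25 = qs[2], median = qs[3],
             median_lo = lo, median_hi = hi, p75 = qs[4], p95 = qs[5],
             max = max(x))
}

#' Descriptive exposure table with reference-value strata
#'
#' Builds an exposure-table summary: per chemical, the percentile row from
#' [summarize_percentiles()] and the two reference-threshold strata with
#' counts and percentages from [dichotomize()].
#'
#' @param data cohort data frame.
#' @param chemicals chemical column names.
#' @param thresholds a [reference_thresholds()] object.
#' @return List with `percentiles` (data frame, one row per chemical) and
#'   `strata` (data frame of threshold strata).
#' @export
exposure_summary_table <- function(data, chemicals = c("Pb", "Hg", "Cd", "As"),
                                   thresholds = reference_thresholds()) {
  pct <- do.call(rbind, lapply(chemicals, function(ch) {
    cbind(chemical = ch, summarize_percentiles(data[[ch]]))
  }))
  strata <- do.call(rbind, lapply(chemicals, function(ch) {
    dichotomize(data[[ch]], ch, thresholds)$summary
  }))
  rownames(pct) <- rownames(strata) <- NULL
  list(percentiles = pct, strata = strata)
}

#' Read a subject-level cohort table
#'
#' Reads CSV, or SPSS `.sav` (via the foreign package) for deposited
#' de-identified study tables.
#'
#' @param path file path ending in `.csv` or `.sav`.
#' @return data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "sav") {
    foreign::read.spss(path, to.data.frame = TRUE)
  } else {
    stop("unsupported cohort format: .", ext, " (use .csv or .sav)")
  }
}

#' Complete-case filter over the columns a model uses
#'
#' @param data cohort data frame.
#' @param cols columns that must be non-missing.
#' @return data frame of complete rows, with attribute `n_dropped`.
#' @export
complete_cases <- function(data, cols) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("column(s) missing from cohort: ", paste(missing_cols, collapse = ", "))
  }
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  out <- data[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
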