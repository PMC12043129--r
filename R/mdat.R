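#' Synthetic MDAT item bank
#'
#' Parameter table for a synthetic developmental-assessment instrument in
#' the shape of the MDAT: four domains (gross motor, fine motor, language,
#' social), 34 pass/fail items each by default. Each item follows a
#' two-parameter logistic response model,
#' `P(pass) = plogis(a * (theta + age_slope * z_age - d))`, with latent
#' ability `theta ~ N(0,1)` per domain, standardized age `z_age`, common
#' discrimination `a` and item difficulties evenly spaced over
#' `difficulty_range`. The instrument's real normative data are proprietary
#' and are not reproduced; this bank exists so the classification rule and
#' reliability computations are testable.
#'
#' @param domains character vector of domain names.
#' @param items_per_domain items per domain (34 matches a total raw score
#'   of 0-34 per domain).
#' @param discrimination common slope `a`; the default 1.2 yields internal
#'   consistency (Cronbach's alpha) near 0.9 for a 34-item domain, the
#'   reliability band instruments of this class report.
#' @param difficulty_range range over which item difficulties are spread;
#'   mostly negative so that typical children pass most items.
#' @param age_slope ability gain per standard deviation of age.
#' @param age_center,age_sd centering/scale for age in months.
#' @return data frame with columns `domain`, `item`, `difficulty` and
#'   attributes `discrimination`, `age_slope`, `age_center`, `age_sd`.
#' @export
mdat_item_bank <- function(domains = c("gross_motor", "fine_motor",
                                       "language", "social"),
                           items_per_domain = 34L,
                           discrimination = 1.2,
                           difficulty_range = c(-3.5, 0.5),
                           age_slope = 0.5, age_center = 43.9,
                           age_sd = 3.4) {
  if (items_per_domain < 1L) stop("items_per_domain must be >= 1")
  diffs <- seq(difficulty_range[1], difficulty_range[2],
               length.out = items_per_domain)
  bank <- do.call(rbind, lapply(domains, function(d) {
    data.frame(domain = d,
               item = sprintf("%s_i%02d", d, seq_len(items_per_domain)),
               difficulty = diffs)
  }))
  attr(bank, "discrimination") <- discrimination
  attr(bank, "age_slope") <- age_slope
  attr(bank, "age_center") <- age_center
  attr(bank, "age_sd") <- age_sd
  bank
}

mdat_pass_prob <- function(bank, theta, age) {
  a <- attr(bank, "discrimination")
  z_age <- (age - attr(bank, "age_center")) / attr(bank, "age_sd")
  # outer over items: subjects x items
  stats::plogis(a * (outer(theta + attr(bank, "age_slope") * z_age,
                           bank$difficulty, `-`)))
}

#' Simulate pass/fail item responses
#'
#' Draws binary item responses from the two-parameter logistic model of a
#' [mdat_item_bank()]: pass probability increases with latent ability and
#' with age. Abilities can be supplied (e.g. to build cohorts differing
#' only in ability) or drawn as independent standard normals per domain.
#'
#' @param n number of children.
#' @param ages ages in months (recycled scalar allowed); default draws
#'   from the cohort age distribution.
#' @param bank a [mdat_item_bank()].
#' @param ability optional n x domains matrix of latent abilities.
#' @param seed integer seed.
#' @return list with `responses` (data frame, one 0/1 column per item),
#'   `ages`, `ability`.
#' @export
generate_mdat_items <- function(n, ages = NULL, bank = mdat_item_bank(),
                                ability = NULL, seed = 1L) {
  set.seed(seed + 3L)
  if (is.null(ages)) ages <- pmin(pmax(stats::rnorm(n, 43.9, 3.4), 36), 59)
  ages <- rep_len(ages, n)
  domains <- unique(bank$domain)
  if (is.null(ability)) {
    ability <- matrix(stats::rnorm(n * length(domains)), n, length(domains),
                      dimnames = list(NULL, domains))
  }
  resp <- lapply(domains, function(d) {
    sub <- bank[bank$domain == d, ]
    p <- mdat_pass_prob(structure(sub, discrimination = attr(bank, "discrimination"),
                                  age_slope = attr(bank, "age_slope"),
                                  age_center = attr(bank, "age_center"),
                                  age_sd = attr(bank, "age_sd")),
                        ability[, d], ages)
    m <- matrix(stats::rbinom(length(p), 1L, p), nrow = n,
                dimnames = list(NULL, sub$item))
    as.data.frame(m)
  })
  list(responses = do.call(cbind, resp), ages = ages, ability = ability)
}

#' Age-referenced 90th-percentile norm table
#'
#' For each item and age band, records whether at least 90% of reference
#' children of that age pass the item (computed from the item bank's
#' response model by averaging pass probabilities over the reference
#' ability distribution). An item a child fails while it carries an
#' `expected_pass` norm counts as a failure against the norm. A loader for
#' user-supplied norms is [read_norm_table()].
#'
#' @param bank a [mdat_item_bank()].
#' @param age_breaks age-band boundaries in months (left-closed bands).
#' @param n_ref reference-population size per band.
#' @param seed integer seed.
#' @return data frame `domain`, `item`, `age_band`, `pass_rate`,
#'   `expected_pass`, with attribute `age_breaks`.
#' @export
make_norm_table <- function(bank, age_breaks = c(36, 42, 48, 60),
                            n_ref = 5000L, seed = 1L) {
  set.seed(seed + 4L)
  bands <- levels(cut(age_breaks[1], age_breaks, right = FALSE,
                      include.lowest = TRUE))
  out <- do.call(rbind, lapply(seq_along(bands), function(b) {
    ages <- stats::runif(n_ref, age_breaks[b], age_breaks[b + 1])
    theta <- stats::rnorm(n_ref)
    p <- mdat_pass_prob(bank, theta, ages)
    colnames(p) <- bank$item
    data.frame(domain = bank$domain, item = bank$item, age_band = bands[b],
               pass_rate = colMeans(p))
  }))
  out$expected_pass <- out$pass_rate >= 0.90
  rownames(out) <- NULL
  attr(out, "age_breaks") <- age_breaks
  out
}

#' Read a user-supplied norm table
#'
#' CSV with columns `domain`, `item`, `age_band`, `expected_pass` (0/1 or
#' logical) and one leading comment-free header row; the age-band labels
#' must be `[lo,hi)` interval labels and are used to recover the breaks.
#'
#' @param path CSV file path.
#' @return norm table data frame as from [make_norm_table()].
#' @export
read_norm_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("domain", "item", "age_band", "expected_pass")
  if (!all(req %in% names(out))) {
    stop("norm table needs columns: ", paste(req, collapse = ", "))
  }
  out$expected_pass <- as.logical(out$expected_pass)
  lo <- as.numeric(sub("^\\[([0-9.]+),.*$", "\\1", unique(out$age_band)))
  hi <- as.numeric(sub("^.*,([0-9.]+)[])]$", "\\1", unique(out$age_band)))
  attr(out, "age_breaks") <- sort(unique(c(lo, hi)))
  out
}

age_band_of <- function(age, norms) {
  breaks <- attr(norms, "age_breaks")
  if (is.null(breaks)) stop("norm table lacks an age_breaks attribute")
  band <- cut(age, breaks, right = FALSE, include.lowest = TRUE)
  if (anyNA(band)) stop("age outside norm coverage: ",
                        paste(age[is.na(band)], collapse = ", "))
  as.character(band)
}

#' Score one domain and classify impairment
#'
#' Applies the impairment rule: a child failing more than two items that
#' carry an age-referenced 90th-percentile pass norm is classified
#' impaired for the domain; failing zero, one or two such items is usual.
#'
#' @param responses named 0/1 vector of this domain's item responses
#'   (names matching the norm table's `item` column).
#' @param age child age in months.
#' @param norms norm table from [make_norm_table()] or [read_norm_table()].
#' @param domain domain name.
#' @return one-row data frame: `domain`, `raw_score`, `failed_vs_norm`,
#'   `impaired` (0/1). A missing item response excludes the child from the
#'   domain: all result fields are NA and `exclusion_reason` names the
#'   item.
#' @export
score_domain <- function(responses, age, norms, domain) {
  band <- age_band_of(age, norms)
  sub <- norms[norms$domain == domain & norms$age_band == band, ]
  if (!nrow(sub)) stop("no norms for domain ", domain, " in band ", band)
  r <- responses[sub$item]
  if (anyNA(r)) {
    bad <- sub$item[which(is.na(r))[1]]
    return(data.frame(domain = domain, raw_score = NA_integer_,
                      failed_vs_norm = NA_integer_, impaired = NA_integer_,
                      exclusion_reason = paste("missing item:", bad)))
  }
  failed <- sum(r == 0 & sub$expected_pass)
  data.frame(domain = domain, raw_score = as.integer(sum(r)),
             failed_vs_norm = as.integer(failed),
             impaired = as.integer(failed > 2L),
             exclusion_reason = NA_character_)
}

#' Score all domains for a cohort of children
#'
#' Vectorized scoring of a wide item-response table against a norm table,
#' producing per-domain raw scores and impairment flags plus the global
#' impairment status (impaired in at least one domain).
#'
#' @param responses data frame of 0/1 item columns (as produced by
#'   [generate_mdat_items()]).
#' @param ages child ages in months.
#' @param norms norm table.
#' @return data frame with per-domain `score_<domain>` and
#'   `impaired_<domain>` columns and `impaired_global`.
#' @export
score_mdat <- function(responses, ages, norms) {
  domains <- unique(norms$domain)
  n <- nrow(responses)
  bands <- age_band_of(ages, norms)
  out <- data.frame(row.names = seq_len(n))
  flags <- matrix(NA_integer_, n, length(domains),
                  dimnames = list(NULL, domains))
  for (d in domains) {
    items <- unique(norms$item[norms$domain == d])
    if (!all(items %in% names(responses))) {
      stop("response table lacks item column(s) for domain ", d)
    }
    R <- as.matrix(responses[, items, drop = FALSE])
    # expected-pass indicator per band: items x bands
    ub <- unique(bands)
    E <- vapply(ub, function(b) {
      sub <- norms[norms$domain == d & norms$age_band == b, ]
      as.numeric(sub$expected_pass[match(items, sub$item)])
    }, numeric(length(items)))
    E <- matrix(E, ncol = length(ub), dimnames = list(items, ub))
    failed_by_band <- (1 - R) %*% E          # n x bands
    failed <- failed_by_band[cbind(seq_len(n), match(bands, ub))]
    out[[paste0("score_", d)]] <- as.integer(rowSums(R))
    flags[, d] <- as.integer(failed > 2)
    out[[paste0("impaired_", d)]] <- flags[, d]
  }
  out$impaired_global <- global_status(flags)
  out
}

#' Global neurodevelopmental impairment status
#'
#' A child impaired in at least one of the four domains is globally
#' impaired; a child usual on all domains is typically developing.
#'
#' @param flags matrix or data frame of per-domain 0/1 impairment flags
#'   (four columns), one row per child.
#' @return integer 0/1 vector.
#' @export
global_status <- function(flags) {
  f <- as.matrix(flags)
  if (ncol(f) != 4L) stop("global status needs all four domain flags")
  if (anyNA(f)) stop("missing domain flag; score all four domains first")
  as.integer(rowSums(f) > 0L)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a set of items:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`.
#'
#' @param x numeric matrix or data frame, subjects in rows, items in
#'   columns (k >= 2 items, >= 2 subjects).
#' @return alpha coefficient.
#' @export
cronbach_alpha <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) < 2L) stop("alpha needs at least 2 items")
  if (nrow(m) < 2L) stop("alpha needs at least 2 subjects")
  vtot <- stats::var(rowSums(m))
  if (vtot == 0) stop("total-score variance is zero; alpha is undefined")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vtot)
}
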