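#' Percent change implied by a prevalence ratio
#'
#' `(1 - PR) * 100` (a percent reduction) for PR below 1, `(PR - 1) * 100`
#' otherwise.
#'
#' @param pr prevalence ratio(s).
#' @return percent change, full precision (tables round to one decimal).
#' @examples
#' percent_change(0.822)  # 17.8
#' @export
percent_change <- function(pr) {
  ifelse(pr < 1, (1 - pr) * 100, (pr - 1) * 100)
}

#' Render mixture fits as a model table
#'
#' Long-format model table in the layout of a mixture-effects results
#' table: for each outcome, the `psi1` row (PR with CI and percent
#' change), the directional partial-effect rows with their member lists,
#' and one signed weight row per chemical. Every number is copied from the
#' `mixture_fit` fields -- nothing is recomputed at render time. Percent
#' change and weights are rounded to one decimal/three decimals in the
#' CSV; the JSON serialization keeps full precision.
#'
#' @param fits named list of [fit_mixture_model()] results (names label
#'   the outcomes); all fits must share `q`.
#' @param file optional CSV path to write.
#' @return data frame with columns `outcome`, `term`, `members`,
#'   `estimate`, `conf_low`, `conf_high`, `direction`, `percent_change`.
#' @export
render_model_table <- function(fits, file = NULL) {
  if (inherits(fits, "mixture_fit")) fits <- list(model = fits)
  qs <- vapply(fits, `[[`, integer(1), "q")
  if (length(unique(qs)) != 1L) stop("fits mix different q; refusing to tabulate")
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    out <- data.frame(
      outcome = nm, term = "psi1",
      members = paste(f$chemicals, collapse = " + "),
      estimate = f$pr, conf_low = f$pr_ci[1], conf_high = f$pr_ci[2],
      direction = if (f$pr < 1) "-" else "+",
      percent_change = round(percent_change(f$pr), 1))
    if (length(f$members_pos)) {
      out <- rbind(out, data.frame(
        outcome = nm, term = "partial_positive",
        members = paste(f$members_pos, collapse = " + "),
        estimate = f$partial_pos, conf_low = NA, conf_high = NA,
        direction = "+", percent_change = NA))
    }
    if (length(f$members_neg)) {
      out <- rbind(out, data.frame(
        outcome = nm, term = "partial_negative",
        members = paste(f$members_neg, collapse = " + "),
        estimate = f$partial_neg, conf_low = NA, conf_high = NA,
        direction = "-", percent_change = NA))
    }
    w <- f$weights
    rbind(out, data.frame(
      outcome = nm, term = paste0("weight_", names(w)), members = names(w),
      estimate = round(abs(w), 3), conf_low = NA, conf_high = NA,
      direction = ifelse(w < 0, "-", "+"), percent_change = NA))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(file)) utils::write.csv(tab, file, row.names = FALSE)
  tab
}

#' Signed weight data for a bar chart
#'
#' One signed magnitude per chemical: bars to the right (positive) are
#' chemicals contributing in the risk-increasing direction, bars to the
#' left the inverse contributors; magnitudes within each direction sum
#' to 1.
#'
#' @param fit a [fit_mixture_model()] result.
#' @param file optional CSV path.
#' @return data frame `chemical`, `weight` (signed), `direction`; empty
#'   with attribute `undefined = TRUE` when all mixture coefficients were
#'   exactly zero.
#' @export
export_weight_plot_data <- function(fit, file = NULL) {
  if (!isTRUE(fit$weights_defined)) {
    out <- data.frame(chemical = character(0), weight = numeric(0),
                      direction = character(0))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  w <- fit$weights
  out <- data.frame(chemical = names(w), weight = as.numeric(w),
                    direction = ifelse(w < 0, "negative", "positive"))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Standardized-probability curve data for the MSM figure
#'
#' @param fit a [fit_mixture_model()] result.
#' @param file optional CSV path.
#' @return data frame `level`, `std_prob`, `msm_fit` (the fitted
#'   log-linear MSM line).
#' @export
export_msm_curve <- function(fit, file = NULL) {
  out <- fit$msm_curve
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Serialize / read back a mixture fit
#'
#' Writes every `mixture_fit` field to JSON at full precision so the file
#' round-trips exactly; [read_mixture_fit()] restores the object.
#'
#' @param fit a [fit_mixture_model()] result.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_mixture_fit <- function(fit, path) {
  x <- unclass(fit)
  x$glm <- unclass(x$glm)
  # jsonlite serializes atomic vectors as bare arrays; named vectors go
  # through lists so the names survive the round trip
  x$glm$coefficients <- as.list(x$glm$coefficients)
  x$weights <- as.list(x$weights)
  if (!is.null(x$weight_sd)) x$weight_sd <- as.list(x$weight_sd)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_mixture_fit
#' @export
read_mixture_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$glm <- structure(as.list(x$glm), class = "qgc_glm")
  x$glm$coefficients <- unlist(x$glm$coefficients)
  x$weights <- unlist(x$weights)
  x$msm_curve <- as.data.frame(x$msm_curve)
  for (nm in c("pr_ci", "weight_sd")) x[[nm]] <- unlist(x[[nm]])
  structure(x, class = "mixture_fit")
}

#' Run the full pipeline from a YAML (or list) configuration
#'
#' Composes the stages end to end: `simulate` (synthetic cohort with a
#' provenance JSON), `prep` (exposure summary table and reference-value
#' strata), `score` (MDAT scoring when item responses are simulated),
#' `fit` (crude and adjusted mixture models plus chemical-specific models
#' per outcome) and `report` (model table, weight bar data, MSM curve
#' data, run manifest). All randomness derives from the configured seed.
#'
#' Configuration keys (all optional except where noted): `seed`, `n`,
#' `quantiles`, `bootstrap`, `chemicals`, `outcomes` (names of default
#' generative truths), `covariates`, `adjusted`, `cohort_csv` (skip
#' simulation and read this file; its outcome columns must then exist).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to run, in pipeline order.
#' @return named list of the artifacts written (paths) and the fitted
#'   models, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "prep", "score", "fit",
                                    "report")) {
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  } else {
    config_path <- NULL
  }
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- utils::modifyList(list(
    seed = 1L, n = 1000L, quantiles = 4L, bootstrap = 200L,
    chemicals = c("Pb", "Hg", "Cd", "As"),
    outcomes = c("language", "gross_motor", "fine_motor", "social",
                 "global"),
    covariates = c("sex", "birth_weight_kg", "maternal_education",
                   "child_age_months", "ses_score"),
    adjusted = TRUE, cohort_csv = NULL, simulate_items = FALSE
  ), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  paths <- character(0)

  if (!is.null(cfg$cohort_csv)) {
    cohort <- read_cohort(cfg$cohort_csv)
  } else if ("simulate" %in% stages) {
    truths <- lapply(cfg$outcomes, default_mixture_truth, q = cfg$quantiles)
    names(truths) <- cfg$outcomes
    cohort <- generate_cohort(cfg$n, truths = truths, seed = cfg$seed)
    p <- file.path(out_dir, "cohort.csv")
    utils::write.csv(cohort, p, row.names = FALSE)
    jsonlite::write_json(list(seed = cfg$seed, n = cfg$n,
                              generated = TRUE),
                         file.path(out_dir, "cohort_provenance.json"),
                         auto_unbox = TRUE)
    paths <- c(paths, cohort = p,
               provenance = file.path(out_dir, "cohort_provenance.json"))
  } else {
    stop("no cohort: provide cohort_csv or include the simulate stage")
  }
  for (oc in cfg$outcomes) {
    col <- paste0("impaired_", oc)
    if (!col %in% names(cohort)) {
      stop("cohort is missing outcome column: ", col)
    }
  }

  if ("prep" %in% stages) {
    summ <- exposure_summary_table(cohort, cfg$chemicals)
    p1 <- file.path(out_dir, "exposure_percentiles.csv")
    p2 <- file.path(out_dir, "exposure_strata.csv")
    utils::write.csv(summ$percentiles, p1, row.names = FALSE)
    utils::write.csv(summ$strata, p2, row.names = FALSE)
    paths <- c(paths, exposure_percentiles = p1, exposure_strata = p2)
    artifacts$exposure_summary <- summ
  }

  if ("score" %in% stages && isTRUE(cfg$simulate_items)) {
    bank <- mdat_item_bank()
    norms <- make_norm_table(bank, seed = cfg$seed)
    items <- generate_mdat_items(nrow(cohort), ages = cohort$child_age_months,
                                 bank = bank, seed = cfg$seed)
    scored <- score_mdat(items$responses, items$ages, norms)
    p <- file.path(out_dir, "mdat_scores.csv")
    utils::write.csv(scored, p, row.names = FALSE)
    paths <- c(paths, mdat_scores = p)
    artifacts$mdat_scores <- scored
  }

  if ("fit" %in% stages) {
    covs <- if (isTRUE(cfg$adjusted)) cfg$covariates else NULL
    fits <- list()
    for (oc in cfg$outcomes) {
      fits[[oc]] <- fit_mixture_model(
        cohort, paste0("impaired_", oc), chemicals = cfg$chemicals,
        covariates = covs, q = cfg$quantiles, B = cfg$bootstrap,
        seed = cfg$seed)
      p <- file.path(out_dir, paste0("fit_", oc, ".json"))
      write_mixture_fit(fits[[oc]], p)
      paths <- c(paths, stats::setNames(p, paste0("fit_", oc)))
    }
    artifacts$fits <- fits
  }

  if ("report" %in% stages) {
    if (is.null(artifacts$fits)) stop("report stage requires the fit stage")
    p <- file.path(out_dir, "model_table.csv")
    render_model_table(artifacts$fits, file = p)
    paths <- c(paths, model_table = p)
    for (oc in names(artifacts$fits)) {
      pw <- file.path(out_dir, paste0("weights_", oc, ".csv"))
      pm <- file.path(out_dir, paste0("msm_curve_", oc, ".csv"))
      export_weight_plot_data(artifacts$fits[[oc]], file = pw)
      export_msm_curve(artifacts$fits[[oc]], file = pm)
      paths <- c(paths, stats::setNames(c(pw, pm),
                                        paste0(c("weights_", "msm_curve_"), oc)))
    }
    manifest <- run_manifest(cfg, config_path, paths, out_dir)
    paths <- c(paths, manifest = manifest)
  }
  invisible(c(artifacts, list(paths = paths, cohort = cohort)))
}

# Provenance manifest: config hash, seed, artifact paths, package version.
run_manifest <- function(cfg, config_path, paths, out_dir) {
  cfg_file <- if (!is.null(config_path)) config_path else {
    tmp <- file.path(out_dir, "config_resolved.yaml")
    yaml::write_yaml(cfg, tmp)
    tmp
  }
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    artifacts = as.list(paths),
    package_version = as.character(utils::packageVersion("qgcmix")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE)
  p
}
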