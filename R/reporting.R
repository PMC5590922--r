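# Phase I / Phase II batch drivers. These are the targets of the bundled
# command-line script (inst/cli/gsbup.R) and convenient entry points for
# scripted runs: each writes plain CSV reports at full precision plus a
# resolved-configuration copy for provenance.

#' Run Phase I: scores, slacks, returns to scale, Malmquist
#'
#' Validates the panel, scores every DMU in every requested period, labels
#' returns to scale, and (when two or more periods are present) computes
#' the Malmquist table over consecutive periods. Writes `scores.csv`,
#' `rts.csv`, `malmquist.csv` and `config.yml` into `out_dir`.
#'
#' @param panel a `dea_panel`, or a path to a panel CSV.
#' @param spec a [factor_spec()], or a path to a YAML spec config
#'   (required when `panel` is a path).
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @param gamma intensity-set kind, see [solve_gsbup()].
#' @param periods periods to score (default: all in the panel).
#' @param zero_policy passed to [validate_panel()].
#' @param tol efficiency tolerance.
#' @return list with `scores` (a `gsbup_table`), `rts` (data frame),
#'   `malmquist` (a `malmquist_table` or `NULL`), `validation` (report).
#' @export
run_phase1 <- function(panel, spec = NULL, out_dir = NULL, gamma = "CRS",
                       periods = NULL, zero_policy = "substitute",
                       tol = 1e-6) {
  if (is.character(panel)) {
    if (is.character(spec)) spec <- read_factor_spec(spec)
    if (!inherits(spec, "factor_spec")) {
      stop("when 'panel' is a path, 'spec' must be a factor_spec or a path")
    }
    panel <- load_panel(panel, spec)
  }
  if (!gamma %in% GAMMA_KINDS) {
    stop("unknown gamma kind '", gamma, "'; use one of ",
         paste(GAMMA_KINDS, collapse = ", "))
  }
  val <- validate_panel(panel, zero_policy)
  panel <- val$panel
  if (is.null(periods)) periods <- panel_periods(panel)
  scores <- efficiency_table(panel, period = periods, gamma = gamma,
                             tol = tol)
  rts <- do.call(rbind, lapply(periods, function(p) {
    df <- panel$data[panel$data$period == p, , drop = FALSE]
    do.call(rbind, lapply(df$dmu_id, function(d) {
      r <- tryCatch(classify_rts(panel, d, p), error = function(e)
        list(label = NA_character_, sum_lambda_range = c(NA_real_, NA_real_)))
      data.frame(dmu_id = d, period = as.character(p), rts = r$label,
                 sum_lambda_min = r$sum_lambda_range[1],
                 sum_lambda_max = r$sum_lambda_range[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  mal <- if (length(periods) >= 2) {
    sub <- dea_panel(panel$data[panel$data$period %in% periods, ,
                                drop = FALSE], panel$spec)
    malmquist_table(sub, gamma = gamma)
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(scores),
                     file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(rts, file.path(out_dir, "rts.csv"), row.names = FALSE)
    if (!is.null(mal)) {
      utils::write.csv(as.data.frame(mal),
                       file.path(out_dir, "malmquist.csv"),
                       row.names = FALSE)
    }
    yaml::write_yaml(list(gamma = gamma, periods = as.character(periods),
                          zero_policy = zero_policy, tol = tol),
                     file.path(out_dir, "config.yml"))
  }
  invisible(list(scores = scores, rts = rts, malmquist = mal,
                 validation = val$report))
}

#' Run Phase II: Tobit regression of scores on covariates
#'
#' Joins efficiency scores with an exogenous-covariate table on
#' `(dmu_id, period)` and fits the censored-normal regression. A covariate
#' row missing for any scored `(dmu_id, period)` key is an explicit error
#' listing the offending keys.
#'
#' @param scores a `gsbup_table` / data frame with `dmu_id`, `period`,
#'   `delta`, or a path to `scores.csv`.
#' @param covariates data frame keyed by `dmu_id`, `period` with numeric
#'   covariate columns, or a path to a CSV.
#' @param lower,upper censoring bounds for the score.
#' @param out_dir optional output directory for `tobit.csv`.
#' @return list with `fit` (a `tobit_fit`) and `report` (a `tobit_report`).
#' @export
run_phase2 <- function(scores, covariates, lower = 0, upper = 1,
                       out_dir = NULL) {
  if (is.character(scores)) {
    scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  }
  if (is.character(covariates)) {
    covariates <- utils::read.csv(covariates, stringsAsFactors = FALSE)
  }
  need <- c("dmu_id", "period")
  stopifnot(all(c(need, "delta") %in% names(scores)),
            all(need %in% names(covariates)))
  key_s <- paste(scores$dmu_id, scores$period, sep = "/")
  key_c <- paste(covariates$dmu_id, covariates$period, sep = "/")
  miss <- setdiff(key_s, key_c)
  if (length(miss) > 0) {
    stop("covariate table is missing (dmu_id, period) key(s): ",
         paste(miss, collapse = ", "))
  }
  cov <- covariates[match(key_s, key_c), , drop = FALSE]
  xcols <- setdiff(names(cov), need)
  X <- cbind("(Intercept)" = 1, as.matrix(cov[, xcols, drop = FALSE]))
  y <- pmin(pmax(scores$delta, lower), upper)
  design <- tobit_design(y, X, lower, upper)
  fit <- fit_tobit(design)
  report <- tobit_report(fit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "tobit.csv"), row.names = FALSE)
  }
  invisible(list(fit = fit, report = report))
}
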