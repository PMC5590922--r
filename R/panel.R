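#' Construct a DMU panel
#'
#' A panel holds the observed factor values of each decision-making unit
#' (DMU) in each period, together with the factor specification. Every
#' `(dmu_id, period)` pair must be unique, all factor values must be
#' non-negative, and each record must have at least one strictly positive
#' input and one strictly positive output.
#'
#' @param data data frame with columns `dmu_id`, `period`, and one numeric
#'   column per factor in `spec`.
#' @param spec a [factor_spec()].
#' @return an object of class `dea_panel`.
#' @export
dea_panel <- function(data, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  data <- as.data.frame(data)
  need <- c("dmu_id", "period", spec$name)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(data) == 0) stop("panel has no records")
  for (f in spec$name) {
    if (!is.numeric(data[[f]])) {
      stop(sprintf("factor column '%s' is not numeric", f))
    }
    if (anyNA(data[[f]])) {
      stop(sprintf("factor column '%s' contains missing values", f))
    }
  }
  key <- paste(data$dmu_id, data$period, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (dmu_id, period) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  structure(list(data = data[, need, drop = FALSE], spec = spec,
                 dims = spec_dims(spec)),
            class = "dea_panel")
}

#' Load a DMU panel from a CSV file
#'
#' Expects a comma-separated file with a header row containing `dmu_id`,
#' `period` and one column per factor of `spec` ('.' decimal, UTF-8). Row
#' order is preserved. A missing factor column is a schema error; a
#' non-numeric cell is a parse error naming the offending row and column.
#' Negative values are accepted here and rejected by [validate_panel()].
#'
#' @param path path to the CSV file.
#' @param spec a [factor_spec()].
#' @return a `dea_panel`.
#' @export
load_panel <- function(path, spec) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) stop("panel file has an empty data section: ", path)
  miss <- setdiff(c("dmu_id", "period", spec$name), names(raw))
  if (length(miss) > 0) {
    stop("panel file is missing column(s): ", paste(miss, collapse = ", "))
  }
  for (f in spec$name) {
    v <- suppressWarnings(as.numeric(raw[[f]]))
    bad <- which(is.na(v) & !is.na(raw[[f]]) & raw[[f]] != "NA")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s', data row %d",
                   raw[[f]][bad[1]], f, bad[1]))
    }
    raw[[f]] <- v
  }
  dea_panel(raw, spec)
}

#' Write a DMU panel to CSV
#'
#' Inverse of [load_panel()]: numeric cells are written at full precision so
#' that a decimal-text round trip reproduces them bit-exactly.
#'
#' @param panel a `dea_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "dea_panel"))
  df <- panel$data
  for (f in panel$spec$name) df[[f]] <- format(df[[f]], digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a panel
#'
#' Checks non-negativity and positivity requirements and applies the zero
#' policy. Any negative factor value is an error, as is a DMU record with
#' all-zero inputs or all-zero outputs. Exact zeros in individual factors are
#' handled according to `zero_policy`: under `"substitute"` each zero is
#' replaced by `1e-3` times that factor's cross-DMU mean within the same
#' period (the peer set the model's ratio constraints divide by) and the
#' replacement is logged; under `"reject"` any zero raises an error.
#' Validation is idempotent: re-validating a substituted panel makes no
#' further changes.
#'
#' @param panel a `dea_panel`.
#' @param zero_policy `"substitute"` (default) or `"reject"`.
#' @return list with elements `panel` (possibly modified) and `report`, an
#'   object of class `validation_report` with fields `passed`, `issues`
#'   (data frame: dmu_id, period, factor, code, message) and
#'   `zero_substitutions` (data frame of applied replacements).
#' @export
validate_panel <- function(panel, zero_policy = c("substitute", "reject")) {
  stopifnot(inherits(panel, "dea_panel"))
  zero_policy <- match.arg(zero_policy)
  spec <- panel$spec
  df <- panel$data
  issues <- list()
  subs <- list()
  add_issue <- function(dmu, period, factor, code, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(
      dmu_id = dmu, period = as.character(period), factor = factor,
      code = code, message = msg, stringsAsFactors = FALSE)
  }
  in_cols <- spec$name[spec$role %in% c("DI", "UI")]
  out_cols <- spec$name[spec$role %in% c("DO", "UO")]
  for (r in seq_len(nrow(df))) {
    row <- df[r, spec$name]
    neg <- spec$name[row < 0]
    for (f in neg) {
      add_issue(df$dmu_id[r], df$period[r], f, "negative",
                sprintf("negative value %g", df[[f]][r]))
    }
    if (all(df[r, in_cols] == 0)) {
      add_issue(df$dmu_id[r], df$period[r], "", "all_zero_inputs",
                "every input factor is zero")
    }
    if (all(df[r, out_cols] == 0)) {
      add_issue(df$dmu_id[r], df$period[r], "", "all_zero_outputs",
                "every output factor is zero")
    }
  }
  n_err <- length(issues)
  if (n_err == 0) {
    for (f in spec$name) {
      z <- which(df[[f]] == 0)
      if (length(z) == 0) next
      if (zero_policy == "reject") {
        for (r in z) {
          add_issue(df$dmu_id[r], df$period[r], f, "zero",
                    "zero value enters a ratio constraint")
        }
      } else {
        for (r in z) {
          per <- df$period[r]
          mu <- mean(df[[f]][df$period == per])
          repl <- 1e-3 * mu
          if (repl <= 0) {
            add_issue(df$dmu_id[r], df$period[r], f, "zero_column",
                      "factor is zero for every DMU in the period")
          } else {
            subs[[length(subs) + 1L]] <- data.frame(
              dmu_id = df$dmu_id[r], period = as.character(per), factor = f,
              old = 0, new = repl, stringsAsFactors = FALSE)
            df[[f]][r] <- repl
          }
        }
      }
    }
  }
  issues_df <- if (length(issues)) do.call(rbind, issues) else
    data.frame(dmu_id = character(), period = character(), factor = character(),
               code = character(), message = character())
  subs_df <- if (length(subs)) do.call(rbind, subs) else
    data.frame(dmu_id = character(), period = character(), factor = character(),
               old = numeric(), new = numeric())
  report <- structure(list(passed = nrow(issues_df) == 0,
                           issues = issues_df,
                           zero_substitutions = subs_df),
                      class = "validation_report")
  if (!report$passed) {
    stop("panel validation failed:\n",
         paste(sprintf("  [%s] %s/%s %s: %s", issues_df$code, issues_df$dmu_id,
                       issues_df$period, issues_df$factor, issues_df$message),
               collapse = "\n"))
  }
  panel$data <- df
  list(panel = panel, report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Panel validation: %s, %d issue(s), %d zero substitution(s)\n",
              if (x$passed) "passed" else "FAILED",
              nrow(x$issues), nrow(x$zero_substitutions)))
  if (nrow(x$zero_substitutions) > 0) print(x$zero_substitutions)
  invisible(x)
}

#' Periods present in a panel
#' @param panel a `dea_panel`.
#' @return sorted vector of unique period labels.
#' @export
panel_periods <- function(panel) sort(unique(panel$data$period))

#' Restrict a panel to one period
#' @param panel a `dea_panel`.
#' @param period a period label present in the panel.
#' @return a `dea_panel` containing only that period's records.
#' @export
panel_period <- function(panel, period) {
  keep <- panel$data$period == period
  if (!any(keep)) stop("period not present in panel: ", period)
  dea_panel(panel$data[keep, , drop = FALSE], panel$spec)
}

# factor matrices for one period: each block is (n_factors x n_dmus)
#' @noRd
panel_matrices <- function(panel, period = NULL) {
  df <- panel$data
  if (!is.null(period)) {
    df <- df[df$period == period, , drop = FALSE]
    if (nrow(df) == 0) stop("period not present in panel: ", period)
  } else if (length(unique(df$period)) > 1) {
    stop("panel spans several periods; pass 'period'")
  }
  spec <- panel$spec
  block <- function(role) {
    cols <- spec$name[spec$role == role]
    mt <- t(as.matrix(df[, cols, drop = FALSE]))
    rownames(mt) <- cols
    colnames(mt) <- df$dmu_id
    mt
  }
  list(xD = block("DI"), xI = block("UI"), yG = block("DO"), yB = block("UO"),
       dmu_id = df$dmu_id, period = unique(df$period))
}

#' Descriptive statistics and correlations for one period
#'
#' Reports max, min, median, mean, sample standard deviation (n - 1
#' denominator), Fisher skewness and excess kurtosis per factor, plus the
#' Pearson correlation matrix across factors. A constant column yields zero
#' SD and undefined (NaN) skewness/kurtosis with a warning.
#'
#' @param panel a `dea_panel`.
#' @param period period label.
#' @return list of class `dea_descriptives` with elements `stats` (data
#'   frame, one row per summary statistic) and `correlation` (matrix).
#' @export
descriptive_stats <- function(panel, period) {
  stopifnot(inherits(panel, "dea_panel"))
  df <- panel$data[panel$data$period == period, , drop = FALSE]
  if (nrow(df) < 2) stop("descriptive statistics need at least 2 records")
  X <- as.matrix(df[, panel$spec$name, drop = FALSE])
  if (any(apply(X, 2, stats::sd) == 0)) {
    warning("constant factor column: skewness/kurtosis undefined (NaN)")
  }
  stats_tbl <- data.frame(
    statistic = c("max", "min", "median", "mean", "sd", "skewness", "kurtosis"),
    rbind(apply(X, 2, max), apply(X, 2, min), apply(X, 2, stats::median),
          colMeans(X), apply(X, 2, stats::sd),
          apply(X, 2, function(v) suppressWarnings(e1071::skewness(v, type = 1))),
          apply(X, 2, function(v) suppressWarnings(e1071::kurtosis(v, type = 1)))),
    check.names = FALSE)
  corr <- suppressWarnings(stats::cor(X))  # constant columns give NA here
  structure(list(stats = stats_tbl, correlation = corr, period = period,
                 n = nrow(df)),
            class = "dea_descriptives")
}

#' @export
print.dea_descriptives <- function(x, digits = 3, ...) {
  cat(sprintf("Descriptive statistics, period %s (n = %d)\n",
              as.character(x$period), x$n))
  tbl <- x$stats
  tbl[, -1] <- round(tbl[, -1], digits)
  print(tbl, row.names = FALSE)
  cat("\nPearson correlations\n")
  print(round(x$correlation, digits))
  invisible(x)
}

#' @export
print.dea_panel <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "DMU panel: %d record(s), %d DMU(s), %d period(s); m=%d q=%d s=%d k=%d\n",
    nrow(x$data), length(unique(x$data$dmu_id)),
    length(unique(x$data$period)), d["m"], d["q"], d["s"], d["k"]))
  print(utils::head(x$data, 10), row.names = FALSE)
  if (nrow(x$data) > 10) cat(sprintf("... %d more row(s)\n", nrow(x$data) - 10))
  invisible(x)
}
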