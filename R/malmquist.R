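# Malmquist productivity index on top of the slacks-based scores.
#
# Four efficiency evaluations enter each index: the target's period-t and
# period-(t+1) data, each scored against the period-t and period-(t+1)
# frontiers. Writing d[frontier, data],
#
#   M0  = sqrt( d[t,t]/d[t,t+1] * d[t+1,t]/d[t+1,t+1] )
#   TEC = d[t,t] / d[t+1,t+1]
#   FS  = sqrt( d[t+1,t+1]/d[t,t+1] * d[t+1,t]/d[t,t] )
#
# so that M0 = TEC * FS identically. The sign convention follows the model
# family this index is built on: M0 < 1 denotes productivity improvement,
# TEC < 1 improving own efficiency, FS < 1 frontier progress. (This inverts
# the classical Malmquist reading; it is applied exactly as defined.)

#' Cross-period efficiency evaluation
#'
#' Scores one DMU's data from period `s` against the frontier of period `t`
#' (possibly the same period, in which case the result coincides with
#' [solve_gsbup()]). Mixed-period programs can be infeasible under the
#' paper-faithful ratio bounds; see [score_record()] for the relaxation
#' policy and the `relaxed` flag.
#'
#' @param target_panel panel supplying the target's data.
#' @param dmu target `dmu_id`.
#' @param data_period period of the target's data.
#' @param frontier_panel panel supplying the frontier DMUs.
#' @param frontier_period period of the frontier.
#' @param gamma intensity-set kind, see [solve_gsbup()].
#' @param relax relaxation policy, see [score_record()].
#' @return a `gsbup_solution`.
#' @export
cross_period_delta <- function(target_panel, dmu, data_period,
                               frontier_panel = target_panel, frontier_period,
                               gamma = "CRS", relax = "auto") {
  record <- as_record(target_panel, dmu, data_period)
  score_record(record, frontier_panel, frontier_period, gamma = gamma,
               relax = relax)
}

#' Malmquist productivity index for one DMU across two periods
#'
#' @param panel a validated `dea_panel` containing both periods (or see
#'   `panel_t1` to pass two single-period panels).
#' @param dmu target `dmu_id`, present in both periods.
#' @param t,t1 the two period labels (consecutive periods in the intended
#'   use).
#' @param panel_t1 optional second panel holding period `t1`; defaults to
#'   `panel`.
#' @param gamma intensity-set kind.
#' @return object of class `malmquist_result`: list with the four component
#'   scores `d_tt`, `d_t_t1`, `d_t1_t`, `d_t1_t1` (named `d[frontier,
#'   data]`), the indices `M0`, `TEC0`, `FS0`, and `flags` (possibly
#'   containing `"mixed_period_relaxed"` or `"infeasible"`).
#' @examples
#' des <- frontier_design(n_efficient = 4, n_inefficient = 2, seed = 7)
#' pans <- generate_drift_series(des, periods = 2, g = 1.05)
#' malmquist(pans, dmu = "D1", t = 1, t1 = 2)
#' @export
malmquist <- function(panel, dmu, t, t1, panel_t1 = panel, gamma = "CRS") {
  d <- list(
    tt    = cross_period_delta(panel, dmu, t, panel, t, gamma = gamma),
    t_t1  = cross_period_delta(panel_t1, dmu, t1, panel, t, gamma = gamma),
    t1_t  = cross_period_delta(panel, dmu, t, panel_t1, t1, gamma = gamma),
    t1_t1 = cross_period_delta(panel_t1, dmu, t1, panel_t1, t1, gamma = gamma))
  flags <- character()
  if (any(vapply(d, function(s) isTRUE(s$relaxed), TRUE))) {
    flags <- c(flags, "mixed_period_relaxed")
  }
  dv <- vapply(d, function(s) if (s$status == "optimal") s$delta else NA_real_,
               0)
  if (anyNA(dv) || any(dv <= 0)) {
    flags <- c(flags, "infeasible")
    M0 <- TEC0 <- FS0 <- NA_real_
  } else {
    M0 <- sqrt((dv["tt"] / dv["t_t1"]) * (dv["t1_t"] / dv["t1_t1"]))
    TEC0 <- dv["tt"] / dv["t1_t1"]
    FS0 <- sqrt((dv["t1_t1"] / dv["t_t1"]) * (dv["t1_t"] / dv["tt"]))
  }
  structure(list(dmu_id = dmu, period_pair = c(t, t1),
                 d_tt = dv[["tt"]], d_t_t1 = dv[["t_t1"]],
                 d_t1_t = dv[["t1_t"]], d_t1_t1 = dv[["t1_t1"]],
                 M0 = unname(M0), TEC0 = unname(TEC0), FS0 = unname(FS0),
                 flags = flags),
            class = "malmquist_result")
}

#' @export
print.malmquist_result <- function(x, digits = 4, ...) {
  cat(sprintf("Malmquist %s, %s -> %s: M0 = %.*f (TEC %.*f x FS %.*f)%s\n",
              x$dmu_id, as.character(x$period_pair[1]),
              as.character(x$period_pair[2]),
              digits, x$M0, digits, x$TEC0, digits, x$FS0,
              if (length(x$flags)) paste0("  [", paste(x$flags,
                                                       collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Malmquist table across consecutive periods
#'
#' Computes the index for every DMU over every consecutive period pair and
#' appends per-DMU averages over the pairs. Because the indices are
#' multiplicative, the averaging convention is the geometric mean; the
#' arithmetic mean is reported alongside for comparison. A DMU absent from
#' some period is excluded from the affected pairs with a warning.
#'
#' @param panel a validated `dea_panel` with at least two periods.
#' @param gamma intensity-set kind.
#' @return data frame of class `malmquist_table` with one row per DMU and
#'   pair (`t`, `t1`, component scores, `M0`, `TEC0`, `FS0`, `flags`);
#'   per-DMU averages are in attribute `averages`.
#' @export
malmquist_table <- function(panel, gamma = "CRS") {
  periods <- panel_periods(panel)
  if (length(periods) < 2) stop("malmquist_table() needs at least 2 periods")
  dmus <- unique(panel$data$dmu_id)
  rows <- list()
  for (i in seq_len(length(periods) - 1L)) {
    t <- periods[i]; t1 <- periods[i + 1L]
    present <- function(p) unique(panel$data$dmu_id[panel$data$period == p])
    both <- intersect(present(t), present(t1))
    missing <- setdiff(dmus, both)
    if (length(missing) > 0) {
      warning(sprintf("DMU(s) absent from pair %s-%s: %s",
                      t, t1, paste(missing, collapse = ", ")))
    }
    for (d in both) {
      r <- malmquist(panel, d, t, t1, gamma = gamma)
      rows[[length(rows) + 1L]] <- data.frame(
        dmu_id = d, t = as.character(t), t1 = as.character(t1),
        d_tt = r$d_tt, d_t_t1 = r$d_t_t1, d_t1_t = r$d_t1_t,
        d_t1_t1 = r$d_t1_t1, M0 = r$M0, TEC0 = r$TEC0, FS0 = r$FS0,
        flags = paste(r$flags, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  gm <- function(v) exp(mean(log(v)))
  avg <- do.call(rbind, lapply(split(out, out$dmu_id), function(g) {
    fin <- is.finite(g$M0)
    data.frame(dmu_id = g$dmu_id[1], n_pairs = sum(fin),
               M0_gmean = if (any(fin)) gm(g$M0[fin]) else NA_real_,
               TEC0_gmean = if (any(fin)) gm(g$TEC0[fin]) else NA_real_,
               FS0_gmean = if (any(fin)) gm(g$FS0[fin]) else NA_real_,
               M0_amean = if (any(fin)) mean(g$M0[fin]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(avg) <- NULL
  attr(out, "averages") <- avg
  class(out) <- c("malmquist_table", "data.frame")
  out
}

#' @export
print.malmquist_table <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  cat("\nPer-DMU averages over pairs (geometric; arithmetic M0 alongside)\n")
  avg <- attr(x, "averages")
  avg[, -1] <- round(avg[, -1], digits)
  print(avg, row.names = FALSE)
  invisible(x)
}
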