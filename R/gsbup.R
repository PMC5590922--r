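# The GSBUP model: a generalized, non-oriented slacks-based DEA model with
# desirable/undesirable inputs and outputs and preference weights.
#
# For a target unit with observed blocks (x0D, x0I, y0G, y0B) and a frontier
# panel of n peers, the fractional program minimizes
#
#   delta0 = (sum_i omega_i alpha_i + sum_h nu_h theta_h) /
#            (sum_l sigma_l gamma_l + sum_r mu_r beta_r)
#
# over intensity weights lambda >= 0 and ratio variables
# 0 <= alpha <= 1 (DI contraction), gamma >= 1 (UI expansion),
# beta >= 1 (DO expansion), 0 <= theta <= 1 (UO contraction), subject to
# sum_j lambda_j x_j = (ratio) * x0 per factor and the intensity constraint
# Gamma on sum(lambda). The Charnes-Cooper substitution a = t*alpha,
# b = t*gamma, c = t*beta, d = t*theta, zeta = t*lambda with
# t = 1 / (sigma.gamma + mu.beta) turns it into an LP whose optimum tau0
# equals delta0. Slacks are recovered as sD- = (1-alpha)*x0D,
# sI+ = (gamma-1)*x0I, sG+ = (beta-1)*y0G, sB- = (1-theta)*y0B.
#
# Factor rows are scaled by the target's own values before solving, so the
# LP coefficients are O(1) regardless of measurement units.

GAMMA_KINDS <- c("CRS", "IRS", "DRS", "FREE")

#' @noRd
as_record <- function(panel, dmu, period = NULL) {
  df <- panel$data
  if (!is.null(period)) df <- df[df$period == period, , drop = FALSE]
  df <- df[df$dmu_id == dmu, , drop = FALSE]
  if (nrow(df) == 0) stop("DMU not present in panel: ", dmu)
  if (nrow(df) > 1) stop("DMU '", dmu, "' appears in several periods; pass 'period'")
  spec <- panel$spec
  grab <- function(role) {
    v <- as.numeric(df[1, spec$name[spec$role == role]])
    names(v) <- spec$name[spec$role == role]
    v
  }
  list(dmu_id = df$dmu_id[1], period = df$period[1],
       xD = grab("DI"), xI = grab("UI"), yG = grab("DO"), yB = grab("UO"))
}

# Core LP solve: score one record against a frontier (matrices from
# panel_matrices). Returns the raw solution pieces.
#' @noRd
gsbup_lp <- function(record, mats, w, gamma = "CRS",
                     tmin = 1e-6, eps_gamma = 1e-9,
                     relax = FALSE, relax_U = 10, relax_eps = 0.1) {
  m <- length(record$xD); q <- length(record$xI)
  s <- length(record$yG); k <- length(record$yB)
  n <- length(mats$dmu_id)
  N <- m + q + s + k + n + 1L
  ia <- seq_len(m); ib <- m + seq_len(q); ic <- m + q + seq_len(s)
  id_ <- m + q + s + seq_len(k); iz <- m + q + s + k + seq_len(n); it <- N

  x0 <- c(record$xD, record$xI, record$yG, record$yB)
  if (any(x0 <= 0)) {
    stop("target record has non-positive factor value(s); ",
         "run validate_panel() with a zero policy first")
  }
  obj <- numeric(N); obj[ia] <- w$omega; obj[id_] <- w$nu

  rows <- list(); dirs <- character(); rhs <- numeric()
  add <- function(r, d, b) {
    rows[[length(rows) + 1L]] <<- r; dirs[length(dirs) + 1L] <<- d
    rhs[length(rhs) + 1L] <<- b
  }
  r <- numeric(N); r[ib] <- w$sigma; r[ic] <- w$mu; add(r, "==", 1)
  blocks <- list(list(mats$xD, record$xD, ia), list(mats$xI, record$xI, ib),
                 list(mats$yG, record$yG, ic), list(mats$yB, record$yB, id_))
  for (bl in blocks) {
    mat <- bl[[1]]; x0b <- bl[[2]]; idx <- bl[[3]]
    for (i in seq_along(idx)) {
      r <- numeric(N); r[iz] <- mat[i, ] / x0b[i]; r[idx[i]] <- -1
      add(r, "==", 0)
    }
  }
  if (gamma == "CRS") {
    r <- numeric(N); r[iz] <- 1; r[it] <- -1; add(r, "==", 0)
  } else if (gamma == "IRS") {
    r <- numeric(N); r[iz] <- 1; r[it] <- -(1 - eps_gamma); add(r, "<=", 0)
  } else if (gamma == "DRS") {
    r <- numeric(N); r[iz] <- 1; r[it] <- -(1 + eps_gamma); add(r, ">=", 0)
  }
  ub_con <- if (relax) relax_U else 1   # a, d <= ub_con * t
  lb_exp <- if (relax) relax_eps else 1 # b, c >= lb_exp * t
  for (i in c(ia, id_)) {
    r <- numeric(N); r[i] <- 1; r[it] <- -ub_con; add(r, "<=", 0)
  }
  for (i in c(ib, ic)) {
    r <- numeric(N); r[i] <- 1; r[it] <- -lb_exp; add(r, ">=", 0)
  }
  r <- numeric(N); r[it] <- 1; add(r, ">=", tmin)

  res <- simplex_lp(obj, do.call(rbind, rows), dirs, rhs, maximize = FALSE)
  if (res$status != "optimal") {
    return(list(status = if (res$status == "infeasible") "infeasible"
                else "numerical"))
  }
  t <- res$x[it]
  if (t <= 0) return(list(status = "numerical"))
  list(status = "optimal", delta = res$value, lp_t = t,
       alpha = res$x[ia] / t, gamma_ = res$x[ib] / t,
       beta = res$x[ic] / t, theta = res$x[id_] / t,
       lambda = stats::setNames(res$x[iz] / t, mats$dmu_id))
}

#' @noRd
make_solution <- function(raw, record, mats, w, gamma, relaxed = FALSE) {
  if (raw$status != "optimal") {
    return(structure(list(status = raw$status, delta = NA_real_,
                          dmu_id = record$dmu_id, period = record$period,
                          gamma = gamma, relaxed = relaxed),
                     class = "gsbup_solution"))
  }
  slacks <- list(
    sD = (1 - raw$alpha) * record$xD,
    sI = (raw$gamma_ - 1) * record$xI,
    sG = (raw$beta - 1) * record$yG,
    sB = (1 - raw$theta) * record$yB)
  structure(list(status = "optimal", delta = raw$delta,
                 alpha = stats::setNames(raw$alpha, names(record$xD)),
                 beta = stats::setNames(raw$beta, names(record$yG)),
                 gamma_ = stats::setNames(raw$gamma_, names(record$xI)),
                 theta = stats::setNames(raw$theta, names(record$yB)),
                 lambda = raw$lambda, slacks = slacks, lp_t = raw$lp_t,
                 dmu_id = record$dmu_id, period = record$period,
                 target = record, frontier = mats, weights = w,
                 gamma = gamma, relaxed = relaxed),
            class = "gsbup_solution")
}

#' Score one DMU with the GSBUP model
#'
#' Builds and solves the Charnes-Cooper linear form of the slacks-based
#' fractional program for one target DMU against the frontier of all DMUs
#' observed in the same period, and back-transforms the ratio variables,
#' intensity vector and slacks.
#'
#' @param panel a validated `dea_panel`.
#' @param dmu the target `dmu_id`.
#' @param period period label; may be omitted if the panel has one period.
#' @param gamma intensity-set kind: `"CRS"` (sum of intensities equal to 1,
#'   the default), `"IRS"` (< 1), `"DRS"` (> 1) or `"FREE"` (unconstrained).
#' @param tmin lower bound standing in for the strict positivity of the
#'   Charnes-Cooper scalar `t`; inert by scale invariance.
#' @param eps_gamma closure margin for the strict IRS/DRS inequalities.
#' @return an object of class `gsbup_solution` with fields `delta` (the
#'   efficiency score in `[0, 1]`), `alpha`, `beta`, `gamma_`, `theta`
#'   (ratio variables), `lambda` (intensities), `slacks` (`sD`, `sI`, `sG`,
#'   `sB`), `lp_t`, and `status`.
#' @examples
#' hk <- hk_clusters_2013()
#' sol <- solve_gsbup(hk$panel, "KEC")
#' sol$delta
#' @export
solve_gsbup <- function(panel, dmu, period = NULL, gamma = c("CRS", "IRS", "DRS", "FREE"),
                        tmin = 1e-6, eps_gamma = 1e-9) {
  gamma <- match.arg(gamma)
  if (is.null(period)) {
    pers <- panel_periods(panel)
    if (length(pers) > 1) stop("panel spans several periods; pass 'period'")
    period <- pers
  }
  record <- as_record(panel, dmu, period)
  check_weights(panel$spec)
  mats <- panel_matrices(panel, period)
  w <- spec_weights(panel$spec)
  raw <- gsbup_lp(record, mats, w, gamma, tmin = tmin, eps_gamma = eps_gamma)
  make_solution(raw, record, mats, w, gamma)
}

#' Is a solved DMU efficient?
#'
#' A DMU is GSBUP-efficient iff the optimal ratio variables are all 1,
#' equivalently iff every slack is zero. The test is on the scale-free ratio
#' variables: `max |ratio - 1| <= tol`.
#'
#' @param sol a `gsbup_solution` with `status == "optimal"`.
#' @param tol efficiency tolerance (default `1e-6`).
#' @return logical.
#' @export
is_efficient <- function(sol, tol = 1e-6) {
  stopifnot(inherits(sol, "gsbup_solution"))
  if (sol$status != "optimal") {
    stop("is_efficient() needs an optimal solution (status: ", sol$status, ")")
  }
  dev <- max(abs(c(sol$alpha, sol$beta, sol$gamma_, sol$theta) - 1))
  dev <= tol
}

#' Frontier projection of a solved DMU
#'
#' Returns the frontier point the optimal solution maps the target onto:
#' `(alpha* x0D, beta* y0G, gamma* x0I, theta* y0B)`. The same point is
#' recomputed from the intensity vector (`sum_j lambda_j x_j` per factor);
#' the two forms must agree within `tol` or an error is raised.
#'
#' @param sol an optimal `gsbup_solution`.
#' @param tol maximum allowed relative disagreement between the two forms.
#' @return a record-like list with fields `dmu_id`, `xD`, `xI`, `yG`, `yB`.
#' @export
project <- function(sol, tol = 1e-6) {
  stopifnot(inherits(sol, "gsbup_solution"))
  if (sol$status != "optimal") {
    stop("project() needs an optimal solution (status: ", sol$status, ")")
  }
  rec <- sol$target
  via_ratio <- list(xD = sol$alpha * rec$xD, xI = sol$gamma_ * rec$xI,
                    yG = sol$beta * rec$yG, yB = sol$theta * rec$yB)
  mats <- sol$frontier
  via_lambda <- list(xD = drop(mats$xD %*% sol$lambda),
                     xI = drop(mats$xI %*% sol$lambda),
                     yG = drop(mats$yG %*% sol$lambda),
                     yB = drop(mats$yB %*% sol$lambda))
  for (b in c("xD", "xI", "yG", "yB")) {
    if (length(rec[[b]]) == 0) next
    scale <- pmax(abs(unlist(rec[b])), 1)
    if (max(abs(via_ratio[[b]] - via_lambda[[b]]) / scale) > tol) {
      stop("projection forms disagree beyond tolerance (numerical error)")
    }
  }
  c(list(dmu_id = paste0(rec$dmu_id, "_proj"), period = rec$period), via_ratio)
}

#' Efficiency table for a whole panel
#'
#' Solves the model once per DMU and period and tabulates scores, efficiency
#' flags and slacks. Per-period summary rows (mean score, number of
#' efficient DMUs, number above the mean) are attached as the `summary`
#' attribute. Solver failures for individual DMUs are reported in the
#' `status` column without aborting the batch.
#'
#' @param panel a validated `dea_panel`.
#' @param period optional period label; default is every period in turn.
#' @param gamma intensity-set kind, see [solve_gsbup()].
#' @param tol efficiency tolerance passed to [is_efficient()].
#' @param keep_solutions logical; attach the full `gsbup_solution` list as
#'   attribute `solutions`.
#' @return a data frame of class `gsbup_table`: `dmu_id`, `period`, `delta`,
#'   `efficient`, `status`, then one `slack_*` column per factor.
#' @examples
#' hk <- hk_clusters_2013()
#' efficiency_table(hk$panel)
#' @export
efficiency_table <- function(panel, period = NULL, gamma = "CRS", tol = 1e-6,
                             keep_solutions = FALSE) {
  periods <- if (is.null(period)) panel_periods(panel) else period
  rows <- list(); sols <- list(); summaries <- list()
  for (p in periods) {
    df <- panel$data[panel$data$period == p, , drop = FALSE]
    deltas <- rep(NA_real_, nrow(df))
    for (i in seq_len(nrow(df))) {
      sol <- tryCatch(solve_gsbup(panel, df$dmu_id[i], p, gamma = gamma),
                      error = function(e) {
                        structure(list(status = paste("error:",
                                                      conditionMessage(e)),
                                       delta = NA_real_,
                                       dmu_id = df$dmu_id[i], period = p),
                                  class = "gsbup_solution")
                      })
      sols[[paste(df$dmu_id[i], p, sep = ".")]] <- sol
      slk <- if (sol$status == "optimal") {
        unlist(sol$slacks[c("sD", "sI", "sG", "sB")], use.names = FALSE)
      } else rep(NA_real_, sum(panel$dims))
      deltas[i] <- sol$delta
      rows[[length(rows) + 1L]] <- data.frame(
        dmu_id = df$dmu_id[i], period = as.character(p), delta = sol$delta,
        efficient = if (sol$status == "optimal") is_efficient(sol, tol) else NA,
        status = sol$status,
        rbind(stats::setNames(slk, paste0("slack_", panel$spec$name))),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
    fin <- deltas[is.finite(deltas)]
    summaries[[as.character(p)]] <- data.frame(
      period = as.character(p), mean_delta = mean(fin),
      n_efficient = sum(fin >= 1 - tol),
      n_above_mean = sum(fin > mean(fin)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- do.call(rbind, summaries)
  if (keep_solutions) attr(out, "solutions") <- sols
  class(out) <- c("gsbup_table", "data.frame")
  out
}

#' @export
print.gsbup_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  cat("\nSummary by period\n")
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}

#' Classify the returns to scale of one DMU
#'
#' Solves the model with an unconstrained intensity set, then pins the
#' objective to its optimum and solves two auxiliary LPs (in the original,
#' untransformed variables, where the optimal face is linear) maximizing and
#' minimizing the intensity sum. The label follows the range of the sum over
#' alternative optima: entirely below 1 is `IRS`, entirely above 1 is `DRS`,
#' a range containing 1 is `CRS`.
#'
#' @param panel a validated `dea_panel`.
#' @param dmu target `dmu_id`.
#' @param period period label (optional for single-period panels).
#' @param tol half-width of the band around 1 treated as "containing 1".
#' @param cut_tol slack allowed on the optimal-objective cut; absorbs solver
#'   round-off so the optimal face is non-empty.
#' @return an object of class `rts_label`: list with `label` (`"CRS"`,
#'   `"IRS"` or `"DRS"`), `sum_lambda_range` (min, max) and `delta_free`.
#' @examples
#' hk <- hk_clusters_2013()
#' classify_rts(hk$panel, "KEC")
#' @export
classify_rts <- function(panel, dmu, period = NULL, tol = 1e-6,
                         cut_tol = 1e-9) {
  sol <- solve_gsbup(panel, dmu, period, gamma = "FREE")
  if (sol$status != "optimal") {
    stop("free-intensity solve failed (status: ", sol$status, ")")
  }
  record <- sol$target; mats <- sol$frontier; w <- sol$weights
  m <- length(record$xD); q <- length(record$xI)
  s <- length(record$yG); k <- length(record$yB)
  n <- length(mats$dmu_id)
  # variables: alpha(m), gamma(q), beta(s), theta(k), lambda(n), all >= 0
  N <- m + q + s + k + n
  ia <- seq_len(m); ib <- m + seq_len(q); ic <- m + q + seq_len(s)
  id_ <- m + q + s + seq_len(k); iz <- m + q + s + k + seq_len(n)
  rows <- list(); dirs <- character(); rhs <- numeric()
  add <- function(r, d, b) {
    rows[[length(rows) + 1L]] <<- r; dirs[length(dirs) + 1L] <<- d
    rhs[length(rhs) + 1L] <<- b
  }
  blocks <- list(list(mats$xD, record$xD, ia), list(mats$xI, record$xI, ib),
                 list(mats$yG, record$yG, ic), list(mats$yB, record$yB, id_))
  for (bl in blocks) {
    mat <- bl[[1]]; x0b <- bl[[2]]; idx <- bl[[3]]
    for (i in seq_along(idx)) {
      r <- numeric(N); r[iz] <- mat[i, ] / x0b[i]; r[idx[i]] <- -1
      add(r, "==", 0)
    }
  }
  for (i in c(ia, id_)) { r <- numeric(N); r[i] <- 1; add(r, "<=", 1) }
  for (i in c(ib, ic)) { r <- numeric(N); r[i] <- 1; add(r, ">=", 1) }
  # optimal face: numerator - delta* x denominator <= cut_tol (>= holds by
  # optimality of delta*, so this pins the objective within round-off)
  r <- numeric(N); r[ia] <- w$omega; r[id_] <- w$nu
  r[ib] <- -sol$delta * w$sigma; r[ic] <- -sol$delta * w$mu
  add(r, "<=", cut_tol)
  A <- do.call(rbind, rows)
  obj <- numeric(N); obj[iz] <- 1
  lo <- simplex_lp(obj, A, dirs, rhs, maximize = FALSE)
  hi <- simplex_lp(obj, A, dirs, rhs, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal") {
    stop("returns-to-scale auxiliary LP failed (", lo$status, "/",
         hi$status, ")")
  }
  rng <- c(lo$value, hi$value)
  label <- if (rng[2] < 1 - tol) "IRS" else if (rng[1] > 1 + tol) "DRS"
           else "CRS"
  structure(list(label = label, sum_lambda_range = rng,
                 delta_free = sol$delta, dmu_id = record$dmu_id,
                 period = record$period),
            class = "rts_label")
}

#' @export
print.rts_label <- function(x, ...) {
  cat(sprintf("%s (%s): %s; sum(lambda) in [%.6f, %.6f]; delta_free = %.6f\n",
              x$dmu_id, as.character(x$period), x$label,
              x$sum_lambda_range[1], x$sum_lambda_range[2], x$delta_free))
  invisible(x)
}

#' Score an arbitrary record against a frontier panel
#'
#' Evaluates the slacks-based program for a free-standing record (for
#' example a frontier projection, or a unit observed in a different period)
#' against the frontier spanned by `frontier_panel`'s DMUs. This is the
#' building block of the cross-period Malmquist evaluations and of the
#' projection-efficiency diagnostics.
#'
#' The box bounds on the ratio variables (`alpha, theta <= 1 <= beta,
#' gamma`) can make the program infeasible when the record lies outside the
#' frontier's attainable set, a standard cross-period pathology. With
#' `relax = "auto"` (default) a failed solve is retried with widened bounds
#' (`alpha, theta <= relax_U`, `beta, gamma >= relax_eps`) and the solution
#' is flagged `relaxed`.
#'
#' @param record a record list (`dmu_id`, `xD`, `xI`, `yG`, `yB`) or a
#'   `(dmu, period)` pair drawn from a panel via [solve_gsbup()].
#' @param frontier_panel a validated single-period `dea_panel` (or a panel
#'   plus `period`).
#' @param period optional period selecting the frontier within the panel.
#' @param gamma intensity-set kind, see [solve_gsbup()].
#' @param relax `"auto"`, `"never"` or `"always"`.
#' @param relax_U,relax_eps widened box bounds used on relaxation.
#' @param tmin,eps_gamma see [solve_gsbup()].
#' @return a `gsbup_solution` (with `relaxed = TRUE` if the widened bounds
#'   were used); `status = "infeasible"` if even the relaxed program fails.
#' @export
score_record <- function(record, frontier_panel, period = NULL, gamma = "CRS",
                         relax = c("auto", "never", "always"),
                         relax_U = 10, relax_eps = 0.1,
                         tmin = 1e-6, eps_gamma = 1e-9) {
  relax <- match.arg(relax)
  stopifnot(inherits(frontier_panel, "dea_panel"))
  check_weights(frontier_panel$spec)
  mats <- panel_matrices(frontier_panel, period)
  w <- spec_weights(frontier_panel$spec)
  stopifnot(is.list(record), all(c("xD", "xI", "yG", "yB") %in% names(record)))
  use_relax <- relax == "always"
  raw <- gsbup_lp(record, mats, w, gamma, tmin = tmin, eps_gamma = eps_gamma,
                  relax = use_relax, relax_U = relax_U, relax_eps = relax_eps)
  if (raw$status == "infeasible" && relax == "auto") {
    raw <- gsbup_lp(record, mats, w, gamma, tmin = tmin,
                    eps_gamma = eps_gamma, relax = TRUE,
                    relax_U = relax_U, relax_eps = relax_eps)
    use_relax <- TRUE
  }
  make_solution(raw, record, mats, w, gamma, relaxed = use_relax)
}

#' Re-score frontier projections against the original frontier
#'
#' Projects every DMU of a period onto the frontier and scores the
#' projections against the *original* peer set. By the projection theorem
#' every projection is efficient, so the updated scores equal 1 up to solver
#' tolerance; the function exists as an executable diagnostic of that
#' property on real data.
#'
#' @param panel a validated `dea_panel`.
#' @param period period label (optional for single-period panels).
#' @param gamma intensity-set kind.
#' @return data frame with `dmu_id`, `delta` (original score) and
#'   `delta_updated` (projection re-scored).
#' @export
updated_efficiency <- function(panel, period = NULL, gamma = "CRS") {
  if (is.null(period)) {
    pers <- panel_periods(panel)
    if (length(pers) > 1) stop("panel spans several periods; pass 'period'")
    period <- pers
  }
  df <- panel$data[panel$data$period == period, , drop = FALSE]
  out <- data.frame(dmu_id = df$dmu_id, delta = NA_real_,
                    delta_updated = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    sol <- solve_gsbup(panel, df$dmu_id[i], period, gamma = gamma)
    out$delta[i] <- sol$delta
    proj <- project(sol)
    out$delta_updated[i] <-
      score_record(proj, panel, period, gamma = gamma, relax = "never")$delta
  }
  out
}

#' @export
print.gsbup_solution <- function(x, digits = 4, ...) {
  cat(sprintf("GSBUP solution for %s (%s), Gamma = %s: status %s\n",
              x$dmu_id, as.character(x$period), x$gamma, x$status))
  if (x$status == "optimal") {
    cat(sprintf("  delta = %.*f%s\n", digits, x$delta,
                if (isTRUE(x$relaxed)) "  [relaxed bounds]" else ""))
    cat("  alpha:", round(x$alpha, digits), "\n")
    cat("  beta: ", round(x$beta, digits), "\n")
    cat("  gamma:", round(x$gamma_, digits), "\n")
    cat("  theta:", round(x$theta, digits), "\n")
    lam <- x$lambda[x$lambda > 1e-9]
    cat("  lambda:", paste(sprintf("%s=%.*f", names(lam), digits, lam),
                           collapse = ", "), "\n")
  }
  invisible(x)
}
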