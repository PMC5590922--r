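# Shared fixtures (built in code) and the independent brute-force oracle
# for the slacks-based fractional program.

# one desirable input, one desirable output
toy_spec_11 <- function() factor_spec(c("x", "y"), c("DI", "DO"))

# A dominates B (same output from half the input)
toy_panel_AB <- function() {
  dea_panel(data.frame(dmu_id = c("A", "B"), period = 1,
                       x = c(1, 2), y = c(1, 1)), toy_spec_11())
}

toy_panel_ABC <- function() {
  dea_panel(data.frame(dmu_id = c("A", "B", "C"), period = 1,
                       x = c(1, 2, 4), y = c(1, 4, 6)), toy_spec_11())
}

# full role set: 1 DI, 1 UI, 1 DO, 1 UO, three units
toy_spec_full <- function() {
  factor_spec(c("di", "ui", "do_", "uo"), c("DI", "UI", "DO", "UO"))
}

toy_panel_full <- function() {
  dea_panel(data.frame(
    dmu_id = c("P", "Q", "R"), period = 1,
    di = c(2, 3, 4), ui = c(5, 4, 6), do_ = c(4, 3, 5), uo = c(1, 2, 3)),
    toy_spec_full())
}

# enumerate lambda vectors on the unit simplex (sum = 1) at resolution step
simplex_grid <- function(n, step) {
  k <- round(1 / step)
  if (n == 1) return(matrix(1, 1, 1))
  free <- as.matrix(expand.grid(rep(list(0:k), n - 1)))
  keep <- rowSums(free) <= k
  free <- free[keep, , drop = FALSE]
  cbind(free, k - rowSums(free)) / k
}

# Brute-force search of the fractional program over the lambda simplex
# (convex-hull intensity constraint), with local refinement. Independent of
# the LP path: evaluates the ratio objective directly. Pseudolinearity of
# linear-fractional objectives makes local refinement globally valid.
brute_gsbup <- function(panel, dmu = NULL, period = 1, step = 0.02,
                        rounds = 4, feas_tol = 1e-9, record = NULL) {
  spec <- panel$spec
  df <- panel$data[panel$data$period == period, , drop = FALSE]
  Fm <- t(as.matrix(df[, spec$name, drop = FALSE]))  # factors x dmus
  x0 <- if (is.null(record)) Fm[, match(dmu, df$dmu_id)] else
    record[spec$name]
  role <- spec$role
  w <- numeric(length(role))
  con <- role %in% c("DI", "UO")
  num_w <- spec$weight * con
  den_w <- spec$weight * !con
  eval_pts <- function(Lam) {  # Lam: npts x n
    R <- (Lam %*% t(Fm)) / rep(x0, each = nrow(Lam))  # ratios, npts x nf
    lo_ok <- R[, con, drop = FALSE] <= 1 + feas_tol
    hi_ok <- R[, !con, drop = FALSE] >= 1 - feas_tol
    feas <- rowSums(!lo_ok) + rowSums(!hi_ok) == 0
    delta <- (R %*% num_w) / (R %*% den_w)
    list(delta = drop(delta), feas = feas)
  }
  n <- ncol(Fm)
  Lam <- simplex_grid(n, step)
  best <- NULL
  cur_step <- step
  for (r in seq_len(rounds)) {
    ev <- eval_pts(Lam)
    if (any(ev$feas)) {
      idx <- which(ev$feas)[which.min(ev$delta[ev$feas])]
      cand <- list(delta = ev$delta[idx], lambda = Lam[idx, ])
      if (is.null(best) || cand$delta < best$delta) best <- cand
    }
    if (is.null(best)) {  # widen the coarse grid once before giving up
      if (r == 1) { Lam <- simplex_grid(n, step / 2); next } else break
    }
    cur_step <- cur_step / 5
    off <- as.matrix(expand.grid(rep(list(-5:5), n - 1))) * cur_step
    free <- sweep(off, 2, best$lambda[-n], "+")
    keep <- rowSums(free < -1e-12) == 0 & rowSums(free) <= 1 + 1e-12
    free <- free[keep, , drop = FALSE]
    Lam <- cbind(free, pmax(1 - rowSums(free), 0))
  }
  if (is.null(best)) return(list(delta = NA_real_, lambda = NULL))
  best
}

# Box-grid enumeration oracle for the free-intensity program: lambda is
# enumerated on [0, lam_max]^n, the ratio objective evaluated directly, and
# the range of sum(lambda) collected over near-optimal feasible points.
brute_free_rts <- function(panel, dmu, period = 1, lam_max = 2, step = 0.02,
                           delta_tol = 1e-6, feas_tol = 1e-9) {
  spec <- panel$spec
  df <- panel$data[panel$data$period == period, , drop = FALSE]
  Fm <- t(as.matrix(df[, spec$name, drop = FALSE]))
  x0 <- Fm[, match(dmu, df$dmu_id)]
  role <- spec$role
  con <- role %in% c("DI", "UO")
  num_w <- spec$weight * con
  den_w <- spec$weight * !con
  n <- ncol(Fm)
  Lam <- as.matrix(expand.grid(rep(list(seq(0, lam_max, by = step)), n)))
  R <- (Lam %*% t(Fm)) / rep(x0, each = nrow(Lam))
  feas <- rowSums(R[, con, drop = FALSE] > 1 + feas_tol) +
    rowSums(R[, !con, drop = FALSE] < 1 - feas_tol) == 0
  delta <- drop((R %*% num_w) / (R %*% den_w))
  delta[!feas] <- Inf
  dstar <- min(delta)
  sums <- rowSums(Lam)[delta <= dstar + delta_tol]
  list(delta = dstar, sum_range = range(sums))
}

# fixture set of small panels (n <= 4, total dimension <= 4) for the
# LP-vs-brute-force equivalence checks
small_fixture_panels <- function() {
  sp21 <- factor_spec(c("x1", "x2", "y"), c("DI", "DI", "DO"))
  sp_ui <- factor_spec(c("x", "u", "y"), c("DI", "UI", "DO"))
  sp_uo <- factor_spec(c("x", "y", "b"), c("DI", "DO", "UO"))
  list(
    AB = toy_panel_AB(),
    ABC = toy_panel_ABC(),
    full3 = toy_panel_full(),
    two_in = dea_panel(data.frame(
      dmu_id = c("A", "B", "C", "D"), period = 1,
      x1 = c(1, 2, 3, 2.5), x2 = c(3, 1, 2, 2.5), y = c(2, 2, 3, 2)), sp21),
    with_ui = dea_panel(data.frame(
      dmu_id = c("A", "B", "C"), period = 1,
      x = c(1, 2, 1.5), u = c(3, 2, 2.5), y = c(2, 2.5, 2)), sp_ui),
    with_uo = dea_panel(data.frame(
      dmu_id = c("A", "B", "C", "D"), period = 1,
      x = c(1, 2, 1.5, 3), y = c(2, 2.5, 2, 3.5), b = c(1, 2, 2, 1.5)),
      sp_uo))
}
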