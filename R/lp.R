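# Dense two-phase primal simplex for the small linear programs this package
# builds (a few dozen variables). All structural variables are >= 0; general
# bounds are passed as explicit rows by the callers.
#
# Neither of the LP routines shipped with the R stack used here survives the
# GSBUP programs: they are heavily degenerate (almost every right-hand side is
# zero), which cycles or crashes textbook pricing. Bland's rule is used
# throughout; it is slower than Dantzig pricing but terminates on degenerate
# problems, and the programs are tiny.

#' Solve a small dense linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `A x (dir) rhs`, `x >= 0`,
#' by the two-phase primal simplex method with Bland's anti-cycling rule.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n).
#' @param dir character vector of `"<="`, `">="`, `"=="` per row.
#' @param rhs numeric right-hand sides (length m).
#' @param maximize logical; maximize instead of minimize.
#' @param tol pivot / feasibility tolerance.
#' @param max_iter iteration cap per phase.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `x` (primal solution) and `value` (objective).
#' @keywords internal
#' @noRd
simplex_lp <- function(obj, A, dir, rhs, maximize = FALSE,
                       tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m)
  if (!all(dir %in% c("<=", ">=", "=="))) {
    stop("constraint directions must be one of '<=', '>=', '=='")
  }
  cvec <- if (maximize) -obj else obj

  # normalize to rhs >= 0
  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]
  }

  n_le <- sum(dir == "<=")
  n_ge <- sum(dir == ">=")
  n_eq <- sum(dir == "==")
  n_art <- n_ge + n_eq
  ncols <- n + n_le + n_ge + n_art

  Tb <- matrix(0, m, ncols + 1L)
  Tb[, seq_len(n)] <- A
  Tb[, ncols + 1L] <- rhs
  basis <- integer(m)
  slack_j <- n
  art_j <- n + n_le + n_ge
  surp_j <- n + n_le
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      slack_j <- slack_j + 1L
      Tb[i, slack_j] <- 1
      basis[i] <- slack_j
    } else {
      if (dir[i] == ">=") {
        surp_j <- surp_j + 1L
        Tb[i, surp_j] <- -1
      }
      art_j <- art_j + 1L
      Tb[i, art_j] <- 1
      basis[i] <- art_j
    }
  }
  artificial <- seq.int(n + n_le + n_ge + 1L, ncols)
  is_art <- rep(FALSE, ncols)
  if (n_art > 0) is_art[artificial] <- TRUE

  pivot <- function(Tb, red, i, j) {
    piv <- Tb[i, j]
    Tb[i, ] <- Tb[i, ] / piv
    fac <- Tb[, j]
    fac[i] <- 0
    Tb <- Tb - outer(fac, Tb[i, ])
    red <- red - red[j] * Tb[i, ]
    list(Tb = Tb, red = red)
  }

  run_phase <- function(Tb, basis, red, blocked) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit",
                                     Tb = Tb, basis = basis, red = red))
      cand <- which(red[seq_len(ncols)] < -tol & !blocked)
      if (length(cand) == 0L) {
        return(list(status = "optimal", Tb = Tb, basis = basis, red = red))
      }
      j <- cand[1L]  # Bland: smallest index enters
      col <- Tb[, j]
      ok <- which(col > tol)
      if (length(ok) == 0L) {
        return(list(status = "unbounded", Tb = Tb, basis = basis, red = red))
      }
      ratio <- Tb[ok, ncols + 1L] / col[ok]
      rmin <- min(ratio)
      ties <- ok[ratio <= rmin + tol * (1 + abs(rmin))]
      i <- ties[which.min(basis[ties])]  # Bland: smallest basic index leaves
      up <- pivot(Tb, red, i, j)
      Tb <- up$Tb
      red <- up$red
      basis[i] <- j
    }
  }

  # phase 1: minimize sum of artificials
  if (n_art > 0) {
    red1 <- c(numeric(ncols), 0)
    red1[artificial] <- 1
    for (i in which(is_art[basis])) red1 <- red1 - Tb[i, ]
    ph1 <- run_phase(Tb, basis, red1, blocked = rep(FALSE, ncols))
    if (ph1$status != "optimal") {
      return(list(status = ph1$status, x = NULL, value = NA_real_))
    }
    Tb <- ph1$Tb
    basis <- ph1$basis
    scale1 <- max(1, abs(rhs))
    if (-ph1$red[ncols + 1L] > 1e-7 * scale1) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    # drive leftover artificials out of the basis
    for (i in which(is_art[basis])) {
      j_ok <- which(!is_art[seq_len(ncols)] & abs(Tb[i, seq_len(ncols)]) > tol)
      if (length(j_ok) > 0L) {
        up <- pivot(Tb, numeric(ncols + 1L), i, j_ok[1L])
        Tb <- up$Tb
        basis[i] <- j_ok[1L]
      } else {
        Tb[i, ncols + 1L] <- 0  # redundant row
      }
    }
  }

  # phase 2
  red2 <- c(cvec, numeric(ncols - n), 0)
  for (i in seq_len(m)) red2 <- red2 - red2[basis[i]] * Tb[i, ]
  ph2 <- run_phase(Tb, basis, red2, blocked = is_art)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, x = NULL, value = NA_real_))
  }
  x_full <- numeric(ncols)
  x_full[ph2$basis] <- ph2$Tb[, ncols + 1L]
  x <- x_full[seq_len(n)]
  val <- sum(cvec * x)
  list(status = "optimal", x = x, value = if (maximize) -val else val)
}
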