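# Seeded generators producing panels with a known ("planted") frontier,
# known temporal drift, and censored-regression data with known
# coefficients, so that every stage of the toolkit can be validated without
# external data.
#
# Frontier construction: a point set on a hyperplane  sum(g * z) = c  with
# g > 0 on the contraction factors (DI, UO) and g < 0 on the expansion
# factors (UI, DO) is mutually undominated under the convex-hull intensity
# constraint (sum(lambda) = 1): any point of the production set is weakly
# worse than some hull point, and every hull point sits on the hyperplane,
# so no feasible point can improve on a frontier point in any direction.
# Planted-efficient DMUs are therefore guaranteed to score 1 under that
# constraint. Inefficient DMUs are frontier points degraded role-wise
# (DI and UO inflated, DO and UI deflated), which leaves the frontier
# untouched and guarantees a score below 1.

# run code under a fixed seed without disturbing the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Design for a synthetic panel with a planted frontier
#'
#' @param n_efficient number of planted-efficient DMUs (at least 1).
#' @param n_inefficient number of planted-inefficient DMUs.
#' @param dims named vector `c(m, q, s, k)`: desirable inputs, undesirable
#'   inputs, desirable outputs, undesirable outputs. The default matches the
#'   hospital-cluster application (2 DI, 1 UI, 3 DO, 1 UO).
#' @param scales typical magnitude per factor (length `sum(dims)`); the
#'   default reproduces the magnitudes of the hospital panel (staff ~2747,
#'   beds ~1030, discharge rate ~84, patient-days ~445, ED attendances
#'   ~126, outpatient attendances ~733, mortality ~22) when `dims` is the
#'   default, and 100 per factor otherwise.
#' @param ineff_range range of the per-factor degradation severity `u` of
#'   inefficient DMUs (`u <= 1`; DI and UO are divided by `u`, DO and UI
#'   multiplied by `u`).
#' @param multipliers optional explicit degradation matrix
#'   (`n_inefficient` rows, one column per factor) overriding the sampled
#'   severities; entries must lie in `(0, 1]`.
#' @param jitter half-width of the multiplicative spread of frontier points
#'   around `scales`.
#' @param seed integer seed; the same seed reproduces the panel bit-exactly.
#' @return object of class `frontier_design`.
#' @export
frontier_design <- function(n_efficient, n_inefficient = 0,
                            dims = c(m = 2, q = 1, s = 3, k = 1),
                            scales = NULL, ineff_range = c(0.8, 0.95),
                            multipliers = NULL, jitter = 0.1, seed = 1) {
  stopifnot(n_efficient >= 1, n_inefficient >= 0)
  dims <- as.integer(dims[c("m", "q", "s", "k")])
  names(dims) <- c("m", "q", "s", "k")
  if (dims["m"] + dims["q"] == 0) stop("need at least one input factor")
  if (dims["s"] + dims["k"] == 0) stop("need at least one output factor")
  if (dims["m"] == 0 && dims["s"] == 0) {
    stop("need at least one DI or DO factor to anchor the frontier")
  }
  if (is.null(scales)) {
    scales <- if (identical(unname(dims), c(2L, 1L, 3L, 1L))) {
      c(2747, 1030, 84, 445, 126, 733, 22)
    } else rep(100, sum(dims))
  }
  if (length(scales) != sum(dims)) stop("'scales' has wrong length")
  stopifnot(all(scales > 0), all(ineff_range > 0), all(ineff_range <= 1),
            jitter > 0, jitter < 1)
  if (!is.null(multipliers)) {
    multipliers <- as.matrix(multipliers)
    stopifnot(nrow(multipliers) == n_inefficient,
              ncol(multipliers) == sum(dims),
              all(multipliers > 0), all(multipliers <= 1))
  }
  structure(list(n_efficient = n_efficient, n_inefficient = n_inefficient,
                 dims = dims, scales = scales, ineff_range = ineff_range,
                 multipliers = multipliers, jitter = jitter,
                 seed = as.integer(seed)),
            class = "frontier_design")
}

#' @noRd
design_spec <- function(design) {
  d <- design$dims
  nm <- c(sprintf("DI%d", seq_len(d["m"])), sprintf("UI%d", seq_len(d["q"])),
          sprintf("DO%d", seq_len(d["s"])), sprintf("UO%d", seq_len(d["k"])))
  role <- c(rep("DI", d["m"]), rep("UI", d["q"]),
            rep("DO", d["s"]), rep("UO", d["k"]))
  factor_spec(nm, role)
}

#' Generate a panel with a planted frontier
#'
#' Samples `n_efficient` DMUs on a common frontier hyperplane (role-wise
#' jitter, projected back onto the hyperplane through the anchor factor) and
#' `n_inefficient` DMUs obtained by degrading a random convex combination of
#' the efficient DMUs (so the generating point is attainable and domination
#' is guaranteed). The efficiency ground truth holds under the convex-hull
#' intensity constraint (`gamma = "CRS"` in [solve_gsbup()]'s labeling).
#'
#' @param design a [frontier_design()].
#' @param period period label for the generated records.
#' @return list with `panel` (a `dea_panel`), `truth` (data frame:
#'   `dmu_id`, `efficient`, degradation multiplier per factor, generating
#'   frontier point per factor) and `spec`.
#' @examples
#' g <- generate_frontier_panel(frontier_design(3, 2, seed = 42))
#' efficiency_table(g$panel)
#' @export
generate_frontier_panel <- function(design, period = 1) {
  stopifnot(inherits(design, "frontier_design"))
  d <- design$dims
  spec <- design_spec(design)
  role <- spec$role
  sc <- design$scales
  gcoef <- ifelse(role %in% c("DI", "UO"), 1, -1) / sc
  cc <- sum(role %in% c("DI", "UO")) - sum(role %in% c("UI", "DO"))
  anchor <- if (d["m"] > 0) 1L else which(role == "DO")[1]
  nf <- length(sc)
  with_seed(design$seed, {
    sample_frontier_point <- function() {
      for (try in 1:200) {
        z <- sc * stats::runif(nf, 1 - design$jitter, 1 + design$jitter)
        rest <- sum(gcoef[-anchor] * z[-anchor])
        z[anchor] <- (cc - rest) / gcoef[anchor]
        if (z[anchor] > 0.2 * sc[anchor] && z[anchor] < 3 * sc[anchor]) {
          return(z)
        }
      }
      stop("could not sample a positive frontier point; widen 'scales'")
    }
    n <- design$n_efficient + design$n_inefficient
    pts <- t(vapply(seq_len(design$n_efficient),
                    function(i) sample_frontier_point(), numeric(nf)))
    eff_flag <- rep(c(TRUE, FALSE), c(design$n_efficient,
                                      design$n_inefficient))
    gen <- matrix(NA_real_, n, nf)
    mult <- matrix(1, n, nf)
    data <- matrix(NA_real_, n, nf)
    data[seq_len(design$n_efficient), ] <- pts
    gen[seq_len(design$n_efficient), ] <- pts
    if (design$n_inefficient > 0) {
      for (i in seq_len(design$n_inefficient)) {
        wts <- stats::runif(design$n_efficient)
        src <- drop(crossprod(pts, wts / sum(wts)))
        u <- if (!is.null(design$multipliers)) design$multipliers[i, ] else
          stats::runif(nf, design$ineff_range[1], design$ineff_range[2])
        z <- ifelse(role %in% c("DI", "UO"), src / u, src * u)
        row <- design$n_efficient + i
        data[row, ] <- z
        gen[row, ] <- src
        mult[row, ] <- u
      }
    }
    ids <- sprintf("D%d", seq_len(n))
    df <- data.frame(dmu_id = ids, period = period, data,
                     stringsAsFactors = FALSE)
    names(df)[-(1:2)] <- spec$name
    truth <- data.frame(dmu_id = ids, efficient = eff_flag,
                        stringsAsFactors = FALSE)
    truth[paste0("mult_", spec$name)] <- mult
    truth[paste0("gen_", spec$name)] <- gen
    list(panel = dea_panel(df, spec), truth = truth, spec = spec)
  })
}

#' Generate a multi-period panel with multiplicative frontier drift
#'
#' Builds the base panel from `design`, then scales every DMU's desirable
#' outputs by `g^(p-1)` in period `p`, so the frontier technology drifts by
#' the factor `g` per period while each DMU keeps its position relative to
#' the frontier. DMUs listed in `static_dmus` keep their period-1 data
#' (they fall behind a progressing frontier); DMUs named in `tec_decay`
#' additionally have their desirable outputs multiplied by the named factor
#' per elapsed period (their own efficiency erodes).
#'
#' @param design a [frontier_design()].
#' @param periods number of periods (at least 2).
#' @param g multiplicative frontier shift per period (> 0; `g > 1` is
#'   technological progress).
#' @param static_dmus character vector of DMU ids frozen at period-1 data.
#' @param tec_decay named numeric vector (names = DMU ids) of per-period
#'   own-efficiency decay factors applied to desirable outputs.
#' @return a multi-period `dea_panel` (periods `1..periods`), with the
#'   generation `truth` attached as attribute `truth`.
#' @export
generate_drift_series <- function(design, periods, g = 1.05,
                                  static_dmus = character(),
                                  tec_decay = NULL) {
  stopifnot(periods >= 2)
  if (g <= 0) stop("drift factor 'g' must be positive")
  base <- generate_frontier_panel(design, period = 1)
  spec <- base$spec
  do_cols <- spec$name[spec$role == "DO"]
  rows <- list()
  for (p in seq_len(periods)) {
    df <- base$panel$data
    df$period <- p
    keep <- df$dmu_id %in% static_dmus
    df[!keep, do_cols] <- df[!keep, do_cols] * g^(p - 1)
    if (!is.null(tec_decay)) {
      for (dmu in names(tec_decay)) {
        sel <- df$dmu_id == dmu
        df[sel, do_cols] <- df[sel, do_cols] * tec_decay[[dmu]]^(p - 1)
      }
    }
    rows[[p]] <- df
  }
  panel <- dea_panel(do.call(rbind, rows), spec)
  attr(panel, "truth") <- base$truth
  panel
}

#' Generate censored-regression data with known coefficients
#'
#' Draws a standard-normal covariate matrix with an intercept column,
#' forms the latent response `y* = X beta + sigma * e`, and clips it to
#' `[lower, upper]`. The achieved censoring fraction is attached as an
#' attribute; if `censor_rate_target` is given and the achieved fraction
#' differs from it by more than 5 percentage points, a warning is raised
#' (generation proceeds).
#'
#' @param n number of observations (must exceed `length(beta_true)`).
#' @param beta_true true coefficients, intercept first.
#' @param sigma_true non-negative latent error SD (0 gives a deterministic
#'   response, for which the censored-normal likelihood is unbounded).
#' @param censor_rate_target optional target total censoring fraction.
#' @param seed integer seed.
#' @param lower,upper censoring bounds.
#' @return a [tobit_design()] with attributes `beta_true`, `sigma_true`,
#'   `achieved_censoring`, `y_latent`.
#' @export
generate_tobit_panel <- function(n, beta_true, sigma_true,
                                 censor_rate_target = NULL, seed = 1,
                                 lower = 0, upper = 1) {
  p <- length(beta_true)
  if (n <= p) stop("need n > length(beta_true)")
  if (sigma_true < 0) stop("sigma_true must be non-negative")
  with_seed(seed, {
    X <- cbind(1, matrix(stats::rnorm(n * (p - 1L)), n, p - 1L))
    colnames(X) <- c("(Intercept)",
                     if (p > 1) sprintf("x%d", seq_len(p - 1L)))
    ystar <- drop(X %*% beta_true) + sigma_true * stats::rnorm(n)
    y <- pmin(pmax(ystar, lower), upper)
    achieved <- mean(ystar > upper | ystar < lower)
    if (!is.null(censor_rate_target) &&
        abs(achieved - censor_rate_target) > 0.05) {
      warning(sprintf(
        "achieved censoring %.3f differs from target %.3f under beta_true",
        achieved, censor_rate_target))
    }
    design <- tobit_design(y, X, lower, upper)
    attr(design, "beta_true") <- beta_true
    attr(design, "sigma_true") <- sigma_true
    attr(design, "achieved_censoring") <- achieved
    attr(design, "y_latent") <- ystar
    design
  })
}
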