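#' Factor specification: roles and preference weights
#'
#' A factor specification maps each data column to one of the four roles of
#' the non-oriented slacks-based model: desirable input (`DI`), undesirable
#' input (`UI`), desirable output (`DO`), undesirable output (`UO`). Each
#' factor carries a non-negative preference weight; the model requires the
#' weights of the "contraction" group (DI and UO) to sum to one, and those of
#' the "expansion" group (UI and DO) to sum to one. When `weight` is `NULL`
#' the parameter-free equal split within each group is used.
#'
#' @param name character vector of factor (column) names.
#' @param role character vector of roles, one of `"DI"`, `"UI"`, `"DO"`, `"UO"`.
#' @param weight optional numeric vector of non-negative preference weights;
#'   `NULL` (default) assigns equal weights within each normalization group.
#' @param unit optional character vector of free-text unit annotations.
#' @return an object of class `factor_spec`: a data frame with columns
#'   `name`, `role`, `weight`, `unit`.
#' @examples
#' spec <- factor_spec(
#'   name = c("staff", "beds", "discharge_rate", "stay", "mortality"),
#'   role = c("DI", "DI", "UI", "DO", "UO"))
#' spec
#' @export
factor_spec <- function(name, role, weight = NULL, unit = NULL) {
  name <- as.character(name)
  role <- as.character(role)
  if (length(role) != length(name)) {
    stop("'name' and 'role' must have the same length")
  }
  if (anyDuplicated(name)) stop("factor names must be unique")
  bad <- setdiff(role, c("DI", "UI", "DO", "UO"))
  if (length(bad) > 0) {
    stop("unknown factor role(s): ", paste(bad, collapse = ", "))
  }
  if (!any(role %in% c("DI", "UI"))) stop("at least one input factor required")
  if (!any(role %in% c("DO", "UO"))) stop("at least one output factor required")
  if (is.null(unit)) unit <- rep("", length(name))
  spec <- data.frame(name = name, role = role,
                     weight = NA_real_, unit = as.character(unit),
                     stringsAsFactors = FALSE)
  class(spec) <- c("factor_spec", "data.frame")
  if (is.null(weight)) {
    spec <- equal_weights(spec)
  } else {
    if (length(weight) != length(name)) stop("'weight' has wrong length")
    if (any(weight < 0)) stop("preference weights must be non-negative")
    spec$weight <- as.numeric(weight)
    check_weights(spec)
  }
  spec
}

#' Equal preference weights within each normalization group
#'
#' Sets every DI/UO weight to `1 / (m + k)` and every UI/DO weight to
#' `1 / (q + s)`, the symmetric, parameter-free choice consistent with the
#' model's two weight-normalization constraints.
#'
#' @param spec a [factor_spec()].
#' @return the spec with the `weight` column replaced.
#' @export
equal_weights <- function(spec) {
  stopifnot(inherits(spec, "factor_spec"))
  con <- spec$role %in% c("DI", "UO")   # contraction group
  exp_ <- spec$role %in% c("UI", "DO")  # expansion group
  spec$weight[con] <- 1 / sum(con)
  spec$weight[exp_] <- 1 / sum(exp_)
  spec
}

#' @noRd
check_weights <- function(spec, tol = 1e-12) {
  s_con <- sum(spec$weight[spec$role %in% c("DI", "UO")])
  s_exp <- sum(spec$weight[spec$role %in% c("UI", "DO")])
  if (abs(s_con - 1) > tol || abs(s_exp - 1) > tol) {
    stop(sprintf(paste0("preference weights must sum to 1 within each ",
                        "normalization group (DI+UO = %.12f, UI+DO = %.12f)"),
                 s_con, s_exp))
  }
  invisible(spec)
}

#' Dimensions (m, q, s, k) implied by a factor spec
#'
#' @param spec a [factor_spec()].
#' @return named integer vector with the number of desirable inputs `m`,
#'   undesirable inputs `q`, desirable outputs `s`, undesirable outputs `k`.
#' @export
spec_dims <- function(spec) {
  stopifnot(inherits(spec, "factor_spec"))
  c(m = sum(spec$role == "DI"), q = sum(spec$role == "UI"),
    s = sum(spec$role == "DO"), k = sum(spec$role == "UO"))
}

# weight vectors (omega, sigma, mu, nu) in factor order within role
#' @noRd
spec_weights <- function(spec) {
  list(omega = spec$weight[spec$role == "DI"],
       sigma = spec$weight[spec$role == "UI"],
       mu    = spec$weight[spec$role == "DO"],
       nu    = spec$weight[spec$role == "UO"])
}

#' Read a factor specification from a YAML config file
#'
#' The config maps each factor name to its `role` and optional `weight` and
#' `unit`, e.g.
#' ```yaml
#' factors:
#'   DI1: {role: DI, unit: "1 person"}
#'   UO1: {role: UO, unit: "per mille"}
#' ```
#' If any factor omits `weight`, equal weights are assigned within each group.
#'
#' @param path path to the YAML file.
#' @return a [factor_spec()].
#' @export
read_factor_spec <- function(path) {
  if (!file.exists(path)) stop("spec config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$factors)) stop("spec config must have a 'factors' section")
  nm <- names(cfg$factors)
  role <- vapply(cfg$factors, function(f) as.character(f$role), "")
  w <- vapply(cfg$factors, function(f)
    if (is.null(f$weight)) NA_real_ else as.numeric(f$weight), 0)
  un <- vapply(cfg$factors, function(f)
    if (is.null(f$unit)) "" else as.character(f$unit), "")
  if (all(is.na(w))) {
    factor_spec(nm, role, weight = NULL, unit = un)
  } else {
    if (anyNA(w)) stop("either all or none of the factors may set 'weight'")
    factor_spec(nm, role, weight = w, unit = un)
  }
}

#' @export
print.factor_spec <- function(x, ...) {
  d <- spec_dims(x)
  cat(sprintf("Factor spec: %d DI, %d UI, %d DO, %d UO\n",
              d["m"], d["q"], d["s"], d["k"]))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
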