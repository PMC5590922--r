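test_that("factor specs enforce roles and weight normalization", {
  expect_error(factor_spec(c("a", "b"), c("DI", "XX")), "unknown factor role")
  expect_error(factor_spec("a", "DI"), "output factor")
  expect_error(factor_spec(c("a", "a"), c("DI", "DO")), "unique")
  # weights must sum to 1 within each group, to 1e-12
  expect_error(factor_spec(c("a", "b"), c("DI", "DO"),
                           weight = c(0.9, 1)), "sum to 1")
  expect_error(factor_spec(c("a", "b"), c("DI", "DO"),
                           weight = c(-1, 2)), "non-negative")
  sp <- factor_spec(c("a", "b", "u", "y", "m"),
                    c("DI", "DI", "UI", "DO", "UO"))
  expect_equal(sp$weight, c(1/3, 1/3, 1/2, 1/2, 1/3))
  expect_equal(unname(spec_dims(sp)), c(2L, 1L, 1L, 1L))
})

test_that("panels load from CSV with schema and parse errors", {
  hk <- hk_clusters_2013()
  expect_s3_class(hk$panel, "dea_panel")
  expect_equal(nrow(hk$panel$data), 7)
  expect_equal(unname(hk$panel$dims), c(2L, 1L, 3L, 1L))
  sp <- toy_spec_11()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("dmu_id,period,x,y", f)
  expect_error(load_panel(f, sp), "empty data section")
  writeLines(c("dmu_id,period,x", "A,1,1"), f)
  expect_error(load_panel(f, sp), "missing column")
  writeLines(c("dmu_id,period,x,y", "A,1,oops,2"), f)
  expect_error(load_panel(f, sp), "non-numeric value 'oops' in column 'x', data row 1")
  # negative values pass loading but fail validation
  writeLines(c("dmu_id,period,x,y", "A,1,-1,2", "B,1,1,1"), f)
  p <- load_panel(f, sp)
  expect_s3_class(p, "dea_panel")
  expect_error(validate_panel(p), "negative")
})

test_that("zero policy substitutes or rejects, and is idempotent", {
  sp <- factor_spec(c("x", "y", "z"), c("DI", "DO", "DO"))
  p <- dea_panel(data.frame(dmu_id = c("A", "B", "C"), period = 1,
                            x = c(1, 2, 3), y = c(2, 0, 4), z = c(1, 1, 1)),
                 sp)
  v <- validate_panel(p, "substitute")
  expect_true(v$report$passed)
  expect_equal(nrow(v$report$zero_substitutions), 1)
  expect_equal(v$report$zero_substitutions$new, 1e-3 * mean(c(2, 0, 4)))
  expect_gt(v$panel$data$y[2], 0)
  # idempotent: a second pass makes no further substitutions
  v2 <- validate_panel(v$panel, "substitute")
  expect_equal(nrow(v2$report$zero_substitutions), 0)
  expect_identical(v2$panel$data, v$panel$data)
  expect_error(validate_panel(p, "reject"), "zero")
  # all-zero outputs are an error regardless of policy
  p2 <- dea_panel(data.frame(dmu_id = c("A", "B"), period = 1,
                             x = c(1, 1), y = c(2, 0), z = c(1, 0)), sp)
  expect_error(validate_panel(p2, "substitute"), "all_zero_outputs|output factor")
})

test_that("panel CSV round trip is bit-exact for decimal text", {
  hk <- hk_clusters_2013()
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(hk$panel, f)
  again <- load_panel(f, hk$spec)
  for (col in hk$spec$name) {
    expect_identical(again$data[[col]], hk$panel$data[[col]])
  }
})

test_that("descriptive statistics match direct formula evaluation", {
  # brute-force oracle: the textbook formulas evaluated directly
  x <- c(2, 7, 3)
  n <- length(x)
  mbar <- sum(x) / n
  m2 <- sum((x - mbar)^2) / n
  m3 <- sum((x - mbar)^3) / n
  m4 <- sum((x - mbar)^4) / n
  exp_sd <- sqrt(sum((x - mbar)^2) / (n - 1))
  exp_skew <- m3 / m2^1.5
  exp_kurt <- m4 / m2^2 - 3
  sp <- toy_spec_11()
  p <- dea_panel(data.frame(dmu_id = c("A", "B", "C"), period = 1,
                            x = x, y = c(1, 2, 3)), sp)
  ds <- descriptive_stats(p, 1)
  got <- function(stat) ds$stats$x[ds$stats$statistic == stat]
  expect_equal(got("mean"), mbar)
  expect_equal(got("median"), 3)
  expect_equal(got("sd"), exp_sd)
  expect_equal(got("skewness"), exp_skew)
  expect_equal(got("kurtosis"), exp_kurt)
  expect_equal(got("max"), 7)
  expect_equal(got("min"), 2)
})

test_that("correlation matrix is symmetric, unit-diagonal, bounded", {
  g <- generate_frontier_panel(frontier_design(5, 3, seed = 21))
  ds <- descriptive_stats(g$panel, 1)
  C <- ds$correlation
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, ncol(C)))
  expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12))
})

test_that("degenerate descriptive inputs are flagged", {
  sp <- toy_spec_11()
  p1 <- dea_panel(data.frame(dmu_id = "A", period = 1, x = 1, y = 1), sp)
  expect_error(descriptive_stats(p1, 1), "at least 2")
  p2 <- dea_panel(data.frame(dmu_id = c("A", "B"), period = 1,
                             x = c(1, 1), y = c(1, 2)), sp)
  expect_warning(ds <- descriptive_stats(p2, 1), "constant")
  expect_true(is.nan(ds$stats$x[ds$stats$statistic == "skewness"]))
})
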