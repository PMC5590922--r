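test_that("dominated toy unit scores 0.5 and projects onto its dominator", {
  p <- toy_panel_AB()
  solB <- solve_gsbup(p, "B")
  expect_equal(solB$status, "optimal")
  expect_equal(solB$delta, 0.5, tolerance = 1e-9)
  expect_equal(unname(solB$lambda["A"]), 1, tolerance = 1e-9)
  expect_false(is_efficient(solB))
  projB <- project(solB)
  expect_equal(unname(projB$xD), 1, tolerance = 1e-9)
  expect_equal(unname(projB$yG), 1, tolerance = 1e-9)
  # matches the independent grid-search oracle
  expect_equal(solB$delta, brute_gsbup(p, "B")$delta, tolerance = 1e-6)
  solA <- solve_gsbup(p, "A")
  expect_equal(solA$delta, 1)
  expect_true(is_efficient(solA))
  projA <- project(solA)
  expect_equal(unname(projA$xD), 1)
})

test_that("a single-unit panel is self-referential and efficient", {
  sp <- toy_spec_full()
  p <- dea_panel(data.frame(dmu_id = "P", period = 1,
                            di = 2, ui = 5, do_ = 4, uo = 1), sp)
  sol <- solve_gsbup(p, "P")
  expect_equal(sol$delta, 1)
  expect_equal(unname(sol$lambda), 1, tolerance = 1e-9)
  expect_equal(unname(c(sol$alpha, sol$beta, sol$gamma_, sol$theta)),
               rep(1, 4), tolerance = 1e-9)
  expect_equal(classify_rts(p, "P")$label, "CRS")
})

test_that("efficiency flag follows the slack tolerance threshold", {
  sol <- solve_gsbup(toy_panel_AB(), "A")
  tol <- 1e-6
  shifted <- sol
  shifted$alpha[1] <- 1 - 10 * tol
  expect_false(is_efficient(shifted, tol))
  shifted$alpha[1] <- 1 - 0.5 * tol
  expect_true(is_efficient(shifted, tol))
  bad <- sol
  bad$status <- "infeasible"
  expect_error(is_efficient(bad), "optimal")
})

test_that("a panel of identical units is uniformly efficient", {
  sp <- toy_spec_full()
  p <- dea_panel(data.frame(dmu_id = c("P1", "P2", "P3"), period = 1,
                            di = 2, ui = 5, do_ = 4, uo = 1), sp)
  tab <- efficiency_table(p)
  expect_equal(tab$delta, rep(1, 3))
  expect_true(all(tab$efficient))
  s <- attr(tab, "summary")
  expect_equal(s$n_efficient, 3)
})

test_that("LP optimum matches the fractional-program oracle on small panels", {
  for (p in small_fixture_panels()[c("full3", "with_uo")]) {
    for (d in p$data$dmu_id) {
      lp <- solve_gsbup(p, d)$delta
      expect_equal(lp, brute_gsbup(p, d)$delta, tolerance = 1e-3)
    }
  }
})

test_that("Charnes-Cooper back-transformation reproduces the objective", {
  hk <- hk_clusters_2013()
  w <- gsbup:::spec_weights(hk$spec)
  for (d in hk$panel$data$dmu_id) {
    sol <- solve_gsbup(hk$panel, d)
    frac <- (sum(w$omega * sol$alpha) + sum(w$nu * sol$theta)) /
      (sum(w$sigma * sol$gamma_) + sum(w$mu * sol$beta))
    expect_equal(frac, sol$delta, tolerance = 1e-8)
    expect_true(sol$delta >= 0 && sol$delta <= 1 + 1e-9)
    # slack recovery identities against the intensity-combination form
    mats <- sol$frontier
    rec <- sol$target
    expect_equal(drop(mats$xD %*% sol$lambda), rec$xD - sol$slacks$sD,
                 tolerance = 1e-6)
    expect_equal(drop(mats$xI %*% sol$lambda), rec$xI + sol$slacks$sI,
                 tolerance = 1e-6)
    expect_equal(drop(mats$yG %*% sol$lambda), rec$yG + sol$slacks$sG,
                 tolerance = 1e-6)
    expect_equal(drop(mats$yB %*% sol$lambda), rec$yB - sol$slacks$sB,
                 tolerance = 1e-6)
  }
})

test_that("scores are invariant to the units of any factor column", {
  hk <- hk_clusters_2013()
  base <- efficiency_table(hk$panel)$delta
  for (f in hk$spec$name) {
    df <- hk$panel$data
    df[[f]] <- df[[f]] * 1e3
    scaled <- dea_panel(df, hk$spec)
    expect_equal(efficiency_table(scaled)$delta, base, tolerance = 1e-7)
  }
})

test_that("appending a dominated unit changes no other score", {
  g <- generate_frontier_panel(frontier_design(4, 2, seed = 31))
  base <- efficiency_table(g$panel)$delta
  df <- g$panel$data
  worst <- df[1, ]
  worst$dmu_id <- "DOMINATED"
  spec <- g$panel$spec
  for (f in spec$name) {
    worse <- if (spec$role[spec$name == f] %in% c("DI", "UO")) 1.3 else 0.7
    worst[[f]] <- worst[[f]] * worse
  }
  p2 <- dea_panel(rbind(df, worst), spec)
  tab2 <- efficiency_table(p2)
  expect_equal(tab2$delta[seq_along(base)], base, tolerance = 1e-6)
  expect_lt(tab2$delta[nrow(tab2)], 1 - 1e-6)
})

test_that("projections of inefficient units re-score as efficient", {
  for (seed in 1:8) {
    g <- generate_frontier_panel(frontier_design(
      n_efficient = 2 + seed %% 4, n_inefficient = 2, seed = 100 + seed))
    tab <- efficiency_table(g$panel, keep_solutions = TRUE)
    sols <- attr(tab, "solutions")
    for (sol in sols) {
      if (is_efficient(sol)) next
      proj <- project(sol)
      re <- score_record(proj, g$panel, relax = "never")
      expect_equal(re$status, "optimal")
      expect_equal(re$delta, 1, tolerance = 1e-6)
    }
  }
})

test_that("returns-to-scale labels agree with grid enumeration on a toy", {
  p <- toy_panel_ABC()
  expected <- c(A = "IRS", B = "CRS", C = "DRS")
  for (d in names(expected)) {
    r <- classify_rts(p, d)
    expect_equal(r$label, expected[[d]])
    bf <- brute_free_rts(p, d, lam_max = 2, step = 0.01)
    expect_equal(r$delta_free, bf$delta, tolerance = 1e-3)
    # the grid's near-optimal sum(lambda) range implies the same label
    bf_label <- if (bf$sum_range[2] < 1 - 1e-3) "IRS"
                else if (bf$sum_range[1] > 1 + 1e-3) "DRS" else "CRS"
    expect_equal(bf_label, expected[[d]])
  }
})

test_that("cluster benchmark returns-to-scale labels reproduce where the data allow", {
  hk <- hk_clusters_2013()
  expect_equal(classify_rts(hk$panel, "KEC")$label, "CRS")
  expect_equal(classify_rts(hk$panel, "NTWC")$label, "CRS")
  expect_equal(classify_rts(hk$panel, "HKEC")$label, "IRS")
  expect_equal(classify_rts(hk$panel, "KCC")$label, "DRS")
  expect_equal(classify_rts(hk$panel, "NTEC")$label, "DRS")
})

test_that("intensity-set kinds order the scores as supersets", {
  # FREE relaxes every other intensity set, so its optimum is the smallest
  hk <- hk_clusters_2013()
  for (d in c("HKEC", "KCC")) {
    d_crs <- solve_gsbup(hk$panel, d, gamma = "CRS")$delta
    d_free <- solve_gsbup(hk$panel, d, gamma = "FREE")$delta
    d_irs <- solve_gsbup(hk$panel, d, gamma = "IRS")$delta
    d_drs <- solve_gsbup(hk$panel, d, gamma = "DRS")$delta
    expect_lte(d_free, min(d_irs, d_drs, d_crs) + 1e-9)
    expect_lte(min(d_irs, d_drs), d_crs + 1e-6)
  }
})
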