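fake_fit <- function(a, b, asymptotic = TRUE) {
  structure(list(cell_id = NA_character_, a = a, b = b,
                 asymptote = if (asymptotic) a / b else NA_real_,
                 sse = 0, r2 = 1, n_iter = 1, converged = TRUE,
                 asymptotic = asymptotic), class = "clench_fit")
}

test_that("the sufficiency ratio is observed over asymptote", {
  expect_equal(sufficiency_ratio(35, fake_fit(5, 0.1)), 0.70)
  expect_equal(sufficiency_ratio(50, fake_fit(5, 0.1)), 1.0)
  expect_true(is.na(sufficiency_ratio(35, fake_fit(5, 0.1, asymptotic = FALSE))))
  set.seed(14)
  for (i in 1:25) {
    a <- runif(1, 1, 30); b <- runif(1, 0.01, 1); S <- sample(1:200, 1)
    # algebraic oracle: S/(a/b) = S*b/a
    expect_equal(sufficiency_ratio(S, fake_fit(a, b)), S * b / a,
                 tolerance = 1e-12)
  }
})

test_that("threshold classification is boundary-inclusive and monotone", {
  cl <- classify_sufficiency(0.70)
  expect_equal(unname(cl), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(classify_sufficiency(1.0)))
  expect_false(any(classify_sufficiency(0.0)))
  set.seed(3)
  for (r in runif(50, 0, 1.2)) {
    v <- classify_sufficiency(r)
    expect_true(all(diff(as.integer(v)) <= 0))  # sufficient at t => at t' < t
  }
})

test_that("the effort formula satisfies its closed-form identity", {
  expect_equal(effort_required(fake_fit(5, 0.1), 0.7), 70 / 3, tolerance = 1e-12)
  expect_equal(effort_required(fake_fit(5, 0.1), 0.5), 1 / 0.1)
  expect_error(effort_required(fake_fit(5, 0.1), 1), "between 0 and 1")
  set.seed(6)
  for (i in 1:50) {
    a <- runif(1, 0.5, 40); b <- runif(1, 0.001, 2); q <- runif(1, 0.05, 0.95)
    nq <- effort_required(fake_fit(a, b), q)
    expect_gt(nq, 0)
    expect_equal(clench(nq, a, b), q * a / b, tolerance = 1e-10)
  }
})

make_results <- function(ratios, low_veg = rep(FALSE, length(ratios)),
                         excluded = rep(FALSE, length(ratios))) {
  d <- data.frame(cell_id = sprintf("1_%d_0", seq_along(ratios)),
                  resolution = 1, ratio = ratios,
                  excluded_few_plots = excluded, low_vegetation = low_veg,
                  stringsAsFactors = FALSE)
  for (q in c(0.60, 0.65, 0.70, 0.75, 0.80))
    d[[sprintf("sufficient_q%02d", round(100 * q))]] <- ratios >= q
  d
}

test_that("threshold summary counts both reporting modes", {
  s <- summarize_sufficiency(make_results(rep(0.72, 10)))
  at <- function(q, m) s[s$threshold == q & s$mode == m, ]
  expect_equal(at(0.70, "excluding")$n_sufficient, 10)
  expect_equal(at(0.70, "including")$n_sufficient, 10)
  expect_equal(at(0.75, "excluding")$n_sufficient, 0)
  expect_equal(at(0.70, "excluding")$pct_sufficient, 100)

  # one low-vegetation grid with a poor ratio is excused in including mode
  s2 <- summarize_sufficiency(make_results(c(rep(0.72, 9), 0.4),
                                           low_veg = c(rep(FALSE, 9), TRUE)))
  a60 <- s2[s2$threshold == 0.60, ]
  expect_equal(a60$n_sufficient[a60$mode == "including"] -
                 a60$n_sufficient[a60$mode == "excluding"], 1)
})

test_that("few-plot grids leave the denominators and mixed resolutions error", {
  s <- summarize_sufficiency(make_results(c(0.9, 0.9, 0.1),
                                          excluded = c(FALSE, FALSE, TRUE)))
  expect_true(all(s$n_total == 2))
  bad <- make_results(c(0.9, 0.9))
  bad$resolution <- c(1, 2)
  expect_error(summarize_sufficiency(bad), "single fishnet resolution")
})

test_that("summary counts are monotone across thresholds on random cohorts", {
  set.seed(44)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    res <- make_results(runif(n, 0.3, 1.1),
                        low_veg = runif(n) < 0.15)
    s <- summarize_sufficiency(res)
    for (m in c("excluding", "including")) {
      counts <- s$n_sufficient[s$mode == m][order(s$threshold[s$mode == m])]
      expect_true(all(diff(counts) <= 0))
    }
    inc <- s$n_sufficient[s$mode == "including"]
    exc <- s$n_sufficient[s$mode == "excluding"]
    expect_true(all(inc >= exc))
  }
})

test_that("sufficiency classification tracks the true completeness", {
  # unbiased survey at moderate-to-high effort: the q=0.70 call from the
  # Clench ratio agrees with the true-ratio call in >= 80% of cells
  L <- simulate_landscape(small_lconf(seed = 3))
  S <- simulate_survey(L, small_sconf(seed = 4, quadrats = 50, bias = 0))
  q <- aggregate_quadrats(S$records)
  cells <- L$cells[, c("cell_id", "resolution", "lon_min", "lat_min",
                       "lon_max", "lat_max")]
  res <- assess_sufficiency(assign_quadrats(q, cells), veg = L$veg_table,
                            n_perm = 50, global_seed = 5)
  res <- merge(res, S$truth, by = "cell_id")
  ok <- res$asymptotic %in% TRUE
  agree <- (res$ratio[ok] >= 0.70) == (res$S_obs[ok] / res$S_true[ok] >= 0.70)
  expect_gte(mean(agree), 0.80)
})
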