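pair_count_auc <- function(w1, w2) {
  s <- 0
  for (a in w1) for (b in w2) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(w1) * length(w2))
}

test_that("choice binarization uses the 0.5 rule with tie exclusion", {
  expect_equal(binarize_saccade_choice(c(0.9, 0.1, 0.5, NA)),
               c(1L, 2L, NA_integer_, NA_integer_))
})

test_that("ROC sweep equals pairwise dominance counting", {
  expect_equal(choice_probability(c(4, 5, 6, 1, 2, 3),
                                  c(1, 1, 1, 2, 2, 2))$auc, 1)
  expect_equal(choice_probability(c(1, 2, 3, 1, 2, 3),
                                  c(1, 1, 1, 2, 2, 2))$auc, 0.5)
  r <- choice_probability(c(1, 3, 2, 4), c(1, 1, 2, 2))
  expect_equal(r$auc, 0.25)
  expect_equal(choice_probability(c(1, 3, 2, 4), c(2, 2, 1, 1))$auc, 0.75)
  expect_true(all(diff(r$hit_rate) >= 0) && all(diff(r$false_alarm) >= 0))

  withr::with_seed(61, {
    for (i in 1:30) {
      n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
      w1 <- sample(1:10, n1, replace = TRUE) + stats::rnorm(n1, 0, 0.01)
      w2 <- sample(1:10, n2, replace = TRUE)
      auc <- choice_probability(c(w1, w2), rep(c(1, 2), c(n1, n2)))$auc
      expect_equal(auc, pair_count_auc(w1, w2), tolerance = 1e-12)
      # invariance under a strictly monotone transform
      f <- function(x) exp(0.3 * x) - 5
      expect_equal(choice_probability(f(c(w1, w2)),
                                      rep(c(1, 2), c(n1, n2)))$auc, auc,
                   tolerance = 1e-12)
      # relabeling the classes reflects the auc
      expect_equal(choice_probability(c(w1, w2), rep(c(2, 1), c(n1, n2)))$auc,
                   1 - auc, tolerance = 1e-12)
    }
  })
  expect_error(choice_probability(1:3, c(1, 1, 1)), "non-empty")
})

test_that("bootstrap CP intervals are deterministic and cover the truth", {
  w <- c(10, 11, 12, 1, 2, 3); lab <- rep(c(1, 2), each = 3)
  b <- bootstrap_cp_ci(w, lab, B = 100, seed = 2)
  expect_equal(b$ci_low, 1); expect_equal(b$ci_high, 1)

  wn <- withr::with_seed(3, stats::rnorm(60))
  labn <- rep(c(1, 2), 30)
  b1 <- bootstrap_cp_ci(wn, labn, B = 200, seed = 4)
  b2 <- bootstrap_cp_ci(wn, labn, B = 200, seed = 4)
  expect_identical(b1$aucs, b2$aucs)

  # unit-separated normals: analytic auc = pnorm(1/sqrt(2))
  target <- stats::pnorm(1 / sqrt(2))
  hits <- withr::with_seed(5, {
    vapply(1:100, function(i) {
      x <- stats::rnorm(200, 1); y <- stats::rnorm(200, 0)
      ci <- bootstrap_cp_ci(c(x, y), rep(c(1, 2), each = 200), B = 500,
                            seed = i)
      ci$ci_low <= target && target <= ci$ci_high
    }, logical(1))
  })
  expect_gte(sum(hits), 90)

  # CI width shrinks with sample size
  widths <- withr::with_seed(6, {
    vapply(c(50, 200, 800), function(n) {
      x <- stats::rnorm(n, 1); y <- stats::rnorm(n)
      ci <- bootstrap_cp_ci(c(x, y), rep(c(1, 2), each = n), B = 300, seed = n)
      ci$ci_high - ci$ci_low
    }, numeric(1))
  })
  expect_true(all(diff(widths) < 0))
})

test_that("epoch comparisons behave under nulls and constructed effects", {
  a <- withr::with_seed(7, stats::rnorm(100, 2, 0.5))
  r <- compare_pre_post(a, a + 3.2)
  expect_lt(r$p, 1e-6)
  expect_equal(r$mean2 - r$mean1, 3.2, tolerance = 1e-12)

  # zero-variance groups are flagged degenerate, not tested
  rd <- compare_pre_post(rep(1, 10), rep(3, 10))
  expect_true(rd$degenerate)
  expect_true(is.na(rd$p))

  # null calibration: p-values uniform across replicates
  ps <- withr::with_seed(8, {
    vapply(1:200, function(i) {
      compare_pre_post(stats::rnorm(200), stats::rnorm(200))$p
    }, numeric(1))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  expect_error(compare_pre_post(1, 1:5), "n >= 2")
})

test_that("time binning reduces to overall means and suppresses small bins", {
  m <- tibble::tibble(pre_time = rep(110, 10), post_time = rep(130, 10),
                      pre_proj = 1:10, post_proj = 11:20)
  b <- binned_time_comparison(m, bin_width_ms = 50)
  expect_equal(nrow(b), 2)
  expect_equal(b$mean[b$epoch == "pre"], mean(1:10))
  expect_equal(b$mean[b$epoch == "post"], mean(11:20))
  expect_equal(unique(b$bin_center), 125)

  expect_equal(nrow(binned_time_comparison(m[1:3, ], min_per_bin = 5)), 0)
  expect_equal(nrow(binned_time_comparison(m[0, ])), 0)
})

test_that("matched/mismatched KS test respects subgroup rules and nulls", {
  withr::with_seed(9, {
    n <- 240
    sacc <- rep(c(1L, 2L), each = n / 2)
    prec <- ifelse(stats::runif(n) < 0.5, sacc, 3L - sacc)
    post <- stats::rnorm(n, 5)
    r <- matched_mismatch_test(post, sacc, prec, min_n = 30)
    expect_false(any(r$skipped))
    expect_true(all(r$p > 0 & r$p <= 1))

    # constructed shift is detected
    post2 <- post + ifelse(prec != sacc, 3, 0)
    r2 <- matched_mismatch_test(post2, sacc, prec, min_n = 30)
    expect_true(all(r2$p < 0.01))

    # a 29-trial subgroup is skipped
    sacc3 <- rep(1L, 60)
    prec3 <- rep(c(1L, 2L), c(31, 29))
    r3 <- matched_mismatch_test(stats::rnorm(60), sacc3, prec3, min_n = 30)
    expect_true(all(r3$skipped))

    # null calibration across replicates: the exact two-sample KS p-value is
    # discrete, so calibration is checked at its rejection rates rather than
    # by a continuous-uniformity test
    ps <- vapply(1:200, function(i) {
      suppressWarnings(stats::ks.test(stats::rnorm(60), stats::rnorm(60)))$p.value
    }, numeric(1))
    expect_lte(mean(ps < 0.05), 0.09)
    expect_gt(mean(ps < 0.5), 0.38)
    expect_lt(mean(ps < 0.5), 0.62)
  })
})

test_that("enhancement regression measures saccade-metric dependence", {
  dur <- c(18, 20, 22, 24, 26)
  r <- enhancement_vs_saccade_metric(2 * dur, dur)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)

  r2 <- enhancement_vs_saccade_metric(c(1, 2), c(3, 4))
  expect_true(r2$degenerate)

  expect_error(enhancement_vs_saccade_metric(1:5, rep(2, 5)), "zero variance")

  # independent increase: R^2 < 0.05 in nearly all replicates at n = 150
  small <- withr::with_seed(10, {
    vapply(1:40, function(i) {
      enhancement_vs_saccade_metric(stats::rnorm(150),
                                    stats::runif(150, 15, 30))$r_squared
    }, numeric(1))
  })
  expect_gte(mean(small < 0.05), 0.9)
})

test_that("time-resolved CP matches the headline post CP and tracks coupling", {
  conds <- list(fx_cond(1, 5, 0, 1), fx_cond(1, 5, 90, 1),
                fx_cond(2, 5, c(0, 90), 1))
  # pre-saccadic weights carry no choice information; coupling is post only
  p <- eye_model_params(pre_weight_modes = c(0.5, 0.5), pre_weight_sd = 0.05,
                        selection_coupling = 0.5)
  cfg <- run_config(conds, n_per_condition = 70, params = p, seed = 31,
                    fixed_latency = 190, cp_B = 0)
  rep2 <- run_two_target_analysis(cfg)

  # innermost post interval is the standard post window: identical auc
  tcp <- rep2$time_cp
  post25 <- tcp$auc[tcp$epoch == "post" & tcp$gap == 25]
  expect_equal(post25,
               rep2$table2$choice_probability[rep2$table2$epoch == "post"],
               tolerance = 1e-12)

  # without pre-saccadic coupling, pre intervals hover at chance
  pre_auc <- tcp$auc[tcp$epoch == "pre" & !tcp$skipped]
  expect_true(all(abs(pre_auc - 0.5) < 0.15))
  expect_true(all(tcp$auc[tcp$epoch == "post" & !tcp$skipped] > 0.9))

  # intervals inside the buffer are refused
  tcp10 <- time_resolved_cp(list(), tibble::tibble(trial_id = character(),
                                                   saccade_onset = numeric(),
                                                   saccade_offset = numeric(),
                                                   choice = integer()),
                            list(T1 = c(1, 0), T2 = c(0, 1)),
                            list(T1 = c(1, 0), T2 = c(0, 1)), gaps = 10)
  expect_true(all(tcp10$skipped))
  expect_match(tcp10$reason[1], "buffer")
})
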