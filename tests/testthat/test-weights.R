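test_that("weight solver is exact at anchors and matches a scan oracle", {
  T1 <- c(1, 0); T2 <- c(0, 1)
  expect_identical(solve_weight(T1, T2, T1), 1)
  expect_identical(solve_weight(T1, T2, T2), 0)
  expect_equal(solve_weight(T1, T2, c(1, 1) / sqrt(2)), 0.5)

  scan_oracle <- function(T1, T2, E) {
    ws <- seq(-1, 2, by = 1e-5)
    obj <- (ws * T1[1] + (1 - ws) * T2[1] - E[1])^2 +
      (ws * T1[2] + (1 - ws) * T2[2] - E[2])^2
    ws[which.min(obj)]
  }
  expect_equal(solve_weight(T1, T2, c(0.6, 0.8)),
               scan_oracle(T1, T2, c(0.6, 0.8)), tolerance = 1e-4)

  withr::with_seed(8, {
    for (i in 1:25) {
      # reference pairs at least 90 deg apart, as in the two-target pairings;
      # that keeps the least-squares weight inside the scanned range
      th <- stats::runif(1, 0, 2 * pi)
      sep <- stats::runif(1, pi / 2, pi)
      a <- c(cos(th), sin(th)); b <- c(cos(th + sep), sin(th + sep))
      e <- rand_unit()
      w <- solve_weight(a, b, e)
      expect_lt(abs(w - scan_oracle(a, b, e)), 1e-4)
      # swapping references maps w -> 1 - w
      expect_equal(solve_weight(b, a, e), 1 - w, tolerance = 1e-10)
    }
  })
  expect_error(solve_weight(T1, T1, c(1, 0)), "degenerate")
})

test_that("orthonormal references reduce the weight to a projection", {
  withr::with_seed(9, {
    for (i in 1:20) {
      a <- rand_unit()
      b <- c(-a[2], a[1])           # orthogonal unit vector
      e <- rand_unit()
      expect_equal(solve_weight(a, b, e), sum((e - b) * (a - b)) / 2,
                   tolerance = 1e-12)
    }
  })
})

test_that("saccade weights read the post-saccadic landing target", {
  mk <- function(t1, t2, pp) {
    tibble::tibble(tgt1_sx = t1[1], tgt1_sy = t1[2], tgt2_sx = t2[1],
                   tgt2_sy = t2[2], post_pos_x = pp[1], post_pos_y = pp[2])
  }
  # eye exactly on target 1's direction
  expect_equal(saccade_weights(mk(c(3, 0), c(0, 3), c(3.5, 0)))$w_saccade, 1)
  # landing on the bisector of symmetric targets
  expect_equal(saccade_weights(mk(c(3, 0), c(0, 3), c(2, 2)))$w_saccade, 0.5)
  # zero post-position is undefined
  expect_true(is.na(saccade_weights(mk(c(3, 0), c(0, 3), c(0, 0)))$w_saccade))

  # simulation: with 0.2 deg landing noise the weight follows the choice
  cond <- fx_cond(2, speed = 5, direction = c(0, 90), step = 1)
  ds <- generate_dataset(cond, 200, eye_model_params(selection_coupling = 1),
                         seed = 17)
  st <- fx_measures(ds)
  w <- saccade_weights(st$measures)
  truth <- ds$manifest$true_choice[match(w$trial_id, ds$manifest$trial_id)]
  agree <- (w$w_saccade > 0.5) == (truth == 1)
  expect_gte(mean(agree, na.rm = TRUE), 0.95)
})

test_that("reference vectors average single-target unit velocities", {
  m <- tibble::tibble(dir1 = c(90, 90), pre_vx = c(0, 0), pre_vy = c(2, 4))
  refs <- reference_pursuit_vectors(
    dplyr::bind_rows(m, tibble::tibble(dir1 = 0, pre_vx = 3, pre_vy = 0)),
    directions = c(90, 0), epoch = "pre")
  expect_equal(refs$T1, c(0, 1), tolerance = 1e-12)
  expect_equal(refs$T2, c(1, 0), tolerance = 1e-12)

  # two unit vectors at 80 and 100 deg average to 90 deg
  m2 <- tibble::tibble(
    dir1 = c(90, 90, 0),
    pre_vx = c(cos(80 * pi / 180), cos(100 * pi / 180), 1),
    pre_vy = c(sin(80 * pi / 180), sin(100 * pi / 180), 0))
  refs2 <- reference_pursuit_vectors(m2, c(90, 0), "pre")
  expect_equal(refs2$T1, c(0, 1), tolerance = 1e-12)

  expect_error(reference_pursuit_vectors(m2, c(90, 180), "pre"), "180")

  # simulated single-target set: reference within 3 deg of the motion
  # direction (80 trials per direction; per-trial unit vectors carry several
  # degrees of angular noise at the pre-saccadic speed)
  ds <- generate_dataset(list(fx_cond(1, 5, 0, 1), fx_cond(1, 5, 90, 1)),
                         80, eye_model_params(position_noise_sd = 0.05),
                         seed = 19)
  st <- fx_measures(ds)
  inc <- apply_inclusion_filters(st$measures, 190)
  refs3 <- reference_pursuit_vectors(inc$retained, c(0, 90), "pre")
  ang1 <- atan2(refs3$T1[2], refs3$T1[1]) * 180 / pi
  ang2 <- atan2(refs3$T2[2], refs3$T2[1]) * 180 / pi
  expect_lt(abs(ang1 - 0), 3)
  expect_lt(abs(ang2 - 90), 3)
})

test_that("pursuit weights recover anchors and the bimodal mixture", {
  refs <- list(T1 = c(1, 0), T2 = c(0, 1))
  m <- tibble::tibble(pre_vx = c(4, 2), pre_vy = c(0, 2),
                      post_vx = c(0, 1), post_vy = c(3, 1))
  w <- pursuit_weights(m, refs, refs)
  expect_equal(w$w_pre, c(1, 0.5), tolerance = 1e-12)
  expect_equal(w$w_post, c(0, 0.5), tolerance = 1e-12)

  # recovery: mixture modes land within 0.1 of the configured 0.2 / 0.8
  conds <- list(fx_cond(1, 5, 0, 1), fx_cond(1, 5, 90, 1),
                fx_cond(2, 5, c(0, 90), 1))
  ds <- generate_dataset(conds, 150,
                         eye_model_params(position_noise_sd = 0.05),
                         seed = 23)
  st <- fx_measures(ds)
  inc <- apply_inclusion_filters(st$measures, 190)
  singles <- inc$retained[inc$retained$n_targets == 1, ]
  twos <- inc$retained[inc$retained$n_targets == 2, ]
  refs_pre <- reference_pursuit_vectors(singles, c(0, 90), "pre")
  refs_post <- reference_pursuit_vectors(singles, c(0, 90), "post")
  w2 <- pursuit_weights(twos, refs_pre, refs_post)
  hi <- stats::median(w2$w_pre[w2$w_pre > 0.5], na.rm = TRUE)
  lo <- stats::median(w2$w_pre[w2$w_pre < 0.5], na.rm = TRUE)
  expect_lt(abs(hi - 0.8), 0.1)
  expect_lt(abs(lo - 0.2), 0.1)
})

test_that("weight regression matches the closed-form normal equations", {
  w <- tibble::tibble(w_saccade = c(0, 0.5, 1), w_pre = c(0, 0.5, 1))
  r <- fit_weight_relation(w, "pre")
  expect_equal(r$m, 1); expect_equal(r$c, 0); expect_equal(r$r_squared, 1)

  wc <- tibble::tibble(w_saccade = c(0, 0.5, 1), w_pre = c(0.4, 0.4, 0.4))
  rc <- fit_weight_relation(wc, "pre")
  expect_equal(rc$m, 0); expect_equal(rc$r_squared, 0)

  sim <- withr::with_seed(51, {
    x <- stats::runif(50)
    tibble::tibble(w_saccade = x,
                   w_post = 0.6 * x + 0.2 + stats::rnorm(50, 0, 0.15))
  })
  r2 <- fit_weight_relation(sim, "post")
  X <- cbind(1, sim$w_saccade)
  beta <- solve(t(X) %*% X, t(X) %*% sim$w_post)
  expect_equal(r2$m, beta[2], tolerance = 1e-9)
  expect_equal(r2$c, beta[1], tolerance = 1e-9)
  expect_lt(abs(r2$m - 0.6), 0.15)

  expect_error(fit_weight_relation(w[1:2, ], "pre"), "3 trials")
  expect_error(fit_weight_relation(
    tibble::tibble(w_saccade = rep(0.5, 5), w_pre = stats::runif(5)), "pre"),
    "zero variance")
})
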