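#' Build step-ramp target trajectories
#'
#' Targets sit at the fixation point until `motion_onset`, then jump by
#' `step_size` degrees along the motion direction (signed: negative steps are
#' opposite to motion, so the ramp re-crosses the fixation point
#' `|step_size| / speed` seconds later) and translate at constant speed.
#'
#' @param condition A [trial_condition()].
#' @param motion_onset Motion onset time in ms.
#' @param time Integer time base in ms (1 ms steps).
#'
#' @return A list with one `length(time) x 2` position matrix (deg) per target.
#' @export
make_target_trajectory <- function(condition, motion_onset, time) {
  stopifnot(inherits(condition, "trial_condition"))
  if (any(condition$speed <= 0)) {
    stop("invalid condition: non-positive target speed", call. = FALSE)
  }
  lapply(seq_len(condition$n_targets), function(k) {
    u <- direction_unit(condition$direction[k])
    s <- numeric(length(time))
    post <- time >= motion_onset
    s[post] <- condition$step_size[k] +
      condition$speed[k] * (time[post] - motion_onset) / 1000
    cbind(x = s * u[1], y = s * u[2])
  })
}

# minimum-jerk displacement fraction for normalized time in [0, 1]
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Simulate one step-ramp pursuit trial
#'
#' Generates a 1 kHz gaze trace under the piecewise-constant-gain pursuit
#' model of [eye_model_params()]: fixation, pursuit at `pre_gain` from the
#' latent latency, one catch-up saccade (minimum-jerk profile, duration from
#' the amplitude main-sequence) landing at the chosen target, then pursuit at
#' `post_gain`. Two-target trials blend target velocities by the latent
#' selection weights. Uses the current RNG state; seed via
#' [generate_dataset()] or [withr::local_seed()] for reproducibility.
#'
#' @param condition A [trial_condition()].
#' @param params An [eye_model_params()].
#' @param trial_id Identifier string.
#'
#' @return A `pursuit_trial` object: list with `trial_id`, `condition`, `time`
#'   (ms), `eye` (n x 2 deg), `target` (list of n x 2 deg matrices, the
#'   unselected target `NA` after its offset), `motion_onset`,
#'   `unselected_target_offset` and a `truth` block holding the latent saccade
#'   event, latency, gains, weights and choice.
#' @export
simulate_eye_trace <- function(condition, params, trial_id = "trial") {
  stopifnot(inherits(condition, "trial_condition"),
            inherits(params, "eye_model_params"))

  fix_dur <- condition$fixation_duration
  if (is.null(fix_dur)) fix_dur <- stats::runif(1, 500, 1000) + stats::runif(1, 200, 500)
  mot_dur <- condition$motion_duration
  if (is.null(mot_dur)) mot_dur <- stats::runif(1, 700, 800)
  motion_onset <- round(fix_dur)
  n_time <- motion_onset + round(mot_dur) + 1L
  time <- seq.int(0L, n_time - 1L)

  target <- make_target_trajectory(condition, motion_onset, time)
  v_t <- lapply(seq_len(condition$n_targets), function(k) {
    condition$speed[k] * direction_unit(condition$direction[k])
  })

  # latent selection weights and saccade choice
  if (condition$n_targets == 2L) {
    mode <- sample.int(2L, 1L)
    w_pre <- stats::rnorm(1, params$pre_weight_modes[mode], params$pre_weight_sd)
    pre_choice <- if (w_pre >= 0.5) 1L else 2L
    choice <- if (stats::runif(1) < params$selection_coupling) {
      pre_choice
    } else {
      3L - pre_choice
    }
    w_post <- stats::rnorm(1, if (choice == 1L) 1 else 0, params$post_weight_sd)
    v_pre <- params$pre_gain * (w_pre * v_t[[1]] + (1 - w_pre) * v_t[[2]])
    v_post <- params$post_gain * (w_post * v_t[[1]] + (1 - w_post) * v_t[[2]])
  } else {
    w_pre <- 1; w_post <- 1; pre_choice <- 1L; choice <- 1L
    v_pre <- params$pre_gain * v_t[[1]]
    v_post <- params$post_gain * v_t[[1]]
  }

  lat <- round(params$pursuit_latency_ms)
  pursuit_onset <- motion_onset + lat

  # saccade latency: redraw values at or below the pursuit latency
  flagged <- FALSE
  sac_lat <- NA_real_
  for (i in seq_len(100L)) {
    sac_lat <- stats::rnorm(1, params$saccade_latency_mean_ms,
                            params$saccade_latency_sd_ms)
    if (sac_lat > params$pursuit_latency_ms) break
    sac_lat <- NA_real_
  }
  if (is.na(sac_lat)) {
    flagged <- TRUE
    sac_lat <- params$pursuit_latency_ms + 1
  }
  sac_on <- motion_onset + round(sac_lat)
  sac_on <- min(sac_on, n_time - 2L)

  eye_on <- v_pre / 1000 * max(sac_on - pursuit_onset, 0)
  tgt_on <- target[[choice]][sac_on + 1L, ]
  amp0 <- sqrt(sum((tgt_on - eye_on)^2))
  dur <- max(1L, round(params$saccade_duration_floor_ms +
                         params$saccade_duration_per_deg * amp0))
  sac_off <- min(sac_on + dur, n_time - 1L)
  dur <- sac_off - sac_on

  landing <- target[[choice]][sac_off + 1L, ] +
    stats::rnorm(2, 0, params$landing_sd)
  disp <- landing - eye_on

  # piecewise noise-free trace
  eye <- matrix(0, n_time, 2L, dimnames = list(NULL, c("x", "y")))
  pre_idx <- time > pursuit_onset & time <= sac_on
  eye[pre_idx, ] <- outer(time[pre_idx] - pursuit_onset, v_pre / 1000)
  sac_idx <- time > sac_on & time <= sac_off
  frac <- min_jerk((time[sac_idx] - sac_on) / dur)
  eye[sac_idx, ] <- rep(eye_on, each = sum(sac_idx)) + outer(frac, c(1, 1)) *
    rep(disp, each = sum(sac_idx))
  post_idx <- time > sac_off
  eye[post_idx, ] <- rep(landing, each = sum(post_idx)) +
    outer(time[post_idx] - sac_off, v_post / 1000)

  if (params$position_noise_sd > 0) {
    eye <- eye + matrix(stats::rnorm(2L * n_time, 0, params$position_noise_sd),
                        n_time, 2L)
  }

  unsel_off <- NA_real_
  if (condition$n_targets == 2L) {
    unsel_off <- min(sac_off + round(stats::runif(1, 100, 300)), n_time - 1L)
    other <- 3L - choice
    target[[other]][time > unsel_off, ] <- NA_real_
  }

  truth <- list(
    saccade = tibble::tibble(
      onset = as.numeric(sac_on), offset = as.numeric(sac_off),
      amplitude = sqrt(sum(disp^2)), duration = as.numeric(dur)
    ),
    pursuit_latency_ms = params$pursuit_latency_ms,
    pre_gain = params$pre_gain, post_gain = params$post_gain,
    w_pre = w_pre, w_post = w_post,
    pre_choice = pre_choice, choice = choice,
    saccade_latency_ms = sac_lat, flagged = flagged
  )

  rec <- structure(
    list(
      trial_id = trial_id, condition = condition, time = time, eye = eye,
      target = target, motion_onset = motion_onset,
      unselected_target_offset = unsel_off, truth = truth
    ),
    class = "pursuit_trial"
  )
  if (params$artifact_enabled) {
    rec <- inject_tracker_artifact(rec, params$artifact_span_ms,
                                   params$artifact_magnitude_deg)
  }
  rec
}

#' @export
print.pursuit_trial <- function(x, ...) {
  cat(sprintf(
    "<pursuit_trial> %s: %d samples at 1 kHz, %d target(s), motion onset %d ms\n",
    x$trial_id, length(x$time), x$condition$n_targets, x$motion_onset
  ))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: saccade %g-%g ms, choice target %d\n",
                x$truth$saccade$onset, x$truth$saccade$offset, x$truth$choice))
  }
  invisible(x)
}

#' Inject a pupil-tracker edge artifact around each saccade
#'
#' Video-based pupil trackers can distort the recorded gaze near saccade
#' edges: the eye appears to pause or briefly reverse. This helper emulates
#' that distortion by subtracting a triangular-profile excursion along the
#' saccade direction over a `span_ms`-wide stretch centered on each saccade
#' onset and offset; samples outside those spans are untouched. The 25 ms
#' analysis buffer together with the 25 ms median filter keeps a default
#' 10 ms artifact out of the peri-saccadic velocity windows (the filter
#' rejects up to 12 contaminated samples per window); spans of 25 ms or more
#' would invade the windows directly and trigger a warning.
#'
#' @param record A `pursuit_trial` with at least one truth saccade.
#' @param span_ms Total width of the distorted span centered at each edge (ms).
#' @param magnitude_deg Peak excursion in degrees.
#' @return The distorted `pursuit_trial`.
#' @export
inject_tracker_artifact <- function(record, span_ms = 10, magnitude_deg = 0.3) {
  stopifnot(inherits(record, "pursuit_trial"))
  sac <- record$truth$saccade
  if (is.null(sac) || nrow(sac) == 0) {
    stop("record has no truth saccade to anchor the artifact", call. = FALSE)
  }
  if (span_ms >= 25) {
    warning("artifact span >= 25 ms would invade the peri-saccadic analysis windows")
  }
  for (i in seq_len(nrow(sac))) {
    u <- (record$eye[sac$offset[i] + 1L, ] - record$eye[sac$onset[i] + 1L, ])
    nu <- sqrt(sum(u^2))
    u <- if (nu > 0) u / nu else c(1, 0)
    half <- span_ms / 2
    for (edge in c(sac$onset[i], sac$offset[i])) {
      idx <- which(abs(record$time - edge) <= half)
      w <- 1 - abs(record$time[idx] - edge) / (half + 1)
      record$eye[idx, ] <- record$eye[idx, ] -
        magnitude_deg * outer(w, u)
    }
  }
  record
}

#' Generate a reproducible step-ramp dataset
#'
#' Simulates `n_per_condition` trials for each condition, interleaving
#' conditions round-robin as in interleaved experimental blocks, and returns
#' the trials with a manifest of conditions and latent truth summaries.
#'
#' @param conditions A [trial_condition()] or list of them.
#' @param n_per_condition Trials per condition (> 0).
#' @param params An [eye_model_params()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#'
#' @return A `pursuit_dataset`: list with `trials` (named list of
#'   `pursuit_trial`), `manifest` (tibble), `conditions`, `params`, `seed`.
#' @examples
#' ds <- generate_dataset(trial_condition(1, 5, 0, 1), 3,
#'                        eye_model_params(), seed = 1)
#' ds$manifest
#' @export
generate_dataset <- function(conditions, n_per_condition, params, seed) {
  if (inherits(conditions, "trial_condition")) conditions <- list(conditions)
  stopifnot(length(conditions) >= 1, n_per_condition > 0,
            inherits(params, "eye_model_params"))
  withr::local_seed(seed)

  cond_id <- sprintf("c%02d", seq_along(conditions))
  trials <- list()
  rows <- list()
  k <- 0L
  for (rep in seq_len(n_per_condition)) {
    for (ci in seq_along(conditions)) {
      k <- k + 1L
      cond <- conditions[[ci]]
      id <- sprintf("%s_t%05d", cond_id[ci], rep)
      tr <- simulate_eye_trace(cond, params, trial_id = id)
      trials[[id]] <- tr
      rows[[k]] <- tibble::tibble(
        trial_id = id, condition_id = cond_id[ci],
        n_targets = cond$n_targets,
        speed = cond$speed[1],
        dir1 = cond$direction[1],
        dir2 = if (cond$n_targets == 2L) cond$direction[2] else NA_real_,
        step1 = cond$step_size[1],
        step2 = if (cond$n_targets == 2L) cond$step_size[2] else NA_real_,
        motion_onset = tr$motion_onset,
        saccade_onset = tr$truth$saccade$onset,
        saccade_offset = tr$truth$saccade$offset,
        true_latency_ms = tr$truth$pursuit_latency_ms,
        true_w_pre = tr$truth$w_pre,
        true_pre_choice = tr$truth$pre_choice,
        true_choice = tr$truth$choice,
        flagged = tr$truth$flagged
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (anyDuplicated(manifest$trial_id)) {
    stop("duplicate trial_id in generated manifest", call. = FALSE)
  }
  structure(
    list(trials = trials, manifest = manifest, conditions = conditions,
         params = params, seed = seed),
    class = "pursuit_dataset"
  )
}

#' @export
print.pursuit_dataset <- function(x, ...) {
  cat(sprintf("<pursuit_dataset> %d trials, %d condition(s), seed %s\n",
              length(x$trials), length(x$conditions), format(x$seed)))
  print(dplyr::count(x$manifest, .data$condition_id, .data$n_targets))
  invisible(x)
}
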