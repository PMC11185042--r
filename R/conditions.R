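#' Define a step-ramp trial condition
#'
#' A condition describes the target kinematics of one step-ramp (Rashbass)
#' trial type: one or two targets that, after a fixation period, step by a
#' signed offset along (or against) their motion direction and then translate
#' at constant speed. Signs follow the usual convention: a positive step is in
#' the direction of upcoming motion, a negative step is opposite, so that a
#' negative step's ramp crosses the fixation point `|step|/speed` seconds
#' after motion onset.
#'
#' @param n_targets 1 or 2.
#' @param speed Target speed(s) in deg/s, recycled to `n_targets`.
#' @param direction Motion direction(s) in degrees counterclockwise
#'   (0 = rightward, 90 = upward); must be distinct for two targets.
#' @param step_size Signed step(s) in degrees along the motion direction.
#' @param fixation_duration Fixation period in ms before motion onset, or
#'   `NULL` to draw per trial as uniform 500-1000 ms plus a 200-500 ms grace
#'   period.
#' @param motion_duration Ramp duration in ms, or `NULL` to draw per trial
#'   uniformly from 700-800 ms.
#' @param sample_rate Sampling rate in Hz; fixed at 1000.
#'
#' @return A `trial_condition` object (list).
#' @examples
#' trial_condition(1, speed = 5, direction = 0, step_size = 1)
#' trial_condition(2, speed = 8, direction = c(180, 90), step_size = -1.6)
#' @export
trial_condition <- function(n_targets = 1, speed = 5, direction = 0,
                            step_size = 1, fixation_duration = NULL,
                            motion_duration = NULL, sample_rate = 1000) {
  n_targets <- as.integer(n_targets)
  if (!n_targets %in% c(1L, 2L)) {
    stop("`n_targets` must be 1 or 2", call. = FALSE)
  }
  speed <- rep_len(as.numeric(speed), n_targets)
  direction <- rep_len(as.numeric(direction), n_targets)
  step_size <- rep_len(as.numeric(step_size), n_targets)
  if (any(speed <= 0)) stop("target speed must be positive", call. = FALSE)
  if (n_targets == 2L && direction[1] == direction[2]) {
    stop("two-target conditions require distinct directions", call. = FALSE)
  }
  if (sample_rate != 1000) {
    stop("only 1 kHz sampling is supported", call. = FALSE)
  }
  if (!is.null(fixation_duration) && fixation_duration <= 0) {
    stop("`fixation_duration` must be positive", call. = FALSE)
  }
  if (!is.null(motion_duration) && motion_duration <= 0) {
    stop("`motion_duration` must be positive", call. = FALSE)
  }
  structure(
    list(
      n_targets = n_targets, speed = speed, direction = direction,
      step_size = step_size, fixation_duration = fixation_duration,
      motion_duration = motion_duration, sample_rate = 1000
    ),
    class = "trial_condition"
  )
}

#' @export
print.trial_condition <- function(x, ...) {
  cat(sprintf(
    "<trial_condition> %d target(s): speed %s deg/s, direction %s deg, step %s deg\n",
    x$n_targets, paste(x$speed, collapse = "/"),
    paste(x$direction, collapse = "/"), paste(x$step_size, collapse = "/")
  ))
  invisible(x)
}

#' Latent eye-model parameters for the step-ramp simulator
#'
#' Ground-truth parameters of the generative gaze model. Pursuit is modelled
#' as piecewise-constant-gain velocity matching: the eye is still during
#' fixation, tracks at `pre_gain` times the (blended) target velocity from
#' `pursuit_latency_ms` after motion onset, makes one catch-up saccade with a
#' minimum-jerk profile and amplitude-dependent duration, and thereafter
#' tracks at `post_gain` (post-saccadic enhancement requires
#' `pre_gain < post_gain`). For two-target trials the pre-saccadic velocity is
#' the weight-blended vector `w * v1 + (1 - w) * v2` with `w` drawn from a
#' bimodal Gaussian mixture; the saccade goes to the target favoured by that
#' weight with probability `selection_coupling`, and the post-saccadic weight
#' concentrates at the saccade choice with spread `post_weight_sd`.
#'
#' @param pursuit_latency_ms Latent pursuit latency in ms.
#' @param pre_gain,post_gain Pre-/post-saccadic pursuit gains (fractions of
#'   target speed); must satisfy `pre_gain < post_gain` unless
#'   `allow_equal_gains`.
#' @param saccade_latency_mean_ms,saccade_latency_sd_ms Gaussian saccade
#'   latency (ms from motion onset); draws at or below the pursuit latency are
#'   redrawn.
#' @param saccade_duration_floor_ms,saccade_duration_per_deg Saccade duration
#'   main-sequence: `floor + per_deg * amplitude` ms.
#' @param position_noise_sd White Gaussian position noise per channel (deg).
#' @param landing_sd Saccade landing error (deg, per channel).
#' @param selection_coupling Probability that the saccade choice equals the
#'   pre-saccadic pursuit choice (two-target trials).
#' @param pre_weight_modes,pre_weight_sd Means and common sd of the bimodal
#'   pre-saccadic weight mixture (equal mixing).
#' @param post_weight_sd Spread of the post-saccadic weight around the saccade
#'   choice (1 for target 1, 0 for target 2).
#' @param artifact_enabled Inject a pupil-tracker edge artifact around each
#'   saccade (see [inject_tracker_artifact()]).
#' @param artifact_span_ms,artifact_magnitude_deg Artifact extent and size.
#' @param allow_equal_gains Permit `pre_gain == post_gain` (null simulations).
#'
#' @return An `eye_model_params` object (list).
#' @export
eye_model_params <- function(pursuit_latency_ms = 190,
                             pre_gain = 0.4, post_gain = 0.8,
                             saccade_latency_mean_ms = 320,
                             saccade_latency_sd_ms = 60,
                             saccade_duration_floor_ms = 15,
                             saccade_duration_per_deg = 2.5,
                             position_noise_sd = 0.1,
                             landing_sd = 0.2,
                             selection_coupling = 0.7,
                             pre_weight_modes = c(0.2, 0.8),
                             pre_weight_sd = 0.1,
                             post_weight_sd = 0.1,
                             artifact_enabled = FALSE,
                             artifact_span_ms = 10,
                             artifact_magnitude_deg = 0.3,
                             allow_equal_gains = FALSE) {
  stopifnot(
    pursuit_latency_ms > 0, saccade_latency_mean_ms > 0,
    saccade_latency_sd_ms >= 0, saccade_duration_floor_ms > 0,
    saccade_duration_per_deg >= 0, position_noise_sd >= 0, landing_sd >= 0,
    length(pre_weight_modes) == 2, pre_weight_sd >= 0, post_weight_sd >= 0
  )
  if (selection_coupling < 0 || selection_coupling > 1) {
    stop("`selection_coupling` must lie in [0, 1]", call. = FALSE)
  }
  if (any(pre_weight_modes < 0) || any(pre_weight_modes > 1)) {
    stop("`pre_weight_modes` must lie in [0, 1]", call. = FALSE)
  }
  if (pre_gain >= post_gain && !allow_equal_gains) {
    stop("`pre_gain` must be below `post_gain` (post-saccadic enhancement); ",
         "set `allow_equal_gains = TRUE` for null simulations", call. = FALSE)
  }
  structure(
    list(
      pursuit_latency_ms = pursuit_latency_ms,
      pre_gain = pre_gain, post_gain = post_gain,
      saccade_latency_mean_ms = saccade_latency_mean_ms,
      saccade_latency_sd_ms = saccade_latency_sd_ms,
      saccade_duration_floor_ms = saccade_duration_floor_ms,
      saccade_duration_per_deg = saccade_duration_per_deg,
      position_noise_sd = position_noise_sd,
      landing_sd = landing_sd,
      selection_coupling = selection_coupling,
      pre_weight_modes = as.numeric(pre_weight_modes),
      pre_weight_sd = pre_weight_sd,
      post_weight_sd = post_weight_sd,
      artifact_enabled = isTRUE(artifact_enabled),
      artifact_span_ms = artifact_span_ms,
      artifact_magnitude_deg = artifact_magnitude_deg
    ),
    class = "eye_model_params"
  )
}

#' @export
print.eye_model_params <- function(x, ...) {
  cat(sprintf(
    paste0("<eye_model_params> latency %g ms, gains %g -> %g, saccade latency ",
           "%g +/- %g ms, noise sd %g deg\n"),
    x$pursuit_latency_ms, x$pre_gain, x$post_gain,
    x$saccade_latency_mean_ms, x$saccade_latency_sd_ms, x$position_noise_sd
  ))
  invisible(x)
}

# unit vector for a direction in degrees CCW (0 = rightward, 90 = upward)
direction_unit <- function(direction_deg) {
  th <- direction_deg * pi / 180
  c(cos(th), sin(th))
}
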