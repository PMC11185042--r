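# Shared fixtures: all synthetic, built in code at test time.

fx_cond <- function(n_targets = 1, speed = 5, direction = 0, step = 1,
                    fixation = 600, motion = 750) {
  trial_condition(n_targets, speed, direction, step,
                  fixation_duration = fixation, motion_duration = motion)
}

# deterministic saccade timing, no noise: windows are guaranteed clean
fx_clean_params <- function(pre_gain = 0.4, post_gain = 0.8, ...) {
  eye_model_params(pre_gain = pre_gain, post_gain = post_gain,
                   position_noise_sd = 0, landing_sd = 0,
                   saccade_latency_mean_ms = 350, saccade_latency_sd_ms = 0,
                   ...)
}

fx_trial <- function(cond, params, seed = 1, id = "trial") {
  withr::with_seed(seed, simulate_eye_trace(cond, params, trial_id = id))
}

# hand-built minimal trial from an eye matrix (for window/units tests)
fx_manual_trial <- function(eye, motion_onset, cond = fx_cond(),
                            id = "manual") {
  n <- nrow(eye)
  structure(
    list(trial_id = id, condition = cond, time = seq.int(0L, n - 1L),
         eye = eye, target = make_target_trajectory(cond, motion_onset,
                                                    seq.int(0L, n - 1L)),
         motion_onset = motion_onset, unselected_target_offset = NA_real_,
         truth = NULL),
    class = "pursuit_trial"
  )
}

fx_truth_events <- function(dataset) {
  tibble::tibble(trial_id = dataset$manifest$trial_id,
                 onset = dataset$manifest$saccade_onset,
                 offset = dataset$manifest$saccade_offset)
}

# measures for every trial of a dataset using truth saccades
fx_measures <- function(dataset, ...) {
  dataset_measures(dataset, run_config(events = "truth", ...))
}

rand_unit <- function() {
  th <- stats::runif(1, 0, 2 * pi)
  c(cos(th), sin(th))
}
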