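#' Estimate eye velocity from 1 kHz position traces
#'
#' Position is median filtered over 25 ms per channel, then differentiated by
#' two central differences whose spans correspond to 25 Hz and 50 Hz
#' differentiation (40 ms and 20 ms), and the two estimates are averaged
#' samplewise. The median filter suppresses impulsive tracker noise near
#' saccade edges while leaving smooth (locally monotone) traces untouched;
#' the dual-rate difference is a standard low-pass differentiator. Samples
#' whose filter support is incomplete are `NA` (differences) and flagged
#' invalid (full cascade support, 32 ms at each end).
#'
#' @param pos An `n x 2` position matrix in degrees, sampled at 1 ms steps.
#' @param sample_rate Sampling rate in Hz (must be 1000).
#' @param median_ms Median filter length in ms (odd).
#' @param diff_spans_ms Central-difference full spans in ms.
#'
#' @return A `velocity_trace`: list with `vel` (`n x 2`, deg/s), `valid`
#'   (logical, full filter support) and `provenance`.
#' @export
estimate_velocity <- function(pos, sample_rate = 1000, median_ms = 25,
                              diff_spans_ms = c(40, 20)) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 2, median_ms %% 2 == 1, all(diff_spans_ms %% 2 == 0))
  if (sample_rate != 1000) stop("only 1 kHz traces are supported", call. = FALSE)
  n <- nrow(pos)
  support <- (median_ms - 1) / 2 + max(diff_spans_ms) / 2
  if (n <= 2 * support) {
    stop("trace shorter than the filter support", call. = FALSE)
  }

  central_diff <- function(f, h) {
    v <- rep(NA_real_, n)
    v[(h + 1):(n - h)] <- (f[(2 * h + 1):n] - f[1:(n - 2 * h)]) / (2 * h) * 1000
    v
  }
  vel <- apply(pos, 2, function(x) {
    f <- stats::runmed(x, median_ms, endrule = "keep")
    ests <- vapply(diff_spans_ms / 2, function(h) central_diff(f, h), numeric(n))
    rowMeans(ests)
  })
  colnames(vel) <- c("x", "y")
  valid <- seq_len(n) > support & seq_len(n) <= n - support
  structure(
    list(vel = vel, valid = valid,
         provenance = list(median_ms = median_ms,
                           diff_spans_ms = diff_spans_ms,
                           sample_rate = sample_rate)),
    class = "velocity_trace"
  )
}

#' @rdname estimate_velocity
#' @param trial A `pursuit_trial`.
#' @param ... Passed to [estimate_velocity()].
#' @export
trial_velocity <- function(trial, ...) {
  stopifnot(inherits(trial, "pursuit_trial"))
  estimate_velocity(trial$eye, ...)
}

#' Detect saccades by a speed threshold
#'
#' Convenience detector for synthetic or exploratory use (curated analyses
#' should use externally marked or ground-truth events): maximal runs with
#' speed above `speed_threshold` lasting at least `min_duration_ms` become
#' events, and events separated by less than `merge_gap_ms` are merged.
#'
#' @param vel A `velocity_trace`.
#' @param speed_threshold Speed threshold in deg/s.
#' @param min_duration_ms Minimum event duration in ms.
#' @param merge_gap_ms Merge events separated by less than this gap.
#' @param pos Optional position matrix; when given, event edges are refined
#'   with a sharp 6 ms central difference of the median-filtered position
#'   (the 40/20 ms differentiation spans used for the pursuit analysis smear
#'   saccade edges by up to 20 ms), and event amplitudes are computed.
#'
#' @return A tibble of events: `onset`, `offset` (ms, trace-relative),
#'   `duration`, `peak_speed`, `amplitude` (deg, `NA` without `pos`).
#' @export
detect_saccades <- function(vel, speed_threshold = 20, min_duration_ms = 8,
                            merge_gap_ms = 10, pos = NULL) {
  stopifnot(inherits(vel, "velocity_trace"))
  speed <- sqrt(rowSums(vel$vel^2))
  # extend edge estimates so boundary NAs do not truncate events
  ok <- which(!is.na(speed))
  if (length(ok) == 0) return(empty_events())
  speed[seq_len(ok[1] - 1)] <- speed[ok[1]]
  n <- length(speed)
  speed[seq_len(n - ok[length(ok)]) + ok[length(ok)]] <- speed[ok[length(ok)]]

  above <- speed > speed_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- starts[r$values]
  off <- ends[r$values]
  if (length(on) == 0) return(empty_events())

  # merge runs separated by short gaps
  merged_on <- on[1]; merged_off <- off[1]
  for (i in seq_along(on)[-1]) {
    if (on[i] - merged_off[length(merged_off)] - 1 < merge_gap_ms) {
      merged_off[length(merged_off)] <- off[i]
    } else {
      merged_on <- c(merged_on, on[i]); merged_off <- c(merged_off, off[i])
    }
  }
  dur <- merged_off - merged_on
  keep <- dur >= min_duration_ms
  if (!any(keep)) return(empty_events())
  on <- merged_on[keep]; off <- merged_off[keep]
  amp <- rep(NA_real_, length(on))
  if (!is.null(pos)) {
    pos <- as.matrix(pos)
    med_ms <- vel$provenance$median_ms
    f <- apply(pos, 2, stats::runmed, k = med_ms, endrule = "keep")
    h <- 3L
    sharp <- rep(0, n)
    mid <- (h + 1):(n - h)
    sharp[mid] <- sqrt(rowSums((f[mid + h, , drop = FALSE] -
                                  f[mid - h, , drop = FALSE])^2)) / (2 * h) * 1000
    for (i in seq_along(on)) {
      lo <- max(on[i] - 5L, 1L); hi <- min(off[i] + 5L, n)
      inside <- lo:hi
      cross <- inside[sharp[inside] > speed_threshold]
      if (length(cross) > 0) {
        on[i] <- cross[1]; off[i] <- cross[length(cross)]
      }
    }
    amp <- sqrt(rowSums((pos[off, , drop = FALSE] - pos[on, , drop = FALSE])^2))
  }
  tibble::tibble(
    onset = as.numeric(on - 1), offset = as.numeric(off - 1),
    duration = as.numeric(off - on),
    peak_speed = vapply(seq_along(on),
                        function(i) max(speed[on[i]:off[i]]), numeric(1)),
    amplitude = amp
  )
}

empty_events <- function() {
  tibble::tibble(onset = numeric(), offset = numeric(), duration = numeric(),
                 peak_speed = numeric(), amplitude = numeric())
}

#' First saccade after motion onset
#'
#' The first saccade whose onset falls strictly after motion onset anchors
#' all peri-saccadic analysis. Events straddling motion onset (onset before,
#' offset after) are not selected.
#'
#' @param events Event tibble with `onset`/`offset` columns (ms).
#' @param motion_onset Motion onset time in ms.
#' @return A one-row tibble with `is_first_after_motion = TRUE`, or `NULL`
#'   when no event qualifies.
#' @export
first_saccade_after_motion <- function(events, motion_onset) {
  cand <- events[!is.na(events$onset) & events$onset > motion_onset, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  first <- cand[which.min(cand$onset), , drop = FALSE]
  first$is_first_after_motion <- TRUE
  first
}

#' Peri-saccadic window measures
#'
#' Computes the fixation, pre-saccadic and post-saccadic mean velocity
#' vectors and the post-saccadic mean eye position over the standard
#' windows: fixation = 30 ms ending at motion onset; pre = \[onset-54,
#' onset-25\] ms; post = \[offset+25, offset+54\] ms; post position =
#' \[offset+25, offset+34\] ms. The 25 ms stand-off keeps pupil-tracker edge
#' artifacts and filter transients out of every window. Projections are dot
#' products with the target-motion unit vector; measurement times are window
#' centers relative to motion onset. Windows that do not fit inside the
#' trace (or its full-support velocity region) invalidate the trial rather
#' than shrink.
#'
#' @param trial A `pursuit_trial`.
#' @param vel Its `velocity_trace`.
#' @param saccade One-row event (from truth, marking, or detection).
#' @param direction Projection direction in degrees; defaults to the
#'   condition's first target direction.
#' @param buffer_ms Stand-off from saccade edges (ms).
#' @param window_ms Velocity window length (ms).
#' @param pos_window_ms Post-saccadic position window length (ms).
#'
#' @return A one-row tibble of measures (velocity vectors, projections,
#'   speeds, post-saccadic position, window times, validity flag, and --
#'   for two-target trials -- target positions at saccade onset).
#' @export
peri_saccadic_measures <- function(trial, vel, saccade, direction = NULL,
                                   buffer_ms = 25, window_ms = 30,
                                   pos_window_ms = 10) {
  stopifnot(inherits(trial, "pursuit_trial"), inherits(vel, "velocity_trace"))
  if (is.null(direction)) direction <- trial$condition$direction[1]
  u <- direction_unit(direction)
  n <- length(trial$time)
  on <- saccade$onset[1]; off <- saccade$offset[1]
  mo <- trial$motion_onset

  win <- list(
    fix = c(mo - window_ms, mo - 1),
    pre = c(on - buffer_ms - window_ms + 1, on - buffer_ms),
    post = c(off + buffer_ms, off + buffer_ms + window_ms - 1),
    post_pos = c(off + buffer_ms, off + buffer_ms + pos_window_ms - 1)
  )
  support <- (vel$provenance$median_ms - 1) / 2 +
    max(vel$provenance$diff_spans_ms) / 2
  ok <- vapply(win, function(w) w[1] >= support && w[2] <= n - 1 - support,
               logical(1))
  valid <- all(ok)

  wmean <- function(w, m) {
    if (w[1] < 0 || w[2] > n - 1) return(c(NA_real_, NA_real_))
    colMeans(m[(w[1]:w[2]) + 1L, , drop = FALSE])
  }
  fix_v <- if (ok[["fix"]]) wmean(win$fix, vel$vel) else c(NA_real_, NA_real_)
  pre_v <- if (ok[["pre"]]) wmean(win$pre, vel$vel) else c(NA_real_, NA_real_)
  post_v <- if (ok[["post"]]) wmean(win$post, vel$vel) else c(NA_real_, NA_real_)
  post_p <- if (ok[["post_pos"]]) wmean(win$post_pos, trial$eye) else c(NA_real_, NA_real_)

  cond <- trial$condition
  fields <- list(
    trial_id = trial$trial_id,
    n_targets = cond$n_targets,
    speed = cond$speed[1],
    dir1 = cond$direction[1],
    dir2 = if (cond$n_targets == 2L) cond$direction[2] else NA_real_,
    motion_onset = as.numeric(mo),
    saccade_onset = as.numeric(on), saccade_offset = as.numeric(off),
    saccade_duration = as.numeric(off - on),
    saccade_amplitude = if ("amplitude" %in% names(saccade)) {
      as.numeric(saccade$amplitude[1])
    } else NA_real_,
    fix_vx = unname(fix_v[1]), fix_vy = unname(fix_v[2]),
    pre_vx = unname(pre_v[1]), pre_vy = unname(pre_v[2]),
    post_vx = unname(post_v[1]), post_vy = unname(post_v[2]),
    fix_proj = sum(fix_v * u), pre_proj = sum(pre_v * u),
    post_proj = sum(post_v * u),
    pre_speed = sqrt(sum(pre_v^2)), post_speed = sqrt(sum(post_v^2)),
    post_pos_x = unname(post_p[1]), post_pos_y = unname(post_p[2]),
    pre_time = mean(win$pre) - mo, post_time = mean(win$post) - mo,
    windows_valid = valid
  )
  if (cond$n_targets == 2L) {
    t1 <- trial$target[[1]][on + 1L, ]
    t2 <- trial$target[[2]][on + 1L, ]
    fields <- c(fields, list(tgt1_sx = unname(t1[1]), tgt1_sy = unname(t1[2]),
                             tgt2_sx = unname(t2[1]), tgt2_sy = unname(t2[2])))
  }
  tibble::new_tibble(fields, nrow = 1L)
}

#' Apply the peri-saccadic trial-inclusion rules
#'
#' A trial is retained iff its saccade latency exceeds the pursuit latency by
#' more than `margin_ms` (guaranteeing pursuit throughout the pre-saccadic
#' window), both the pre- and post-saccadic window-mean speeds exceed
#' `min_speed` (guarding the unit-vector normalization used by the weight
#' analysis), and all analysis windows fit inside the trace.
#'
#' @param measures Tibble from [peri_saccadic_measures()] rows.
#' @param pursuit_latency Scalar latency in ms, or a data frame with
#'   `condition_id` and `latency_ms` to be matched against a `condition_id`
#'   column in `measures`.
#' @param margin_ms Required saccade-latency margin above pursuit latency.
#' @param min_speed Minimum pre/post window-mean speed in deg/s.
#'
#' @return A list: `retained` (filtered measures), `flags` (measures plus
#'   per-rule pass flags) and `report` (one-row counts tibble).
#' @export
apply_inclusion_filters <- function(measures, pursuit_latency, margin_ms = 55,
                                    min_speed = 0.5) {
  if (is.data.frame(pursuit_latency)) {
    stopifnot(all(c("condition_id", "latency_ms") %in% names(pursuit_latency)),
              "condition_id" %in% names(measures))
    lat <- pursuit_latency$latency_ms[
      match(measures$condition_id, pursuit_latency$condition_id)]
  } else {
    lat <- rep_len(pursuit_latency, nrow(measures))
  }
  if (anyNA(lat)) stop("missing pursuit latency for some trials", call. = FALSE)

  flags <- measures
  flags$pass_latency <- (measures$saccade_onset - measures$motion_onset) >
    lat + margin_ms
  flags$pass_pre_amp <- !is.na(measures$pre_speed) & measures$pre_speed > min_speed
  flags$pass_post_amp <- !is.na(measures$post_speed) & measures$post_speed > min_speed
  flags$pass_windows <- measures$windows_valid
  flags$retained <- flags$pass_latency & flags$pass_pre_amp &
    flags$pass_post_amp & flags$pass_windows

  report <- tibble::tibble(
    n_input = nrow(measures),
    n_fail_latency = sum(!flags$pass_latency),
    n_fail_pre_amp = sum(!flags$pass_pre_amp),
    n_fail_post_amp = sum(!flags$pass_post_amp),
    n_fail_windows = sum(!flags$pass_windows),
    n_retained = sum(flags$retained)
  )
  list(retained = measures[flags$retained, , drop = FALSE],
       flags = flags, report = report)
}
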