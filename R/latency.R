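#' Select trials eligible for latency estimation
#'
#' Pursuit latency is estimated from trials whose initial response is
#' saccade-free: any trial with a saccade onset within `window_ms` of motion
#' onset is excluded.
#'
#' @param trials Named list of `pursuit_trial` objects.
#' @param events Tibble with `trial_id`, `onset` (ms) rows, e.g. the truth
#'   events or a detector/marking export; multiple rows per trial allowed.
#' @param window_ms Exclusion window after motion onset (ms).
#' @return The subset of `trials` without an early saccade.
#' @export
select_latency_trials <- function(trials, events, window_ms = 200) {
  keep <- vapply(trials, function(tr) {
    ev <- events[events$trial_id == tr$trial_id, , drop = FALSE]
    if (nrow(ev) == 0) return(TRUE)
    rel <- ev$onset - tr$motion_onset
    !any(rel > 0 & rel <= window_ms)
  }, logical(1))
  trials[keep]
}

#' Prepare a position trace for latency fitting
#'
#' Projects the raw eye position onto the motion direction over the first
#' `fit_window_ms` after motion onset (inclusive, so 201 samples by default),
#' smooths it with a length-5 median filter, and subtracts the mean of the
#' first `baseline_ms` after motion start.
#'
#' @param trial A `pursuit_trial` covering motion onset + `fit_window_ms`.
#' @param fit_window_ms Fit window length in ms.
#' @param baseline_ms Baseline period in ms.
#' @param filter_k Median filter length in samples (odd).
#' @return Numeric vector of length `fit_window_ms + 1` (deg), baseline-zeroed.
#' @export
prepare_trace <- function(trial, fit_window_ms = 200, baseline_ms = 50,
                          filter_k = 5) {
  stopifnot(inherits(trial, "pursuit_trial"))
  mo <- trial$motion_onset
  idx <- (mo:(mo + fit_window_ms)) + 1L
  if (max(idx) > length(trial$time)) {
    stop("trial too short for the latency fit window", call. = FALSE)
  }
  u <- direction_unit(trial$condition$direction[1])
  p <- trial$eye[idx, , drop = FALSE] %*% u
  p <- as.numeric(stats::runmed(as.numeric(p), filter_k, endrule = "keep"))
  p - mean(p[seq_len(baseline_ms)])
}

#' Threshold-linear fit of an averaged position trace
#'
#' Least-squares fit of `ep(t) = g * max(t - l, 0) + c` over `t = 0..200` ms:
#' the latency `l` is searched on a 1 ms grid with the conditional linear
#' least-squares solution for `(g, c)` at each candidate (the objective is
#' piecewise quadratic in `l`, so the grid brackets the global minimum),
#' then refined to sub-ms resolution by golden-section search in the
#' bracketing interval. Ties resolve to the smallest `l`.
#'
#' @param trace Numeric position trace (deg) sampled at 1 ms from motion
#'   onset; at least 201 samples used.
#' @param time Time base in ms (default `0:(length(trace)-1)`).
#' @return A `threshold_linear_fit`: list with `g` (deg/ms), `l` (ms), `c`
#'   (deg), `rss`, and `degenerate` (all-flat trace, `l` undefined).
#' @export
fit_threshold_linear <- function(trace, time = seq_along(trace) - 1) {
  stopifnot(length(trace) >= 201, length(time) == length(trace))
  if (stats::sd(trace) < 1e-12) {
    return(structure(list(g = 0, l = NA_real_, c = trace[1], rss = 0,
                          degenerate = TRUE),
                     class = "threshold_linear_fit"))
  }
  t_max <- max(time)

  fit_at <- function(l) {
    r <- pmax(time - l, 0)
    sr <- sum(r); srr <- sum(r * r); sry <- sum(r * trace)
    n <- length(trace); sy <- sum(trace)
    det <- n * srr - sr * sr
    if (det < 1e-12) {          # rectifier vanishes: intercept-only fit
      g <- 0; cc <- sy / n
    } else {
      g <- (n * sry - sr * sy) / det
      cc <- (sy - g * sr) / n
    }
    rss <- sum((trace - g * r - cc)^2)
    list(g = g, c = cc, rss = rss)
  }

  grid <- seq(0, t_max, by = 1)
  rss <- vapply(grid, function(l) fit_at(l)$rss, numeric(1))
  i <- which.min(rss)           # first minimum: ties resolve to smallest l
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(function(l) fit_at(l)$rss, c(lo, hi), tol = 1e-4)
  l_star <- if (opt$objective < rss[i]) opt$minimum else grid[i]
  best <- fit_at(l_star)
  structure(list(g = best$g, l = l_star, c = best$c, rss = best$rss,
                 degenerate = FALSE),
            class = "threshold_linear_fit")
}

#' @export
print.threshold_linear_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<threshold_linear_fit> degenerate (flat trace), latency undefined\n")
  } else {
    cat(sprintf(
      "<threshold_linear_fit> g = %.5f deg/ms, l = %.2f ms, c = %.4f deg (rss %.4g)\n",
      x$g, x$l, x$c, x$rss))
  }
  invisible(x)
}

#' Bootstrap pursuit latency from prepared traces
#'
#' Resamples the prepared traces with replacement `B` times; each replicate
#' averages the resampled traces pointwise and fits the threshold-linear
#' model. The summary latency is the arithmetic mean of the replicate
#' latencies.
#'
#' @param traces Matrix with one prepared trace per row (see
#'   [prepare_trace()]), or a list of equal-length traces.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed for the resampling.
#' @return A `latency_fit`: list with `latencies` (length `B`),
#'   `mean_latency`, `B`, `seed`, and `n_traces`.
#' @export
bootstrap_latency <- function(traces, B = 1000, seed = 1) {
  if (is.list(traces)) traces <- do.call(rbind, traces)
  traces <- as.matrix(traces)
  if (nrow(traces) < 2) stop("need at least 2 traces", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  withr::local_seed(seed)
  n <- nrow(traces)
  lat <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_threshold_linear(colMeans(traces[idx, , drop = FALSE]))$l
  }, numeric(1))
  structure(
    list(latencies = lat, mean_latency = mean(lat, na.rm = TRUE),
         B = B, seed = seed, n_traces = n),
    class = "latency_fit"
  )
}

#' @export
print.latency_fit <- function(x, ...) {
  q <- stats::quantile(x$latencies, c(0.025, 0.5, 0.975), na.rm = TRUE)
  cat(sprintf(
    "<latency_fit> mean latency %.1f ms (B = %d, n = %d traces; 2.5/50/97.5%%: %.1f/%.1f/%.1f ms)\n",
    x$mean_latency, x$B, x$n_traces, q[1], q[2], q[3]))
  invisible(x)
}

#' Estimate pursuit latency for a set of trials
#'
#' Convenience wrapper: drops trials with a saccade in the first 200 ms,
#' prepares each remaining trace, and runs the bootstrap.
#'
#' @inheritParams select_latency_trials
#' @inheritParams bootstrap_latency
#' @return A `latency_fit` (with `n_traces` trials used), or `NULL` when
#'   fewer than 2 eligible trials remain.
#' @export
estimate_pursuit_latency <- function(trials, events, B = 1000, seed = 1) {
  eligible <- select_latency_trials(trials, events)
  if (length(eligible) < 2) return(NULL)
  traces <- t(vapply(eligible, prepare_trace, numeric(201)))
  bootstrap_latency(traces, B = B, seed = seed)
}
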