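#' Binarize the saccade choice from saccade weights
#'
#' Choice is target 1 when `w_saccade > 0.5` and target 2 when `< 0.5`;
#' exact ties at 0.5 (and undefined weights) are excluded as `NA`.
#'
#' @param w_saccade Numeric vector of saccade weights.
#' @return Integer vector (1, 2 or `NA`).
#' @export
binarize_saccade_choice <- function(w_saccade) {
  out <- rep(NA_integer_, length(w_saccade))
  out[!is.na(w_saccade) & w_saccade > 0.5] <- 1L
  out[!is.na(w_saccade) & w_saccade < 0.5] <- 2L
  out
}

# rank-based AUC: P(X1 > X2) + 0.5 P(X1 = X2), identical to the ROC sweep
auc_rank <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  r <- rank(c(x1, x2))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC choice probability
#'
#' Separability of the pursuit-weight distributions conditioned on the
#' saccade choice: the criterion sweeps all unique weight values; at each
#' criterion the hit rate is the fraction of target-1 trials above it and the
#' false-alarm rate the fraction of target-2 trials above it. The area under
#' the resulting ROC curve (trapezoidal integration) equals the pairwise
#' dominance probability `P(w1 > w2) + 0.5 P(w1 = w2)`; 0.5 means no linkage
#' between pursuit and the saccade choice, 1 perfect prediction.
#'
#' @param weights Numeric per-trial weights.
#' @param labels Choice labels (1 or 2; `NA` dropped); target 1 is the
#'   "greater" class.
#' @return An `roc_result`: list with `criteria`, `hit_rate`, `false_alarm`,
#'   `auc`, and class sizes `n`.
#' @export
choice_probability <- function(weights, labels) {
  ok <- !is.na(weights) & !is.na(labels)
  w1 <- weights[ok & labels == 1]
  w2 <- weights[ok & labels == 2]
  if (length(w1) == 0 || length(w2) == 0) {
    stop("both choice classes must be non-empty", call. = FALSE)
  }
  crit <- c(Inf, sort(unique(c(w1, w2)), decreasing = TRUE), -Inf)
  hit <- vapply(crit, function(cr) mean(w1 > cr), numeric(1))
  fa <- vapply(crit, function(cr) mean(w2 > cr), numeric(1))
  auc <- sum(diff(fa) * (utils::head(hit, -1) + utils::tail(hit, -1)) / 2)
  structure(
    list(criteria = crit, hit_rate = hit, false_alarm = fa, auc = auc,
         n = c(n1 = length(w1), n2 = length(w2))),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> auc = %.3f (n1 = %d, n2 = %d)", x$auc,
              x$n["n1"], x$n["n2"]))
  if (!is.null(x$ci_low)) {
    cat(sprintf(", 95%% CI [%.3f, %.3f], B = %d", x$ci_low, x$ci_high, x$B))
  }
  cat("\n")
  invisible(x)
}

#' Bootstrap confidence interval for the choice probability
#'
#' Resamples trials (weight and label jointly) with replacement `B` times and
#' recomputes the AUC per replicate; the CI is the 2.5/97.5 percentile of the
#' replicate distribution. Replicates that lose a class are redrawn (bounded);
#' if redraws are exhausted the interval is flagged `widened`.
#'
#' @inheritParams choice_probability
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @param stratified Resample within each label class instead of pooled.
#' @return An `roc_result` with `ci_low`, `ci_high`, `aucs`, `B`, `seed`.
#' @export
bootstrap_cp_ci <- function(weights, labels, B = 1000, seed = 1,
                            stratified = FALSE) {
  ok <- !is.na(weights) & !is.na(labels)
  w <- weights[ok]; lab <- labels[ok]
  if (sum(lab == 1) < 2 || sum(lab == 2) < 2) {
    stop("need at least 2 trials per class", call. = FALSE)
  }
  res <- choice_probability(w, lab)
  withr::local_seed(seed)
  n <- length(w)
  i1 <- which(lab == 1); i2 <- which(lab == 2)
  widened <- FALSE
  aucs <- vapply(seq_len(B), function(b) {
    for (try in seq_len(100L)) {
      idx <- if (stratified) {
        c(sample(i1, length(i1), replace = TRUE),
          sample(i2, length(i2), replace = TRUE))
      } else {
        sample.int(n, n, replace = TRUE)
      }
      l <- lab[idx]
      if (any(l == 1) && any(l == 2)) {
        return(auc_rank(w[idx][l == 1], w[idx][l == 2]))
      }
    }
    widened <<- TRUE
    NA_real_
  }, numeric(1))
  ci <- stats::quantile(aucs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  res$aucs <- aucs; res$ci_low <- ci[1]; res$ci_high <- ci[2]
  res$B <- B; res$seed <- seed; res$widened <- widened
  res
}

#' Time-resolved choice probability around the saccade
#'
#' Recomputes pursuit weights from 30 ms velocity windows stepped away from
#' the saccade (window gaps measured from saccade onset for pre intervals and
#' from saccade offset for post intervals; the innermost gap of 25 ms
#' reproduces the standard pre/post windows) and reports the AUC against the
#' saccade choice per interval. Intervals that would intrude into the 25 ms
#' artifact buffer are skipped, as are intervals with fewer than
#' `min_per_class` trials in either class.
#'
#' @param vels Named list of `velocity_trace` objects (by trial id).
#' @param measures Tibble with `trial_id`, `saccade_onset`, `saccade_offset`
#'   and a `choice` column (1/2).
#' @param refs_pre,refs_post Epoch references from
#'   [reference_pursuit_vectors()].
#' @param gaps Window gaps from the saccade edge in ms.
#' @param window_ms Window length in ms.
#' @param buffer_ms Artifact buffer in ms.
#' @param min_per_class Minimum trials per class per interval.
#' @return Tibble with `epoch`, `gap`, `center_offset_ms` (signed, relative
#'   to the saccade edge), `n1`, `n2`, `auc`, `skipped`, `reason`.
#' @export
time_resolved_cp <- function(vels, measures, refs_pre, refs_post,
                             gaps = c(25, 55, 85), window_ms = 30,
                             buffer_ms = 25, min_per_class = 5) {
  rows <- list()
  for (epoch in c("pre", "post")) {
    refs <- if (epoch == "pre") refs_pre else refs_post
    for (gap in gaps) {
      if (gap < buffer_ms) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          epoch = epoch, gap = gap,
          center_offset_ms = NA_real_, n1 = NA_integer_, n2 = NA_integer_,
          auc = NA_real_, skipped = TRUE, reason = "inside artifact buffer")
        next
      }
      w <- rep(NA_real_, nrow(measures))
      for (i in seq_len(nrow(measures))) {
        vt <- vels[[measures$trial_id[i]]]
        win <- if (epoch == "pre") {
          c(measures$saccade_onset[i] - gap - window_ms + 1,
            measures$saccade_onset[i] - gap)
        } else {
          c(measures$saccade_offset[i] + gap,
            measures$saccade_offset[i] + gap + window_ms - 1)
        }
        nv <- nrow(vt$vel)
        sup <- (vt$provenance$median_ms - 1) / 2 +
          max(vt$provenance$diff_spans_ms) / 2
        if (win[1] < sup || win[2] > nv - 1 - sup) next
        E <- unit_vec(colMeans(vt$vel[(win[1]:win[2]) + 1L, , drop = FALSE]))
        if (anyNA(E)) next
        w[i] <- solve_weight(refs$T1, refs$T2, E)
      }
      ok <- !is.na(w) & !is.na(measures$choice)
      n1 <- sum(ok & measures$choice == 1)
      n2 <- sum(ok & measures$choice == 2)
      if (n1 < min_per_class || n2 < min_per_class) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          epoch = epoch, gap = gap, center_offset_ms = NA_real_,
          n1 = n1, n2 = n2, auc = NA_real_, skipped = TRUE,
          reason = "fewer than min_per_class trials in a class")
        next
      }
      auc <- auc_rank(w[ok & measures$choice == 1], w[ok & measures$choice == 2])
      center <- (gap + (window_ms - 1) / 2) * if (epoch == "pre") -1 else 1
      rows[[length(rows) + 1]] <- tibble::tibble(
        epoch = epoch, gap = gap, center_offset_ms = center,
        n1 = n1, n2 = n2, auc = auc, skipped = FALSE, reason = NA_character_)
    }
  }
  dplyr::bind_rows(rows)
}

#' Compare projected velocities between epochs
#'
#' Two-sample t test (Welch by default) between two sets of projected
#' velocities, e.g. pre- vs post-saccadic or fixation vs pre-saccadic.
#' Degenerate (essentially constant) inputs are flagged rather than tested.
#'
#' @param a,b Numeric vectors of projected velocities (deg/s).
#' @param labels Length-2 character vector naming the groups.
#' @param paired Use a paired t test (same trials in both epochs).
#' @return One-row tibble: group means and SEMs, `statistic`, `p`, `test`,
#'   `n1`, `n2`, `degenerate`.
#' @export
compare_pre_post <- function(a, b, labels = c("pre", "post"), paired = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group", call. = FALSE)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  res <- tryCatch(
    stats::t.test(a, b, paired = paired),
    error = function(e) NULL
  )
  tibble::tibble(
    group1 = labels[1], group2 = labels[2],
    mean1 = mean(a), sem1 = sem(a), mean2 = mean(b), sem2 = sem(b),
    statistic = if (is.null(res)) NA_real_ else unname(res$statistic),
    p = if (is.null(res)) NA_real_ else res$p.value,
    test = if (paired) "paired t" else "Welch t",
    n1 = length(a), n2 = length(b),
    degenerate = is.null(res)
  )
}

#' Pre/post velocity comparison binned by measurement time
#'
#' Bins the pre- and post-saccadic projected velocities by the center of the
#' measurement window relative to motion onset, separating the effect of the
#' saccade itself from the natural rise of pursuit with time. Bins with fewer
#' than `min_per_bin` entries are suppressed.
#'
#' @param measures Measures tibble with `pre_time`, `post_time`, `pre_proj`,
#'   `post_proj`.
#' @param bin_width_ms Bin width in ms.
#' @param min_per_bin Minimum entries per bin.
#' @return Tibble with `epoch`, `bin_center`, `n`, `mean`, `sem`.
#' @export
binned_time_comparison <- function(measures, bin_width_ms = 50, min_per_bin = 5) {
  if (nrow(measures) == 0) {
    return(tibble::tibble(epoch = character(), bin_center = numeric(),
                          n = integer(), mean = numeric(), sem = numeric()))
  }
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = "pre", time = measures$pre_time, v = measures$pre_proj),
    tibble::tibble(epoch = "post", time = measures$post_time, v = measures$post_proj)
  )
  long <- long[!is.na(long$v) & !is.na(long$time), , drop = FALSE]
  long$bin_center <- floor(long$time / bin_width_ms) * bin_width_ms +
    bin_width_ms / 2
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$epoch, .data$bin_center),
    n = dplyr::n(), mean = mean(.data$v),
    sem = stats::sd(.data$v) / sqrt(dplyr::n()), .groups = "drop"
  )
  out[out$n >= min_per_bin, , drop = FALSE]
}

#' Matched vs mismatched post-saccadic velocity test
#'
#' Within each saccade choice, splits trials by whether the pre-saccadic
#' pursuit choice (binarized from `w_pre` at 0.5) matched the saccade choice,
#' and compares the post-saccadic projected velocities of the two subgroups
#' with a two-sample KS test. A comparison is made only when both subgroups
#' have at least `min_n` trials.
#'
#' @param post_proj Post-saccadic projected velocity per trial (deg/s).
#' @param saccade_choice,pre_choice Integer choices (1/2) per trial.
#' @param min_n Minimum subgroup size.
#' @return Tibble with one row per saccade choice: subgroup sizes, KS
#'   `statistic`, `p`, `skipped`, `reason`.
#' @export
matched_mismatch_test <- function(post_proj, saccade_choice, pre_choice,
                                  min_n = 30) {
  rows <- lapply(c(1L, 2L), function(g) {
    sel <- !is.na(saccade_choice) & !is.na(pre_choice) & !is.na(post_proj) &
      saccade_choice == g
    matched <- post_proj[sel & pre_choice == g]
    mismatched <- post_proj[sel & pre_choice != g]
    if (length(matched) < min_n || length(mismatched) < min_n) {
      return(tibble::tibble(
        saccade_choice = g, n_matched = length(matched),
        n_mismatched = length(mismatched), statistic = NA_real_, p = NA_real_,
        skipped = TRUE, reason = sprintf("subgroup below %d trials", min_n)))
    }
    ks <- suppressWarnings(stats::ks.test(matched, mismatched))
    tibble::tibble(
      saccade_choice = g, n_matched = length(matched),
      n_mismatched = length(mismatched),
      statistic = unname(ks$statistic), p = ks$p.value,
      skipped = FALSE, reason = NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' Relate the post-saccadic velocity increase to saccade metrics
#'
#' OLS regression of the per-trial velocity increase (post minus pre
#' projection) on a saccade metric (duration or amplitude); the R-squared
#' quantifies whether the enhancement depends on the saccade's kinematics.
#'
#' @param increase Per-trial velocity increase (deg/s).
#' @param metric Saccade duration (ms) or amplitude (deg) per trial.
#' @return List with `r_squared`, `slope`, `intercept`, `p`, `n`,
#'   `degenerate` (fewer than 3 points gives a perfect, meaningless fit).
#' @export
enhancement_vs_saccade_metric <- function(increase, metric) {
  ok <- stats::complete.cases(increase, metric)
  increase <- increase[ok]; metric <- metric[ok]
  if (stats::sd(metric) < 1e-12) {
    stop("zero variance in the saccade metric: fit undefined", call. = FALSE)
  }
  fit <- stats::lm(increase ~ metric)
  s <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  list(
    r_squared = s$r.squared,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    p = if (nrow(s$coefficients) > 1 && ncol(s$coefficients) >= 4 &&
            length(increase) > 2) s$coefficients[2, 4] else NA_real_,
    n = length(increase),
    degenerate = length(increase) <= 2
  )
}
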