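#' Build a pipeline run configuration
#'
#' Collects every knob of the analysis pipeline with defaults equal to the
#' standard analysis values: 25 ms artifact buffer, 30 ms velocity windows,
#' 55 ms saccade-latency margin, 0.5 deg/s amplitude gate, 1000 bootstrap
#' replicates.
#'
#' @param conditions A [trial_condition()] or list of them (ignored when
#'   `dataset` or `input_dir` supplies the data).
#' @param n_per_condition Trials per condition for synthetic runs.
#' @param params An [eye_model_params()] for synthetic runs.
#' @param seed Global seed; fans out to per-stage substreams (simulation,
#'   latency bootstrap, choice-probability bootstrap).
#' @param dataset Optional in-memory `pursuit_dataset`.
#' @param input_dir Optional dataset directory (see [read_dataset()]).
#' @param events `"truth"` (simulator/marked events from the manifest) or
#'   `"detect"` (velocity-threshold detector).
#' @param buffer_ms,window_ms,margin_ms,min_speed Peri-saccadic window and
#'   inclusion settings.
#' @param latency_B,cp_B Bootstrap replicate counts (`cp_B = 0` skips the
#'   choice-probability CI).
#' @param fixed_latency Optional known pursuit latency in ms; skips the
#'   latency bootstrap.
#' @param bin_width_ms Bin width of the time-binned comparison.
#' @param gaps Window gaps for the time-resolved choice probability.
#' @param detector Detector settings (`speed_threshold`, `min_duration_ms`,
#'   `merge_gap_ms`).
#' @return A `run_config` (list).
#' @export
run_config <- function(conditions = NULL, n_per_condition = 100,
                       params = eye_model_params(), seed = 1,
                       dataset = NULL, input_dir = NULL,
                       events = c("truth", "detect"),
                       buffer_ms = 25, window_ms = 30, margin_ms = 55,
                       min_speed = 0.5, latency_B = 1000, cp_B = 1000,
                       fixed_latency = NULL, bin_width_ms = 50,
                       gaps = c(25, 55, 85),
                       detector = list(speed_threshold = 20,
                                       min_duration_ms = 8,
                                       merge_gap_ms = 10)) {
  if (inherits(conditions, "trial_condition")) conditions <- list(conditions)
  structure(
    list(conditions = conditions, n_per_condition = n_per_condition,
         params = params, seed = seed, dataset = dataset,
         input_dir = input_dir, events = match.arg(events),
         buffer_ms = buffer_ms, window_ms = window_ms, margin_ms = margin_ms,
         min_speed = min_speed, latency_B = latency_B, cp_B = cp_B,
         fixed_latency = fixed_latency, bin_width_ms = bin_width_ms,
         gaps = gaps, detector = detector),
    class = "run_config"
  )
}

stage_seeds <- function(seed) {
  s <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  list(sim = s[1], latency = s[2], cp = s[3])
}

resolve_dataset <- function(config) {
  if (!is.null(config$dataset)) return(config$dataset)
  if (!is.null(config$input_dir)) return(read_dataset(config$input_dir))
  if (is.null(config$conditions)) {
    stop("config supplies neither a dataset, an input directory, nor conditions",
         call. = FALSE)
  }
  generate_dataset(config$conditions, config$n_per_condition, config$params,
                   seed = stage_seeds(config$seed)$sim)
}

#' Compute per-trial velocities, first saccades and window measures
#'
#' The measurement stage shared by both analyses: estimates the velocity
#' trace of every trial, picks the first saccade after motion onset (from
#' the truth events or the convenience detector), and computes the
#' peri-saccadic window measures.
#'
#' @param dataset A `pursuit_dataset`.
#' @param config A [run_config()].
#' @return List: `measures` (tibble with `condition_id`), `vels` (named list
#'   of `velocity_trace`), `dropped` (trial ids without a usable saccade).
#' @export
dataset_measures <- function(dataset, config = run_config()) {
  rows <- list(); vels <- list(); dropped <- character()
  manifest <- dataset$manifest
  for (tr in dataset$trials) {
    vel <- trial_velocity(tr)
    sac <- if (config$events == "truth") {
      if (is.null(tr$truth)) {
        stop("events = 'truth' but trial has no truth block", call. = FALSE)
      }
      first_saccade_after_motion(tr$truth$saccade, tr$motion_onset)
    } else {
      first_saccade_after_motion(
        detect_saccades(vel,
                        speed_threshold = config$detector$speed_threshold,
                        min_duration_ms = config$detector$min_duration_ms,
                        merge_gap_ms = config$detector$merge_gap_ms,
                        pos = tr$eye),
        tr$motion_onset)
    }
    if (is.null(sac)) {
      dropped <- c(dropped, tr$trial_id)
      next
    }
    m <- peri_saccadic_measures(tr, vel, sac, buffer_ms = config$buffer_ms,
                                window_ms = config$window_ms)
    rows[[tr$trial_id]] <- m
    vels[[tr$trial_id]] <- vel
  }
  measures <- dplyr::bind_rows(rows)
  measures$condition_id <- manifest$condition_id[
    match(measures$trial_id, manifest$trial_id)]
  list(measures = measures, vels = vels, dropped = dropped)
}

latency_table <- function(dataset, config, condition_ids) {
  seeds <- stage_seeds(config$seed)
  if (!is.null(config$fixed_latency)) {
    return(tibble::tibble(condition_id = condition_ids,
                          latency_ms = config$fixed_latency,
                          n_traces = NA_integer_, B = 0L,
                          q025 = NA_real_, q500 = NA_real_, q975 = NA_real_))
  }
  rows <- lapply(seq_along(condition_ids), function(i) {
    cid <- condition_ids[i]
    ids <- dataset$manifest$trial_id[dataset$manifest$condition_id == cid]
    trials <- dataset$trials[ids]
    events <- tibble::tibble(
      trial_id = dataset$manifest$trial_id,
      onset = dataset$manifest$saccade_onset)
    fit <- estimate_pursuit_latency(trials, events, B = config$latency_B,
                                    seed = seeds$latency + i)
    if (is.null(fit)) {
      return(tibble::tibble(condition_id = cid, latency_ms = NA_real_,
                            n_traces = 0L, B = config$latency_B,
                            q025 = NA_real_, q500 = NA_real_, q975 = NA_real_))
    }
    q <- stats::quantile(fit$latencies, c(0.025, 0.5, 0.975), na.rm = TRUE)
    tibble::tibble(condition_id = cid, latency_ms = fit$mean_latency,
                   n_traces = fit$n_traces, B = fit$B,
                   q025 = q[1], q500 = q[2], q975 = q[3])
  })
  dplyr::bind_rows(rows)
}

#' Single-target post-saccadic enhancement analysis
#'
#' Runs the full single-target pipeline: pursuit latency per condition,
#' peri-saccadic measures, inclusion filters, the per-condition velocity
#' table (fixation / pre-saccadic / post-saccadic means with t tests), the
#' time-binned pre/post comparison, and the regressions of the velocity
#' increase on saccade duration and amplitude.
#'
#' @param config A [run_config()].
#' @return A `run_report` with elements `latency`, `inclusion`, `table1`,
#'   `binned`, `enhancement`, `dropped`, `config`.
#' @export
run_single_target_analysis <- function(config) {
  dataset <- resolve_dataset(config)
  manifest <- dataset$manifest
  single_ids <- unique(manifest$condition_id[manifest$n_targets == 1])
  if (length(single_ids) == 0) {
    stop("no single-target conditions in the dataset", call. = FALSE)
  }
  keep <- manifest$trial_id[manifest$condition_id %in% single_ids]
  sub <- dataset
  sub$trials <- dataset$trials[keep]
  sub$manifest <- manifest[manifest$trial_id %in% keep, ]

  lat <- latency_table(sub, config, single_ids)
  stage <- dataset_measures(sub, config)
  inc <- apply_inclusion_filters(
    stage$measures,
    lat[, c("condition_id", "latency_ms")],
    margin_ms = config$margin_ms, min_speed = config$min_speed)
  ret <- inc$retained

  per_cond <- lapply(split(ret, ret$condition_id), function(m) {
    if (nrow(m) < 2) {
      return(tibble::tibble(condition_id = m$condition_id[1], n = nrow(m)))
    }
    t_pp <- compare_pre_post(m$pre_proj, m$post_proj, c("pre", "post"))
    t_fp <- compare_pre_post(m$fix_proj, m$pre_proj, c("fixation", "pre"))
    tibble::tibble(
      condition_id = m$condition_id[1], n = nrow(m),
      direction = m$dir1[1], speed = m$speed[1],
      fix_mean = t_fp$mean1, fix_sem = t_fp$sem1,
      pre_mean = t_pp$mean1, pre_sem = t_pp$sem1,
      post_mean = t_pp$mean2, post_sem = t_pp$sem2,
      p_pre_post = t_pp$p, p_fix_pre = t_fp$p
    )
  })
  table1 <- dplyr::bind_rows(per_cond)

  binned <- dplyr::bind_rows(lapply(split(ret, ret$condition_id), function(m) {
    b <- binned_time_comparison(m, bin_width_ms = config$bin_width_ms)
    if (nrow(b)) b$condition_id <- m$condition_id[1]
    b
  }))

  enh <- dplyr::bind_rows(lapply(split(ret, ret$condition_id), function(m) {
    if (nrow(m) < 3) return(NULL)
    inc_v <- m$post_proj - m$pre_proj
    dplyr::bind_rows(lapply(c("duration", "amplitude"), function(metric) {
      x <- if (metric == "duration") m$saccade_duration else m$saccade_amplitude
      if (all(is.na(x)) || stats::sd(x, na.rm = TRUE) < 1e-12) return(NULL)
      r <- enhancement_vs_saccade_metric(inc_v, x)
      tibble::tibble(condition_id = m$condition_id[1], metric = metric,
                     r_squared = r$r_squared, slope = r$slope, p = r$p,
                     n = r$n)
    }))
  }))

  structure(
    list(kind = "single_target", latency = lat, inclusion = inc$report,
         inclusion_flags = inc$flags, table1 = table1, binned = binned,
         enhancement = enh, dropped = stage$dropped, config = config),
    class = "run_report"
  )
}

#' Two-target saccade-pursuit selection analysis
#'
#' Runs the full two-target pipeline: single-target reference vectors per
#' epoch, per-trial saccade and pursuit weights, the pursuit-vs-saccade
#' weight regressions, ROC choice probabilities with bootstrap CIs, the
#' time-resolved choice probability, and the matched/mismatched
#' post-saccadic velocity test. The dataset must contain single-target
#' conditions for both directions of the two-target pairing (they provide
#' the pursuit references).
#'
#' @param config A [run_config()].
#' @return A `run_report` with elements `table2`, `weights`, `refs`,
#'   `time_cp`, `matched`, `latency`, `inclusion`, `config`.
#' @export
run_two_target_analysis <- function(config) {
  dataset <- resolve_dataset(config)
  manifest <- dataset$manifest
  two_ids <- unique(manifest$condition_id[manifest$n_targets == 2])
  single_ids <- unique(manifest$condition_id[manifest$n_targets == 1])
  if (length(two_ids) == 0) {
    stop("no two-target conditions in the dataset", call. = FALSE)
  }
  cond_of <- function(cid) {
    dataset$conditions[[match(cid, sprintf("c%02d", seq_along(dataset$conditions)))]]
  }
  single_dirs <- vapply(single_ids, function(cid) cond_of(cid)$direction[1],
                        numeric(1))

  lat <- latency_table(
    within_dataset(dataset, manifest$condition_id %in% single_ids),
    config, single_ids)
  stage <- dataset_measures(dataset, config)

  # two-target trials inherit the mean latency of their two single-target partners
  lat_map <- lat$latency_ms
  names(lat_map) <- lat$condition_id
  lat_rows <- lapply(two_ids, function(cid) {
    dirs <- cond_of(cid)$direction
    partner <- single_ids[match(dirs, single_dirs)]
    if (anyNA(partner)) {
      stop(sprintf(
        "missing single-target condition for direction %s (needed by %s)",
        paste(dirs[is.na(partner)], collapse = ", "), cid), call. = FALSE)
    }
    tibble::tibble(condition_id = cid,
                   latency_ms = mean(lat_map[partner]))
  })
  lat_all <- dplyr::bind_rows(lat[, c("condition_id", "latency_ms")],
                              dplyr::bind_rows(lat_rows))

  inc <- apply_inclusion_filters(stage$measures, lat_all,
                                 margin_ms = config$margin_ms,
                                 min_speed = config$min_speed)
  ret <- inc$retained
  seeds <- stage_seeds(config$seed)

  out <- lapply(seq_along(two_ids), function(ti) {
    cid <- two_ids[ti]
    cond <- cond_of(cid)
    dirs <- cond$direction
    singles <- ret[ret$condition_id %in% single_ids & ret$dir1 %in% dirs, ]
    twos <- ret[ret$condition_id == cid, ]
    refs_pre <- reference_pursuit_vectors(singles, dirs, "pre")
    refs_post <- reference_pursuit_vectors(singles, dirs, "post")

    w <- saccade_weights(twos)
    w <- pursuit_weights(w, refs_pre, refs_post)
    w$choice <- binarize_saccade_choice(w$w_saccade)
    w$pre_choice <- binarize_saccade_choice(w$w_pre)
    # projection of the post-saccadic velocity onto the chosen target's motion
    w$post_proj_choice <- vapply(seq_len(nrow(w)), function(i) {
      if (is.na(w$choice[i])) return(NA_real_)
      u <- direction_unit(dirs[w$choice[i]])
      sum(c(w$post_vx[i], w$post_vy[i]) * u)
    }, numeric(1))

    rel_pre <- fit_weight_relation(w, "pre")
    rel_post <- fit_weight_relation(w, "post")
    cp <- lapply(c(pre = "w_pre", post = "w_post"), function(col) {
      if (config$cp_B > 0) {
        bootstrap_cp_ci(w[[col]], w$choice, B = config$cp_B,
                        seed = seeds$cp + ti)
      } else {
        choice_probability(w[[col]], w$choice)
      }
    })

    table2 <- tibble::tibble(
      condition_id = cid,
      directions = paste(dirs, collapse = "/"),
      n = nrow(w),
      epoch = c("pre", "post"),
      slope = c(rel_pre$m, rel_post$m),
      intercept = c(rel_pre$c, rel_post$c),
      choice_probability = c(cp$pre$auc, cp$post$auc),
      cp_ci_low = c(cp$pre$ci_low %||% NA_real_, cp$post$ci_low %||% NA_real_),
      cp_ci_high = c(cp$pre$ci_high %||% NA_real_, cp$post$ci_high %||% NA_real_),
      r_squared = c(rel_pre$r_squared, rel_post$r_squared)
    )
    tcp <- time_resolved_cp(stage$vels, w, refs_pre, refs_post,
                            gaps = config$gaps, window_ms = config$window_ms,
                            buffer_ms = config$buffer_ms)
    tcp$condition_id <- cid
    mm <- matched_mismatch_test(w$post_proj_choice, w$choice, w$pre_choice)
    mm$condition_id <- cid
    list(table2 = table2, weights = w, time_cp = tcp, matched = mm,
         refs = list(pre = refs_pre, post = refs_post))
  })
  names(out) <- two_ids

  structure(
    list(kind = "two_target",
         table2 = dplyr::bind_rows(lapply(out, `[[`, "table2")),
         weights = dplyr::bind_rows(lapply(out, `[[`, "weights")),
         time_cp = dplyr::bind_rows(lapply(out, `[[`, "time_cp")),
         matched = dplyr::bind_rows(lapply(out, `[[`, "matched")),
         refs = lapply(out, `[[`, "refs"),
         latency = lat, inclusion = inc$report, inclusion_flags = inc$flags,
         dropped = stage$dropped, config = config),
    class = "run_report"
  )
}

within_dataset <- function(dataset, keep_rows) {
  ids <- dataset$manifest$trial_id[keep_rows]
  dataset$trials <- dataset$trials[ids]
  dataset$manifest <- dataset$manifest[keep_rows, ]
  dataset
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s analysis\n", x$kind))
  cat("Inclusion:\n"); print(x$inclusion)
  if (x$kind == "single_target") {
    cat("Velocity table (deg/s, projections on motion direction):\n")
    print(x$table1)
  } else {
    cat("Weight relations and choice probabilities:\n")
    print(x$table2)
  }
  invisible(x)
}

#' Write a run report to CSV files and a text summary
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df)) {
      readr::write_csv(df, file.path(dir, name), progress = FALSE)
    }
  }
  wr(report$latency, "latency.csv")
  wr(report$inclusion, "inclusion.csv")
  wr(report$inclusion_flags, "measures.csv")
  if (report$kind == "two_target" && length(report$refs)) {
    refs_df <- dplyr::bind_rows(lapply(names(report$refs), function(cid) {
      dplyr::bind_rows(lapply(c("pre", "post"), function(ep) {
        r <- report$refs[[cid]][[ep]]
        tibble::tibble(condition_id = cid, epoch = ep,
                       T1_x = r$T1[1], T1_y = r$T1[2],
                       T2_x = r$T2[1], T2_y = r$T2[2],
                       n1 = r$n[1], n2 = r$n[2])
      }))
    }))
    wr(refs_df, "reference_vectors.csv")
  }
  if (report$kind == "single_target") {
    wr(report$table1, "velocity_table.csv")
    wr(report$binned, "binned_comparison.csv")
    wr(report$enhancement, "enhancement_vs_saccade.csv")
  } else {
    wr(report$table2, "weight_table.csv")
    wr(report$weights, "weights.csv")
    wr(report$time_cp, "time_resolved_cp.csv")
    wr(report$matched, "matched_mismatch.csv")
  }
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(dir)
}

#' Read a YAML run configuration
#'
#' Maps a YAML file with `conditions` (list of n_targets/speed/direction/
#' step_size blocks), `params` (see [eye_model_params()]) and any scalar
#' [run_config()] field onto a `run_config`.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  conditions <- lapply(y$conditions, function(cd) do.call(trial_condition, cd))
  params <- if (is.null(y$params)) eye_model_params() else {
    do.call(eye_model_params, y$params)
  }
  args <- y[setdiff(names(y), c("conditions", "params"))]
  args$conditions <- conditions
  args$params <- params
  if (!is.null(seed)) args$seed <- seed
  do.call(run_config, args)
}
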