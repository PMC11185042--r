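#' Write a dataset to plain-text files
#'
#' One CSV per trial (`time_ms, eye_x, eye_y, tgt1_x, tgt1_y, tgt2_x,
#' tgt2_y`; fields are empty after a target's offset), an events CSV
#' (`trial_id, saccade_onset_ms, saccade_offset_ms, source`), and a JSON
#' sidecar holding the manifest, conditions, model parameters and truth
#' blocks.
#'
#' @param dataset A `pursuit_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pursuit_dataset"))
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  for (tr in dataset$trials) {
    df <- tibble::tibble(
      time_ms = tr$time,
      eye_x = tr$eye[, 1], eye_y = tr$eye[, 2],
      tgt1_x = tr$target[[1]][, 1], tgt1_y = tr$target[[1]][, 2],
      tgt2_x = if (length(tr$target) > 1) tr$target[[2]][, 1] else NA_real_,
      tgt2_y = if (length(tr$target) > 1) tr$target[[2]][, 2] else NA_real_
    )
    readr::write_csv(df, file.path(dir, "trials", paste0(tr$trial_id, ".csv")),
                     na = "", progress = FALSE)
  }
  ev <- dplyr::bind_rows(lapply(dataset$trials, function(tr) {
    tibble::tibble(trial_id = tr$trial_id,
                   saccade_onset_ms = tr$truth$saccade$onset,
                   saccade_offset_ms = tr$truth$saccade$offset,
                   source = "truth")
  }))
  readr::write_csv(ev, file.path(dir, "events.csv"), progress = FALSE)

  side <- list(
    seed = dataset$seed,
    params = unclass(dataset$params),
    conditions = lapply(dataset$conditions, function(cd) {
      cd <- unclass(cd)
      cd$fixation_duration <- cd$fixation_duration %||% NA
      cd$motion_duration <- cd$motion_duration %||% NA
      cd
    }),
    manifest = dataset$manifest,
    truth = lapply(dataset$trials, function(tr) {
      tt <- tr$truth
      tt$saccade <- as.list(tt$saccade)
      tt$motion_onset <- tr$motion_onset
      tt$unselected_target_offset <- tr$unselected_target_offset
      tt
    })
  )
  jsonlite::write_json(side, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `pursuit_dataset`. Real-data exports in the same layout are
#'   read identically; they simply lack truth blocks.
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "dataset.json")
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  num_or_null <- function(x) {
    if (is.null(x) || is.na(x[1])) NULL else unlist(x)
  }
  conds <- lapply(raw$conditions, function(cd) {
    trial_condition(
      n_targets = cd$n_targets, speed = unlist(cd$speed),
      direction = unlist(cd$direction), step_size = unlist(cd$step_size),
      fixation_duration = num_or_null(cd$fixation_duration),
      motion_duration = num_or_null(cd$motion_duration)
    )
  })
  manifest <- tibble::as_tibble(side$manifest)
  cond_ids <- sprintf("c%02d", seq_along(conds))
  trials <- lapply(manifest$trial_id, function(id) {
    df <- readr::read_csv(file.path(dir, "trials", paste0(id, ".csv")),
                          show_col_types = FALSE, progress = FALSE)
    row <- manifest[manifest$trial_id == id, ]
    cond <- conds[[match(row$condition_id, cond_ids)]]
    target <- list(cbind(x = df$tgt1_x, y = df$tgt1_y))
    if (cond$n_targets == 2L) {
      target[[2]] <- cbind(x = df$tgt2_x, y = df$tgt2_y)
    }
    tt <- side$truth[[id]]
    truth <- NULL
    if (!is.null(tt)) {
      truth <- tt
      truth$saccade <- tibble::as_tibble(tt$saccade)
    }
    structure(
      list(trial_id = id, condition = cond, time = df$time_ms,
           eye = cbind(x = df$eye_x, y = df$eye_y), target = target,
           motion_onset = row$motion_onset,
           unselected_target_offset = tt$unselected_target_offset %||% NA_real_,
           truth = truth),
      class = "pursuit_trial"
    )
  })
  names(trials) <- manifest$trial_id
  structure(
    list(trials = trials, manifest = manifest, conditions = conds,
         params = do.call(eye_model_params,
                          c(side$params, list(allow_equal_gains = TRUE))),
         seed = side$seed),
    class = "pursuit_dataset"
  )
}

#' Read the events CSV of a dataset directory
#'
#' @param dir Dataset directory.
#' @return Tibble with `trial_id`, `onset`, `offset`, `source`.
#' @export
read_events <- function(dir) {
  ev <- readr::read_csv(file.path(dir, "events.csv"), show_col_types = FALSE,
                        progress = FALSE)
  tibble::tibble(trial_id = ev$trial_id, onset = ev$saccade_onset_ms,
                 offset = ev$saccade_offset_ms, source = ev$source)
}
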