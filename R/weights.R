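#' Solve the two-target selection-weight decomposition
#'
#' Solves `w T1 + (1 - w) T2 = E` for the scalar selection weight `w` in the
#' least-squares sense for unit 2-vectors: `w = ((E - T2) . (T1 - T2)) /
#' ||T1 - T2||^2`. `w = 1` means the eye movement is fully consistent with
#' target 1's reference, `w = 0` with target 2's; the raw value is returned
#' unclipped (it may fall outside \[0, 1\]).
#'
#' @param T1,T2 Unit reference 2-vectors (distinct).
#' @param E Unit eye 2-vector (position or velocity).
#' @return The scalar weight `w`.
#' @examples
#' solve_weight(c(1, 0), c(0, 1), c(1, 0))           # 1
#' solve_weight(c(1, 0), c(0, 1), c(1, 1) / sqrt(2)) # 0.5
#' @export
solve_weight <- function(T1, T2, E) {
  d <- T1 - T2
  nd2 <- sum(d^2)
  if (nd2 < 1e-12) {
    stop("degenerate references: T1 and T2 coincide", call. = FALSE)
  }
  sum((E - T2) * d) / nd2
}

unit_vec <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-6) return(c(NA_real_, NA_real_))
  v / nv
}

#' Per-trial saccade weights from post-saccadic eye position
#'
#' For each two-target trial, `T1`/`T2` are the unit vectors of the two
#' target positions at saccade onset and `E` is the unit vector of the mean
#' eye position in the 10 ms post-saccadic position window; the weight comes
#' from [solve_weight()]. Trials whose post-saccadic position norm is below
#' 1e-6 deg get `NA` (undefined weight).
#'
#' @param measures Tibble of two-target [peri_saccadic_measures()] rows
#'   (columns `tgt1_sx` ... `post_pos_y`).
#' @return `measures` with a `w_saccade` column appended.
#' @export
saccade_weights <- function(measures) {
  stopifnot(all(c("tgt1_sx", "tgt1_sy", "tgt2_sx", "tgt2_sy",
                  "post_pos_x", "post_pos_y") %in% names(measures)))
  measures$w_saccade <- vapply(seq_len(nrow(measures)), function(i) {
    T1 <- unit_vec(c(measures$tgt1_sx[i], measures$tgt1_sy[i]))
    T2 <- unit_vec(c(measures$tgt2_sx[i], measures$tgt2_sy[i]))
    E <- unit_vec(c(measures$post_pos_x[i], measures$post_pos_y[i]))
    if (anyNA(c(T1, T2, E))) return(NA_real_)
    solve_weight(T1, T2, E)
  }, numeric(1))
  measures
}

#' Reference pursuit vectors from single-target trials
#'
#' For each of the two directions of a two-target pairing, averages the
#' per-trial unit pursuit-velocity vectors (epoch-matched: pre-saccadic for
#' the `pre` reference, post-saccadic for `post`) of the corresponding
#' single-target trials, then renormalizes the mean to unit length.
#'
#' @param measures Tibble of single-target [peri_saccadic_measures()] rows,
#'   already inclusion-filtered.
#' @param directions Length-2 vector: the target-1 and target-2 motion
#'   directions (deg) of the pairing; target-1 identity is fixed by this
#'   order.
#' @param epoch `"pre"` or `"post"`.
#' @return A list with unit vectors `T1`, `T2`, `epoch` and per-target trial
#'   counts `n`.
#' @export
reference_pursuit_vectors <- function(measures, directions, epoch = c("pre", "post")) {
  epoch <- match.arg(epoch)
  vx <- measures[[paste0(epoch, "_vx")]]
  vy <- measures[[paste0(epoch, "_vy")]]
  refs <- lapply(directions, function(d) {
    sel <- which(measures$dir1 == d)
    if (length(sel) == 0) {
      stop(sprintf("no single-target trials for direction %g", d), call. = FALSE)
    }
    units <- t(vapply(sel, function(i) unit_vec(c(vx[i], vy[i])), numeric(2)))
    units <- units[stats::complete.cases(units), , drop = FALSE]
    list(v = unit_vec(colMeans(units)), n = nrow(units))
  })
  list(T1 = refs[[1]]$v, T2 = refs[[2]]$v, epoch = epoch,
       n = c(refs[[1]]$n, refs[[2]]$n))
}

#' Per-trial pursuit weights for both epochs
#'
#' `E` is the unit vector of the trial's pre- or post-saccadic window-mean
#' velocity; weights come from [solve_weight()] against the epoch's
#' single-target references. Run after the inclusion filters so the 0.5
#' deg/s amplitude gate protects the normalization.
#'
#' @param measures Tibble of two-target measures rows.
#' @param refs_pre,refs_post References from [reference_pursuit_vectors()].
#' @return `measures` with `w_pre` and `w_post` columns appended.
#' @export
pursuit_weights <- function(measures, refs_pre, refs_post) {
  wcol <- function(vx, vy, refs) {
    vapply(seq_along(vx), function(i) {
      E <- unit_vec(c(vx[i], vy[i]))
      if (anyNA(E)) return(NA_real_)
      solve_weight(refs$T1, refs$T2, E)
    }, numeric(1))
  }
  measures$w_pre <- wcol(measures$pre_vx, measures$pre_vy, refs_pre)
  measures$w_post <- wcol(measures$post_vx, measures$post_vy, refs_post)
  measures
}

#' Linear relation between pursuit and saccade weights
#'
#' Ordinary least-squares fit of the pursuit weight (`y`) on the saccade
#' weight (`x`): `y = m x + c`. Raw (unclipped) weights are used.
#'
#' @param weights Tibble with `w_saccade` and the epoch's pursuit weight
#'   column (`w_pre` or `w_post`).
#' @param epoch `"pre"` or `"post"`.
#' @return A `weight_relation`: list with `m`, `c`, `r_squared`, `epoch`, `n`.
#' @export
fit_weight_relation <- function(weights, epoch = c("pre", "post")) {
  epoch <- match.arg(epoch)
  y <- weights[[paste0("w_", epoch)]]
  x <- weights$w_saccade
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 trials with defined weights", call. = FALSE)
  if (stats::sd(x) < 1e-12) stop("zero variance in saccade weights: slope undefined", call. = FALSE)
  if (stats::sd(y) < 1e-12) {
    return(structure(list(m = 0, c = mean(y), r_squared = 0, epoch = epoch,
                          n = length(x)),
                     class = "weight_relation"))
  }
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are legitimate
  structure(
    list(m = unname(stats::coef(fit)[2]), c = unname(stats::coef(fit)[1]),
         r_squared = r2, epoch = epoch, n = length(x)),
    class = "weight_relation"
  )
}

#' @export
print.weight_relation <- function(x, ...) {
  cat(sprintf(
    "<weight_relation> %s-saccadic: slope %.3f, intercept %.3f, R^2 %.3f (n = %d)\n",
    x$epoch, x$m, x$c, x$r_squared, x$n))
  invisible(x)
}
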