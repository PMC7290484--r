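#' Four-cell stay probabilities
#'
#' The signature analysis of the two-step task: the probability of
#' repeating the previous trial's first-stage choice, tabulated by the
#' previous trial's outcome (win: points > 0; loss: points <= 0, the zero
#' "nothing" outcome counting as a loss by default) and transition type
#' (common/rare). Trial `t >= 2` is scorable iff trials `t-1` and `t` are
#' both completed (no timeout).
#'
#' @param data A `twostep_session`.
#' @param win_rule `"gt0"` (default): win iff previous points > 0;
#'   `"exclude_zero"`: zero-point outcomes are dropped from the table.
#' @return An object of class `stay_cells`: a data frame with rows
#'   `win_common`, `win_rare`, `loss_common`, `loss_rare` and columns
#'   `stay_prob` (NA when the cell is empty) and `n` (trial counts summing
#'   to the number of scorable trials).
#' @export
stay_probabilities <- function(data, win_rule = c("gt0", "exclude_zero")) {
  win_rule <- match.arg(win_rule)
  done <- completed_trials(data)
  if (!any(done)) stop("session contains no completed trials")
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 trials for stay probabilities")
  t_idx <- 2:n
  scorable <- done[t_idx] & done[t_idx - 1L]
  prev_pts <- data$points[t_idx - 1L]
  prev_trans <- data$transition[t_idx - 1L]
  stay <- data$s1_choice[t_idx] == data$s1_choice[t_idx - 1L]
  if (win_rule == "exclude_zero") scorable <- scorable & prev_pts != 0L
  win <- prev_pts > 0L

  cells <- data.frame(
    cell = c("win_common", "win_rare", "loss_common", "loss_rare"),
    stay_prob = NA_real_, n = 0L, stringsAsFactors = FALSE)
  sel <- list(
    win_common = win & prev_trans == "common",
    win_rare = win & prev_trans == "rare",
    loss_common = !win & prev_trans == "common",
    loss_rare = !win & prev_trans == "rare")
  for (i in seq_along(sel)) {
    idx <- scorable & sel[[i]]
    cells$n[i] <- sum(idx)
    if (cells$n[i] > 0L) cells$stay_prob[i] <- mean(stay[idx])
  }
  class(cells) <- c("stay_cells", "data.frame")
  cells
}

cell_value <- function(cells, name) {
  stopifnot(inherits(cells, "stay_cells"))
  cells$stay_prob[match(name, cells$cell)]
}

#' Model-free and model-based stay-probability scores
#'
#' `mf_score` is the main effect of the previous outcome on staying:
#' `(stay_win_common + stay_win_rare) - (stay_loss_common + stay_loss_rare)`.
#' `mb_score` is the outcome-by-transition interaction:
#' `(stay_win_common + stay_loss_rare) - (stay_win_rare + stay_loss_common)`.
#' Both lie in `[-2, 2]`; an undefined (empty) cell propagates as `NA`.
#'
#' @param cells A `stay_cells` table from [stay_probabilities()].
#' @return A scalar score.
#' @export
mf_score <- function(cells) {
  (cell_value(cells, "win_common") + cell_value(cells, "win_rare")) -
    (cell_value(cells, "loss_common") + cell_value(cells, "loss_rare"))
}

#' @rdname mf_score
#' @export
mb_score <- function(cells) {
  (cell_value(cells, "win_common") + cell_value(cells, "loss_rare")) -
    (cell_value(cells, "win_rare") + cell_value(cells, "loss_common"))
}

#' Final score of a session
#'
#' Sum of all collected points over completed trials, minus the timeout
#' penalty for each missed response.
#'
#' @param data A `twostep_session`.
#' @param config A [task_config()]; defaults to the one attached to `data`.
#' @return Integer total score.
#' @export
final_score <- function(data, config = NULL) {
  cfg <- session_config(data, config)
  done <- completed_trials(data)
  sum(data$points[done]) - cfg$timeout_penalty_points * sum(!done)
}

#' Full behavioral summary of one session
#'
#' @param data A `twostep_session`.
#' @param config A [task_config()]; defaults to the one attached to `data`.
#' @param rt_summary `"mean"` (default) or `"median"` over completed
#'   trials.
#' @return An object of class `score_set`: the four stay cells with
#'   counts, `mf_score`, `mb_score`, `final_score`, and `rt_stage1_ms` /
#'   `rt_stage2_ms`.
#' @export
score_session <- function(data, config = NULL,
                          rt_summary = c("mean", "median")) {
  rt_summary <- match.arg(rt_summary)
  cfg <- session_config(data, config)
  cells <- stay_probabilities(data)
  done <- completed_trials(data)
  rt_fun <- if (rt_summary == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) median(x, na.rm = TRUE)
  }
  out <- list(
    cells = cells,
    mf_score = mf_score(cells),
    mb_score = mb_score(cells),
    final_score = final_score(data, cfg),
    rt_stage1_ms = rt_fun(data$rt1_ms[done]),
    rt_stage2_ms = rt_fun(data$rt2_ms[done])
  )
  class(out) <- "score_set"
  out
}

#' @export
print.score_set <- function(x, ...) {
  cat("Session behavioral summary\n")
  cat(sprintf("  MF-score %.3f, MB-score %.3f, final score %d\n",
              x$mf_score, x$mb_score, x$final_score))
  cat(sprintf("  RTs: stage 1 %.0f ms, stage 2 %.0f ms\n",
              x$rt_stage1_ms, x$rt_stage2_ms))
  print(as.data.frame(x$cells), row.names = FALSE)
  invisible(x)
}

#' Score every subject-session of a cohort and write a CSV table
#'
#' @param sessions A list of `twostep_session` objects.
#' @param path Optional output CSV path.
#' @return A data frame with one row per session: subject, session label,
#'   the four stay cells, MF-score, MB-score, final score, and RT means.
#' @export
score_table <- function(sessions, path = NULL) {
  rows <- lapply(sessions, function(d) {
    s <- score_session(d)
    data.frame(
      subject_id = d$subject_id[1], session = d$session[1],
      stay_win_common = cell_value(s$cells, "win_common"),
      stay_win_rare = cell_value(s$cells, "win_rare"),
      stay_loss_common = cell_value(s$cells, "loss_common"),
      stay_loss_rare = cell_value(s$cells, "loss_rare"),
      mf_score = s$mf_score, mb_score = s$mb_score,
      final_score = s$final_score,
      rt_stage1_ms = s$rt_stage1_ms, rt_stage2_ms = s$rt_stage2_ms,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
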