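#' Write trial logs to CSV
#'
#' One row per trial with the columns `subject_id`, `session`, `block`,
#' `trial` (1-based within session), `s1_choice` (0/1), `transition`
#' (`common`/`rare`), `s2_state` (0/1), `s2_choice` (0/1), `points`,
#' `rt1_ms`, `rt2_ms`, `timeout`. UTF-8, comma-separated, header
#' mandatory. The format round-trips losslessly through [read_trials()].
#'
#' @param sessions A `twostep_session`, or a (named) list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(sessions, path) {
  if (inherits(sessions, "twostep_session")) sessions <- list(sessions)
  df <- do.call(rbind, lapply(sessions, as.data.frame))
  rownames(df) <- NULL
  write.csv(df[, trial_columns], path, row.names = FALSE)
  invisible(path)
}

trial_columns <- c("subject_id", "session", "block", "trial", "s1_choice",
                   "transition", "s2_state", "s2_choice", "points",
                   "rt1_ms", "rt2_ms", "timeout")

#' Read trial logs from CSV
#'
#' Strictly validates the dialect written by [write_trials()]: required
#' header, per-session 1-based contiguous trial numbering, completed
#' trials carrying both choices plus state and outcome, transition labels
#' consistent with the fixed option-to-common-state mapping, and points
#' inside the configured range. Violations are reported with file line
#' numbers. Unknown extra columns are preserved.
#'
#' @param path Input CSV path.
#' @param config A [task_config()] attached to each returned session.
#' @return A named list of `twostep_session` objects, keyed
#'   `subject_id.session`.
#' @export
read_trials <- function(path, config = task_config()) {
  validate_task_config(config)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_columns, names(df))
  if (length(missing_cols))
    stop("trial file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$timeout <- as.logical(df$timeout)
  lines <- seq_len(nrow(df)) + 1L  # header is line 1

  bad <- which(!df$timeout &
                 (is.na(df$s1_choice) | is.na(df$s2_choice) |
                    is.na(df$s2_state) | is.na(df$points)))
  if (length(bad))
    stop("completed trials with missing choice/state/outcome at line(s): ",
         paste(lines[bad], collapse = ", "))
  done <- !df$timeout
  bad <- which(done & !(df$s1_choice %in% 0:1 & df$s2_choice %in% 0:1 &
                          df$s2_state %in% 0:1))
  if (length(bad))
    stop("choice/state fields must be 0 or 1 at line(s): ",
         paste(lines[bad], collapse = ", "))
  bad <- which(done & !(df$transition %in% c("common", "rare")))
  if (length(bad))
    stop("transition must be 'common' or 'rare' at line(s): ",
         paste(lines[bad], collapse = ", "))
  expected <- ifelse(df$s2_state == df$s1_choice, "common", "rare")
  bad <- which(done & df$transition != expected)
  if (length(bad))
    stop("transition label inconsistent with the option-to-state mapping ",
         "at line(s): ", paste(lines[bad], collapse = ", "))
  bad <- which(done & (df$points < config$points_min |
                         df$points > config$points_max))
  if (length(bad))
    stop("points outside configured range at line(s): ",
         paste(lines[bad], collapse = ", "))

  key <- paste(df$subject_id, df$session, sep = ".")
  out <- lapply(split(df, key), function(chunk) {
    chunk <- chunk[order(chunk$trial), , drop = FALSE]
    if (!identical(as.integer(chunk$trial), seq_len(nrow(chunk))))
      stop("trial numbers must be 1-based and contiguous for ",
           chunk$subject_id[1], "/", chunk$session[1])
    rownames(chunk) <- NULL
    as_twostep_session(chunk, config)
  })
  out[unique(key)]
}

#' Load a run configuration from YAML or JSON
#'
#' The configuration drives [run_pipeline()]: task parameters, walk
#' selection settings, cohort design, fitting settings (priors, restarts),
#' the list of compared measures, and output paths. Every random stage's
#' seed derives from the mandatory top-level `seed`.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A validated configuration list.
#' @export
run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg A configuration list built in code.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$seed))
    stop("run config must set an explicit top-level seed")
  defaults <- list(
    task = list(),
    walk = list(source = "select", n_candidates = 20L,
                n_sims_per_candidate = 100L, path = NULL),
    cohort = list(n_subjects = 25L, session_effect = list()),
    fitting = list(n_restarts = 10L, priors = list()),
    stats = list(measures = c("mb_score", "mf_score", "final_score",
                              "rt_stage1_ms", "rt_stage2_ms", "omega",
                              "alpha", "beta", "lambda", "pi", "bic",
                              "optimal_choice_rate_stage1",
                              "optimal_choice_rate_stage2")),
    recovery = list(enabled = FALSE),
    input_trials = NULL,
    out_dir = NULL
  )
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      cfg[[k]] <- modifyList(defaults[[k]], as.list(cfg[[k]]))
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

pipeline_priors <- function(fitting) {
  if (length(fitting$priors) == 0L) return(prior_spec())
  do.call(prior_spec, fitting$priors)
}

#' Run the full analysis pipeline
#'
#' Executes the study's analysis chain end to end: obtain a reward walk
#' (selected, generated, or loaded), simulate a synthetic crossover cohort
#' (or ingest a trial-log CSV), compute behavioral scores, fit the hybrid
#' model per subject and session, run the paired sober-vs-hungover
#' comparisons with Bayes factors, correlate measures with the AUDIT-like
#' covariate when available, and optionally run a parameter-recovery
#' study. All stages derive their seeds from `config$seed`; two runs with
#' the same config are identical.
#'
#' @param config A configuration list from [run_config()] /
#'   [validate_run_config()].
#' @return A list: `walk_report`, `scores`, `fits`, `comparisons`,
#'   `correlations`, `recovery` (or `NULL`), and `summary` (character
#'   vector). When `config$out_dir` is set, CSV tables and a
#'   `summary.txt` are written there.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  seed <- config$seed
  task <- do.call(task_config, config$task)

  walk_report <- NULL
  if (!is.null(config$walk$path)) {
    walk <- read_reward_walk(config$walk$path, task)
  } else if (identical(config$walk$source, "generate")) {
    walk <- generate_reward_walk(task, seed = seed)
  } else {
    sel <- select_reward_walk(
      task, n_candidates = config$walk$n_candidates,
      n_sims_per_candidate = config$walk$n_sims_per_candidate,
      seed = seed)
    walk <- sel$walk
    walk_report <- sel$report
  }

  if (!is.null(config$input_trials)) {
    sessions <- read_trials(config$input_trials, task)
    cohort <- NULL
  } else {
    design_args <- config$cohort
    design_args$session_effect <- unlist(design_args$session_effect)
    if (is.null(design_args$session_effect))
      design_args$session_effect <- c(omega = 0)
    design_args$seed <- seed + 1L
    design <- do.call(cohort_design, design_args)
    cohort <- generate_cohort(design, task, walk)
    sessions <- cohort$sessions
  }

  scores <- score_table(sessions)
  priors <- pipeline_priors(config$fitting)
  fits <- vector("list", length(sessions))
  names(fits) <- names(sessions)
  for (k in seq_along(sessions)) {
    fits[[k]] <- fit_map(sessions[[k]], priors, task,
                         n_restarts = config$fitting$n_restarts,
                         seed = (seed + 13L * k) %% .Machine$integer.max)
  }
  fitf <- fits_to_frame(fits)

  wide <- merge(scores, fitf, by = c("subject_id", "session"))
  sob <- wide[wide$session == "sober", ]
  hun <- wide[wide$session == "hungover", ]
  hun <- hun[match(sob$subject_id, hun$subject_id), ]
  measures <- intersect(config$stats$measures, names(wide))
  comparisons <- lapply(measures, function(m) {
    paired_compare(sob[[m]], hun[[m]], measure = m)
  })
  names(comparisons) <- measures

  correlations <- NULL
  if (!is.null(cohort)) {
    audit <- cohort$subjects$audit[
      match(sob$subject_id, cohort$subjects$subject_id)]
    corr_measures <- intersect(
      c("mf_score", "mb_score", "final_score", "omega", "pi"), measures)
    correlations <- lapply(corr_measures, function(m) {
      correlate_with_covariate(sob[[m]], audit, label = m)
    })
    names(correlations) <- corr_measures
  }

  recovery <- NULL
  if (isTRUE(config$recovery$enabled) && !is.null(cohort)) {
    recovery <- recovery_study(cohort$design, task, walk, priors,
                               n_restarts = config$fitting$n_restarts,
                               seed = seed + 2L)
  }

  summary_lines <- c(
    sprintf("twostepr pipeline run (seed %d)", seed),
    sprintf("sessions analyzed: %d", length(sessions)),
    if (!is.null(walk_report))
      sprintf("walk selection: MB advantage %.1f points (candidate %d/%d)",
              walk_report$advantage, walk_report$selected_index,
              walk_report$n_candidates),
    "paired sober-vs-hungover comparisons:",
    vapply(comparisons, function(p) {
      sprintf("  %-28s t(%d) = %6.2f, p = %.3f, BF01 = %6.2f  [%s]",
              p$measure, p$dof, p$t_statistic, p$p_two_sided, p$bf01,
              p$evidence)
    }, character(1)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(scores, file.path(config$out_dir, "scores.csv"),
              row.names = FALSE)
    write.csv(fitf, file.path(config$out_dir, "fits.csv"),
              row.names = FALSE)
    comparison_table(comparisons,
                     file.path(config$out_dir, "comparisons.csv"))
    if (!is.null(correlations)) {
      ct <- do.call(rbind, lapply(correlations, function(x)
        data.frame(measure = x$measure, n = x$n, pearson_r = x$pearson_r,
                   pearson_p = x$pearson_p, kendall_tau = x$kendall_tau,
                   kendall_p = x$kendall_p, bf01 = x$bf01_correlation)))
      write.csv(ct, file.path(config$out_dir, "correlations.csv"),
                row.names = FALSE)
    }
    writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))
  }

  list(walk_report = walk_report, scores = scores, fits = fitf,
       comparisons = comparisons, correlations = correlations,
       recovery = recovery, summary = summary_lines)
}
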