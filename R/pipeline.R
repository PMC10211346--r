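#' Synthesize the baseline-corrected frame grid for a labeled cohort
#'
#' Runs, subject by subject (to bound memory): epoch synthesis, multitaper
#' beta power on response- and fixation-locked epochs, the fixed
#' HP-condition dB baseline, baseline correction and 200-ms frame
#' averaging; then concatenates subjects into one `frame_grid`. Subjects
#' without HP trials cannot be baselined and are skipped with a warning.
#'
#' @param labeled labeled trial table ([label_trials()]), usually restricted
#'   to subjects from [balanced_subjects()]
#' @param cfg a [run_config()]
#' @param keep_power also return the per-trial dB power grids (memory-heavy;
#'   default FALSE)
#' @return list: `frames` (a `frame_grid` over all subjects' analyzed
#'   trials), `baseline_db`, optionally `power` (list of per-subject
#'   `beta_power_grid`s)
#' @export
synthesize_power <- function(labeled, cfg, keep_power = FALSE) {
  layout <- make_layout(cfg$n_sensors)
  subjects <- unique(labeled$subject_id)
  frames_list <- list()
  rows_list <- list()
  subj_list <- list()
  base_list <- list()
  power_list <- list()
  for (s in subjects) {
    rows_s <- which(labeled$subject_id == s)
    lab_s <- labeled[rows_s, , drop = FALSE]
    if (!any(lab_s$analyzed & lab_s$choice_type == "HP")) {
      warning("subject ", s, " has no HP trials; skipped (no baseline)")
      next
    }
    seed_s <- .derive_seed(cfg$master_seed, 1000L + match(s, subjects))
    ep <- generate_epochs(lab_s, layout, cfg$templates, cfg$noise,
                          seed = seed_s, epoch_ms = cfg$epoch_ms,
                          baseline_epoch_ms = cfg$baseline_epoch_ms,
                          sfreq = cfg$sfreq)
    pw <- multitaper_band_power(ep$response, cfg$tfr)
    pw <- combine_pairs(pw) # identity at combined-sensor level
    bw <- multitaper_band_power(ep$baseline, cfg$tfr)
    bl <- hp_baseline(bw, rep(s, dim(bw$power)[1]))
    grid <- apply_baseline(pw, bl$baseline_db,
                           rep(s, dim(pw$power)[1]))
    fr <- frame_average(grid)
    frames_list[[length(frames_list) + 1L]] <- fr$values
    rows_list[[length(rows_list) + 1L]] <- rows_s[ep$response$trial_rows]
    subj_list[[length(subj_list) + 1L]] <- rep(s, dim(fr$values)[1])
    base_list[[as.character(s)]] <- bl$baseline_db
    if (keep_power) power_list[[as.character(s)]] <- grid
  }
  if (!length(frames_list)) stop("no subjects could be synthesized")
  vals <- do.call(abind3, frames_list)
  frames <- structure(list(values = vals,
                           centers_ms = seq(-800, 2400, by = 200),
                           width_ms = 200,
                           trial_rows = unlist(rows_list),
                           subject_ids = unlist(subj_list),
                           layout = layout),
                      class = "frame_grid")
  out <- list(frames = frames,
              baseline_db = do.call(rbind, base_list))
  if (keep_power) out$power <- power_list
  out
}

# bind arrays along dim 1 (trials); dims 2:3 must agree
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(x) dim(x)[1], integer(1)))
  out <- array(NA_real_, dim = c(n, d[2], d[3]))
  at <- 0L
  for (x in parts) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Run the complete pipeline on a synthetic cohort
#'
#' Behaviour simulation, trial labeling, balance-rule subject selection,
#' epoch synthesis and beta-band power, stage-one screening and stage-two
#' effect models, all driven from one configuration and one master seed.
#'
#' @param cfg a [run_config()]
#' @param out_dir optional directory; if given, the trial table, config,
#'   screening result and a Markdown run report are written there
#' @return list of class `pipeline_result`: `labeled`, `subjects_used`,
#'   `frames`, `screen`, `effects` (stage-two model list), `rt` (RT model),
#'   `config`
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  validate_config(cfg)
  cohort <- simulate_cohort(cfg$n_subjects, cfg$task, cfg$agent,
                            seed = .derive_seed(cfg$master_seed, 1L))
  labeled <- label_trials(cohort)
  keep <- balanced_subjects(labeled)
  if (!length(keep)) stop("no subject satisfies the 8-cell balance rule")
  lab_keep <- labeled[labeled$subject_id %in% keep, , drop = FALSE]
  syn <- synthesize_power(lab_keep, cfg)
  frames <- syn$frames
  trial_labels <- lab_keep[frames$trial_rows, , drop = FALSE]
  screen <- run_screen(frames, trial_labels, cfg$windows, cfg$q)

  effects <- list()
  cl <- screen$clusters
  if (length(cl$decision$erd)) {
    pooled_dec <- pool_cluster(frames, lab_keep, cl$decision$erd,
                               cl$decision$frames)
    effects$decision <- pooled_effect_model(pooled_dec, "choice")
    effects$decision_rt <- beta_rt_regression(pooled_dec)
    effects$decision_pooled <- pooled_dec
  }
  if (length(cl$early_feedback$erd)) {
    pooled_early <- pool_cluster(frames, lab_keep, cl$early_feedback$erd,
                                 cl$early_feedback$frames)
    effects$early_feedback <- pooled_effect_model(pooled_early,
                                                  "choice_feedback")
    effects$early_pooled <- pooled_early
  }
  if (length(cl$late_feedback$ers)) {
    pooled_late <- pool_cluster(frames, lab_keep, cl$late_feedback$ers,
                                cl$late_feedback$frames)
    effects$late_anterior <- pooled_effect_model(pooled_late,
                                                 "choice_feedback")
    effects$late_anterior_prev <- tryCatch(
      pooled_effect_model(pooled_late, "choice_feedback_prev"),
      error = function(e) e)
    effects$late_pooled <- pooled_late
  }
  rt <- rt_model(lab_keep)

  res <- structure(list(labeled = labeled, subjects_used = keep,
                        frames = frames, screen = screen, effects = effects,
                        rt = rt, config = cfg),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trial_table(labeled, file.path(out_dir, "trials.tsv"))
    write_config(cfg, file.path(out_dir, "config.json"))
    write_screen_result(screen, file.path(out_dir, "screen.json"))
    write_run_report(res, file.path(out_dir, "report.md"))
  }
  res
}

#' Write a Markdown run report
#'
#' Summarizes exclusions, per-condition trial counts, recovered clusters and
#' the headline stage-two statistics of a pipeline run.
#'
#' @param res a `pipeline_result`
#' @param path output file
#' @export
write_run_report <- function(res, path) {
  l <- res$labeled
  lines <- c("# betaxplore run report", "",
             sprintf("- subjects simulated: %d; retained by balance rule: %d",
                     length(unique(l$subject_id)), length(res$subjects_used)),
             sprintf("- trials generated: %d; analyzed: %d",
                     nrow(l), sum(l$analyzed)),
             "- exclusions:")
  tab <- table(l$exclusion_reason)
  for (r in names(tab))
    lines <- c(lines, sprintf("    - %s: %d", r, tab[[r]]))
  lines <- c(lines, "", "## Analyzed trials per choice type x feedback", "")
  an <- l[l$analyzed, ]
  ct <- table(an$choice_type, an$feedback)
  lines <- c(lines, paste("|  |", paste(colnames(ct), collapse = " | "), "|"),
             paste("|---|", paste(rep("---", ncol(ct)), collapse = " | "), "|"))
  for (i in rownames(ct))
    lines <- c(lines, paste("|", i, "|", paste(ct[i, ], collapse = " | "), "|"))
  lines <- c(lines, "", "## Screening clusters", "")
  for (w in names(res$screen$clusters)) {
    cl <- res$screen$clusters[[w]]
    lines <- c(lines, sprintf(
      "- %s (%s, %d..%d ms): %d sensors (ERD %d, ERS %d)", w, cl$effect,
      cl$window_ms[1], cl$window_ms[2], length(cl$sensors),
      length(cl$erd), length(cl$ers)))
  }
  if (!is.null(res$effects$decision_rt)) {
    r <- res$effects$decision_rt
    lines <- c(lines, "", sprintf(
      "## Decision beta ~ log RT: slope %.3f dB per log-RT unit (p = %.2g, R2 = %.2f)",
      r$slope, r$p, r$r2))
  }
  writeLines(lines, path)
  invisible(path)
}
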