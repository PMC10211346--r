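#' Pool a beta-power grid over a cluster and window
#'
#' Collapses frame-grid dB values across a cluster's sensors and the frames
#' of its window, yielding one value per analyzed trial, joined with the
#' trial's design factors and log-RT.
#'
#' @param frames a [frame_average()] result
#' @param labeled the labeled trial table the grid indexes into
#' @param sensors cluster sensor indices
#' @param window_frames frame indices of the window
#' @return data.frame: `subject_id`, `block`, `trial`, `choice_type`,
#'   `feedback`, `previous_feedback`, `log_rt`, `beta_db`
#' @export
pool_cluster <- function(frames, labeled, sensors, window_frames) {
  stopifnot(inherits(frames, "frame_grid"), length(sensors) >= 1,
            length(window_frames) >= 1)
  vals <- frames$values[, sensors, window_frames, drop = FALSE]
  pooled <- apply(vals, 1, mean)
  tr <- labeled[frames$trial_rows, , drop = FALSE]
  data.frame(subject_id = tr$subject_id, block = tr$block, trial = tr$trial,
             choice_type = tr$choice_type, feedback = tr$feedback,
             previous_feedback = tr$previous_feedback,
             log_rt = log(tr$rt_ms), beta_db = pooled,
             stringsAsFactors = FALSE)
}

# drop subjects with an empty cell in the given factor crossing
.drop_unbalanced <- function(data, factors) {
  tab <- table(data$subject_id,
               interaction(data[factors], drop = FALSE, lex.order = TRUE))
  ok <- rownames(tab)[apply(tab > 0, 1, all)]
  data[as.character(data$subject_id) %in% ok, , drop = FALSE]
}

#' Response-time mixed model
#'
#' `log RT ~ Choice type * Previous feedback + (1 | Subject)` on analyzed
#' trials with a defined previous feedback; subjects with an empty design
#' cell are dropped (the balance rule). Returns the omnibus tests and Tukey
#' HSD contrasts over the four choice types.
#'
#' @param labeled labeled trial table ([label_trials()])
#' @return list: `fit`, `anova`, `tukey` (choice-type pairs), `n_subjects`
#' @export
rt_model <- function(labeled) {
  d <- labeled[labeled$analyzed & labeled$previous_feedback != "none", ,
               drop = FALSE]
  d$log_rt <- log(d$rt_ms)
  d$choice_type <- factor(d$choice_type,
                          levels = c("HP", "pre-LP", "LP", "post-LP"))
  d$previous_feedback <- factor(d$previous_feedback,
                                levels = c("gain", "loss"))
  d <- .drop_unbalanced(d, c("choice_type", "previous_feedback"))
  if (!nrow(d)) stop("no subjects with a complete design")
  fit <- lmm_ri(log_rt ~ choice_type * previous_feedback, d, d$subject_id)
  list(fit = fit, anova = anova_lmm(fit),
       tukey = tukey_lmm(fit, "choice_type", d),
       n_subjects = length(unique(d$subject_id)))
}

#' Effect-level pooled mixed model with Tukey HSD contrasts
#'
#' Stage-two analysis of one screened effect on pooled per-trial beta power:
#' * `"choice"`: `beta ~ Choice type + (1|Subject)` (decision window);
#' * `"choice_feedback"`: `beta ~ Choice type * Feedback + (1|Subject)`
#'   (post-feedback windows), with Tukey families over choice types and over
#'   the eight Choice type x Feedback cells;
#' * `"choice_feedback_prev"`: the triple model
#'   `beta ~ Feedback * Previous feedback * Choice type + (1|Subject)`,
#'   restricted to HP and LP trials with defined previous feedback (the
#'   anterior-ERS follow-up).
#'
#' @param pooled data.frame from [pool_cluster()]
#' @param design one of `"choice"`, `"choice_feedback"`,
#'   `"choice_feedback_prev"`
#' @return list: `fit`, `anova`, `tukey` (list of contrast tables by
#'   family), `data`
#' @export
pooled_effect_model <- function(pooled,
                                design = c("choice", "choice_feedback",
                                           "choice_feedback_prev")) {
  design <- match.arg(design)
  d <- pooled
  if (design == "choice_feedback_prev") {
    d <- d[d$choice_type %in% c("HP", "LP") & d$previous_feedback != "none", ,
           drop = FALSE]
    d$choice_type <- factor(d$choice_type, levels = c("HP", "LP"))
    d$previous_feedback <- factor(d$previous_feedback,
                                  levels = c("gain", "loss"))
  } else {
    d$choice_type <- factor(d$choice_type,
                            levels = c("HP", "pre-LP", "LP", "post-LP"))
  }
  d$feedback <- factor(d$feedback, levels = c("gain", "loss"))
  fml <- switch(design,
                choice = beta_db ~ choice_type,
                choice_feedback = beta_db ~ choice_type * feedback,
                choice_feedback_prev =
                  beta_db ~ feedback * previous_feedback * choice_type)
  fac <- intersect(all.vars(fml)[-1],
                   c("choice_type", "feedback", "previous_feedback"))
  cells <- table(interaction(d[fac], drop = FALSE, lex.order = TRUE))
  if (any(cells == 0))
    stop("rank-deficient design; empty cell(s): ",
         paste(names(cells)[cells == 0], collapse = ", "))
  fit <- lmm_ri(fml, d, d$subject_id)
  tk <- list(choice_type = tukey_lmm(fit, "choice_type", d))
  if (design == "choice_feedback")
    tk$cells <- tukey_lmm(fit, c("choice_type", "feedback"), d)
  if (design == "choice_feedback_prev")
    tk$cells <- tukey_lmm(fit, c("choice_type", "feedback",
                                 "previous_feedback"), d)
  list(fit = fit, anova = anova_lmm(fit), tukey = tk, data = d)
}

#' Regression of pooled decision-window beta power on response time
#'
#' `beta ~ log RT * Choice type * Previous feedback + (1|Subject)` on trials
#' with a defined previous feedback. With sum-to-zero contrasts the log-RT
#' main coefficient is the across-condition average slope (dB per log-RT
#' unit); a negative slope means deeper beta suppression for slower
#' decisions. `r2` is the squared correlation between conditional fitted
#' values and the data.
#'
#' @param pooled data.frame from [pool_cluster()] (decision window)
#' @return list: `slope`, `se`, `t`, `p`, `r2`, `fit`
#' @export
beta_rt_regression <- function(pooled) {
  d <- pooled[pooled$previous_feedback != "none", , drop = FALSE]
  if (stats::sd(d$log_rt) < 1e-12) stop("degenerate regressor: constant RT")
  d$choice_type <- factor(d$choice_type,
                          levels = c("HP", "pre-LP", "LP", "post-LP"))
  d$previous_feedback <- factor(d$previous_feedback,
                                levels = c("gain", "loss"))
  fit <- lmm_ri(beta_db ~ log_rt * choice_type * previous_feedback, d,
                d$subject_id)
  i <- match("log_rt", names(fit$beta))
  slope <- fit$beta[i]
  se <- sqrt(fit$vcov[i, i])
  tv <- slope / se
  list(slope = unname(slope), se = unname(se), t = unname(tv),
       p = 2 * stats::pt(abs(tv), fit$ddf, lower.tail = FALSE),
       r2 = stats::cor(fit$fitted, fit$y)^2, fit = fit)
}

#' Cross-trial regression: post-LP decision beta on LP-loss anterior beta
#'
#' Pairs every LP trial followed by a loss with its immediately following
#' post-LP trial (within subject and block), then regresses the post-LP
#' trial's pooled posterior decision-window beta on the LP trial's pooled
#' anterior late-feedback beta with a subject random intercept. With
#' `mode = "subject"` the regression runs on per-subject mean pairs
#' (ordinary least squares), the aggregate reading of the same question.
#'
#' @param anterior_pooled [pool_cluster()] frame for the anterior late
#'   window (all trials; LP-loss rows are selected internally)
#' @param posterior_pooled [pool_cluster()] frame for the posterior decision
#'   window (post-LP rows selected internally)
#' @param mode `"trial"` (default) or `"subject"`
#' @return list: `slope`, `se`, `p`, `r2`, `n_pairs`, `mode`
#' @export
cross_trial_regression <- function(anterior_pooled, posterior_pooled,
                                   mode = c("trial", "subject")) {
  mode <- match.arg(mode)
  lp <- anterior_pooled[anterior_pooled$choice_type == "LP" &
                          anterior_pooled$feedback == "loss", , drop = FALSE]
  post <- posterior_pooled[posterior_pooled$choice_type == "post-LP", ,
                           drop = FALSE]
  key <- paste(post$subject_id, post$block, post$trial)
  lp$match <- match(paste(lp$subject_id, lp$block, lp$trial + 1L), key)
  lp <- lp[!is.na(lp$match), , drop = FALSE]
  if (!nrow(lp)) stop("no LP-loss -> post-LP pairs")
  d <- data.frame(subject_id = lp$subject_id,
                  x = lp$beta_db, y = post$beta_db[lp$match])
  if (mode == "subject") {
    agg <- stats::aggregate(cbind(x, y) ~ subject_id, d, mean)
    if (nrow(agg) < 3) stop("too few subjects for the aggregate regression")
    fit <- stats::lm(y ~ x, agg)
    sm <- summary(fit)
    return(list(slope = unname(stats::coef(fit)[2]),
                se = sm$coefficients[2, 2], p = sm$coefficients[2, 4],
                r2 = sm$r.squared, n_pairs = nrow(agg), mode = mode))
  }
  fit <- lmm_ri(y ~ x, d, d$subject_id)
  se <- sqrt(fit$vcov[2, 2])
  tv <- fit$beta[2] / se
  list(slope = unname(fit$beta[2]), se = unname(se),
       p = 2 * stats::pt(abs(tv), fit$ddf, lower.tail = FALSE),
       r2 = stats::cor(fit$fitted, fit$y)^2, n_pairs = nrow(d), mode = mode)
}

#' Two-step (valence-balanced) condition averaging
#'
#' For visualization of choice types with feedback valences pooled: within
#' each group, average the trials of each feedback valence first, then
#' average the two valence means in a 1:1 ratio, so the unbalanced gain/loss
#' frequencies cannot bias the pooled mean. Groups missing a valence yield
#' `NA` and are reported, never silently skipped.
#'
#' @param value numeric per-trial values
#' @param feedback `"gain"`/`"loss"` per trial
#' @param group grouping factor (e.g. interaction of subject and choice type)
#' @return data.frame: `group`, `mean` (NA where a valence is missing),
#'   `missing_valence`
#' @export
two_step_average <- function(value, feedback, group) {
  stopifnot(length(value) == length(feedback),
            length(value) == length(group))
  group <- factor(group)
  out <- data.frame(group = levels(group), mean = NA_real_,
                    missing_valence = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(levels(group))) {
    sel <- group == levels(group)[i]
    mg <- mean(value[sel & feedback == "gain"])
    ml <- mean(value[sel & feedback == "loss"])
    if (is.nan(mg) || is.nan(ml)) out$missing_valence[i] <- TRUE
    else out$mean[i] <- (mg + ml) / 2
  }
  out
}
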