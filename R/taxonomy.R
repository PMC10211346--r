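#' Find the learning point of one block
#'
#' The learning criterion requires four consecutive choices of the
#' advantageous option; all trials from the start of the block up to and
#' including that 4-run are excluded. This returns the 0-based index of the
#' first trial *after* the earliest such run, or `NA` if no run of four
#' consecutive advantageous choices exists.
#'
#' @param choices character vector of `"advantageous"` / `"disadvantageous"`
#'   (abbreviations `"A"` / `"D"` accepted), ordered within one block
#' @return 0-based integer index, or `NA_integer_`
#' @export
find_learning_point <- function(choices) {
  stopifnot(length(choices) >= 1)
  adv <- choices %in% c("advantageous", "A")
  run <- 0L
  for (i in seq_along(adv)) {
    run <- if (adv[i]) run + 1L else 0L
    if (run == 4L) return(i) # 0-based index of the next trial == i (1-based i)
  }
  NA_integer_
}

#' Post-criterion performance rule for one block
#'
#' A block is retained only if, among the trials after the learning point, the
#' fraction of advantageous choices is strictly above 65%. The threshold is
#' motivated by the exact one-tailed binomial test: in ~30 trials, 65% or
#' more advantageous choices is significantly above chance (p < 0.05).
#' An empty post-criterion segment fails the rule.
#'
#' @param post_point_choices choices after the learning point (may be empty)
#' @return logical
#' @export
block_passes_criterion <- function(post_point_choices) {
  n <- length(post_point_choices)
  if (n == 0L) return(FALSE)
  mean(post_point_choices %in% c("advantageous", "A")) > 0.65
}

#' Classify choice types within one block
#'
#' The four-level taxonomy over advantageous (A) / disadvantageous (D)
#' choices, applied only to trials at or after the learning point but with
#' predecessor/successor context taken from the full within-block sequence:
#' * `HP`      A with A predecessor and A successor (stable exploitation);
#' * `pre-LP`  A with A predecessor and D successor;
#' * `LP`      D with A predecessor and A successor (isolated exploration);
#' * `post-LP` A with D predecessor and A successor.
#' Anything else (runs of D, A between two D, the final block trial, which
#' has no successor) is `none`. The 4-run preceding the learning point
#' guarantees an A predecessor for the first analyzed trial.
#'
#' @param choices full within-block choice sequence
#' @param learning_point 0-based learning point from [find_learning_point()]
#' @return character vector of labels, `"none"` outside the analyzed range
#' @export
classify_choice_types <- function(choices, learning_point) {
  n <- length(choices)
  out <- rep("none", n)
  if (is.na(learning_point) || learning_point >= n) return(out)
  adv <- choices %in% c("advantageous", "A")
  for (i in (learning_point + 1L):n) { # 1-based trial index
    has_prev <- i > 1L
    has_next <- i < n
    if (!has_next) next
    p_adv <- has_prev && adv[i - 1L]
    p_dis <- has_prev && !adv[i - 1L]
    n_adv <- adv[i + 1L]
    if (adv[i] && p_adv && n_adv) out[i] <- "HP"
    else if (adv[i] && p_adv && !n_adv) out[i] <- "pre-LP"
    else if (!adv[i] && p_adv && n_adv) out[i] <- "LP"
    else if (adv[i] && p_dis && n_adv) out[i] <- "post-LP"
  }
  out
}

#' Attach current- and previous-trial feedback factors
#'
#' `feedback` is the trial's own outcome; `previous_feedback` is the outcome
#' of the chronologically preceding trial within the same block (regardless of
#' that trial's analyzed status -- the participant experienced it), `"none"`
#' at the block start. Blocks never inherit feedback across their boundary.
#'
#' @param outcomes character vector of `"gain"`/`"loss"`, ordered within block
#' @return data.frame with columns `feedback`, `previous_feedback`
#' @export
attach_feedback_factors <- function(outcomes) {
  n <- length(outcomes)
  data.frame(feedback = outcomes,
             previous_feedback = if (n) c("none", outcomes[-n]) else character(0),
             stringsAsFactors = FALSE)
}

#' Extreme response-time exclusion
#'
#' Trials with RT < 300 ms or > 4000 ms are excluded from all analyses;
#' values exactly at the boundaries are retained.
#'
#' @param rt_ms numeric RT in milliseconds (must be positive)
#' @return logical vector, `TRUE` = excluded
#' @export
filter_rt <- function(rt_ms) {
  if (any(rt_ms <= 0, na.rm = TRUE)) stop("non-positive RT encountered")
  rt_ms < 300 | rt_ms > 4000
}

#' Label a cohort trial table
#'
#' Applies, per subject and block: the learning criterion, the >65%
#' post-criterion performance rule, the choice-type taxonomy, feedback
#' factors and RT exclusion. Every trial receives exactly one
#' `exclusion_reason` from `{block-failed, pre-criterion, rt-extreme,
#' unlabeled-type, none}` (in that precedence); `choice_type` is `"none"`
#' for every non-analyzed trial so that a non-`none` type implies `analyzed`.
#'
#' @param trials tidy trial table from [simulate_cohort()]
#' @return the table with columns `analyzed`, `exclusion_reason`,
#'   `choice_type`, `feedback`, `previous_feedback` appended
#' @export
label_trials <- function(trials) {
  need <- c("subject_id", "block", "trial", "choice", "outcome", "rt_ms")
  stopifnot(all(need %in% names(trials)))
  trials <- trials[order(trials$subject_id, trials$block, trials$trial), ,
                   drop = FALSE]
  parts <- split(trials, list(trials$subject_id, trials$block), drop = TRUE)
  out <- lapply(parts, function(bl) {
    n <- nrow(bl)
    lp <- find_learning_point(bl$choice)
    fb <- attach_feedback_factors(bl$outcome)
    bl$feedback <- fb$feedback
    bl$previous_feedback <- fb$previous_feedback
    reason <- rep("none", n)
    ctype <- rep("none", n)
    if (is.na(lp)) {
      reason[] <- "pre-criterion"
    } else if (!block_passes_criterion(bl$choice[(lp + 1L):n])) {
      reason[] <- "block-failed"
    } else {
      ctype <- classify_choice_types(bl$choice, lp)
      if (lp >= 1L) reason[seq_len(min(lp, n))] <- "pre-criterion"
      rt_bad <- filter_rt(bl$rt_ms)
      reason[reason == "none" & rt_bad] <- "rt-extreme"
      reason[reason == "none" & ctype == "none"] <- "unlabeled-type"
      ctype[reason != "none"] <- "none"
    }
    bl$analyzed <- reason == "none"
    bl$exclusion_reason <- reason
    bl$choice_type <- ctype
    bl
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$subject_id, out$block, out$trial), , drop = FALSE]
}

#' Per-subject counts of the four choice types (analyzed trials)
#'
#' @param labeled table from [label_trials()]
#' @return data.frame subject_id x choice type counts
#' @export
choice_type_counts <- function(labeled) {
  an <- labeled[labeled$analyzed, , drop = FALSE]
  tab <- table(factor(an$subject_id, levels = unique(labeled$subject_id)),
               factor(an$choice_type, levels = c("HP", "pre-LP", "LP", "post-LP")))
  as.data.frame.matrix(tab)
}

#' Subjects with a complete Choice type x Feedback design
#'
#' Mirrors the balance rule: a subject enters factorial analyses only if all
#' eight Choice type x Feedback cells contain at least one analyzed trial.
#'
#' @param labeled table from [label_trials()]
#' @return vector of subject ids with all 8 cells non-empty
#' @export
balanced_subjects <- function(labeled) {
  an <- labeled[labeled$analyzed, , drop = FALSE]
  tab <- table(an$subject_id,
               factor(an$choice_type, levels = c("HP", "pre-LP", "LP", "post-LP")),
               factor(an$feedback, levels = c("gain", "loss")))
  full <- apply(tab > 0, 1, all)
  ids <- dimnames(tab)[[1]][full]
  if (is.numeric(labeled$subject_id)) as.numeric(ids) else ids
}
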