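#' Reinforcement schemes of the probabilistic reward task
#'
#' The task is a two-alternative probabilistic gambling game played in six
#' blocks of 40 trials. In every block one option (the "advantageous" one)
#' yields the better outcome with probability 0.7 (0.6 in the final block),
#' the other with probability 0.3 (0.4). The point values attached to the
#' better/worse outcome differ between blocks; the six canonical schemes are
#' (I) -20/+20, (II) 0/+20, (III) -20/0, (IV) +20/+50, (V) -50/-20 and
#' (VI) -20/+20 at the shallower 0.6/0.4 contingency.
#'
#' @param loss_points points for the worse outcome (signed integer)
#' @param gain_points points for the better outcome (signed integer)
#' @param p_gain_advantageous probability of the better outcome for the
#'   advantageous option, in `[0, 1]`
#' @param p_gain_disadvantageous same for the disadvantageous option; must be
#'   strictly smaller than `p_gain_advantageous`
#' @return an object of class `reinforcement_scheme`
#' @export
reinforcement_scheme <- function(loss_points, gain_points,
                                 p_gain_advantageous = 0.7,
                                 p_gain_disadvantageous = 0.3) {
  stopifnot(is.numeric(loss_points), is.numeric(gain_points))
  if (!is.numeric(p_gain_advantageous) || p_gain_advantageous < 0 ||
      p_gain_advantageous > 1 ||
      !is.numeric(p_gain_disadvantageous) || p_gain_disadvantageous < 0 ||
      p_gain_disadvantageous > 1)
    stop("gain probabilities must lie in [0, 1]")
  if (p_gain_advantageous <= p_gain_disadvantageous)
    stop("p_gain_advantageous must exceed p_gain_disadvantageous")
  structure(list(loss_points = as.integer(loss_points),
                 gain_points = as.integer(gain_points),
                 p_gain_advantageous = p_gain_advantageous,
                 p_gain_disadvantageous = p_gain_disadvantageous),
            class = "reinforcement_scheme")
}

#' Expected payoff of one option under a scheme
#'
#' @param scheme a [reinforcement_scheme()]
#' @param option `"advantageous"` or `"disadvantageous"`
#' @return expected points per trial
#' @export
expected_payoff <- function(scheme, option = c("advantageous", "disadvantageous")) {
  option <- match.arg(option)
  p <- if (option == "advantageous") scheme$p_gain_advantageous else
    scheme$p_gain_disadvantageous
  p * scheme$gain_points + (1 - p) * scheme$loss_points
}

#' The six canonical reinforcement schemes
#'
#' @return named list of six [reinforcement_scheme()] objects I..VI
#' @export
default_schemes <- function() {
  list(I   = reinforcement_scheme(-20, 20),
       II  = reinforcement_scheme(0, 20),
       III = reinforcement_scheme(-20, 0),
       IV  = reinforcement_scheme(20, 50),
       V   = reinforcement_scheme(-50, -20),
       VI  = reinforcement_scheme(-20, 20, 0.6, 0.4))
}

# the three permitted counterbalancing orders of schemes across blocks
.scheme_orders <- list(c("I", "II", "III", "IV", "V", "VI"),
                       c("I", "IV", "III", "V", "II", "VI"),
                       c("I", "IV", "III", "II", "V", "VI"))

#' Task configuration
#'
#' @param n_blocks number of blocks (default 6)
#' @param trials_per_block trials per block (default 40)
#' @param scheme_order integer 1..3 selecting one of the three permitted
#'   counterbalancing sequences, or a character vector of scheme labels
#' @param max_outcome_run longest permitted run of identical outcomes in the
#'   pre-built quasirandom outcome sequences (default 3)
#' @return object of class `task_config` with an ordered `schemes` list
#' @export
task_config <- function(n_blocks = 6L, trials_per_block = 40L,
                        scheme_order = 1L, max_outcome_run = 3L) {
  if (is.numeric(scheme_order)) {
    if (!scheme_order %in% 1:3)
      stop("scheme_order index must be 1, 2 or 3")
    order_labels <- .scheme_orders[[scheme_order]]
  } else {
    ok <- vapply(.scheme_orders, identical, logical(1), y = as.character(scheme_order))
    if (!any(ok))
      stop("scheme_order is not one of the three permitted sequences: ",
           paste(vapply(.scheme_orders, paste, "", collapse = "-"), collapse = ", "))
    order_labels <- as.character(scheme_order)
  }
  if (n_blocks < 1 || trials_per_block < 1 || max_outcome_run < 1)
    stop("n_blocks, trials_per_block and max_outcome_run must be >= 1")
  schemes <- default_schemes()[order_labels]
  if (n_blocks != length(schemes)) {
    # truncated designs (fewer blocks) reuse the leading schemes; longer
    # designs are not part of the task and are refused
    if (n_blocks > length(schemes))
      stop("n_blocks may not exceed the ", length(schemes), " schemes of the order")
    schemes <- schemes[seq_len(n_blocks)]
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 scheme_order = order_labels,
                 schemes = schemes,
                 max_outcome_run = as.integer(max_outcome_run)),
            class = "task_config")
}

#' Behavioural agent parameters
#'
#' A two-phase choice model: an initial learning phase with undecided choices,
#' then a stationary preference for the advantageous option with rare,
#' by default isolated, explorative lapses. Response times are log-normal with
#' a mean that depends on the local choice-type context, matching the
#' qualitative ordering LP > pre-LP ~ post-LP > HP.
#'
#' @param n_learning_trials mean number of pre-criterion trials per block
#' @param p_advantageous_stable stationary probability of choosing the
#'   advantageous option after learning (default 0.90)
#' @param p_lp_isolated probability that an explorative (disadvantageous)
#'   choice is flanked by advantageous ones (default 1: strictly isolated)
#' @param rt_log_mean_by_type named numeric, mean log-RT (RT in ms) for
#'   `HP`, `pre-LP`, `LP`, `post-LP` contexts
#' @param rt_log_sd standard deviation of log-RT
#' @return object of class `agent_params`
#' @export
agent_params <- function(n_learning_trials = 8,
                         p_advantageous_stable = 0.90,
                         p_lp_isolated = 1.0,
                         rt_log_mean_by_type = c("HP" = log(650),
                                                 "pre-LP" = log(780),
                                                 "LP" = log(950),
                                                 "post-LP" = log(780)),
                         rt_log_sd = 0.35) {
  stopifnot(p_advantageous_stable > 0, p_advantageous_stable <= 1,
            p_lp_isolated >= 0, p_lp_isolated <= 1, rt_log_sd > 0)
  need <- c("HP", "pre-LP", "LP", "post-LP")
  if (!all(need %in% names(rt_log_mean_by_type)))
    stop("rt_log_mean_by_type must name all of: ", paste(need, collapse = ", "))
  structure(list(n_learning_trials = n_learning_trials,
                 p_advantageous_stable = p_advantageous_stable,
                 p_lp_isolated = p_lp_isolated,
                 rt_log_mean_by_type = rt_log_mean_by_type[need],
                 rt_log_sd = rt_log_sd),
            class = "agent_params")
}

# Can `gains` gains and `losses` losses still be arranged with no run of
# identical outcomes longer than `max_run`, given that the sequence currently
# ends in `run_len` repetitions of `run_is_gain`? Slot-counting argument:
# gain runs fit into (losses + 1) slots of size max_run, the slot continuing
# the current run has only (max_run - run_len) room; symmetrically for losses.
.outcome_feasible <- function(gains, losses, max_run, run_is_gain = NA, run_len = 0L) {
  if (gains < 0 || losses < 0) return(FALSE)
  gain_room <- max_run * losses +
    if (isTRUE(run_is_gain)) max_run - run_len else max_run
  loss_room <- max_run * gains +
    if (isFALSE(run_is_gain)) max_run - run_len else max_run
  gains <= gain_room && losses <= loss_room
}

#' Build a quasirandom interleaved outcome sequence
#'
#' Outcomes are pre-built so that the realized gain count equals
#' `round(p_gain * n)` exactly, with no run of identical outcomes longer than
#' `max_run` (the "interleaved" constraint that prevents multiple successive
#' repetitions of the same outcome). Sampling is sequential: at each position
#' a feasible outcome is drawn with probability proportional to its remaining
#' count, so the order depends only on the RNG state.
#'
#' @param p_gain probability of the better outcome for this option
#' @param n sequence length (>= 1)
#' @param max_run longest permitted run of identical outcomes (>= 1)
#' @return character vector of `"gain"` / `"loss"` of length `n`
#' @export
build_outcome_sequence <- function(p_gain, n, max_run = 3L) {
  stopifnot(n >= 1, max_run >= 1, p_gain >= 0, p_gain <= 1)
  gains <- as.integer(round(p_gain * n))
  losses <- n - gains
  if (!.outcome_feasible(gains, losses, max_run))
    stop(sprintf(paste0("infeasible outcome sequence: %d gains / %d losses ",
                        "cannot be interleaved with max run %d"),
                 gains, losses, max_run))
  out <- character(n)
  run_is_gain <- NA
  run_len <- 0L
  for (i in seq_len(n)) {
    can_gain <- gains > 0L && !(isTRUE(run_is_gain) && run_len >= max_run) &&
      .outcome_feasible(gains - 1L, losses, max_run,
                        run_is_gain = TRUE,
                        run_len = if (isTRUE(run_is_gain)) run_len + 1L else 1L)
    can_loss <- losses > 0L && !(isFALSE(run_is_gain) && run_len >= max_run) &&
      .outcome_feasible(gains, losses - 1L, max_run,
                        run_is_gain = FALSE,
                        run_len = if (isFALSE(run_is_gain)) run_len + 1L else 1L)
    if (!can_gain && !can_loss)
      stop("internal error: dead end while interleaving outcomes") # nocov
    pick_gain <- if (can_gain && can_loss)
      stats::runif(1) < gains / (gains + losses) else can_gain
    if (pick_gain) {
      out[i] <- "gain"
      gains <- gains - 1L
      run_len <- if (isTRUE(run_is_gain)) run_len + 1L else 1L
      run_is_gain <- TRUE
    } else {
      out[i] <- "loss"
      losses <- losses - 1L
      run_len <- if (isFALSE(run_is_gain)) run_len + 1L else 1L
      run_is_gain <- FALSE
    }
  }
  out
}

# classify the local A/D context of each choice in a block; used only to
# condition the simulated RT on the eventual choice type. `none` contexts
# (choice patterns matching no taxonomy cell) fall back to HP timing.
.context_type <- function(choices) {
  n <- length(choices)
  out <- rep("none", n)
  prev <- c("A", choices[-n]) # virtual advantageous predecessor at block start
  nxt <- c(choices[-1], NA)
  adv <- choices == "advantageous"
  adv_prev <- prev == "advantageous" | prev == "A"
  adv_next <- !is.na(nxt) & nxt == "advantageous"
  dis_next <- !is.na(nxt) & nxt == "disadvantageous"
  out[adv & adv_prev & adv_next] <- "HP"
  out[adv & adv_prev & dis_next] <- "pre-LP"
  out[!adv & adv_prev & adv_next] <- "LP"
  out[adv & !adv_prev & adv_next & prev == "disadvantageous"] <- "post-LP"
  out
}

#' Simulate one subject's behaviour in the task
#'
#' Per block: a learning phase of geometric-like length with undecided
#' choices, then stationary preference with `p_advantageous_stable`;
#' explorative lapses are isolated (never two disadvantageous choices in a
#' row) when `p_lp_isolated = 1`. Each trial reveals the pre-built outcome
#' assigned to the chosen option at that trial position, and draws a
#' log-normal RT conditioned on the trial's local choice-type context.
#'
#' @param config a [task_config()]
#' @param agent an [agent_params()]
#' @param subject_id identifier copied into the output
#' @return data.frame with one row per trial: `subject_id`, `block`, `trial`
#'   (both 0-based), `choice`, `outcome`, `points`, `rt_ms`
#' @export
simulate_subject <- function(config, agent, subject_id = 1L) {
  stopifnot(inherits(config, "task_config"), inherits(agent, "agent_params"))
  res <- vector("list", config$n_blocks)
  q_explore <- (1 - agent$p_advantageous_stable) / agent$p_advantageous_stable
  for (b in seq_len(config$n_blocks)) {
    scheme <- config$schemes[[b]]
    ntr <- config$trials_per_block
    seq_adv <- build_outcome_sequence(scheme$p_gain_advantageous, ntr,
                                      config$max_outcome_run)
    seq_dis <- build_outcome_sequence(scheme$p_gain_disadvantageous, ntr,
                                      config$max_outcome_run)
    # learning phase length: at least 1, mean ~ n_learning_trials
    n_learn <- min(ntr, 1L + stats::rpois(1, max(agent$n_learning_trials - 1, 0)))
    choices <- character(ntr)
    for (i in seq_len(ntr)) {
      if (i <= n_learn) {
        choices[i] <- if (stats::runif(1) < 0.5) "advantageous" else "disadvantageous"
      } else if (i > 1 && choices[i - 1] == "disadvantageous") {
        # isolation: after an explorative choice, return to the advantageous
        # option with probability p_lp_isolated
        choices[i] <- if (stats::runif(1) < agent$p_lp_isolated)
          "advantageous"
        else if (stats::runif(1) < agent$p_advantageous_stable)
          "advantageous" else "disadvantageous"
      } else {
        # stationary phase; with strict isolation (D forces a following A)
        # an explore hazard of q/(1+q) from A gives marginal P(D) = q/(1+q)
        # after renormalization, so hazard q yields P(D) = 1 - p_stable
        choices[i] <- if (stats::runif(1) < q_explore &&
                          i < ntr) "disadvantageous" else "advantageous"
      }
    }
    ctx <- .context_type(choices)
    mu <- agent$rt_log_mean_by_type[ifelse(ctx == "none", "HP", ctx)]
    rt <- exp(stats::rnorm(ntr, mean = mu, sd = agent$rt_log_sd))
    outcome <- ifelse(choices == "advantageous",
                      seq_adv[seq_len(ntr)], seq_dis[seq_len(ntr)])
    points <- ifelse(outcome == "gain", scheme$gain_points, scheme$loss_points)
    res[[b]] <- data.frame(subject_id = subject_id,
                           block = b - 1L,
                           trial = seq_len(ntr) - 1L,
                           choice = choices,
                           outcome = outcome,
                           points = as.integer(points),
                           rt_ms = rt,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Simulate a cohort of subjects
#'
#' @param n_subjects number of subjects
#' @param config a [task_config()]; scheme order is rotated across subjects
#'   over the three permitted sequences when `counterbalance = TRUE`
#' @param agent an [agent_params()]
#' @param seed RNG seed for the whole cohort (reproducible)
#' @param counterbalance rotate the three scheme orders across subjects
#' @return tidy trial table (data.frame), one row per trial
#' @export
simulate_cohort <- function(n_subjects, config = task_config(),
                            agent = agent_params(), seed = 1L,
                            counterbalance = TRUE) {
  set.seed(seed)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg <- if (counterbalance)
      task_config(config$n_blocks, config$trials_per_block,
                  scheme_order = ((s - 1L) %% 3L) + 1L,
                  max_outcome_run = config$max_outcome_run)
    else config
    out[[s]] <- simulate_subject(cfg, agent, subject_id = s)
  }
  do.call(rbind, out)
}
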