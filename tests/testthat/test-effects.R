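# pooled per-trial beta values generated directly at the stage the
# stage-two models consume: condition mean + subject intercept + noise
make_pooled <- function(lab, cell_means, tau = 0.4, sigma = 1, seed = 1,
                        rt_slope = 0, prev_gain_add = NULL) {
  set.seed(seed)
  n <- nrow(lab)
  u <- stats::rnorm(length(unique(lab$subject_id)), 0, tau)
  mu <- cell_means[cbind(match(lab$choice_type, rownames(cell_means)),
                         match(lab$feedback, colnames(cell_means)))]
  if (!is.null(prev_gain_add))
    mu <- mu + ifelse(lab$previous_feedback == "gain",
                      prev_gain_add[cbind(
                        match(lab$choice_type, rownames(cell_means)),
                        match(lab$feedback, colnames(cell_means)))], 0)
  lrt <- log(lab$rt_ms)
  y <- mu + rt_slope * (lrt - mean(lrt)) +
    u[match(lab$subject_id, unique(lab$subject_id))] +
    stats::rnorm(n, 0, sigma)
  data.frame(subject_id = lab$subject_id, block = lab$block,
             trial = lab$trial, choice_type = lab$choice_type,
             feedback = lab$feedback,
             previous_feedback = lab$previous_feedback,
             log_rt = lrt, beta_db = y, stringsAsFactors = FALSE)
}

cm <- function(hp, pre, lp, post) {
  m <- rbind(hp, pre, lp, post)
  rownames(m) <- c("HP", "pre-LP", "LP", "post-LP")
  colnames(m) <- c("gain", "loss")
  m
}

test_that("two-step averaging weights valences 1:1", {
  v <- c(rep(2, 90), rep(0, 10))
  fb <- c(rep("gain", 90), rep("loss", 10))
  out <- two_step_average(v, fb, rep("g1", 100))
  expect_equal(out$mean, 1) # not the flat mean 1.8
  # equal counts: identical to the flat mean
  v2 <- stats::rnorm(20)
  fb2 <- rep(c("gain", "loss"), 10)
  expect_equal(two_step_average(v2, fb2, rep("a", 20))$mean, mean(v2))
  # invariant to duplicating all gain trials
  out3 <- two_step_average(c(v, rep(2, 90)), c(fb, rep("gain", 90)),
                           rep("g1", 190))
  expect_equal(out3$mean, 1)
  # missing valence flagged, not skipped
  out4 <- two_step_average(1:3, rep("gain", 3), rep("g", 3))
  expect_true(out4$missing_valence)
  expect_true(is.na(out4$mean))
})

test_that("RT model recovers the injected choice-type pattern", {
  co <- simulate_cohort(40, task_config(), agent_params(), seed = 51)
  lab <- label_trials(co)
  res <- rt_model(lab)
  tk <- res$tukey
  lp_hp <- tk[(tk$lhs == "LP" & tk$rhs == "HP") |
                (tk$lhs == "HP" & tk$rhs == "LP"), ]
  est_lp_hp <- if (lp_hp$lhs == "LP") lp_hp$estimate else -lp_hp$estimate
  expect_gt(est_lp_hp, 0)
  expect_lt(lp_hp$p_tukey, 0.01)
  # LP slower than every other condition
  lp_rows <- tk[tk$lhs == "LP" | tk$rhs == "LP", ]
  expect_true(all(lp_rows$p_tukey < 0.01))
  est <- ifelse(lp_rows$lhs == "LP", lp_rows$estimate, -lp_rows$estimate)
  expect_true(all(est > 0))
  # pre-LP and post-LP slower than HP
  for (other in c("pre-LP", "post-LP")) {
    r <- tk[(tk$lhs == other & tk$rhs == "HP") |
              (tk$lhs == "HP" & tk$rhs == other), ]
    est <- if (r$lhs == "HP") -r$estimate else r$estimate
    expect_gt(est, 0)
    expect_lt(r$p_tukey, 0.01)
  }
  expect_lt(res$anova$p[res$anova$term == "choice_type"], 1e-6)
})

test_that("RT model under the null keeps Tukey error rates nominal", {
  lab <- make_labels(12, 60, seed = 53)
  reject <- matrix(FALSE, 60, 6)
  for (r in 1:60) {
    set.seed(1000 + r)
    lab$rt_ms <- exp(stats::rnorm(nrow(lab), log(800), 0.3) +
                       stats::rnorm(12, 0, 0.2)[lab$subject_id])
    res <- rt_model(lab)
    reject[r, ] <- res$tukey$p_tukey < 0.05
  }
  # familywise: each pair individually non-significant in >= 94% of reps
  expect_true(all(colMeans(reject) <= 0.06))
})

test_that("pooled decision model recovers the LP-specific ERD", {
  lab <- make_labels(20, 80, seed = 55)
  pooled <- make_pooled(lab, cm(c(-1.4, -1.4), c(-1.4, -1.4),
                                c(-2.1, -2.1), c(-1.4, -1.4)), seed = 55)
  res <- pooled_effect_model(pooled, "choice")
  tk <- res$tukey$choice_type
  for (other in c("HP", "pre-LP", "post-LP")) {
    r <- tk[tk$lhs == "LP" & tk$rhs == other |
              tk$lhs == other & tk$rhs == "LP", ]
    est <- if (r$lhs == "LP") r$estimate else -r$estimate
    expect_lt(est, 0)
    expect_lt(r$p_tukey, 0.001)
  }
})

test_that("pooled late model recovers the loss-only LP ERS pattern", {
  lab <- make_labels(24, 100, seed = 57)
  pooled <- make_pooled(lab, cm(c(0.6, 0.6), c(0.25, 0.25),
                                c(-0.9, 0.6), c(0.2, 0.6)), seed = 57)
  res <- pooled_effect_model(pooled, "choice_feedback")
  expect_lt(res$anova$p[res$anova$term == "choice_type:feedback"], 1e-4)
  tk <- res$tukey$cells
  lp <- tk[tk$lhs == "LP.gain" & tk$rhs == "LP.loss", ]
  expect_lt(lp$estimate, 0) # losses carry the ERS
  expect_lt(lp$p_tukey, 0.001)
  hp <- tk[tk$lhs == "HP.gain" & tk$rhs == "HP.loss", ]
  expect_gt(hp$p_tukey, 0.05) # gains and losses equal for HP
})

test_that("null pooled model keeps omnibus rates nominal", {
  lab <- make_labels(12, 60, seed = 59)
  ps <- replicate(60, {
    pooled <- make_pooled(lab, cm(c(0, 0), c(0, 0), c(0, 0), c(0, 0)),
                          seed = sample.int(1e6, 1))
    pooled_effect_model(pooled, "choice")$anova$p[1]
  })
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps < 0.5), 0.25)
})

test_that("triple-interaction couplings are recovered (previous feedback)", {
  lab <- make_labels(30, 120, seed = 61)
  prev <- cm(c(0.4, 0), c(0, 0), c(0, 0.5), c(0, 0))
  pooled <- make_pooled(lab, cm(c(0.6, 0.6), c(0.25, 0.25), c(-0.9, 0.6),
                                c(0.2, 0.6)),
                        prev_gain_add = prev, seed = 61, sigma = 0.8)
  res <- pooled_effect_model(pooled, "choice_feedback_prev")
  a <- res$anova
  expect_lt(a$p[a$term == "feedback:previous_feedback:choice_type"], 0.05)
  tk <- res$tukey$cells
  # HP current gain: previous gain enhances the ERS
  r <- tk[tk$lhs == "HP.gain.gain" & tk$rhs == "HP.gain.loss", ]
  expect_gt(r$estimate, 0); expect_lt(r$p_tukey, 0.05)
  # LP current loss: previous outcome modulates the ERS
  r2 <- tk[tk$lhs == "LP.loss.gain" & tk$rhs == "LP.loss.loss", ]
  expect_gt(r2$estimate, 0); expect_lt(r2$p_tukey, 0.05)
  # LP current gain: unaffected by the previous outcome
  r3 <- tk[tk$lhs == "LP.gain.gain" & tk$rhs == "LP.gain.loss", ]
  expect_gt(r3$p_tukey, 0.05)
})

test_that("beta ~ RT regression recovers the injected slope", {
  lab <- make_labels(40, 30, seed = 63)
  pooled <- make_pooled(lab, cm(c(-1.5, -1.5), c(-1.5, -1.5),
                                c(-2.2, -2.2), c(-1.5, -1.5)),
                        rt_slope = -2, seed = 63)
  res <- beta_rt_regression(pooled)
  expect_lt(abs(res$slope - (-2)), 0.3)
  expect_lt(res$p, 0.001)
  expect_error(
    beta_rt_regression(transform(pooled, log_rt = 1)), "degenerate")
})

test_that("beta ~ RT slope CI covers 0 under the null", {
  lab <- make_labels(15, 40, seed = 65)
  cover <- replicate(60, {
    pooled <- make_pooled(lab, cm(c(0, 0), c(0, 0), c(0, 0), c(0, 0)),
                          rt_slope = 0, seed = sample.int(1e6, 1))
    r <- beta_rt_regression(pooled)
    abs(r$slope) < 1.96 * r$se
  })
  expect_gte(mean(cover), 0.85)
})

test_that("cross-trial regression pairs LP-loss with following post-LP", {
  set.seed(67)
  n_s <- 25; n_per <- 12
  rows <- list()
  for (s in 1:n_s) for (k in 1:n_per) {
    z <- stats::rnorm(1)
    t0 <- (k - 1) * 3
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = s, block = 0, trial = c(t0, t0 + 1),
      choice_type = c("LP", "post-LP"), feedback = c("loss", "gain"),
      previous_feedback = "gain", log_rt = log(800),
      beta_db = c(0.6 + z + stats::rnorm(1, 0, 0.3),
                  -1.5 + 0.5 * z + stats::rnorm(1, 0, 0.3)))
  }
  pooled <- do.call(rbind, rows)
  res <- cross_trial_regression(pooled, pooled)
  expect_equal(res$n_pairs, n_s * n_per)
  expect_lt(abs(res$slope - 0.5), 2 * res$se + 0.05)
  expect_lt(res$p, 0.001)
  # independent generators: slope not significant (typical run)
  pooled2 <- pooled
  set.seed(68)
  pooled2$beta_db <- stats::rnorm(nrow(pooled2))
  res2 <- cross_trial_regression(pooled2, pooled2)
  expect_gt(res2$p, 0.01)
  # subject-aggregate mode
  res3 <- cross_trial_regression(pooled, pooled, mode = "subject")
  expect_equal(res3$n_pairs, n_s)
  expect_gt(res3$slope, 0)
  # no pairs -> error
  expect_error(cross_trial_regression(pooled2[pooled2$choice_type == "LP", ],
                                      pooled2[pooled2$choice_type == "LP", ]),
               "no LP-loss")
})

test_that("rank-deficient stage-two designs name the empty cell", {
  lab <- make_labels(6, 40, seed = 69)
  pooled <- make_pooled(lab, cm(c(0, 0), c(0, 0), c(0, 0), c(0, 0)))
  pooled$feedback[pooled$choice_type == "LP"] <- "loss"
  expect_error(pooled_effect_model(pooled, "choice_feedback"), "LP.gain")
})
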