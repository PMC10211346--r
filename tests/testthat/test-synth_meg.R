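# full small-scale synthesis: labeled table -> epochs -> band power -> dB grid
synth_db_grid <- function(labels, layout, templates, seed = 1L,
                          noise = noise_params()) {
  ep <- generate_epochs(labels, layout, templates, noise, seed = seed)
  pw <- multitaper_band_power(ep$response)
  bw <- multitaper_band_power(ep$baseline)
  subs_base <- labels$subject_id[ep$baseline$trial_rows]
  bl <- hp_baseline(bw, subs_base)
  subs_resp <- labels$subject_id[ep$response$trial_rows]
  apply_baseline(pw, bl$baseline_db, subs_resp)
}

test_that("template windows outside the epoch span are refused", {
  lay <- make_layout(12)
  bad <- effect_template("bad", "posterior", c(2600, 3000), matrix(-1, 4, 2))
  lab <- make_labels(2, 10, seed = 1)
  expect_error(generate_epochs(lab, lay, list(bad)), "outside the epoch")
})

test_that("epoch synthesis is seed-reproducible", {
  lay <- make_layout(8)
  lab <- make_labels(2, 6, seed = 2)
  a <- generate_epochs(lab, lay, default_effect_templates(), seed = 7)
  b <- generate_epochs(lab, lay, default_effect_templates(), seed = 7)
  expect_identical(a$response$data, b$response$data)
  expect_identical(a$baseline$data, b$baseline$data)
})

test_that("injected dB is recovered within 0.2 dB; clean sensors stay at 0", {
  lay <- make_layout(12)
  post <- region_sensors(lay, "posterior")
  clean <- setdiff(seq_len(12), post)
  tp <- effect_template("erd", "posterior", c(-800, 0), matrix(-1, 4, 2))
  lab <- make_labels(2, 60, seed = 4)
  grid <- synth_db_grid(lab, lay, list(tp), seed = 4)
  # window interior: full multitaper support inside the effect window
  tin <- grid$times_ms >= -550 & grid$times_ms <= -250
  tout <- grid$times_ms >= 1500 & grid$times_ms <= 2400
  m_in <- mean(grid$values[, post, tin])
  m_clean <- mean(grid$values[, clean, tin])
  m_out <- mean(grid$values[, post, tout])
  expect_lt(abs(m_in - (-1)), 0.2)
  expect_lt(abs(m_clean), 0.2)
  expect_lt(abs(m_out), 0.2)
})

test_that("the null generator produces ~0 dB everywhere", {
  lay <- make_layout(8)
  tp <- effect_template("null", "posterior", c(-800, 0), matrix(0, 4, 2))
  lab <- make_labels(6, 50, seed = 6)
  grid <- synth_db_grid(lab, lay, list(tp), seed = 6)
  v <- grid$values[, , grid$valid]
  # the HP-baseline estimate is shared within subject, so the clustering
  # unit for the uncertainty of the grand mean is the subject
  subj_means <- tapply(apply(v, 1, mean),
                       grid$subject_ids, mean)
  se <- stats::sd(subj_means) / sqrt(length(subj_means))
  expect_lt(abs(mean(v)), 3 * se + 0.05)
})

test_that("single-template LP-vs-HP difference is recovered (~ -1 dB)", {
  lay <- make_layout(12)
  post <- region_sensors(lay, "posterior")
  d <- matrix(-1, 4, 2); d[3, ] <- -2
  tp <- effect_template("erd", "posterior", c(-1300, 100), d)
  lab <- make_labels(20, 30, seed = 8)
  grid <- synth_db_grid(lab, lay, list(tp), seed = 8)
  tin <- grid$times_ms >= -650 & grid$times_ms <= -550
  per_trial <- apply(grid$values[, post, tin, drop = FALSE], 1, mean)
  ct <- lab$choice_type[grid$trial_rows]
  tt <- stats::t.test(per_trial[ct == "LP"], per_trial[ct == "HP"])
  d_est <- unname(tt$estimate[1] - tt$estimate[2])
  half <- diff(tt$conf.int) / 2
  # recovery within the generator's stated +-0.2 dB consistency band (the
  # 5% broadband noise floor slightly attenuates injected contrasts),
  # plus the estimation uncertainty of this finite sample
  expect_lt(abs(d_est - (-1)), 0.2 + half)
  expect_lt(tt$p.value, 1e-3) # and clearly present
})

test_that("per-trial deltas resolve couplings correctly", {
  lab <- data.frame(
    subject_id = 1, block = 0, trial = 0:4,
    choice_type = c("HP", "pre-LP", "LP", "post-LP", "HP"),
    feedback = c("gain", "gain", "loss", "gain", "loss"),
    previous_feedback = c("gain", "gain", "gain", "loss", "gain"),
    rt_ms = c(650, 780, 950, 780, 650), analyzed = TRUE,
    stringsAsFactors = FALSE)
  tps <- default_effect_templates(rt_slope = -2, prev_gain_hp = 0.25,
                                  prev_gain_lp_loss = 0.3,
                                  cross_trial_gain = 0.5)
  d <- trial_effect_deltas(lab, tps, seed = 3)
  # RT at the per-type centre: decision delta = base (no RT shift)
  expect_equal(unname(d[1, "decision_erd"]), -1.5, tolerance = 1e-9)
  expect_equal(unname(d[3, "late_anterior_ers"] - 0.5 *
                        (d[4, "decision_erd"] - (-1.5)) / 0.5),
               0.6 + 0.3, tolerance = 1e-9) # prev-gain LP-loss modulation
  # cross-trial latent shared between LP-loss and following post-LP
  z_from_lp <- unname((d[3, "late_anterior_ers"] - 0.9) / 0.5)
  z_from_post <- unname((d[4, "decision_erd"] - (-1.5)) / 0.5)
  expect_equal(z_from_lp, z_from_post, tolerance = 1e-9)
  # previous-gain modulation hits HP gains
  expect_equal(unname(d[1, "late_anterior_ers"]), 0.6 + 0.25,
               tolerance = 1e-9)
  # RT coupling: slower-than-typical HP trial gets deeper decision ERD
  lab2 <- lab; lab2$rt_ms[1] <- 650 * exp(0.5)
  d2 <- trial_effect_deltas(lab2, tps, seed = 3)
  expect_equal(unname(d2[1, "decision_erd"]), -1.5 - 2 * 0.5,
               tolerance = 1e-9)
})
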