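#' Effect template: a condition-dependent beta-power change
#'
#' Describes one injectable event-related change of beta-band power: in the
#' sensors of `regions`, inside `window_ms` (relative to the response), the
#' beta amplitude envelope is scaled by `10^(delta/20)` so that measured beta
#' *power* changes by `delta` dB. `delta_db` is a 4 x 2 matrix (choice type x
#' feedback). Optional couplings: `prev_gain_delta` is added when the
#' previous trial's feedback was a gain; `rt_slope` adds
#' `slope * (log RT - typical log RT of the trial's choice type)` (dB per
#' log-RT unit; negative slope = deeper suppression for slower decisions);
#' `cross_trial_gain` couples a shared latent between an LP-loss trial (added
#' here) and the decision-window change of the following post-LP trial.
#'
#' @param name template label
#' @param regions region names of a [make_layout()]
#' @param window_ms `c(start, end)` in ms relative to response onset
#' @param delta_db 4 x 2 numeric matrix, rows `HP, pre-LP, LP, post-LP`,
#'   columns `gain, loss`
#' @param prev_gain_delta optional 4 x 2 matrix, default all zero
#' @param rt_slope optional scalar, default 0
#' @param cross_trial_gain optional scalar, default 0
#' @return object of class `effect_template`
#' @export
effect_template <- function(name, regions, window_ms, delta_db,
                            prev_gain_delta = NULL, rt_slope = 0,
                            cross_trial_gain = 0) {
  delta_db <- as.matrix(delta_db)
  stopifnot(nrow(delta_db) == 4, ncol(delta_db) == 2,
            length(window_ms) == 2, window_ms[1] < window_ms[2],
            all(is.finite(delta_db)))
  dimnames(delta_db) <- list(c("HP", "pre-LP", "LP", "post-LP"),
                             c("gain", "loss"))
  if (is.null(prev_gain_delta))
    prev_gain_delta <- matrix(0, 4, 2)
  prev_gain_delta <- as.matrix(prev_gain_delta)
  stopifnot(nrow(prev_gain_delta) == 4, ncol(prev_gain_delta) == 2)
  dimnames(prev_gain_delta) <- dimnames(delta_db)
  structure(list(name = name, regions = regions, window_ms = window_ms,
                 delta_db = delta_db, prev_gain_delta = prev_gain_delta,
                 rt_slope = rt_slope, cross_trial_gain = cross_trial_gain),
            class = "effect_template")
}

#' Default effect templates: the three sensor-level beta effects
#'
#' The default synthetic world injects, with invented but documented
#' magnitudes, effects whose time extent exceeds the analysis windows that
#' probe them — as in the real phenomenon, where the decision ERD spans the
#' whole pre-response period, the posterior feedback ERD covers feedback
#' processing, and the anterior ERS rises before the late analysis window
#' and persists beyond it. The analysis windows therefore sit inside
#' regions of full effect expression, not on their smeared edges:
#' 1. *decision ERD* (posterior + left-central, -1300..100 ms, probed at
#'    -900..-300 ms): -1.5 dB for all choice types with an extra -0.75 dB
#'    for LP, plus an RT coupling of `rt_slope` dB per log-RT unit
#'    (default -2);
#' 2. *early feedback ERD* (posterior, 1000..1600 ms after the response,
#'    probed at 100..500 ms post-feedback): -1.0 dB, LP at -1.75 dB,
#'    identical for gains and losses;
#' 3. *late anterior ERS* (anterior, 1350..2100 ms, probed at 500..900 ms
#'    post-feedback): +0.6 dB for HP gains and losses, reduced (+0.25) for
#'    pre-LP, for LP driven exclusively by losses (+0.6) with gains followed
#'    by suppression below baseline (-0.9), and for post-LP stronger for
#'    losses (+0.6) than gains (+0.2).
#'
#' @param rt_slope decision-window RT coupling (dB per log-RT unit)
#' @param prev_gain_hp extra late ERS for HP gains after a previous gain
#' @param prev_gain_lp_loss extra late ERS for LP losses after a previous gain
#' @param cross_trial_gain latent coupling between LP-loss late ERS and the
#'   following post-LP decision-window power (default 0 = off)
#' @return list of [effect_template()] objects
#' @export
default_effect_templates <- function(rt_slope = -2.0, prev_gain_hp = 0,
                                     prev_gain_lp_loss = 0,
                                     cross_trial_gain = 0) {
  dec <- matrix(-1.5, 4, 2)
  dec[3, ] <- -2.25
  early <- matrix(-1.0, 4, 2)
  early[3, ] <- -1.75
  late <- rbind("HP" = c(0.6, 0.6), "pre-LP" = c(0.25, 0.25),
                "LP" = c(-0.9, 0.6), "post-LP" = c(0.2, 0.6))
  prev <- matrix(0, 4, 2)
  prev[1, 1] <- prev_gain_hp
  prev[3, 2] <- prev_gain_lp_loss
  list(
    effect_template("decision_erd", c("posterior", "left_central"),
                    c(-1300, 100), dec, rt_slope = rt_slope,
                    cross_trial_gain = cross_trial_gain),
    effect_template("early_feedback_erd", "posterior", c(1000, 1600), early),
    effect_template("late_anterior_ers", "anterior", c(1350, 2100), late,
                    prev_gain_delta = prev,
                    cross_trial_gain = cross_trial_gain))
}

#' Noise and signal parameters of the epoch generator
#'
#' @param beta_band beta carrier band in Hz (default `c(16, 30)`)
#' @param noise_beta_frac 16-30 Hz power of the broadband 1/f noise as a
#'   fraction of the carrier's baseline beta power (default 0.05; keeps the
#'   injected-dB vs measured-dB mismatch well under 0.2 dB)
#' @param subject_gain_sd log-normal SD of the per-subject amplitude factor
#'   (absorbed by the dB baseline; default 0.2)
#' @param ramp_ms envelope ramp duration at effect-window edges (default 50)
#' @return list of class `noise_params`
#' @export
noise_params <- function(beta_band = c(16, 30), noise_beta_frac = 0.05,
                         subject_gain_sd = 0.2, ramp_ms = 50) {
  structure(list(beta_band = beta_band, noise_beta_frac = noise_beta_frac,
                 subject_gain_sd = subject_gain_sd, ramp_ms = ramp_ms),
            class = "noise_params")
}

# raised-cosine window indicator: 0 outside [start, end], ramping over ramp_ms
.effect_ramp <- function(t_ms, start, end, ramp_ms) {
  r <- numeric(length(t_ms))
  inside <- t_ms >= start & t_ms <= end
  r[inside] <- 1
  if (ramp_ms > 0) {
    up <- t_ms >= start & t_ms < start + ramp_ms
    dn <- t_ms > end - ramp_ms & t_ms <= end
    r[up] <- 0.5 - 0.5 * cos(pi * (t_ms[up] - start) / ramp_ms)
    r[dn] <- 0.5 - 0.5 * cos(pi * (end - t_ms[dn]) / ramp_ms)
  }
  r
}

# smallest 5-smooth (2^a 3^b 5^c) integer >= n: R's mixed-radix FFT is
# efficient only for small prime factors (epoch lengths like 1351 = 7 x 193
# would otherwise dominate the runtime)
.next_fast_len <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

# band-limited unit-variance Gaussian noise, one column per channel;
# synthesized at an FFT-friendly length and truncated (stationary, so
# truncation preserves the spectrum up to negligible windowing leakage)
.band_noise <- function(n_samples, n_chan, sfreq, band) {
  m <- .next_fast_len(n_samples)
  w <- matrix(stats::rnorm(m * n_chan), m, n_chan)
  f <- abs(seq(0, sfreq, length.out = m + 1)[seq_len(m)])
  f <- pmin(f, sfreq - f)
  keep <- f >= band[1] & f <= band[2]
  wf <- stats::mvfft(w)
  wf[!keep, ] <- 0
  x <- Re(stats::mvfft(wf, inverse = TRUE)) / m
  # theoretical variance after masking = fraction of retained bins
  x[seq_len(n_samples), , drop = FALSE] / sqrt(mean(keep))
}

# broadband 1/f ("pink") noise scaled so its power inside `band` equals
# `target_band_power`
.pink_noise <- function(n_samples, n_chan, sfreq, band, target_band_power) {
  m <- .next_fast_len(n_samples)
  w <- matrix(stats::rnorm(m * n_chan), m, n_chan)
  f <- abs(seq(0, sfreq, length.out = m + 1)[seq_len(m)])
  f <- pmin(f, sfreq - f)
  amp <- ifelse(f >= 1, 1 / sqrt(f), 1) # flat below 1 Hz, 1/f power above
  wf <- stats::mvfft(w) * amp
  x <- Re(stats::mvfft(wf, inverse = TRUE)) / m
  band_frac <- sum(amp[f >= band[1] & f <= band[2]]^2) / m
  x[seq_len(n_samples), , drop = FALSE] *
    sqrt(target_band_power / band_frac)
}

#' Generate synthetic response-locked and fixation-locked epochs
#'
#' Every analyzed trial of `labeled` receives a response-locked epoch
#' (-1750..2750 ms, 300 Hz): per sensor, a 16-30 Hz Gaussian carrier whose
#' amplitude envelope is the baseline level scaled by `10^(delta/20)` inside
#' each matching effect window (50-ms cosine ramps), plus broadband 1/f
#' noise. Feedback onset is 1000 ms after the response. HP trials also
#' receive a fixation-locked baseline epoch (-700..300 ms) carrying the
#' baseline envelope only. A per-subject amplitude factor (log-normal)
#' emulates inter-subject power differences and must be absorbed by the dB
#' baseline.
#'
#' @param labeled labeled trial table ([label_trials()]); only analyzed rows
#'   get response-locked epochs
#' @param layout a [make_layout()]
#' @param templates list of [effect_template()]s (default
#'   [default_effect_templates()])
#' @param noise a [noise_params()]
#' @param seed RNG seed
#' @param epoch_ms response-locked epoch span (default `c(-1750, 2750)`)
#' @param baseline_epoch_ms fixation-locked span (default `c(-700, 300)`)
#' @param sfreq sampling rate (default 300)
#' @return list with `response` and `baseline` `epoch_set` objects; each has
#'   `data` (trials x sensors x samples), `sfreq`, `t0_ms`, `lock`,
#'   `trial_rows` (row indices into `labeled`), and the layout
#' @export
generate_epochs <- function(labeled, layout,
                            templates = default_effect_templates(),
                            noise = noise_params(), seed = 1L,
                            epoch_ms = c(-1750, 2750),
                            baseline_epoch_ms = c(-700, 300), sfreq = 300) {
  stopifnot(inherits(layout, "sensor_layout"))
  for (tp in templates)
    if (tp$window_ms[1] < epoch_ms[1] || tp$window_ms[2] > epoch_ms[2])
      stop("template '", tp$name, "' window [",
           paste(tp$window_ms, collapse = ", "),
           "] falls outside the epoch span")
  set.seed(seed)
  an_rows <- which(labeled$analyzed)
  if (!length(an_rows)) stop("no analyzed trials to synthesize")
  an <- labeled[an_rows, , drop = FALSE]
  hp_rows <- an_rows[an$choice_type == "HP"]

  n_samp <- round(diff(epoch_ms) / 1000 * sfreq) + 1L
  t_ms <- seq(epoch_ms[1], epoch_ms[2], length.out = n_samp)
  nb_samp <- round(diff(baseline_epoch_ms) / 1000 * sfreq) + 1L

  deltas <- trial_effect_deltas(labeled, templates, seed = seed)

  subjects <- unique(labeled$subject_id)
  gain <- stats::setNames(
    exp(stats::rnorm(length(subjects), 0, noise$subject_gain_sd)), subjects)

  ns <- layout$n
  resp <- array(NA_real_, dim = c(length(an_rows), ns, n_samp))
  base <- array(NA_real_, dim = c(length(hp_rows), ns, nb_samp))
  # per-template sensor membership
  tmpl_sensors <- lapply(templates, function(tp) region_sensors(layout, tp$regions))

  for (k in seq_along(an_rows)) {
    row <- an_rows[k]
    g <- gain[as.character(labeled$subject_id[row])]
    carrier <- .band_noise(n_samp, ns, sfreq, noise$beta_band)
    env <- matrix(1, n_samp, ns)
    for (j in seq_along(templates)) {
      d <- deltas[k, j]
      if (d == 0) next
      ramp <- .effect_ramp(t_ms, templates[[j]]$window_ms[1],
                           templates[[j]]$window_ms[2], noise$ramp_ms)
      mult <- 1 + (10^(d / 20) - 1) * ramp
      env[, tmpl_sensors[[j]]] <- env[, tmpl_sensors[[j]]] * mult
    }
    pink <- .pink_noise(n_samp, ns, sfreq, noise$beta_band,
                        noise$noise_beta_frac)
    resp[k, , ] <- t(g * (carrier * env + pink))
  }
  for (k in seq_along(hp_rows)) {
    g <- gain[as.character(labeled$subject_id[hp_rows[k]])]
    carrier <- .band_noise(nb_samp, ns, sfreq, noise$beta_band)
    pink <- .pink_noise(nb_samp, ns, sfreq, noise$beta_band,
                        noise$noise_beta_frac)
    base[k, , ] <- t(g * (carrier + pink))
  }
  list(response = structure(list(data = resp, sfreq = sfreq,
                                 t0_ms = epoch_ms[1], lock = "response",
                                 trial_rows = an_rows, layout = layout),
                            class = "epoch_set"),
       baseline = structure(list(data = base, sfreq = sfreq,
                                 t0_ms = baseline_epoch_ms[1], lock = "fixation",
                                 trial_rows = hp_rows, layout = layout),
                            class = "epoch_set"))
}

#' Per-trial injected dB change for each template
#'
#' Resolves, for every analyzed trial, the dB change each template injects:
#' the condition cell of `delta_db`, plus the previous-gain modulation, the
#' RT coupling (centred on the agent's typical log-RT per choice type) and
#' the cross-trial latent shared between an LP-loss trial and its following
#' post-LP trial. Exposed so tests can compare injected against recovered
#' values trial by trial.
#'
#' @param labeled labeled trial table
#' @param templates list of [effect_template()]s
#' @param seed seed for the cross-trial latents (must match the one used for
#'   generation)
#' @param rt_center named log-RT centres per choice type used by the RT
#'   coupling; defaults to the [agent_params()] defaults
#' @return matrix (analyzed trials x templates) of injected dB
#' @export
trial_effect_deltas <- function(labeled, templates, seed = 1L,
                                rt_center = agent_params()$rt_log_mean_by_type) {
  an_rows <- which(labeled$analyzed)
  an <- labeled[an_rows, , drop = FALSE]
  nt <- length(an_rows)
  # cross-trial latents: one per LP trial with loss feedback, deterministic
  # in `seed` and independent of the carrier noise draws
  lp_loss <- an$choice_type == "LP" & an$feedback == "loss"
  z <- numeric(nt)
  if (any(lp_loss)) {
    rs <- .derive_seed(seed, 104729L)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(rs)
    z[lp_loss] <- stats::rnorm(sum(lp_loss))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  # map each post-LP trial to its immediately preceding LP trial (same
  # subject/block, previous trial index among generated trials)
  post_link <- rep(NA_integer_, nt)
  key <- paste(an$subject_id, an$block, an$trial)
  prev_key <- paste(an$subject_id, an$block, an$trial - 1L)
  idx <- match(prev_key, key)
  is_post <- an$choice_type == "post-LP"
  post_link[is_post] <- idx[is_post]

  out <- matrix(0, nt, length(templates))
  for (j in seq_along(templates)) {
    tp <- templates[[j]]
    d <- tp$delta_db[cbind(match(an$choice_type, rownames(tp$delta_db)),
                           match(an$feedback, colnames(tp$delta_db)))]
    pg <- an$previous_feedback == "gain"
    d <- d + ifelse(pg, tp$prev_gain_delta[
      cbind(match(an$choice_type, rownames(tp$delta_db)),
            match(an$feedback, colnames(tp$delta_db)))], 0)
    if (tp$rt_slope != 0 && tp$name == "decision_erd") {
      ctr <- rt_center[an$choice_type]
      d <- d + tp$rt_slope * (log(an$rt_ms) - ctr)
    }
    if (tp$cross_trial_gain != 0) {
      if (tp$name == "late_anterior_ers")
        d <- d + tp$cross_trial_gain * z
      if (tp$name == "decision_erd") {
        ok <- is_post & !is.na(post_link)
        link_ok <- ok
        link_ok[ok] <- lp_loss[post_link[ok]]
        d[link_ok] <- d[link_ok] +
          tp$cross_trial_gain * z[post_link[link_ok]]
      }
    }
    out[, j] <- d
  }
  colnames(out) <- vapply(templates, `[[`, "", "name")
  out
}
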