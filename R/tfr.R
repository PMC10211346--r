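#' Discrete prolate spheroidal sequence (DPSS) tapers
#'
#' Computed from the classical symmetric tridiagonal formulation (the
#' eigenvectors of the tridiagonal matrix associated with the time-frequency
#' concentration problem), which is numerically stable and needs no external
#' dependency. Tapers are unit-energy; signs follow the usual convention
#' (non-negative mean for symmetric tapers, positive initial lobe otherwise).
#'
#' @param n taper length in samples
#' @param nw half time-bandwidth product (e.g. 2)
#' @param k number of tapers (typically `2*nw - 1`)
#' @return `n x k` matrix, one taper per column, ordered by concentration
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  w <- nw / n
  i <- seq_len(n) - 1
  diagv <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  offv <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  m <- diag(diagv)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- offv
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- offv
  e <- eigen(m, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' Multitaper parameters for beta-band power
#'
#' Frequencies 16..30 Hz in 2-Hz steps with the number of cycles set to f/2,
#' so the sliding window is 500 ms at every frequency; the time-bandwidth
#' product of 4 (window length x full smoothing bandwidth) gives 8 Hz of
#' frequency smoothing and `4 - 1 = 3` DPSS tapers. Output is sampled every
#' 25 ms on the absolute-time lattice.
#'
#' @param freqs_hz analysis frequencies (Hz)
#' @param cycles_rule function mapping frequency to number of cycles
#' @param time_bandwidth window length x full bandwidth product
#' @param step_ms output sampling step in ms
#' @return list of class `tfr_params`
#' @export
tfr_params <- function(freqs_hz = seq(16, 30, by = 2),
                       cycles_rule = function(f) f / 2,
                       time_bandwidth = 4, step_ms = 25) {
  stopifnot(length(freqs_hz) >= 1, time_bandwidth > 1, step_ms > 0)
  structure(list(freqs_hz = freqs_hz, cycles_rule = cycles_rule,
                 time_bandwidth = time_bandwidth, step_ms = step_ms),
            class = "tfr_params")
}

#' Window duration (s) and frequency smoothing (Hz) implied by tfr params
#'
#' @param params a [tfr_params()]
#' @return data.frame with `freq_hz`, `duration_s`, `smoothing_hz`, `n_tapers`
#' @export
tfr_param_identities <- function(params) {
  dur <- params$cycles_rule(params$freqs_hz) / params$freqs_hz
  data.frame(freq_hz = params$freqs_hz,
             duration_s = dur,
             smoothing_hz = params$time_bandwidth / dur,
             n_tapers = max(1L, floor(params$time_bandwidth) - 1L))
}

# complex demodulation kernels: for each (frequency, taper), a tapered
# complex exponential of the window length; returned as real/imaginary parts
# so band power needs only two real GEMMs per trial
.mt_kernels <- function(win_samp, sfreq, freqs, time_bandwidth) {
  nw <- time_bandwidth / 2
  k <- max(1L, floor(time_bandwidth) - 1L)
  tap <- dpss_tapers(win_samp, nw, k)
  tt <- (seq_len(win_samp) - 1) / sfreq
  re <- matrix(0, length(freqs) * k, win_samp)
  im <- matrix(0, length(freqs) * k, win_samp)
  r <- 0L
  for (f in freqs) for (j in seq_len(k)) {
    r <- r + 1L
    re[r, ] <- tap[, j] * cos(2 * pi * f * tt)
    im[r, ] <- tap[, j] * sin(2 * pi * f * tt)
  }
  list(re = re, im = im, n_tapers = k, n_freqs = length(freqs))
}

#' Single-trial multitaper beta-band power
#'
#' DPSS multitaper estimation of band power: at every 25-ms lattice time with
#' full window support, the 500-ms window around it is projected on tapered
#' complex exponentials at each analysis frequency; squared moduli are
#' averaged over tapers and summed over the 16-30 Hz band. Times whose
#' window would cross an epoch edge are returned as `NA` (marked invalid),
#' never zero-padded.
#'
#' @param epochs an `epoch_set` (see [generate_epochs()])
#' @param params a [tfr_params()]
#' @return object of class `band_power`: `power` (trials x sensors x times,
#'   linear units), `times_ms`, `valid` (logical per time), `sfreq`,
#'   `trial_rows`, `layout`
#' @export
multitaper_band_power <- function(epochs, params = tfr_params()) {
  stopifnot(inherits(epochs, "epoch_set"))
  sfreq <- epochs$sfreq
  if (sfreq < 2 * max(params$freqs_hz))
    stop("sampling rate ", sfreq, " Hz is below Nyquist for ",
         max(params$freqs_hz), " Hz")
  dur <- params$cycles_rule(params$freqs_hz) / params$freqs_hz
  if (max(abs(dur - dur[1])) > 1e-9)
    stop("cycles_rule must give a common window duration across frequencies")
  win_samp <- round(dur[1] * sfreq)
  dims <- dim(epochs$data)
  n_trials <- dims[1]; n_sens <- dims[2]; n_samp <- dims[3]
  if (n_samp < win_samp)
    stop("epoch too short for the ", round(dur[1] * 1000), "-ms window")
  t0 <- epochs$t0_ms
  tend <- t0 + (n_samp - 1) / sfreq * 1000
  step <- params$step_ms
  times <- seq(ceiling(t0 / step) * step, floor(tend / step) * step, by = step)
  half_ms <- (win_samp - 1) / 2 / sfreq * 1000
  valid <- times - half_ms >= t0 - 1e-9 & times + half_ms <= tend + 1e-9
  kern <- .mt_kernels(win_samp, sfreq, params$freqs_hz, params$time_bandwidth)
  starts <- round((times[valid] - t0) / 1000 * sfreq - (win_samp - 1) / 2) + 1L
  starts <- pmin(pmax(starts, 1L), n_samp - win_samp + 1L)
  nv <- length(starts)
  idx <- outer(seq_len(win_samp) - 1L, starts, `+`) # win x nv
  big <- as.vector(idx) +
    rep((seq_len(n_sens) - 1L) * n_samp, each = win_samp * nv)
  scale <- 2 / sfreq
  out <- array(NA_real_, dim = c(n_trials, n_sens, length(times)))
  for (tr in seq_len(n_trials)) {
    x <- t(matrix(epochs$data[tr, , ], n_sens, n_samp)) # samples x sensors
    w <- matrix(x[big], win_samp, nv * n_sens)
    p <- (kern$re %*% w)^2 + (kern$im %*% w)^2
    band <- colSums(p) / kern$n_tapers * scale
    out[tr, , valid] <- t(matrix(band, nv, n_sens))
  }
  structure(list(power = out, times_ms = times, valid = valid, sfreq = sfreq,
                 trial_rows = epochs$trial_rows, layout = epochs$layout),
            class = "band_power")
}

#' Combine planar-gradiometer pairs by summing linear power
#'
#' When power was estimated on 2N raw planar gradiometers, orthogonal pairs
#' are combined by adding their time-frequency (here: band) power, yielding N
#' combined sensors. Data already generated at combined-sensor level passes
#' through unchanged when `pairing` is `NULL`.
#'
#' @param power `band_power` object (or plain trials x sensors x times array)
#' @param pairing integer matrix with 2 rows, one column per combined sensor,
#'   or `NULL` for identity pass-through
#' @return same class as the input with sensors combined
#' @export
combine_pairs <- function(power, pairing = NULL) {
  arr <- if (inherits(power, "band_power")) power$power else power
  if (is.null(pairing)) return(power)
  pairing <- as.matrix(pairing)
  if (nrow(pairing) != 2) stop("pairing must have 2 rows")
  n_sens <- dim(arr)[2]
  used <- as.integer(sort(as.vector(pairing)))
  if (!identical(used, seq_len(n_sens)))
    stop("pairing must use every sensor exactly once (unpaired sensor?)")
  comb <- arr[, pairing[1, ], , drop = FALSE] + arr[, pairing[2, ], , drop = FALSE]
  if (inherits(power, "band_power")) {
    power$power <- comb
    power
  } else comb
}

#' Decibel transform of band power
#'
#' `10*log10(power)`, flooring non-positive or underflowing values at `eps`
#' with a warning (synthetic data can in principle produce zero band power).
#'
#' @param power numeric array of linear power
#' @param eps floor (default 1e-300)
#' @return array of dB values
#' @export
power_db <- function(power, eps = 1e-300) {
  n_bad <- sum(power < eps, na.rm = TRUE)
  if (n_bad > 0) {
    warning(n_bad, " power value(s) at or below ", eps, " floored before log")
    power <- pmax(power, eps)
  }
  10 * log10(power)
}

#' Fixed HP-condition baseline in dB
#'
#' The dB baseline for every subject and sensor is the mean of dB-transformed
#' power over the [-350, -50] ms window of the fixation-locked epochs of HP
#' trials, averaged over time points and over all HP trials of that subject.
#' One fixed reference per subject x sensor corrects all conditions.
#'
#' @param baseline_power `band_power` computed on fixation-locked HP epochs
#' @param subject_ids subject of each baseline trial (parallel to trials)
#' @param window_ms baseline window (default `c(-350, -50)`)
#' @param eps dB floor passed to [power_db()]
#' @param all_subjects optional full roster of subject ids; those without HP
#'   trials are reported in `excluded_subjects` (flagged for exclusion)
#' @return list: `baseline_db` (subjects x sensors matrix, rownames =
#'   subject ids), `excluded_subjects` (ids with zero HP trials among
#'   `all_subjects`, if given)
#' @export
hp_baseline <- function(baseline_power, subject_ids,
                        window_ms = c(-350, -50), eps = 1e-300,
                        all_subjects = NULL) {
  stopifnot(inherits(baseline_power, "band_power"))
  tsel <- which(baseline_power$times_ms >= window_ms[1] &
                  baseline_power$times_ms <= window_ms[2] &
                  baseline_power$valid)
  if (!length(tsel)) stop("baseline window has no valid time points")
  db <- power_db(baseline_power$power[, , tsel, drop = FALSE], eps = eps)
  subs <- unique(subject_ids)
  n_sens <- dim(db)[2]
  out <- matrix(NA_real_, length(subs), n_sens,
                dimnames = list(as.character(subs), NULL))
  for (s in seq_along(subs)) {
    rows <- which(subject_ids == subs[s])
    out[s, ] <- apply(db[rows, , , drop = FALSE], 2, mean)
  }
  excluded <- if (is.null(all_subjects)) character(0) else
    setdiff(as.character(all_subjects), as.character(subs))
  list(baseline_db = out, excluded_subjects = excluded)
}

#' Baseline-corrected beta power grid in dB
#'
#' dB-transforms single-trial band power and subtracts each trial's
#' subject/sensor baseline, yielding the trials x sensors x times grid all
#' statistics run on.
#'
#' @param response_power `band_power` on response-locked epochs
#' @param baseline_db subjects x sensors matrix from [hp_baseline()]
#' @param subject_ids subject of each response trial
#' @param eps dB floor
#' @return object of class `beta_power_grid`: `values` (dB array), plus the
#'   time axis / validity / trial bookkeeping of the input
#' @export
apply_baseline <- function(response_power, baseline_db, subject_ids,
                           eps = 1e-300) {
  stopifnot(inherits(response_power, "band_power"))
  miss <- setdiff(as.character(unique(subject_ids)), rownames(baseline_db))
  if (length(miss))
    stop("no baseline for subject(s): ", paste(miss, collapse = ", "),
         " (no HP trials?)")
  db <- power_db(response_power$power, eps = eps)
  bl <- baseline_db[as.character(subject_ids), , drop = FALSE]
  # recycle the trials x sensors baseline block along the time dimension
  db <- db - array(bl, dim = dim(db))
  structure(list(values = db, times_ms = response_power$times_ms,
                 valid = response_power$valid,
                 trial_rows = response_power$trial_rows,
                 subject_ids = subject_ids,
                 layout = response_power$layout),
            class = "beta_power_grid")
}
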