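# shared fixtures: built in code at test time, no stored data

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# a labeled-trial table drawn from realistic condition proportions, with all
# eight choice-type x feedback cells guaranteed non-empty in the pooled data
make_labels <- function(n_subjects, n_trials, seed = 1L) {
  set.seed(seed)
  ct_p <- c("HP" = 0.70, "pre-LP" = 0.10, "LP" = 0.10, "post-LP" = 0.10)
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    ct <- sample(names(ct_p), n_trials, TRUE, prob = ct_p)
    fb <- ifelse(ct == "LP",
                 ifelse(stats::runif(n_trials) < 0.3, "gain", "loss"),
                 ifelse(stats::runif(n_trials) < 0.7, "gain", "loss"))
    data.frame(subject_id = s, block = 0L, trial = seq_len(n_trials) - 1L,
               choice_type = ct, feedback = fb,
               previous_feedback = sample(c("gain", "loss"), n_trials, TRUE),
               rt_ms = exp(stats::rnorm(n_trials, log(800), 0.3)),
               analyzed = TRUE, stringsAsFactors = FALSE)
  }))
  # force the eight pooled cells non-empty
  cells <- expand.grid(ct = names(ct_p), fb = c("gain", "loss"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    hit <- out$choice_type == cells$ct[i] & out$feedback == cells$fb[i]
    if (!any(hit)) {
      out$choice_type[i] <- cells$ct[i]
      out$feedback[i] <- cells$fb[i]
    }
  }
  out
}

# wrap a trials x sensors x times dB array as a beta_power_grid on the
# standard 25-ms lattice
make_grid <- function(values, times_ms, subject_ids, layout = NULL) {
  structure(list(values = values, times_ms = times_ms,
                 valid = rep(TRUE, length(times_ms)),
                 trial_rows = seq_len(dim(values)[1]),
                 subject_ids = subject_ids, layout = layout),
            class = "beta_power_grid")
}

# wrap an array as a band_power object
make_band_power <- function(power, times_ms, layout = NULL) {
  structure(list(power = power, times_ms = times_ms,
                 valid = rep(TRUE, length(times_ms)), sfreq = 300,
                 trial_rows = seq_len(dim(power)[1]), layout = layout),
            class = "band_power")
}

# brute-force Benjamini-Hochberg step-up: reference oracle
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= q * seq_len(m) / m)
  keep <- logical(m)
  if (length(below)) keep[o[seq_len(max(below))]] <- TRUE
  keep
}
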