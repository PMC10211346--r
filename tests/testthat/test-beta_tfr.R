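test_that("DPSS tapers are orthonormal and spectrally concentrated", {
  tap <- dpss_tapers(150, 2, 3)
  expect_equal(crossprod(tap), diag(3), tolerance = 1e-10)
  # concentration oracle: energy of taper 1 inside |f| <= W computed by
  # direct quadratic form with the Dirichlet kernel
  n <- 150; w <- 2 / n
  i <- outer(seq_len(n), seq_len(n), `-`)
  K <- ifelse(i == 0, 2 * w, sin(2 * pi * w * i) / (pi * i))
  conc <- drop(t(tap[, 1]) %*% K %*% tap[, 1])
  expect_gt(conc, 0.999)
  expect_gt(drop(t(tap[, 3]) %*% K %*% tap[, 3]), 0.9)
})

test_that("multitaper parameter identities hold (500 ms, 8 Hz, 3 tapers)", {
  ids <- tfr_param_identities(tfr_params())
  expect_true(all(ids$duration_s == 0.5))
  expect_true(all(ids$smoothing_hz == 8))
  expect_true(all(ids$n_tapers == 3))
})

test_that("a constant-amplitude sinusoid gives a flat band-power course", {
  lay <- make_layout(8)
  n <- 1351
  t_ms <- seq(-1750, 2750, length.out = n)
  x <- aperm(array(sin(2 * pi * 22 * t_ms / 1000), dim = c(n, 8, 1)),
             c(3, 2, 1))
  ep <- structure(list(data = x, sfreq = 300, t0_ms = -1750,
                       lock = "response", trial_rows = 1L, layout = lay),
                  class = "epoch_set")
  bp <- multitaper_band_power(ep)
  v <- bp$power[1, 1, bp$valid]
  expect_lt(stats::sd(v) / mean(v), 0.05)
})

test_that("edge times lacking window support are invalid, not zero-padded", {
  lay <- make_layout(8)
  x <- array(stats::rnorm(8 * 301), dim = c(1, 8, 301))
  ep <- structure(list(data = x, sfreq = 300, t0_ms = -700,
                       lock = "fixation", trial_rows = 1L, layout = lay),
                  class = "epoch_set")
  bp <- multitaper_band_power(ep)
  expect_true(all(is.na(bp$power[, , !bp$valid])))
  expect_true(all(is.finite(bp$power[, , bp$valid])))
  # 500-ms window: first valid centre >= t0 + 250 ms
  expect_true(min(bp$times_ms[bp$valid]) >= -700 + 250 - 12.5)
  # too-short epoch errors
  ep$data <- ep$data[, , 1:100, drop = FALSE]
  expect_error(multitaper_band_power(ep), "too short")
})

test_that("sub-Nyquist sampling rates are refused", {
  lay <- make_layout(8)
  ep <- structure(list(data = array(0, c(1, 8, 100)), sfreq = 50,
                       t0_ms = 0, lock = "response", trial_rows = 1L,
                       layout = lay), class = "epoch_set")
  expect_error(multitaper_band_power(ep), "Nyquist")
})

test_that("multitaper agrees with a periodogram-average oracle on stationary noise", {
  # long stationary band-limited (10-40 Hz) signal
  set.seed(13)
  n <- 60000; sfreq <- 300
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- abs(seq(0, sfreq, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, sfreq - f)
  xf[!(f >= 10 & f <= 40)] <- 0
  x <- Re(stats::fft(xf, inverse = TRUE)) / n
  # oracle: rectangular-window periodogram of disjoint 150-sample segments,
  # evaluated at the same 8 band frequencies with the same scaling
  win <- 150
  segs <- matrix(x[seq_len(win * floor(n / win))], win)
  tt <- (seq_len(win) - 1) / sfreq
  E <- exp(-2i * pi * outer(seq(16, 30, 2), tt))
  pg <- Mod(E %*% segs)^2 / win
  oracle <- mean(colSums(pg)) * 2 / sfreq
  lay <- make_layout(8)
  ep <- structure(list(data = array(rep(x[1:3000], each = 8), c(1, 8, 3000)),
                       sfreq = sfreq, t0_ms = 0, lock = "response",
                       trial_rows = 1L, layout = lay), class = "epoch_set")
  bp <- multitaper_band_power(ep)
  mt <- mean(bp$power[1, 1, bp$valid])
  expect_lt(abs(mt / oracle - 1), 0.1)
})

test_that("pair combination sums linear power and validates the pairing", {
  arr <- array(stats::runif(2 * 4 * 5), dim = c(2, 4, 5))
  pairing <- rbind(c(1, 3), c(2, 4))
  comb <- combine_pairs(arr, pairing)
  expect_equal(dim(comb), c(2L, 2L, 5L))
  expect_equal(comb[, 1, ], arr[, 1, ] + arr[, 2, ])
  # order within a pair is irrelevant
  comb2 <- combine_pairs(arr, rbind(c(2, 4), c(1, 3)))
  expect_equal(comb, comb2)
  # (p, p) -> 2p
  arr2 <- arr[, 1:2, , drop = FALSE]; arr2[, 2, ] <- arr2[, 1, ]
  expect_equal(combine_pairs(arr2, rbind(1, 2))[, 1, ], 2 * arr2[, 1, ])
  expect_error(combine_pairs(arr, rbind(1, 2)), "every sensor")
  # identity pass-through for combined-level data
  expect_identical(combine_pairs(arr), arr)
})

test_that("dB transform floors non-positive power with a warning", {
  expect_warning(v <- power_db(c(1, 0, 10), eps = 1e-12), "floored")
  expect_equal(v, c(0, -120, 10))
})

test_that("HP baseline: self-subtraction ~0, 10x power = +10 dB, fixed ref", {
  set.seed(3)
  # stationary synthetic band power: trials x sensors x times
  p0 <- array(stats::rexp(40 * 3 * 13, rate = 1), dim = c(40, 3, 13))
  times <- seq(-450, -150, by = 25)
  bw <- make_band_power(p0, times)
  subs <- rep(1:2, each = 20)
  bl <- hp_baseline(bw, subs, window_ms = c(-450, -150))
  # applying the baseline to the baseline data itself: mean ~ 0 dB
  db <- power_db(p0) - array(bl$baseline_db[as.character(subs), ],
                             dim = dim(p0))
  expect_lt(abs(mean(db)), 1e-9)
  # response power 10x baseline power -> +10 dB everywhere
  rp <- make_band_power(p0 * 10, times)
  grid <- apply_baseline(rp, bl$baseline_db, subs)
  expect_equal(mean(grid$values), mean(db) + 10, tolerance = 1e-9)
  # the reference is one value per subject x sensor: identical across trials
  expect_equal(dim(bl$baseline_db), c(2L, 3L))
  # subjects without HP trials are flagged
  bl2 <- hp_baseline(bw, subs, window_ms = c(-450, -150),
                     all_subjects = 1:3)
  expect_equal(bl2$excluded_subjects, "3")
  expect_error(apply_baseline(rp, bl$baseline_db, rep(3, 40)),
               "no baseline")
})

test_that("amplitude rescaling is absorbed by the baseline (dB additivity)", {
  lay <- make_layout(8)
  lab <- make_labels(2, 12, seed = 9)
  tps <- default_effect_templates()
  ep <- generate_epochs(lab, lay, tps, seed = 9)
  grid1 <- {
    pw <- multitaper_band_power(ep$response)
    bw <- multitaper_band_power(ep$baseline)
    bl <- hp_baseline(bw, lab$subject_id[ep$baseline$trial_rows])
    apply_baseline(pw, bl$baseline_db, lab$subject_id[ep$response$trial_rows])
  }
  ep$response$data <- ep$response$data * 3.7
  ep$baseline$data <- ep$baseline$data * 3.7
  grid2 <- {
    pw <- multitaper_band_power(ep$response)
    bw <- multitaper_band_power(ep$baseline)
    bl <- hp_baseline(bw, lab$subject_id[ep$baseline$trial_rows])
    apply_baseline(pw, bl$baseline_db, lab$subject_id[ep$response$trial_rows])
  }
  expect_equal(grid1$values, grid2$values, tolerance = 1e-8)
})
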