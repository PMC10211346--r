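# a beta_power_grid with constant value on the full -1500..2500 lattice
const_grid <- function(n_trials, n_sensors, value = 0, subject_ids = NULL) {
  times <- seq(-1500, 2500, by = 25)
  vals <- array(value, dim = c(n_trials, n_sensors, length(times)))
  make_grid(vals, times, subject_ids %||% rep(1, n_trials))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("frame averaging yields 17 frames tiling -900..2500", {
  g <- const_grid(3, 4, value = 2.5)
  fr <- frame_average(g)
  expect_equal(dim(fr$values), c(3, 4, 17))
  expect_equal(fr$centers_ms, seq(-800, 2400, by = 200))
  expect_true(all(fr$values == 2.5)) # constant in -> constant out
  # a 17 x 102 grid has 1,734 cells
  expect_equal(17 * 102, 1734)
})

test_that("frame averaging refuses grids without full coverage", {
  g <- const_grid(2, 3)
  g$valid[g$times_ms < -800] <- FALSE
  expect_error(frame_average(g), "coverage")
})

test_that("frames are the mean of their 8 half-open lattice points", {
  g <- const_grid(1, 1)
  # value = time in ms, so each frame mean is its centre minus 12.5
  g$values[1, 1, ] <- g$times_ms
  fr <- frame_average(g)
  expect_equal(fr$values[1, 1, ], fr$centers_ms - 12.5)
})

test_that("BH mask matches the brute-force step-up oracle", {
  p <- c(0.001, 0.02, 0.03, 0.5)
  expect_equal(fdr_mask(p, 0.05), bh_oracle(p, 0.05))
  expect_equal(fdr_mask(rep(1, 20), 0.05), rep(FALSE, 20))
  set.seed(2)
  for (i in 1:20) {
    p <- stats::runif(50)^sample(1:3, 1)
    expect_equal(fdr_mask(p, 0.05), bh_oracle(p, 0.05))
  }
  # shape preserved
  pm <- matrix(stats::runif(12), 3, 4)
  expect_equal(dim(fdr_mask(pm)), dim(pm))
})

test_that("lowering a p-value never removes BH discoveries (monotonicity)", {
  set.seed(4)
  p <- stats::runif(40)
  m1 <- fdr_mask(p, 0.05)
  for (i in 1:10) {
    p2 <- p
    j <- sample(40, 1)
    p2[j] <- p2[j] / 10
    m2 <- fdr_mask(p2, 0.05)
    expect_true(all(m2[m1]))
  }
})

test_that("cluster extraction enforces persistence and neighbour pruning", {
  lay <- make_layout(24)
  mask <- matrix(FALSE, 4, 24)
  # sensor 1 significant in 3 of 4 frames: excluded
  mask[1:3, 1] <- TRUE
  # a compact patch: a sensor and all its neighbours, all frames
  nb <- which(lay$neighbors[5, ])
  patch <- c(5, nb)
  mask[, patch] <- TRUE
  cl <- extract_clusters(mask, 1:4, lay)
  expect_false(1 %in% cl)
  expect_true(5 %in% cl)
  # an isolated persistent sensor (no significant neighbours) is pruned
  far <- setdiff(seq_len(24), c(patch, unlist(lapply(patch, function(s)
    which(lay$neighbors[s, ])))))
  mask2 <- matrix(FALSE, 4, 24)
  mask2[, far[1]] <- TRUE
  expect_length(extract_clusters(mask2, 1:4, lay), 0)
  # fully significant grid: every sensor kept (layout guarantees degree >= 2)
  expect_equal(extract_clusters(matrix(TRUE, 4, 24), 1:4, lay),
               seq_len(24))
})

test_that("sign splitting drops non-significant sensors and splits by mean", {
  set.seed(6)
  sm <- cbind(matrix(-1 + stats::rnorm(40, 0, 0.01), 10, 4),
              matrix(1 + stats::rnorm(20, 0, 0.01), 10, 2),
              matrix(stats::rnorm(20, 0, 1), 10, 2))
  sp <- split_by_sign(1:8, sm)
  expect_equal(sp$erd, 1:4)
  expect_equal(sp$ers, 5:6)
  expect_true(all(7:8 %in% sp$dropped))
  # exactly constant zero mean: dropped (degenerate, not significant)
  sm0 <- matrix(0, 10, 1)
  expect_equal(split_by_sign(1, sm0)$dropped, 1)
})

test_that("screening recovers an injected frame-level effect", {
  lay <- make_layout(36)
  lab <- make_labels(12, 40, seed = 31)
  sens <- region_sensors(lay, "posterior")
  # base ERD in all conditions (so the sign split sees a pooled deviation
  # from baseline) plus an LP-specific deepening that drives the screen
  d <- matrix(-1, 4, 2); d[3, ] <- -2.2
  vals <- simulate_frame_grid(lab, 36, 6,
                              effect = list(sensors = sens, frames = 2:4,
                                            delta = d),
                              tau = 0.4, sigma = 1, seed = 31)
  fr <- structure(list(values = vals, centers_ms = seq(-800, 200, 200),
                       width_ms = 200, trial_rows = seq_len(nrow(lab)),
                       subject_ids = lab$subject_id, layout = lay),
                  class = "frame_grid")
  win <- list(dec = list(window_ms = c(-500, -100), effect = "choice_type"))
  sc <- run_screen(fr, lab, win)
  expect_gte(jaccard(sc$clusters$dec$sensors, sens), 0.8)
  expect_equal(sc$clusters$dec$erd, sc$clusters$dec$sensors)
  # determinism: identical inputs -> identical result
  sc2 <- run_screen(fr, lab, win)
  expect_identical(sc, sc2)
})

test_that("null screening yields no persistent clusters (typical case)", {
  lay <- make_layout(20)
  lab <- make_labels(10, 30, seed = 33)
  vals <- simulate_frame_grid(lab, 20, 6, seed = 33)
  fr <- structure(list(values = vals, centers_ms = seq(-800, 200, 200),
                       width_ms = 200, trial_rows = seq_len(nrow(lab)),
                       subject_ids = lab$subject_id, layout = lay),
                  class = "frame_grid")
  sc <- run_screen(fr, lab,
                   list(w = list(window_ms = c(-700, -300),
                                 effect = "interaction")))
  expect_length(sc$clusters$w$sensors, 0)
})
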