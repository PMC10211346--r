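#' Frame-average a beta power grid into 200-ms frames
#'
#' Averages dB values over consecutive non-overlapping 200-ms windows
#' centred on -800, -600, ..., 2400 ms relative to the response (17 frames).
#' Each frame covers the half-open interval `[centre - 100, centre + 100)`
#' on the 25-ms lattice, i.e. 8 lattice points, so the frames tile
#' [-900, 2500) without overlap and use every lattice point exactly once.
#'
#' @param grid a `beta_power_grid` ([apply_baseline()])
#' @param centers_ms frame centres (default `seq(-800, 2400, by = 200)`)
#' @param width_ms frame width (default 200)
#' @return object of class `frame_grid`: `values` (trials x sensors x
#'   frames), `centers_ms`, trial bookkeeping carried over
#' @export
frame_average <- function(grid, centers_ms = seq(-800, 2400, by = 200),
                          width_ms = 200) {
  stopifnot(inherits(grid, "beta_power_grid"))
  step <- diff(grid$times_ms[1:2])
  npt <- width_ms / step
  dims <- dim(grid$values)
  out <- array(NA_real_, dim = c(dims[1], dims[2], length(centers_ms)))
  for (f in seq_along(centers_ms)) {
    lo <- centers_ms[f] - width_ms / 2
    sel <- which(grid$times_ms >= lo - 1e-9 &
                   grid$times_ms < lo + width_ms - 1e-9)
    if (length(sel) != npt || !all(grid$valid[sel]))
      stop("frame centred at ", centers_ms[f],
           " ms lacks full valid coverage of the power grid")
    out[, , f] <- apply(grid$values[, , sel, drop = FALSE], c(1, 2), mean)
  }
  structure(list(values = out, centers_ms = centers_ms,
                 width_ms = width_ms, trial_rows = grid$trial_rows,
                 subject_ids = grid$subject_ids, layout = grid$layout),
            class = "frame_grid")
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up FDR over all supplied p-values jointly (for screening: the
#' flattened frames x sensors grid of one effect).
#'
#' @param p numeric vector/array of p-values in `[0, 1]`
#' @param q FDR level (default 0.05)
#' @return logical mask of the same shape, `TRUE` = discovery
#' @export
fdr_mask <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(as.vector(p), method = "BH")
  m <- adj <= q & !is.na(adj)
  if (!is.null(dim(p))) dim(m) <- dim(p)
  m
}

#' Extract a persistent, neighbour-pruned sensor cluster
#'
#' Keeps sensors significant in *every* frame of the window, then removes in
#' a single pass any kept sensor with fewer than two kept neighbours (the
#' compactness rule; pruning is simultaneous, not iterated to a fixed
#' point).
#'
#' @param mask logical frames x sensors significance mask for one effect
#' @param window_frames integer indices of the frames forming the window
#' @param layout a [make_layout()] (for the neighbour graph)
#' @return sorted integer vector of cluster sensor indices
#' @export
extract_clusters <- function(mask, window_frames, layout) {
  stopifnot(length(window_frames) >= 1, inherits(layout, "sensor_layout"))
  keep <- which(colSums(mask[window_frames, , drop = FALSE]) ==
                  length(window_frames))
  if (!length(keep)) return(integer(0))
  adj <- layout$neighbors[keep, keep, drop = FALSE]
  deg <- rowSums(adj)
  sort(keep[deg >= 2])
}

#' Split a cluster into ERD and ERS subclusters
#'
#' Per sensor, tests the subject-level window-mean dB (all conditions
#' pooled) against zero (two-sided t-test, p < 0.05, uncorrected); sensors
#' failing the test are dropped, the rest are split by the sign of the mean
#' into ERD (< 0) and ERS (> 0) subclusters.
#'
#' @param cluster sensor indices from [extract_clusters()]
#' @param subject_means subjects x sensors matrix of window-mean dB
#' @return list: `erd`, `ers` (sorted sensor indices), `dropped`
#' @export
split_by_sign <- function(cluster, subject_means) {
  stopifnot(length(cluster) >= 1)
  erd <- integer(0); ers <- integer(0); dropped <- integer(0)
  for (s in cluster) {
    x <- subject_means[, s]
    x <- x[is.finite(x)]
    if (length(unique(x)) < 2) { dropped <- c(dropped, s); next }
    tt <- stats::t.test(x)
    if (tt$p.value >= 0.05) dropped <- c(dropped, s)
    else if (mean(x) < 0) erd <- c(erd, s)
    else ers <- c(ers, s)
  }
  list(erd = sort(erd), ers = sort(ers), dropped = sort(dropped))
}

#' Default analysis windows of the screening stage
#'
#' Explicit configuration with the canonical defaults: the decision window
#' -900..-300 ms before the response (Choice type effect), the early
#' feedback window 100..500 ms after feedback onset (Choice type effect) and
#' the late feedback window 500..900 ms after feedback onset (Choice type x
#' Feedback interaction). Feedback onset is 1000 ms after the response, so
#' post-feedback windows are offset accordingly on the response-locked axis.
#'
#' @param feedback_onset_ms feedback delay after the response (default 1000)
#' @return named list of `list(window_ms, effect)` entries
#' @export
screen_windows <- function(feedback_onset_ms = 1000) {
  list(decision = list(window_ms = c(-900, -300), effect = "choice_type"),
       early_feedback = list(window_ms = feedback_onset_ms + c(100, 500),
                             effect = "choice_type"),
       late_feedback = list(window_ms = feedback_onset_ms + c(500, 900),
                            effect = "interaction"))
}

# frames whose [start, end) support lies inside window_ms
.window_frames <- function(centers_ms, width_ms, window_ms) {
  lo <- centers_ms - width_ms / 2
  which(lo >= window_ms[1] - 1e-9 & lo + width_ms <= window_ms[2] + 1e-9)
}

#' Stage-one data-driven screening
#'
#' Runs the full first-stage procedure on a frame grid: per-cell mixed
#' models (`beta ~ choice_type * feedback + (1|subject)`), Benjamini-Hochberg
#' FDR at `q` over the flattened frames x sensors grid per effect, then for
#' each configured analysis window: persistence filtering, neighbour
#' pruning, and the ERD/ERS sign split on subject-level window means.
#'
#' @param frames a [frame_average()] result
#' @param labels labeled trial table rows aligned with the frame grid trials
#'   (needs `choice_type`, `feedback`, `subject_id`)
#' @param windows list as produced by [screen_windows()]
#' @param q FDR level (default 0.05)
#' @return object of class `screen_result`: `p_grid` (effects x frames x
#'   sensors), `fdr_mask` (same shape), `clusters` (per window: sensor sets
#'   and the ERD/ERS split), `windows`, `failed` cells
#' @export
run_screen <- function(frames, labels, windows = screen_windows(), q = 0.05) {
  stopifnot(inherits(frames, "frame_grid"))
  dims <- dim(frames$values)
  n_trials <- dims[1]; n_sens <- dims[2]; n_frames <- dims[3]
  Y <- matrix(frames$values, n_trials, n_sens * n_frames)
  fit <- lmm_grid_screen(Y, labels)
  effects <- colnames(fit$p)
  p_grid <- array(NA_real_, dim = c(3, n_frames, n_sens),
                  dimnames = list(effects, NULL, NULL))
  mask <- array(FALSE, dim = dim(p_grid), dimnames = dimnames(p_grid))
  for (e in seq_along(effects)) {
    pm <- matrix(fit$p[, e], n_sens, n_frames) # cells were sensor-major
    p_grid[e, , ] <- t(pm)
    mask[e, , ] <- fdr_mask(t(pm), q = q)
  }
  subj <- factor(labels$subject_id)
  clusters <- list()
  for (w in names(windows)) {
    eff <- windows[[w]]$effect
    wf <- .window_frames(frames$centers_ms, frames$width_ms,
                         windows[[w]]$window_ms)
    if (!length(wf)) stop("window '", w, "' covers no frames")
    cl <- extract_clusters(mask[eff, , , drop = TRUE][wf, , drop = FALSE],
                           seq_along(wf), frames$layout)
    # subject-level window means, all conditions pooled
    wm <- apply(frames$values[, , wf, drop = FALSE], c(1, 2), mean)
    sm <- rowsum(wm, subj) / as.vector(table(subj))
    split <- if (length(cl)) split_by_sign(cl, sm)
    else list(erd = integer(0), ers = integer(0), dropped = integer(0))
    clusters[[w]] <- list(effect = eff, window_ms = windows[[w]]$window_ms,
                          frames = wf, sensors = cl,
                          erd = split$erd, ers = split$ers,
                          dropped = split$dropped)
  }
  structure(list(p_grid = p_grid, fdr_mask = mask, q = q,
                 clusters = clusters, windows = windows,
                 failed = fit$failed, centers_ms = frames$centers_ms),
            class = "screen_result")
}

#' Simulate a frame grid directly (no spectral synthesis)
#'
#' Generates frame-level dB values from the screening model itself: a
#' subject random intercept plus Gaussian trial noise, with an optional
#' injected effect in chosen sensors/frames given per-condition means. Used
#' for FDR calibration and statistical-power checks at scales where full
#' epoch synthesis would be wasteful, and as the null world for the
#' screening stage.
#'
#' @param labels labeled trial data.frame (`choice_type`, `feedback`,
#'   `subject_id`); one grid row per row of `labels`
#' @param n_sensors,n_frames grid dimensions
#' @param effect optional list(`sensors`, `frames`, `delta`) where `delta`
#'   is a 4 x 2 matrix of condition means (choice type x feedback)
#' @param tau subject intercept SD (default 0.5 dB)
#' @param sigma trial noise SD (default 1 dB)
#' @param seed RNG seed
#' @return trials x sensors x frames array
#' @export
simulate_frame_grid <- function(labels, n_sensors, n_frames, effect = NULL,
                                tau = 0.5, sigma = 1, seed = 1L) {
  set.seed(seed)
  n <- nrow(labels)
  subs <- factor(labels$subject_id)
  u <- stats::rnorm(nlevels(subs), 0, tau)
  vals <- array(stats::rnorm(n * n_sensors * n_frames, 0, sigma),
                dim = c(n, n_sensors, n_frames))
  vals <- vals + u[as.integer(subs)]
  if (!is.null(effect)) {
    d <- as.matrix(effect$delta)
    rownames(d) <- c("HP", "pre-LP", "LP", "post-LP")
    colnames(d) <- c("gain", "loss")
    shift <- d[cbind(match(labels$choice_type, rownames(d)),
                     match(labels$feedback, colnames(d)))]
    vals[, effect$sensors, effect$frames] <-
      vals[, effect$sensors, effect$frames, drop = FALSE] + shift
  }
  vals
}
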