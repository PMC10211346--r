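# deterministic stage-seed derivation: keeps every derived seed a positive
# 32-bit integer, reproducible from (master, salt) alone
.derive_seed <- function(master, salt) {
  x <- (as.numeric(master) %% 2147483647) * 48271 + as.numeric(salt)
  as.integer(x %% 2147483647)
}

#' Full run configuration
#'
#' Bundles every parameter of an end-to-end run: task and agent, sensor
#' layout size, effect templates, noise, multitaper settings, screening
#' windows and FDR level, epoch spans and the master seed from which all
#' stage seeds derive.
#'
#' @param n_subjects cohort size
#' @param task a [task_config()]
#' @param agent an [agent_params()]
#' @param n_sensors combined sensors in the layout (default 102)
#' @param templates list of [effect_template()]s
#' @param noise a [noise_params()]
#' @param tfr a [tfr_params()]
#' @param windows a [screen_windows()] list
#' @param q FDR level
#' @param epoch_ms response-locked epoch span
#' @param baseline_epoch_ms fixation-locked epoch span
#' @param sfreq sampling rate (Hz)
#' @param master_seed master RNG seed (< 2^31)
#' @return object of class `run_config`
#' @export
run_config <- function(n_subjects = 20L, task = task_config(),
                       agent = agent_params(), n_sensors = 102L,
                       templates = default_effect_templates(),
                       noise = noise_params(), tfr = tfr_params(),
                       windows = screen_windows(), q = 0.05,
                       epoch_ms = c(-1750, 2750),
                       baseline_epoch_ms = c(-700, 300),
                       sfreq = 300, master_seed = 1L) {
  cfg <- structure(list(n_subjects = as.integer(n_subjects), task = task,
                        agent = agent, n_sensors = as.integer(n_sensors),
                        templates = templates, noise = noise, tfr = tfr,
                        windows = windows, q = q, epoch_ms = epoch_ms,
                        baseline_epoch_ms = baseline_epoch_ms,
                        sfreq = sfreq, master_seed = as.integer(master_seed)),
                   class = "run_config")
  validate_config(cfg)
}

#' Validate and normalize a run configuration
#'
#' Checks every cross-field invariant (windows inside the epoch span,
#' template windows inside the epoch span, legal scheme order, probabilities
#' in range, feasible outcome interleaving, FDR level in (0, 1), Nyquist)
#' and reports all violations together, each naming the offending field.
#'
#' @param cfg a [run_config()] (or a bare list with the same fields)
#' @return the validated config, invisibly classed `run_config`
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  add <- function(...) errs <<- c(errs, paste0(...))
  if (!inherits(cfg$task, "task_config")) add("task: not a task_config")
  if (!inherits(cfg$agent, "agent_params")) add("agent: not agent_params")
  if (cfg$n_subjects < 1) add("n_subjects: must be >= 1")
  if (cfg$q <= 0 || cfg$q >= 1) add("q: FDR level must be in (0, 1)")
  if (cfg$sfreq < 2 * max(cfg$tfr$freqs_hz))
    add("sfreq: below Nyquist for ", max(cfg$tfr$freqs_hz), " Hz")
  if (inherits(cfg$task, "task_config")) {
    ok <- vapply(.scheme_orders,
                 function(o) identical(o[seq_along(cfg$task$scheme_order)],
                                       cfg$task$scheme_order),
                 logical(1))
    if (!any(ok)) add("task$scheme_order: not one of the three permitted sequences")
    for (nm in names(cfg$task$schemes)) {
      s <- cfg$task$schemes[[nm]]
      n <- cfg$task$trials_per_block
      for (p in c(s$p_gain_advantageous, s$p_gain_disadvantageous)) {
        gains <- round(p * n)
        if (!.outcome_feasible(gains, n - gains, cfg$task$max_outcome_run))
          add("task$schemes$", nm, ": infeasible under max_outcome_run ",
              cfg$task$max_outcome_run)
      }
    }
  }
  for (tp in cfg$templates)
    if (tp$window_ms[1] < cfg$epoch_ms[1] || tp$window_ms[2] > cfg$epoch_ms[2])
      add("templates$", tp$name, ": window [",
          paste(tp$window_ms, collapse = ", "), "] outside epoch span [",
          paste(cfg$epoch_ms, collapse = ", "), "]")
  for (w in names(cfg$windows)) {
    win <- cfg$windows[[w]]$window_ms
    if (win[1] < cfg$epoch_ms[1] + 250 || win[2] > cfg$epoch_ms[2] - 250)
      add("windows$", w, ": [", paste(win, collapse = ", "),
          "] lacks full multitaper support within the epoch")
    if (!cfg$windows[[w]]$effect %in% c("choice_type", "feedback",
                                        "interaction"))
      add("windows$", w, ": unknown effect '", cfg$windows[[w]]$effect, "'")
  }
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  invisible(cfg)
}

#' Write / read the tidy trial table
#'
#' Plain TSV, numeric fidelity float64 (full precision); round-trips
#' identically.
#'
#' @param trials trial table data.frame
#' @param path file path
#' @return (read) the table; (write) the path, invisibly
#' @export
write_trial_table <- function(trials, path) {
  data.table::fwrite(trials, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write / read an epoch array
#'
#' The epoch tensor (trials x sensors x samples) is stored as little-endian
#' float64 with a JSON sidecar (`<path>.json`) recording dims, sampling
#' rate, epoch origin, lock event and trial-row mapping — a self-describing
#' array-file layout. Reading without the sidecar is a schema error.
#'
#' @param epochs an `epoch_set`
#' @param path binary file path (sidecar written at `<path>.json`)
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  meta <- list(format = "betaxplore-epochs", version = 1L,
               dims = dim(epochs$data), sfreq = epochs$sfreq,
               t0_ms = epochs$t0_ms, lock = epochs$lock,
               trial_rows = epochs$trial_rows,
               layout = list(n = epochs$layout$n,
                             positions = epochs$layout$positions,
                             neighbor_threshold = epochs$layout$neighbor_threshold))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("schema error: missing sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$format, "betaxplore-epochs"))
    stop("schema error: not a betaxplore epoch file (format field)")
  need <- c("dims", "sfreq", "t0_ms", "lock")
  if (!all(need %in% names(meta)))
    stop("schema error: sidecar lacks field(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  con <- file(path, "rb")
  on.exit(close(con))
  n <- prod(meta$dims)
  dat <- readBin(con, "double", n = n, size = 8, endian = "little")
  lay <- make_layout(meta$layout$n)
  structure(list(data = array(dat, dim = meta$dims), sfreq = meta$sfreq,
                 t0_ms = meta$t0_ms, lock = meta$lock,
                 trial_rows = meta$trial_rows, layout = lay),
            class = "epoch_set")
}

#' Write / read a screening result as JSON
#'
#' Full-precision JSON serialization of the p-value grid, FDR mask and
#' extracted clusters; re-reading reproduces the cluster sets exactly.
#'
#' @param screen a `screen_result` from [run_screen()]
#' @param path output path
#' @export
write_screen_result <- function(screen, path) {
  stopifnot(inherits(screen, "screen_result"))
  obj <- list(format = "betaxplore-screen", version = 1L,
              dims = dim(screen$p_grid),
              effects = dimnames(screen$p_grid)[[1]],
              p_grid = as.vector(screen$p_grid),
              fdr_mask = as.vector(screen$fdr_mask),
              q = screen$q, centers_ms = screen$centers_ms,
              failed = which(screen$failed),
              clusters = lapply(screen$clusters, function(cl)
                list(effect = cl$effect, window_ms = cl$window_ms,
                     frames = cl$frames, sensors = cl$sensors,
                     erd = cl$erd, ers = cl$ers, dropped = cl$dropped)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_screen_result
#' @export
read_screen_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "betaxplore-screen"))
    stop("schema error: not a betaxplore screen file")
  p_grid <- array(obj$p_grid, dim = obj$dims,
                  dimnames = list(obj$effects, NULL, NULL))
  mask <- array(obj$fdr_mask, dim = obj$dims,
                dimnames = list(obj$effects, NULL, NULL))
  clusters <- lapply(obj$clusters, function(cl) {
    cl$sensors <- as.integer(unlist(cl$sensors))
    cl$erd <- as.integer(unlist(cl$erd))
    cl$ers <- as.integer(unlist(cl$ers))
    cl$dropped <- as.integer(unlist(cl$dropped))
    cl
  })
  failed <- logical(prod(obj$dims[2:3]))
  failed[unlist(obj$failed)] <- TRUE
  structure(list(p_grid = p_grid, fdr_mask = mask, q = obj$q,
                 clusters = clusters, centers_ms = obj$centers_ms,
                 failed = failed),
            class = "screen_result")
}

#' Serialize / restore a run configuration as JSON
#'
#' @param cfg a [run_config()]
#' @param path file path
#' @export
write_config <- function(cfg, path) {
  ser <- list(n_subjects = cfg$n_subjects,
              task = list(n_blocks = cfg$task$n_blocks,
                          trials_per_block = cfg$task$trials_per_block,
                          scheme_order = cfg$task$scheme_order,
                          max_outcome_run = cfg$task$max_outcome_run),
              agent = {
                ag <- unclass(cfg$agent)
                # named vectors serialize nameless as JSON arrays; keep the
                # per-type names by writing an object
                ag$rt_log_mean_by_type <- as.list(ag$rt_log_mean_by_type)
                ag
              },
              n_sensors = cfg$n_sensors,
              templates = lapply(cfg$templates, unclass),
              noise = unclass(cfg$noise),
              tfr = list(freqs_hz = cfg$tfr$freqs_hz,
                         time_bandwidth = cfg$tfr$time_bandwidth,
                         step_ms = cfg$tfr$step_ms),
              windows = cfg$windows, q = cfg$q, epoch_ms = cfg$epoch_ms,
              baseline_epoch_ms = cfg$baseline_epoch_ms, sfreq = cfg$sfreq,
              master_seed = cfg$master_seed)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  run_config(
    n_subjects = o$n_subjects,
    task = task_config(o$task$n_blocks, o$task$trials_per_block,
                       scheme_order = unlist(o$task$scheme_order),
                       max_outcome_run = o$task$max_outcome_run),
    agent = agent_params(o$agent$n_learning_trials,
                         o$agent$p_advantageous_stable,
                         o$agent$p_lp_isolated,
                         unlist(o$agent$rt_log_mean_by_type),
                         o$agent$rt_log_sd),
    n_sensors = o$n_sensors,
    templates = lapply(o$templates, function(tp) {
      as_m42 <- function(x) if (is.matrix(x)) x else
        matrix(unlist(x), 4, 2, byrow = TRUE)
      effect_template(tp$name, unlist(tp$regions), unlist(tp$window_ms),
                      as_m42(tp$delta_db), as_m42(tp$prev_gain_delta),
                      tp$rt_slope, tp$cross_trial_gain)
    }),
    noise = noise_params(unlist(o$noise$beta_band), o$noise$noise_beta_frac,
                         o$noise$subject_gain_sd, o$noise$ramp_ms),
    tfr = tfr_params(freqs_hz = unlist(o$tfr$freqs_hz),
                     time_bandwidth = o$tfr$time_bandwidth,
                     step_ms = o$tfr$step_ms),
    windows = lapply(o$windows, function(w)
      list(window_ms = unlist(w$window_ms), effect = w$effect)),
    q = o$q, epoch_ms = unlist(o$epoch_ms),
    baseline_epoch_ms = unlist(o$baseline_epoch_ms),
    sfreq = o$sfreq, master_seed = o$master_seed)
}
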