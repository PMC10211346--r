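#' Synthetic combined-gradiometer sensor layout
#'
#' A deterministic quasi-uniform arrangement of `n_combined` sensors on the
#' unit disc (a flattened helmet seen from above, nose up: positive y is
#' anterior). Points follow the sunflower (golden-angle) spiral; the neighbor
#' graph connects sensors closer than a distance threshold, chosen by sweeping
#' upward from the median nearest-neighbour distance until every sensor has at
#' least two neighbours. Region masks used for effect injection are angular /
#' positional sectors: `anterior` (front), `posterior` (back) and
#' `left_central` (left middle band); the three masks are disjoint.
#'
#' @param n_combined number of combined sensors (default 102)
#' @param jitter_sd optional positional jitter (fraction of disc radius);
#'   default 0 gives a fully deterministic layout
#' @param seed RNG seed, used only when `jitter_sd > 0`
#' @return object of class `sensor_layout`: `positions` (n x 2 matrix),
#'   `neighbors` (symmetric logical adjacency matrix), `region_masks`
#'   (named list of logical vectors)
#' @export
make_layout <- function(n_combined = 102L, jitter_sd = 0, seed = 1L) {
  stopifnot(n_combined >= 8)
  i <- seq_len(n_combined)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n_combined)
  th <- i * golden
  pos <- cbind(x = r * cos(th), y = r * sin(th))
  if (jitter_sd > 0) {
    set.seed(seed)
    pos <- pos + matrix(stats::rnorm(2 * n_combined, sd = jitter_sd), ncol = 2)
  }
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  thr <- stats::median(nn) * 1.1
  repeat {
    adj <- d <= thr
    if (all(rowSums(adj) >= 2)) break
    thr <- thr * 1.05
  }
  masks <- list(anterior = pos[, "y"] > 0.40,
                posterior = pos[, "y"] < -0.40,
                left_central = pos[, "x"] < -0.45 & abs(pos[, "y"]) <= 0.40)
  structure(list(n = as.integer(n_combined), positions = pos,
                 neighbors = adj, neighbor_threshold = thr,
                 region_masks = masks),
            class = "sensor_layout")
}

#' Sensor indices of one or more named regions
#'
#' @param layout a [make_layout()] object
#' @param regions character vector of region names
#' @return sorted integer vector of sensor indices in the union of regions
#' @export
region_sensors <- function(layout, regions) {
  stopifnot(inherits(layout, "sensor_layout"))
  bad <- setdiff(regions, names(layout$region_masks))
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  m <- Reduce(`|`, layout$region_masks[regions])
  sort(which(m))
}

#' Plot a sensor topography
#'
#' Draws sensors on the flattened-helmet disc, coloured by `values`
#' (blue = negative / ERD, red = positive / ERS), optionally ringing a set of
#' highlighted sensors (e.g. a recovered cluster).
#'
#' @param layout a [make_layout()] object
#' @param values numeric per-sensor values (optional)
#' @param highlight integer sensor indices to ring
#' @param main plot title
#' @return invisibly, the colour values used
#' @export
plot_topomap <- function(layout, values = NULL, highlight = integer(0),
                         main = "") {
  pos <- layout$positions
  graphics::plot(pos, asp = 1, pch = 21, cex = 1.6, main = main,
                 xlab = "", ylab = "", axes = FALSE,
                 bg = if (is.null(values)) "grey80" else {
                   v <- values / max(abs(values), 1e-12)
                   grDevices::rgb(pmax(v, 0), 0, pmax(-v, 0), alpha = 0.8)
                 })
  graphics::symbols(0, 0, circles = 1.05, inches = FALSE, add = TRUE)
  if (length(highlight))
    graphics::points(pos[highlight, , drop = FALSE], pch = 1, cex = 2.4,
                     lwd = 2, col = "darkgreen")
  invisible(values)
}
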