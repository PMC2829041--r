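#' Velocity map (kymograph) object
#'
#' A positions-by-time matrix of edge velocities (nm/s) with an optional
#' mask of invalid cells (e.g. positions where edge tracking failed).
#' Masked cells carry no velocity information and break connectivity in
#' event segmentation.
#'
#' @param v Numeric matrix, rows = positions along the edge, columns =
#'   time points.
#' @param mask Logical matrix of the same dimension; `TRUE` marks invalid
#'   cells. Default: no masked cells.
#' @param t,y Optional time (min) and position (um) coordinates.
#' @return An object of class `velocity_map`.
#' @export
velocity_map <- function(v, mask = NULL, t = NULL, y = NULL) {
  v <- as.matrix(v)
  if (!is.numeric(v)) stop("v must be a numeric matrix")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(v), ncol(v))
  mask <- as.matrix(mask)
  if (!is.logical(mask) || !identical(dim(mask), dim(v)))
    stop("mask must be a logical matrix with the same dimensions as v")
  if (any(!is.finite(v[!mask]))) stop("unmasked velocities must be finite")
  if (is.null(t)) t <- seq_len(ncol(v)) - 1
  if (is.null(y)) y <- seq_len(nrow(v)) - 1
  if (length(t) != ncol(v) || length(y) != nrow(v))
    stop("t and y must match the matrix dimensions")
  structure(list(v = v, mask = mask, t = as.numeric(t), y = as.numeric(y)),
            class = "velocity_map")
}

#' @export
print.velocity_map <- function(x, ...) {
  cat(sprintf("velocity map: %d positions x %d time points, %d masked cells\n",
              nrow(x$v), ncol(x$v), sum(x$mask)))
  cat(sprintf("  v range (unmasked): [%.3g, %.3g] nm/s\n",
              min(x$v[!x$mask]), max(x$v[!x$mask])))
  invisible(x)
}

#' Moving-average smoothing of a velocity trace
#'
#' Centered moving average with a window that shrinks symmetrically near
#' the trace boundaries (no padding, no phase shift): sample `i` is
#' averaged over `[i - h, i + h]` with `h = min(floor(window/2), i - 1,
#' n - i)`.
#'
#' @param v Numeric vector.
#' @param window Window width in samples (default 20, i.e. 10 min at the
#'   default 0.5-min sampling).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_trace <- function(v, window = 20) {
  n <- length(v)
  if (window < 1) stop("window must be >= 1")
  h <- window %/% 2
  if (h == 0 || n == 0) return(v)
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  hh <- pmin(h, i - 1L, n - i)
  (cs[i + hh + 1] - cs[i - hh]) / (2 * hh + 1)
}

#' Classify a protrusion-velocity trace into a motility phenotype
#'
#' Applies a fixed rule set to the post-burn-in, smoothed trace:
#' \describe{
#'   \item{`minimal_protrusion`}{low baseline (median below `v_threshold`)
#'     and no excursion ever exceeds the threshold.}
#'   \item{`transient_protrusions`}{low baseline interrupted by excursions
#'     above the threshold.}
#'   \item{`stable_protrusion`}{high baseline with no pause of at least
#'     `pause_min` minutes below the threshold.}
#'   \item{`protrusion_with_pauses`}{high baseline interrupted by at least
#'     one such pause.}
#' }
#'
#' @param v Velocity trace (dimensionless model velocity, 0..1).
#' @param t Sample times (min), uniformly spaced.
#' @param burn_in Initial transient to discard (min, default 100).
#' @param v_threshold Low/high split (default 0.5).
#' @param pause_min Minimum pause duration (min, default 2).
#' @param window Smoothing window in samples, passed to [smooth_trace()].
#' @return A single character label.
#' @export
classify_trace <- function(v, t, burn_in = 100, v_threshold = 0.5,
                           pause_min = 2, window = 20) {
  if (length(v) != length(t)) stop("v and t must have equal length")
  keep <- t >= burn_in
  if (sum(keep) < 2) stop("trace too short for the requested burn_in")
  vs <- smooth_trace(v[keep], window = window)
  tt <- t[keep]
  hi <- vs > v_threshold
  if (stats::median(vs) <= v_threshold) {
    if (any(hi)) "transient_protrusions" else "minimal_protrusion"
  } else {
    r <- rle(!hi)
    dt <- tt[2] - tt[1]
    pause <- any(r$values & (r$lengths * dt >= pause_min))
    if (pause) "protrusion_with_pauses" else "stable_protrusion"
  }
}

# internal: label 4-connected components of `active` cells (masked cells
# are never active) by breadth-first flood fill
flood_fill_label <- function(active) {
  ny <- nrow(active); nt <- ncol(active)
  labels <- matrix(0L, ny, nt)
  next_label <- 0L
  queue <- integer(length(active))
  for (start in which(active & labels == 0L)) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    labels[start] <- next_label
    queue[1] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      idx <- queue[head]; head <- head + 1L
      i <- ((idx - 1L) %% ny) + 1L
      j <- ((idx - 1L) %/% ny) + 1L
      for (nb in c(if (i > 1L) idx - 1L, if (i < ny) idx + 1L,
                   if (j > 1L) idx - ny, if (j < nt) idx + ny)) {
        if (active[nb] && labels[nb] == 0L) {
          labels[nb] <- next_label
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }
  labels
}

#' Segment protrusion events in a velocity map
#'
#' Two-threshold (hysteresis) segmentation: cells with velocity at or above
#' `low` are grouped into 4-connected components (no diagonal adjacency;
#' masked cells break connectivity), and a component is accepted as a
#' protrusion event only if it contains at least one cell at or above
#' `high`. This keeps the full spatial-temporal extent of an event while
#' rejecting patches of weak activity that never reach a clear protrusion
#' speed.
#'
#' @param map A [velocity_map()] (velocities in nm/s).
#' @param low,high Thresholds in nm/s (defaults 1 and 5); `low <= high`
#'   required.
#' @return A list of class `protrusion_events`: `labels` (integer matrix, 0
#'   outside events, `1..n_events` inside, events ordered by first cell in
#'   column-major order), `n_events`, and `events`, a data.frame with one
#'   row per event (`id`, `n_cells`, `max_v`, `t_start`, `t_end`,
#'   `activity` = sum of `v - low` over the event's cells).
#' @export
segment_protrusion_events <- function(map, low = 1, high = 5) {
  stopifnot(inherits(map, "velocity_map"))
  if (!is.finite(low) || !is.finite(high) || low > high)
    stop("thresholds must be finite with low <= high")
  active <- (map$v >= low) & !map$mask
  comp <- flood_fill_label(active)
  n_comp <- max(comp)
  labels <- matrix(0L, nrow(comp), ncol(comp))
  keep_ids <- integer(0)
  if (n_comp > 0) {
    has_core <- vapply(seq_len(n_comp), function(k)
      any(map$v[comp == k] >= high), logical(1))
    keep_ids <- which(has_core)
    for (new_id in seq_along(keep_ids))
      labels[comp == keep_ids[new_id]] <- new_id
  }
  ev <- lapply(seq_along(keep_ids), function(new_id) {
    cells <- which(labels == new_id)
    cols <- ((cells - 1L) %/% nrow(labels)) + 1L
    data.frame(id = new_id, n_cells = length(cells),
               max_v = max(map$v[cells]),
               t_start = min(map$t[cols]), t_end = max(map$t[cols]),
               activity = sum(map$v[cells] - low))
  })
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(id = integer(0), n_cells = integer(0), max_v = numeric(0),
               t_start = numeric(0), t_end = numeric(0), activity = numeric(0))
  structure(list(labels = labels, n_events = length(keep_ids), events = events,
                 low = low, high = high),
            class = "protrusion_events")
}

#' @export
print.protrusion_events <- function(x, ...) {
  cat(sprintf("protrusion events: %d event(s) (low = %g, high = %g nm/s)\n",
              x$n_events, x$low, x$high))
  if (x$n_events > 0) print.data.frame(x$events)
  invisible(x)
}

#' Total protrusive activity of a velocity map
#'
#' Sums the above-low-threshold velocity excess (`v - low`) over all cells
#' belonging to accepted protrusion events, i.e. the summed `activity`
#' column of [segment_protrusion_events()]. Weak activity outside events
#' contributes nothing.
#'
#' @inheritParams segment_protrusion_events
#' @return A single non-negative number (nm/s summed over event cells).
#' @export
total_protrusive_activity <- function(map, low = 1, high = 5) {
  seg <- segment_protrusion_events(map, low = low, high = high)
  sum(seg$events$activity)
}

#' Synthetic velocity-map generator with ground truth
#'
#' Generates a seeded random kymograph emulating edge-velocity maps from
#' live-cell imaging: a quiet background below the low threshold,
#' rectangular protrusion events (a core above the high threshold wrapped
#' in a rim of intermediate velocity), and optional masked cells away from
#' the events. Events are placed with at least one cell of clearance, so
#' the ground-truth labeling has exactly `n_events` 4-connected components;
#' if the requested events cannot be placed without overlap the generator
#' fails rather than returning a map with fewer events.
#'
#' @param n_y,n_t Map dimensions (positions, time points).
#' @param n_events Number of events to place.
#' @param seed Integer RNG seed.
#' @param low,high Thresholds the map is built around (nm/s).
#' @param event_size Integer 2-vector: maximum event extent in positions
#'   and time points (minimum is 2 x 2 to fit a core).
#' @param n_masked Number of masked background cells (placed at least one
#'   cell away from every event).
#' @return A [velocity_map()] with extra attributes `truth` (integer
#'   ground-truth label matrix) and `n_events`.
#' @export
make_synthetic_velocity_map <- function(n_y, n_t, n_events, seed,
                                        low = 1, high = 5,
                                        event_size = c(6, 10), n_masked = 0) {
  if (n_y < 3 || n_t < 3) stop("map too small")
  if (n_events < 0) stop("n_events must be non-negative")
  if (length(event_size) != 2 || any(event_size < 2))
    stop("event_size must be two integers >= 2")
  set.seed(seed)
  rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  v <- matrix(runif(n_y * n_t, 0, 0.5 * low), n_y, n_t)
  truth <- matrix(0L, n_y, n_t)
  occupied <- matrix(FALSE, n_y, n_t) # events plus one-cell clearance
  for (k in seq_len(n_events)) {
    placed <- FALSE
    for (attempt in 1:200) {
      hy <- rint(2L, min(event_size[1], n_y))
      ht <- rint(2L, min(event_size[2], n_t))
      i0 <- rint(1L, n_y - hy + 1L)
      j0 <- rint(1L, n_t - ht + 1L)
      ii <- i0:(i0 + hy - 1); jj <- j0:(j0 + ht - 1)
      if (any(occupied[ii, jj])) next
      # rim between the thresholds, core above high
      v[ii, jj] <- runif(hy * ht, 1.2 * low, 0.9 * high)
      ci <- ii[1 + (length(ii) - 1) %/% 2]
      cj <- jj[1 + (length(jj) - 1) %/% 2]
      v[ci, cj] <- runif(1, 1.2 * high, 2 * high)
      truth[ii, jj] <- k
      gi <- max(1, i0 - 1):min(n_y, i0 + hy)
      gj <- max(1, j0 - 1):min(n_t, j0 + ht)
      occupied[gi, gj] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", n_events, " non-overlapping events on a ",
           n_y, " x ", n_t, " map")
  }
  mask <- matrix(FALSE, n_y, n_t)
  if (n_masked > 0) {
    free <- which(!occupied)
    if (length(free) < n_masked)
      stop("not enough free cells for the requested mask")
    mask[free[sample.int(length(free), n_masked)]] <- TRUE
  }
  out <- velocity_map(v, mask = mask)
  attr(out, "truth") <- truth
  attr(out, "n_events") <- as.integer(n_events)
  out
}
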