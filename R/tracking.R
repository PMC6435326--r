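#' Construct a cell track
#'
#' An ordered series of 3D nucleus positions for one cell, with timestamps.
#'
#' @param track_id identifier string.
#' @param frames integer frame indices (same length as times).
#' @param times timestamps in seconds, strictly increasing.
#' @param positions numeric matrix (n x 3) of x/y/z coordinates in
#'   micrometres.
#' @return object of class `track`.
#' @export
track <- function(track_id, frames, times, positions) {
  positions <- as.matrix(positions)
  if (!is.numeric(times) || length(times) < 2L) {
    stop_invalid("a track needs at least 2 time points")
  }
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  if (!is.numeric(positions) || ncol(positions) != 3L ||
      nrow(positions) != length(times) || any(!is.finite(positions))) {
    stop_invalid("positions must be a finite numeric matrix with 3 columns, one row per time")
  }
  if (length(frames) != length(times)) {
    stop_invalid("frames and times must have equal length")
  }
  structure(list(track_id = as.character(track_id),
                 frames = as.integer(frames),
                 times = as.numeric(times), positions = positions),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("Track %s: %d points, %.1f s to %.1f s\n", x$track_id,
              length(x$times), x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

check_uniform_dt <- function(tr) {
  dts <- diff(tr$times)
  if (any(abs(dts - dts[1L]) > 1e-6 * dts[1L])) {
    stop_invalid("track times must be uniformly spaced")
  }
  dts[1L]
}

#' Instantaneous speeds along a track
#'
#' Per-step speed `|p[i+1] - p[i]| / (t[i+1] - t[i])` converted to
#' micrometres per minute. Requires uniformly spaced, strictly increasing
#' timestamps.
#'
#' @param tr a [track()].
#' @return numeric vector of length `n_points - 1`, in um/min.
#' @export
instantaneous_speeds <- function(tr) {
  if (!inherits(tr, "track")) stop_invalid("tr must be a track object")
  check_uniform_dt(tr)
  steps <- diff(tr$positions)
  dists <- sqrt(rowSums(steps^2))
  dists / diff(tr$times) * 60
}

#' Condition-level mean speed over a set of tracks
#'
#' Each track contributes one vote: its instantaneous speeds are averaged
#' first, then the per-track means are averaged across tracks. The standard
#' error is computed over tracks; with a single track it is `NA` and the
#' result is flagged.
#'
#' @param tracks list of [track()] objects.
#' @return list with `mean`, `se`, `n_tracks`, `track_means` and
#'   `single_track` flag; speeds in um/min.
#' @export
condition_mean_speed <- function(tracks) {
  if (!is.list(tracks) || length(tracks) == 0L) {
    stop_invalid("tracks must be a non-empty list of track objects")
  }
  track_means <- vapply(tracks, function(tr) mean(instantaneous_speeds(tr)),
                        numeric(1))
  n <- length(track_means)
  list(mean = mean(track_means),
       se = if (n > 1L) stats::sd(track_means) / sqrt(n) else NA_real_,
       n_tracks = n, track_means = track_means, single_track = n == 1L)
}

#' Directionality of a track over fixed-length segments
#'
#' The trajectory is split into segments of `window` frames; per segment the
#' directionality is the straight-line distance from segment start to end
#' divided by the summed step path length, so 1 is perfectly straight motion
#' and values near 0 indicate wandering. Segment values are averaged over
#' the track. A stationary segment (zero path length) is defined as 0 and
#' counted in the `n_zero_path` attribute. The default splits the track into
#' non-overlapping consecutive segments; `overlapping = TRUE` slides the
#' window one frame at a time instead. Trailing frames short of a full
#' window are dropped.
#'
#' @param tr a [track()].
#' @param window segment length in frames (number of positions per segment).
#' @param overlapping slide the window by one frame instead of tiling.
#' @return mean segment directionality in `[0, 1]`, with attributes
#'   `segment_values`, `n_zero_path` and `windowing`.
#' @export
directionality <- function(tr, window = 10L, overlapping = FALSE) {
  if (!inherits(tr, "track")) stop_invalid("tr must be a track object")
  if (!is_count(window) || window < 2) {
    stop_invalid("window must be an integer >= 2")
  }
  n <- nrow(tr$positions)
  if (n < window) {
    stop_invalid("track shorter than the segment window",
                 class = "gt_track_too_short")
  }
  starts <- if (overlapping) seq_len(n - window + 1L)
    else seq(1L, n - window + 1L, by = window - 1L)
  # non-overlapping tiling: consecutive segments share their boundary frame,
  # covering every step exactly once
  vals <- vapply(starts, function(s) {
    seg <- tr$positions[s:(s + window - 1L), , drop = FALSE]
    path <- sum(sqrt(rowSums(diff(seg)^2)))
    if (path == 0) return(0)
    net <- sqrt(sum((seg[window, ] - seg[1L, ])^2))
    net / path
  }, numeric(1))
  structure(mean(vals), segment_values = vals,
            n_zero_path = sum(vals == 0 &
                                vapply(starts, function(s) {
                                  seg <- tr$positions[s:(s + window - 1L), ,
                                                      drop = FALSE]
                                  sum(abs(diff(seg))) == 0
                                }, logical(1))),
            windowing = if (overlapping) "sliding" else "tiled")
}

#' Mean directionality over a condition
#'
#' Averages [directionality()] over tracks, one vote per track; tracks
#' shorter than the window are excluded and reported.
#'
#' @param tracks list of [track()] objects.
#' @inheritParams directionality
#' @return list with `mean`, `se`, `n_tracks`, `n_excluded`, `track_values`.
#' @export
condition_directionality <- function(tracks, window = 10L,
                                     overlapping = FALSE) {
  if (!is.list(tracks) || length(tracks) == 0L) {
    stop_invalid("tracks must be a non-empty list of track objects")
  }
  vals <- rep(NA_real_, length(tracks))
  for (i in seq_along(tracks)) {
    v <- tryCatch(directionality(tracks[[i]], window, overlapping),
                  gt_track_too_short = function(e) NA_real_)
    vals[i] <- as.numeric(v)
  }
  keep <- !is.na(vals)
  if (!any(keep)) stop_invalid("no track is at least `window` frames long")
  v <- vals[keep]
  list(mean = mean(v),
       se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
       n_tracks = length(v), n_excluded = sum(!keep), track_values = vals)
}

#' Tissue entry time from boundary crossings
#'
#' T0 is the earliest time any track satisfies the edge predicate (a nucleus
#' reaches the tissue boundary); T1 the earliest time any track satisfies
#' the inside predicate (a nucleus is just within the tissue). The two
#' events may come from different tracks. The entry time is `T1 - T0` in
#' minutes. The boundary is supplied externally, either as two predicate
#' functions taking a position matrix and returning a logical per row, or as
#' a planar threshold specification
#' `list(axis = "x"|"y"|"z", edge = e, inside = i, direction = ">="|"<=")`.
#'
#' @param tracks list of [track()] objects.
#' @param boundary predicate pair `list(at_edge = f, inside = g)` or a planar
#'   threshold specification (see details).
#' @return list of class `entry_time` with `t_edge`, `t_inside` (minutes)
#'   and `entry_min = t_inside - t_edge`.
#' @export
germband_entry_time <- function(tracks, boundary) {
  if (!is.list(tracks) || length(tracks) == 0L) {
    stop_invalid("tracks must be a non-empty list of track objects")
  }
  preds <- boundary_predicates(boundary)
  first_time <- function(pred) {
    t_min <- Inf
    for (tr in tracks) {
      hit <- which(pred(tr$positions))
      if (length(hit)) t_min <- min(t_min, tr$times[hit[1L]])
    }
    t_min
  }
  t_edge <- first_time(preds$at_edge)
  t_inside <- first_time(preds$inside)
  if (!is.finite(t_edge) || !is.finite(t_inside)) {
    stop(errorCondition("no track crosses the boundary",
                        class = c("gt_no_entry", "gt_error")))
  }
  if (t_inside < t_edge) {
    stop_invalid("inside crossing precedes edge crossing; check the boundary definition")
  }
  structure(list(t_edge = t_edge / 60, t_inside = t_inside / 60,
                 entry_min = (t_inside - t_edge) / 60),
            class = "entry_time")
}

#' @export
print.entry_time <- function(x, ...) {
  cat(sprintf("Edge reached at %.2f min, inside at %.2f min: entry time %.2f min\n",
              x$t_edge, x$t_inside, x$entry_min))
  invisible(x)
}

boundary_predicates <- function(boundary) {
  if (is.list(boundary) && is.function(boundary$at_edge) &&
      is.function(boundary$inside)) {
    return(boundary)
  }
  if (is.list(boundary) && !is.null(boundary$axis)) {
    ax <- match(boundary$axis, c("x", "y", "z"))
    if (is.na(ax)) stop_invalid("boundary axis must be x, y or z")
    dir <- if (is.null(boundary$direction)) ">=" else boundary$direction
    cmp <- switch(dir, ">=" = `>=`, "<=" = `<=`,
                  stop_invalid("boundary direction must be '>=' or '<='"))
    return(list(
      at_edge = function(p) cmp(p[, ax], boundary$edge),
      inside = function(p) cmp(p[, ax], boundary$inside)
    ))
  }
  stop_invalid("boundary must be predicate functions or a planar threshold spec")
}

#' Percent reduction of a test mean relative to control
#'
#' `round((control - test) / control * 100)` to the nearest integer, the
#' form in which condition-level speed differences are reported.
#'
#' @param control_mean positive control condition mean.
#' @param test_mean test condition mean.
#' @return integer percent reduction (negative if the test mean is larger).
#' @examples
#' percent_reduction(2.72, 1.55)  # 43
#' percent_reduction(2.46, 2.02)  # 18
#' @export
percent_reduction <- function(control_mean, test_mean) {
  if (!is.numeric(control_mean) || length(control_mean) != 1L ||
      !is.finite(control_mean) || control_mean <= 0) {
    stop_invalid("control_mean must be a single positive number")
  }
  if (!is.numeric(test_mean) || length(test_mean) != 1L ||
      !is.finite(test_mean)) {
    stop_invalid("test_mean must be a single finite number")
  }
  as.integer(round((control_mean - test_mean) / control_mean * 100))
}
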