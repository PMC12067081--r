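#' Per-frame kinematic series from a midline sequence
#'
#' Computes, per frame:
#' * `speed` (m/s): magnitude of the centred-difference velocity of the
#'   centroid after local quadratic (Savitzky-Golay) smoothing of the
#'   centroid path — the smoothing suppresses pixel-quantisation jitter at
#'   200-923 fps;
#' * `heading` (radians): direction from the 75%-arclength point to the
#'   head;
#' * `bend_angle` (degrees, signed): angle between the chord of the first
#'   20% and the chord of the last 20% of arclength;
#' * `curvature` (1/m): per-point signed curvature from finite differences
#'   of the arclength-parameterised midline (rows = frames).
#'
#' @param midlines a [midline_sequence()].
#' @param smooth_window centroid smoothing window in frames (odd; default 5).
#' @param chord_frac arclength fraction of the head/tail chords.
#' @return object of class `kinematic_series`: list with `speed`, `heading`,
#'   `bend_angle`, `curvature`, `centroid`, `frame_rate`.
#' @export
compute_kinematics <- function(midlines, smooth_window = 5, chord_frac = 0.2) {
  stopifnot(inherits(midlines, "midline_sequence"))
  nf <- n_frames(midlines)
  if (nf < 3) stop("need at least 3 frames")
  fr <- midlines$frame_rate
  cx <- rowMeans(midlines$points[, , 1, drop = FALSE], dims = 1)
  cy <- rowMeans(midlines$points[, , 2, drop = FALSE], dims = 1)
  win <- min(smooth_window, if (nf %% 2 == 1) nf else nf - 1)
  if (win >= 3 && win %% 2 == 1 && nf > win) {
    cx <- signal::sgolayfilt(cx, p = 2, n = win)
    cy <- signal::sgolayfilt(cy, p = 2, n = win)
  }
  vx <- centred_diff(cx) * fr
  vy <- centred_diff(cy) * fr
  geo <- series_geometry(midlines$points, chord_frac)
  structure(list(speed = sqrt(vx^2 + vy^2), velocity = cbind(vx, vy),
                 heading = geo$heading, bend_angle = geo$bend * 180 / pi,
                 curvature = geo$curvature,
                 centroid = cbind(cx, cy), frame_rate = fr),
            class = "kinematic_series")
}

centred_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

#' Activity fraction of a recording
#'
#' Fraction of video frames in which swimming speed strictly exceeded the
#' threshold (0.025 m/s in the source assay), normalised to the recording
#' period: frames above threshold divided by `period * frame_rate`.
#'
#' @param series a [compute_kinematics()] result.
#' @param threshold speed threshold, m/s.
#' @param period recording period, s; defaults to the series duration.
#' @return fraction in `[0, 1]`.
#' @export
activity_fraction <- function(series, threshold = 0.025, period = NULL) {
  stopifnot(inherits(series, "kinematic_series"))
  n <- length(series$speed)
  if (n == 0) stop("empty kinematic series")
  if (is.null(period)) period <- n / series$frame_rate
  if (period <= 0) stop("period must be > 0")
  min(1, sum(series$speed > threshold) / (period * series$frame_rate))
}

#' Detect body-bend events
#'
#' A bend is one tail-beat half cycle: a local extremum of the signed
#' head-tail bend angle. Extrema are kept when the swing from the previous
#' accepted extremum is at least `min_amplitude` (a hysteresis rule, which
#' is what "prominence" means for an alternating signal) and events are at
#' least `min_interval` apart.
#'
#' @param series a [compute_kinematics()] result.
#' @param min_amplitude minimum swing, degrees (> 0; default 10).
#' @param min_interval minimum event spacing, s.
#' @param smooth_s Savitzky-Golay pre-smoothing window in seconds (local
#'   quadratic); suppresses frame-to-frame tracking jitter that would
#'   otherwise split one bend into several. 0 disables.
#' @return object of class `bend_events`: list with `times` (s, strictly
#'   increasing) and `amplitudes` (degrees, > 0, `|bend|` at the extremum).
#' @export
detect_bends <- function(series, min_amplitude = 10, min_interval = 0.02,
                         smooth_s = 0.05) {
  stopifnot(inherits(series, "kinematic_series"))
  if (min_amplitude <= 0) stop("min_amplitude must be > 0")
  b <- series$bend_angle
  fr <- series$frame_rate
  n <- length(b)
  if (smooth_s > 0) {
    win <- max(5, round(smooth_s * fr))
    if (win %% 2 == 0) win <- win + 1
    if (n > win) b <- signal::sgolayfilt(b, p = 2, n = win)
  }
  idx <- integer(0)
  if (n >= 3) {
    d <- diff(b)
    ext <- which(d[-length(d)] * d[-1] <= 0 & d[-length(d)] != 0) + 1L
    # turning-point filter with hysteresis: an extremum counts when the
    # swing from the previously committed extremum reaches min_amplitude;
    # a pending extremum is extended while the excursion keeps growing
    anchor <- b[1]; pend <- NA_integer_; pdir <- 0
    for (i in ext) {
      if (is.na(pend)) {
        sw <- b[i] - anchor
        if (abs(sw) >= min_amplitude) { pend <- i; pdir <- sign(sw) }
      } else if (sign(b[i] - b[pend]) == pdir) {
        pend <- i                                   # excursion grew further
      } else if (abs(b[i] - b[pend]) >= min_amplitude) {
        idx <- c(idx, pend)                         # genuine reversal: commit
        anchor <- b[pend]; pend <- i; pdir <- -pdir
      }                                             # else: sub-threshold wiggle
    }
    if (!is.na(pend)) idx <- c(idx, pend)
  }
  times <- (idx - 1) / fr
  amps <- abs(b[idx])
  if (length(times) > 1 && min_interval > 0) {
    sel <- 1L; acc_t <- times[1]
    for (j in seq_along(times)[-1])
      if (times[j] - acc_t >= min_interval) { sel <- c(sel, j); acc_t <- times[j] }
    times <- times[sel]; amps <- amps[sel]
  }
  structure(list(times = times, amplitudes = amps), class = "bend_events")
}

#' Propulsion efficiency
#'
#' Primary orientation: forward distance covered per body bend (metres per
#' bend), so that fish that must bend more to cover the same distance score
#' lower. The variant `per_degree` is the distance per degree of summed
#' bend amplitude; `bends_per_m` exposes the literal inverse. With zero
#' bends and nonzero distance the value is undefined (a glide) and is
#' flagged rather than reported as 0.
#'
#' @param path_length distance covered in the window, m.
#' @param bends a [detect_bends()] result.
#' @param window time window, s (> 0).
#' @return list with `m_per_bend`, `m_per_degree`, `bends_per_m`,
#'   `n_bends`, and logical `defined`.
#' @export
propulsion_efficiency <- function(path_length, bends, window) {
  stopifnot(inherits(bends, "bend_events"))
  if (window <= 0) stop("window must be > 0")
  in_win <- bends$times < window
  nb <- sum(in_win)
  if (nb == 0) {
    return(list(m_per_bend = NA_real_, m_per_degree = NA_real_,
                bends_per_m = NA_real_, n_bends = 0L,
                defined = path_length == 0))
  }
  list(m_per_bend = path_length / nb,
       m_per_degree = path_length / sum(bends$amplitudes[in_win]),
       bends_per_m = nb / path_length,
       n_bends = nb, defined = TRUE)
}

#' Thrust series
#'
#' Signed component of the centroid velocity along the current heading;
#' forward positive.
#'
#' @param series a [compute_kinematics()] result.
#' @return numeric vector, m/s per frame.
#' @export
thrust_series <- function(series) {
  stopifnot(inherits(series, "kinematic_series"))
  series$velocity[, 1] * cos(series$heading) +
    series$velocity[, 2] * sin(series$heading)
}

#' Median curvature amplitude inside a response window
#'
#' Median of the per-extremum `|bend angle|` amplitudes whose event times
#' fall inside the window. Undefined (flagged) when the window contains no
#' extrema.
#'
#' @param series a [compute_kinematics()] result.
#' @param response_window `c(start, end)` in seconds.
#' @param min_amplitude passed to [detect_bends()].
#' @return list with `value` (degrees or NA) and `defined`.
#' @export
median_curvature_amplitude <- function(series, response_window,
                                       min_amplitude = 10) {
  stopifnot(inherits(series, "kinematic_series"))
  bends <- detect_bends(series, min_amplitude = min_amplitude)
  sel <- bends$times >= response_window[1] & bends$times < response_window[2]
  if (!any(sel)) return(list(value = NA_real_, defined = FALSE))
  list(value = stats::median(bends$amplitudes[sel]), defined = TRUE)
}

#' Mean distance to the stream centreline
#'
#' @param centroids data.frame with `x_m`, `y_m` (or 2-column matrix).
#' @param centreline list with `point` (length-2, m) and `direction`
#'   (length-2, need not be unit).
#' @return mean perpendicular distance, m.
#' @export
distance_to_stream_centre <- function(centroids, centreline) {
  p <- as.matrix(if (is.data.frame(centroids))
    centroids[, c("x_m", "y_m")] else centroids)
  if (nrow(p) < 1) stop("need at least one centroid")
  d <- centreline$direction / sqrt(sum(centreline$direction^2))
  rel <- sweep(p, 2, centreline$point)
  mean(abs(rel[, 1] * d[2] - rel[, 2] * d[1]))
}

#' Positional occupancy map with marginals
#'
#' 2D histogram of centroid positions over the arena, normalised to total
#' mass 1; marginal densities are the axis sums of the grid.
#'
#' @param centroids data.frame with `x_m`, `y_m` (or 2-column matrix).
#' @param xlim,ylim arena extent, m.
#' @param bins `c(nx, ny)` bin counts, each >= 2.
#' @return object of class `occupancy_map`: list with `grid` (ny x nx,
#'   rows = y), `x_edges`, `y_edges`, `x_marginal`, `y_marginal`.
#' @export
occupancy_map <- function(centroids, xlim, ylim, bins = c(40, 20)) {
  p <- as.matrix(if (is.data.frame(centroids))
    centroids[, c("x_m", "y_m")] else centroids)
  if (any(bins < 2)) stop("need at least 2 bins per axis")
  out_n <- sum(p[, 1] < xlim[1] | p[, 1] > xlim[2] |
               p[, 2] < ylim[1] | p[, 2] > ylim[2])
  if (out_n > 0)
    stop(out_n, " positions fall outside the arena bounds")
  xe <- seq(xlim[1], xlim[2], length.out = bins[1] + 1)
  ye <- seq(ylim[1], ylim[2], length.out = bins[2] + 1)
  ix <- pmin(findInterval(p[, 1], xe, rightmost.closed = TRUE), bins[1])
  iy <- pmin(findInterval(p[, 2], ye, rightmost.closed = TRUE), bins[2])
  grid <- matrix(tabulate((ix - 1L) * bins[2] + iy, nbins = prod(bins)),
                 bins[2], bins[1])
  grid <- grid / sum(grid)
  structure(list(grid = grid, x_edges = xe, y_edges = ye,
                 x_marginal = colSums(grid), y_marginal = rowSums(grid)),
            class = "occupancy_map")
}
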