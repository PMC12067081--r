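#' Parameters of the synthetic undulatory swimmer
#'
#' The swimmer is a travelling tangent-angle wave: the body tangent at
#' arclength `s` (0 = head) and time `t` deviates from the heading by
#' `phi(s, t) = E(s) * A * sin(2*pi*(f*t - s/lambda))`, where `E(s)` is a
#' monotone head-to-tail amplitude envelope, `A` the peak tail amplitude
#' (radians), `f` the tail-beat frequency and `lambda` the body wavelength
#' in metres. Forward speed is coupled to the wave as
#' `v = slip * f * lambda * A`, the simplest model in which forward
#' movement is proportional to both the wave speed and the extent of body
#' bending. Defaults emulate an adult zebrafish cruising in a shallow
#' arena filmed at 200 frames/s for 30 s.
#'
#' @param body_length body length in metres.
#' @param n_points number of midline samples (>= 5).
#' @param bend_amplitude peak tangent-angle amplitude at the tail, radians.
#' @param tailbeat_freq tail-beat frequency, Hz (>= 0).
#' @param body_wavelength undulation wavelength as a fraction of body length.
#' @param amplitude_envelope function of arclength fraction in `[0, 1]`
#'   returning a multiplier in `[0, 1]`, non-decreasing head to tail.
#' @param slip dimensionless slip factor in (0, 1] coupling forward speed to
#'   wave speed.
#' @param frame_rate video frame rate, Hz.
#' @param duration recording duration, s.
#' @param heading initial heading, radians (image convention, x right, y down).
#' @param start head position at t = 0, metres, length-2.
#' @param seed integer seed; every simulation is bit-reproducible given it.
#' @return a `swimmer_params` list.
#' @export
swimmer_params <- function(body_length = 0.03,
                           n_points = 51,
                           bend_amplitude = 0.5,
                           tailbeat_freq = 5,
                           body_wavelength = 0.95,
                           amplitude_envelope = function(u) 0.1 + 0.9 * u,
                           slip = 0.7,
                           frame_rate = 200,
                           duration = 30,
                           heading = 0,
                           start = c(0, 0),
                           seed = 1L) {
  p <- list(body_length = body_length, n_points = as.integer(n_points),
            bend_amplitude = bend_amplitude, tailbeat_freq = tailbeat_freq,
            body_wavelength = body_wavelength,
            amplitude_envelope = amplitude_envelope, slip = slip,
            frame_rate = frame_rate, duration = duration,
            heading = heading, start = start, seed = as.integer(seed))
  validate_swimmer_params(p)
  structure(p, class = "swimmer_params")
}

validate_swimmer_params <- function(p) {
  if (p$body_length <= 0) stop("body_length must be > 0")
  if (p$tailbeat_freq < 0) stop("tailbeat_freq must be >= 0")
  if (p$slip <= 0 || p$slip > 1) stop("slip must be in (0, 1]")
  if (p$frame_rate <= 0) stop("frame_rate must be > 0")
  if (p$duration <= 0) stop("duration must be > 0")
  if (p$n_points < 5) stop("n_points must be >= 5")
  u <- seq(0, 1, length.out = 64)
  e <- p$amplitude_envelope(u)
  if (any(e < -1e-12) || any(e > 1 + 1e-12) || any(diff(e) < -1e-12))
    stop("amplitude_envelope must be non-decreasing with values in [0, 1]")
  invisible(p)
}

# midline points (M x 2, metres) of the travelling-wave body at time t,
# given the head position and heading. The body trails behind the head:
# P(s) = head - integral_0^s (cos, sin)(heading + phi(s')) ds'.
wave_midline <- function(p, t, head_pos, heading) {
  L <- p$body_length
  s <- seq(0, L, length.out = p$n_points)
  lambda <- p$body_wavelength * L
  phi <- p$amplitude_envelope(s / L) * p$bend_amplitude *
    sin(2 * pi * (p$tailbeat_freq * t - s / lambda))
  theta <- heading + phi
  ds <- L / (p$n_points - 1)
  # trapezoidal integration of the tangent along arclength
  cx <- cumsum(c(0, (cos(theta[-1]) + cos(theta[-p$n_points])) / 2 * ds))
  cy <- cumsum(c(0, (sin(theta[-1]) + sin(theta[-p$n_points])) / 2 * ds))
  cbind(head_pos[1] - cx, head_pos[2] - cy, deparse.level = 0)
}

kinematics_truth <- function(centroid, heading, bend_angle, bend_times,
                             path_length, wave = NULL, frame_rate,
                             extra = list()) {
  structure(c(list(centroid = centroid, heading = heading,
                   bend_angle = bend_angle, bend_times = bend_times,
                   path_length = path_length, wave = wave,
                   frame_rate = frame_rate), extra),
            class = "kinematics_truth")
}

#' Simulate an undulatory swimmer with known ground truth
#'
#' Generates a midline sequence from the travelling-wave model of
#' [swimmer_params()], translating the body along its heading at
#' `v = slip * f * lambda * A`, together with the exact kinematic truth:
#' per-frame centroid, heading and head-tail bend angle, the analytic times
#' of the tail bend extrema (each extremum is one body bend, i.e. one
#' tail-beat half cycle), and the forward path length.
#'
#' @param params a [swimmer_params()] object.
#' @return list with elements `midlines` (a [midline_sequence()]) and
#'   `truth` (a `kinematics_truth` list).
#' @export
simulate_swimmer <- function(params) {
  p <- validate_swimmer_params(params)
  nf <- as.integer(round(p$duration * p$frame_rate))
  tt <- (seq_len(nf) - 1) / p$frame_rate
  lambda <- p$body_wavelength * p$body_length
  v <- p$slip * p$tailbeat_freq * lambda * abs(p$bend_amplitude)
  dir <- c(cos(p$heading), sin(p$heading))
  pts <- array(NA_real_, c(nf, p$n_points, 2))
  for (i in seq_len(nf)) {
    head_pos <- p$start + v * tt[i] * dir
    pts[i, , ] <- wave_midline(p, tt[i], head_pos, p$heading)
  }
  ml <- midline_sequence(pts, p$frame_rate)

  centroid <- cbind(rowMeans(pts[, , 1, drop = FALSE], dims = 1),
                    rowMeans(pts[, , 2, drop = FALSE], dims = 1))
  bend <- series_geometry(pts)$bend
  # tail tangent angle A*sin(2*pi*(f*t - L/lambda)) has extrema where the
  # cosine vanishes: t = (L/lambda + 1/4 + k/2) / f, counted on [0, T)
  bend_times <- numeric(0)
  if (p$tailbeat_freq > 0 && abs(p$bend_amplitude) > 0) {
    cphase <- p$body_length / lambda
    k0 <- ceiling((0 - cphase - 0.25) * 2)
    k1 <- floor((p$duration * p$tailbeat_freq - cphase - 0.25) * 2)
    ks <- seq(k0, k1)
    bend_times <- (cphase + 0.25 + ks / 2) / p$tailbeat_freq
    bend_times <- bend_times[bend_times >= 0 & bend_times < p$duration]
  }
  truth <- kinematics_truth(
    centroid = centroid, heading = rep(p$heading, nf), bend_angle = bend,
    bend_times = bend_times, path_length = v * p$duration,
    wave = list(amplitude = p$bend_amplitude, freq = p$tailbeat_freq,
                wavelength = lambda, speed = v),
    frame_rate = p$frame_rate, extra = list(seed = p$seed))
  list(midlines = ml, truth = truth)
}

#' Simulate a C-start escape response
#'
#' The fish is quiescent (straight, stationary) until
#' `stimulus_onset + latency`, then performs the stereotyped fast-start:
#' a rapid unilateral bend into a C shape reaching `peak_bend` (stage 1),
#' a counter-bend of opposite sign (stage 2), and forward acceleration with
#' the bend decaying (stage 3). Body curvature is uniform along the trunk
#' during the bend, matching the C-shaped outlines seen in high-speed
#' silhouette sequences. The response begins exactly at frame
#' `round(stimulus_onset*frame_rate) + round(latency*frame_rate)` (0-based),
#' and the truth bend-angle series attains `peak_bend` exactly at the end of
#' stage 1.
#'
#' @param params a [swimmer_params()] object; its `frame_rate` should match
#'   the high-speed regime (default 923 fps) and `duration` the 5 s trial.
#' @param latency_ms response latency after stimulus onset, ms (>= 0).
#' @param peak_bend peak head-tail bend angle, radians (> 0).
#' @param stimulus_onset stimulus time, s.
#' @param rise_ms,counter_ms,decay_ms stage durations, ms.
#' @param peak_speed asymptotic escape speed, m/s.
#' @return list with `midlines`, `truth` (truth additionally carries
#'   `stimulus_onset`, `onset_frame`, `response_frame`, `peak_bend`).
#' @export
simulate_cstart <- function(params, latency_ms = 12, peak_bend = pi / 2,
                            stimulus_onset = 1,
                            rise_ms = 10, counter_ms = 20, decay_ms = 60,
                            peak_speed = 0.5) {
  p <- validate_swimmer_params(params)
  if (latency_ms < 0) stop("latency_ms must be >= 0")
  if (peak_bend <= 0) stop("peak_bend must be > 0")
  fr <- p$frame_rate
  nf <- as.integer(round(p$duration * fr))
  onset_frame <- as.integer(round(stimulus_onset * fr))       # 0-based
  response_frame <- onset_frame + as.integer(round(latency_ms / 1000 * fr))
  if (response_frame >= nf) stop("latency places the response beyond the trial")

  n_rise <- max(1L, as.integer(round(rise_ms / 1000 * fr)))
  n_counter <- max(1L, as.integer(round(counter_ms / 1000 * fr)))
  n_decay <- max(1L, as.integer(round(decay_ms / 1000 * fr)))

  # bend-parameter series b[frame]; nonzero from response_frame on
  b <- numeric(nf)
  idx <- seq_len(nf) - 1L                                      # 0-based
  k <- idx - response_frame
  rise <- k >= 0 & k < n_rise
  b[rise] <- peak_bend * sin(pi / 2 * (k[rise] + 1) / n_rise)  # hits peak exactly
  cb <- k >= n_rise & k < n_rise + n_counter
  jcb <- (k[cb] - n_rise + 1) / n_counter
  b[cb] <- peak_bend * (0.85 * cos(pi * jcb) + 0.15)   # peak -> -0.7*peak
  dc <- k >= n_rise + n_counter & k < n_rise + n_counter + n_decay
  b0 <- -0.7 * peak_bend
  b[dc] <- b0 * (1 - (k[dc] - n_rise - n_counter + 1) / n_decay)

  # forward speed: zero until the counter-bend begins, then a fast-start
  # pulse (quick rise, slower coast-down as the glide dissipates)
  vel <- numeric(nf)
  ka <- k - n_rise
  acc <- ka >= 0
  tau <- (ka[acc] + 1) / fr
  vel[acc] <- peak_speed * (1 - exp(-tau / 0.01)) * exp(-tau / 0.25)

  dirv <- c(cos(p$heading), sin(p$heading))
  pos <- cbind(cumsum(vel) / fr * dirv[1] + p$start[1],
               cumsum(vel) / fr * dirv[2] + p$start[2])
  L <- p$body_length
  s <- seq(0, L, length.out = p$n_points)
  ds <- L / (p$n_points - 1)
  pts <- array(NA_real_, c(nf, p$n_points, 2))
  for (i in seq_len(nf)) {
    # uniform curvature: tangent angle varies linearly head -> tail by b[i]
    theta <- p$heading + b[i] * s / L
    cx <- cumsum(c(0, (cos(theta[-1]) + cos(theta[-p$n_points])) / 2 * ds))
    cy <- cumsum(c(0, (sin(theta[-1]) + sin(theta[-p$n_points])) / 2 * ds))
    pts[i, , ] <- cbind(pos[i, 1] - cx, pos[i, 2] - cy)
  }
  ml <- midline_sequence(pts, fr)
  centroid <- cbind(rowMeans(pts[, , 1, drop = FALSE], dims = 1),
                    rowMeans(pts[, , 2, drop = FALSE], dims = 1))
  truth <- kinematics_truth(
    centroid = centroid, heading = rep(p$heading, nf), bend_angle = b,
    bend_times = (response_frame + n_rise - 1) / fr,
    path_length = sum(vel) / fr, wave = NULL, frame_rate = fr,
    extra = list(stimulus_onset = stimulus_onset, onset_frame = onset_frame,
                 response_frame = response_frame, peak_bend = peak_bend,
                 speed = vel, seed = p$seed))
  list(midlines = ml, truth = truth)
}
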