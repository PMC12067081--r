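# shared fixtures, built in code at test time

PX <- 1e-4  # 0.1 mm per pixel, used throughout the image fixtures

# straight horizontal rod midline (head at the right), one or more frames
rod_midlines <- function(n_frames = 1, M = 51, x_head = 170, x_tail = 20,
                         y = 30) {
  pts <- array(NA_real_, c(n_frames, M, 2))
  for (i in seq_len(n_frames)) {
    pts[i, , 1] <- seq(x_head, x_tail, length.out = M) * PX
    pts[i, , 2] <- rep(y, M) * PX
  }
  midline_sequence(pts, 100)
}

# circular-arc midline of given radius (px) spanning `span` radians
arc_midlines <- function(radius_px = 100, span = pi / 2, M = 51,
                         centre = c(120, 150)) {
  th <- seq(0.2, 0.2 + span, length.out = M)
  pts <- array(NA_real_, c(1, M, 2))
  pts[1, , 1] <- (centre[1] + radius_px * cos(th)) * PX
  pts[1, , 2] <- (centre[2] - radius_px * sin(th)) * PX
  midline_sequence(pts, 100)
}

# replicate a single-frame midline sequence to n frames
rep_frames <- function(ml, n) {
  M <- dim(ml$points)[2]
  pts <- array(NA_real_, c(n, M, 2))
  for (i in seq_len(n)) pts[i, , ] <- ml$points[1, , ]
  midline_sequence(pts, ml$frame_rate)
}

# symmetric Hausdorff distance between two point sets (rows = points)
hausdorff <- function(A, B) {
  d <- function(P, Q) max(apply(P, 1, function(x)
    min(sqrt((Q[, 1] - x[1])^2 + (Q[, 2] - x[2])^2))))
  max(d(A, B), d(B, A))
}

# independent exhaustive enumeration oracle for the two-sample permutation
# test (deliberately written without the package's code path)
enumerate_perm_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  obs <- abs(mean(a) - mean(b))
  splits <- utils::combn(length(pool), n1)
  hits <- 0
  for (j in seq_len(ncol(splits))) {
    g1 <- pool[splits[, j]]
    g2 <- pool[-splits[, j]]
    if (abs(mean(g1) - mean(g2)) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(splits)
}

# kinematic series stub with a prescribed bend-angle trace
series_from_bend <- function(bend, frame_rate = 100) {
  n <- length(bend)
  structure(list(speed = rep(0, n), velocity = cbind(rep(0, n), rep(0, n)),
                 heading = rep(0, n), bend_angle = bend,
                 curvature = matrix(0, n, 5),
                 centroid = cbind(rep(0, n), rep(0, n)),
                 frame_rate = frame_rate),
            class = "kinematic_series")
}

# kinematic series stub with a prescribed speed trace
series_from_speed <- function(speed, frame_rate = 100) {
  n <- length(speed)
  structure(list(speed = speed, velocity = cbind(speed, rep(0, n)),
                 heading = rep(0, n), bend_angle = rep(0, n),
                 curvature = matrix(0, n, 5),
                 centroid = cbind(cumsum(speed) / frame_rate, rep(0, n)),
                 frame_rate = frame_rate),
            class = "kinematic_series")
}
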