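#' Midline sequence container
#'
#' An ordered, head-oriented body midline per video frame. Point 1 is the
#' head; points are spaced at (near-)equal arclength. Coordinates are metres
#' in the image convention: origin top-left, x to the right, y downward.
#'
#' @param points numeric array of dimension `n_frames x M x 2` (last axis is
#'   x, y in metres), or a list of `M x 2` matrices.
#' @param frame_rate frames per second (Hz), > 0.
#' @return object of class `midline_sequence`.
#' @export
midline_sequence <- function(points, frame_rate) {
  if (is.list(points)) {
    M <- nrow(points[[1]])
    arr <- array(NA_real_, c(length(points), M, 2))
    for (i in seq_along(points)) {
      if (!identical(dim(points[[i]]), c(M, 2L)))
        stop("all frames must have the same number of midline points")
      arr[i, , ] <- points[[i]]
    }
    points <- arr
  }
  stopifnot(is.array(points), length(dim(points)) == 3, dim(points)[3] == 2)
  if (dim(points)[2] < 5) stop("a midline needs at least 5 points")
  if (anyNA(points)) stop("midline points must not contain NA")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  structure(list(points = points, frame_rate = as.numeric(frame_rate)),
            class = "midline_sequence")
}

#' @export
print.midline_sequence <- function(x, ...) {
  d <- dim(x$points)
  cat(sprintf("<midline_sequence> %d frames, %d points/frame, %.6g fps\n",
              d[1], d[2], x$frame_rate))
  invisible(x)
}

n_frames <- function(ml) dim(ml$points)[1]

frame_points <- function(ml, i) {
  m <- ml$points[i, , , drop = FALSE]
  dim(m) <- dim(ml$points)[2:3]
  m
}

# cumulative arclength of an M x 2 point matrix, from the head
cum_arclength <- function(p) {
  d <- sqrt(rowSums(diff(p)^2))
  c(0, cumsum(d))
}

# point interpolated at arclength fraction f (0 = head, 1 = tail)
point_at_fraction <- function(p, f) {
  s <- cum_arclength(p)
  tot <- s[length(s)]
  if (tot == 0) return(p[1, ])
  c(stats::approx(s, p[, 1], xout = f * tot, rule = 2)$y,
    stats::approx(s, p[, 2], xout = f * tot, rule = 2)$y)
}

# wrap an angle to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

# signed head-tail bend angle (radians) of one midline: angle from the
# direction of the head chord (first `chord_frac` of arclength, pointing
# head-ward) to the direction of the tail chord (last `chord_frac`,
# pointing head-ward). Straight body -> 0.
bend_angle_of <- function(p, chord_frac = 0.2) {
  a <- point_at_fraction(p, chord_frac)
  head_dir <- p[1, ] - a                       # toward the head
  b <- point_at_fraction(p, 1 - chord_frac)
  tail_dir <- b - p[nrow(p), ]                 # also toward the head
  cross <- head_dir[1] * tail_dir[2] - head_dir[2] * tail_dir[1]
  dot <- sum(head_dir * tail_dir)
  atan2(cross, dot)
}

# heading (radians) of one midline: direction from the point at 75% of
# arclength to the head, wrapped to (-pi, pi]
heading_of <- function(p) {
  q <- point_at_fraction(p, 0.75)
  wrap_angle(atan2(p[1, 2] - q[2], p[1, 1] - q[1]))
}

# vectorised per-frame geometry over a whole midline array
# (n_frames x M x 2). Exploits the equal-arclength invariant: the point at
# arclength fraction f is linearly interpolated between the two bracketing
# midline indices. Returns bend angle (rad), heading (rad) and the
# n_frames x M curvature matrix (1/m).
series_geometry <- function(points, chord_frac = 0.2) {
  nf <- dim(points)[1]; M <- dim(points)[2]
  at_frac <- function(f) {
    g <- 1 + f * (M - 1)
    i0 <- min(M - 1, floor(g)); w <- g - i0
    (1 - w) * points[, i0, , drop = FALSE] +
      w * points[, i0 + 1, , drop = FALSE]
  }
  drop2 <- function(a) { dim(a) <- c(nf, 2); a }
  p_head <- drop2(points[, 1, , drop = FALSE])
  p_tail <- drop2(points[, M, , drop = FALSE])
  a <- drop2(at_frac(chord_frac))
  b <- drop2(at_frac(1 - chord_frac))
  hd <- p_head - a                   # head-chord direction, head-ward
  td <- b - p_tail                   # tail-chord direction, head-ward
  bend <- atan2(hd[, 1] * td[, 2] - hd[, 2] * td[, 1],
                hd[, 1] * td[, 1] + hd[, 2] * td[, 2])
  q <- drop2(at_frac(0.75))
  heading <- wrap_angle(atan2(p_head[, 2] - q[, 2], p_head[, 1] - q[, 1]))

  segx <- points[, -1, 1] - points[, -M, 1]
  segy <- points[, -1, 2] - points[, -M, 2]
  if (nf == 1) { segx <- rbind(segx); segy <- rbind(segy) }
  theta <- atan2(segy, segx)                       # nf x (M-1)
  seglen <- sqrt(segx^2 + segy^2)
  s <- cbind(0, t(apply(seglen, 1, cumsum)))       # nf x M
  smid <- (s[, -1, drop = FALSE] + s[, -ncol(s), drop = FALSE]) / 2
  dth <- wrap_angle(theta[, -1, drop = FALSE] - theta[, -(M - 1), drop = FALSE])
  dsm <- smid[, -1, drop = FALSE] - smid[, -(M - 1), drop = FALSE]
  k_mid <- dth / dsm                               # nf x (M-2)
  curv <- cbind(k_mid[, 1], k_mid, k_mid[, M - 2])
  list(bend = bend, heading = heading, curvature = curv)
}

# signed curvature (1/m) along an arclength-parameterised midline by
# central differences of the unwrapped tangent angle; endpoints get the
# one-sided neighbour value
curvature_of <- function(p) {
  seg <- diff(p)
  theta <- atan2(seg[, 2], seg[, 1])
  theta <- theta[1] + c(0, cumsum(wrap_angle(diff(theta))))  # unwrap
  s <- cum_arclength(p)
  smid <- (s[-1] + s[-length(s)]) / 2
  n <- length(theta)
  if (n < 2) return(rep(0, nrow(p)))
  k_mid <- diff(theta) / diff(smid)            # at interior points 2..M-1
  k <- c(k_mid[1], k_mid, k_mid[length(k_mid)])
  k
}
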