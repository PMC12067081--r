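#' Extract ordered, head-oriented midlines from a silhouette stack
#'
#' Per frame: the largest foreground component is selected; the centerline
#' is the ridge of the interior Euclidean distance transform, traced as the
#' minimum-cost path between the two geodesically most distant foreground
#' pixels with step costs inversely weighted by the distance transform (so
#' the path hugs the medial axis); the path is smoothed, the end caps are
#' trimmed back by the local body half-width, and the result is resampled
#' to `M` equal-arclength points in metres. Head/tail assignment: the head
#' is the endpoint whose offset from the centroid best aligns with centroid
#' motion (+/- 5-frame window), propagated across frames by
#' nearest-endpoint continuity; when the fish barely moves, the wider
#' endpoint is taken as the head.
#'
#' @param stack a [silhouette_stack()].
#' @param M number of midline points (default 51; odd, so there is a true
#'   midpoint).
#' @param min_component minimum size in pixels of the subject component.
#' @return a [midline_sequence()] in metres.
#' @export
extract_midline <- function(stack, M = 51, min_component = 50) {
  stopifnot(inherits(stack, "silhouette_stack"))
  nf <- length(stack$frames)
  pts <- array(NA_real_, c(nf, M, 2))
  end_widths <- matrix(NA_real_, nf, 2)  # half-width (px) at each end
  for (i in seq_len(nf)) {
    res <- tryCatch(frame_centerline(stack$frames[[i]], M, min_component),
                    error = function(e)
                      stop("frame ", i - 1, ": ", conditionMessage(e),
                           call. = FALSE))
    pts[i, , ] <- res$points * stack$pixel_scale
    end_widths[i, ] <- res$end_widths
  }
  # nearest-endpoint continuity of orientation across frames
  for (i in seq_len(nf)[-1]) {
    d_same <- sum((pts[i, 1, ] - pts[i - 1, 1, ])^2)
    d_flip <- sum((pts[i, M, ] - pts[i - 1, 1, ])^2)
    if (d_flip < d_same) {
      pts[i, , ] <- pts[i, M:1, ]
      end_widths[i, ] <- end_widths[i, 2:1]
    }
  }
  # global head decision from centroid motion
  cx <- rowMeans(pts[, , 1, drop = FALSE], dims = 1)
  cy <- rowMeans(pts[, , 2, drop = FALSE], dims = 1)
  score <- 0
  w <- 5L
  for (i in seq_len(nf)) {
    a <- max(1L, i - w); b <- min(nf, i + w)
    mv <- c(cx[b] - cx[a], cy[b] - cy[a])
    nm <- sqrt(sum(mv^2))
    if (nm < stack$pixel_scale / 2) next   # sub-pixel motion: uninformative
    hv <- c(pts[i, 1, 1] - cx[i], pts[i, 1, 2] - cy[i])
    score <- score + sum(hv * mv) / (nm * sqrt(sum(hv^2)))
  }
  flip <- if (abs(score) > 1e-9) score < 0 else
    end_widths[1, 1] < end_widths[1, 2]   # heads are wider than tails
  if (flip) pts <- pts[, M:1, , drop = FALSE]
  midline_sequence(pts, stack$frame_rate)
}

# centerline of one binary frame, in pixel coordinates (0-based centres).
# Returns M x 2 points, the size of the selected component and the local
# half-widths at the two ends.
frame_centerline <- function(img, M, min_component = 50) {
  if (sum(img) == 0) stop("empty frame (no foreground)")
  lab <- EBImage::bwlabel(img)
  sizes <- tabulate(lab[lab > 0])
  biggest <- max(sizes)
  if (sum(sizes == biggest) > 1)
    stop("multiple equal-size foreground components (ambiguous subject)")
  if (biggest < min_component)
    stop("foreground component smaller than ", min_component, " pixels")
  mask <- (lab == which.max(sizes)) * 1L
  dt <- EBImage::distmap(mask)

  idx <- which(mask == 1L)
  nr <- nrow(mask)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  vid <- integer(length(mask)); vid[idx] <- seq_along(idx)

  # 8-neighbour edges (4 directions cover both orientations)
  steps <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  ef <- integer(0); et <- integer(0); elen <- numeric(0)
  nc <- ncol(mask)
  for (s in steps) {
    r2 <- row + s[1]; c2 <- col + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[j] == 1L
    ef <- c(ef, vid[idx[ok]][hit])
    et <- c(et, vid[j][hit])
    elen <- c(elen, rep(sqrt(sum(s^2)), sum(hit)))
  }
  g <- igraph::graph_from_edgelist(cbind(ef, et), directed = FALSE)
  if (igraph::vcount(g) < length(idx))
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))

  # geodesic diameter endpoints (two sweeps of shortest-path distances)
  d0 <- igraph::distances(g, v = 1, weights = elen)[1, ]
  e1 <- which.max(d0)
  d1 <- igraph::distances(g, v = e1, weights = elen)[1, ]
  e2 <- which.max(d1)

  # ridge path: penalise steps away from the distance-transform crest
  dtv <- as.numeric(dt)[idx]
  wr <- elen / pmax(dtv[ef] + dtv[et], 0.5)
  sp <- igraph::shortest_paths(g, from = e1, to = e2, weights = wr,
                               output = "vpath")$vpath[[1]]
  pv <- as.integer(sp)
  path <- cbind(col[pv] - 1, row[pv] - 1)   # x, y in 0-based pixel coords
  dpath <- dtv[pv]
  if (nrow(path) < 5) stop("foreground component too small to trace")

  # smooth the pixel chain
  n <- nrow(path)
  win <- min(9L, if (n %% 2 == 1L) n else n - 1L)
  if (win >= 5) {
    path[, 1] <- signal::sgolayfilt(path[, 1], p = 2, n = win)
    path[, 2] <- signal::sgolayfilt(path[, 2], p = 2, n = win)
  }
  s <- cum_arclength(path)

  # trim the rounded end caps: inside a cap the boundary distance grows
  # linearly with arclength; the cap ends where that growth stalls
  trim_at <- function(sv, dv) {
    excess <- (sv - sv[1]) - (dv - dv[1])
    i <- which(excess > 0.75)[1]
    if (is.na(i)) 0 else max(0, sv[i] - excess[i] + 1.5)
  }
  t1 <- trim_at(s, dpath)
  rs <- rev(s[length(s)] - s)
  t2 <- trim_at(rs, rev(dpath))
  lo <- t1; hi <- s[length(s)] - t2
  if (hi - lo < 2) { lo <- 0; hi <- s[length(s)] }   # degenerate: keep all

  ss <- seq(lo, hi, length.out = M)
  out <- cbind(stats::approx(s, path[, 1], xout = ss)$y,
               stats::approx(s, path[, 2], xout = ss)$y)
  # sub-pixel refinement: recentre each point between the silhouette
  # boundaries along the local normal, then re-parameterise so point
  # spacing is equal in arclength
  wmax <- max(dpath) + 2
  for (pass in 1:2) {
    out <- recentre_normal(out, mask, wmax)
    out <- correct_ends(out, mask, wmax)
    s2 <- cum_arclength(out)
    ss2 <- seq(0, s2[M], length.out = M)
    out <- cbind(stats::approx(s2, out[, 1], xout = ss2)$y,
                 stats::approx(s2, out[, 2], xout = ss2)$y)
  }
  wend <- c(stats::approx(s, dpath, xout = lo, rule = 2)$y,
            stats::approx(s, dpath, xout = hi, rule = 2)$y)
  list(points = out, component_size = biggest, end_widths = wend)
}

# bilinear sample of a binary mask at 0-based pixel coords (x, y)
mask_at <- function(mask, x, y) {
  nr <- nrow(mask); nc <- ncol(mask)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(xx, yy) {
    ok <- xx >= 0 & xx < nc & yy >= 0 & yy < nr
    v <- numeric(length(xx))
    v[ok] <- mask[cbind(yy[ok] + 1L, xx[ok] + 1L)]
    v
  }
  (1 - fx) * (1 - fy) * val(x0, y0) + fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) + fx * fy * val(x0 + 1, y0 + 1)
}

# distance from a point to the mask boundary along a unit direction
march_to_edge <- function(mask, p, dir, reach, step = 0.25) {
  ts <- seq(step, reach, by = step)
  v <- mask_at(mask, p[1] + ts * dir[1], p[2] + ts * dir[2])
  j <- which(v < 0.5)[1]
  if (is.na(j)) return(NA_real_)
  if (j == 1) return(ts[1] * (mask_at(mask, p[1], p[2]) - 0.5) /
                       max(mask_at(mask, p[1], p[2]) - v[1], 1e-9))
  ts[j - 1] + step * (v[j - 1] - 0.5) / max(v[j - 1] - v[j], 1e-9)
}

# relocate each endpoint using the rounded-cap geometry: the body tip lies
# local-half-width short of the boundary along the end tangent
correct_ends <- function(p, mask, reach) {
  M <- nrow(p)
  for (end in c(1L, M)) {
    inner <- if (end == 1L) 4L else M - 3L
    tg <- p[end, ] - p[inner, ]
    nt <- sqrt(sum(tg^2)); if (nt == 0) next
    tg <- tg / nt
    nrm <- c(-tg[2], tg[1])
    dplus <- march_to_edge(mask, p[inner, ], nrm, reach)
    dminus <- march_to_edge(mask, p[inner, ], -nrm, reach)
    dout <- march_to_edge(mask, p[end, ], tg, reach)
    if (anyNA(c(dplus, dminus, dout))) next
    p[end, ] <- p[end, ] + (dout - (dplus + dminus) / 2) * tg
  }
  p
}

# move each point to the midpoint of the foreground section of its normal
recentre_normal <- function(p, mask, reach) {
  M <- nrow(p)
  tg <- rbind(p[2, ] - p[1, ], p[3:M, ] - p[1:(M - 2), ],
              p[M, ] - p[M - 1, ])
  tn <- sqrt(rowSums(tg^2)); tn[tn == 0] <- 1
  nx <- -tg[, 2] / tn; ny <- tg[, 1] / tn
  step <- 0.25
  ts <- seq(step, reach, by = step)
  out <- p
  for (i in seq_len(M)) {
    # march outward on each side until the mask is exited
    vplus <- mask_at(mask, p[i, 1] + ts * nx[i], p[i, 2] + ts * ny[i])
    vminus <- mask_at(mask, p[i, 1] - ts * nx[i], p[i, 2] - ts * ny[i])
    ip <- which(vplus < 0.5)[1]; im <- which(vminus < 0.5)[1]
    if (is.na(ip) || is.na(im)) next
    # linear sub-step interpolation to the 0.5 crossing
    edge <- function(v, j) {
      if (j == 1) return(ts[1])
      ts[j - 1] + step * (v[j - 1] - 0.5) / max(v[j - 1] - v[j], 1e-9)
    }
    dplus <- edge(vplus, ip); dminus <- edge(vminus, im)
    shift <- (dplus - dminus) / 2
    out[i, 1] <- p[i, 1] + shift * nx[i]
    out[i, 2] <- p[i, 2] + shift * ny[i]
  }
  out
}

#' Per-frame centroid and heading of a midline sequence
#'
#' Centroid is the arithmetic mean of the midline points; heading is the
#' direction from the point at 75% of arclength to the head, wrapped to
#' (-pi, pi].
#'
#' @param midlines a [midline_sequence()].
#' @return data.frame with columns `frame` (0-based), `x_m`, `y_m`,
#'   `heading`.
#' @export
centroid_and_heading <- function(midlines) {
  stopifnot(inherits(midlines, "midline_sequence"))
  nf <- n_frames(midlines)
  out <- data.frame(frame = seq_len(nf) - 1L,
                    x_m = rowMeans(midlines$points[, , 1, drop = FALSE],
                                   dims = 1),
                    y_m = rowMeans(midlines$points[, , 2, drop = FALSE],
                                   dims = 1),
                    heading = NA_real_)
  for (i in seq_len(nf))
    out$heading[i] <- heading_of(frame_points(midlines, i))
  out
}
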