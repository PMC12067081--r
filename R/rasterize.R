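#' Silhouette stack container
#'
#' @param frames list of binary (0/1) integer matrices, all the same shape.
#'   Matrix rows are image rows (y, downward), columns are x. Pixel centres
#'   sit at integer coordinates, 0-based, origin top-left.
#' @param pixel_scale metres per pixel, > 0.
#' @param frame_rate frames per second, Hz.
#' @return object of class `silhouette_stack`.
#' @export
silhouette_stack <- function(frames, pixel_scale, frame_rate) {
  stopifnot(is.list(frames), length(frames) >= 1)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), d)) stop("all frames must share one shape")
    if (anyNA(f) || any(f != 0 & f != 1)) stop("frames must be binary 0/1")
  }
  if (!is.numeric(pixel_scale) || pixel_scale <= 0)
    stop("pixel_scale must be > 0")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be > 0")
  structure(list(frames = frames, pixel_scale = pixel_scale,
                 frame_rate = frame_rate), class = "silhouette_stack")
}

#' @export
print.silhouette_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<silhouette_stack> %d frames of %dx%d px, %.3g m/px, %.6g fps\n",
              length(x$frames), d[2], d[1], x$pixel_scale, x$frame_rate))
  invisible(x)
}

#' Rasterize a midline sequence into binary silhouettes
#'
#' A pixel is foreground when its centre lies within the local body
#' half-width of the midline polyline (equivalently: within the union of
#' the capsules spanned by consecutive midline points, with the half-width
#' interpolated along each segment). Pixel centres are at integer
#' coordinates, origin top-left, x right, y down; world coordinates map to
#' pixels as `px = x_m / pixel_scale`.
#'
#' @param midlines a [midline_sequence()].
#' @param width_profile function of arclength fraction in `[0, 1]` returning
#'   the local body half-width in metres, or a single number for a uniform
#'   half-width.
#' @param pixel_scale metres per pixel.
#' @param image_size `c(width, height)` in pixels.
#' @param offset world coordinates (m) of pixel (0, 0); defaults to `c(0, 0)`.
#' @return a [silhouette_stack()].
#' @export
rasterize_silhouettes <- function(midlines, width_profile, pixel_scale,
                                  image_size, offset = c(0, 0)) {
  stopifnot(inherits(midlines, "midline_sequence"))
  if (is.numeric(width_profile)) {
    w0 <- width_profile[1]
    width_profile <- function(u) rep(w0, length(u))
  }
  W <- as.integer(image_size[1]); H <- as.integer(image_size[2])
  nf <- n_frames(midlines)
  M <- dim(midlines$points)[2]
  r_px <- width_profile(seq(0, 1, length.out = M)) / pixel_scale
  if (any(r_px <= 0)) stop("width_profile must be positive")
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    p <- frame_points(midlines, i)
    if (nrow(unique(p)) < 2) stop("zero-length midline in frame ", i - 1)
    px <- (p[, 1] - offset[1]) / pixel_scale
    py <- (p[, 2] - offset[2]) / pixel_scale
    if (any(px - r_px < -0.5) || any(px + r_px > W - 0.5) ||
        any(py - r_px < -0.5) || any(py + r_px > H - 0.5))
      stop("fish exits the image bounds in frame ", i - 1)
    img <- matrix(0L, H, W)
    for (j in seq_len(M - 1)) {
      r0 <- r_px[j]; r1 <- r_px[j + 1]; rmax <- max(r0, r1)
      x0 <- max(0L, floor(min(px[j], px[j + 1]) - rmax))
      x1 <- min(W - 1L, ceiling(max(px[j], px[j + 1]) + rmax))
      y0 <- max(0L, floor(min(py[j], py[j + 1]) - rmax))
      y1 <- min(H - 1L, ceiling(max(py[j], py[j + 1]) + rmax))
      xs <- x0:x1; ys <- y0:y1
      ax <- px[j]; ay <- py[j]
      bx <- px[j + 1] - ax; by <- py[j + 1] - ay
      len2 <- bx^2 + by^2
      gx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - ax
      gy <- matrix(ys, length(ys), length(xs)) - ay
      tt <- pmin(pmax((gx * bx + gy * by) / len2, 0), 1)
      d2 <- (gx - tt * bx)^2 + (gy - tt * by)^2
      rt <- r0 + tt * (r1 - r0)
      hit <- d2 <= rt^2
      sub <- img[ys + 1L, xs + 1L, drop = FALSE]
      sub[hit] <- 1L
      img[ys + 1L, xs + 1L] <- sub
    }
    frames[[i]] <- img
  }
  silhouette_stack(frames, pixel_scale, midlines$frame_rate)
}
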