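#' @name swimkin-io
#' @title File formats
#' @description
#' All tabular outputs are plain CSV with documented schemas; image stacks
#' are numbered PNG frames; metadata travels in JSON sidecars. Schemas:
#' * midline CSV: `frame` (0-based), `point_index` (0-based, 0 = head),
#'   `x_m`, `y_m`; sidecar carries `frame_rate`.
#' * centroid/trajectory CSV: `frame`, `x_m`, `y_m` (plus `id`, `genotype`
#'   for cohorts).
#' * trace CSV: `t_s`, `volts`; sidecar carries `sample_rate`,
#'   `stimulus_onset_s`. WAV alternative: mono 32-bit IEEE float.
#' * results CSV: `panel`, `comparison`, `statistic`, `value`, `p_raw`,
#'   `p_adjusted`, `n_resamples`, `seed`.
#' No reader or writer mutates its inputs; `read(write(x))` recovers `x`
#' to at least 1e-9 relative in all numeric fields.
NULL

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  for (cl in numeric_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v))[1]
      stop(path, ": line ", bad + 1, ", column '", cl,
           "': not a number ('", v[bad], "')")
    }
    if (anyNA(v) && cl %in% required) {
      bad <- which(is.na(v))[1]
      stop(path, ": line ", bad + 1, ", column '", cl, "': missing value")
    }
  }
  df
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing JSON sidecar: ", sp)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read a midline sequence as CSV (+ JSON sidecar)
#'
#' @param midlines a [midline_sequence()].
#' @param path CSV path; the sidecar (frame rate) goes to the same name
#'   with extension `.json`.
#' @return `write_midline_csv` returns `path` invisibly; `read_midline_csv`
#'   returns a [midline_sequence()].
#' @export
write_midline_csv <- function(midlines, path) {
  stopifnot(inherits(midlines, "midline_sequence"))
  nf <- n_frames(midlines); M <- dim(midlines$points)[2]
  df <- data.frame(frame = rep(seq_len(nf) - 1L, each = M),
                   point_index = rep(seq_len(M) - 1L, nf),
                   x_m = as.vector(t(midlines$points[, , 1])),
                   y_m = as.vector(t(midlines$points[, , 2])))
  utils::write.csv(df, path, row.names = FALSE)
  write_sidecar(path, list(frame_rate = midlines$frame_rate,
                           n_frames = nf, n_points = M))
  invisible(path)
}

#' @rdname write_midline_csv
#' @export
read_midline_csv <- function(path) {
  df <- read_checked_csv(path, c("frame", "point_index", "x_m", "y_m"),
                         c("frame", "point_index", "x_m", "y_m"))
  meta <- read_sidecar(path)
  frames <- sort(unique(df$frame))
  M <- sum(df$frame == frames[1])
  pts <- array(NA_real_, c(length(frames), M, 2))
  df <- df[order(df$frame, df$point_index), ]
  pts[, , 1] <- matrix(df$x_m, length(frames), M, byrow = TRUE)
  pts[, , 2] <- matrix(df$y_m, length(frames), M, byrow = TRUE)
  midline_sequence(pts, meta$frame_rate)
}

#' Write / read a silhouette stack as numbered PNG frames (+ sidecar)
#'
#' @param stack a [silhouette_stack()].
#' @param dir output directory (created if needed); frames are written as
#'   `frame_0000.png`, ... with a `stack.json` sidecar (pixel scale, frame
#'   rate).
#' @return the directory (write) or a [silhouette_stack()] (read).
#' @export
write_silhouette_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "silhouette_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$frames)) {
    png::writePNG(stack$frames[[i]] + 0.0,   # writePNG wants doubles in [0,1]
                  file.path(dir, sprintf("frame_%04d.png", i - 1)))
  }
  jsonlite::write_json(list(pixel_scale = stack$pixel_scale,
                            frame_rate = stack$frame_rate,
                            n_frames = length(stack$frames)),
                       file.path(dir, "stack.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_silhouette_stack
#' @export
read_silhouette_stack <- function(dir) {
  mp <- file.path(dir, "stack.json")
  if (!file.exists(mp)) stop("missing stack.json in ", dir)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) != meta$n_frames)
    stop(dir, ": expected ", meta$n_frames, " frames, found ", length(files))
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    (img > 0.5) * 1L
  })
  silhouette_stack(frames, meta$pixel_scale, meta$frame_rate)
}

#' Write / read an extracellular trace as 2-column CSV (+ sidecar)
#'
#' @param trace an [ephys_trace()].
#' @param path CSV path (`t_s`, `volts`); the sidecar carries
#'   `sample_rate` and `stimulus_onset_s`.
#' @return path (write) or an [ephys_trace()] (read).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ephys_trace"))
  n <- length(trace$samples)
  df <- data.frame(t_s = (seq_len(n) - 1) / trace$sample_rate,
                   volts = trace$samples)
  utils::write.csv(df, path, row.names = FALSE)
  write_sidecar(path, list(sample_rate = trace$sample_rate,
                           stimulus_onset_s = trace$stimulus_onset))
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read_checked_csv(path, c("t_s", "volts"), c("t_s", "volts"))
  meta <- read_sidecar(path)
  ephys_trace(df$volts, meta$sample_rate, meta$stimulus_onset_s)
}

#' Write / read an extracellular trace as mono 32-bit float WAV (+ sidecar)
#'
#' Minimal RIFF/WAVE with IEEE-float samples (format code 3), which keeps
#' the CSV and WAV encodings of one trace numerically interchangeable
#' (float32 resolution, ~1e-7 relative). Metadata travels in the JSON
#' sidecar as for the CSV form.
#'
#' @param trace an [ephys_trace()]; @param path `.wav` path.
#' @return path (write) or an [ephys_trace()] (read).
#' @export
write_trace_wav <- function(trace, path) {
  stopifnot(inherits(trace, "ephys_trace"))
  n <- length(trace$samples)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")       # IEEE float
  writeBin(1L, con, size = 2, endian = "little")       # mono
  writeBin(as.integer(trace$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(trace$sample_rate * 4), con, size = 4,
           endian = "little")
  writeBin(4L, con, size = 2, endian = "little")       # block align
  writeBin(32L, con, size = 2, endian = "little")      # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(trace$samples, con, size = 4, endian = "little")
  write_sidecar(path, list(sample_rate = trace$sample_rate,
                           stimulus_onset_s = trace$stimulus_onset))
  invisible(path)
}

#' @rdname write_trace_wav
#' @export
read_trace_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop(path, ": not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop(path, ": not a WAVE file")
  fmt <- NULL; samples <- NULL; fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8))
      if (fmt[1] != 3L) stop(path, ": only 32-bit float WAV is supported")
    } else if (id == "data") {
      samples <- readBin(con, numeric(), n = sz / 4, size = 4,
                         endian = "little")
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop(path, ": no data chunk")
  meta <- read_sidecar(path)
  ephys_trace(samples, meta$sample_rate, meta$stimulus_onset_s)
}

#' Write / read a per-fish metric table
#'
#' @param metrics data.frame with at least `id`, `genotype`, `sex` plus
#'   metric columns; @param path CSV path.
#' @return path (write) or the data.frame (read).
#' @export
write_metric_table <- function(metrics, path) {
  stopifnot(all(c("id", "genotype", "sex") %in% names(metrics)))
  if (anyDuplicated(metrics$id)) stop("duplicate fish ids")
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  df <- read_checked_csv(path, c("id", "genotype", "sex"), "id")
  if (anyDuplicated(df$id)) stop(path, ": duplicate fish ids")
  df
}

#' Write / read a statistics results table
#'
#' Schema: `panel`, `comparison`, `statistic`, `value`, `p_raw`,
#' `p_adjusted`, `n_resamples`, `seed`.
#'
#' @param results data.frame in the schema above; @param path CSV path.
#' @return path (write) or the data.frame (read).
#' @export
write_results_table <- function(results, path) {
  need <- c("panel", "comparison", "statistic", "value", "p_raw",
            "p_adjusted", "n_resamples", "seed")
  stopifnot(all(need %in% names(results)))
  utils::write.csv(results[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  read_checked_csv(path, c("panel", "comparison", "statistic", "value",
                           "p_raw", "p_adjusted", "n_resamples", "seed"),
                   c("value", "p_raw", "p_adjusted"))
}

#' Write / read an occupancy map (CSV grid + JSON bin edges)
#'
#' @param map an [occupancy_map()]; @param path CSV path for the grid
#'   (rows = y bins); bin edges and marginals go to the JSON sidecar.
#' @return path (write) or an [occupancy_map()] (read).
#' @export
write_occupancy_map <- function(map, path) {
  stopifnot(inherits(map, "occupancy_map"))
  utils::write.table(map$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  write_sidecar(path, list(x_edges = map$x_edges, y_edges = map$y_edges))
  invisible(path)
}

#' @rdname write_occupancy_map
#' @export
read_occupancy_map <- function(path) {
  grid <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(grid) <- NULL
  meta <- read_sidecar(path)
  structure(list(grid = grid, x_edges = meta$x_edges,
                 y_edges = meta$y_edges,
                 x_marginal = colSums(grid), y_marginal = rowSums(grid)),
            class = "occupancy_map")
}
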