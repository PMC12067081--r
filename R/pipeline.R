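derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483563) + 1L
}

#' Simulate a free-swimming cohort and measure its kinematic metrics
#'
#' Each fish swims at a per-fish target speed (log-normal jitter around the
#' configured speed) with a per-fish bend amplitude scaled by its genotype;
#' the tail-beat frequency follows from the speed-amplitude coupling, so a
#' fish with reduced amplitude must beat its tail faster to hold speed —
#' covering the same distance with more bends and hence lower propulsion
#' efficiency. Metrics are measured from the midlines by the analysis
#' chain, never copied from the generator.
#'
#' @param cfg a [run_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return list with `metrics` (data.frame: id, genotype, sex, activity,
#'   m_per_bend, m_per_degree, bends_per_m, n_bends, path_length_m,
#'   median_bend_amplitude_deg) and `truth` (per-fish generating
#'   parameters).
#' @export
simulate_swim_cohort <- function(cfg, seed = cfg$seed) {
  fs <- cfg$free_swim
  set.seed(derive_seed(seed, 1L))
  rows <- list(); truths <- list(); id <- 0L
  for (g in names(cfg$effects)) {
    eff <- cfg$effects[[g]]
    n <- cfg$n_per_group[[g]]
    A <- fs$bend_amplitude * eff$amplitude_mult *
      exp(stats::rnorm(n, 0, fs$amplitude_cv))
    v <- fs$target_speed * exp(stats::rnorm(n, 0, fs$speed_cv))
    for (j in seq_len(n)) {
      id <- id + 1L
      lambda <- 0.95 * fs$body_length
      f <- v[j] / (0.7 * lambda * A[j])
      p <- swimmer_params(body_length = fs$body_length,
                          bend_amplitude = A[j], tailbeat_freq = f,
                          slip = 0.7, frame_rate = fs$frame_rate,
                          duration = fs$duration, seed = id)
      sim <- simulate_swimmer(p)
      ser <- compute_kinematics(sim$midlines)
      bends <- detect_bends(ser, min_amplitude = cfg$bend_min_amplitude)
      path <- sum(sqrt(rowSums(diff(ser$centroid)^2)))
      eff_m <- propulsion_efficiency(path, bends, fs$duration)
      rows[[id]] <- data.frame(
        id = id, genotype = g, sex = cfg$sex,
        activity = activity_fraction(ser, cfg$activity_threshold,
                                     fs$duration),
        m_per_bend = eff_m$m_per_bend, m_per_degree = eff_m$m_per_degree,
        bends_per_m = eff_m$bends_per_m, n_bends = eff_m$n_bends,
        path_length_m = path,
        median_bend_amplitude_deg =
          if (length(bends$amplitudes)) stats::median(bends$amplitudes)
          else NA_real_)
      truths[[id]] <- data.frame(id = id, genotype = g, amplitude = A[j],
                                 tailbeat_freq = f, target_speed = v[j])
    }
  }
  list(metrics = do.call(rbind, rows), truth = do.call(rbind, truths))
}

#' Simulate C-start trials with field potentials and measure them
#'
#' Per fish: a true latency (genotype shift plus jitter), a post-stimulus
#' spike burst whose size is scaled by the genotype, and a C-start midline
#' whose peak bend is scaled by the genotype. The field potential is
#' band-passed (300-500 Hz), notched at 50 Hz and thresholded; latency,
#' spike count and median instantaneous frequency come from the detected
#' train, and the median curvature amplitude from the midline analysis.
#'
#' @param cfg a [run_config()].
#' @param seed integer seed.
#' @return list with `metrics` (id, genotype, sex, latency_ms, spike_count,
#'   median_instantaneous_hz, curvature_amplitude_deg, latency_defined) and
#'   `truth` (true latency and spike count per fish).
#' @export
simulate_cstart_cohort <- function(cfg, seed = cfg$seed) {
  cs <- cfg$cstart; ep <- cfg$ephys
  set.seed(derive_seed(seed, 2L))
  rows <- list(); truths <- list(); id <- 0L
  for (g in names(cfg$effects)) {
    eff <- cfg$effects[[g]]
    n <- cfg$n_per_group[[g]]
    lat <- pmax(1, cs$latency_base_ms + eff$latency_shift +
                  stats::rnorm(n, 0, cs$latency_sd_ms))
    cnt <- pmax(1L, as.integer(round(ep$spike_count_base *
                                       eff$spike_count_mult *
                                       exp(stats::rnorm(n, 0, 0.15)))))
    pk <- cs$peak_bend * eff$amplitude_mult * exp(stats::rnorm(n, 0, 0.08))
    fish_seeds <- sample.int(1e6, n)
    for (j in seq_len(n)) {
      id <- id + 1L
      # spike burst: first spike at the true latency, then gamma ISIs
      set.seed(fish_seeds[j])
      isi <- stats::rgamma(cnt[j] - 1, shape = 4, rate = 4 / 0.02)
      isi <- pmax(isi, 0.006)
      st <- cs$stimulus_onset + lat[j] / 1000 + c(0, cumsum(isi))
      st <- st[st < cs$duration - 0.01]
      tr <- simulate_field_potential(
        ephys_truth(st, cs$stimulus_onset, ep$noise_sd),
        duration = cs$duration, sample_rate = ep$sample_rate,
        spike_amplitude = ep$snr * ep$noise_sd,
        mains_amplitude = ep$mains_amplitude, seed = fish_seeds[j])
      filt <- notch_mains(bandpass(tr, ep$band[1], ep$band[2]),
                          cfg$ephys$notch)
      train <- detect_spikes(filt)
      lt <- spike_latency(train, cs$stimulus_onset)
      instf <- instantaneous_frequency(train)
      instf <- instf$freq_hz[instf$time >= cs$stimulus_onset]

      mlp <- swimmer_params(frame_rate = cs$frame_rate,
                            duration = cs$duration, tailbeat_freq = 0,
                            bend_amplitude = 0, seed = id)
      sim <- simulate_cstart(mlp, latency_ms = lat[j], peak_bend = pk[j],
                             stimulus_onset = cs$stimulus_onset)
      ser <- compute_kinematics(sim$midlines)
      mca <- median_curvature_amplitude(
        ser, c(cs$stimulus_onset, cs$stimulus_onset + 1),
        min_amplitude = cfg$bend_min_amplitude)
      rows[[id]] <- data.frame(
        id = id, genotype = g, sex = cfg$sex,
        latency_ms = lt$latency_ms, latency_defined = lt$defined,
        spike_count = spike_count(train, cs$stimulus_onset,
                                  ep$count_window),
        median_instantaneous_hz =
          if (length(instf)) stats::median(instf) else NA_real_,
        curvature_amplitude_deg = mca$value)
      truths[[id]] <- data.frame(id = id, genotype = g,
                                 true_latency_ms = lat[j],
                                 true_spike_count = length(st),
                                 true_peak_bend = pk[j])
    }
  }
  list(metrics = do.call(rbind, rows), truth = do.call(rbind, truths))
}

#' Measure a counter-current cohort
#'
#' Simulates the cohort trajectories, then measures each fish's mean
#' distance to the stream centreline and builds per-genotype occupancy
#' maps.
#'
#' @param cfg a [run_config()].
#' @param seed integer seed.
#' @return list with `metrics` (id, genotype, sex, centre_distance_m),
#'   `occupancy` (named list of [occupancy_map()] per genotype), `truth`.
#' @export
simulate_counter_current_metrics <- function(cfg, seed = cfg$seed) {
  cc <- cfg$counter_current
  arena <- list(length = cc$arena_length, width = cc$arena_width)
  sim <- simulate_counter_current_cohort(
    effects = cfg$effects, n_per_group = cfg$n_per_group, arena = arena,
    duration = cc$duration, frame_rate = cc$frame_rate,
    baseline_offset = cc$baseline_offset, seed = derive_seed(seed, 3L))
  centreline <- list(point = c(0, arena$width / 2), direction = c(1, 0))
  ids <- unique(sim$trajectories$id)
  rows <- lapply(ids, function(i) {
    tr <- sim$trajectories[sim$trajectories$id == i, ]
    data.frame(id = i, genotype = tr$genotype[1], sex = cfg$sex,
               centre_distance_m = distance_to_stream_centre(tr, centreline))
  })
  occ <- lapply(split(sim$trajectories, sim$trajectories$genotype),
                function(tr) occupancy_map(tr, c(0, arena$length),
                                           c(0, arena$width),
                                           cfg$occupancy_bins))
  list(metrics = do.call(rbind, rows), occupancy = occ, truth = sim$truth)
}

#' Pairwise genotype comparisons for a panel of metrics
#'
#' For each metric (panel), runs Fisher's permutation test on every
#' genotype pair and applies Benjamini-Hochberg correction within the
#' panel, mirroring per-panel reporting.
#'
#' @param metrics metric table (id, genotype, ... metric columns).
#' @param panels character vector of metric column names.
#' @param n_resamples,seed passed to [permutation_test()].
#' @return results data.frame in the schema of [write_results_table()].
#' @export
compare_genotypes <- function(metrics, panels, n_resamples = 200000,
                              seed = 1L) {
  gs <- unique(metrics$genotype)
  out <- list()
  sd_i <- as.integer(seed)
  for (panel in panels) {
    prs <- utils::combn(gs, 2)
    fam <- list()
    for (j in seq_len(ncol(prs))) {
      g1 <- prs[1, j]; g2 <- prs[2, j]
      x1 <- metrics[[panel]][metrics$genotype == g1]
      x2 <- metrics[[panel]][metrics$genotype == g2]
      x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]  # undefined excluded
      pt <- permutation_test(x1, x2, n_resamples = n_resamples, seed = sd_i)
      sd_i <- sd_i + 1L
      fam[[j]] <- data.frame(panel = panel,
                             comparison = paste(g1, "vs", g2),
                             statistic = pt$statistic_name,
                             value = pt$observed, p_raw = pt$p_raw,
                             p_adjusted = NA_real_,
                             n_resamples = pt$n_resamples,
                             seed = if (pt$exact) NA_integer_ else pt$seed)
    }
    fam <- do.call(rbind, fam)
    fam$p_adjusted <- bh_adjust(fam$p_raw)
    out[[panel]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the end-to-end pipeline
#'
#' Simulate -> measure -> compare, in declared order: free-swim kinematics,
#' C-start electrophysiology and curvature, counter-current distance and
#' occupancy, then the permutation/BH statistics layer. All outputs are
#' written under `outdir` as CSV (+ JSON sidecars) stamped with the config
#' hash and seed; re-running with an identical config reproduces every
#' output bit-identically.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory.
#' @return (invisibly) list with `metrics`, `results`, `occupancy`,
#'   `truth`, `config_hash`.
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- force(expr)
    message(sprintf("[swimkin] %-18s %6.1f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }
  swim <- stage("free_swim", simulate_swim_cohort(cfg))
  cstart <- stage("cstart_ephys", simulate_cstart_cohort(cfg))
  cc <- stage("counter_current", simulate_counter_current_metrics(cfg))

  tables <- list(
    swim = list(metrics = swim$metrics,
                panels = c("activity", "m_per_bend",
                           "median_bend_amplitude_deg")),
    cstart = list(metrics = cstart$metrics,
                  panels = c("latency_ms", "spike_count",
                             "curvature_amplitude_deg")),
    counter_current = list(metrics = cc$metrics,
                           panels = "centre_distance_m"))
  results <- stage("stats", {
    res <- list()
    for (k in seq_along(tables))
      res[[k]] <- compare_genotypes(tables[[k]]$metrics,
                                    tables[[k]]$panels,
                                    n_resamples = cfg$n_resamples,
                                    seed = derive_seed(cfg$seed, 4L + k))
    do.call(rbind, res)
  })

  metrics <- lapply(tables, `[[`, "metrics")
  for (k in names(metrics))
    write_metric_table(metrics[[k]],
                       file.path(outdir, paste0("metrics_", k, ".csv")))
  write_results_table(results, file.path(outdir, "results.csv"))
  for (g in names(cc$occupancy))
    write_occupancy_map(cc$occupancy[[g]],
                        file.path(outdir, paste0("occupancy_", g, ".csv")))
  jsonlite::write_json(list(config_hash = hash, seed = cfg$seed),
                       file.path(outdir, "run_meta.json"),
                       auto_unbox = TRUE)
  invisible(list(metrics = metrics, results = results,
                 occupancy = cc$occupancy,
                 truth = list(swim = swim$truth, cstart = cstart$truth,
                              counter_current = cc$truth),
                 config_hash = hash))
}
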