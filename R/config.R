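#' Build a validated pipeline run configuration
#'
#' Defaults reproduce the study's recording regimes: free/motivated swims
#' 30 s at 200 frames/s, counter-current trials 30 s at 501 frames/s,
#' escape responses 5 s at 923 frames/s with the stimulus at 1 s, a
#' 300-500 Hz field-potential pass band with 50 Hz mains rejection, the
#' 0.025 m/s activity threshold, and 200,000 permutation resamples.
#' Unknown keys are rejected (typo safety).
#'
#' @param ... overrides of the default keys; nested lists replace whole
#'   sections.
#' @return validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_per_group = c(wt = 8L, het = 8L, hom = 8L),
    sex = "f",
    effects = default_genotype_effects(),
    free_swim = list(frame_rate = 200, duration = 30,
                     body_length = 0.03, bend_amplitude = 0.5,
                     tailbeat_freq = 5, target_speed = 0.05,
                     amplitude_cv = 0.12, speed_cv = 0.10),
    counter_current = list(frame_rate = 501, duration = 30,
                           arena_length = 0.172, arena_width = 0.044,
                           baseline_offset = 0.004),
    cstart = list(frame_rate = 923, duration = 5, stimulus_onset = 1,
                  peak_bend = 1.8, latency_base_ms = 12,
                  latency_sd_ms = 3),
    ephys = list(sample_rate = 10000, noise_sd = 1e-5, snr = 5,
                 mains_amplitude = 2e-5, band = c(300, 500),
                 notch = 50, spike_count_base = 10,
                 count_window = 0.5),
    activity_threshold = 0.025,
    bend_min_amplitude = 10,
    n_resamples = 200000L,
    occupancy_bins = c(40, 20))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(over)) {
    if (is.list(cfg[[k]]) && is.list(over[[k]]) && k != "effects") {
      bad <- setdiff(names(over[[k]]), names(cfg[[k]]))
      if (length(bad))
        stop("unknown config key(s) in '", k, "': ",
             paste(bad, collapse = ", "))
      cfg[[k]][names(over[[k]])] <- over[[k]]
    } else {
      cfg[[k]] <- over[[k]]
    }
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  rates <- c(cfg$free_swim$frame_rate, cfg$counter_current$frame_rate,
             cfg$cstart$frame_rate, cfg$ephys$sample_rate)
  if (any(rates <= 0)) stop("all rates must be > 0")
  if (cfg$activity_threshold <= 0) stop("activity_threshold must be > 0")
  nyq <- cfg$ephys$sample_rate / 2
  if (cfg$ephys$band[2] >= nyq || cfg$ephys$band[1] >= cfg$ephys$band[2])
    stop("filter band must satisfy low < high < Nyquist")
  if (cfg$ephys$notch >= nyq) stop("notch frequency must be below Nyquist")
  if (any(cfg$n_per_group < 1)) stop("n_per_group must be >= 1")
  if (cfg$n_resamples < 1) stop("n_resamples must be >= 1")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat, human-readable key-value document; unknown keys are rejected.
#' Keys mirror [run_config()].
#'
#' @param path YAML file path.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if ("effects" %in% names(raw)) {
    raw$effects <- lapply(raw$effects, function(e)
      do.call(genotype_effect, e))
  }
  if ("n_per_group" %in% names(raw)) raw$n_per_group <- unlist(raw$n_per_group)
  do.call(run_config, raw)
}

# stable content hash of a config (written into every output bundle)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(cfg), function(x)
    if (is.function(x)) deparse(x) else x, how = "replace")
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}
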