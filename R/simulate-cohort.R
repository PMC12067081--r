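#' Genotype effect on locomotor and electrophysiological metrics
#'
#' Encodes how a genotype scales or shifts the simulated phenotype relative
#' to wild type: multiplicative effects on bend amplitude, propulsion
#' efficiency and post-stimulus spike count, an additive shift of the
#' escape-response spike latency, and an additive shift of the equilibrium
#' distance to the stream centreline in counter-current trials.
#'
#' @param label one of `"wt"`, `"het"`, `"hom"`.
#' @param amplitude_mult,efficiency_mult,spike_count_mult dimensionless
#'   multipliers, > 0.
#' @param latency_shift additive latency shift, ms.
#' @param centre_distance_shift additive shift of equilibrium lateral
#'   offset, metres.
#' @return a `genotype_effect` list.
#' @export
genotype_effect <- function(label, amplitude_mult = 1, efficiency_mult = 1,
                            latency_shift = 0, spike_count_mult = 1,
                            centre_distance_shift = 0) {
  label <- match.arg(label, c("wt", "het", "hom"))
  if (amplitude_mult <= 0 || efficiency_mult <= 0 || spike_count_mult <= 0)
    stop("all multipliers must be > 0")
  structure(list(label = label, amplitude_mult = amplitude_mult,
                 efficiency_mult = efficiency_mult,
                 latency_shift = latency_shift,
                 spike_count_mult = spike_count_mult,
                 centre_distance_shift = centre_distance_shift),
            class = "genotype_effect")
}

#' Default genotype effect table
#'
#' Graded effects in the direction reported for the mutant line: reduced
#' bend amplitude (hence propulsion efficiency and curvature amplitude),
#' longer escape-response spike latency, fewer post-stimulus spikes, and a
#' larger equilibrium distance from the stream centre, with heterozygotes
#' intermediate. The homozygous amplitude multiplier 0.7 and +30 ms latency
#' shift define the study's nominal effect size.
#'
#' @return named list of [genotype_effect()]s for wt, het, hom.
#' @export
default_genotype_effects <- function() {
  list(wt = genotype_effect("wt"),
       het = genotype_effect("het", amplitude_mult = 0.85,
                             efficiency_mult = 0.85, latency_shift = 15,
                             spike_count_mult = 0.8,
                             centre_distance_shift = 0.005),
       hom = genotype_effect("hom", amplitude_mult = 0.7,
                             efficiency_mult = 0.7, latency_shift = 30,
                             spike_count_mult = 0.6,
                             centre_distance_shift = 0.010))
}

#' Simulate a counter-current cohort of centroid trajectories
#'
#' Each fish's lateral offset from the stream centreline follows a
#' mean-reverting (Ornstein-Uhlenbeck) walk whose equilibrium is
#' `baseline_offset + centre_distance_shift` for its genotype, with a small
#' per-fish random equilibrium jitter; the along-stream coordinate reverts
#' to the arena centre. Trajectories are reflected at the arena walls. The
#' arena defaults to the 17.2 x 4.4 cm counter-current tank filmed at
#' 501 frames/s for 30 s.
#'
#' @param effects named list of [genotype_effect()]s.
#' @param n_per_group integer, fish per genotype (scalar or named vector).
#' @param arena list with `length`, `width` (m); the centreline runs along
#'   the length at `width/2`.
#' @param duration s; @param frame_rate Hz.
#' @param baseline_offset wild-type equilibrium lateral offset, m.
#' @param reversion OU reversion rate, 1/s.
#' @param noise_sd OU driving noise, m/sqrt(s).
#' @param offset_jitter_sd per-fish equilibrium jitter, m.
#' @param seed integer seed.
#' @return list with `trajectories` (data.frame: id, genotype, frame, x_m,
#'   y_m), `truth` (data.frame: id, genotype, equilibrium_offset), `arena`,
#'   and `frame_rate`.
#' @export
simulate_counter_current_cohort <- function(effects = default_genotype_effects(),
                                            n_per_group = 50,
                                            arena = list(length = 0.172,
                                                         width = 0.044),
                                            duration = 30, frame_rate = 501,
                                            baseline_offset = 0.004,
                                            reversion = 2, noise_sd = 0.004,
                                            offset_jitter_sd = 0.001,
                                            seed = 1L) {
  if (arena$width <= 0 || arena$length <= 0) stop("arena must have positive size")
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1")
  if (length(n_per_group) == 1)
    n_per_group <- stats::setNames(rep(n_per_group, length(effects)),
                                   names(effects))
  set.seed(as.integer(seed))
  nf <- as.integer(round(duration * frame_rate))
  dt <- 1 / frame_rate
  half_w <- arena$width / 2
  sd_step <- noise_sd * sqrt(dt)
  traj <- list(); truth <- list(); id <- 0L
  for (g in names(effects)) {
    eff <- effects[[g]]
    for (k in seq_len(n_per_group[[g]])) {
      id <- id + 1L
      mu <- baseline_offset + eff$centre_distance_shift +
        stats::rnorm(1, 0, offset_jitter_sd)
      side <- sample(c(-1, 1), 1)
      # lateral offset OU walk (signed, relative to centreline)
      y <- ou_path(nf, x0 = side * mu, mu = side * mu, theta = reversion,
                   dt = dt, sd_step = sd_step)
      y <- reflect_into(y, -half_w, half_w)
      # along-stream OU walk about the arena centre
      x <- ou_path(nf, x0 = arena$length / 2 +
                     stats::rnorm(1, 0, arena$length / 10),
                   mu = arena$length / 2, theta = 0.5, dt = dt,
                   sd_step = 4 * sd_step)
      x <- reflect_into(x, 0, arena$length)
      traj[[id]] <- data.frame(id = id, genotype = g,
                               frame = seq_len(nf) - 1L,
                               x_m = x, y_m = y + half_w)
      truth[[id]] <- data.frame(id = id, genotype = g,
                                equilibrium_offset = mu)
    }
  }
  list(trajectories = do.call(rbind, traj), truth = do.call(rbind, truth),
       arena = arena, frame_rate = frame_rate, seed = as.integer(seed))
}

# discrete Ornstein-Uhlenbeck path via a recursive linear filter
ou_path <- function(n, x0, mu, theta, dt, sd_step) {
  a <- 1 - theta * dt
  drive <- theta * mu * dt + stats::rnorm(n - 1, 0, sd_step)
  c(x0, as.numeric(stats::filter(drive, a, method = "recursive",
                                 init = x0)))
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  x <- ifelse(x > span, 2 * span - x, x)
  x + lo
}

#' Simulate per-fish scalar metrics for genotype cohorts
#'
#' Gaussian per-fish metrics whose group means are the base means scaled by
#' the genotype effect multipliers; the truth records the generating means
#' exactly. Used to exercise the statistics layer at the study's cohort
#' sizes with known ground truth.
#'
#' @param effects named list of [genotype_effect()]s.
#' @param n_per_group fish per group (scalar or named vector).
#' @param base_means named numeric vector of wild-type metric means; names
#'   in `c("efficiency", "amplitude", "latency", "spike_count",
#'   "centre_distance")` pick up the matching effect, others default to a
#'   multiplier of 1.
#' @param base_sds named numeric vector, same names, all >= 0.
#' @param sex sex label(s) to assign (recycled).
#' @param seed integer seed.
#' @return list with `metrics` (data.frame: id, genotype, sex, one column
#'   per metric) and `truth` (matrix of generating means, groups x metrics).
#' @export
simulate_cohort_metrics <- function(effects = default_genotype_effects(),
                                    n_per_group = 50,
                                    base_means = c(efficiency = 0.005,
                                                   amplitude = 40,
                                                   latency = 12,
                                                   spike_count = 10),
                                    base_sds = NULL, sex = "f", seed = 1L) {
  if (is.null(base_sds)) base_sds <- abs(base_means) * 0.25
  if (any(base_sds < 0)) stop("base_sds must be >= 0")
  if (!all(names(base_sds) == names(base_means)))
    stop("base_means and base_sds must share names")
  if (length(n_per_group) == 1)
    n_per_group <- stats::setNames(rep(n_per_group, length(effects)),
                                   names(effects))
  set.seed(as.integer(seed))
  mult_of <- function(eff, metric) {
    switch(metric,
           efficiency = eff$efficiency_mult,
           amplitude = eff$amplitude_mult,
           spike_count = eff$spike_count_mult,
           1)
  }
  shift_of <- function(eff, metric) {
    switch(metric,
           latency = eff$latency_shift,
           centre_distance = eff$centre_distance_shift,
           0)
  }
  groups <- names(effects)
  truth <- matrix(NA_real_, length(groups), length(base_means),
                  dimnames = list(groups, names(base_means)))
  rows <- list(); id <- 0L
  for (g in groups) {
    eff <- effects[[g]]
    n <- n_per_group[[g]]
    vals <- matrix(NA_real_, n, length(base_means))
    for (j in seq_along(base_means)) {
      m <- names(base_means)[j]
      truth[g, j] <- base_means[j] * mult_of(eff, m) + shift_of(eff, m)
      vals[, j] <- stats::rnorm(n, truth[g, j], base_sds[j])
    }
    df <- data.frame(id = id + seq_len(n), genotype = g,
                     sex = rep_len(sex, n))
    id <- id + n
    colnames(vals) <- names(base_means)
    rows[[g]] <- cbind(df, as.data.frame(vals))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, truth = truth, seed = as.integer(seed))
}
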