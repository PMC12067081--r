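#' Fisher's permutation test for a two-group comparison
#'
#' Pools the two samples and recomputes the statistic (difference of group
#' means by default; difference of medians optionally) over relabelings of
#' the pooled observations drawn without replacement. Two-sided p-value
#' with the add-one correction, `p = (#{|T*| >= |T_obs|} + 1) / (R + 1)`,
#' which is a valid p-value at any finite number of resamples. When the
#' number of distinct splits `choose(n1+n2, n1)` does not exceed
#' `exhaustive_cutoff`, all splits are enumerated and the exact p-value
#' `#{|T*| >= |T_obs|} / n_splits` is reported instead.
#'
#' The default of 200,000 resamples matches the source assay's convention
#' ("bootstrapped 200,000 times" there names label permutation, not a
#' with-replacement bootstrap; set `replace = TRUE` for the literal
#' bootstrap null).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param statistic `"mean_diff"` or `"median_diff"` (a - b).
#' @param n_resamples Monte-Carlo resamples R.
#' @param seed integer seed for the Monte-Carlo draw.
#' @param exhaustive_cutoff enumerate exactly when the number of distinct
#'   splits is at most this (default 1e5).
#' @param replace draw relabelings with replacement (bootstrap null)
#'   instead of permutation; non-default.
#' @return object of class `permutation_result`: `observed`, `p_raw`,
#'   `p_adjusted` (NA until [bh_adjust()] is applied to a family),
#'   `n_resamples` (resamples actually used), `exact`, `seed`,
#'   `statistic_name`, `n1`, `n2`.
#' @export
permutation_test <- function(a, b, statistic = c("mean_diff", "median_diff"),
                             n_resamples = 200000, seed = 1L,
                             exhaustive_cutoff = 1e5, replace = FALSE) {
  statistic <- match.arg(statistic)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 observations")
  stat_fun <- if (statistic == "mean_diff") {
    function(x, y) mean(x) - mean(y)
  } else {
    function(x, y) stats::median(x) - stats::median(y)
  }
  pool <- c(a, b)
  n1 <- length(a); n <- length(pool)
  t_obs <- stat_fun(a, b)
  tol <- 1e-9 * (1 + abs(t_obs))          # guard against FP ties
  n_splits <- choose(n, n1)
  if (!replace && n_splits <= exhaustive_cutoff) {
    idx <- utils::combn(n, n1)
    tstar <- apply(idx, 2, function(ii) stat_fun(pool[ii], pool[-ii]))
    p <- sum(abs(tstar) >= abs(t_obs) - tol) / n_splits
    res <- list(observed = t_obs, p_raw = p, p_adjusted = NA_real_,
                n_resamples = as.integer(n_splits), exact = TRUE,
                seed = NA_integer_, statistic_name = statistic,
                n1 = n1, n2 = n - n1)
  } else {
    set.seed(as.integer(seed))
    count <- 0L
    fast_mean <- statistic == "mean_diff"
    tot <- sum(pool)
    for (r in seq_len(n_resamples)) {
      ii <- sample.int(n, n1, replace = replace)
      ts <- if (fast_mean && !replace) {
        sa <- sum(pool[ii])
        sa / n1 - (tot - sa) / (n - n1)
      } else {
        stat_fun(pool[ii],
                 if (replace) pool[sample.int(n, n - n1, replace = TRUE)]
                 else pool[-ii])
      }
      if (abs(ts) >= abs(t_obs) - tol) count <- count + 1L
    }
    p <- (count + 1) / (n_resamples + 1)
    res <- list(observed = t_obs, p_raw = p, p_adjusted = NA_real_,
                n_resamples = as.integer(n_resamples), exact = FALSE,
                seed = as.integer(seed), statistic_name = statistic,
                n1 = n1, n2 = n - n1)
  }
  structure(res, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s = %.6g, p = %.4g (%s, R = %d)%s\n",
              x$statistic_name, x$observed, x$p_raw,
              if (x$exact) "exact" else "Monte-Carlo", x$n_resamples,
              if (is.na(x$p_adjusted)) "" else
                sprintf(", BH-adjusted p = %.4g", x$p_adjusted)))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment of a family of p-values, returned in input
#' order and capped at 1. The family should be the set of comparisons
#' reported together (e.g. all pairwise comparisons of one figure panel).
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Percentile bootstrap confidence interval
#'
#' CI of the mean of `values` (or of any statistic supplied) by the
#' percentile method; deterministic given the seed. For a category
#' proportion, pass a 0/1 membership vector (the mean is the proportion).
#'
#' @param values numeric vector, length >= 2.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples.
#' @param statistic function of a numeric vector (default mean).
#' @param seed integer seed.
#' @return named numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, level = 0.95, n_boot = 10000,
                         statistic = mean, seed = 1L) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  set.seed(as.integer(seed))
  n <- length(values)
  bs <- vapply(seq_len(n_boot),
               function(i) statistic(values[sample.int(n, n, replace = TRUE)]),
               numeric(1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Analyse ordered staining categories across groups
#'
#' Per-group per-category proportions with bootstrap CIs, optional pooled
#' category subsets (e.g. categories 1-3 together versus 4), and pairwise
#' group comparisons by permuting cell-level category labels across groups
#' with the difference of proportions as the statistic.
#'
#' @param counts integer matrix, groups x categories (rownames = group
#'   labels, K >= 2 categories).
#' @param pool named list of category index vectors to pool (must not
#'   overlap); each pooled subset is analysed like a single category.
#' @param n_resamples,seed passed to the cell-level permutation.
#' @param ci_boot bootstrap resamples for the proportion CIs.
#' @return list with `proportions` (data.frame: group, category, count,
#'   total, proportion, ci_lower, ci_upper) and `comparisons` (data.frame:
#'   category, group_a, group_b, statistic, p_raw, p_adjusted — BH within
#'   each category family across the group pairs).
#' @export
category_analysis <- function(counts, pool = NULL, n_resamples = 2000,
                              seed = 1L, ci_boot = 2000) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 groups")
  if (ncol(counts) < 2) stop("need at least 2 categories")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("group", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cat", seq_len(ncol(counts)))
  totals <- rowSums(counts)   # cells per group, over original categories
  if (!is.null(pool)) {
    all_idx <- unlist(pool)
    if (anyDuplicated(all_idx)) stop("pooled category subsets must not overlap")
    pooled <- vapply(pool, function(ii) rowSums(counts[, ii, drop = FALSE]),
                     numeric(nrow(counts)))
    counts <- cbind(counts, pooled)
  }
  groups <- rownames(counts)
  props <- list(); comp <- list()
  sd_i <- as.integer(seed)
  for (cat in colnames(counts)) {
    for (g in groups) {
      k <- counts[g, cat]; ntot <- totals[g]
      memb <- c(rep(1, k), rep(0, ntot - k))
      ci <- if (ntot >= 2) bootstrap_ci(memb, n_boot = ci_boot, seed = sd_i)
            else c(lower = NA_real_, upper = NA_real_)
      sd_i <- sd_i + 1L
      props[[length(props) + 1]] <- data.frame(
        group = g, category = cat, count = k, total = ntot,
        proportion = k / ntot, ci_lower = ci[["lower"]],
        ci_upper = ci[["upper"]])
    }
    prs <- utils::combn(groups, 2)
    fam <- list()
    for (j in seq_len(ncol(prs))) {
      g1 <- prs[1, j]; g2 <- prs[2, j]
      m1 <- c(rep(1, counts[g1, cat]), rep(0, totals[g1] - counts[g1, cat]))
      m2 <- c(rep(1, counts[g2, cat]), rep(0, totals[g2] - counts[g2, cat]))
      pt <- permutation_test(m1, m2, n_resamples = n_resamples, seed = sd_i,
                             exhaustive_cutoff = 0)
      sd_i <- sd_i + 1L
      fam[[j]] <- data.frame(category = cat, group_a = g1, group_b = g2,
                             statistic = pt$observed, p_raw = pt$p_raw,
                             p_adjusted = NA_real_)
    }
    fam <- do.call(rbind, fam)
    fam$p_adjusted <- bh_adjust(fam$p_raw)
    comp[[length(comp) + 1]] <- fam
  }
  list(proportions = do.call(rbind, props),
       comparisons = do.call(rbind, comp))
}

#' Per-area event rates and group comparison
#'
#' Per-animal event rate per 1000 square micrometres, and a permutation
#' comparison of the per-animal rates between the two groups.
#'
#' @param events data.frame with columns `group`, `count`, `area_um2`
#'   (surveyed area per animal, > 0).
#' @param n_resamples,seed passed to [permutation_test()] (exhaustive
#'   enumeration is used automatically at small n).
#' @return list with `rates` (input plus `rate_per_1000um2`) and
#'   `comparison` (a `permutation_result`, or NULL when either group has
#'   fewer than 2 animals).
#' @export
event_rate <- function(events, n_resamples = 200000, seed = 1L) {
  stopifnot(all(c("group", "count", "area_um2") %in% names(events)))
  if (any(events$area_um2 <= 0)) stop("surveyed area must be > 0")
  if (any(events$count < 0)) stop("event counts must be >= 0")
  events$rate_per_1000um2 <- events$count / events$area_um2 * 1000
  gs <- unique(events$group)
  comparison <- NULL
  if (length(gs) == 2) {
    r1 <- events$rate_per_1000um2[events$group == gs[1]]
    r2 <- events$rate_per_1000um2[events$group == gs[2]]
    if (length(r1) >= 2 && length(r2) >= 2)
      comparison <- permutation_test(r1, r2, n_resamples = n_resamples,
                                     seed = seed)
  }
  list(rates = events, comparison = comparison)
}

#' Audit the type-I error of the permutation test
#'
#' Simulates null Gaussian cohorts (both groups from one distribution),
#' runs the Monte-Carlo permutation test on each, and reports the fraction
#' rejected at `alpha`. Under the null that fraction should sit at the
#' nominal level within binomial error.
#'
#' @param n_per_group observations per group.
#' @param n_datasets number of simulated null datasets (>= 100).
#' @param alpha rejection threshold.
#' @param n_resamples Monte-Carlo resamples per test.
#' @param seed integer seed.
#' @return list with `rejection_fraction`, `n_datasets`, `alpha`.
#' @export
type1_error_audit <- function(n_per_group = 20, n_datasets = 1000,
                              alpha = 0.05, n_resamples = 2000, seed = 1L) {
  if (n_datasets < 100) stop("n_datasets must be >= 100")
  set.seed(as.integer(seed))
  n <- 2L * n_per_group
  rej <- 0L
  for (d in seq_len(n_datasets)) {
    x <- stats::rnorm(n)
    tot <- sum(x)
    t_obs <- abs(sum(x[seq_len(n_per_group)]) / n_per_group -
                 (tot - sum(x[seq_len(n_per_group)])) / n_per_group)
    count <- 0L
    for (r in seq_len(n_resamples)) {
      sa <- sum(x[sample.int(n, n_per_group)])
      if (abs(sa / n_per_group - (tot - sa) / n_per_group) >=
          t_obs - 1e-12) count <- count + 1L
    }
    if ((count + 1) / (n_resamples + 1) <= alpha) rej <- rej + 1L
  }
  list(rejection_fraction = rej / n_datasets, n_datasets = n_datasets,
       alpha = alpha)
}
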