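test_that("symmetric inputs give p = 1 and extreme separation the minimal p", {
  pt <- permutation_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pt$observed, 0)
  expect_equal(pt$p_raw, 1)
  pt2 <- permutation_test(c(0, 0, 0, 0), c(10, 10, 10, 10))
  expect_true(pt2$exact)
  expect_equal(pt2$n_resamples, choose(8, 4))
  expect_equal(pt2$p_raw, 2 / 70)
})

test_that("exact mode reproduces an independent enumeration bit-for-bit", {
  cases <- list(list(a = c(0, 0, 0, 0), b = c(10, 10, 10, 10)),
                list(a = c(1, 3, 5, 7), b = c(2, 4, 6, 8, 10)),
                list(a = c(-1, 0, 2), b = c(5, 6, 7)),
                list(a = c(1.5, 2.5), b = c(1.5, 2.5, 9)))
  for (cs in cases) {
    pt <- permutation_test(cs$a, cs$b)
    expect_true(pt$exact)
    expect_identical(pt$p_raw, enumerate_perm_p(cs$a, cs$b))
  }
})

test_that("Monte-Carlo p agrees with exact p within binomial error", {
  set.seed(31)
  for (rep in 1:5) {
    a <- rnorm(4); b <- rnorm(5) + rep / 3
    pe <- permutation_test(a, b)$p_raw
    pm <- permutation_test(a, b, n_resamples = 2000, seed = rep,
                           exhaustive_cutoff = 0)$p_raw
    bound <- 3 * sqrt(pe * (1 - pe) / 2000) + 1 / 2001
    expect_lt(abs(pm - pe), bound + 1e-12)
  }
})

test_that("permutation p is invariant to group swap and location shift", {
  set.seed(32)
  a <- rnorm(6); b <- rnorm(7) + 0.8
  p_ab <- permutation_test(a, b)$p_raw
  p_ba <- permutation_test(b, a)$p_raw
  expect_identical(p_ab, p_ba)
  p_shift <- permutation_test(a + 100, b + 100)$p_raw
  expect_identical(p_ab, p_shift)
  # Monte-Carlo p respects its attainable range
  pm <- permutation_test(a, b, n_resamples = 999, seed = 2,
                         exhaustive_cutoff = 0)
  expect_gte(pm$p_raw, 1 / 1000)
  expect_lte(pm$p_raw, 1)
  expect_error(permutation_test(numeric(0), b), "2 observations")
})

test_that("median-difference statistic is available", {
  a <- c(1, 2, 100); b <- c(4, 5, 6)
  pt <- permutation_test(a, b, statistic = "median_diff")
  expect_equal(pt$observed, 2 - 5)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # hand-worked mixed example: sorted (0.005, 0.04, 0.04, 0.8);
  # q4 = 0.8, q3 = min(4*0.04/3, 0.8) = 0.0533..., q2 = same, q1 = 0.02
  expect_equal(bh_adjust(c(0.04, 0.8, 0.005, 0.04)),
               c(4 * 0.04 / 3, 0.8, 0.02, 4 * 0.04 / 3))
  expect_identical(bh_adjust(0.37), 0.37)   # m = 1: identity
  set.seed(33)
  p <- runif(20)
  q <- bh_adjust(p)
  expect_true(all(q >= p))                  # never decreases
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))    # monotone in sorted order
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("bootstrap CI: degenerate, deterministic, and near Wilson", {
  expect_equal(unname(bootstrap_ci(rep(3.2, 10))), c(3.2, 3.2))
  x <- c(rep(1, 170), rep(0, 30))
  ci1 <- bootstrap_ci(x, n_boot = 10000, seed = 3L)
  ci2 <- bootstrap_ci(x, n_boot = 10000, seed = 3L)
  expect_identical(ci1, ci2)
  wilson <- stats::prop.test(170, 200, correct = FALSE)$conf.int
  expect_lt(abs(ci1[["lower"]] - wilson[1]), 0.01)
  expect_lt(abs(ci1[["upper"]] - wilson[2]), 0.01)
})

test_that("category analysis: proportions, pooling, and null symmetry", {
  counts <- rbind(wt = c(10, 10, 10, 170), mut = c(60, 30, 20, 90))
  colnames(counts) <- paste0("cat", 1:4)
  res <- category_analysis(counts, pool = list(cat123 = 1:3),
                           n_resamples = 2000, seed = 7L)
  p4 <- res$proportions
  expect_equal(p4$proportion[p4$group == "wt" & p4$category == "cat4"],
               0.85)
  expect_equal(p4$proportion[p4$group == "wt" & p4$category == "cat123"],
               0.15)
  expect_error(category_analysis(counts, pool = list(a = 1:3, b = 3:4)),
               "overlap")
  # identical groups: all pairwise p well above any rejection level
  same <- rbind(g1 = c(50, 50, 50, 50), g2 = c(50, 50, 50, 50))
  res2 <- category_analysis(same, n_resamples = 2000, seed = 8L)
  expect_true(all(res2$comparisons$p_raw >= 0.5))
})

test_that("a 30% category shift is detected with high power", {
  # moved cells: 45 of 150 from cat4 to cat1
  counts <- rbind(wt = c(5, 10, 10, 125), mut = c(50, 10, 10, 80))
  hits <- 0
  for (s in 1:50) {
    res <- category_analysis(counts, pool = list(c123 = 1:3),
                             n_resamples = 500, seed = s)
    pp <- res$comparisons
    if (pp$p_raw[pp$category == "c123"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("event rates are per 1000 um2 with a permutation comparison", {
  ev <- data.frame(group = c("wt", "wt", "mut", "mut", "mut"),
                   count = c(6, 0, 12, 9, 15),
                   area_um2 = c(3000, 2500, 3000, 2000, 2500))
  out <- event_rate(ev, seed = 4L)
  expect_equal(out$rates$rate_per_1000um2[1], 2)
  expect_equal(out$rates$rate_per_1000um2[2], 0)
  expect_true(out$comparison$exact)   # C(5,2) = 10 splits: enumerated
  expect_error(event_rate(data.frame(group = "a", count = 1,
                                     area_um2 = 0)), "area")
})

test_that("event-rate comparison recovers a doubled Poisson rate direction", {
  # small-n electron-microscopy design: 2 wt vs 5 mutant animals
  set.seed(35)
  correct_sign <- 0
  for (r in 1:200) {
    ev <- data.frame(group = rep(c("wt", "mut"), c(2, 5)),
                     count = c(rpois(2, 4), rpois(5, 8)),
                     area_um2 = 3000)
    out <- event_rate(ev, seed = r)
    correct_sign <- correct_sign + (out$comparison$observed < 0)
  }
  expect_gte(correct_sign / 200, 0.9)
})

test_that("type-I error audit sits at the nominal level", {
  out <- type1_error_audit(n_per_group = 10, n_datasets = 200,
                           n_resamples = 500, seed = 6L)
  expect_gte(out$rejection_fraction, 0.05 - 3 * sqrt(0.05 * 0.95 / 200))
  expect_lte(out$rejection_fraction, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  expect_error(type1_error_audit(n_datasets = 10), "100")
})

test_that("effect of 1 sd at n = 60 per group is detected with power >= 0.9", {
  set.seed(36)
  rejections <- 0
  for (r in 1:200) {
    a <- rnorm(60); b <- rnorm(60) + 1
    p <- permutation_test(a, b, n_resamples = 500, seed = r)$p_raw
    if (p <= 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 200, 0.9)
})
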