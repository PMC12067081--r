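#!/usr/bin/env Rscript
# Stage 5 — the statistics layer over the stage-3/4 metric tables.
#
# Pairwise Fisher permutation tests per panel with Benjamini-Hochberg
# correction within each panel, bootstrap CIs for the group means, and the
# categorical/per-area analyses on small worked examples (staining
# categories, myelin split events). Writes results/results.csv.

library(swimkin)

swim <- read_metric_table("results/metrics_swim.csv")
cstart <- read_metric_table("results/metrics_cstart.csv")
cc <- read_metric_table("results/metrics_counter_current.csv")

res <- rbind(
  compare_genotypes(swim, c("activity", "m_per_bend",
                            "median_bend_amplitude_deg"),
                    n_resamples = 20000, seed = 71L),
  compare_genotypes(cstart, c("latency_ms", "spike_count",
                              "curvature_amplitude_deg"),
                    n_resamples = 20000, seed = 72L),
  compare_genotypes(cc, "centre_distance_m", n_resamples = 20000,
                    seed = 73L))
write_results_table(res, "results/results.csv")
sig <- res[!is.na(res$p_adjusted) & res$p_adjusted < 0.05, ]
message(sprintf("%d of %d comparisons significant after BH:", nrow(sig),
                nrow(res)))
for (i in seq_len(nrow(sig)))
  message(sprintf("  %-28s %-10s diff %+.4g, p_adj %.3g", sig$panel[i],
                  sig$comparison[i], sig$value[i], sig$p_adjusted[i]))

# bootstrap 95% CI of the wild-type efficiency mean
ci <- bootstrap_ci(swim$m_per_bend[swim$genotype == "wt"], seed = 74L)
message(sprintf("wt m/bend mean %.4g, 95%% CI [%.4g, %.4g]",
                mean(swim$m_per_bend[swim$genotype == "wt"]),
                ci[["lower"]], ci[["upper"]]))

# worked categorical example: four staining severity categories
counts <- rbind(wt = c(5, 10, 15, 161), mut = c(44, 26, 20, 56))
colnames(counts) <- paste0("category", 1:4)
cat_res <- category_analysis(counts, pool = list(categories123 = 1:3),
                             n_resamples = 20000, seed = 75L)
write.csv(cat_res$proportions, "results/category_proportions.csv",
          row.names = FALSE)
write.csv(cat_res$comparisons, "results/category_comparisons.csv",
          row.names = FALSE)
p123 <- cat_res$comparisons[cat_res$comparisons$category == "categories123", ]
message(sprintf("pooled categories 1-3: wt %.2f vs mut %.2f, p_adj %.3g",
                cat_res$proportions$proportion[
                  cat_res$proportions$group == "wt" &
                    cat_res$proportions$category == "categories123"],
                cat_res$proportions$proportion[
                  cat_res$proportions$group == "mut" &
                    cat_res$proportions$category == "categories123"],
                p123$p_adjusted))

# worked per-area example: severe myelin split events per 1000 um^2
ev <- data.frame(group = rep(c("wt", "mut"), c(2, 5)),
                 count = c(1, 2, 9, 12, 7, 11, 8),
                 area_um2 = c(3100, 2900, 3000, 3200, 2800, 3050, 2950))
er <- event_rate(ev, seed = 76L)
write.csv(er$rates, "results/myelin_event_rates.csv", row.names = FALSE)
message(sprintf("myelin split rate: wt %.2f vs mut %.2f per 1000 um^2, p %.3g (%s)",
                mean(er$rates$rate_per_1000um2[er$rates$group == "wt"]),
                mean(er$rates$rate_per_1000um2[er$rates$group == "mut"]),
                er$comparison$p_raw,
                if (er$comparison$exact) "exact" else "Monte-Carlo"))
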