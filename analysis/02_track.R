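#!/usr/bin/env Rscript
# Stage 2 — extract midlines from the stage-1 silhouette stack and check
# them against the generator's truth.
#
# Writes the tracked midlines as CSV and a one-row accuracy table; the
# per-frame Hausdorff distance against the true midlines should sit below
# one pixel for the 3 px half-width body used here.

library(swimkin)

stack <- read_silhouette_stack("results/raw/swim_stack")
tracked <- extract_midline(stack, M = 51)
write_midline_csv(tracked, "results/tracked_midlines.csv")

truth <- read_midline_csv("results/raw/swim_true_midlines.csv")
px <- stack$pixel_scale
haus <- vapply(seq_len(dim(tracked$points)[1]), function(i) {
  A <- tracked$points[i, , ] / px
  B <- truth$points[i, , ] / px
  d <- function(P, Q) max(apply(P, 1, function(x)
    min(sqrt((Q[, 1] - x[1])^2 + (Q[, 2] - x[2])^2))))
  max(d(A, B), d(B, A))
}, numeric(1))
head_err <- sqrt(rowSums((tracked$points[, 1, ] - truth$points[, 1, ])^2)) / px

acc <- data.frame(frames = length(haus),
                  hausdorff_px_mean = mean(haus),
                  hausdorff_px_max = max(haus),
                  head_err_px_mean = mean(head_err))
write.csv(acc, "results/tracking_accuracy.csv", row.names = FALSE)
message(sprintf("tracked %d frames: Hausdorff mean %.2f px, max %.2f px, head error %.2f px",
                acc$frames, acc$hausdorff_px_mean, acc$hausdorff_px_max,
                acc$head_err_px_mean))
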