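#!/usr/bin/env Rscript
# Closed-form results of the Go-or-Grow traveling-wave analysis: the wave
# speed and its dichotomy, the division-contribution fraction phi over the
# (a0, doubling time) plane, the shape-based speed estimate, and the
# two-threshold variant solved by bisection.
#
# Findings (printed below and written to results/):
#  - at the experimental parameters (a0 = 1 um/min, 8 h doubling, D = 30)
#    the wave is pushed: sigma = 1.04 um/min, phi = 40%;
#  - the shape-based estimate from the ring morphology alone gives
#    ~0.9 um/min, consistent with the measured ring speed;
#  - the two-threshold variant never deviates more than a fraction of a
#    percent from the elementary formula over the scanned range.

library(aerowave)
dir.create("results", showWarnings = FALSE)

r0 <- log(2) / 480
w <- wave_speed(a0 = 1, r0 = r0, D = 30)
cat(sprintf("elementary wave speed: sigma = %.3f um/min (%s), phi = %.0f%%\n",
            w$sigma, w$regime, 100 * w$phi))
cat(sprintf("Fisher half-speed sqrt(r0 D) = %.3f um/min\n", sqrt(r0 * 30)))
cat(sprintf("shape-based estimate (L = 300 um, ratio 4): %.2f um/min\n",
            shape_speed_estimate(300, 4, r0)))

grid <- phi_grid(a0 = seq(0.05, 2, by = 0.05),
                 doubling_h = seq(2, 24, by = 0.5), D = 30)
write.csv(grid, "results/phi_heatmap.csv", row.names = FALSE)
cat("phi heatmap grid written to results/phi_heatmap.csv\n")

scan <- do.call(rbind, lapply(seq(0.2, 2, by = 0.2), function(a0) {
  do.call(rbind, lapply(seq(4, 16, by = 2), function(td) {
    r0g <- log(2) / (td * 60)
    if (a0 <= sqrt(r0g * 30)) return(NULL)
    res <- tryCatch(two_threshold_speed(mean_field_params(a0 = a0, r0 = r0g)),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(a0 = a0, doubling_h = td, sigma_two_threshold = res$sigma,
               sigma_elementary = res$sigma_elementary, gap_um = res$h,
               rel_dev = abs(res$sigma - res$sigma_elementary) /
                 res$sigma_elementary)
  }))
}))
write.csv(scan, "results/two_threshold_scan.csv", row.names = FALSE)
cat(sprintf("two-threshold scan: max relative deviation %.3f%% over %d points\n",
            100 * max(scan$rel_dev), nrow(scan)))
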