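#!/usr/bin/env Rscript
# Speed versus local surface coverage (all / inside / outside stationary
# aggregates), the fraction of cell area in aggregates per coverage bin,
# and radial profiles of the wild-type-like vs mutant-like series.

library(swarmaggr)

runs <- readRDS("results/runs.rds")
dir.create("results/coverage", showWarnings = FALSE, recursive = TRUE)

# pooled speed-coverage relation across the wild-type fields
rel <- do.call(rbind, lapply(seq_along(runs$wt), function(i) {
  r <- speed_coverage_relations(runs$wt[[i]]$analysis)
  r$seed <- runs$wt[[i]]$config$seed
  r
}))
write.csv(rel, "results/coverage/speed_by_coverage.csv", row.names = FALSE)

an1 <- runs$wt[[1]]$analysis
P <- dim(an1$speeds)[3]
af <- aggregate_fraction_by_coverage(an1$coverages[, , seq_len(P)],
                                     an1$stationary, an1$cfg)
write.csv(af, "results/coverage/aggregate_fraction_by_coverage.csv",
          row.names = FALSE)

out <- rel[rel$region == "OUTSIDE" & rel$coverage >= 0.3, ]
fit <- suppressWarnings(cor.test(out$coverage, out$mean_speed,
                                 method = "spearman"))
message(sprintf(
  "outside aggregates the mean speed rises with coverage: Spearman rho = %.2f (p = %.2g)",
  fit$estimate, fit$p.value))

cvs <- unlist(lapply(runs$wt, function(r) {
  r$analysis$coverages[, , seq_len(dim(r$analysis$speeds)[3])]
}))
ins <- unlist(lapply(runs$wt, function(r) r$analysis$stationary))
message(sprintf("mean local coverage inside / outside aggregates: %.2f",
                mean(cvs[ins]) / mean(cvs[!ins])))

# radial profiles: distance from the inoculum edge is metadata per field;
# here successive seeds stand in for successive positions
rp <- rbind(
  radial_profile(lapply(runs$wt[1:3], `[[`, "analysis"),
                 distances_mm = c(4, 8, 12), series = "WT"),
  radial_profile(lapply(runs$mut, `[[`, "analysis"),
                 distances_mm = c(4, 8, 12), series = "mutant"))
write.csv(rp, "results/coverage/radial_profiles.csv", row.names = FALSE)
print(rp)
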