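#!/usr/bin/env Rscript
# Stage 4: seasonal environmental summary (the thermal and resource
# envelope of the two hot-dry seasons): reference-miniglobe and dry-bulb
# daily extremes, solar, wind, rainfall totals and rainy days, NDVI, and
# the preceding wet-season rainfall carried by each window.

library(droughtlogger)

dataset <- read_study_dataset("results/simulated_study")

env <- environmental_summary(
  weather = dataset$weather, rainfall = dataset$rainfall,
  ndvi = dataset$ndvi, windows = season_windows(),
  reference_globe = dataset$reference_globe)
write.csv(env, "results/environmental_summary.csv", row.names = FALSE)

message("environmental conditions per hot-dry season (mean +/- SD):")
for (lab in unique(env$season)) {
  message("  ", lab, ":")
  sub <- env[env$season == lab, ]
  for (i in seq_len(nrow(sub))) {
    message(sprintf("    %-22s %8.2f%s", sub$variable[i], sub$mean[i],
                    ifelse(is.na(sub$sd[i]), "",
                           sprintf(" +/- %.2f", sub$sd[i]))))
  }
}
message("written to results/environmental_summary.csv")
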