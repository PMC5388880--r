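#!/usr/bin/env Rscript
# Simulate the two bolus-tracking cohorts: a healthy-control-like cohort
# (147 vessels, strong hypercapnic flow increase) and a disease-like
# cohort (117 vessels, abolished flow response, blunted reactivity).
# Writes the trace files and ground-truth tables under results/cohorts/.

library(neurovasc)

out <- "results/cohorts"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg_ntg <- bolus_cohort_config(
  n_vessels_per_type = c(arteriole = 49, capillary = 49, venule = 49),
  flow_change_true = 74,
  reactivity_true_by_type = c(arteriole = 15, capillary = 13, venule = 15),
  seed = 101)
cfg_tg <- bolus_cohort_config(
  n_vessels_per_type = c(arteriole = 39, capillary = 39, venule = 39),
  flow_change_true = -5.3,
  reactivity_true_by_type = c(arteriole = 8.0, capillary = 8.4,
                              venule = 7.3),
  seed = 102)

for (g in c("nTg", "Tg")) {
  cfg <- if (g == "nTg") cfg_ntg else cfg_tg
  co <- generate_bolus_cohort(cfg, traces = TRUE)
  write_bolus_cohort(co, file.path(out, g))
  message(sprintf("%s: %d vessels simulated (true flow change %+.1f%%)",
                  g, nrow(co$truth), cfg$flow_change_true))
}
message("traces and ground truth written under ", out)
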