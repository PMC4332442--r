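#!/usr/bin/env Rscript
# Quantify transvalvular flow on the canonical phantom with retrospective
# valve tracking: per-phase measurement planes perpendicular to the jet,
# 15 mm into the receiving chamber, flow-rate integration over the tracked
# intervals, and internal validation of the effective forward volume
# against aortic outflow. Writes the subject report and per-phase rates.

library(lavvflow)

report <- run_pipeline(pipeline_config(seed = 101,
                                       out_dir = "results/quantification"))

print(report$flow)
cat("\nrecovery errors vs the phantom manifest:\n")
for (k in names(report$deltas)) {
  cat(sprintf("  %-22s %+.3f\n", k, report$deltas[[k]]))
}
cat("\nwrote results/quantification/report.json and rates.csv\n")
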