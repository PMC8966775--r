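#!/usr/bin/env Rscript
# Generate the canonical synthetic recording set: one dual-channel
# recording per stimulation preset and one per artefact class, each with
# its ground-truth annotation. Everything downstream (02-05) reads from
# results/recordings/.

suppressPackageStartupMessages(library(fictiveswim))

seed <- 20260925L
out <- "results/recordings"
manifest <- make_fixtures(out, seed = seed, duration_s = 60)

cat("wrote", nrow(manifest), "fixture sets to", out, "\n")
print(as.data.frame(manifest))

# quick audit: bouts per preset and their injected frequency spread
for (p in c("spontaneous", "nmda", "electrical", "optomotor")) {
  gt <- read_ground_truth_json(file.path(out, paste0(p, "_truth.json")))
  cat(sprintf(
    "%-11s %2d bouts, injected freq %5.1f-%5.1f Hz, %2.0f%% cross 30 Hz\n",
    p, nrow(gt$bouts), min(gt$bouts$mean_freq_hz, na.rm = TRUE),
    max(gt$bouts$mean_freq_hz, na.rm = TRUE),
    100 * mean(gt$bouts$crosses_30hz)))
}
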