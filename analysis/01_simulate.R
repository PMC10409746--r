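#!/usr/bin/env Rscript
# Generate the two-media dropout experiment dataset.
#
# Simulates the full 12-strain consortium plus all twelve single-strain
# dropout communities in a glucose-like (AF) and a polysaccharide-like (APF)
# medium: 3 biological x 3 technical replicates, 96 h of serial batch culture
# (1:100 every 24 h), qPCR observation model with strain-specific detection
# limits, plus pH records and a metabolite proxy table.

library(ommdropout)

seed <- 20230
out <- "results/fixture"

exp <- make_fixture("combined_two_media", seed = seed, dir = out)

at <- exp$abundance
message(sprintf("wrote %s: %d samples, %d abundance entries (%.1f%% censored)",
                out, nrow(at$samples), nrow(at$entries),
                100 * mean(at$entries$censored)))
stopifnot(nrow(at$samples) == 2 * 13 * 9)

truth <- exp$truth
excl <- truth[truth$community == "full" & truth$environment == "APF" &
                truth$strain_id == "M.in", "true_abundance"]
message(sprintf(
  "ground truth: M.in true abundance in the full APF community = %.3g/ml (pH exclusion)",
  excl))
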