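#!/usr/bin/env Rscript
# Stage 2 — signal-level check: simulate one participant's 20 Hz slider
# and 625 Hz skin-conductance traces, run the full extraction chain
# (preprocess -> deconvolve -> detect -> window), and compare the
# extracted per-manoeuvre indicators with the generative ground truth.
# A 10-trial session keeps this stage quick; stage 1 covers study scale.

library(riskbn)
dir.create("results", showWarnings = FALSE)

design <- build_design(participant_id = 1L, seed = 101L)
design$trials <- design$trials[1:10, ]
tv <- simulate_traces(design, seed = 11L)

ind <- extract_indicators(tv$slider, tv$eda, design)
chk <- merge(ind, tv$truth, by = "trial_id", suffixes = c("", "_true"))
write.csv(chk, "results/extraction_check.csv", row.names = FALSE)

cat(sprintf("participant w_start: %.2f s (slider anticipation)\n",
            attr(ind, "w_start")))
cat(sprintf("mSA max |error|: %.4f; iSA max |error|: %.4f\n",
            max(abs(chk$mSA - chk$mSA_true)),
            max(abs(chk$iSA - chk$iSA_true))))
cat(sprintf("nSCR exact matches: %d/%d; mSCR max |error|: %.4f uS\n",
            sum(chk$nSCR == chk$nSCR_true), nrow(chk),
            max(abs(chk$mSCR - chk$mSCR_true))))
cat("wrote results/extraction_check.csv\n")
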