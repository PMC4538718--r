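#!/usr/bin/env Rscript

# Printer-calibration mathematics on the bundled synthetic sample table:
# cubic grey-to-ink fit, pooled linear ink-to-counts fit (decay-corrected),
# and the inverted look-up used to choose grey levels for target activity
# ratios. Outputs to results/calibration/.

suppressPackageStartupMessages(library(ssphantom))

out <- "results/calibration"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

csv <- system.file("extdata", "synthetic_calibration_samples.csv",
                   package = "ssphantom")
samples <- read_calibration_csv(csv)   # decay-corrects to the common time

cubic <- fit_grey_to_ink(samples)
linear <- fit_ink_to_counts(samples)
message(sprintf("grey -> ink cubic:  R^2 = %.4f", cubic$r_squared))
message(sprintf("ink  -> counts lin: R^2 = %.4f (pooled, %d activities)",
                linear$r_squared, length(unique(samples$activity_rel))))

curve_to_json(cubic, file.path(out, "grey_to_ink.json"))
curve_to_json(linear, file.path(out, "ink_to_counts.json"))

# grey levels to print for the uptake ratios of the phantom batteries:
# background, lesion low level, lesion high level at TBR 4 (relative to max)
targets <- c(background = 1 / 7, lesion_L = 4 / 7, lesion_H = 1)
lookup <- data.frame(
  level = names(targets),
  target_relative_activity = unname(targets),
  grey_level = vapply(targets, grey_for_target_activity, numeric(1),
                      grey_to_ink = cubic, ink_to_counts = linear))
write.csv(lookup, file.path(out, "grey_lookup.csv"), row.names = FALSE)
print(lookup, row.names = FALSE)
message("note the non-linearity: equal activity steps need unequal grey steps")
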