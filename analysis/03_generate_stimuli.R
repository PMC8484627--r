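#!/usr/bin/env Rscript
# Step 3: construct the abstract scene stimuli.
#
# Builds a synthetic contour pool covering all 24 length x angularity x
# orientation bins on the 800x600 tracing canvas, then assembles the
# 480-image stimulus set (20 images per bin on a 200x150 canvas, contours
# scaled by 4 and appended until each image exceeds 1000 px of contour).

suppressMessages(library(contouraffect))

seed <- 42
pool <- synth_pool(n_per_bin = 150, seed = seed)
cat(sprintf("pool: %d contours, classifier mismatch rate %.4f\n",
            24 * 150, pool$mismatch_rate))

cpool <- build_contour_pool(pool$drawings)
ss <- generate_stimulus_set(cpool, n_per_bin = 20, length_budget = 1000,
                            seed = seed + 1)
print(ss)

dir.create("results", showWarnings = FALSE)
write_stimulus_set(ss, "results/stimuli")
cat(sprintf("wrote %d SVGs + manifest under results/stimuli/\n",
            nrow(ss$manifest)))
cat(sprintf("contours per image: %d-%d; min total length %.1f px\n",
            min(ss$manifest$n_contours), max(ss$manifest$n_contours),
            min(ss$manifest$total_length)))
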