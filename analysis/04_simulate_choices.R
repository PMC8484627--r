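#!/usr/bin/env Rscript
# Step 4: simulate the forced-choice sessions.
#
# 157 simulated participants per task view the 480 stimuli in 120
# four-image trials (each image once) and pick the most positive/safest
# and most negative/most threatening image by maximizing a cell utility
# plus Gumbel noise.  The valence observer prefers long, smooth,
# horizontal contours; the threat observer weights contour length more
# heavily, making Length the dominant effect.

suppressMessages(library(contouraffect))

manifest <- read_manifest("results/stimuli/manifest.csv")

valence_obs <- observer_spec()
threat_obs <- observer_spec(length_utility = c(short = -0.9, long = 0.9),
                            angularity_utility = c(low = 0.45, medium = 0,
                                                   high = -0.45),
                            orientation_utility = c(horizontal = 0.5,
                                                    vertical = -0.17,
                                                    both = -0.17,
                                                    diagonal = -0.16))

trials_2a <- synth_choice_session(manifest, valence_obs,
                                  n_participants = 157, task = "valence",
                                  seed = 421)
trials_2b <- synth_choice_session(manifest, threat_obs,
                                  n_participants = 157, task = "threat",
                                  seed = 422)

write_trials(trials_2a, "results/trials_valence.csv")
write_trials(trials_2b, "results/trials_threat.csv")
cat(sprintf("valence task: %d trials from %d participants\n",
            nrow(trials_2a), length(unique(trials_2a$participant_id))))
cat(sprintf("threat task:  %d trials from %d participants\n",
            nrow(trials_2b), length(unique(trials_2b$participant_id))))
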