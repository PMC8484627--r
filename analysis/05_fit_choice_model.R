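#!/usr/bin/env Rscript
# Step 5: analyse the forced-choice judgements.
#
# Expands each task's trials into binary observations (chosen-positive = 1,
# chosen-negative = 0, neutral images excluded), fits the random-intercept
# logistic model over the full Length x Angularity x Orientation factorial
# with sum-to-zero contrasts, and runs per-effect likelihood-ratio tests.

suppressMessages(library(contouraffect))

manifest <- read_manifest("results/stimuli/manifest.csv")

for (task in c("valence", "threat")) {
  cat("\n==", task, "task ==\n")
  trials <- read_trials(sprintf("results/trials_%s.csv", task))
  obs <- build_choice_observations(trials, manifest)
  cat(sprintf("%d modelled observations (2 per trial)\n", nrow(obs)))

  lrt <- likelihood_ratio_tests(obs)
  print(lrt)
  utils::write.csv(as.data.frame(lrt),
                   sprintf("results/lrt_%s.csv", task), row.names = FALSE)

  fx <- attr(lrt, "full_fixef")
  utils::write.csv(data.frame(term = names(fx), estimate = unname(fx)),
                   sprintf("results/fixef_%s.csv", task), row.names = FALSE)

  cs <- condition_summaries(obs)
  utils::write.csv(cs$cells, sprintf("results/cell_summary_%s.csv", task),
                   row.names = FALSE)
  utils::write.csv(cs$by_participant,
                   sprintf("results/cell_summary_by_participant_%s.csv",
                           task),
                   row.names = FALSE)

  best <- cs$cells[which.max(cs$cells$prop_high), ]
  worst <- cs$cells[which.min(cs$cells$prop_high), ]
  cat(sprintf("most %s cell:  %s/%s/%s (prop %.2f)\n",
              if (task == "valence") "positive" else "safe",
              best$length_class, best$angularity_class,
              best$orientation_class, best$prop_high))
  cat(sprintf("most %s cell: %s/%s/%s (prop %.2f)\n",
              if (task == "valence") "negative" else "threatening",
              worst$length_class, worst$angularity_class,
              worst$orientation_class, worst$prop_high))
}
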