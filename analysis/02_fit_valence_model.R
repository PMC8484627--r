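#!/usr/bin/env Rscript
# Step 2: regress mean valence on the contour features.
#
# Ordinary least squares of the simulated ratings on the 23
# sqrt-transformed feature columns, followed by partial-regression series
# for the truly nonzero predictors and separate close/far subset fits.

suppressMessages(library(contouraffect))

features <- read_feature_table("results/valence_features.csv")
ratings <- utils::read.csv("results/valence_ratings.csv",
                           stringsAsFactors = FALSE)

fit <- fit_valence_model(features, ratings)
print(fit)
write_valence_fit(fit, "results/valence_coefficients.csv",
                  "results/valence_model_summary.csv")

for (pred in c("O5", "L7", "A8")) {
  pr <- partial_regression_data(fit, pred)
  utils::write.csv(pr, sprintf("results/partial_regression_%s.csv", pred),
                   row.names = FALSE)
  cat(sprintf("partial slope %s: %+.4f (multiple-regression beta %+.4f)\n",
              pred, attr(pr, "slope"),
              fit$coefficients$beta[fit$coefficients$name == pred]))
}

subs <- subset_analysis(features, ratings)
for (cl in names(subs)) {
  if (inherits(subs[[cl]], "error")) {
    cat(cl, "subset:", conditionMessage(subs[[cl]]), "\n")
  } else {
    cat(sprintf("%s subset: n = %d, F(%d, %d) = %.3f, p = %.4g, R^2 = %.4f\n",
                cl, subs[[cl]]$n, subs[[cl]]$df1, subs[[cl]]$df2,
                subs[[cl]]$F, subs[[cl]]$p_overall, subs[[cl]]$r_squared))
    write_valence_fit(subs[[cl]],
                      sprintf("results/valence_coefficients_%s.csv", cl))
  }
}
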