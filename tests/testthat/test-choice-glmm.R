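test_that("trials expand to exactly two observations with neutrals dropped", {
  man <- design_manifest(1)
  ids <- man$image_id[1:4]
  trials <- data.frame(participant_id = "p1", task = "valence",
                       trial_index = 1,
                       img1 = ids[1], img2 = ids[2], img3 = ids[3],
                       img4 = ids[4],
                       choice_high = ids[1], choice_low = ids[3],
                       stringsAsFactors = FALSE)
  obs <- build_choice_observations(trials, man)
  expect_equal(nrow(obs), 2)
  expect_equal(obs$image_id[obs$outcome == 1], ids[1])
  expect_equal(obs$image_id[obs$outcome == 0], ids[3])

  bad <- trials; bad$choice_low <- ids[1]
  expect_error(build_choice_observations(bad, man), "choice_high equals")
  bad2 <- trials; bad2$choice_high <- "unknown_id"
  expect_error(build_choice_observations(bad2, man), "not among the four")
  bad3 <- trials; bad3$img2 <- "mystery"; bad3$choice_high <- "mystery"
  expect_error(build_choice_observations(bad3, man), "manifest")
  # missing choices are dropped and counted
  trials2 <- rbind(trials, trials)
  trials2$trial_index <- 1:2
  trials2$choice_high[2] <- NA
  obs2 <- build_choice_observations(trials2, man)
  expect_equal(nrow(obs2), 2)
  expect_equal(attr(obs2, "n_dropped"), 1)
})

test_that("a full session yields 2 observations per trial", {
  man <- design_manifest(20)
  trials <- synth_choice_session(man, n_participants = 3, seed = 2)
  expect_equal(nrow(trials), 3 * 120)
  obs <- build_choice_observations(trials, man)
  expect_equal(nrow(obs), 3 * 120 * 2)
  expect_true(all(table(obs$participant_id, obs$outcome) == 120))
})

test_that("perfectly balanced data give near-zero fixed effects", {
  # every cell 50/50 within every participant: symmetry forces all
  # sum-to-zero effects to zero
  man <- design_manifest(1)
  obs <- do.call(rbind, lapply(1:4, function(p)
    data.frame(participant_id = sprintf("p%d", p),
               trial_index = seq_len(48),
               image_id = rep(man$image_id, 2),
               outcome = rep(c(1L, 0L), each = 24),
               length_class = rep(man$length_class, 2),
               angularity_class = rep(man$angularity_class, 2),
               orientation_class = rep(man$orientation_class, 2),
               stringsAsFactors = FALSE)))
  fit <- fit_logistic_glmm(obs)
  expect_lt(max(abs(fit$fixef)), 1e-5)
})

test_that("zero-variance data reproduce the plain-logistic oracle", {
  set.seed(61)
  man <- design_manifest(20)
  obs <- synth_choice_observations(man, observer_spec(participant_sd = 0),
                                   n_participants = 40,
                                   n_obs_per_participant = 240, seed = 611)
  fit <- fit_logistic_glmm(obs)
  mm <- contouraffect:::choice_model_matrix(obs)
  oracle <- stats::glm.fit(mm, obs$outcome, family = stats::binomial())
  expect_lt(max(abs(fit$fixef - oracle$coefficients)), 1e-3)
  expect_lt(fit$ranef_sd[1], 0.05)
  # the mixed model nests the fixed-effects model
  ll_glm <- -oracle$deviance / 2
  expect_gte(fit$loglik, ll_glm - 1e-6)
})

test_that("glmmTMB and glmer engines agree on the same data", {
  man <- design_manifest(5)
  obs <- synth_choice_observations(man, observer_spec(participant_sd = 0.5),
                                   n_participants = 12,
                                   n_obs_per_participant = 120, seed = 71)
  f1 <- fit_logistic_glmm(obs, engine = "glmmTMB")
  f2 <- fit_logistic_glmm(obs, engine = "glmer")
  expect_lt(max(abs(f1$fixef - f2$fixef)), 1e-3)
  expect_lt(abs(f1$ranef_sd[1] - f2$ranef_sd[1]), 1e-3)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-4)
})

test_that("LRT chi-squares match an independent deviance oracle", {
  set.seed(81)
  man <- design_manifest(5)
  obs <- synth_choice_observations(man, observer_spec(participant_sd = 0),
                                   n_participants = 10,
                                   n_obs_per_participant = 96, seed = 811)
  lrt <- likelihood_ratio_tests(obs)
  expect_equal(lrt$df, c(1, 2, 3, 2, 3, 6, 6))
  expect_true(all(lrt$chisq >= 0))
  # with participant SD ~ 0 the GLMM deviances match plain-logistic
  # deviances, so chi-squares can be checked against glm.fit
  mm <- contouraffect:::choice_model_matrix(obs)
  asg <- attr(mm, "assign")
  full_dev <- stats::glm.fit(mm, obs$outcome,
                             family = stats::binomial())$deviance
  for (i in seq_len(7)) {
    red_dev <- stats::glm.fit(mm[, asg != i, drop = FALSE], obs$outcome,
                              family = stats::binomial())$deviance
    expect_equal(lrt$chisq[i], red_dev - full_dev, tolerance = 0.05)
  }
})

test_that("effects can be restricted to a subset", {
  man <- design_manifest(2)
  obs <- synth_choice_observations(man, n_participants = 6,
                                   n_obs_per_participant = 96, seed = 5)
  lrt <- likelihood_ratio_tests(obs, effects = c("Length", "Orientation"))
  expect_equal(lrt$effect, c("Length", "Orientation"))
})

test_that("condition summaries report per-cell choice proportions", {
  man <- design_manifest(10)
  trials <- synth_choice_session(man, n_participants = 6, seed = 13)
  obs <- build_choice_observations(trials, man)
  cs <- condition_summaries(obs)
  expect_lte(nrow(cs$cells), 24)
  expect_true(all(cs$cells$prop_high >= 0 & cs$cells$prop_high <= 1))
  expect_equal(sum(cs$cells$n), nrow(obs))
  # a cell holding only outcome-1 rows has proportion 1
  one <- obs[obs$outcome == 1, ][1:5, ]
  one$length_class <- "long"; one$angularity_class <- "low"
  one$orientation_class <- "horizontal"
  rest <- obs[obs$length_class != "long" | obs$angularity_class != "low" |
                obs$orientation_class != "horizontal", ]
  cs2 <- condition_summaries(rbind(one, rest))
  row <- cs2$cells[cs2$cells$length_class == "long" &
                     cs2$cells$angularity_class == "low" &
                     cs2$cells$orientation_class == "horizontal", ]
  expect_equal(row$prop_high, 1)
})

test_that("trial CSVs round-trip and flag schema problems", {
  man <- design_manifest(3)
  trials <- synth_choice_session(man, n_participants = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(back, trials)
  extra <- trials; extra$rt_ms <- 500
  write_trials(extra, path)
  expect_warning(read_trials(path), "unknown")
  utils::write.csv(trials[, -1], path, row.names = FALSE)
  expect_error(read_trials(path), "missing required")
})
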