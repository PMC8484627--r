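#' Specify a synthetic observer
#'
#' Logit-scale utilities per factor level used to simulate forced-choice
#' judgements.  Defaults follow the qualitative direction of human
#' judgements: long contours, low angularity and horizontal orientation
#' raise the utility of calling an image positive/safe.  Each factor's
#' utilities sum to zero so they sit on the same sum-to-zero scale as the
#' fitted model's coefficients.
#'
#' @param length_utility named numeric over `short`/`long`.
#' @param angularity_utility named numeric over `low`/`medium`/`high`.
#' @param orientation_utility named numeric over
#'   `horizontal`/`vertical`/`both`/`diagonal`.
#' @param intercept grand-mean logit (tendency to call images positive).
#' @param participant_sd standard deviation of the per-participant random
#'   intercept.
#' @return object of class `observer_spec`.
#' @export
observer_spec <- function(length_utility = c(short = -0.4, long = 0.4),
                          angularity_utility = c(low = 0.5, medium = 0,
                                                 high = -0.5),
                          orientation_utility = c(horizontal = 0.6,
                                                  vertical = -0.2,
                                                  both = -0.2,
                                                  diagonal = -0.2),
                          intercept = 0, participant_sd = 0.5) {
  stopifnot(all(length_levels %in% names(length_utility)),
            all(angularity_levels %in% names(angularity_utility)),
            all(orientation_levels %in% names(orientation_utility)),
            participant_sd >= 0)
  structure(list(length_utility = length_utility,
                 angularity_utility = angularity_utility,
                 orientation_utility = orientation_utility,
                 intercept = intercept,
                 participant_sd = participant_sd),
            class = "observer_spec")
}

# cell utility (logit scale, no participant effect) for manifest rows
cell_utility <- function(observer, length_class, angularity_class,
                         orientation_class) {
  observer$intercept +
    observer$length_utility[length_class] +
    observer$angularity_utility[angularity_class] +
    observer$orientation_utility[orientation_class]
}

#' True sum-to-zero coefficients implied by an observer
#'
#' Projects the observer's 24 cell utilities onto the full factorial
#' sum-to-zero model matrix, giving the coefficient vector a correctly
#' specified logistic model would recover from bernoulli-direct data.
#'
#' @param observer an [observer_spec()].
#' @return named numeric vector (24 entries, matching
#'   [fit_logistic_glmm()]'s `fixef`).
#' @export
observer_fixef <- function(observer) {
  g <- expand.grid(length_class = length_levels,
                   angularity_class = angularity_levels,
                   orientation_class = orientation_levels,
                   stringsAsFactors = FALSE)
  eta <- mapply(cell_utility, g$length_class, g$angularity_class,
                g$orientation_class, MoreArgs = list(observer = observer))
  mm <- choice_model_matrix(g)
  stats::setNames(drop(solve(crossprod(mm), crossprod(mm, eta))),
                  colnames(mm))
}

#' Simulate forced-choice sessions
#'
#' For each participant the stimulus set is randomly partitioned into
#' trials of four images (each image shown exactly once); the image with
#' the highest realized utility (cell utility + participant intercept +
#' standard Gumbel noise) is chosen as most positive/safe, the lowest as
#' most negative/threatening.
#'
#' @param manifest stimulus manifest data frame (image count divisible
#'   by 4; 480 images give 120 trials).
#' @param observer an [observer_spec()].
#' @param n_participants number of simulated participants.
#' @param task `"valence"` or `"threat"` (label only).
#' @param seed optional RNG seed.
#' @return data frame of trial records (`participant_id`, `task`,
#'   `trial_index`, `img1`..`img4`, `choice_high`, `choice_low`).
#' @export
synth_choice_session <- function(manifest, observer = observer_spec(),
                                 n_participants = 157,
                                 task = c("valence", "threat"),
                                 seed = NULL) {
  task <- match.arg(task)
  if (!is.null(seed)) set.seed(seed)
  n_img <- nrow(manifest)
  if (n_img %% 4L != 0L)
    stop("manifest size must be divisible by 4", call. = FALSE)
  n_trials <- n_img %/% 4L
  eta <- cell_utility(observer, manifest$length_class,
                      manifest$angularity_class, manifest$orientation_class)
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    b_p <- stats::rnorm(1, 0, observer$participant_sd)
    perm <- sample.int(n_img)
    imgs <- matrix(perm, nrow = n_trials, ncol = 4L)
    # Gumbel noise: -log(-log(U))
    v <- matrix(eta[perm] + b_p - log(-log(stats::runif(n_img))),
                nrow = n_trials, ncol = 4L)
    hi <- max.col(v)
    lo <- max.col(-v)
    ids <- matrix(manifest$image_id[imgs], nrow = n_trials)
    out[[p]] <- data.frame(
      participant_id = sprintf("p%03d", p),
      task = task,
      trial_index = seq_len(n_trials),
      img1 = ids[, 1], img2 = ids[, 2], img3 = ids[, 3], img4 = ids[, 4],
      choice_high = ids[cbind(seq_len(n_trials), hi)],
      choice_low = ids[cbind(seq_len(n_trials), lo)],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate choice observations directly from the logistic model
#'
#' Bernoulli-direct mode: emits long-format binary observations whose
#' outcome is drawn from `plogis(cell utility + participant intercept)`.
#' Unlike the four-alternative choice rule, this matches the fitted
#' random-intercept logistic model exactly, so parameter-recovery tests
#' have a well-defined truth ([observer_fixef()]).
#'
#' @inheritParams synth_choice_session
#' @param n_obs_per_participant observations per participant (default 240,
#'   the number of modelled observations a 120-trial session yields);
#'   images are sampled with replacement from the manifest.
#' @return data frame shaped like [build_choice_observations()] output.
#' @export
synth_choice_observations <- function(manifest, observer = observer_spec(),
                                      n_participants = 157,
                                      n_obs_per_participant = 240,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_participants * n_obs_per_participant
  pid <- rep(sprintf("p%03d", seq_len(n_participants)),
             each = n_obs_per_participant)
  idx <- sample.int(nrow(manifest), n, replace = TRUE)
  b <- stats::rnorm(n_participants, 0, observer$participant_sd)
  eta <- cell_utility(observer, manifest$length_class[idx],
                      manifest$angularity_class[idx],
                      manifest$orientation_class[idx]) +
    rep(b, each = n_obs_per_participant)
  data.frame(participant_id = pid,
             trial_index = rep(seq_len(n_obs_per_participant),
                               n_participants),
             image_id = manifest$image_id[idx],
             outcome = stats::rbinom(n, 1, stats::plogis(eta)),
             length_class = manifest$length_class[idx],
             angularity_class = manifest$angularity_class[idx],
             orientation_class = manifest$orientation_class[idx],
             stringsAsFactors = FALSE)
}
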