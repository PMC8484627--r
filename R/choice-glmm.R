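#' Expand 4AFC trials into binary choice observations
#'
#' Each four-image trial yields exactly two modelled observations: the
#' image chosen as most positive (or safest) with outcome 1 and the image
#' chosen as most negative (or most threatening) with outcome 0.  The two
#' unselected ("neutral") images are excluded from modelling.
#'
#' @param trials data frame of trial records: `participant_id`, `task`,
#'   `trial_index`, `img1`..`img4`, `choice_high`, `choice_low`.  Rows with
#'   a missing choice are dropped and counted.
#' @param manifest stimulus manifest (data frame with `image_id`,
#'   `length_class`, `angularity_class`, `orientation_class`).
#' @return data frame of choice observations: `participant_id`,
#'   `trial_index`, `image_id`, the three factor columns, `outcome` (1/0);
#'   attribute `n_dropped` counts trials removed for missing choices.
#' @export
build_choice_observations <- function(trials, manifest) {
  req <- c("participant_id", "trial_index", "img1", "img2", "img3", "img4",
           "choice_high", "choice_low")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trial table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- !is.na(trials$choice_high) & !is.na(trials$choice_low)
  n_dropped <- sum(!ok)
  trials <- trials[ok, , drop = FALSE]
  if (any(trials$choice_high == trials$choice_low))
    stop("malformed trial: choice_high equals choice_low", call. = FALSE)
  imgs <- as.matrix(trials[, c("img1", "img2", "img3", "img4")])
  in_trial <- trials$choice_high == imgs[, 1] | trials$choice_high == imgs[, 2] |
    trials$choice_high == imgs[, 3] | trials$choice_high == imgs[, 4]
  in_trial_lo <- trials$choice_low == imgs[, 1] | trials$choice_low == imgs[, 2] |
    trials$choice_low == imgs[, 3] | trials$choice_low == imgs[, 4]
  if (any(!in_trial | !in_trial_lo))
    stop("malformed trial: a chosen image is not among the four displayed",
         call. = FALSE)
  obs <- data.frame(
    participant_id = rep(trials$participant_id, 2L),
    trial_index = rep(trials$trial_index, 2L),
    image_id = c(trials$choice_high, trials$choice_low),
    outcome = rep(c(1L, 0L), each = nrow(trials)),
    stringsAsFactors = FALSE)
  m <- match(obs$image_id, manifest$image_id)
  if (anyNA(m))
    stop(sprintf("%d chosen image id(s) not present in the manifest",
                 sum(is.na(m))), call. = FALSE)
  obs$length_class <- manifest$length_class[m]
  obs$angularity_class <- manifest$angularity_class[m]
  obs$orientation_class <- manifest$orientation_class[m]
  obs <- obs[order(obs$participant_id, obs$trial_index, -obs$outcome), ]
  rownames(obs) <- NULL
  attr(obs, "n_dropped") <- n_dropped
  obs
}

# Sum-to-zero coded model matrix of the full Length x Angularity x
# Orientation factorial, with the term index (attr "assign") and term
# labels preserved.  Factor levels are alphabetical.
choice_model_matrix <- function(obs) {
  d <- data.frame(
    L = factor(obs$length_class, sort(unique(length_levels))),
    A = factor(obs$angularity_class, sort(unique(angularity_levels))),
    O = factor(obs$orientation_class, sort(unique(orientation_levels))))
  mm <- stats::model.matrix(~ L * A * O, d,
                            contrasts.arg = list(L = stats::contr.sum,
                                                 A = stats::contr.sum,
                                                 O = stats::contr.sum))
  mm
}

glmm_engine_fit <- function(y, X, g, engine, trial = NULL, se = TRUE) {
  dat <- data.frame(.y = y, .g = g)
  if (!is.null(trial)) dat$.t <- trial
  dat <- cbind(dat, as.data.frame(X))
  xn <- make.names(colnames(X), unique = TRUE)
  names(dat)[-seq_len(if (is.null(trial)) 2L else 3L)] <- xn
  rhs <- paste(c("0", xn, "(1 | .g)", if (!is.null(trial)) "(1 | .g:.t)"),
               collapse = " + ")
  f <- stats::as.formula(paste(".y ~", rhs))
  if (engine == "glmmTMB") {
    fit <- glmmTMB::glmmTMB(f, data = dat, family = stats::binomial(),
                            se = se)
    vc <- glmmTMB::VarCorr(fit)$cond
    sds <- vapply(vc, function(v) sqrt(v[1, 1]), numeric(1))
    beta <- glmmTMB::fixef(fit)$cond
    conv <- isTRUE(fit$fit$convergence == 0)
  } else {
    fit <- lme4::glmer(f, data = dat, family = stats::binomial(),
                       control = lme4::glmerControl(calc.derivs = FALSE))
    vc <- lme4::VarCorr(fit)
    sds <- vapply(vc, function(v) sqrt(v[1, 1]), numeric(1))
    beta <- lme4::fixef(fit)
    conv <- length(fit@optinfo$conv$lme4) == 0L
  }
  names(beta) <- colnames(X)
  list(fit = fit, beta = beta, sd = sds,
       loglik = as.numeric(stats::logLik(fit)), converged = conv)
}

#' Fit the random-intercept logistic choice model
#'
#' Maximum-likelihood logistic regression of the binary choice outcome
#' (positive/safe = 1, negative/threatening = 0) on the full
#' Length x Angularity x Orientation factorial with sum-to-zero contrasts,
#' plus a Gaussian random intercept per participant (optionally also per
#' trial within participant).  Integration over the random effects uses the
#' Laplace approximation.
#'
#' @param obs choice observations from [build_choice_observations()].
#' @param random_structure `"participant"` (default) or
#'   `"participant_trial"`.  The per-trial intercept is weakly identified
#'   with one 1 and one 0 per trial, hence off by default.
#' @param engine `"glmmTMB"` (default; Laplace via TMB) or `"glmer"`
#'   (lme4).  Both maximize the same Laplace-approximate likelihood.
#' @return object of class `choice_glmm_fit`: `fixef` (named, sum-to-zero
#'   scale), `ranef_sd`, `loglik`, `converged`, `n_obs`, `engine`, plus the
#'   underlying model object in `$fit` and the model matrix metadata.
#' @export
fit_logistic_glmm <- function(obs,
                              random_structure = c("participant",
                                                   "participant_trial"),
                              engine = c("glmmTMB", "glmer")) {
  random_structure <- match.arg(random_structure)
  engine <- match.arg(engine)
  if (length(unique(obs$participant_id)) < 2L)
    stop("need at least 2 participants", call. = FALSE)
  mm <- choice_model_matrix(obs)
  cells <- interaction(obs$length_class, obs$angularity_class,
                       obs$orientation_class, drop = TRUE)
  inestimable <- 24L - nlevels(cells)
  trial <- if (random_structure == "participant_trial") obs$trial_index
  res <- glmm_engine_fit(obs$outcome, mm, factor(obs$participant_id),
                         engine, trial)
  structure(list(fixef = res$beta, ranef_sd = res$sd, loglik = res$loglik,
                 converged = res$converged, n_obs = nrow(obs),
                 engine = engine, random_structure = random_structure,
                 n_missing_cells = inestimable,
                 assign = attr(mm, "assign"),
                 term_labels = attr(stats::terms(~ L * A * O), "term.labels"),
                 fit = res$fit),
            class = "choice_glmm_fit")
}

#' @exportS3Method print choice_glmm_fit
print.choice_glmm_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept logistic choice model (%s, %s)\n  n = %d, logLik = %.2f, participant SD = %.3f%s\n",
    x$engine, x$random_structure, x$n_obs, x$loglik, x$ranef_sd[1],
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Likelihood-ratio tests for every effect of the choice model
#'
#' For each of the seven effects of the Length x Angularity x Orientation
#' factorial (three main effects, three two-way interactions, the three-way
#' interaction), the model is refit with that effect's sum-to-zero model
#' matrix columns removed while all other terms are retained, and twice the
#' log-likelihood difference is referred to a chi-square distribution with
#' degrees of freedom equal to the number of removed columns.
#'
#' @inheritParams fit_logistic_glmm
#' @param effects optional character vector restricting which effects to
#'   test (by pretty name, e.g. `c("Length", "Angularity", "Orientation")`);
#'   default all seven.
#' @return data frame of class `lrt_result`: `effect`, `chisq`, `df`, `p`;
#'   attribute `full_loglik`.  Effects whose reduced model fails to
#'   converge get `NA` statistics.
#' @export
likelihood_ratio_tests <- function(obs,
                                   random_structure = c("participant",
                                                        "participant_trial"),
                                   engine = c("glmmTMB", "glmer"),
                                   effects = NULL) {
  random_structure <- match.arg(random_structure)
  engine <- match.arg(engine)
  mm <- choice_model_matrix(obs)
  asg <- attr(mm, "assign")
  labels <- attr(stats::terms(~ L * A * O), "term.labels")
  trial <- if (random_structure == "participant_trial") obs$trial_index
  g <- factor(obs$participant_id)
  full <- glmm_engine_fit(obs$outcome, mm, g, engine, trial, se = FALSE)
  if (!full$converged)
    stop("full model did not converge; cannot run likelihood-ratio tests",
         call. = FALSE)
  pretty <- c(L = "Length", A = "Angularity", O = "Orientation",
              `L:A` = "Length:Angularity", `L:O` = "Length:Orientation",
              `A:O` = "Angularity:Orientation",
              `L:A:O` = "Length:Angularity:Orientation")
  which_terms <- seq_along(labels)
  if (!is.null(effects))
    which_terms <- which(pretty[labels] %in% effects)
  rows <- lapply(which_terms, function(i) {
    drop_cols <- which(asg == i)
    red <- tryCatch(
      glmm_engine_fit(obs$outcome, mm[, -drop_cols, drop = FALSE], g,
                      engine, trial, se = FALSE),
      error = function(e) NULL)
    if (is.null(red) || !red$converged)
      return(data.frame(effect = pretty[[labels[i]]], chisq = NA_real_,
                        df = length(drop_cols), p = NA_real_,
                        stringsAsFactors = FALSE))
    chisq <- max(0, 2 * (full$loglik - red$loglik))
    data.frame(effect = pretty[[labels[i]]], chisq = chisq,
               df = length(drop_cols),
               p = stats::pchisq(chisq, length(drop_cols),
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_loglik") <- full$loglik
  attr(out, "full_fixef") <- full$beta
  attr(out, "ranef_sd") <- full$sd
  class(out) <- c("lrt_result", "data.frame")
  out
}

#' @exportS3Method print lrt_result
print.lrt_result <- function(x, ...) {
  cat("Likelihood-ratio tests (Type III, sum-to-zero coding)\n")
  y <- x
  class(y) <- "data.frame"
  y$chisq <- round(y$chisq, 2)
  y$p <- signif(y$p, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Per-cell choice summaries
#'
#' Mean outcome (proportion of modelled observations that were the
#' chosen-positive/safe image) per design cell, overall and per
#' participant.  This is the tabular counterpart of interval plots of
#' average positive vs negative scores by contour feature.
#'
#' @param obs choice observations from [build_choice_observations()].
#' @return list with `cells` (up to 24 rows: the three factor columns,
#'   `n`, `prop_high`) and `by_participant` (long table with
#'   `participant_id` added).
#' @export
condition_summaries <- function(obs) {
  if (!nrow(obs)) stop("no observations", call. = FALSE)
  f <- list(length_class = obs$length_class,
            angularity_class = obs$angularity_class,
            orientation_class = obs$orientation_class)
  cells <- stats::aggregate(obs$outcome, f,
                            FUN = function(z) c(n = length(z), p = mean(z)))
  cells <- data.frame(cells[, 1:3], n = cells$x[, "n"],
                      prop_high = cells$x[, "p"])
  fp <- c(list(participant_id = obs$participant_id), f)
  byp <- stats::aggregate(obs$outcome, fp,
                          FUN = function(z) c(n = length(z), p = mean(z)))
  byp <- data.frame(byp[, 1:4], n = byp$x[, "n"], prop_high = byp$x[, "p"])
  list(cells = cells, by_participant = byp)
}

#' Read / write trial CSV files
#'
#' @param trials trial data frame (see [build_choice_observations()]).
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "task", "trial_index", "img1", "img2", "img3",
           "img4", "choice_high", "choice_low")
  miss <- setdiff(req, names(tr))
  if (length(miss))
    stop("trial CSV missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(tr), req)
  if (length(extra))
    warning("ignoring unknown trial CSV columns: ",
            paste(extra, collapse = ", "), call. = FALSE)
  tr
}
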