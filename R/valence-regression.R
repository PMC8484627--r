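#' Fit the valence regression model
#'
#' Ordinary least squares of per-image mean valence ratings (1-9 scale,
#' unhappy to happy) on the square-root-transformed contour-feature vector,
#' with an intercept.  Collinear predictor columns are dropped by the
#' pivoted QR decomposition and reported by name.
#'
#' @param features data frame with `image_id` and numeric feature columns
#'   (as produced by [feature_table()]).
#' @param ratings data frame with columns `image_id`, `valence` (in
#'   `[1, 9]`), and optionally `distance_class`
#'   (`"close"`/`"far"`/`"unlabeled"`).
#' @return an object of class `valence_fit`: coefficient table
#'   (`name`, `beta`, `se`, `t`, `p`), overall `F` with `df1`/`df2`,
#'   `r_squared`, `n`, `dropped` (names of eliminated columns), and the
#'   underlying `lm` fit.
#' @export
fit_valence_model <- function(features, ratings) {
  if (!"image_id" %in% names(features) || !"image_id" %in% names(ratings))
    stop("both tables need an `image_id` column", call. = FALSE)
  if (any(ratings$valence < 1 | ratings$valence > 9))
    stop("valence ratings must lie in [1, 9]", call. = FALSE)
  m <- match(ratings$image_id, features$image_id)
  if (anyNA(m))
    stop(sprintf("ratings reference %d image_id(s) missing from the feature table",
                 sum(is.na(m))), call. = FALSE)
  X <- as.matrix(features[m, setdiff(names(features), "image_id"),
                          drop = FALSE])
  storage.mode(X) <- "double"
  y <- ratings$valence
  n <- length(y)
  if (n < ncol(X) + 2L)
    stop(sprintf("underdetermined system: %d rows for %d predictors (need at least %d)",
                 n, ncol(X), ncol(X) + 2L), call. = FALSE)
  dat <- data.frame(.valence = y, X, check.names = FALSE)
  fit <- stats::lm(.valence ~ ., data = dat)
  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  dropped <- sub("^`(.*)`$", "\\1", dropped)
  sm <- summary(fit)
  tab <- sm$coefficients
  out <- data.frame(name = sub("^`(.*)`$", "\\1", rownames(tab)),
                    beta = tab[, 1], se = tab[, 2], t = tab[, 3],
                    p = tab[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  fs <- sm$fstatistic
  structure(list(coefficients = out,
                 F = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
                 p_overall = stats::pf(fs[1], fs[2], fs[3],
                                       lower.tail = FALSE),
                 r_squared = sm$r.squared, n = n, dropped = dropped,
                 lm_fit = fit),
            class = "valence_fit")
}

#' @exportS3Method print valence_fit
print.valence_fit <- function(x, ...) {
  cat(sprintf("Valence regression: n = %d, R^2 = %.4f, F(%d, %d) = %.3f, p = %.4g\n",
              x$n, x$r_squared, x$df1, x$df2, x$F, x$p_overall))
  if (length(x$dropped))
    cat("Dropped (collinear):", paste(x$dropped, collapse = ", "), "\n")
  sig <- x$coefficients[x$coefficients$p < 0.05 &
                          x$coefficients$name != "(Intercept)", ]
  if (nrow(sig)) {
    cat("Significant predictors (p < 0.05):\n")
    print(sig, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Partial-regression (added-variable) data for one predictor
#'
#' Returns the residuals of the response on all predictors except the one
#' named, paired with the residuals of that predictor on the rest.  By the
#' Frisch-Waugh-Lovell identity the slope of this pair equals the
#' predictor's multiple-regression coefficient.
#'
#' @param fit a `valence_fit` from [fit_valence_model()].
#' @param predictor name of a retained predictor column.
#' @return data frame with columns `x_resid` and `y_resid`, plus attributes
#'   `slope` (the partial slope) and `predictor`.
#' @export
partial_regression_data <- function(fit, predictor) {
  stopifnot(inherits(fit, "valence_fit"))
  if (predictor %in% fit$dropped)
    stop(sprintf("predictor '%s' was dropped as collinear", predictor),
         call. = FALSE)
  mm <- stats::model.matrix(fit$lm_fit)
  keep <- !is.na(stats::coef(fit$lm_fit))[colnames(mm)]
  mm <- mm[, keep, drop = FALSE]
  cols <- sub("^`(.*)`$", "\\1", colnames(mm))
  j <- match(predictor, cols)
  if (is.na(j) || predictor == "(Intercept)")
    stop(sprintf("unknown predictor '%s'", predictor), call. = FALSE)
  y <- stats::model.response(stats::model.frame(fit$lm_fit))
  others <- mm[, -j, drop = FALSE]
  rx <- stats::lsfit(others, mm[, j], intercept = FALSE)$residuals
  ry <- stats::lsfit(others, y, intercept = FALSE)$residuals
  slope <- sum(rx * ry) / sum(rx^2)
  out <- data.frame(x_resid = rx, y_resid = ry)
  attr(out, "slope") <- slope
  attr(out, "predictor") <- predictor
  out
}

#' Separate regressions for close and far images
#'
#' Splits the rating table by `distance_class` ("close": central object
#' dominates, background barely visible; "far": scene background visible)
#' and fits an independent valence regression per class.  Images labelled
#' `"unlabeled"` are excluded.  A class with too few rows yields a
#' `try-error`-style condition object in its slot rather than aborting the
#' other class.
#'
#' @inheritParams fit_valence_model
#' @return list with elements `close` and `far`, each a `valence_fit` or a
#'   `simpleError` describing why that class could not be fit.
#' @export
subset_analysis <- function(features, ratings) {
  if (!"distance_class" %in% names(ratings))
    stop("ratings need a `distance_class` column", call. = FALSE)
  out <- lapply(c(close = "close", far = "far"), function(cl) {
    sub <- ratings[ratings$distance_class == cl, , drop = FALSE]
    if (!nrow(sub))
      return(simpleError(sprintf("no '%s' images", cl)))
    tryCatch(fit_valence_model(features, sub), error = function(e) e)
  })
  out
}

#' Write regression outputs as CSV
#'
#' @param fit a `valence_fit`.
#' @param coef_path,summary_path output file paths (either may be `NULL`).
#' @export
write_valence_fit <- function(fit, coef_path = NULL, summary_path = NULL) {
  stopifnot(inherits(fit, "valence_fit"))
  if (!is.null(coef_path))
    utils::write.csv(fit$coefficients, coef_path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(data.frame(F = fit$F, df1 = fit$df1, df2 = fit$df2,
                                p = fit$p_overall, r_squared = fit$r_squared,
                                n = fit$n,
                                dropped = paste(fit$dropped, collapse = ";")),
                     summary_path, row.names = FALSE)
  invisible(fit)
}
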