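make_feature_frame <- function(X, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_len(nrow(X)))
  data.frame(image_id = ids, X, check.names = FALSE,
             stringsAsFactors = FALSE)
}

test_that("a perfect single-predictor fit is recovered exactly", {
  feats <- make_feature_frame(data.frame(x = c(0, 1, 2)))
  ratings <- data.frame(image_id = feats$image_id, valence = c(1, 2, 3))
  fit <- suppressWarnings(fit_valence_model(feats, ratings))
  expect_equal(fit$coefficients$beta, c(1, 1), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$df2, 1)   # n - df1 - 1
})

test_that("coefficients match a normal-equations oracle", {
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 3), 20, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- runif(20, 2, 8)
    fit <- fit_valence_model(make_feature_frame(as.data.frame(X)),
                             data.frame(image_id = sprintf("img_%03d", 1:20),
                                        valence = y))
    Xi <- cbind(1, X)
    beta_oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
    expect_equal(fit$coefficients$beta, drop(beta_oracle),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # R^2 identity
    yhat <- drop(Xi %*% beta_oracle)
    expect_equal(fit$r_squared,
                 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }
})

test_that("input validation catches the documented error cases", {
  feats <- make_feature_frame(data.frame(x = rnorm(5)))
  ratings <- data.frame(image_id = feats$image_id, valence = rep(5, 5))
  bad <- ratings; bad$image_id[1] <- "nope"
  expect_error(fit_valence_model(feats, bad), "missing from")
  bad2 <- ratings; bad2$valence[1] <- 12
  expect_error(fit_valence_model(feats, bad2), "\\[1, 9\\]")
  wide <- make_feature_frame(as.data.frame(matrix(rnorm(5 * 6), 5, 6)))
  expect_error(
    fit_valence_model(wide, data.frame(image_id = wide$image_id,
                                       valence = rep(5, 5))),
    "underdetermined")
})

test_that("duplicated columns are dropped, reported, and harmless", {
  set.seed(8)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  X$dup <- X$a
  feats <- make_feature_frame(X)
  ratings <- data.frame(image_id = feats$image_id,
                        valence = pmin(9, pmax(1, 5 + X$a + rnorm(30, 0, .2))))
  fit <- fit_valence_model(feats, ratings)
  expect_equal(fit$dropped, "dup")
  fit_ref <- fit_valence_model(make_feature_frame(X[, 1:2]), ratings)
  expect_equal(fitted(fit$lm_fit), fitted(fit_ref$lm_fit),
               tolerance = 1e-10)
})

test_that("partial-regression slope equals the multiple-regression beta", {
  set.seed(14)
  X <- as.data.frame(matrix(rnorm(60 * 4), 60, 4))
  names(X) <- c("w", "x", "y2", "z")
  feats <- make_feature_frame(X)
  ratings <- data.frame(image_id = feats$image_id,
                        valence = pmin(9, pmax(1, 5 + 0.5 * X$x +
                                                 rnorm(60, 0, 0.5))))
  fit <- fit_valence_model(feats, ratings)
  pr <- partial_regression_data(fit, "x")
  beta_x <- fit$coefficients$beta[fit$coefficients$name == "x"]
  expect_equal(attr(pr, "slope"), beta_x, tolerance = 1e-8)
  expect_error(partial_regression_data(fit, "nothere"), "unknown")

  # predictors orthogonal to each other and the intercept: partial slope
  # equals the simple slope
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(50 * 2), 50, 2))))[, 2:3]
  feats2 <- make_feature_frame(data.frame(p1 = Q[, 1], p2 = Q[, 2]))
  y <- 5 + Q[, 1] - 2 * Q[, 2] + rnorm(50, 0, 0.05)
  ratings2 <- data.frame(image_id = feats2$image_id, valence = y)
  fit2 <- fit_valence_model(feats2, ratings2)
  pr2 <- partial_regression_data(fit2, "p1")
  simple <- stats::coef(stats::lm(y ~ Q[, 1]))[2]
  expect_equal(attr(pr2, "slope"), unname(simple), tolerance = 1e-8)

  # constant predictor is dropped, then rejected by the partial path
  X3 <- data.frame(good = rnorm(30), flat = rep(1, 30))
  feats3 <- make_feature_frame(X3)
  ratings3 <- data.frame(image_id = feats3$image_id, valence = runif(30, 3, 7))
  fit3 <- fit_valence_model(feats3, ratings3)
  expect_true("flat" %in% fit3$dropped)
  expect_error(partial_regression_data(fit3, "flat"), "dropped")
})

test_that("subset analysis fits classes independently and isolates errors", {
  set.seed(23)
  X <- data.frame(x = rnorm(60))
  feats <- make_feature_frame(X)
  ratings <- data.frame(
    image_id = feats$image_id,
    valence = pmin(9, pmax(1, 5 + ifelse(seq_len(60) > 30, 1, 0) * X$x +
                             rnorm(60, 0, 0.3))),
    distance_class = rep(c("close", "far"), each = 30))
  res <- subset_analysis(feats, ratings)
  expect_s3_class(res$close, "valence_fit")
  expect_s3_class(res$far, "valence_fit")
  expect_equal(res$far$n, 30)

  # all-far labels: close slot carries the error, far still fits
  ratings$distance_class <- "far"
  res2 <- subset_analysis(feats, ratings)
  expect_s3_class(res2$close, "simpleError")
  expect_s3_class(res2$far, "valence_fit")
})

test_that("far-only effects are recovered by the far fit", {
  set.seed(51)
  n <- 120
  X <- data.frame(x = rnorm(n))
  feats <- make_feature_frame(X)
  hits <- 0; nulls <- 0
  for (rep in 1:30) {
    beta_far <- 0.6
    y <- 5 + ifelse(seq_len(n) > n / 2, beta_far, 0) * X$x + rnorm(n, 0, 1)
    ratings <- data.frame(image_id = feats$image_id,
                          valence = pmin(9, pmax(1, y)),
                          distance_class = rep(c("close", "far"),
                                               each = n / 2))
    res <- subset_analysis(feats, ratings)
    cf <- res$far$coefficients
    b <- cf$beta[cf$name == "x"]; se <- cf$se[cf$name == "x"]
    if (abs(b - beta_far) <= 2 * se) hits <- hits + 1
    if (res$close$p_overall > 0.05) nulls <- nulls + 1
  }
  expect_gte(hits, 26)   # ~95% coverage over 30 replicates
  expect_gte(nulls, 24)  # close fit should rarely reach significance
})
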