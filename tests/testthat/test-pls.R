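test_that("evaluation statistics match their textbook examples", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(predictive_r2(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.6)
  y <- c(0.3, 1.7, -2.2, 0.4)
  expect_equal(predictive_r2(y, y), 1.0)
  expect_equal(predictive_r2(y, rep(mean(y), 4)), 0.0)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(1, 2, 3, 4), c(1, 3, 2, 4)), sqrt(0.5))
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "sibcut_error_degenerate")
  expect_error(predictive_r2(c(2, 2), c(1, 3)),
               class = "sibcut_error_degenerate")
  expect_error(rmse(1:3, 1:4), class = "sibcut_error_contract")
})

test_that("pearson_r is symmetric and invariant under positive affine maps", {
  set.seed(2)
  for (rep in 1:20) {
    y <- rnorm(30); p <- rnorm(30)
    expect_equal(pearson_r(y, p), pearson_r(p, y))
    expect_equal(pearson_r(2.5 * y + 3, p), pearson_r(y, p),
                 tolerance = 1e-12)
    expect_equal(pearson_r(y, p), cor(y, p), tolerance = 1e-12)
  }
})

test_that("predictive r2 equals squared correlation for the affine fit", {
  set.seed(4)
  for (rep in 1:10) {
    y <- rnorm(40); p0 <- 0.6 * y + rnorm(40)
    fitcoef <- coef(lm(y ~ p0))
    p <- fitcoef[1] + fitcoef[2] * p0
    expect_equal(predictive_r2(y, p), pearson_r(y, p)^2, tolerance = 1e-10)
  }
})

test_that("a noiseless linear target is interpolated exactly", {
  enc <- make_toy_encoded(n = 60, noise_sd = 0)
  fit <- suppressWarnings(fit_pls(enc, n_components = "all"))
  expect_lt(max(abs(fit$fitted - enc$potency)), 1e-6)
  expect_equal(fit$training_stats$r, 1, tolerance = 1e-8)
})

test_that("one component on a single column is the least-squares line", {
  set.seed(7)
  x <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "x1"))
  y <- 2 + 3 * x[, 1] + rnorm(40, 0, 0.4)
  fit <- fit_pls(x, y = y, n_components = 1)
  ls <- coef(lm(y ~ x[, 1]))
  expect_equal(fit$intercept, unname(ls[1]), tolerance = 1e-8)
  expect_equal(fit$coefficients, unname(ls[2]), tolerance = 1e-8)
})

test_that("all components on a full-rank wide-sample design recover OLS", {
  set.seed(8)
  n <- 80; p <- 12
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- drop(X %*% rnorm(p)) + rnorm(n, 0, 0.3)
  fit <- fit_pls(X, y = y, n_components = "all")
  ols <- drop(cbind(1, X) %*% coef(lm(y ~ X)))
  expect_lt(max(abs(predict(fit, X) - ols)), 1e-6)
})

test_that("training correlation is non-decreasing in component count", {
  enc <- make_toy_encoded(n = 50, noise_sd = 0.5)
  rs <- vapply(1:8, function(nc) {
    suppressWarnings(fit_pls(enc, n_components = nc))$training_stats$r
  }, numeric(1))
  expect_true(all(diff(rs) >= -1e-10))
})

test_that("score-path and coefficient-path predictions coincide", {
  enc <- make_toy_encoded(n = 40, noise_sd = 0.4)
  X <- as.matrix(enc[, -(1:2)])
  fit <- suppressWarnings(fit_pls(enc, n_components = 3))
  expect_lt(max(abs(predict(fit, X) - sibcut:::predict_via_scores(fit, X))),
            1e-8)
  # duplicated rows get identical predictions
  Xdup <- X[rep(1, 5), , drop = FALSE]
  expect_equal(diff(range(predict(fit, Xdup))), 0)
  expect_error(predict(fit, X[, 1:10]), class = "sibcut_error_contract")
})

test_that("model serialization round-trips predictions exactly", {
  enc <- make_toy_encoded(n = 30, noise_sd = 0.2)
  X <- as.matrix(enc[, -(1:2)])
  fit <- suppressWarnings(fit_pls(enc, n_components = 2))
  path <- withr::local_tempfile(fileext = ".json")
  pls_save(fit, path)
  fit2 <- pls_load(path)
  expect_identical(predict(fit2, X), predict(fit, X))
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_pls(X, y = rep(1, 10)),
               class = "sibcut_error_degenerate")
  expect_error(fit_pls(X, y = c(rnorm(9), NA)),
               class = "sibcut_error_input")
  expect_error(fit_pls(X, y = rnorm(10), n_components = 50),
               class = "sibcut_error_contract")
})

test_that("tidy and glance expose coefficients and fit statistics", {
  enc <- make_toy_encoded(n = 30, noise_sd = 0.2)
  fit <- suppressWarnings(fit_pls(enc, n_components = 2))
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 60L)      # 5 positions x 12 descriptors
  expect_named(td, c("term", "estimate", "estimate_scaled"))
  gl <- generics::glance(fit)
  expect_equal(gl$n, 30L)
  expect_equal(gl$n_components, 2L)
})
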