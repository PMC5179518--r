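test_that("orthonormal-design lasso equals the soft-thresholding closed form", {
  x <- make_orthonormal_design()
  set.seed(42)
  beta_true <- c(2, -1.5, 0.8, 0, 0)
  y <- as.numeric(x %*% beta_true + rnorm(nrow(x), 0, 0.3))
  b_ols <- crossprod(x, y - mean(y)) / nrow(x)
  for (lam in c(0.05, 0.4, 1.2)) {
    fit <- fit_lasso_path(x, y, lambda = lam, tol = 1e-10)
    expected <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
    expect_equal(unname(fit$beta[, 1]), as.numeric(expected),
                 tolerance = 1e-6)
  }
})

test_that("all coefficients vanish above the null-path bound", {
  set.seed(43)
  x <- matrix(runif(60 * 4), 60)
  y <- rnorm(60)
  xc <- scale(x, scale = FALSE)
  lam_max <- max(abs(crossprod(xc, y - mean(y)))) / nrow(x)
  fit <- fit_lasso_path(x, y, lambda = lam_max * 1.0001)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept[1], mean(y))
})

test_that("the vanishing-penalty limit matches the normal equations", {
  set.seed(44)
  x <- matrix(runif(50 * 6), 50)
  colnames(x) <- paste0("x", 1:6)
  y <- as.numeric(x %*% rnorm(6) + rnorm(50, 0, 0.5))
  fit <- fit_lasso_path(x, y, lambda = c(1, 1e-8), tol = 1e-12)
  xc <- scale(x, scale = FALSE)
  ols <- solve(crossprod(xc), crossprod(xc, y - mean(y)))
  expect_equal(unname(fit$beta[, 2]), as.numeric(ols), tolerance = 1e-5)
})

test_that("the penalized objective never increases across sweeps", {
  set.seed(45)
  x <- matrix(runif(80 * 10), 80)
  y <- as.numeric(x %*% rnorm(10) + rnorm(80))
  fit <- fit_lasso_path(x, y, trace = TRUE)
  for (tr in fit$objective_trace) {
    expect_true(all(diff(tr) <= 1e-10))
  }
})

test_that("coefficient paths agree with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(46)
  x <- matrix(runif(100 * 8), 100)
  colnames(x) <- paste0("x", 1:8)
  y <- as.numeric(x %*% c(3, -2, 1, 0, 0, 0, 0.5, 0) + rnorm(100, 0, 0.4))
  lam <- exp(seq(log(0.5), log(0.001), length.out = 20))
  fit <- fit_lasso_path(x, y, lambda = lam, tol = 1e-10)
  g <- glmnet::glmnet(x, y, lambda = lam, standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(unname(as.matrix(g$beta)), unname(fit$beta),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("active sets shrink as the penalty grows", {
  set.seed(47)
  x <- matrix(runif(80 * 10), 80)
  y <- as.numeric(x %*% rnorm(10) + rnorm(80, 0, 0.5))
  fit <- fit_lasso_path(x, y)
  active <- colSums(fit$beta != 0)
  # lambda grid is decreasing, so active counts along it are non-decreasing
  expect_true(all(diff(active) >= 0))
})

test_that("repeated CV is deterministic given the seed", {
  d <- generate_design(times = c(3, 5))
  fr <- simulate_fractions(d, default_effects(), 6, seed = 48)
  dm <- build_design(d, fr)
  cv1 <- suppressWarnings(cross_validate(dm, n_repeats = 5, seed = 7))
  cv2 <- suppressWarnings(cross_validate(dm, n_repeats = 5, seed = 7))
  expect_identical(cv1$lambda_opt, cv2$lambda_opt)
  expect_identical(cv1$cv_mean_error, cv2$cv_mean_error)
  cv3 <- suppressWarnings(cross_validate(dm, n_repeats = 5, seed = 8))
  expect_false(identical(cv3$cv_mean_error, cv1$cv_mean_error))
})

test_that("CV error at the all-zero end approaches the response variance", {
  set.seed(49)
  x <- matrix(runif(200 * 5), 200)
  y <- rnorm(200, 10, 2)
  cv <- cross_validate(x, y, n_repeats = 10, seed = 1)
  expect_lt(abs(cv$cv_mean_error[1] - var(y)) / var(y), 0.1)
})

test_that("averaging more CV repeats stabilizes the selected lambda", {
  d <- generate_design(times = c(3, 5))
  fr <- simulate_fractions(d, default_effects(noise_sd = 4), 6, seed = 50)
  dm <- build_design(d, fr)
  opt_few <- vapply(1:8, function(s)
    suppressWarnings(cross_validate(dm, n_repeats = 2, seed = s))$lambda_opt,
    0)
  opt_many <- vapply(1:8, function(s)
    suppressWarnings(cross_validate(dm, n_repeats = 40, seed = s))$lambda_opt,
    0)
  expect_lt(sd(log(opt_many)), sd(log(opt_few)) + 1e-12)
})

test_that("net effects combine singles and interactions as stated", {
  d <- generate_design(times = c(3, 5))
  fr <- simulate_fractions(d, default_effects(), 6, seed = 51)
  dm <- build_design(d, fr)
  cv <- suppressWarnings(cross_validate(dm, n_repeats = 5, seed = 1))
  ne <- net_effects(cv)
  td <- tidy(cv)
  cf <- stats::setNames(td$estimate, td$term)
  pair <- ne |> dplyr::filter(type == "pair")
  expect_equal(pair$net_effect,
               pair$coef_a + pair$coef_b + pair$coef_interaction)
  i <- which(pair$term == "IL-23:IL-6")
  expect_equal(pair$net_effect[i],
               unname(cf["IL-23"] + cf["IL-6"] + cf["IL-23:IL-6"]))
  singles <- ne |> dplyr::filter(type == "cytokine")
  expect_equal(singles$net_effect, unname(cf[singles$term]))

  # all-zero fit gives all-zero net effects
  fit0 <- fit_lasso_path(dm$x, dm$y, lambda = 1e6)
  fit0$columns <- dm$columns
  ne0 <- net_effects(fit0, lambda = 1e6)
  expect_true(all(ne0$net_effect == 0))
})

test_that("degenerate designs and fold counts are rejected", {
  x <- cbind(a = rep(1, 10), b = runif(10))
  expect_error(fit_lasso_path(x, rnorm(10)), "constant")
  expect_error(cross_validate(matrix(runif(8), 4), rnorm(4), n_folds = 10),
               "folds")
})
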