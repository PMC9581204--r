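theta_sig <- c(0.72, 3.14, 2.80)

test_that("linear model evaluates, scales and guards its inputs", {
  th <- c(3.69, 0.066)
  expect_equal(ava_linear(0, 1, th), 0)
  expect_equal(ava_linear(1.0, 1, th), 3.69 * 0.066)
  expect_equal(ava_linear(2 * 0.7, 1.2, th), 2 * ava_linear(0.7, 1.2, th))
  # power form differs from ratio form away from s = 1
  expect_equal(ava_linear(1, 1, th, form = "power"), 3.69 * 0.066)
  expect_false(ava_linear(1, 2, th, form = "power") ==
                 ava_linear(1, 2, th, form = "ratio"))
  expect_error(ava_linear(1, 0, th), "positive")
  expect_error(ava_linear(1, -1, th), "positive")
})

test_that("sigmoid model is zero at rest, saturating, and decreasing in stiffness", {
  expect_identical(ava_sigmoid(0, 1, theta_sig), 0)
  # saturation at theta3 / (2 s^theta4)
  expect_equal(ava_sigmoid(1e4, 1, theta_sig), 0.36, tolerance = 1e-9)
  # frozen scalar evaluation at the flow of a normal cardiac output
  expect_equal(ava_sigmoid(0.96, 1, theta_sig), 0.3141467,
               tolerance = 1e-6)
  # strict monotonicity: increasing and bounded in Q, decreasing in s
  q <- seq(0.05, 3, by = 0.05)
  f <- ava_sigmoid(q, 1, theta_sig)
  expect_true(all(diff(f) > 0))
  expect_true(all(f < 0.36))
  expect_true(all(ava_sigmoid(q, 1.16, theta_sig) < f))
  # the linear model is increasing and unbounded by contrast
  g <- ava_linear(q, 1, c(3.69, 0.066))
  expect_true(all(diff(g) > 0))
  expect_gt(ava_linear(1e3, 1, c(3.69, 0.066)), 1)
  expect_error(ava_sigmoid(1, 0, theta_sig), "positive")
})

test_that("hyperparameter fitting recovers noise-free ground truth", {
  tr <- noise_free_truth()
  d <- generate_peak_dataset(tiny_config(seed = 4), tr)

  fit <- ava_model(d, kind = "sigmoid")
  expect_lt(max(abs(coef(fit) - theta_sig)), 1e-6)
  expect_lt(fit$deviance, 1e-20)

  # linear ratio form: only the product theta1*theta2 is identifiable
  d_lin <- d
  d_lin$ava_peak_frac <- ava_linear(d$q_peak_idx_mps, d$s, c(3.69, 0.066))
  fl <- ava_model(d_lin, kind = "linear")
  expect_equal(prod(coef(fl)), 3.69 * 0.066, tolerance = 1e-6)

  # underdetermined: fewer points than hyperparameters
  expect_error(ava_model(d[1:2, ], kind = "sigmoid"), "underdetermined")
  expect_error(ava_model(d[1:3, ], kind = "sigmoid"), "underdetermined")

  # single stiffness value: the exponent is not identifiable
  expect_warning(ava_model(d[d$grade == "a", ], kind = "sigmoid"),
                 "single stiffness")
})

test_that("the fitted objective never exceeds the objective at the truth", {
  tr <- ground_truth()   # default noise
  d <- generate_peak_dataset(tiny_config(seed = 8), tr)
  fit <- ava_model(d, kind = "sigmoid")
  obj_truth <- sum((d$ava_peak_frac -
                      ava_sigmoid(d$q_peak_idx_mps, d$s,
                                  tr$theta_star))^2)
  expect_lte(fit$deviance, obj_truth + 1e-12)
})

test_that("stiffness fitting inverts the model and matches a grid search", {
  tr <- noise_free_truth()
  model <- list(kind = "sigmoid", theta = theta_sig, form = "ratio")
  q <- seq(0.25, 0.95, length.out = 10)
  for (s_true in c(1, 1.34)) {
    d <- data.frame(q_peak_idx_mps = q,
                    ava_peak_frac = ava_sigmoid(q, s_true, theta_sig))
    expect_equal(as.numeric(fit_stiffness(d, model)), s_true,
                 tolerance = 1e-6)
  }

  # noisy case: optimizer agrees with a fine grid search within 1e-3
  set.seed(5)
  d <- data.frame(q_peak_idx_mps = q,
                  ava_peak_frac = ava_sigmoid(q, 1.16, theta_sig) +
                    rnorm(10, 0, 0.02))
  s_hat <- as.numeric(fit_stiffness(d, model))
  grid <- seq(0.5, 2.5, by = 1e-4)
  sse <- vapply(grid, function(s)
    sum((d$ava_peak_frac - ava_sigmoid(q, s, theta_sig))^2), numeric(1))
  expect_lt(abs(s_hat - grid[which.min(sse)]), 1e-3)

  expect_error(fit_stiffness(d[0, ], model), "at least one")
})

test_that("ava_model methods are coherent", {
  tr <- ground_truth()
  d <- generate_peak_dataset(tiny_config(seed = 2), tr)
  fit <- ava_model(d, kind = "sigmoid")

  expect_s3_class(fit, "ava_model")
  expect_named(coef(fit), c("theta3", "theta4", "theta5"))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), d$ava_peak_frac - fitted(fit))
  nd <- data.frame(q_peak_idx_mps = c(0.3, 0.9), s = c(1, 1.34))
  expect_equal(predict(fit, nd),
               ava_sigmoid(nd$q_peak_idx_mps, nd$s, coef(fit)))

  sm <- summary(fit)
  expect_equal(sm$mse, mean(residuals(fit)^2))
  expect_equal(sm$aic, aic_from_mse(sm$mse, nrow(d), 3))

  s1 <- simulate(fit, nsim = 2, seed = 10)
  s2 <- simulate(fit, nsim = 2, seed = 10)
  expect_identical(s1, s2)
  expect_true(all(unlist(s1) >= 0 & unlist(s1) <= 1))

  expect_output(print(fit), "sigmoid")
  expect_output(print(sm), "AIC")
})
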