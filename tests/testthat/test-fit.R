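# Weighted nonlinear least-squares engine: exact recovery on noiseless
# data, covariance correctness, chi-square calibration and interval
# coverage.

test_that("noiseless self-consistency: each model recovers its own parameters", {
  x <- seq(0, 10, by = 0.5)
  truth_l <- c(A = 100, mu = 3, sigma = 0.8)
  fit_l <- fit_model(
    model_spec("lorentzian"), x,
    lorentzian_model(x, 100, 3, 0.8)
  )
  expect_true(fit_l$converged)
  expect_equal(fit_l$params[names(truth_l)], truth_l, tolerance = 1e-6)
  expect_lt(fit_l$chi2_red, 1e-12)

  xp <- seq(0.5, 15, by = 0.5)
  truth_g <- c(A = 3.5, mu = 2, sigma = 0.25)
  fit_g <- fit_model(
    model_spec("lognorm"), xp,
    lognorm_model(xp, 3.5, 2, 0.25)
  )
  expect_true(fit_g$converged)
  expect_equal(fit_g$params[names(truth_g)], truth_g, tolerance = 1e-6)

  truth_s <- c(A = 2, b0 = 2.8, b1 = 0.25, mu = 4)
  spec_s <- model_spec("linked_linear_constant", fixed = c(sigma_link = 0.25))
  fit_s <- fit_model(
    spec_s, x,
    linked_linear_constant_model(x, 2, 2.8, 0.25, 4, 0.25)
  )
  expect_true(fit_s$converged)
  expect_equal(fit_s$params[names(truth_s)], truth_s, tolerance = 1e-6)
})

test_that("anchored lognorm fits increase-since-x0 data exactly", {
  x <- 5:12
  y <- lognorm_model(x, 3.5, 2, 0.25) - lognorm_model(4, 3.5, 2, 0.25)
  fit <- fit_model(model_spec("lognorm", fixed = c(x0 = 4)), x, y)
  expect_true(fit$converged)
  expect_equal(fit$params[c("A", "mu", "sigma")],
    c(A = 3.5, mu = 2, sigma = 0.25),
    tolerance = 1e-6
  )
})

test_that("fit is equivariant to a time-axis shift", {
  x <- seq(0, 10, by = 0.5)
  y <- lorentzian_model(x, 100, 3, 0.8)
  c_shift <- 57.5
  f1 <- fit_model(model_spec("lorentzian"), x, y)
  f2 <- fit_model(model_spec("lorentzian"), x + c_shift, y)
  expect_equal(f2$params[["mu"]] - f1$params[["mu"]], c_shift,
    tolerance = 1e-6
  )
  expect_equal(f2$params[["A"]], f1$params[["A"]], tolerance = 1e-6)
  expect_equal(f2$params[["sigma"]], f1$params[["sigma"]], tolerance = 1e-6)
})

test_that("standard errors match an analytic-Jacobian covariance oracle", {
  set.seed(7)
  x <- seq(0, 10, by = 0.25)
  sd <- 1.5
  y <- lorentzian_model(x, 100, 3, 0.8) + rnorm(length(x), 0, sd)
  fit <- fit_model(model_spec("lorentzian"), x, y, y_err = rep(sd, length(x)))
  A <- fit$params[["A"]]
  mu <- fit$params[["mu"]]
  s <- fit$params[["sigma"]]
  D <- (x - mu)^2 + s^2
  J <- cbind(
    A = (s / pi) / D,
    mu = (A / pi) * s * 2 * (x - mu) / D^2,
    sigma = (A / pi) * (D - 2 * s^2) / D^2
  ) / sd
  cov_oracle <- solve(crossprod(J))
  expect_equal(
    unname(fit$standard_errors),
    unname(sqrt(diag(cov_oracle))),
    tolerance = 0.01
  )
})

test_that("reduced chi-square is calibrated under correct weighting", {
  set.seed(11)
  x <- seq(0, 10, by = 0.5)
  mu_true <- lorentzian_model(x, 100, 3, 0.8)
  sd <- 2
  chi2 <- replicate(500, {
    y <- mu_true + rnorm(length(x), 0, sd)
    fit_model(model_spec("lorentzian"), x, y,
      y_err = rep(sd, length(x))
    )$chi2_red
  })
  expect_gt(mean(chi2), 0.9)
  expect_lt(mean(chi2), 1.1)
})

test_that("68% Wald intervals for the Lorentzian peak have nominal-ish coverage", {
  set.seed(13)
  x <- seq(0, 10, by = 0.5)
  mu_true <- lorentzian_model(x, 100, 3, 0.8)
  sd <- 3
  hits <- replicate(1000, {
    y <- mu_true + rnorm(length(x), 0, sd)
    fit <- fit_model(model_spec("lorentzian"), x, y,
      y_err = rep(sd, length(x))
    )
    fit$converged &&
      abs(fit$params[["mu"]] - 3) <= fit$standard_errors[["mu"]]
  })
  expect_gte(mean(hits), 0.60)
  expect_lte(mean(hits), 0.76)
})

test_that("constant data fitted with the linked model converge to the constant", {
  x <- 0:10
  y <- rep(5, 11)
  fit <- fit_model(
    model_spec("linked_linear_constant"), x, y,
    init = c(b1 = 0)
  )
  expect_true(fit$converged)
  expect_lt(fit$chi2_red, 1e-20)
  expect_equal(fit$params[["A"]], 5, tolerance = 1e-8)
  expect_equal(fit$params[["b0"]], 5, tolerance = 1e-8)
})

test_that("unweighted fits scale the covariance by the reduced chi-square", {
  set.seed(17)
  x <- seq(0, 10, by = 0.5)
  y <- lorentzian_model(x, 100, 3, 0.8) + rnorm(length(x), 0, 2)
  f_u <- fit_model(model_spec("lorentzian"), x, y)
  f_w <- fit_model(model_spec("lorentzian"), x, y, y_err = rep(1, length(x)))
  # identical optimum; unit-weight covariance = chi2_red * unweighted-Jacobian
  expect_equal(f_u$params, f_w$params, tolerance = 1e-8)
  expect_equal(f_u$covariance, f_w$covariance * f_u$chi2_red,
    tolerance = 1e-6
  )
})

test_that("fit input validation and non-convergence reporting are honest", {
  x <- c(1, 2, 3)
  expect_error(
    fit_model(model_spec("lorentzian"), x, c(1, 2)),
    "equal length"
  )
  expect_error(
    fit_model(model_spec("lorentzian"), x, c(1, 2, 1)),
    "dof"
  )
  expect_error(
    fit_model(
      model_spec("lorentzian"), seq(0, 5, 0.5),
      lorentzian_model(seq(0, 5, 0.5), 10, 2, 1),
      y_err = rep(0, 11)
    ),
    "y_err"
  )
  # a single LM step from a far-off start must not report convergence
  xx <- seq(0, 10, by = 0.5)
  yy <- lorentzian_model(xx, 100, 3, 0.8)
  bad <- suppressWarnings(fit_model(model_spec("lorentzian"), xx, yy,
    init = c(A = 1, mu = 50, sigma = 5),
    control = minpack.lm::nls.lm.control(maxiter = 1)
  ))
  expect_false(bad$converged)
})
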