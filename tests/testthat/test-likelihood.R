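test_that("loglikelihood matches closed forms and the density-sum oracle", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  tt <- c(0, 100, 300, 600, 1000)
  mu <- solve_logistic(tt, 0.01, 100, 5)
  theta <- list(lambda = 0.01, K = 100)
  # zero residuals: -I (log sigma + log(2 pi)/2)
  d0 <- tibble::tibble(time = tt, observation = mu)
  expect_equal(log_likelihood(d0, m, theta, sigma = 5),
               -5 * (log(5) + 0.5 * log(2 * pi)), tolerance = 1e-12)
  # one point with residual exactly sigma
  d1 <- tibble::tibble(time = 100, observation = mu[2] + 5)
  expect_equal(log_likelihood(d1, m, theta, sigma = 5),
               -log(5) - 0.5 * log(2 * pi) - 0.5, tolerance = 1e-12)
  # two-point toy against the independent per-point density oracle
  d2 <- tibble::tibble(time = c(100, 600), observation = c(15.1, 68.4))
  expect_equal(log_likelihood(d2, m, theta, sigma = 3),
               oracle_gaussian_loglik(d2$observation, mu[c(2, 4)], 3),
               tolerance = 1e-12)
  # additivity over data points
  parts <- vapply(seq_along(tt), function(i) {
    log_likelihood(d0[i, ], m, theta, sigma = 5)
  }, numeric(1))
  expect_equal(sum(parts), log_likelihood(d0, m, theta, sigma = 5),
               tolerance = 1e-12)
})

test_that("sigma sensitivity has the closed-form sign Sum(r^2)/s^3 - I/s", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  tt <- c(0, 200, 500)
  mu <- solve_logistic(tt, 0.01, 100, 5)
  r <- c(2, -7, 4)
  d <- tibble::tibble(time = tt, observation = mu + r)
  theta <- list(lambda = 0.01, K = 100)
  for (s in c(2, 4, 8)) {
    h <- 1e-6
    fd <- (log_likelihood(d, m, theta, sigma = s + h) -
             log_likelihood(d, m, theta, sigma = s - h)) / (2 * h)
    expect_equal(fd, sum(r^2) / s^3 - length(r) / s, tolerance = 1e-5)
  }
})

test_that("sigma must be resolved and positive", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  d <- tibble::tibble(time = c(0, 1), observation = c(5, 5))
  expect_error(log_likelihood(d, m, list(lambda = 0.01, K = 100)), "sigma")
  expect_error(log_likelihood(d, m, list(lambda = 0.01, K = 100), sigma = -1),
               "positive")
  # sigma supplied through params works
  expect_equal(log_likelihood(d, m, list(lambda = 0.01, K = 100, sigma = 5)),
               log_likelihood(d, m, list(lambda = 0.01, K = 100), sigma = 5))
})

test_that("normalization subtracts the supremum and preserves ordering", {
  expect_equal(normalize_loglik(c(-3, -1, -7)), c(-2, 0, -6))
  expect_equal(normalize_loglik(-42), 0)
  x <- c(-10, -2, -5, -Inf)
  expect_equal(normalize_loglik(x + 13.7), normalize_loglik(x))
  expect_error(normalize_loglik(c(-Inf, -Inf)), "no admissible")
})

test_that("parameter_box validates axes and resolutions", {
  b <- parameter_box(lambda = c(0, 1), K = c(50, 200), resolution = 11)
  expect_equal(b$resolution, c(lambda = 11L, K = 11L))
  expect_error(parameter_box(lambda = c(1, 0)), "lower < upper")
  expect_error(parameter_box(lambda = c(0, 1), resolution = 1), ">= 2")
  expect_error(parameter_box(c(0, 1)), "name")
})

test_that("grid search finds truth planted on a grid node, normalized to 0", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  tt <- 100 * (0:10)
  # bounds chosen so the truth (0.01, 100) sits exactly on node (6, 6) of 11^2
  box <- parameter_box(lambda = c(0.005, 0.015), K = c(50, 150),
                       resolution = 11)
  d <- simulate_growth_data(m, list(lambda = 0.01, K = 100), tt, sigma = 0)
  g <- fit_mle_grid(d, m, box, sigma = 5)
  expect_equal(unname(g$mle), c(0.01, 100), tolerance = 1e-12)
  expect_identical(max(g$values), 0)
  expect_true(all(g$values <= 0))
  expect_equal(g$mle_index, c(6L, 6L))
})

test_that("grid and optimizer MLEs agree within one grid spacing per axis", {
  m <- case1_model()
  d <- fixture_case1()
  b <- case1_bounds()
  box <- do.call(parameter_box, c(b, list(resolution = 41)))
  g <- fit_mle_grid(d, m, box, sigma = 5)
  fit <- fit_mle(d, m, b, sigma = 5, seed = 1)
  spacing <- vapply(b, function(x) diff(x) / 40, numeric(1))
  # the non-identified ridge means the arg-max locations may differ, but the
  # achieved suprema must agree and the optimizer can never do worse
  expect_gte(fit$loglik, g$loglik_max_raw - 1e-6)
  expect_lt(fit$loglik - g$loglik_max_raw, 0.05)
  # on an identifiable 2-parameter problem the locations agree too
  m2 <- growth_model("logistic", fixed = list(C0 = 5))
  d2 <- simulate_growth_data(m2, list(lambda = 0.01, K = 100), 100 * (0:10),
                             sigma = 5, seed = 8)
  b2 <- list(lambda = c(1e-3, 0.05), K = c(50, 200))
  g2 <- fit_mle_grid(d2, m2, do.call(parameter_box,
                                     c(b2, list(resolution = 101))),
                     sigma = 5)
  f2 <- fit_mle(d2, m2, b2, sigma = 5, seed = 1)
  sp2 <- vapply(b2, function(x) diff(x) / 100, numeric(1))
  expect_true(all(abs(g2$mle - f2$par) <= sp2 + 1e-12))
})

test_that("optimizer recovers noise-free truth and respects bounds exactly", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  d <- simulate_growth_data(m, list(lambda = 0.01, K = 100), 100 * (0:10),
                            sigma = 0)
  f <- fit_mle(d, m, list(lambda = c(1e-3, 0.05), K = c(50, 200)), sigma = 5,
               seed = 2)
  expect_lt(max(abs(f$par - c(0.01, 100)) / c(0.01, 100)), 1e-3)
  # truth outside the box: the estimate lands exactly on the bound
  fb <- fit_mle(d, m, list(lambda = c(1e-3, 0.05), K = c(50, 90)), sigma = 5,
                seed = 2)
  expect_identical(unname(fb$par["K"]), 90)
})

test_that("likelihood_grid tidiers expose the MLE and summary", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  d <- simulate_growth_data(m, list(lambda = 0.01, K = 100), 100 * (0:10),
                            sigma = 5, seed = 1)
  g <- fit_mle_grid(d, m, parameter_box(lambda = c(1e-3, 0.05),
                                        K = c(50, 200), resolution = 21),
                    sigma = 5)
  expect_named(tidy(g), c("term", "estimate"))
  expect_equal(glance(g)$n_nodes, 21^2)
  tb <- tibble::as_tibble(g)
  expect_equal(nrow(tb), 21^2)
  expect_equal(max(tb$loglik), 0)
})
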