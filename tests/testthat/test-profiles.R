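test_that("likelihood-ratio thresholds match the chi-squared quantiles", {
  expect_equal(chisq_threshold(1), -qchisq(0.95, 1) / 2, tolerance = 1e-12)
  expect_equal(round(chisq_threshold(1), 2), -1.92)
  expect_equal(round(chisq_threshold(2), 2), -3.00)
  expect_equal(round(chisq_threshold(3), 2), -3.91)
  expect_equal(round(chisq_threshold(4), 2), -4.74)
  expect_error(chisq_threshold(0), "df")
  expect_error(chisq_threshold(1, level = 1.2), "level")
})

# shared small grid for the grid-profiling tests
local_case1_grid <- local({
  g <- NULL
  function() {
    if (is.null(g)) {
      g <<- fit_mle_grid(fixture_case1(), case1_model(),
                         do.call(parameter_box,
                                 c(case1_bounds(), list(resolution = 21))),
                         sigma = 5)
    }
    g
  }
})

test_that("grid profiles equal a brute-force maximization over nuisances", {
  g <- local_case1_grid()
  tb <- tibble::as_tibble(g)
  pr <- profile_grid(g, "lambda")
  brute <- tb |>
    dplyr::group_by(lambda) |>
    dplyr::summarise(value = max(loglik), .groups = "drop")
  expect_equal(pr$profile$value, brute$value, tolerance = 1e-12)
  # recorded nuisance values reproduce the profile (omega* bookkeeping)
  recomputed <- vapply(seq_len(nrow(pr$profile)), function(j) {
    row <- pr$profile[j, ]
    log_likelihood(g$data, g$model,
                   list(lambda = row$psi, d = row$d, K = row$K), sigma = 5)
  }, numeric(1)) - g$loglik_max_raw
  expect_equal(recomputed, pr$profile$value, tolerance = 1e-9)
  # bivariate: same check against grouped max
  sf <- profile_grid(g, c("lambda", "d"))
  brute2 <- tb |>
    dplyr::group_by(lambda, d) |>
    dplyr::summarise(value = max(loglik), .groups = "drop") |>
    dplyr::arrange(d, lambda)
  expect_equal(sf$profile$value, brute2$value, tolerance = 1e-12)
})

test_that("profiles satisfy the sup property and peak at zero", {
  g <- local_case1_grid()
  tb <- tibble::as_tibble(g)
  pr <- profile_grid(g, "K")
  expect_equal(max(pr$profile$value), 0)
  # every full-likelihood value is dominated by its profile value
  prof_by_K <- stats::setNames(pr$profile$value, format(pr$profile$psi))
  expect_true(all(tb$loglik <= prof_by_K[format(tb$K)] + 1e-12))
  # profiling the bivariate surface down one axis equals the univariate
  sf <- profile_grid(g, c("K", "d"))
  collapsed <- sf$profile |>
    dplyr::group_by(K) |>
    dplyr::summarise(value = max(value), .groups = "drop")
  expect_equal(collapsed$value, pr$profile$value, tolerance = 1e-12)
})

test_that("confidence-set regions are nested across thresholds", {
  g <- local_case1_grid()
  sf <- profile_grid(g, c("lambda", "d"))
  in2 <- sf$profile$value >= chisq_threshold(2)
  in3 <- sf$profile$value >= chisq_threshold(3)
  expect_true(all(!in2 | in3))  # -3.00 region contained in -3.91 region
})

test_that("profile errors when nothing is left to profile", {
  g <- local_case1_grid()
  expect_error(profile_grid(g, c("lambda", "d", "K")), "one or two")
  expect_error(profile_likelihood(fixture_case1(), case1_model(),
                                  c("lambda", "d", "K"), case1_bounds(),
                                  sigma = 5), "one or two")
})

test_that("optimizer profiles agree with grid profiles on a shared mesh", {
  g <- local_case1_grid()
  d <- fixture_case1()
  fit <- fit_mle(d, case1_model(), case1_bounds(), sigma = 5, seed = 1)
  psi <- g$axes$lambda
  pr_g <- profile_grid(g, "lambda")
  pr_o <- profile_likelihood(d, case1_model(), "lambda", case1_bounds(),
                             sigma = 5, psi_grid = psi, fit = fit)
  # on the raw (unnormalized) scale the optimizer profile dominates the grid
  # profile up to optimizer tolerance; the excess is nuisance-grid
  # discretization. Each route normalizes by its own supremum, so raw values
  # are the comparable scale.
  gap <- (pr_o$profile$value + fit$loglik) -
    (pr_g$profile$value + g$loglik_max_raw)
  expect_true(all(gap > -0.01))
  # the excess shrinks as the nuisance grid refines
  g41 <- fit_mle_grid(d, case1_model(),
                      do.call(parameter_box,
                              c(case1_bounds(), list(resolution = 41))),
                      sigma = 5)
  pr_g41 <- profile_grid(g41, "lambda")
  pr_o41 <- profile_likelihood(d, case1_model(), "lambda", case1_bounds(),
                               sigma = 5, psi_grid = g41$axes$lambda,
                               fit = fit)
  gap41 <- (pr_o41$profile$value + fit$loglik) -
    (pr_g41$profile$value + g41$loglik_max_raw)
  rel21 <- pr_g$profile$value >= -10
  rel41 <- pr_g41$profile$value >= -10
  expect_lt(max(gap41[rel41]), max(gap[rel21]))
  # the inference the profiles support coincides: CI endpoints within one
  # psi-grid spacing, identical truncation flags
  ci_g <- ci_from_profile(pr_g)
  ci_o <- ci_from_profile(pr_o)
  spacing <- diff(case1_bounds()$lambda) / 20
  expect_lt(abs(ci_g$lower - ci_o$lower), spacing)
  expect_lt(abs(ci_g$upper - ci_o$upper), spacing)
  expect_identical(ci_g[c("truncated_lower", "truncated_upper")],
                   ci_o[c("truncated_lower", "truncated_upper")])
})

test_that("interval extraction inverts a quadratic profile in closed form", {
  a <- 2.5
  w <- 0.8
  psi <- seq(0, 5, length.out = 401)
  curve <- profilewise:::new_profile_curve(
    "x", tibble::tibble(psi = psi, value = -(psi - a)^2 / w),
    mle = c(x = a), threshold = chisq_threshold(1), source = "test")
  ci <- ci_from_profile(curve)
  half <- sqrt(-chisq_threshold(1) * w)
  expect_equal(ci$lower, a - half, tolerance = 1e-3)
  expect_equal(ci$upper, a + half, tolerance = 1e-3)
  expect_false(ci$truncated_lower || ci$truncated_upper)
  # a flat profile at 0 spans the whole box with both flags raised
  flat <- profilewise:::new_profile_curve(
    "x", tibble::tibble(psi = psi, value = rep(0, length(psi))),
    mle = c(x = a), threshold = chisq_threshold(1), source = "test")
  cif <- ci_from_profile(flat)
  expect_equal(c(cif$lower, cif$upper), range(psi))
  expect_true(cif$truncated_lower && cif$truncated_upper)
  # everything below threshold is an error
  low <- profilewise:::new_profile_curve(
    "x", tibble::tibble(psi = psi, value = rep(-9, length(psi))),
    mle = c(x = a), threshold = chisq_threshold(1), source = "test")
  expect_error(ci_from_profile(low), "below the threshold")
})

test_that("contour sampling hits a circular quadratic at radius sqrt(3)", {
  gx <- seq(-3, 3, length.out = 201)
  surf <- profilewise:::new_profile_surface(
    c("x", "y"),
    dplyr::mutate(profilewise:::tidyr_expand_grid(list(x = gx, y = gx)),
                  value = -(x^2 + y^2)),
    psi_grids = list(x = gx, y = gx),
    mle = c(x = 0, y = 0), threshold = -3, source = "test")
  cs <- sample_contour(surf, level = -3, n_points = 100, seed = 5)
  expect_false(any(cs$on_bound))
  expect_true(all(abs(cs$value - (-3)) <= 1e-4))
  r <- sqrt(cs$x^2 + cs$y^2)
  expect_true(all(abs(r - sqrt(3)) < 5e-3))  # bilinear interpolation error
  # seeded reproducibility
  cs2 <- sample_contour(surf, level = -3, n_points = 100, seed = 5)
  expect_identical(as.data.frame(cs), as.data.frame(cs2))
})

test_that("open contours terminate on the bounds and are flagged", {
  gx <- seq(-1, 1, length.out = 41)
  flat <- profilewise:::new_profile_surface(
    c("x", "y"),
    dplyr::mutate(profilewise:::tidyr_expand_grid(list(x = gx, y = gx)),
                  value = 0),
    psi_grids = list(x = gx, y = gx),
    mle = c(x = 0, y = 0), threshold = -3, source = "test")
  cs <- sample_contour(flat, level = -3, n_points = 25, seed = 2)
  expect_true(all(cs$on_bound))
  on_edge <- abs(abs(cs$x) - 1) < 1e-9 | abs(abs(cs$y) - 1) < 1e-9
  expect_true(all(on_edge))
})

test_that("optimization-based contours carry consistent nuisance values", {
  d <- fixture_case1()
  m <- case1_model()
  b <- case1_bounds()
  fit <- fit_mle(d, m, b, sigma = 5, seed = 1)
  cs <- sample_contour(d, level = chisq_threshold(2), n_points = 25, seed = 9,
                       model = m, interest = c("lambda", "K"), bounds = b,
                       sigma = 5, fit = fit)
  expect_true(all(abs(cs$value[!cs$on_bound] - chisq_threshold(2)) <= 1e-4))
  # pushing (psi, omega*) through the full loglikelihood reproduces the value
  ll <- vapply(seq_len(nrow(cs)), function(i) {
    log_likelihood(d, m, as.list(cs[i, c("lambda", "d", "K")]), sigma = 5)
  }, numeric(1)) - fit$loglik
  expect_equal(ll, cs$value, tolerance = 1e-8)
})
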