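test_that("a single parameter vector gives a zero-width envelope", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  ps <- tibble::tibble(lambda = 0.01, K = 100)
  tt <- seq(0, 1000, length.out = 21)
  e <- envelope_from_parameters(ps, m, tt, mle_params = ps[1, ])
  expect_equal(e$lower, e$upper)
  expect_equal(e$lower, solve_logistic(tt, 0.01, 100, 5))
  expect_equal(e$mle, e$lower)
})

test_that("envelopes are monotone in the parameter set and order-invariant", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  tt <- seq(0, 1000, length.out = 21)
  set.seed(42)
  big <- tibble::tibble(lambda = runif(30, 0.005, 0.02), K = runif(30, 80, 120))
  small <- big[1:10, ]
  e_big <- envelope_from_parameters(big, m, tt)
  e_small <- envelope_from_parameters(small, m, tt)
  expect_true(all(e_big$lower <= e_small$lower + 1e-12))
  expect_true(all(e_big$upper >= e_small$upper - 1e-12))
  e_perm <- envelope_from_parameters(big[sample(30), ], m, tt)
  expect_equal(e_perm$lower, e_big$lower)
  expect_equal(e_perm$upper, e_big$upper)
  expect_error(envelope_from_parameters(big[0, ], m, tt), "empty")
})

test_that("a structural equivalence class collapses to a zero-width envelope", {
  # harvest-model parameters sharing (Lambda, kappa) = (0.008, 80)
  m <- growth_model("logistic_harvest", fixed = list(C0 = 5))
  d <- seq(0, 0.01, length.out = 15)
  lam <- 0.008 + d
  ps <- tibble::tibble(lambda = lam, d = d, K = 80 * lam / 0.008)
  e <- envelope_from_parameters(ps, m, seq(0, 1000, length.out = 21))
  expect_lt(max(e$upper - e$lower), 1e-9)
})

test_that("grid filtering respects the threshold semantics", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  d <- simulate_growth_data(m, list(lambda = 0.01, K = 100), 100 * (0:10),
                            sigma = 5, seed = 8)
  g <- fit_mle_grid(d, m, parameter_box(lambda = c(1e-3, 0.05),
                                        K = c(50, 200), resolution = 41),
                    sigma = 5)
  tt <- seq(0, 1000, length.out = 31)
  # threshold 0 retains only the MLE node(s)
  e0 <- envelope_from_grid(g, 0, tt)
  expect_equal(attr(e0, "n_curves"), 1)
  expect_equal(e0$lower, e0$mle, tolerance = 1e-12)
  # threshold -Inf retains the whole box
  eI <- envelope_from_grid(g, -Inf, tt)
  expect_equal(attr(eI, "n_curves"), 41^2)
  e2 <- envelope_from_grid(g, chisq_threshold(2), tt)
  expect_true(all(eI$lower <= e2$lower & e2$upper <= eI$upper))
  # MLE curve lies inside the envelope
  expect_true(all(e2$lower <= e2$mle & e2$mle <= e2$upper))
})

test_that("rejection-sampled envelopes match grid filtering on a 2-parameter toy", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  d <- simulate_growth_data(m, list(lambda = 0.01, K = 100), 100 * (0:10),
                            sigma = 5, seed = 3)
  b <- list(lambda = c(1e-3, 0.05), K = c(50, 200))
  tt <- seq(0, 1000, length.out = 31)
  er <- envelope_by_rejection(d, m, b, sigma = 5,
                              threshold = chisq_threshold(2),
                              n_accept = 3000, seed = 4, times = tt)
  acc <- attr(er, "accepted")
  expect_true(all(acc$loglik >= chisq_threshold(2)))
  expect_true(all(er$lower <= er$mle & er$mle <= er$upper))
  g <- fit_mle_grid(d, m, do.call(parameter_box, c(b, list(resolution = 201))),
                    sigma = 5)
  eg <- envelope_from_grid(g, chisq_threshold(2), tt)
  # tolerance: one grid spacing propagated through the model response at the
  # MLE (the two constructions discretize the same set differently)
  sp <- vapply(b, function(x) diff(x) / 200, numeric(1))
  mle <- as.list(g$mle)
  base <- solve_logistic(tt, mle$lambda, mle$K, 5)
  tol <- abs(solve_logistic(tt, mle$lambda + sp[1], mle$K + sp[2], 5) - base) +
    0.05 * max(eg$upper - eg$lower)
  expect_true(all(abs(er$lower - eg$lower) <= tol))
  expect_true(all(abs(er$upper - eg$upper) <= tol))
})

test_that("unions contain their components and demand a shared time grid", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  tt <- seq(0, 1000, length.out = 21)
  set.seed(1)
  mk <- function() {
    envelope_from_parameters(
      tibble::tibble(lambda = runif(5, 0.005, 0.02), K = runif(5, 80, 120)),
      m, tt)
  }
  e1 <- mk(); e2 <- mk(); e3 <- mk()
  u <- envelope_union(e1, e2, e3)
  expect_identical(attr(u, "source"), "union")
  for (e in list(e1, e2, e3)) {
    expect_true(all(u$lower <= e$lower & e$upper <= u$upper))
  }
  expect_equal(as.data.frame(envelope_union(e1, e1))[, c("lower", "upper")],
               as.data.frame(e1)[, c("lower", "upper")])
  e_bad <- envelope_from_parameters(
    tibble::tibble(lambda = 0.01, K = 100), m, seq(0, 900, length.out = 21))
  expect_error(envelope_union(e1, e_bad), "time grid")
})

test_that("refining the time grid never narrows the envelope at shared times", {
  m <- growth_model("logistic", fixed = list(C0 = 5))
  set.seed(7)
  ps <- tibble::tibble(lambda = runif(20, 0.005, 0.02), K = runif(20, 80, 120))
  coarse <- seq(0, 1000, length.out = 11)
  fine <- seq(0, 1000, length.out = 101)  # superset of the coarse grid
  ec <- envelope_from_parameters(ps, m, coarse)
  ef <- envelope_from_parameters(ps, m, fine)
  shared <- match(coarse, fine)
  expect_true(all(ef$lower[shared] <= ec$lower + 1e-12))
  expect_true(all(ef$upper[shared] >= ec$upper - 1e-12))
})
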