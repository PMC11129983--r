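#' Simulate a noisy growth dataset
#'
#' Generates observations equal to the model mean trajectory at `times` plus
#' independent additive Gaussian noise of standard deviation `sigma`.
#' Negative observed densities are permitted — the additive noise model does
#' not truncate. `sigma = 0` returns the noise-free trajectory, which is
#' convenient for identifiability diagnostics.
#'
#' @param model A [growth_model()].
#' @param params Named list/vector of the model's free parameters (true
#'   values).
#' @param times Observation times, strictly increasing, non-negative.
#' @param sigma Noise standard deviation (`>= 0`).
#' @param seed Optional integer seed.
#' @return A tibble with columns `time` and `observation`; the generating
#'   design (model name, parameters, sigma, seed) is attached as the
#'   `design` attribute.
#' @examples
#' m <- growth_model("logistic_harvest", fixed = list(C0 = 5))
#' simulate_growth_data(m, list(lambda = 0.01, d = 0.002, K = 100),
#'                      times = 100 * (0:10), sigma = 5, seed = 1)
#' @export
simulate_growth_data <- function(model, params, times, sigma, seed = NULL) {
  stopifnot(inherits(model, "growth_model"))
  if (is.unsorted(times, strictly = TRUE)) {
    rlang::abort("`times` must be strictly increasing")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    rlang::abort("`sigma` must be a single non-negative number")
  }
  mu <- model_solution(model, params, times)
  if (!is.null(seed)) set.seed(seed)
  obs <- mu + if (sigma > 0) stats::rnorm(length(times), 0, sigma) else 0
  out <- tibble::tibble(time = as.numeric(times), observation = obs)
  attr(out, "design") <- list(model = model$name,
                              params = as.list(params),
                              fixed = model$fixed,
                              sigma = sigma, seed = seed)
  out
}

# Case-study designs. The harvesting case uses the printed design exactly:
# truth (lambda, d, K, C0) = (0.01, 0.002, 100, 5), sigma = 5, observations at
# t_i = 100 (i - 1), i = 1..11, with C0 and sigma treated as known. The
# Richards case is a synthetic stand-in for coral-recovery monitoring:
# truth equal to the published Richards MLE for that series, sigma = 2, and 30
# uniform observation times over [0, 3000] days (the real monitoring times are
# not published).
case1_design <- function() {
  list(model = growth_model("logistic_harvest", fixed = list(C0 = 5)),
       params = list(lambda = 0.01, d = 0.002, K = 100),
       times = 100 * (0:10), sigma = 5, seed = 20240527,
       bounds = list(lambda = c(1e-4, 0.05), d = c(0, 0.01), K = c(50, 200)))
}

case2_design <- function() {
  list(model = growth_model("richards"),
       params = list(lambda = 0.0055, beta = 0.341, K = 81.73, C0 = 0.092),
       times = seq(0, 3000, length.out = 30), sigma = 2, seed = 20240528,
       bounds = list(lambda = c(1e-4, 0.05), beta = c(0.01, 3),
                     K = c(50, 120), C0 = c(1e-4, 10)))
}

#' Packaged case-study datasets
#'
#' Fixed-seed synthetic datasets shipped with the package so every stage of
#' the workflow is runnable without external data.
#'
#' `fixture_case1()` is one noisy realisation of the logistic-with-harvesting
#' design: truth \eqn{(\lambda, d, K) = (0.01, 0.002, 100)} with known
#' \eqn{C(0) = 5} and \eqn{\sigma = 5}, observed at \eqn{t_i = 100(i-1)},
#' \eqn{i = 1, \dots, 11}.
#'
#' `fixture_case2()` is a synthetic stand-in for a coral-cover recovery
#' series: one realisation of the Richards model at
#' \eqn{(\lambda, \beta, K, C(0)) = (0.0055, 0.341, 81.73, 0.092)} with
#' \eqn{\sigma = 2} at 30 uniform times over \eqn{[0, 3000]} days. It is
#' generated, not field data.
#'
#' Both are stored as plain CSV under `inst/extdata/` and are bit-identical
#' to regenerating with [simulate_growth_data()] at the recorded seed.
#'
#' @return A tibble with columns `time` and `observation`.
#' @examples
#' fixture_case1()
#' @export
fixture_case1 <- function() {
  read_growth_data(system.file("extdata", "case1_logistic_harvest.csv",
                               package = "profilewise", mustWork = TRUE))
}

#' @rdname fixture_case1
#' @export
fixture_case2 <- function() {
  read_growth_data(system.file("extdata", "case2_richards_synthetic.csv",
                               package = "profilewise", mustWork = TRUE))
}

# regenerate a fixture from its recorded design (used by tests and by
# data-raw-style refresh)
regenerate_fixture <- function(which = c("case1", "case2")) {
  which <- match.arg(which)
  d <- if (which == "case1") case1_design() else case2_design()
  simulate_growth_data(d$model, d$params, d$times, d$sigma, seed = d$seed)
}
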