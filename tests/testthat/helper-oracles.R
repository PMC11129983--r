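# Independent oracles, written directly from the closed forms, against which
# the package implementations are checked.

# logistic solution, direct transcription
oracle_logistic <- function(t, lambda, K, C0) {
  K * C0 / (C0 + (K - C0) * exp(-lambda * t))
}

# von Bertalanffy curve: Richards exponent fixed at 1/3, transcribed with the
# exponent hard-coded
oracle_von_bertalanffy <- function(t, lambda, K, C0) {
  K * C0 / (C0^(1 / 3) + (K^(1 / 3) - C0^(1 / 3)) * exp(-lambda * t / 3))^3
}

# per-point Gaussian density summation, densities written out long-hand
oracle_gaussian_loglik <- function(obs, mu, sigma) {
  dens <- exp(-(obs - mu)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  sum(log(dens))
}

# case-study-1 problem pieces shared across tests
case1_model <- function() growth_model("logistic_harvest", fixed = list(C0 = 5))
case1_bounds <- function() {
  list(lambda = c(1e-4, 0.05), d = c(0, 0.01), K = c(50, 200))
}
case1_truth <- function() list(lambda = 0.01, d = 0.002, K = 100)

richards_truth <- function() {
  list(lambda = 0.0055, beta = 0.341, K = 81.73, C0 = 0.092)
}
richards_bounds <- function() {
  list(lambda = c(1e-4, 0.05), beta = c(0.01, 3), K = c(50, 120),
       C0 = c(1e-4, 10))
}
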