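#' Closed-form population growth models
#'
#' `growth_model()` builds a model specification addressable by name:
#' `"logistic"`, `"logistic_harvest"` (logistic growth with a linear harvesting
#' / removal term), or `"richards"`. A specification records the ordered
#' parameter labels of the model, which of them are held fixed at known values
#' (for example the initial density `C0`, or the noise standard deviation in a
#' fitting context), and the closed-form solution used to evaluate the mean
#' trajectory \eqn{C(t)}.
#'
#' The three models solve, respectively,
#' \deqn{dC/dt = \lambda C (1 - C/K),}
#' \deqn{dC/dt = \lambda C (1 - C/K) - d C,}
#' \deqn{dC/dt = \lambda C (1 - (C/K)^\beta),}
#' all with initial density `C0`. The harvesting model is evaluated through the
#' reparameterization \eqn{\Lambda = \lambda - d}, \eqn{\kappa = K\Lambda/\lambda},
#' under which it is again a logistic equation; distinct \eqn{(\lambda, d, K)}
#' sharing \eqn{(\Lambda, \kappa)} produce identical trajectories, which is the
#' structural non-identifiability this package is built to diagnose.
#'
#' @param name Model name, one of `"logistic"`, `"logistic_harvest"`,
#'   `"richards"`.
#' @param fixed Named list of parameters held fixed at known values, e.g.
#'   `list(C0 = 5)`. Labels must be parameters of the model.
#' @return An object of class `growth_model` with elements `name`,
#'   `param_names`, `free_params`, and `fixed`.
#' @examples
#' m <- growth_model("logistic_harvest", fixed = list(C0 = 5))
#' m$free_params
#' @export
growth_model <- function(name = c("logistic", "logistic_harvest", "richards"),
                         fixed = list()) {
  name <- match.arg(name)
  param_names <- switch(name,
    logistic         = c("lambda", "K", "C0"),
    logistic_harvest = c("lambda", "d", "K", "C0"),
    richards         = c("lambda", "beta", "K", "C0")
  )
  fixed <- as.list(fixed)
  if (length(fixed)) {
    bad <- setdiff(names(fixed), param_names)
    if (length(bad)) {
      rlang::abort(sprintf(
        "fixed parameter(s) %s are not parameters of the '%s' model (expects %s)",
        paste0("'", bad, "'", collapse = ", "), name,
        paste(param_names, collapse = ", ")
      ))
    }
    if (anyDuplicated(names(fixed))) {
      rlang::abort("duplicated labels in `fixed`")
    }
  }
  structure(
    list(
      name = name,
      param_names = param_names,
      free_params = setdiff(param_names, names(fixed)),
      fixed = fixed
    ),
    class = "growth_model"
  )
}

#' @export
print.growth_model <- function(x, ...) {
  cat("<growth_model: ", x$name, ">\n", sep = "")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  if (length(x$fixed)) {
    cat("  fixed:     ",
        paste(names(x$fixed), unlist(x$fixed), sep = " = ", collapse = ", "),
        "\n")
  }
  cat("  free:      ", paste(x$free_params, collapse = ", "), "\n")
  invisible(x)
}

## ---- admissibility -------------------------------------------------------

# Checks pre-conditions parameter-by-parameter so the error names the
# offending parameter. Vectorized parameters are checked element-wise.
check_admissible <- function(name, p) {
  stop_bad <- function(label, rule) {
    rlang::abort(
      sprintf("inadmissible parameter '%s' for model '%s': requires %s",
              label, name, rule),
      class = "profilewise_admissibility_error"
    )
  }
  need_pos <- function(label) {
    v <- p[[label]]
    if (is.null(v) || anyNA(v) || any(v <= 0)) stop_bad(label, "> 0")
  }
  switch(name,
    logistic = {
      need_pos("K"); need_pos("C0")
      if (is.null(p$lambda) || anyNA(p$lambda)) stop_bad("lambda", "a finite value")
    },
    logistic_harvest = {
      need_pos("lambda"); need_pos("K"); need_pos("C0")
      if (is.null(p$d) || anyNA(p$d) || any(p$d < 0)) stop_bad("d", ">= 0")
    },
    richards = {
      need_pos("lambda"); need_pos("beta"); need_pos("K"); need_pos("C0")
    }
  )
  invisible(TRUE)
}

## ---- closed-form solutions ----------------------------------------------
# Cores are plain arithmetic on vectors: either the parameters are scalars and
# `t` a vector (user-facing solvers), or the parameters are long vectors and
# `t` scalar (dense grid evaluation). Regime switches use logical subsetting,
# never ifelse(), so both shapes recycle correctly.

logistic_core <- function(lambda, K, C0, t) {
  K * C0 / (C0 + (K - C0) * exp(-lambda * t))
}

richards_core <- function(lambda, beta, K, C0, t) {
  # C(t) = K C0 / (C0^b + (K^b - C0^b) e^{-lambda b t})^{1/b}
  # evaluated in log space: the bracket is e^a (1 - e^u) + e^b0 e^u with
  # a = b log C0, b0 = b log K, u = -lambda b t, both terms non-negative for
  # t >= 0, so log-sum-exp is stable for extreme exponents (small beta, C0).
  a  <- beta * log(C0)
  b0 <- beta * log(K)
  u  <- -lambda * beta * t
  x <- a + log1p(-exp(u))   # -Inf at t = 0, as it should be
  y <- b0 + u
  m <- pmax(x, y)
  logden <- (m + log(exp(x - m) + exp(y - m))) / beta
  exp(log(K) + log(C0) - logden)
}

#' Closed-form solution of the logistic model
#'
#' Evaluates \eqn{C(t) = K C_0 / (C_0 + (K - C_0) e^{-\lambda t})}.
#'
#' @param times Numeric vector of times (days), finite and non-negative.
#' @param lambda Growth rate (per day).
#' @param K Carrying capacity (density units), `> 0`.
#' @param C0 Initial density, `> 0`.
#' @return Numeric vector of densities, one per time.
#' @examples
#' solve_logistic(c(0, 100, 1000), lambda = 0.01, K = 100, C0 = 5)
#' @export
solve_logistic <- function(times, lambda, K, C0) {
  check_admissible("logistic", list(lambda = lambda, K = K, C0 = C0))
  check_times(times)
  out <- logistic_core(lambda, K, C0, times)
  out[times == 0] <- C0
  out
}

#' Closed-form solution of the logistic model with harvesting
#'
#' Evaluates the logistic-with-harvesting trajectory through the
#' reparameterization \eqn{\Lambda = \lambda - d},
#' \eqn{\kappa = K \Lambda / \lambda}:
#' \eqn{C(t) = \kappa C_0 / (C_0 + (\kappa - C_0) e^{-\Lambda t})}.
#' All three long-time regimes are handled: growth to \eqn{\kappa} when
#' \eqn{\lambda > d}, decay to 0 when \eqn{\lambda < d} (negative \eqn{\kappa}
#' is admissible and the formula is evaluated as written), and the constant
#' solution \eqn{C(t) = C_0} when \eqn{\lambda = d} (detected as
#' \eqn{|\Lambda| < 10^{-12}}, where the reparameterization is singular but the
#' model is not).
#'
#' @inheritParams solve_logistic
#' @param d Removal (harvesting) rate (per day), `>= 0`.
#' @return Numeric vector of densities, one per time.
#' @examples
#' solve_logistic_harvest(c(0, 500, 1000), lambda = 0.01, d = 0.002,
#'                        K = 100, C0 = 5)
#' @export
solve_logistic_harvest <- function(times, lambda, d, K, C0) {
  check_admissible("logistic_harvest",
                   list(lambda = lambda, d = d, K = K, C0 = C0))
  check_times(times)
  if (abs(lambda - d) < 1e-12) {
    return(rep_len(C0, length(times)))
  }
  out <- harvest_core_scalar(lambda, d, K, C0, times)
  out[times == 0] <- C0
  out
}

# scalar-parameter harvest core (vector times)
harvest_core_scalar <- function(lambda, d, K, C0, t) {
  Lam <- lambda - d
  kap <- K * Lam / lambda
  kap * C0 / (C0 + (kap - C0) * exp(-Lam * t))
}

#' Closed-form solution of the Richards model
#'
#' Evaluates
#' \eqn{C(t) = K C_0 / [C_0^\beta + (K^\beta - C_0^\beta) e^{-\lambda\beta t}]^{1/\beta}}
#' in log space (log-sum-exp on \eqn{\beta}-scaled log terms), which stays
#' stable for small \eqn{\beta} or small \eqn{C_0} where naive powers overflow
#' or underflow. Reduces to the logistic solution at \eqn{\beta = 1}; the von
#' Bertalanffy growth curve is the special case \eqn{\beta = 1/3}.
#'
#' @inheritParams solve_logistic
#' @param beta Richards exponent (dimensionless), `> 0`.
#' @return Numeric vector of densities, one per time.
#' @examples
#' solve_richards(c(0, 500, 3000), lambda = 0.0055, beta = 0.341,
#'                K = 81.73, C0 = 0.092)
#' @export
solve_richards <- function(times, lambda, beta, K, C0) {
  check_admissible("richards",
                   list(lambda = lambda, beta = beta, K = K, C0 = C0))
  check_times(times)
  out <- richards_core(lambda, beta, K, C0, times)
  out[times == 0] <- C0
  out
}

check_times <- function(times) {
  if (!is.numeric(times) || anyNA(times) || any(!is.finite(times)) ||
      any(times < 0)) {
    rlang::abort("`times` must be finite, non-negative numbers")
  }
  invisible(TRUE)
}

## ---- generic evaluation --------------------------------------------------

# Full parameter list for a model: free values (named list/vector) merged with
# the spec's fixed values. Errors if a free label is missing.
full_params <- function(model, params) {
  params <- as.list(params)
  p <- c(params[model$free_params], model$fixed)
  missing <- model$free_params[!model$free_params %in% names(params)]
  if (length(missing)) {
    rlang::abort(sprintf("missing free parameter(s): %s",
                         paste0("'", missing, "'", collapse = ", ")))
  }
  p[model$param_names]
}

# Trajectory at scalar/vector times for one parameter set (scalars).
model_solution <- function(model, params, times) {
  p <- full_params(model, params)
  switch(model$name,
    logistic = solve_logistic(times, p$lambda, p$K, p$C0),
    logistic_harvest = solve_logistic_harvest(times, p$lambda, p$d, p$K, p$C0),
    richards = solve_richards(times, p$lambda, p$beta, p$K, p$C0)
  )
}

# Vectorized over parameter vectors at a single scalar time; used by the dense
# grid and rejection-sampling paths. `p` is a named list of equal-length
# vectors covering all model parameters.
model_solution_at <- function(model, p, t) {
  switch(model$name,
    logistic = {
      out <- logistic_core(p$lambda, p$K, p$C0, t)
      if (t == 0) out[] <- p$C0
      out
    },
    logistic_harvest = {
      Lam <- p$lambda - p$d
      kap <- p$K * Lam / p$lambda
      out <- kap * p$C0 / (p$C0 + (kap - p$C0) * exp(-Lam * t))
      const <- abs(Lam) < 1e-12
      if (any(const)) out[const] <- rep_len(p$C0, length(out))[const]
      if (t == 0) out[] <- p$C0
      out
    },
    richards = {
      out <- richards_core(p$lambda, p$beta, p$K, p$C0, t)
      if (t == 0) out[] <- p$C0
      out
    }
  )
}

#' Model trajectory as a tibble
#'
#' Convenience wrapper returning the mean trajectory of a model at the
#' requested times as a two-column tibble, ready for plotting or joining with
#' observations.
#'
#' @param model A [growth_model()].
#' @param params Named list or vector covering the model's free parameters
#'   (fixed parameters are taken from the spec).
#' @param times Numeric vector of times (days), strictly increasing.
#' @return A tibble with columns `time` and `density`.
#' @examples
#' m <- growth_model("logistic")
#' growth_curve(m, list(lambda = 0.01, K = 100, C0 = 5), times = 0:10 * 100)
#' @export
growth_curve <- function(model, params, times) {
  stopifnot(inherits(model, "growth_model"))
  if (is.unsorted(times, strictly = TRUE)) {
    rlang::abort("`times` must be strictly increasing")
  }
  tibble::tibble(time = as.numeric(times),
                 density = model_solution(model, params, times))
}
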