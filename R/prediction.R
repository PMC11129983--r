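new_prediction_envelope <- function(tbl, source, n_curves, threshold = NA_real_) {
  structure(tbl, source = source, n_curves = n_curves, threshold = threshold,
            class = c("prediction_envelope", class(tbl)))
}

#' @export
print.prediction_envelope <- function(x, ...) {
  cat("<prediction_envelope> (", attr(x, "source"), ", ",
      attr(x, "n_curves"), " curves, ", nrow(x), " times)\n", sep = "")
  NextMethod()
}

#' Curvewise prediction envelope from a set of parameter vectors
#'
#' Solves the model mean trajectory for every parameter vector in the set and
#' returns the pointwise minimum and maximum over the family of curves — the
#' curvewise prediction envelope of the parameter confidence set. Large sets
#' are processed in chunks with running min/max, so memory stays bounded.
#'
#' @param params A data frame with one row per parameter vector, columns named
#'   by the model's free parameters (extra columns ignored).
#' @param model A [growth_model()].
#' @param times Prediction time grid (defaults elsewhere to 201 uniform
#'   points over the observation window).
#' @param mle_params Optional named parameter vector whose trajectory is
#'   recorded in the `mle` column (the MLE curve lies inside every
#'   likelihood-filtered envelope by construction).
#' @param source Label recorded on the result.
#' @return A `prediction_envelope`: tibble with columns `time`, `lower`,
#'   `mle` (NA when `mle_params` is absent), `upper`.
#' @examples
#' m <- growth_model("logistic", fixed = list(C0 = 5))
#' ps <- tibble::tibble(lambda = c(0.008, 0.012), K = c(90, 110))
#' envelope_from_parameters(ps, m, times = seq(0, 1000, 100))
#' @export
envelope_from_parameters <- function(params, model, times,
                                     mle_params = NULL,
                                     source = "parameter_set") {
  stopifnot(inherits(model, "growth_model"))
  params <- as.data.frame(params)
  need <- setdiff(model$free_params, names(params))
  if (length(need)) {
    rlang::abort(sprintf("`params` is missing column(s): %s",
                         paste0("'", need, "'", collapse = ", ")))
  }
  if (!nrow(params)) rlang::abort("`params` is empty")
  times <- as.numeric(times)
  lower <- rep(Inf, length(times))
  upper <- rep(-Inf, length(times))
  chunk <- 20000L
  for (start in seq(1L, nrow(params), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(params))
    p <- c(as.list(params[rows, model$free_params, drop = FALSE]),
           model$fixed)
    for (i in seq_along(times)) {
      mu <- model_solution_at(model, p, times[i])
      lower[i] <- min(lower[i], mu)
      upper[i] <- max(upper[i], mu)
    }
  }
  mle_curve <- if (!is.null(mle_params)) {
    model_solution(model, mle_params, times)
  } else rep(NA_real_, length(times))
  new_prediction_envelope(
    tibble::tibble(time = times, lower = lower, mle = mle_curve,
                   upper = upper),
    source = source, n_curves = nrow(params)
  )
}

#' Full-likelihood prediction envelope by grid filtering
#'
#' Retains every node of an evaluated [fit_mle_grid()] whose normalized
#' loglikelihood satisfies \eqn{\hat\ell \ge \ell^*} (interior and boundary
#' of the confidence set alike) and propagates the retained parameter vectors
#' to a curvewise envelope. This is the gold-standard construction against
#' which profile-wise envelopes are compared.
#'
#' @param grid A `likelihood_grid`.
#' @param threshold Likelihood-ratio threshold \eqn{\ell^*}, e.g.
#'   `chisq_threshold(3)` for a three-parameter model at the 95% level.
#' @param times Prediction time grid; default 201 uniform points spanning the
#'   observation window.
#' @return A `prediction_envelope` (source `"full_grid"`); the number of
#'   retained nodes is recorded in the `n_curves` attribute.
#' @export
envelope_from_grid <- function(grid, threshold, times = NULL) {
  stopifnot(inherits(grid, "likelihood_grid"))
  if (is.null(times)) times <- default_time_grid(grid$data)
  keep <- which(grid$values >= threshold)
  if (!length(keep)) {
    rlang::abort("no grid node passes the threshold (the MLE node always should)")
  }
  sub <- arrayInd(keep, dim(grid$values))
  params <- purrr::imap(grid$axes, function(ax, nm) {
    ax[sub[, match(nm, names(grid$axes))]]
  })
  env <- envelope_from_parameters(tibble::as_tibble(params), grid$model,
                                  times, mle_params = grid$mle,
                                  source = "full_grid")
  attr(env, "threshold") <- threshold
  env
}

#' Full-likelihood prediction envelope by rejection sampling
#'
#' Draws parameter vectors uniformly over the bounds box, keeps draws whose
#' normalized loglikelihood clears the threshold, and propagates the accepted
#' vectors to a curvewise envelope. Useful when the parameter space is too
#' large to grid densely; the normalizing supremum is taken from `fit`
#' (computed by [fit_mle()] when omitted).
#'
#' @inheritParams fit_mle
#' @param threshold Likelihood-ratio threshold \eqn{\ell^*} (negative).
#' @param n_accept Number of accepted draws required (default 5000).
#' @param times Prediction time grid; default 201 uniform points over the
#'   observation window.
#' @param fit Optional `growth_fit` supplying the MLE.
#' @param max_draws Cap on total proposals; if the running acceptance rate
#'   makes `n_accept` unreachable within the cap, an error advises tighter
#'   bounds.
#' @return A `prediction_envelope` (source `"full_rejection"`) with the
#'   accepted draws in the `accepted` attribute.
#' @export
envelope_by_rejection <- function(data, model, bounds, sigma = NULL,
                                  threshold, n_accept = 5000, seed = NULL,
                                  times = NULL, fit = NULL,
                                  max_draws = 2e6) {
  stopifnot(inherits(model, "growth_model"))
  data <- validate_dataset(data)
  if (threshold >= 0) rlang::abort("`threshold` must be negative")
  bounds <- check_bounds(bounds, model$free_params)
  sigma <- resolve_sigma(sigma)
  if (is.null(fit)) fit <- fit_mle(data, model, bounds, sigma = sigma, seed = seed)
  if (is.null(times)) times <- default_time_grid(data)
  lower <- purrr::map_dbl(bounds, 1)
  upper <- purrr::map_dbl(bounds, 2)
  if (!is.null(seed)) set.seed(seed)
  obs <- data$observation
  tt <- data$time
  const <- -length(obs) * (log(sigma) + 0.5 * log(2 * pi))
  accepted <- NULL
  drawn <- 0L
  batch <- 20000L
  while (is.null(accepted) || nrow(accepted) < n_accept) {
    if (drawn >= max_draws) {
      rlang::abort(sprintf(
        "acceptance rate too low (%d accepted from %d draws); tighten the bounds",
        if (is.null(accepted)) 0L else nrow(accepted), drawn))
    }
    u <- matrix(stats::runif(batch * length(bounds)), batch)
    p <- purrr::imap(bounds, function(b, nm) {
      b[1] + (b[2] - b[1]) * u[, match(nm, names(bounds))]
    })
    drawn <- drawn + batch
    ssr <- numeric(batch)
    pf <- c(p, model$fixed)
    for (i in seq_along(tt)) {
      mu <- model_solution_at(model, pf, tt[i])
      ssr <- ssr + (obs[i] - mu)^2
    }
    ll <- const - ssr / (2 * sigma^2) - fit$loglik
    keep <- which(is.finite(ll) & ll >= threshold)
    if (length(keep)) {
      block <- tibble::as_tibble(purrr::map(p, function(v) v[keep]))
      block$loglik <- ll[keep]
      accepted <- dplyr::bind_rows(accepted, block)
    }
  }
  accepted <- accepted[seq_len(n_accept), ]
  env <- envelope_from_parameters(accepted, model, times,
                                  mle_params = fit$par[model$free_params],
                                  source = "full_rejection")
  attr(env, "threshold") <- threshold
  attr(env, "accepted") <- accepted
  attr(env, "n_draws") <- drawn
  env
}

#' Profile-wise prediction envelope
#'
#' Propagates a bivariate profile likelihood to a curvewise envelope. Two
#' propagation strategies are exposed, matching the two ways a profile
#' confidence set can be represented: `boundary_only = FALSE` (default)
#' retains every evaluated mesh node with \eqn{\hat\ell_p \ge \ell^*}
#' (interior and boundary), each paired with its optimal nuisance values
#' \eqn{\omega^*(\psi)}; `boundary_only = TRUE` expects a
#' [sample_contour()] result and propagates only the sampled threshold
#' contour, which is cheaper and accurate when the envelope extremes are
#' attained on the set boundary.
#'
#' @param x A `profile_surface`, or (with `boundary_only = TRUE`) a
#'   `contour_sample`.
#' @param model A [growth_model()].
#' @param threshold Threshold \eqn{\ell^*}; defaults to the surface's stored
#'   bivariate threshold. Ignored for contour samples.
#' @param times Prediction time grid.
#' @param boundary_only Propagate only contour points (see above).
#' @return A `prediction_envelope` (source `"profile_pair"`).
#' @export
envelope_from_profile <- function(x, model, threshold = NULL, times,
                                  boundary_only = FALSE) {
  if (boundary_only || inherits(x, "contour_sample")) {
    if (!inherits(x, "contour_sample")) {
      rlang::abort("`boundary_only = TRUE` expects a `contour_sample`")
    }
    params <- as.data.frame(x)[, setdiff(names(x), c("value", "on_bound")),
                               drop = FALSE]
    env <- envelope_from_parameters(params, model, times,
                                    source = "profile_pair")
    attr(env, "threshold") <- attr(x, "level")
    return(env)
  }
  stopifnot(inherits(x, "profile_surface"))
  if (is.null(threshold)) threshold <- x$threshold
  keep <- x$profile[is.finite(x$profile$value) &
                      x$profile$value >= threshold, , drop = FALSE]
  if (!nrow(keep)) rlang::abort("no profile node passes the threshold")
  env <- envelope_from_parameters(keep, model, times,
                                  mle_params = x$mle[model$free_params],
                                  source = "profile_pair")
  attr(env, "threshold") <- threshold
  env
}

#' Union of prediction envelopes
#'
#' Pointwise union: lower bound is the minimum of the component lower bounds,
#' upper bound the maximum of the component uppers. The union of the
#' profile-wise envelopes over all parameter pairs is the package's
#' approximation to the full-likelihood envelope. All components must share
#' the same time grid (no resampling is performed).
#'
#' @param ... `prediction_envelope` objects, or a single list of them.
#' @return A `prediction_envelope` with source `"union"`.
#' @export
envelope_union <- function(...) {
  envs <- list(...)
  if (length(envs) == 1 && !inherits(envs[[1]], "prediction_envelope")) {
    envs <- envs[[1]]
  }
  if (!length(envs)) rlang::abort("no envelopes supplied")
  tgrid <- envs[[1]]$time
  for (e in envs) {
    if (!inherits(e, "prediction_envelope")) {
      rlang::abort("all arguments must be prediction envelopes")
    }
    if (length(e$time) != length(tgrid) || any(e$time != tgrid)) {
      rlang::abort("envelopes have mismatched time grids; no resampling is performed")
    }
  }
  lower <- do.call(pmin, purrr::map(envs, "lower"))
  upper <- do.call(pmax, purrr::map(envs, "upper"))
  mle <- purrr::detect(purrr::map(envs, "mle"),
                       function(m) !all(is.na(m))) %||% rep(NA_real_, length(tgrid))
  new_prediction_envelope(
    tibble::tibble(time = tgrid, lower = lower, mle = mle, upper = upper),
    source = "union", n_curves = sum(purrr::map_dbl(envs, attr, "n_curves"))
  )
}

default_time_grid <- function(data, n = 201) {
  seq(0, max(data$time), length.out = n)
}
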