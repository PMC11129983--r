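#' Gaussian loglikelihood of a growth-model trajectory
#'
#' Computes \eqn{\ell(\theta) = \sum_i \log \phi(C^o(t_i); C(t_i), \sigma^2)}
#' for observations `data` under the additive Gaussian noise model with
#' constant standard deviation, where \eqn{C(t)} is the closed-form solution
#' of `model` at `params`.
#'
#' @param data A data frame with columns `time` and `observation` (see
#'   [read_growth_data()] / [simulate_growth_data()]).
#' @param model A [growth_model()].
#' @param params Named list/vector of the model's free parameters. If `sigma`
#'   is `NULL` it must also contain a `sigma` entry (noise sd estimated as a
#'   parameter).
#' @param sigma Known noise standard deviation (`> 0`), or `NULL` when `sigma`
#'   is part of `params`.
#' @return A single numeric value; `-Inf` (with a warning) if the model
#'   trajectory is non-finite at the supplied parameters.
#' @examples
#' m <- growth_model("logistic_harvest", fixed = list(C0 = 5))
#' d <- fixture_case1()
#' log_likelihood(d, m, list(lambda = 0.01, d = 0.002, K = 100), sigma = 5)
#' @export
log_likelihood <- function(data, model, params, sigma = NULL) {
  data <- validate_dataset(data)
  sigma <- resolve_sigma(sigma, params)
  mu <- tryCatch(model_solution(model, params, data$time),
                 profilewise_admissibility_error = function(e) NULL)
  if (is.null(mu) || any(!is.finite(mu))) {
    rlang::warn("non-finite model output; returning -Inf loglikelihood")
    return(-Inf)
  }
  sum(stats::dnorm(data$observation, mean = mu, sd = sigma, log = TRUE))
}

resolve_sigma <- function(sigma, params = NULL) {
  if (is.null(sigma)) sigma <- as.list(params)[["sigma"]]
  if (is.null(sigma)) {
    rlang::abort("`sigma` must be supplied (known value) or present in `params`")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    rlang::abort("`sigma` must be a single positive number")
  }
  sigma
}

validate_dataset <- function(data) {
  if (!is.data.frame(data)) rlang::abort("`data` must be a data frame")
  for (col in c("time", "observation")) {
    if (!col %in% names(data)) {
      rlang::abort(sprintf("`data` is missing the '%s' column", col))
    }
  }
  if (nrow(data) == 0) rlang::abort("`data` has no rows")
  if (is.unsorted(data$time, strictly = TRUE)) {
    rlang::abort("`data$time` must be strictly increasing")
  }
  data
}

#' Normalize loglikelihood values
#'
#' Subtracts the supremum so the maximum normalized value is exactly 0 and the
#' ordering of values is preserved. `-Inf` entries (inadmissible parameters)
#' stay `-Inf`.
#'
#' @param x Numeric vector (or array) of loglikelihood values; at least one
#'   must be finite.
#' @return `x - max(x)`, same shape as `x`.
#' @examples
#' normalize_loglik(c(-3, -1, -7))
#' @export
normalize_loglik <- function(x) {
  m <- suppressWarnings(max(x, na.rm = TRUE))
  if (!is.finite(m)) {
    rlang::abort("no admissible parameter found: all loglikelihood values are -Inf")
  }
  x - m
}

## ---- parameter boxes and bounds -----------------------------------------

#' Define a parameter box
#'
#' A rectangular region of parameter space with a regular grid resolution per
#' axis, used by [fit_mle_grid()]. Axes are supplied as `name = c(lower,
#' upper)` pairs; grid nodes are placed at the endpoints inclusive with
#' uniform spacing, so the printed bounds themselves are probed.
#'
#' @param ... One `name = c(lower, upper)` pair per free parameter.
#' @param resolution Number of grid points per axis (scalar, recycled, or a
#'   named vector). The default of 101 keeps a three-parameter grid around a
#'   million nodes; a 500-per-axis grid is supported but takes minutes.
#' @return An object of class `parameter_box`.
#' @examples
#' parameter_box(lambda = c(1e-4, 0.05), d = c(0, 0.01), K = c(50, 200),
#'               resolution = 101)
#' @export
parameter_box <- function(..., resolution = 101) {
  bounds <- list(...)
  if (!length(bounds) || is.null(names(bounds)) || any(names(bounds) == "")) {
    rlang::abort("axes must be supplied as `name = c(lower, upper)`")
  }
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (!is.numeric(b) || length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2]) {
      rlang::abort(sprintf("axis '%s' must be c(lower, upper) with lower < upper", nm))
    }
  }
  if (is.null(names(resolution))) {
    resolution <- rep_len(as.integer(resolution), length(bounds))
    names(resolution) <- names(bounds)
  } else {
    resolution <- as.integer(resolution[names(bounds)])
  }
  if (any(is.na(resolution)) || any(resolution < 2)) {
    rlang::abort("`resolution` must be >= 2 for every axis")
  }
  structure(list(bounds = bounds, resolution = resolution),
            class = "parameter_box")
}

box_axes <- function(box) {
  purrr::imap(box$bounds,
              function(b, nm) seq(b[1], b[2], length.out = box$resolution[[nm]]))
}

check_bounds <- function(bounds, free_params) {
  if (!setequal(names(bounds), free_params)) {
    rlang::abort(sprintf(
      "bounds must cover exactly the free parameters (%s); got %s",
      paste(free_params, collapse = ", "), paste(names(bounds), collapse = ", ")
    ))
  }
  bounds[free_params]
}

## ---- bound transforms ----------------------------------------------------
# Finite box bounds are handled by a logit transform so Nelder-Mead works on
# an unconstrained scale; back-transformed values are snapped onto a bound
# when within 1e-8 of the axis span, so optima pushed to a bound respect it
# exactly.

box_to_z <- function(p, lower, upper) {
  u <- (p - lower) / (upper - lower)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  stats::qlogis(u)
}

z_to_box <- function(z, lower, upper) {
  p <- lower + (upper - lower) * stats::plogis(z)
  span <- upper - lower
  snap_lo <- p - lower < 1e-8 * span
  snap_hi <- upper - p < 1e-8 * span
  p[snap_lo] <- lower[snap_lo]
  p[snap_hi] <- upper[snap_hi]
  p
}

## ---- grid MLE ------------------------------------------------------------

#' Maximum likelihood estimation by dense grid evaluation
#'
#' Evaluates the Gaussian loglikelihood on the full tensor-product grid of a
#' [parameter_box()] (in memory-bounded chunks), normalizes so the grid
#' maximum is 0, and reports the arg-max node. Ties at the maximum are broken
#' by the first node in lexicographic axis order and reported via a message.
#'
#' @inheritParams log_likelihood
#' @param box A [parameter_box()] over the model's free parameters.
#' @param chunk_size Number of grid nodes evaluated per chunk.
#' @return An object of class `likelihood_grid`: normalized values (`values`
#'   array, max exactly 0), axes, the MLE node as a named vector (`mle`), its
#'   array index (`mle_index`), and the unnormalized supremum
#'   (`loglik_max_raw`).
#' @examples
#' m <- growth_model("logistic_harvest", fixed = list(C0 = 5))
#' box <- parameter_box(lambda = c(1e-4, 0.05), d = c(0, 0.01),
#'                      K = c(50, 200), resolution = 21)
#' g <- fit_mle_grid(fixture_case1(), m, box, sigma = 5)
#' g$mle
#' @export
fit_mle_grid <- function(data, model, box, sigma = NULL, chunk_size = 200000L) {
  stopifnot(inherits(model, "growth_model"), inherits(box, "parameter_box"))
  data <- validate_dataset(data)
  free <- model$free_params
  axes_names <- names(box$bounds)
  if (!setequal(axes_names, free)) {
    rlang::abort(sprintf("box axes (%s) must match the model's free parameters (%s)",
                         paste(axes_names, collapse = ", "),
                         paste(free, collapse = ", ")))
  }
  est_sigma <- is.null(sigma) && "sigma" %in% axes_names
  if (!est_sigma) sigma <- resolve_sigma(sigma)
  axes <- box_axes(box)
  dims <- lengths(axes)
  total <- prod(dims)
  values <- numeric(total)
  obs <- data$observation
  tt <- data$time
  const <- -length(obs) * 0.5 * log(2 * pi)

  for (start in seq(1L, total, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, total)
    sub <- arrayInd(idx, dims)
    p <- purrr::imap(axes, function(ax, nm) ax[sub[, match(nm, names(axes))]])
    pfull <- c(p, model$fixed)
    sig <- if (est_sigma) p$sigma else sigma
    admis <- admissible_mask(model, pfull)
    if (est_sigma) admis <- admis & sig > 0
    ll <- rep(const, length(idx))
    ssr <- numeric(length(idx))
    ok <- TRUE
    for (i in seq_along(tt)) {
      mu <- model_solution_at(model, lapply(pfull, masked, admis), tt[i])
      ssr <- ssr + (obs[i] - mu)^2
    }
    ll <- ll - length(obs) * log(sig) - ssr / (2 * sig^2)
    ll[!admis | !is.finite(ll)] <- -Inf
    values[idx] <- ll
  }

  if (!any(is.finite(values))) {
    rlang::abort("no admissible node in the parameter box")
  }
  sup <- max(values)
  values <- values - sup
  top <- which(values == 0)
  if (length(top) > 1) {
    message(sprintf("%d grid nodes tied at the maximum; reporting the first in lexicographic axis order", length(top)))
    subs <- arrayInd(top, dims)
    ord <- do.call(order, as.data.frame(subs))
    top <- top[ord[1]]
  }
  mle_index <- arrayInd(top, dims)[1, ]
  mle <- purrr::map2_dbl(axes, mle_index, function(ax, i) ax[i])
  names(mle) <- names(axes)

  structure(
    list(
      axes = axes,
      values = array(values, dim = dims),
      mle = mle,
      mle_index = mle_index,
      loglik_max_raw = sup,
      model = model,
      data = data,
      sigma = if (est_sigma) NULL else sigma
    ),
    class = "likelihood_grid"
  )
}

# element-wise admissibility over vectors of parameters (no error; mask)
admissible_mask <- function(model, p) {
  ok <- rep(TRUE, max(lengths(p)))
  pos <- function(v) ok & rep_len(v > 0, length(ok))
  switch(model$name,
    logistic = pos(p$K) & pos(p$C0),
    logistic_harvest = pos(p$lambda) & pos(p$K) & pos(p$C0) &
      rep_len(p$d >= 0, length(ok)),
    richards = pos(p$lambda) & pos(p$beta) & pos(p$K) & pos(p$C0)
  )
}

# replace inadmissible entries by a safe dummy so vectorized math stays finite
masked <- function(v, admis) {
  if (length(v) == 1) return(v)
  v[!admis] <- 1
  v
}

#' @export
print.likelihood_grid <- function(x, ...) {
  cat("<likelihood_grid: ", x$model$name, ">\n", sep = "")
  cat("  axes: ", paste(sprintf("%s[%d]", names(x$axes), lengths(x$axes)),
                        collapse = " x "), "\n")
  cat("  MLE node:", paste(names(x$mle), signif(x$mle, 4), sep = " = ",
                           collapse = ", "), "\n")
  cat("  sup loglik:", format(x$loglik_max_raw), "\n")
  invisible(x)
}

#' Grid values as a tibble
#'
#' One row per grid node with the normalized loglikelihood in `loglik`; the
#' first axis varies fastest, matching the column-major layout of the values
#' array. Large grids expand to long tibbles.
#'
#' @param x A `likelihood_grid`.
#' @param ... Unused.
#' @importFrom tibble as_tibble
#' @method as_tibble likelihood_grid
#' @export
as_tibble.likelihood_grid <- function(x, ...) {
  grid <- tidyr_expand_grid(x$axes)
  grid$loglik <- as.vector(x$values)
  grid
}

# expand.grid with first axis varying fastest, as a tibble (matches the
# column-major layout of the values array)
tidyr_expand_grid <- function(axes) {
  tibble::as_tibble(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
}

## ---- optimizer MLE -------------------------------------------------------

# Iterated Nelder-Mead on the logit-transformed box: restart from the current
# best point (re-inflating the simplex) until the improvement between rounds
# drops below `round_tol`. Restarts are essential on the flat ridges of
# non-identifiable likelihoods, where a single simplex collapses early.
nm_maximize <- function(fn, z0, reltol = 1e-10, max_rounds = 12,
                        round_tol = 1e-8, maxit = 2000) {
  if (length(z0) == 1) {
    # 1-d: golden-section/Brent on a wide transformed interval
    opt <- stats::optimize(function(z) fn(z), interval = c(-40, 40),
                           maximum = TRUE, tol = 1e-12)
    return(list(z = opt$maximum, value = opt$objective, convergence = 0L))
  }
  best <- -Inf
  z <- z0
  conv <- 1L
  for (r in seq_len(max_rounds)) {
    f <- stats::optim(z, function(zz) -fn(zz), method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
    z <- f$par
    conv <- f$convergence
    if (-f$value - best < round_tol) {
      best <- max(best, -f$value)
      break
    }
    best <- -f$value
  }
  list(z = z, value = best, convergence = conv)
}

#' Maximum likelihood estimation by bounded Nelder-Mead optimization
#'
#' Maximizes the Gaussian loglikelihood over the model's free parameters
#' within finite box bounds, using Nelder-Mead on a logit-transformed scale
#' (so iterates always respect the bounds) with iterated restarts and multiple
#' start points: the box centre plus Latin-hypercube draws, plus any
#' user-supplied starts. The best local optimum over all starts is returned.
#'
#' @inheritParams log_likelihood
#' @param bounds Named list of `c(lower, upper)` for every free parameter
#'   (include a `sigma` axis to estimate the noise sd).
#' @param starts Number of start points (>= 1). The first is the box centre;
#'   the rest are Latin-hypercube draws.
#' @param start_values Optional list/data frame of additional start points
#'   (named values in the original scale).
#' @param seed Optional integer seed for the Latin-hypercube starts.
#' @param reltol,max_rounds Nelder-Mead relative tolerance and maximum number
#'   of restart rounds per start.
#' @return An object of class `growth_fit` with named estimates (`par`),
#'   the maximized loglikelihood (`loglik`), convergence status, and the
#'   inputs needed by downstream profile and prediction functions.
#' @seealso [tidy.growth_fit()], [glance.growth_fit()], [predict.growth_fit()]
#' @examples
#' m <- growth_model("logistic_harvest", fixed = list(C0 = 5))
#' fit <- fit_mle(fixture_case1(), m,
#'                bounds = list(lambda = c(1e-4, 0.05), d = c(0, 0.01),
#'                              K = c(50, 200)),
#'                sigma = 5, seed = 1)
#' tidy(fit)
#' @export
fit_mle <- function(data, model, bounds, sigma = NULL, starts = 10,
                    start_values = NULL, seed = NULL, reltol = 1e-10,
                    max_rounds = 12) {
  stopifnot(inherits(model, "growth_model"))
  data <- validate_dataset(data)
  est_sigma <- is.null(sigma) && "sigma" %in% names(bounds)
  free <- model$free_params
  axes <- if (est_sigma) c(free, "sigma") else free
  bounds <- check_bounds(bounds, axes)
  if (!est_sigma) sigma <- resolve_sigma(sigma)
  lower <- purrr::map_dbl(bounds, 1)
  upper <- purrr::map_dbl(bounds, 2)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    rlang::abort("bounds must be finite")
  }
  if (starts < 1) rlang::abort("`starts` must be >= 1")

  obj <- function(z) {
    p <- as.list(z_to_box(z, lower, upper))
    names(p) <- axes
    sig <- if (est_sigma) p$sigma else sigma
    mu <- tryCatch(model_solution(model, p, data$time),
                   profilewise_admissibility_error = function(e) NULL,
                   error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu)) || sig <= 0) return(-1e12)
    sum(stats::dnorm(data$observation, mu, sig, log = TRUE))
  }

  st <- matrix((lower + upper) / 2, nrow = 1)
  if (starts > 1) {
    if (!is.null(seed)) set.seed(seed)
    u <- lhs::randomLHS(starts - 1L, length(axes))
    st <- rbind(st, sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+"))
  }
  if (!is.null(start_values)) {
    sv <- as.data.frame(start_values)[, axes, drop = FALSE]
    st <- rbind(st, as.matrix(sv))
  }

  best <- NULL
  for (s in seq_len(nrow(st))) {
    res <- tryCatch(nm_maximize(obj, box_to_z(st[s, ], lower, upper),
                                reltol = reltol, max_rounds = max_rounds),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value > best$value)) best <- res
  }
  if (is.null(best) || best$value <= -1e11) {
    rlang::abort("optimization failed from every start point")
  }
  par <- z_to_box(best$z, lower, upper)
  names(par) <- axes

  structure(
    list(
      par = par,
      loglik = best$value,
      convergence = best$convergence,
      model = model,
      data = data,
      sigma = if (est_sigma) unname(par["sigma"]) else sigma,
      sigma_estimated = est_sigma,
      bounds = bounds,
      n_starts = nrow(st)
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit: ", x$model$name, ">\n", sep = "")
  cat("  estimates:", paste(names(x$par), signif(x$par, 4), sep = " = ",
                            collapse = ", "), "\n")
  cat("  loglik:", format(x$loglik), " (", x$n_starts, "starts )\n")
  invisible(x)
}

#' Predicted mean trajectory of a fitted model
#'
#' @param object A `growth_fit`.
#' @param times Times at which to evaluate the fitted trajectory; defaults to
#'   the observation times.
#' @param ... Unused.
#' @return A tibble with columns `time` and `density`.
#' @export
predict.growth_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time
  growth_curve(object$model,
               object$par[object$model$free_params], times)
}
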