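#' Asymptotic likelihood-ratio threshold
#'
#' Returns \eqn{-\Delta_{q,n}/2}, minus one half the `level` quantile of the
#' chi-squared distribution with `df` degrees of freedom. Normalized
#' (profile) loglikelihood values at or above this threshold define the
#' asymptotic `level` confidence set: `df = 1` for univariate profiles,
#' `df = 2` for bivariate profiles, and `df` equal to the number of free
#' parameters for full-likelihood sets.
#'
#' @param df Degrees of freedom (positive integer).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A single negative number (full precision; e.g. -1.92, -3.00,
#'   -3.91, -4.74 at two decimals for `df = 1..4` at the 95% level).
#' @examples
#' chisq_threshold(1)   # -1.92
#' chisq_threshold(3)   # -3.91
#' @export
chisq_threshold <- function(df, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    rlang::abort("`level` must be a single number in (0, 1)")
  }
  if (!is.numeric(df) || length(df) != 1 || df < 1 || df != round(df)) {
    rlang::abort("`df` must be a positive integer")
  }
  -stats::qchisq(level, df) / 2
}

## ---- constructors --------------------------------------------------------

new_profile_curve <- function(interest, profile, mle, threshold, source) {
  structure(
    list(interest = interest, profile = profile, mle = mle,
         threshold = threshold, source = source),
    class = "profile_curve"
  )
}

new_profile_surface <- function(interest, profile, psi_grids, mle, threshold,
                                source) {
  structure(
    list(interest = interest, profile = profile, psi_grids = psi_grids,
         mle = mle, threshold = threshold, source = source),
    class = "profile_surface"
  )
}

#' @export
print.profile_curve <- function(x, ...) {
  cat("<profile_curve: ", x$interest, "> (", x$source, ", ",
      nrow(x$profile), " nodes)\n", sep = "")
  ci <- ci_from_profile(x)
  cat(sprintf("  95%% CI [%g, %g]%s%s\n", ci$lower, ci$upper,
              if (ci$truncated_lower) " (truncated at lower bound)" else "",
              if (ci$truncated_upper) " (truncated at upper bound)" else ""))
  invisible(x)
}

#' @export
print.profile_surface <- function(x, ...) {
  cat("<profile_surface: ", paste(x$interest, collapse = " x "), "> (",
      x$source, ", ", nrow(x$profile), " nodes)\n", sep = "")
  invisible(x)
}

#' @rdname tidy.growth_fit
#' @method tidy profile_curve
#' @export
tidy.profile_curve <- function(x, ...) x$profile

#' @rdname tidy.growth_fit
#' @method tidy profile_surface
#' @export
tidy.profile_surface <- function(x, ...) x$profile

## ---- profiling an evaluated grid ----------------------------------------

#' Profile likelihood from an evaluated grid
#'
#' Maximizes a normalized [fit_mle_grid()] surface over the nuisance axes at
#' every node of the interest axis (one label) or axes (a pair), recording the
#' optimal nuisance values \eqn{\omega^*(\psi)} at each interest node. This is
#' the pure grid-search construction: no further optimization is performed.
#'
#' @param grid A `likelihood_grid` from [fit_mle_grid()].
#' @param interest One or two axis names to profile.
#' @param level Confidence level used for the default threshold
#'   (`chisq_threshold(length(interest), level)`).
#' @return A `profile_curve` (one label) or `profile_surface` (two labels).
#'   The `profile` tibble has one row per interest node with the normalized
#'   profile value (`value`, maximum 0) and one column per nuisance parameter
#'   holding \eqn{\omega^*(\psi)}.
#' @examples
#' m <- growth_model("logistic_harvest", fixed = list(C0 = 5))
#' box <- parameter_box(lambda = c(1e-4, 0.05), d = c(0, 0.01),
#'                      K = c(50, 200), resolution = 21)
#' g <- fit_mle_grid(fixture_case1(), m, box, sigma = 5)
#' profile_grid(g, "lambda")
#' @export
profile_grid <- function(grid, interest, level = 0.95) {
  stopifnot(inherits(grid, "likelihood_grid"))
  axes <- grid$axes
  if (!all(interest %in% names(axes))) {
    rlang::abort("`interest` must name axes of the grid")
  }
  if (!length(interest) %in% 1:2) {
    rlang::abort("`interest` must contain one or two labels")
  }
  if (length(interest) >= length(axes)) {
    rlang::abort("nothing to profile: `interest` covers every free axis")
  }
  dims <- dim(grid$values)
  int_idx <- match(interest, names(axes))
  nuis_idx <- setdiff(seq_along(axes), int_idx)
  nuis_names <- names(axes)[nuis_idx]

  # put interest axes first, flatten nuisance axes into columns
  perm <- c(int_idx, nuis_idx)
  v <- aperm(grid$values, perm)
  n_int <- prod(dims[int_idx])
  vm <- matrix(v, nrow = n_int)
  arg <- max.col(vm, ties.method = "first")
  prof <- vm[cbind(seq_len(n_int), arg)]
  nuis_sub <- arrayInd(arg, dims[nuis_idx])
  nuis_vals <- purrr::map2(axes[nuis_idx], seq_along(nuis_idx),
                           function(ax, j) ax[nuis_sub[, j]])
  names(nuis_vals) <- nuis_names

  int_grid <- tidyr_expand_grid(axes[int_idx])
  profile <- dplyr::bind_cols(
    int_grid,
    tibble::tibble(value = prof),
    tibble::as_tibble(nuis_vals)
  )
  mle <- grid$mle
  threshold <- chisq_threshold(length(interest), level)
  if (length(interest) == 1) {
    names(profile)[1] <- "psi"
    profile$parameter <- interest
    new_profile_curve(interest, profile, mle, threshold, source = "grid")
  } else {
    new_profile_surface(interest, profile, psi_grids = axes[int_idx], mle,
                        threshold, source = "grid")
  }
}

## ---- profiling by nested optimization -----------------------------------

#' Profile likelihood by nested optimization
#'
#' Constructs a univariate or bivariate profile likelihood across a uniform
#' mesh of the interest parameter(s), maximizing the loglikelihood over the
#' nuisance parameters at each mesh node by bounded Nelder-Mead (Brent for a
#' single nuisance parameter). Nodes are visited sweeping outward from the
#' MLE and each node is warm-started from its neighbour's optimal nuisance
#' values, which keeps the optimizer on the correct branch across banana- or
#' ridge-shaped likelihood surfaces; an additional cold start at the MLE
#' nuisance values protects against drift.
#'
#' @inheritParams fit_mle
#' @param interest One or two free-parameter names.
#' @param n_psi Mesh size per interest axis (default 100).
#' @param psi_grid Optional explicit mesh: a numeric vector (one label) or
#'   named list of two vectors (pair). Defaults to a uniform mesh across the
#'   interest bounds.
#' @param fit Optional `growth_fit` for the same problem; computed by
#'   [fit_mle()] (with `seed`) when omitted.
#' @param level Confidence level for the default threshold.
#' @return A `profile_curve` or `profile_surface`; values are normalized by
#'   the MLE loglikelihood so the profile maximum is 0 (renormalized, with a
#'   message, in the rare case a nuisance optimization improves on the MLE).
#'   Nodes whose nuisance optimization fails carry `value = -Inf` and
#'   `converged = FALSE`.
#' @examples
#' m <- growth_model("logistic_harvest", fixed = list(C0 = 5))
#' b <- list(lambda = c(1e-4, 0.05), d = c(0, 0.01), K = c(50, 200))
#' pr <- profile_likelihood(fixture_case1(), m, "lambda", b, sigma = 5,
#'                          n_psi = 30, seed = 1)
#' ci_from_profile(pr)
#' @export
profile_likelihood <- function(data, model, interest, bounds, sigma = NULL,
                               n_psi = 100, psi_grid = NULL, fit = NULL,
                               seed = NULL, level = 0.95) {
  stopifnot(inherits(model, "growth_model"))
  data <- validate_dataset(data)
  est_sigma <- is.null(sigma) && "sigma" %in% names(bounds)
  free <- if (est_sigma) c(model$free_params, "sigma") else model$free_params
  bounds <- check_bounds(bounds, free)
  if (!all(interest %in% free)) {
    rlang::abort("`interest` must name free parameters")
  }
  if (!length(interest) %in% 1:2) {
    rlang::abort("`interest` must contain one or two labels")
  }
  nuis <- setdiff(free, interest)
  if (!length(nuis)) {
    rlang::abort("nothing to profile: `interest` covers every free parameter")
  }
  if (is.null(fit)) {
    fit <- fit_mle(data, model, bounds, sigma = sigma, seed = seed)
  }
  ll_mle <- fit$loglik
  mle <- fit$par

  if (is.null(psi_grid)) {
    psi_grid <- purrr::map(bounds[interest],
                           function(b) seq(b[1], b[2], length.out = n_psi))
  } else if (!is.list(psi_grid)) {
    psi_grid <- stats::setNames(list(psi_grid), interest)
  }

  lower_n <- purrr::map_dbl(bounds[nuis], 1)
  upper_n <- purrr::map_dbl(bounds[nuis], 2)

  obj_at <- function(psi_vals, omega) {
    p <- as.list(c(psi_vals, omega))
    names(p) <- c(interest, nuis)
    sig <- if (est_sigma) p$sigma else sigma
    mu <- tryCatch(model_solution(model, p, data$time),
                   profilewise_admissibility_error = function(e) NULL,
                   error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu)) || sig <= 0) return(-1e12)
    sum(stats::dnorm(data$observation, mu, sig, log = TRUE))
  }

  optimize_nuis <- function(psi_vals, warm) {
    res1 <- tryCatch(
      nm_maximize(function(z) obj_at(psi_vals, z_to_box(z, lower_n, upper_n)),
                  box_to_z(warm, lower_n, upper_n), max_rounds = 8),
      error = function(e) NULL)
    res2 <- if (!identical(warm, unname(mle[nuis]))) {
      tryCatch(
        nm_maximize(function(z) obj_at(psi_vals, z_to_box(z, lower_n, upper_n)),
                    box_to_z(unname(mle[nuis]), lower_n, upper_n),
                    max_rounds = 8),
        error = function(e) NULL)
    }
    cand <- Filter(Negate(is.null), list(res1, res2))
    if (!length(cand)) return(NULL)
    best <- cand[[which.max(purrr::map_dbl(cand, "value"))]]
    list(omega = z_to_box(best$z, lower_n, upper_n), value = best$value)
  }

  if (length(interest) == 1) {
    psi <- psi_grid[[1]]
    n <- length(psi)
    vals <- rep(-Inf, n)
    omg <- matrix(NA_real_, n, length(nuis), dimnames = list(NULL, nuis))
    ok <- rep(FALSE, n)
    start_idx <- which.min(abs(psi - mle[[interest]]))
    for (dir in list(start_idx:n, rev(seq_len(start_idx)))) {
      warm <- unname(mle[nuis])
      for (j in dir) {
        if (ok[j]) { warm <- omg[j, ]; next }
        res <- optimize_nuis(psi[j], warm)
        if (is.null(res)) next
        vals[j] <- res$value
        omg[j, ] <- res$omega
        ok[j] <- TRUE
        warm <- res$omega
      }
    }
    profile <- dplyr::bind_cols(
      tibble::tibble(psi = psi, value = vals - ll_mle),
      tibble::as_tibble(as.data.frame(omg)),
      tibble::tibble(converged = ok)
    )
    profile$parameter <- interest
    profile <- renormalize_profile(profile)
    return(new_profile_curve(interest, profile, mle,
                             chisq_threshold(1, level), source = "optimize"))
  }

  ## bivariate: sweep nodes by ring distance from the MLE node, warm start
  ## from the best already-computed neighbour
  g1 <- psi_grid[[interest[1]]]
  g2 <- psi_grid[[interest[2]]]
  n1 <- length(g1); n2 <- length(g2)
  i0 <- which.min(abs(g1 - mle[[interest[1]]]))
  j0 <- which.min(abs(g2 - mle[[interest[2]]]))
  nodes <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  ring <- pmax(abs(nodes$i - i0), abs(nodes$j - j0))
  ord <- order(ring, abs(nodes$i - i0) + abs(nodes$j - j0))
  vals <- matrix(-Inf, n1, n2)
  ok <- matrix(FALSE, n1, n2)
  omg <- array(NA_real_, c(n1, n2, length(nuis)))
  for (k in ord) {
    i <- nodes$i[k]; j <- nodes$j[k]
    # best computed 8-neighbour as warm start
    ni <- pmax(1, pmin(n1, i + c(-1, -1, -1, 0, 0, 1, 1, 1)))
    nj <- pmax(1, pmin(n2, j + c(-1, 0, 1, -1, 1, -1, 0, 1)))
    nb <- cbind(ni, nj)[ok[cbind(ni, nj)], , drop = FALSE]
    warm <- if (nrow(nb)) {
      b <- nb[which.max(vals[nb]), ]
      omg[b[1], b[2], ]
    } else unname(mle[nuis])
    res <- optimize_nuis(c(g1[i], g2[j]), warm)
    if (is.null(res)) next
    vals[i, j] <- res$value
    omg[i, j, ] <- res$omega
    ok[i, j] <- TRUE
  }
  int_grid <- tidyr_expand_grid(stats::setNames(list(g1, g2), interest))
  nuis_cols <- purrr::map(seq_along(nuis), function(q) as.vector(omg[, , q]))
  names(nuis_cols) <- nuis
  profile <- dplyr::bind_cols(
    int_grid,
    tibble::tibble(value = as.vector(vals) - ll_mle),
    tibble::as_tibble(nuis_cols),
    tibble::tibble(converged = as.vector(ok))
  )
  profile <- renormalize_profile(profile)
  new_profile_surface(interest, profile,
                      psi_grids = stats::setNames(list(g1, g2), interest),
                      mle, chisq_threshold(2, level), source = "optimize")
}

renormalize_profile <- function(profile) {
  m <- max(profile$value[is.finite(profile$value)])
  if (m > 1e-8) {
    message(sprintf(
      "profile maximum exceeds the MLE loglikelihood by %.3g; renormalizing", m))
    profile$value <- profile$value - m
  }
  profile
}

## ---- confidence intervals ------------------------------------------------

#' Likelihood-ratio confidence interval from a profile curve
#'
#' Extracts the interest-parameter set \eqn{\{\psi : \hat\ell_p(\psi) \ge
#' \ell^*\}} as an interval, with endpoints refined by linear interpolation
#' between the grid points bracketing each threshold crossing. If the set
#' reaches a bound of the profiled mesh the corresponding truncation flag is
#' set: with flat profiles this is the signature of (structural)
#' non-identifiability, where the confidence set is limited by the
#' user-imposed bounds rather than by the curvature of the likelihood.
#'
#' @param curve A `profile_curve`.
#' @param threshold Threshold \eqn{\ell^*}; defaults to the curve's stored
#'   threshold (\eqn{-\Delta_{0.95,1}/2 = -1.92} for univariate profiles).
#' @return A one-row tibble: `parameter`, `lower`, `upper`,
#'   `truncated_lower`, `truncated_upper`.
#' @export
ci_from_profile <- function(curve, threshold = NULL) {
  stopifnot(inherits(curve, "profile_curve"))
  if (is.null(threshold)) threshold <- curve$threshold
  psi <- curve$profile$psi
  v <- curve$profile$value
  above <- is.finite(v) & v >= threshold
  if (!any(above)) {
    rlang::abort("profile is everywhere below the threshold; check normalization")
  }
  i_lo <- which(above)[1]
  i_hi <- rev(which(above))[1]
  interp <- function(i_out, i_in) {
    # linear interpolation of the crossing between an outside and inside node
    psi[i_out] + (threshold - v[i_out]) * (psi[i_in] - psi[i_out]) /
      (v[i_in] - v[i_out])
  }
  trunc_lo <- i_lo == 1
  trunc_hi <- i_hi == length(psi)
  lower <- if (trunc_lo) psi[1] else interp(i_lo - 1, i_lo)
  upper <- if (trunc_hi) psi[length(psi)] else interp(i_hi + 1, i_hi)
  tibble::tibble(parameter = curve$interest, lower = lower, upper = upper,
                 truncated_lower = trunc_lo, truncated_upper = trunc_hi)
}

## ---- contour sampling ----------------------------------------------------

#' Sample points on a profile-likelihood threshold contour
#'
#' Randomly identifies `n_points` parameter vectors on the boundary
#' \eqn{\hat\ell_p(\psi) = \ell^*} of a bivariate profile likelihood, each
#' carrying its optimal nuisance values, for propagation to prediction
#' envelopes. Points are found by casting rays from the MLE at seeded random
#' angles in the (bounds-normalized) interest plane and bisecting the profile
#' value along each ray to within `tol` of `level`. Where a ray exits the
#' parameter bounds before crossing the threshold (an open contour, as for
#' non-identified parameters) the point is placed on the bound and flagged
#' `on_bound = TRUE` rather than dropped.
#'
#' Dispatches on its first argument: a `profile_surface` (profile values
#' interpolated bilinearly from the evaluated mesh; nuisance values taken from
#' the nearest mesh node) or a data frame of observations (profile values
#' computed exactly by nested optimization, warm-started along each ray).
#'
#' @param x A `profile_surface`, or a data frame of observations.
#' @param level Contour level \eqn{\ell^*} (negative), e.g.
#'   `chisq_threshold(2)`.
#' @param n_points Number of boundary points (default 500).
#' @param seed Integer seed making the sampled angles reproducible.
#' @param tol Tolerance on `|profile value - level|` (default 1e-4).
#' @param ... Passed to methods.
#' @return A `contour_sample`: a tibble with one row per point (interest
#'   values, nuisance values, `value`, `on_bound`), with the level and
#'   tolerance as attributes.
#' @export
sample_contour <- function(x, level, n_points = 500, seed = NULL, tol = 1e-4,
                           ...) {
  UseMethod("sample_contour")
}

#' @rdname sample_contour
#' @export
sample_contour.profile_surface <- function(x, level, n_points = 500,
                                           seed = NULL, tol = 1e-4, ...) {
  g1 <- x$psi_grids[[1]]
  g2 <- x$psi_grids[[2]]
  vmat <- matrix(x$profile$value, length(g1), length(g2))
  vmat[!is.finite(vmat)] <- -1e12
  fn <- function(u) {
    pracma::interp2(g2, g1, vmat, pmin(pmax(u[2], g2[1]), g2[length(g2)]),
                    pmin(pmax(u[1], g1[1]), g1[length(g1)]))
  }
  nuis <- setdiff(names(x$profile),
                  c(x$interest, "value", "converged", "parameter"))
  nearest_nuis <- function(u) {
    i <- which.min(abs(g1 - u[1])); j <- which.min(abs(g2 - u[2]))
    row <- x$profile[(j - 1) * length(g1) + i, nuis, drop = FALSE]
    as.numeric(row)
  }
  mle_psi <- c(x$mle[[x$interest[1]]], x$mle[[x$interest[2]]])
  pts <- contour_rays(fn, mle_psi,
                      lower = c(g1[1], g2[1]),
                      upper = c(g1[length(g1)], g2[length(g2)]),
                      level = level, n_points = n_points, seed = seed,
                      tol = tol)
  parts <- list(
    tibble::as_tibble(stats::setNames(as.data.frame(pts[, 1:2, drop = FALSE]),
                                      x$interest))
  )
  if (length(nuis)) {
    nv <- matrix(t(apply(pts[, 1:2, drop = FALSE], 1, nearest_nuis)),
                 ncol = length(nuis), dimnames = list(NULL, nuis))
    parts <- c(parts, list(tibble::as_tibble(as.data.frame(nv))))
  }
  out <- dplyr::bind_cols(
    c(parts,
      list(tibble::tibble(value = pts[, 3], on_bound = as.logical(pts[, 4]))))
  )
  new_contour_sample(out, level, tol, x$interest)
}

#' @rdname sample_contour
#' @param model,interest,bounds,sigma,fit As in [profile_likelihood()].
#' @export
sample_contour.data.frame <- function(x, level, n_points = 500, seed = NULL,
                                      tol = 1e-4, model, interest, bounds,
                                      sigma = NULL, fit = NULL, ...) {
  data <- validate_dataset(x)
  if (length(interest) != 2) {
    rlang::abort("contour sampling needs exactly two interest parameters")
  }
  est_sigma <- is.null(sigma) && "sigma" %in% names(bounds)
  free <- if (est_sigma) c(model$free_params, "sigma") else model$free_params
  bounds <- check_bounds(bounds, free)
  nuis <- setdiff(free, interest)
  if (is.null(fit)) {
    fit <- fit_mle(data, model, bounds, sigma = sigma, seed = seed)
  }
  mle <- fit$par
  lower_n <- purrr::map_dbl(bounds[nuis], 1)
  upper_n <- purrr::map_dbl(bounds[nuis], 2)
  obj_at <- function(psi_vals, omega) {
    p <- as.list(c(psi_vals, omega))
    names(p) <- c(interest, nuis)
    sig <- if (est_sigma) p$sigma else sigma
    mu <- tryCatch(model_solution(model, p, data$time),
                   profilewise_admissibility_error = function(e) NULL,
                   error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu)) || sig <= 0) return(-1e12)
    sum(stats::dnorm(data$observation, mu, sig, log = TRUE))
  }
  warm <- unname(mle[nuis])
  last_omega <- warm
  fn <- if (length(nuis)) {
    function(u) {
      res <- tryCatch(
        nm_maximize(function(z) obj_at(u, z_to_box(z, lower_n, upper_n)),
                    box_to_z(last_omega, lower_n, upper_n), max_rounds = 6),
        error = function(e) NULL)
      if (is.null(res)) return(-Inf)
      last_omega <<- z_to_box(res$z, lower_n, upper_n)
      res$value - fit$loglik
    }
  } else {
    # two free parameters: nothing to profile out, the contour lives on the
    # normalized full loglikelihood
    function(u) obj_at(u, numeric(0)) - fit$loglik
  }
  lower_i <- purrr::map_dbl(bounds[interest], 1)
  upper_i <- purrr::map_dbl(bounds[interest], 2)
  mle_psi <- unname(mle[interest])
  reset <- function() last_omega <<- unname(mle[nuis])
  pts <- contour_rays(fn, mle_psi, lower_i, upper_i, level, n_points, seed,
                      tol, on_new_ray = reset,
                      record_omega = if (length(nuis)) function() last_omega)
  parts <- list(
    tibble::as_tibble(stats::setNames(as.data.frame(pts[, 1:2, drop = FALSE]),
                                      interest))
  )
  if (length(nuis)) {
    omg <- attr(pts, "omega")
    colnames(omg) <- nuis
    parts <- c(parts, list(tibble::as_tibble(as.data.frame(omg))))
  }
  out <- dplyr::bind_cols(
    c(parts,
      list(tibble::tibble(value = pts[, 3], on_bound = as.logical(pts[, 4]))))
  )
  new_contour_sample(out, level, tol, interest)
}

new_contour_sample <- function(tbl, level, tol, interest) {
  structure(tbl, level = level, tol = tol, interest = interest,
            class = c("contour_sample", class(tbl)))
}

# Ray-bisection engine in the bounds-normalized unit square. fn() must return
# the normalized profile value at an interest-space point; level < 0.
contour_rays <- function(fn, mle_psi, lower, upper, level, n_points, seed,
                         tol, on_new_ray = NULL, record_omega = NULL) {
  if (!is.numeric(level) || level >= 0) rlang::abort("`level` must be negative")
  v0 <- fn(mle_psi)
  if (!(v0 > level)) {
    rlang::abort("profile value at the MLE does not exceed `level`")
  }
  if (!is.null(seed)) set.seed(seed)
  angles <- stats::runif(n_points, 0, 2 * pi)
  span <- upper - lower
  u0 <- (mle_psi - lower) / span
  out <- matrix(NA_real_, n_points, 4)
  omg <- NULL
  for (q in seq_len(n_points)) {
    if (!is.null(on_new_ray)) on_new_ray()
    dir <- c(cos(angles[q]), sin(angles[q]))
    # distance to the unit-box boundary along dir
    tmax <- min(purrr::map_dbl(1:2, function(k) {
      if (dir[k] > 0) (1 - u0[k]) / dir[k]
      else if (dir[k] < 0) -u0[k] / dir[k]
      else Inf
    }))
    at <- function(t) lower + (u0 + t * dir) * span
    v_end <- fn(at(tmax))
    if (v_end >= level) {
      # open contour in this direction: point sits on the bound
      psi <- at(tmax)
      out[q, ] <- c(psi, v_end, 1)
    } else {
      lo <- 0; hi <- tmax
      v_hit <- v_end; psi <- at(tmax)
      for (it in 1:100) {
        mid <- (lo + hi) / 2
        v <- fn(at(mid))
        if (abs(v - level) <= tol) { psi <- at(mid); v_hit <- v; break }
        if (v > level) lo <- mid else hi <- mid
        psi <- at(mid); v_hit <- v
      }
      out[q, ] <- c(psi, v_hit, 0)
    }
    if (!is.null(record_omega)) {
      omg <- rbind(omg, record_omega())
    }
  }
  if (!is.null(omg)) attr(out, "omega") <- omg
  out
}
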