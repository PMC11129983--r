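#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy fitted objects
#'
#' broom-style accessors. `tidy()` returns the per-term (or per-node) tibble
#' of a fitted object; `glance()` a one-row model summary.
#'
#' @param x A `growth_fit`, `likelihood_grid`, `profile_curve`,
#'   `profile_surface` or `coverage_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.growth_fit
#' @method tidy likelihood_grid
#' @export
tidy.likelihood_grid <- function(x, ...) {
  tibble::tibble(term = names(x$mle), estimate = unname(x$mle))
}

#' Model-level summaries
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_params = length(x$par),
    n_obs = nrow(x$data),
    sigma = x$sigma,
    converged = x$convergence == 0L,
    n_starts = x$n_starts
  )
}

#' @rdname glance.growth_fit
#' @method glance likelihood_grid
#' @export
glance.likelihood_grid <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik_max_raw,
    n_params = length(x$axes),
    n_nodes = length(x$values),
    n_obs = nrow(x$data),
    sigma = x$sigma %||% NA_real_
  )
}
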