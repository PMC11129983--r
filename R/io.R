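#' Read and write growth datasets
#'
#' Datasets are plain CSV with header `time,observation`. Reading validates
#' the columns and ordering; errors name the file and the missing field.
#'
#' @param path Path to a CSV file.
#' @return A tibble with numeric columns `time` and `observation`.
#' @export
read_growth_data <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("dataset file not found: '%s'", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("time", "observation")) {
    if (!col %in% names(df)) {
      rlang::abort(sprintf("'%s' is missing the '%s' column", path, col))
    }
  }
  validate_dataset(tibble::as_tibble(df[, c("time", "observation")]))
}

#' @rdname read_growth_data
#' @param data A data frame with columns `time` and `observation`.
#' @export
write_growth_data <- function(data, path) {
  data <- validate_dataset(data)
  # %.17g keeps doubles bit-exact through a read/write round trip
  out <- data.frame(time = sprintf("%.17g", data$time),
                    observation = sprintf("%.17g", data$observation))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration for the pipeline commands
#'
#' A run configuration is a named list (read from JSON or YAML by file
#' extension) declaring: `model` (name), `fixed` (named values), `dataset`
#' (CSV path) or `simulate` (list: `params`, `times` or `time_from`/
#' `time_to`/`time_n`, `sigma`, `seed`), `sigma`, `bounds` (named list of
#' 2-vectors), `grid_resolution`, `level`, `profile_n`, `contour_points`,
#' `prediction_times` (`from`, `to`, `n`), `coverage` (`n_reps`, `df`,
#' `starts`), `seed`, and `output_dir`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("config file not found: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    rlang::abort(sprintf("'%s': unsupported config format '%s' (use JSON or YAML)",
                         path, ext))
  )
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  cfg <- as.list(cfg)
  if (is.null(cfg$model)) rlang::abort("config field 'model' is required")
  model <- growth_model(cfg$model, fixed = as.list(cfg$fixed))
  if (!is.null(cfg$level)) {
    if (cfg$level <= 0 || cfg$level >= 1) {
      rlang::abort("config field 'level' must be in (0, 1)")
    }
  }
  if (!is.null(cfg$bounds)) {
    cfg$bounds <- purrr::map(cfg$bounds, as.numeric)
    bad <- setdiff(names(cfg$bounds), c(model$param_names, "sigma"))
    if (length(bad)) {
      rlang::abort(sprintf("config bounds name unknown parameter(s): %s",
                           paste(bad, collapse = ", ")))
    }
  }
  cfg$.model <- model
  structure(cfg, class = "run_config")
}

config_dataset <- function(cfg) {
  if (!is.null(cfg$dataset)) {
    read_growth_data(cfg$dataset)
  } else if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    times <- if (!is.null(s$times)) as.numeric(s$times) else {
      seq(s$time_from %||% 0, s$time_to, length.out = s$time_n)
    }
    simulate_growth_data(cfg$.model, s$params, times, s$sigma,
                         seed = s$seed %||% cfg$seed)
  } else {
    rlang::abort("config must declare either 'dataset' (CSV path) or 'simulate'")
  }
}

config_provenance <- function(cfg) {
  clean <- cfg[setdiff(names(cfg), ".model")]
  list(config_hash = rlang::hash(clean), seed = cfg$seed)
}

out_path <- function(cfg, file) {
  dir <- cfg$output_dir %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file.path(dir, file)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

## ---- pipeline commands ---------------------------------------------------

#' Pipeline commands
#'
#' Config-driven entry points tying the modules together; each writes its
#' artifacts (CSV + JSON with config hash and seed for provenance) into the
#' config's `output_dir` and returns its result invisibly. Re-running a
#' command with the same config reproduces the outputs bit-identically.
#'
#' * `pwa_fit()`: MLE by grid (`mode = "grid"`) or optimizer, JSON report with
#'   the estimates and normalized-likelihood diagnostics.
#' * `pwa_profile()`: all univariate and all pairwise bivariate profiles, one
#'   CSV each plus a JSON summary of MLE, confidence intervals, truncation
#'   flags and thresholds.
#' * `pwa_predict()`: bivariate profile-wise envelopes, their union, and the
#'   full-likelihood envelope; one CSV per envelope plus a JSON sidecar.
#' * `pwa_coverage()`: the empirical coverage experiment; one-row CSV plus
#'   JSON with the design.
#' * `pwa_simulate()`: writes a simulated dataset CSV with a JSON design
#'   sidecar.
#'
#' @param cfg A `run_config` (see [read_run_config()]) or path to one.
#' @param mode For `pwa_fit`: `"optimize"` (default) or `"grid"`.
#' @param strategy For `pwa_predict`: `"grid"` propagates all retained mesh
#'   nodes of each bivariate profile (and filters the full grid for the
#'   gold-standard envelope); `"contour"` samples threshold-contour points by
#'   nested optimization and uses rejection sampling for the full-likelihood
#'   envelope.
#' @return The fitted object / list of artifacts, invisibly.
#' @name pipeline
NULL

as_run_config <- function(cfg) {
  if (inherits(cfg, "run_config")) return(cfg)
  if (is.list(cfg)) return(validate_run_config(cfg))
  read_run_config(cfg)
}

#' @rdname pipeline
#' @export
pwa_fit <- function(cfg, mode = c("optimize", "grid")) {
  cfg <- as_run_config(cfg)
  mode <- match.arg(mode)
  data <- config_dataset(cfg)
  model <- cfg$.model
  if (mode == "grid") {
    box <- do.call(parameter_box,
                   c(cfg$bounds[model$free_params],
                     list(resolution = cfg$grid_resolution %||% 101)))
    fit <- fit_mle_grid(data, model, box, sigma = cfg$sigma)
    est <- as.list(fit$mle)
    ll <- fit$loglik_max_raw
  } else {
    fit <- fit_mle(data, model, cfg$bounds[model$free_params],
                   sigma = cfg$sigma, seed = cfg$seed)
    est <- as.list(fit$par)
    ll <- fit$loglik
  }
  report <- c(list(mode = mode, model = model$name, estimates = est,
                   loglik = ll, n_obs = nrow(data)),
              config_provenance(cfg))
  write_json_report(report, out_path(cfg, "fit.json"))
  invisible(fit)
}

#' @rdname pipeline
#' @export
pwa_profile <- function(cfg) {
  cfg <- as_run_config(cfg)
  data <- config_dataset(cfg)
  model <- cfg$.model
  bounds <- cfg$bounds[model$free_params]
  level <- cfg$level %||% 0.95
  fit <- fit_mle(data, model, bounds, sigma = cfg$sigma, seed = cfg$seed)
  n_psi <- cfg$profile_n %||% 100
  free <- model$free_params
  summaries <- list()
  for (p in free) {
    pr <- profile_likelihood(data, model, p, bounds, sigma = cfg$sigma,
                             n_psi = n_psi, fit = fit, level = level)
    utils::write.csv(pr$profile, out_path(cfg, paste0("profile_", p, ".csv")),
                     row.names = FALSE)
    summaries[[p]] <- as.list(ci_from_profile(pr))
  }
  pairs <- utils::combn(free, 2, simplify = FALSE)
  for (pp in pairs) {
    pr <- profile_likelihood(data, model, pp, bounds, sigma = cfg$sigma,
                             n_psi = cfg$profile_n_bivariate %||% 30,
                             fit = fit, level = level)
    utils::write.csv(pr$profile,
                     out_path(cfg, paste0("profile_", pp[1], "_", pp[2], ".csv")),
                     row.names = FALSE)
  }
  report <- c(list(mle = as.list(fit$par), loglik = fit$loglik,
                   thresholds = list(univariate = chisq_threshold(1, level),
                                     bivariate = chisq_threshold(2, level)),
                   level = level, intervals = summaries),
              config_provenance(cfg))
  write_json_report(report, out_path(cfg, "profiles.json"))
  invisible(report)
}

#' @rdname pipeline
#' @export
pwa_predict <- function(cfg, strategy = c("grid", "contour")) {
  cfg <- as_run_config(cfg)
  strategy <- match.arg(strategy)
  data <- config_dataset(cfg)
  model <- cfg$.model
  bounds <- cfg$bounds[model$free_params]
  level <- cfg$level %||% 0.95
  free <- model$free_params
  pt <- cfg$prediction_times
  times <- if (!is.null(pt)) seq(pt$from %||% 0, pt$to, length.out = pt$n %||% 201)
           else default_time_grid(data)
  thr2 <- chisq_threshold(2, level)
  thr_full <- chisq_threshold(length(free), level)
  pairs <- utils::combn(free, 2, simplify = FALSE)
  envs <- list()

  if (strategy == "grid") {
    box <- do.call(parameter_box,
                   c(bounds, list(resolution = cfg$grid_resolution %||% 101)))
    grid <- fit_mle_grid(data, model, box, sigma = cfg$sigma)
    for (pp in pairs) {
      surf <- profile_grid(grid, pp, level = level)
      envs[[paste(pp, collapse = "_")]] <-
        envelope_from_profile(surf, model, thr2, times)
    }
    full <- envelope_from_grid(grid, thr_full, times)
  } else {
    fit <- fit_mle(data, model, bounds, sigma = cfg$sigma, seed = cfg$seed)
    for (pp in pairs) {
      cs <- sample_contour(data, level = thr2,
                           n_points = cfg$contour_points %||% 500,
                           seed = cfg$seed, model = model, interest = pp,
                           bounds = bounds, sigma = cfg$sigma, fit = fit)
      envs[[paste(pp, collapse = "_")]] <-
        envelope_from_profile(cs, model, times = times, boundary_only = TRUE)
    }
    full <- envelope_by_rejection(data, model, bounds, sigma = cfg$sigma,
                                  threshold = thr_full,
                                  n_accept = cfg$n_accept %||% 5000,
                                  seed = cfg$seed, times = times, fit = fit)
  }
  uni <- envelope_union(envs)
  all_envs <- c(envs, list(union = uni, full = full))
  for (nm in names(all_envs)) {
    e <- all_envs[[nm]]
    utils::write.csv(as.data.frame(e)[, c("time", "lower", "mle", "upper")],
                     out_path(cfg, paste0("envelope_", nm, ".csv")),
                     row.names = FALSE)
    write_json_report(
      c(list(source = attr(e, "source"), n_curves = attr(e, "n_curves"),
             threshold = attr(e, "threshold")), config_provenance(cfg)),
      out_path(cfg, paste0("envelope_", nm, ".json")))
  }
  invisible(all_envs)
}

#' @rdname pipeline
#' @export
pwa_coverage <- function(cfg) {
  cfg <- as_run_config(cfg)
  model <- cfg$.model
  cov <- cfg$coverage %||% list()
  s <- cfg$simulate
  if (is.null(s)) rlang::abort("coverage config needs a 'simulate' block (truth + design)")
  times <- if (!is.null(s$times)) as.numeric(s$times) else {
    seq(s$time_from %||% 0, s$time_to, length.out = s$time_n)
  }
  res <- run_coverage(model, s$params, times, s$sigma,
                      bounds = cfg$bounds[model$free_params],
                      n_reps = cov$n_reps %||% 5000,
                      df = cov$df, level = cfg$level %||% 0.95,
                      seed = cfg$seed, starts = cov$starts %||% 4)
  utils::write.csv(glance(res), out_path(cfg, "coverage.csv"),
                   row.names = FALSE)
  write_json_report(
    c(glance(res), list(true_params = as.list(res$true_params),
                        model = model$name, times = times, sigma = s$sigma),
      config_provenance(cfg)),
    out_path(cfg, "coverage.json"))
  invisible(res)
}

#' @rdname pipeline
#' @export
pwa_simulate <- function(cfg) {
  cfg <- as_run_config(cfg)
  data <- config_dataset(cfg)
  write_growth_data(data, out_path(cfg, "dataset.csv"))
  write_json_report(c(attr(data, "design"), config_provenance(cfg)),
                    out_path(cfg, "dataset.json"))
  invisible(data)
}
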