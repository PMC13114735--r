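#' Forward model for the cumulative-adoption observable
#'
#' Spatially homogeneous reduction of the rumor model augmented with the
#' cumulative-adoption equation \eqn{dN/dt = \beta S I^2}: with flat
#' initial data and zero-flux boundaries the diffusion terms vanish
#' identically, leaving four ODEs
#' \deqn{dS = rS(1-S/K) - \beta SI^2 - \mu_1 S,\quad
#'       dI = \beta SI^2 - (\mu_2+\alpha) I,}
#' \deqn{dR = \alpha I - \mu_3 R,\quad dN = \beta SI^2,}
#' integrated by explicit Euler from t = 0 and read off at the requested
#' grid times by linear interpolation.  N is non-decreasing by
#' construction.
#'
#' @param params a [model_params] (diffusion rates are ignored).
#' @param init numeric vector `c(S0, I0, R0, N0)`, non-negative.
#' @param t_grid increasing non-negative output times.
#' @param dt Euler step.
#' @param alpha_switch optional list `list(t = t_switch, alpha = alpha_new)`
#'   replacing the recovery rate from `t_switch` onward (used by
#'   [intervention_run]).
#' @return Data frame with columns `time`, `S`, `I`, `R`, `N`.
#' @export
forward_model <- function(params, init = c(1, 0.1, 0.1, 0.002),
                          t_grid = 1:54, dt = 0.05, alpha_switch = NULL) {
  p <- as_model_params(params)
  if (length(init) != 4L || any(init < 0))
    stop("init must be four non-negative numbers (S0, I0, R0, N0)",
         call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE) || any(t_grid < 0))
    stop("t_grid must be strictly increasing and non-negative",
         call. = FALSE)
  t_sw <- if (is.null(alpha_switch)) Inf else alpha_switch$t
  a_new <- if (is.null(alpha_switch)) p$alpha else alpha_switch$alpha
  if (a_new <= 0) stop("switched alpha must be positive", call. = FALSE)
  out <- .adoption_core(unlist(unclass(p))[1:7], as.numeric(init),
                        as.numeric(t_grid), dt, t_sw, a_new)
  data.frame(time = t_grid, S = out[, 1L], I = out[, 2L],
             R = out[, 3L], N = out[, 4L])
}

#' Observed cumulative-participation series
#'
#' @param times strictly increasing observation times (days).
#' @param values cumulative participation fractions (raw data may jitter;
#'   monotonicity is not enforced).
#' @return An `observed_series` object.
#' @export
observed_series <- function(times, values) {
  if (length(times) != length(values) || !length(times))
    stop("times and values must be non-empty and of equal length",
         call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "observed_series")
}

#' Synthetic noisy cumulative-adoption series
#'
#' Emulates a pre-aggregated national participation curve: the forward
#' model's N(t), plus i.i.d. Gaussian observation noise, clipped at 0.
#' Defaults emulate the study window: daily observations over 54 days,
#' initial state (1, 0.1, 0.1, 0.002), noise sd 0.005.
#'
#' @inheritParams forward_model
#' @param noise_sd observation-noise standard deviation.
#' @param seed integer seed.
#' @return An `observed_series`.
#' @export
synthetic_series <- function(params, init = c(1, 0.1, 0.1, 0.002),
                             t_grid = 1:54, noise_sd = 0.005, seed = 1L,
                             dt = 0.05) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  fm <- forward_model(params, init, t_grid, dt)
  noise <- if (noise_sd > 0)
    with_seed(seed, rnorm(length(t_grid), 0, noise_sd)) else 0
  observed_series(t_grid, pmax(0, fm$N + noise))
}

#' RMSE and MAPE of a model series against observations
#'
#' `mape` excludes zero observations (undefined relative error); the count
#' of exclusions is returned as `n_zero_excluded`.
#'
#' @param series an `observed_series`.
#' @param model_values model predictions at `series$times`.
#' @return A list: `rmse`, `mape` (percent), `n_zero_excluded`.
#' @export
score_series <- function(series, model_values) {
  obs <- series$values
  if (length(model_values) != length(obs))
    stop("model_values length does not match the series", call. = FALSE)
  err <- obs - model_values
  nz <- obs != 0
  if (!any(nz)) stop("MAPE undefined: all observations are zero",
                     call. = FALSE)
  list(rmse = sqrt(mean(err^2)),
       mape = 100 * mean(abs(err[nz] / obs[nz])),
       n_zero_excluded = sum(!nz))
}

default_fit_config <- function() {
  list(initial_state = c(1, 0.1, 0.1, 0.002),
       lower = c(r = 0.1, K = 0.1, beta = 0.05, mu1 = 1e-4, mu2 = 1e-3,
                 mu3 = 1e-2, alpha = 1e-3),
       upper = c(r = 10, K = 2, beta = 2, mu1 = 1, mu2 = 1,
                 mu3 = 2, alpha = 1),
       guess = c(r = 2, K = 0.8, beta = 0.5, mu1 = 0.01, mu2 = 0.1,
                 mu3 = 0.3, alpha = 0.1),
       iterations = 2000L, step_scale = 0.05, seed = 1L, dt = 0.05)
}

#' Fit the cumulative-adoption model by random walk + least squares
#'
#' Greedy random-walk search over the seven kinetic parameters (diffusion
#' rates play no role in the homogeneous reduction): each iteration
#' proposes a multiplicative log-normal perturbation of the current best
#' vector (relative scale `step_scale`), clips it to the box bounds, and
#' accepts iff the sum of squared errors of the modeled N(t) against the
#' series decreases.  The objective trace is best-so-far, hence
#' non-increasing.  Deterministic under `seed`.
#'
#' @param series an `observed_series`.
#' @param config a list as returned by `default_fit_config()`; entries
#'   `guess`, `lower`, `upper` (named over r, K, beta, mu1, mu2, mu3,
#'   alpha), `initial_state`, `iterations`, `step_scale`, `seed`, `dt` may
#'   be overridden individually.
#' @return A `fit_result`: `params` ([model_params] with unit diffusion
#'   placeholders), `estimates` (the seven fitted values), `rmse`, `mape`,
#'   `sse_trace`, `accepted` count.
#' @export
fit_random_walk_ls <- function(series, config = list()) {
  cfg <- utils::modifyList(default_fit_config(), config)
  kin <- names(cfg$guess)
  stopifnot(identical(kin, c("r", "K", "beta", "mu1", "mu2", "mu3", "alpha")))
  if (cfg$iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  tgrid <- as.numeric(series$times)
  init4 <- as.numeric(cfg$initial_state)
  objective <- function(v) {
    out <- .adoption_core(v, init4, tgrid, cfg$dt, Inf, v[["alpha"]])
    sum((series$values - out[, 4L])^2)
  }
  best <- pmin(pmax(cfg$guess, cfg$lower), cfg$upper)
  best_sse <- objective(best)
  trace <- numeric(cfg$iterations)
  accepted <- 0L
  if (cfg$iterations > 0) with_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations)) {
      prop <- best * exp(rnorm(7L, 0, cfg$step_scale))
      prop <- pmin(pmax(prop, cfg$lower), cfg$upper)
      sse <- objective(prop)
      if (sse < best_sse) {
        best <- prop; best_sse <- sse; accepted <- accepted + 1L
      }
      trace[it] <- best_sse
    }
  })
  fm <- forward_model(model_params(r = best[["r"]], K = best[["K"]],
                                   beta = best[["beta"]], mu1 = best[["mu1"]],
                                   mu2 = best[["mu2"]], mu3 = best[["mu3"]],
                                   alpha = best[["alpha"]]),
                      cfg$initial_state, series$times, cfg$dt)
  sc <- score_series(series, fm$N)
  structure(list(estimates = best, sse = best_sse, sse_trace = trace,
                 rmse = sc$rmse, mape = sc$mape, accepted = accepted,
                 config = cfg, fitted = fm$N),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("random-walk least-squares fit\n")
  print(round(x$estimates, 5))
  cat(sprintf("  sse=%.5g rmse=%.5g mape=%.3f%% accepted=%d/%d\n",
              x$sse, x$rmse, x$mape, x$accepted, length(x$sse_trace)))
  invisible(x)
}

#' Recovery-rate intervention experiment
#'
#' Simulates debunking policy: the baseline keeps the recovery rate
#' \eqn{\alpha} throughout, the intervened run switches it to `alpha_new`
#' at `t_switch`.  Boosting recovery before the outbreak saturates lowers
#' the final cumulative adoption N.
#'
#' @inheritParams forward_model
#' @param t_switch intervention time.
#' @param alpha_new post-intervention recovery rate (> 0).
#' @return A list: `baseline` and `intervened` data frames (as from
#'   [forward_model]), `t_switch`, `alpha_new`.
#' @export
intervention_run <- function(params, init = c(1, 0.1, 0.1, 0.002),
                             t_grid = 1:54, t_switch = 30, alpha_new,
                             dt = 0.05) {
  if (alpha_new <= 0) stop("alpha_new must be positive", call. = FALSE)
  base <- forward_model(params, init, t_grid, dt)
  intv <- forward_model(params, init, t_grid, dt,
                        alpha_switch = list(t = t_switch, alpha = alpha_new))
  list(baseline = base, intervened = intv,
       t_switch = t_switch, alpha_new = alpha_new)
}

#' Read an observed series from a two-column CSV
#'
#' Columns are time and cumulative value; a non-numeric first row is
#' treated as a header and skipped.  Times must be strictly increasing.
#'
#' @param path CSV file path.
#' @return An `observed_series`.
#' @export
load_series_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected two columns (time, value)",
                           call. = FALSE)
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(raw[1L, 1L])))) start <- 2L
  tv <- suppressWarnings(apply(raw[start:nrow(raw), 1:2, drop = FALSE], 2,
                               as.numeric))
  tv <- matrix(tv, ncol = 2L)
  bad <- which(!stats::complete.cases(tv))
  if (length(bad))
    stop("non-numeric cell in row ", bad[1L] + start - 1L, call. = FALSE)
  if (anyDuplicated(tv[, 1L])) {
    d <- which(duplicated(tv[, 1L]))[1L]
    stop("duplicated time in row ", d + start - 1L, call. = FALSE)
  }
  if (is.unsorted(tv[, 1L], strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  observed_series(tv[, 1L], tv[, 2L])
}

#' Write an observed series to CSV
#' @param series an `observed_series`.
#' @param path output path.
#' @export
save_series_csv <- function(series, path) {
  utils::write.csv(data.frame(time = series$times, value = series$values),
                   path, row.names = FALSE)
  invisible(path)
}
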