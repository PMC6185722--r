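#' Root mean square error between observed and modeled curves
#'
#' @param observed,modeled Numeric vectors of equal, positive length.
#' @return `sqrt(mean((observed - modeled)^2))`.
#' @export
rmse <- function(observed, modeled) {
  if (length(observed) == 0 || length(observed) != length(modeled))
    stop("observed and modeled must have equal length >= 1", call. = FALSE)
  sqrt(mean((observed - modeled)^2))
}

#' Fit configuration for the inverse estimation
#'
#' @param restarts Number of additional deterministic restarts from
#'   perturbed starting points (default 2).
#' @param reltol Relative convergence tolerance on the objective
#'   (default 1e-10).
#' @param maxit Maximum simplex iterations per start (default 2000).
#' @param fd_step Relative finite-difference step for the sensitivity
#'   matrix (default 1e-5).
#' @param var_pooling `"pooled"` (default) replaces the per-day variances
#'   by their mean when weighting the Fisher Information Matrix —
#'   appropriate when measurement noise is homoscedastic, and far more
#'   stable than inverse per-day variances estimated from few replicates;
#'   `"pointwise"` uses the per-day values as given.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(restarts = 2, reltol = 1e-10, maxit = 2000,
                       fd_step = 1e-5, var_pooling = c("pooled", "pointwise")) {
  structure(list(restarts = restarts, reltol = reltol, maxit = maxit,
                 fd_step = fd_step, var_pooling = match.arg(var_pooling)),
            class = "fit_config")
}

# deterministic perturbed starts around (k0, eta0), used for restarts
fit_starts <- function(init, n_extra) {
  starts <- list(c(init$k, init$eta))
  perturb <- list(c(1.8, 0.08), c(0.5, -0.10), c(1.3, -0.05), c(0.7, 0.05))
  for (i in seq_len(n_extra)) {
    p <- perturb[[(i - 1) %% length(perturb) + 1]]
    starts[[i + 1]] <- c(init$k * p[1],
                         min(max(init$eta + p[2], 0.02), 0.98))
  }
  starts
}

#' Estimate (k, eta) from an incubation curve by inverse modeling
#'
#' Minimizes the unweighted RMSE between the observed mean cumulative
#' mineralization and the forward model [cumulative_mineralization] using
#' the Nelder-Mead simplex. The search runs on transformed coordinates
#' (`log k`, `logit eta`), which enforces `k > 0` and `eta` in `(0, 1)`
#' without explicit constraints. Several deterministic starting points
#' are tried; the lowest RMSE wins, with ties broken toward the lower
#' `k`.
#'
#' @param curve An [incubation_curve] with at least 3 observations.
#' @param soil A [soil_context] giving the BAT factor.
#' @param init Starting [turnover_params] (default `k = 0.3, eta = 0.8`).
#' @param config A [fit_config].
#' @return A list of class `"fit_result"`: `params` ([turnover_params]),
#'   `rmse`, `n_obs`, `converged`, `objective_evaluations`, plus the
#'   curve/soil labels.
#' @export
fit_parameters <- function(curve, soil = soil_context(),
                           init = turnover_params(0.3, 0.8),
                           config = fit_config()) {
  if (length(curve$times) < 3)
    stop("need at least 3 observations to fit two parameters", call. = FALSE)
  if (all(abs(curve$values) < 1e-12))
    stop("unidentifiable: curve is identically zero", call. = FALSE)
  obs <- curve$values
  times <- curve$times
  obj <- function(theta) {
    p <- list(k = exp(theta[1]), eta = stats::plogis(theta[2]))
    rmse(obs, (1 - p$eta) * (1 - exp(-p$k * soil$bat_factor * times)))
  }
  best <- NULL; best_k <- Inf; evals <- 0L
  for (s in fit_starts(init, config$restarts)) {
    o <- stats::optim(c(log(s[1]), stats::qlogis(s[2])), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = config$reltol,
                                     maxit = config$maxit))
    evals <- evals + o$counts[["function"]]
    k_o <- exp(o$par[1])
    better <- is.null(best) || o$value < best$value - 1e-15 ||
      (abs(o$value - best$value) <= 1e-15 && k_o < best_k)
    if (better) { best <- o; best_k <- k_o }
  }
  params <- turnover_params(k = exp(best$par[1]),
                            eta = stats::plogis(best$par[2]))
  structure(list(params = params, rmse = best$value,
                 n_obs = length(times), converged = best$convergence == 0,
                 objective_evaluations = evals,
                 bgr_id = curve$bgr_id, soil_id = curve$soil_id),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit %s / %s: k = %.4f, eta = %.4f, RMSE = %.5f (n = %d, %s)\n",
              x$bgr_id, x$soil_id, x$params$k, x$params$eta, x$rmse, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# sensitivity matrix dm(t_i)/d(k, eta) by central finite differences
model_jacobian <- function(k, eta, times, bat_factor, rel_step = 1e-5) {
  m <- function(k_, eta_) (1 - eta_) * (1 - exp(-k_ * bat_factor * times))
  hk <- rel_step * k
  he <- rel_step * max(eta, rel_step)
  cbind(k = (m(k + hk, eta) - m(k - hk, eta)) / (2 * hk),
        eta = (m(k, eta + he) - m(k, eta - he)) / (2 * he))
}

#' Parameter uncertainty from the Fisher Information Matrix
#'
#' Approximates the covariance of the fitted parameters from the local
#' sensitivity of the model output and the variance of the measured
#' cumulative mineralization at each observation day:
#' `FIM = J' diag(1/sigma_i^2) J`, `cov = FIM^-1`, with `J` the matrix of
#' central finite-difference sensitivities `dm(t_i)/d(k, eta)`.
#'
#' The curve stores the replicate sample variance at each day; since the
#' fitted quantity is the replicate mean, the weights use the variance of
#' the mean, `sigma_i^2 = variance_i / n_rep`. With the default
#' `var_pooling = "pooled"` the per-day variances are averaged first (see
#' [fit_config]).
#'
#' @param fit A converged [fit_parameters] result.
#' @param curve The [incubation_curve] that was fitted, with positive
#'   variances and a known `n_rep`.
#' @param soil The [soil_context] used in the fit.
#' @param config A [fit_config].
#' @return The fitted [turnover_params] completed with `sd_k`, `sd_eta`
#'   and `cov_k_eta`.
#' @export
fim_uncertainty <- function(fit, curve, soil = soil_context(),
                            config = fit_config()) {
  if (!fit$converged)
    stop("uncertainty requires a converged fit", call. = FALSE)
  v <- curve$variances
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all observation variances must be positive", call. = FALSE)
  n_rep <- curve$n_rep
  if (is.na(n_rep) || n_rep < 1) n_rep <- 1L
  if (config$var_pooling == "pooled") v <- rep(mean(v), length(v))
  sigma2 <- v / n_rep
  J <- model_jacobian(fit$params$k, fit$params$eta, curve$times,
                      soil$bat_factor, rel_step = config$fd_step)
  FIM <- t(J) %*% (J / sigma2)
  ev <- eigen(FIM, symmetric = TRUE)
  if (min(ev$values) <= max(ev$values) * 1e-12) {
    dir <- ev$vectors[, which.min(ev$values)]
    stop(sprintf(
      "unidentifiable: singular information matrix; ill-determined direction (%.3f k, %.3f eta)",
      dir[1], dir[2]), call. = FALSE)
  }
  cv <- solve(FIM)
  turnover_params(k = fit$params$k, eta = fit$params$eta,
                  sd_k = sqrt(cv[1, 1]), sd_eta = sqrt(cv[2, 2]),
                  cov_k_eta = cv[1, 2])
}

#' Pool per-soil parameter estimates for one BGR
#'
#' Under the model the turnover parameters depend only on the FOM type,
#' not the soil (soil enters through BAT), so per-soil fits of the same
#' BGR are averaged: arithmetic mean of `k` and of `eta`; the pooled
#' standard deviation is `sqrt(mean(sd^2)) / sqrt(n)` (the sd of the mean
#' under independent per-soil estimates of a common parameter).
#'
#' @param fits A non-empty list of [turnover_params] (or `fit_result`
#'   objects, whose `params` are taken).
#' @return A pooled [turnover_params].
#' @export
pool_across_soils <- function(fits) {
  if (length(fits) == 0) stop("no fits to pool", call. = FALSE)
  ps <- lapply(fits, function(f) if (inherits(f, "fit_result")) f$params else f)
  k <- vapply(ps, function(p) p$k, numeric(1))
  eta <- vapply(ps, function(p) p$eta, numeric(1))
  sdk <- vapply(ps, function(p) p$sd_k, numeric(1))
  sde <- vapply(ps, function(p) p$sd_eta, numeric(1))
  n <- length(ps)
  pool_sd <- function(s) if (any(is.na(s))) NA_real_ else sqrt(mean(s^2)) / sqrt(n)
  turnover_params(k = mean(k), eta = mean(eta),
                  sd_k = pool_sd(sdk), sd_eta = pool_sd(sde))
}

#' Fit all prepared curves and pool per BGR
#'
#' Convenience driver: fits every curve from [prepare_incubation], adds
#' FIM uncertainties, and pools the per-soil results per BGR.
#'
#' @param curves Named list of [incubation_curve] objects (names
#'   `bgr:soil`).
#' @param soils Named list of [soil_context] objects keyed by soil id;
#'   missing soils get `bat_factor = 1`.
#' @param init,config Passed to [fit_parameters].
#' @return A list with `fits` (per curve) and `pooled` (data.frame:
#'   `bgr, k, sd_k, eta, sd_eta, rmse, n_soils`).
#' @export
fit_all_curves <- function(curves, soils = list(),
                           init = turnover_params(0.3, 0.8),
                           config = fit_config()) {
  fits <- lapply(curves, function(cu) {
    soil <- soils[[cu$soil_id]]
    if (is.null(soil)) soil <- soil_context(cu$soil_id)
    f <- fit_parameters(cu, soil, init = init, config = config)
    f$params <- fim_uncertainty(f, cu, soil, config = config)
    f
  })
  bgrs <- vapply(fits, function(f) f$bgr_id, character(1))
  pooled <- do.call(rbind, lapply(unique(bgrs), function(b) {
    fb <- fits[bgrs == b]
    p <- pool_across_soils(fb)
    data.frame(bgr = b, k = p$k, sd_k = p$sd_k, eta = p$eta,
               sd_eta = p$sd_eta,
               rmse = mean(vapply(fb, function(f) f$rmse, numeric(1))),
               n_soils = length(fb))
  }))
  rownames(pooled) <- NULL
  list(fits = fits, pooled = pooled)
}
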