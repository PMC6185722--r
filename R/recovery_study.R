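#' Monte-Carlo recovery and coverage study for the inverse estimation
#'
#' Calibration check of the estimator and its Fisher-information
#' uncertainties under the error model they assume: for each replicate
#' experiment, true parameters are drawn, replicate cumulative
#' mineralization curves on the standard schedule receive iid Gaussian
#' measurement noise at every observation day, replicates are aggregated
#' (mean + sample variance), the curve is truncated to the daily window
#' and refitted, and the FIM interval is checked against the truth.
#'
#' The control-subtraction step is deliberately not part of this study:
#' the polynomial control fit contributes an error that is smooth and
#' therefore correlated across observation days, which the pointwise
#' FIM formula cannot represent (see the methods vignette); its effect
#' is exercised by the preprocessing tests instead.
#'
#' @param n Number of Monte-Carlo replicates (default 200).
#' @param k_range,eta_range Uniform sampling ranges of the true
#'   parameters.
#' @param noise_sd Measurement noise sd per cumulative observation
#'   (fraction of added C; default 0.005).
#' @param replicates Jars per experiment (default 4).
#' @param schedule Observation days (default: the standard incubation
#'   schedule).
#' @param max_day Truncation window (default 20).
#' @param seed Integer seed.
#' @param config A [fit_config].
#' @return A data.frame with one row per replicate: `k_true`,
#'   `eta_true`, `k_hat`, `eta_hat`, `sd_k`, `sd_eta`, `rmse`,
#'   `covered_k`, `covered_eta`.
#' @export
parameter_recovery_study <- function(n = 200,
                                     k_range = c(0.2, 0.7),
                                     eta_range = c(0.75, 0.92),
                                     noise_sd = 0.005,
                                     replicates = 4,
                                     schedule = INCUBATION_SCHEDULE,
                                     max_day = 20,
                                     seed = 1L,
                                     config = fit_config()) {
  set.seed(as.integer(seed))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- stats::runif(1, k_range[1], k_range[2])
    eta <- stats::runif(1, eta_range[1], eta_range[2])
    truth <- cumulative_mineralization(turnover_params(k, eta), schedule)
    nets <- lapply(seq_len(replicates), function(r) {
      noisy <- truth + stats::rnorm(length(schedule), 0, noise_sd)
      data.frame(day = schedule, net = diff(c(0, noisy)))
    })
    cu <- truncate_to_window(aggregate_replicates(nets), max_day)
    f <- fit_parameters(cu, config = config)
    u <- fim_uncertainty(f, cu, config = config)
    rows[[i]] <- data.frame(
      k_true = k, eta_true = eta, k_hat = u$k, eta_hat = u$eta,
      sd_k = u$sd_k, sd_eta = u$sd_eta, rmse = f$rmse,
      covered_k = abs(u$k - k) <= u$sd_k,
      covered_eta = abs(u$eta - eta) <= u$sd_eta)
  }
  do.call(rbind, rows)
}
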