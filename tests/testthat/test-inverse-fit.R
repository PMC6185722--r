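test_that("rmse matches hand computations", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(0.01, -0.01)), 0.01)
  expect_error(rmse(numeric(0), numeric(0)), "length")
})

test_that("noise-free curves are recovered to high precision", {
  cu <- noisefree_curve(0.42, 0.871)
  fit <- fit_parameters(cu)
  expect_true(fit$converged)
  expect_equal(fit$params$k, 0.42, tolerance = 1e-4)
  expect_equal(fit$params$eta, 0.871, tolerance = 1e-4)
  expect_lt(fit$rmse, 1e-7)
  # starting at the optimum returns the oracle RMSE
  fit2 <- fit_parameters(cu, init = turnover_params(0.42, 0.871))
  expect_equal(fit2$rmse,
               rmse(cu$values, cumulative_mineralization(fit2$params, cu$times)),
               tolerance = 1e-12)
})

test_that("fit is invariant to observation order and flags degenerate input", {
  cu <- noisefree_curve(0.3, 0.8)
  set.seed(9)
  noisy <- cu$values + rnorm(length(cu$values), 0, 0.003)
  ord <- sample(seq_along(cu$times))
  # objective is a symmetric mean over points: permuting cannot change it
  f1 <- fit_parameters(incubation_curve(cu$times, noisy, cu$variances, n_rep = 4))
  perm <- order(cu$times[ord])
  f2 <- fit_parameters(incubation_curve(cu$times[ord][perm], noisy[ord][perm],
                                        cu$variances[ord][perm], n_rep = 4))
  expect_equal(f1$params$k, f2$params$k, tolerance = 1e-8)
  flat <- incubation_curve(1:10, rep(0, 10), rep(1e-5, 10), n_rep = 4)
  expect_error(fit_parameters(flat), "unidentifiable")
})

test_that("FIM covariance scales linearly with the observation variances", {
  cu <- noisefree_curve(0.4, 0.85, variance = 4e-5)
  fit <- fit_parameters(cu)
  u1 <- fim_uncertainty(fit, cu)
  cu2 <- incubation_curve(cu$times, cu$values, cu$variances / 2, n_rep = cu$n_rep)
  u2 <- fim_uncertainty(fit, cu2)
  expect_equal(u2$sd_k, u1$sd_k / sqrt(2), tolerance = 1e-10)
  expect_equal(u2$sd_eta, u1$sd_eta / sqrt(2), tolerance = 1e-10)
})

test_that("FIM agrees with a brute-force likelihood curvature oracle", {
  # at a noise-free optimum the Hessian of the weighted least-squares
  # objective equals J' W J exactly, so a dense numerical Hessian is an
  # independent check of the sensitivity-based FIM
  cu <- noisefree_curve(0.35, 0.82, schedule = c(1:10, 12, 15, 20),
                        variance = 2e-5)
  fit <- fit_parameters(cu)
  u <- fim_uncertainty(fit, cu, config = fit_config(var_pooling = "pointwise"))
  nll <- function(k, eta) {
    m <- cumulative_mineralization(list(k = k, eta = eta), cu$times)
    0.5 * sum((cu$values - m)^2 / (cu$variances / cu$n_rep))
  }
  h <- 1e-5; k0 <- fit$params$k; e0 <- fit$params$eta
  H <- matrix(NA_real_, 2, 2)
  H[1, 1] <- (nll(k0 + h, e0) - 2 * nll(k0, e0) + nll(k0 - h, e0)) / h^2
  H[2, 2] <- (nll(k0, e0 + h) - 2 * nll(k0, e0) + nll(k0, e0 - h)) / h^2
  H[1, 2] <- H[2, 1] <- (nll(k0 + h, e0 + h) - nll(k0 + h, e0 - h) -
                           nll(k0 - h, e0 + h) + nll(k0 - h, e0 - h)) / (4 * h^2)
  cv <- solve(H)
  expect_equal(u$sd_k, sqrt(cv[1, 1]), tolerance = 1e-4)
  expect_equal(u$sd_eta, sqrt(cv[2, 2]), tolerance = 1e-4)
  expect_equal(u$cov_k_eta, cv[1, 2], tolerance = 1e-3)
})

test_that("singular information is reported as unidentifiable", {
  # eta = 1 gives a zero output curve: no sensitivity in any direction
  cu <- incubation_curve(1:10, rep(0, 10) + 1e-6, rep(1e-5, 10), n_rep = 4)
  fit <- structure(list(params = turnover_params(0.3, 1 - 1e-12),
                        converged = TRUE),
                   class = "fit_result")
  expect_error(fim_uncertainty(fit, cu), "ill-determined|singular")
})

test_that("pooling across soils averages parameters and shrinks sd", {
  a <- turnover_params(0.30, 0.80, sd_k = 0.02, sd_eta = 0.01)
  b <- turnover_params(0.40, 0.86, sd_k = 0.04, sd_eta = 0.01)
  p <- pool_across_soils(list(a, b))
  expect_equal(p$k, 0.35)
  expect_equal(p$eta, 0.83)
  expect_equal(p$sd_k, sqrt(mean(c(0.02, 0.04)^2)) / sqrt(2))
  single <- pool_across_soils(list(a))
  expect_equal(single$k, a$k)
  expect_equal(single$sd_k, a$sd_k)
  expect_error(pool_across_soils(list()), "no fits")
})

test_that("stochastic refits recover truth within the expected error", {
  # scaled-down version of the full recovery study (the acceptance test
  # runs 200 replicates); 40 replicates through the full pipeline
  set.seed(20)
  n <- 40
  errs <- t(sapply(seq_len(n), function(i) {
    k <- runif(1, 0.2, 0.7); eta <- runif(1, 0.75, 0.92)
    cu <- pipeline_curves(k, eta, noise_sd = 0.005, seed = 1000 + i)[["X:s"]]
    f <- fit_parameters(cu)
    c(dk = abs(f$params$k - k), de = abs(f$params$eta - eta), rmse = f$rmse)
  }))
  expect_lt(median(errs[, "dk"]), 0.02)
  expect_lt(median(errs[, "de"]), 0.01)
  expect_lt(median(errs[, "rmse"]), 0.01)
})

test_that("fit_all_curves pools per BGR over the two soils", {
  spec <- synthetic_spec(params = data.frame(bgr = c("A", "B"),
                                             k = c(0.3, 0.5),
                                             eta = c(0.8, 0.88)),
                         noise_sd = 0.003, seed = 42)
  curves <- prepare_incubation(generate_incubation(spec))
  out <- fit_all_curves(curves)
  expect_equal(nrow(out$pooled), 2)
  expect_equal(out$pooled$n_soils, c(2, 2))
  expect_equal(out$pooled$k, c(0.3, 0.5), tolerance = 0.05)
  expect_equal(out$pooled$eta, c(0.8, 0.88), tolerance = 0.02)
  expect_true(all(out$pooled$sd_k > 0))
})
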