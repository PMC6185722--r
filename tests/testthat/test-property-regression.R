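test_that("derived ratios follow the nitrogen bookkeeping", {
  props <- load_bgr_fixtures("properties")
  d <- derive_ratios(props[, setdiff(names(props), c("norg", "ct_nt", "ct_norg"))])
  expect_equal(d$norg[d$bgr == "D17"], 3.4)
  expect_equal(d$ct_norg[d$bgr == "D17"], 38.4 / 3.4, tolerance = 1e-12)
  expect_equal(round(d$ct_norg[d$bgr == "D61"], 1), 15.6)
  # nh4n = 0 collapses ct_norg onto ct_nt
  z <- derive_ratios(data.frame(ct = 40, nt = 5, nh4n = 0))
  expect_equal(z$ct_norg, z$ct_nt)
  expect_error(derive_ratios(data.frame(ct = 40, nt = 2, nh4n = 3)),
               "invalid chemistry")
})

test_that("simple regression matches a normal-equations oracle", {
  # exact line
  x <- c(1, 2, 3, 5, 8)
  r <- fit_simple_regression(x, 2 * x + 1)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  # random data vs closed-form normal equations
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    r <- fit_simple_regression(x, y)
    m <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    n <- mean(y) - m * mean(x)
    expect_equal(r$slope, m, tolerance = 1e-10)
    expect_equal(r$intercept, n, tolerance = 1e-10)
    expect_equal(r$r_squared, cor(x, y)^2, tolerance = 1e-10)
  }
  expect_error(fit_simple_regression(rep(1, 5), rnorm(5)), "singular")
})

test_that("R-squared is invariant under affine rescaling of x and y", {
  set.seed(13)
  x <- rnorm(10); y <- 0.5 * x + rnorm(10, 0, 0.3)
  r0 <- fit_simple_regression(x, y)$r_squared
  expect_equal(fit_simple_regression(3 * x - 7, y)$r_squared, r0,
               tolerance = 1e-12)
  expect_equal(fit_simple_regression(x, -2 * y + 11)$r_squared, r0,
               tolerance = 1e-12)
})

test_that("screening ranks predictors and matches a column-wise OLS oracle", {
  fx <- load_bgr_fixtures()
  screen <- screen_predictors(fx$properties, fx$parameters)
  top_k <- screen$predictor[screen$parameter == "k"][1]
  top_eta <- screen$predictor[screen$parameter == "eta"][1]
  expect_equal(top_k, "ph")
  expect_equal(top_eta, "ct_norg")
  # against brute-force per-column OLS
  for (i in seq_len(nrow(screen))) {
    x <- fx$properties[[screen$predictor[i]]]
    y <- fx$parameters[[screen$parameter[i]]]
    m <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(screen$slope[i], m, tolerance = 1e-10)
    expect_equal(screen$r_squared[i], cor(x, y)^2, tolerance = 1e-10)
  }
  # pure-noise response cannot produce a strong predictor
  set.seed(99)
  pn <- fx$parameters
  pn$k <- rnorm(6, 0.4, 0.001); pn$eta <- rnorm(6, 0.85, 0.001)
  sn <- screen_predictors(fx$properties, pn)
  expect_lt(max(sn$r_squared), 0.9)
})

test_that("model selection refuses collinear multiple regression", {
  fx <- load_bgr_fixtures()
  screen <- screen_predictors(fx$properties, fx$parameters)
  sel <- select_model(screen, fx$properties, fx$parameters)
  expect_false(sel$multiple_allowed)
  expect_equal(nrow(sel$collinearity), 1)
  expect_equal(round(abs(sel$collinearity$r), 2), 0.43)
  expect_setequal(c(sel$collinearity$predictor_1, sel$collinearity$predictor_2),
                  c("ph", "ct_norg"))
  # orthogonal synthetic predictors are allowed
  set.seed(4)
  props <- data.frame(bgr = sprintf("S%d", 1:8), ph = rep(c(7, 8), 4),
                      ct = 40, nh4n = 2, nt = 6)
  props <- derive_ratios(props)
  props$ct_norg <- rep(c(10, 14), each = 4)  # orthogonal to ph by design
  params <- data.frame(bgr = props$bgr,
                       k = 6 - 0.7 * props$ph + rnorm(8, 0, 0.01),
                       eta = 1.0 - 0.013 * props$ct_norg + rnorm(8, 0, 0.005))
  s2 <- screen_predictors(props, params, properties = c("ph", "ct_norg"))
  sel2 <- select_model(s2, props, params)
  expect_true(sel2$multiple_allowed)
})

test_that("parameter prediction evaluates the fitted equations with OLS errors", {
  fx <- load_bgr_fixtures()
  screen <- screen_predictors(fx$properties, fx$parameters)
  sel <- select_model(screen, fx$properties, fx$parameters)
  new <- derive_ratios(data.frame(bgr = "new", dm = 7, dm_org = 30, ph = 7.7,
                                  ct = 40, nh4n = 3, nt = 7))
  pr <- predict_parameters(new, sel$k_model, sel$eta_model)
  expect_equal(pr$k_star, sel$k_model$slope * 7.7 + sel$k_model$intercept,
               tolerance = 1e-12)
  expect_false(pr$extrapolation)
  # prediction sd is minimal at the calibration mean of the predictor
  km <- sel$k_model
  sd_at <- function(ph) {
    p <- derive_ratios(data.frame(ph = ph, ct = 40, nh4n = 3, nt = 7))
    p$ct_norg <- sel$eta_model$x_mean
    predict_parameters(p, km, sel$eta_model)$sd_k_star
  }
  expect_lt(sd_at(km$x_mean), sd_at(km$x_mean + 0.3))
  expect_lt(sd_at(km$x_mean), sd_at(km$x_mean - 0.3))
  # outside the calibration range -> flagged, not an error
  far <- derive_ratios(data.frame(ph = 9.2, ct = 40, nh4n = 3, nt = 7))
  expect_true(predict_parameters(far, km, sel$eta_model)$extrapolation)
})

test_that("round trip: parameters from inverted models are recovered exactly", {
  # generate properties whose k/eta lie exactly on the fitted lines;
  # refitting the regression on the predictions must return the models
  fx <- load_bgr_fixtures()
  screen <- screen_predictors(fx$properties, fx$parameters)
  sel <- select_model(screen, fx$properties, fx$parameters)
  pr <- predict_parameters(fx$properties, sel$k_model, sel$eta_model)
  refit_k <- fit_simple_regression(fx$properties$ph, pr$k_star)
  expect_equal(refit_k$slope, sel$k_model$slope, tolerance = 1e-10)
  expect_equal(refit_k$intercept, sel$k_model$intercept, tolerance = 1e-10)
  expect_equal(refit_k$r_squared, 1, tolerance = 1e-10)
})

test_that("range coverage is the spanned fraction of the reference range", {
  expect_equal(range_coverage(c(2, 7), 2, 7), 100)
  expect_equal(range_coverage(5, 0, 10), 0)
  expect_equal(range_coverage(c(10.0, 15.6), 5.9, 26.4), 100 * 5.6 / 20.5,
               tolerance = 1e-12)
  expect_error(range_coverage(c(1, 2), 3, 3), "reference range")
})
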