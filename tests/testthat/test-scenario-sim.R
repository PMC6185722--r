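test_that("BGR carbon input follows dose / N_t x C_t arithmetic", {
  expect_equal(bgr_carbon_input(list(nt = 6.3, ct = 38.4), 170),
               170 / 0.063 * 0.384 / 1000, tolerance = 1e-12)
  expect_equal(round(bgr_carbon_input(list(nt = 6.3, ct = 38.4), 170), 3), 1.036)
  expect_equal(bgr_carbon_input(list(nt = 6.3, ct = 38.4), 340),
               2 * bgr_carbon_input(list(nt = 6.3, ct = 38.4), 170))
  expect_equal(bgr_carbon_input(list(nt = 6.3, ct = 38.4), 0), 0)
  expect_error(bgr_carbon_input(list(nt = 0, ct = 38.4)), "nt")
})

test_that("step_year honors trivial limits", {
  site <- site_config()
  frozen <- pool_config(active_decay = 0, stab_return = 0)
  st0 <- pool_state(5, 25, 50)
  out <- step_year(st0, list(), site, frozen)
  expect_equal(out$state$active, 5)
  expect_equal(out$state$stabilized, 25)
  expect_equal(out$co2, 0)
  # eta = 0: decayed FOM goes entirely to CO2, active pool untouched
  out2 <- step_year(st0, list(list(carbon = 1, params = turnover_params(0.5, 0))),
                    site, frozen)
  decayed <- 1 - exp(-0.5 * site$bat_year)
  expect_equal(out2$co2, decayed, tolerance = 1e-9)
  expect_equal(out2$state$active, 5, tolerance = 1e-9)
})

test_that("annual carbon balance closes to 1e-9", {
  site <- site_config()
  pools <- pool_config()
  props <- load_bgr_fixtures("properties")[1, ]
  state <- pool_state(6, 26.4, 48.6)
  for (y in 1:20) {
    out <- step_year(state, list(list(carbon = bgr_carbon_input(props),
                                      params = turnover_params(0.36, 0.84))),
                     site, pools)
    expect_lt(abs(out$balance_error), 1e-9)
    state <- out$state
  }
})

test_that("annual closed-form step matches a daily sub-stepped oracle within 1%", {
  site <- site_config()
  pools <- pool_config()
  set.seed(31)
  for (i in 1:5) {
    state <- pool_state(runif(1, 3, 9), runif(1, 20, 30), 48.6)
    inputs <- list(list(carbon = runif(1, 0.5, 1.5),
                        params = turnover_params(runif(1, 0.25, 0.6),
                                                 runif(1, 0.78, 0.9))))
    a <- step_year(state, inputs, site, pools, method = "closed")
    b <- step_year(state, inputs, site, pools, method = "euler", n_sub = 2000)
    expect_equal(a$state$active, b$state$active, tolerance = 0.01)
    expect_equal(a$state$stabilized, b$state$stabilized, tolerance = 0.01)
    expect_equal(a$co2, b$co2, tolerance = 0.01)
  }
})

test_that("scenario trajectories behave physically", {
  site <- site_config()
  props <- load_bgr_fixtures("properties")[1, ]
  # zero inputs and zero rates: flat at the initial 2%
  flat <- run_scenario(site, management_plan(yield = 0, n_dose = 0), props,
                       turnover_params(0.36, 0.84), years = 10,
                       pools = pool_config(active_decay = 0, stab_return = 0),
                       variants = "mean")
  expect_equal(unique(flat$trajectory$corg_percent), 2)
  expect_equal(nrow(flat$trajectory), 11)
  # higher eta -> strictly higher final C_org
  lo <- run_scenario(site, management_plan(), props, turnover_params(0.36, 0.80),
                     years = 30, variants = "mean")
  hi <- run_scenario(site, management_plan(), props, turnover_params(0.36, 0.88),
                     years = 30, variants = "mean")
  expect_gt(hi$final[["mean"]], lo$final[["mean"]])
  # quasi-equilibrium: annual change shrinks after the initial transient
  tr <- run_scenario(site, management_plan(), props,
                     turnover_params(0.36, 0.84), years = 60,
                     variants = "mean")$trajectory
  steps <- abs(diff(tr$corg_percent))
  expect_true(all(diff(steps[10:59]) <= 1e-10))
})

test_that("treatment ranking follows eta x carbon input under full decay", {
  fx <- load_bgr_fixtures()
  site <- site_config()
  results <- lapply(seq_len(6), function(i) {
    run_scenario(site, management_plan(), fx$properties[i, ],
                 turnover_params(fx$parameters$k[i], fx$parameters$eta[i]),
                 years = 50, variants = "mean",
                 treatment = fx$parameters$bgr[i])
  })
  finals <- sapply(results, function(r) r$final[["mean"]])
  flux <- fx$parameters$eta *
    sapply(seq_len(6), function(i) bgr_carbon_input(fx$properties[i, ]))
  expect_equal(order(finals), order(flux))
  expect_gt(max(finals) - min(finals), 0)
})

test_that("treatment comparison matches an ANOVA decomposition oracle and groups sensibly", {
  make_res <- function(label, finals) {
    structure(list(treatment = label, final = finals,
                   final_mean = mean(finals), final_sd = sd(finals)),
              class = "scenario_result")
  }
  set.seed(17)
  finals <- lapply(1:4, function(i) rnorm(3, mean = 2 + 0.05 * i, sd = 0.02))
  res <- lapply(1:4, function(i) make_res(paste0("T", i), finals[[i]]))
  cmp <- compare_treatments(res)
  # brute-force sum-of-squares oracle
  y <- unlist(finals); g <- rep(1:4, each = 3)
  gm <- mean(y); means <- tapply(y, g, mean)
  ss_t <- sum(3 * (means - gm)^2)
  ss_e <- sum((y - means[g])^2)
  f_oracle <- (ss_t / 3) / (ss_e / 8)
  expect_equal(cmp$anova$f_value[1], f_oracle, tolerance = 1e-10)
  expect_equal(cmp$anova$sum_sq, c(ss_t, ss_e), tolerance = 1e-10)
  # identical treatments share one letter; far-apart treatments do not
  same <- lapply(1:3, function(i) make_res(paste0("S", i), c(1.99, 2.00, 2.01)))
  expect_equal(unique(compare_treatments(same)$groups$letters), "a")
  apart <- list(make_res("lo", c(1.0, 1.01, 0.99)),
                make_res("hi", c(2.0, 2.01, 1.99)))
  g2 <- compare_treatments(apart)$groups
  expect_false(g2$letters[1] == g2$letters[2])
  expect_error(compare_treatments(list(make_res("x", 1), make_res("y", 1))),
               "variance")
})
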